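#' Read a gene-by-sample expression matrix
#'
#' Reads an abundance matrix (FPKM or any comparable non-negative unit)
#' from delimited text or GCT. Delimited files must carry a header row of
#' sample identifiers, with gene identifiers in the first column. GCT
#' versions 1.2 and 1.3 are supported; the Description column and any
#' 1.3 row/column metadata are discarded.
#'
#' Gene identifiers are normalized to upper case (with a small built-in
#' legacy-alias map applied), and the matrix is validated: all values
#' must be finite and non-negative, and gene and sample identifiers must
#' be unique.
#'
#' @param path Path to the file.
#' @param format One of `"auto"` (default, by file extension), `"tsv"`,
#'   `"csv"` or `"gct"`.
#' @return A numeric matrix, genes in rows (upper-cased symbols as row
#'   names), samples in columns.
#' @seealso [write_expression()], [subset_hox_genes()]
#' @export
read_expression <- function(path, format = c("auto", "tsv", "csv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tsv = "tsv", txt = "tsv", csv = "csv", gct = "gct",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format= explicitly"))
  }
  if (format == "gct") return(.read_gct(path))
  sep <- if (format == "csv") "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           quote = "\"", comment.char = "", stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("malformed header: expected a gene-id column plus at least one sample column")
  .finish_expression(tab[[1L]], tab[-1L])
}

# Assemble, normalize and validate a matrix from an id column + value columns.
.finish_expression <- function(gene_ids, values) {
  for (j in seq_along(values)) {
    v <- values[[j]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad) > 0L)
        stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                     v[bad[1L]], gene_ids[bad[1L]], colnames(values)[j]))
      values[[j]] <- num
    }
  }
  m <- as.matrix(values)
  rownames(m) <- .normalize_gene_ids(gene_ids)
  .validate_expression(m)
  m
}

# GCT 1.2: "#1.2" / "<nrow>\t<ncol>" / header (Name, Description, samples).
# GCT 1.3: "#1.3" / "<nrow>\t<ncol>\t<nrowmeta>\t<ncolmeta>"; the first
# nrowmeta columns after id are row metadata and the first ncolmeta data
# lines are column metadata; both are dropped.
.read_gct <- function(path) {
  head2 <- readLines(path, n = 2L)
  if (length(head2) < 2L) stop("malformed GCT: fewer than 2 header lines")
  ver <- trimws(head2[1L])
  if (!ver %in% c("#1.2", "#1.3"))
    stop("malformed GCT: version line must be '#1.2' or '#1.3', got '", ver, "'")
  dims <- suppressWarnings(as.integer(strsplit(head2[2L], "\t", fixed = TRUE)[[1L]]))
  need <- if (ver == "#1.2") 2L else 4L
  if (length(dims) < need || anyNA(dims[seq_len(need)]))
    stop("malformed GCT: dimensions line must carry ", need, " integers")
  nr <- dims[1L]; nc <- dims[2L]
  n_rowmeta <- if (ver == "#1.3") dims[3L] else 1L  # 1.2: the Description column
  n_colmeta <- if (ver == "#1.3") dims[4L] else 0L
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 2L,
                           check.names = FALSE, quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  if (n_colmeta > 0L) tab <- tab[-seq_len(n_colmeta), , drop = FALSE]
  if (nrow(tab) != nr)
    stop(sprintf("malformed GCT: expected %d data rows, found %d", nr, nrow(tab)))
  value_cols <- seq.int(2L + n_rowmeta, length.out = nc)
  if (max(value_cols) > ncol(tab))
    stop(sprintf("malformed GCT: expected %d sample columns, found %d",
                 nc, ncol(tab) - 1L - n_rowmeta))
  vals <- tab[value_cols]
  vals[] <- lapply(vals, function(v) if (is.character(v)) suppressWarnings(.chk_num(v)) else v)
  .finish_expression(tab[[1L]], vals)
}

.chk_num <- function(v) {
  out <- as.numeric(v)
  if (any(is.na(out) & !is.na(v))) return(v)  # leave for error reporting
  out
}

#' Write an expression matrix to TSV, CSV or GCT
#'
#' Values are rendered with full double precision (`%.17g`), so a
#' write/read round trip reproduces the matrix exactly.
#'
#' @param m Numeric genes-by-samples matrix with dimnames.
#' @param path Output path.
#' @param format `"tsv"`, `"csv"` or `"gct"` (GCT 1.2).
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, format = c("tsv", "csv", "gct")) {
  format <- match.arg(format)
  .validate_expression(m)
  if (format == "gct") {
    lines <- c("#1.2",
               paste(nrow(m), ncol(m), sep = "\t"),
               paste(c("Name", "Description", colnames(m)), collapse = "\t"),
               vapply(seq_len(nrow(m)), function(i)
                 paste(c(rownames(m)[i], "na", sprintf("%.17g", m[i, ])),
                       collapse = "\t"), ""))
    writeLines(lines, path)
  } else {
    sep <- if (format == "csv") "," else "\t"
    lines <- c(paste(c("gene_id", colnames(m)), collapse = sep),
               vapply(seq_len(nrow(m)), function(i)
                 paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])),
                       collapse = sep), ""))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects a two-column delimited file with a header: sample identifier,
#' then tissue/group label (for example `"prostate"`, `"AdPCa"`,
#' `"NEPCa"`).
#'
#' @param path Path to a TSV (or CSV, by extension) file.
#' @return A data.frame with columns `sample_id` and `label`.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           quote = "\"", comment.char = "", stringsAsFactors = FALSE,
                           colClasses = "character")
  .as_metadata(tab)
}

#' Write a labelled numeric table (code table, score matrix) to TSV
#'
#' Row labels go in the first column under the header `id`; values are
#' written with full precision so that [read_labelled_table()] recovers
#' them exactly (well within the 1e-9 round-trip contract).
#'
#' @param t Numeric matrix with row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labelled_table <- function(t, path) {
  if (!is.matrix(t) || !is.numeric(t) || nrow(t) < 1L || ncol(t) < 1L)
    stop("table must be a non-empty numeric matrix")
  if (is.null(rownames(t)) || is.null(colnames(t)))
    stop("table must carry row and column names")
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  lines <- c(paste(c("id", colnames(t)), collapse = "\t"),
             vapply(seq_len(nrow(t)), function(i)
               paste(c(rownames(t)[i], fmt(t[i, ])), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a labelled numeric table written by [write_labelled_table()]
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix with row and column names.
#' @export
read_labelled_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           quote = "\"", comment.char = "", stringsAsFactors = FALSE)
  m <- as.matrix(tab[-1L])
  if (!is.numeric(m)) stop("non-numeric values in table ", path)
  rownames(m) <- as.character(tab[[1L]])
  m
}
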