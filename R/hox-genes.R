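#' The 39 human HOX genes
#'
#' The human genome carries 39 HOX homeobox genes organized into four
#' clusters (HOXA, HOXB, HOXC, HOXD) of paralogous genes numbered 1-13.
#' Their combinatorial expression pattern ("HOX code") marks anatomic
#' identity along the body axes and is the gene set over which all tissue
#' codes and correlation scores in this package are computed.
#'
#' Symbols follow current HGNC nomenclature. Note that no cluster carries
#' all 13 paralogs: HOXA lacks 8 and 12, HOXB lacks 10-12, HOXC lacks 1-3
#' and 7, and HOXD lacks 2 and 5-7.
#'
#' @return A data.frame with one row per gene and columns `symbol`
#'   (HGNC symbol), `cluster` (`"A"`, `"B"`, `"C"` or `"D"`) and
#'   `paralog` (integer 1-13), ordered by cluster then paralog.
#' @examples
#' gs <- hox_genes()
#' nrow(gs)            # 39
#' table(gs$cluster)
#' @export
hox_genes <- function() {
  paralogs <- list(
    A = c(1:7, 9:11, 13),
    B = c(1:9, 13),
    C = c(4:6, 8:13),
    D = c(1, 3, 4, 8:13)
  )
  cluster <- rep(names(paralogs), lengths(paralogs))
  paralog <- unlist(paralogs, use.names = FALSE)
  data.frame(
    symbol  = paste0("HOX", cluster, paralog),
    cluster = cluster,
    paralog = as.integer(paralog),
    stringsAsFactors = FALSE
  )
}

# Legacy/variant symbol -> current HGNC symbol. Applied after upper-casing
# and after stripping "-"/"_" separators, so "HoxA-1" already normalizes
# without an entry here. Covers the old HOX1/2/3/4 numbering for a few
# genes that still appear under it in older array annotations.
.hox_alias_map <- c(
  "HOX1F" = "HOXA1",  "HOX1D" = "HOXA4", "HOX1C" = "HOXA5",
  "HOX1A" = "HOXA7",  "HOX1G" = "HOXA9",
  "HOX2G" = "HOXB3",  "HOX2A" = "HOXB5", "HOX2C" = "HOXB7",
  "HOX3C" = "HOXC6",  "HOX3A" = "HOXC8",
  "HOX4A" = "HOXD3",  "HOX4B" = "HOXD4"
)

# Normalize a vector of gene identifiers to canonical HGNC-style symbols:
# upper-case, strip hyphen/underscore separators, then apply the alias map.
.normalize_gene_ids <- function(ids) {
  out <- toupper(trimws(ids))
  out <- gsub("[-_]", "", out)
  hit <- out %in% names(.hox_alias_map)
  out[hit] <- .hox_alias_map[out[hit]]
  out
}
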