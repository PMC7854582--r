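#' Restrict an expression matrix to the HOX gene set
#'
#' Matches row identifiers case-insensitively (after legacy-alias
#' normalization) against a gene set and returns the rows in the gene
#' set's order, regardless of input order.
#'
#' @param m Numeric genes-by-samples matrix.
#' @param genes Gene set as returned by [hox_genes()], or a character
#'   vector of symbols.
#' @param policy `"strict"` requires every gene of the set to be present
#'   and errors otherwise, listing what is missing. `"intersect"` keeps
#'   the present subset (in gene-set order) with a warning, but errors if
#'   fewer than 10 genes remain, since a Pearson correlation over a
#'   handful of genes is not meaningful.
#' @return The subset matrix, rows ordered as in `genes`.
#' @examples
#' m <- matrix(1:8, 2, 4, dimnames = list(c("hoxb13", "HOXA1"), paste0("s", 1:4)))
#' subset_hox_genes(m, policy = "intersect")
#' @export
subset_hox_genes <- function(m, genes = hox_genes(),
                             policy = c("strict", "intersect")) {
  policy <- match.arg(policy)
  .validate_expression(m)
  symbols <- if (is.data.frame(genes)) genes$symbol else as.character(genes)
  symbols <- .normalize_gene_ids(symbols)
  rn <- .normalize_gene_ids(rownames(m))
  idx <- match(symbols, rn)
  missing <- symbols[is.na(idx)]
  if (policy == "strict" && length(missing) > 0L)
    stop("missing gene(s) from expression matrix: ",
         paste(missing, collapse = ", "))
  present <- idx[!is.na(idx)]
  if (policy == "intersect") {
    if (length(present) < 10L)
      stop("only ", length(present),
           " of the gene set present; need at least 10 for correlation scoring")
    if (length(missing) > 0L)
      warning("dropping ", length(missing), " gene(s) absent from the matrix: ",
              paste(missing, collapse = ", "))
  }
  out <- m[present, , drop = FALSE]
  rownames(out) <- rn[present]
  out
}
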