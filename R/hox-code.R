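#' Fit tissue HOX codes from a labelled expression matrix
#'
#' A tissue's HOX code is its characteristic expression profile over the
#' 39 human HOX genes, estimated here as the per-gene median over all
#' samples carrying that tissue label. Samples are grouped by
#' `meta$label`, expression is optionally log2(x+1)-transformed, and the
#' median of the transformed values is taken gene by gene. The resulting
#' code table is the reference against which new samples are scored by
#' Pearson correlation (see [predict.hox_code()]).
#'
#' The median makes each code robust: in a group of odd size, fewer than
#' half the samples may be perturbed arbitrarily without moving any code
#' entry. Even-sized groups use the conventional mean of the two middle
#' values.
#'
#' @param expr Numeric genes-by-samples matrix (rows should already be
#'   restricted to the HOX gene set, e.g. via [subset_hox_genes()]; any
#'   gene set works, but codes and samples must share it).
#' @param meta Sample metadata: a data.frame `(sample_id, label)` or a
#'   named character vector mapping sample id to tissue label. Samples
#'   in `expr` but not in `meta` are dropped with a warning; labels in
#'   `meta` without expression data produce a warning only.
#' @param transform Scale on which medians and all downstream
#'   correlations are computed: `"log2p1"` (default; log2(x+1), the
#'   usual choice for FPKM-like abundances, whose raw scale is dominated
#'   by the most highly expressed gene) or `"none"`.
#' @param min_group_size Minimum number of samples a tissue needs to
#'   receive a code (default 1). Smaller groups are excluded with a
#'   message; if no group qualifies, an error is raised.
#' @return An object of class `"hox_code"`: a list with elements
#'   `codes` (tissues x genes numeric matrix, tissue rows in
#'   lexicographic order, on the transformed scale), `transform`,
#'   `group_sizes` (named integer vector), `gene_ids`, `tissue_ids` and
#'   `n_samples` (number of labelled samples used).
#' @examples
#' sim <- simulate_hox_cohort(n_tissues = 4, samples_per_tissue = 5, seed = 1)
#' fit <- hox_code(sim$expression, sim$metadata)
#' fit
#' coef(fit)[, 1:3]
#' @seealso [predict.hox_code()], [validate_hox_codes()], [simulate_hox_cohort()]
#' @export
hox_code <- function(expr, meta, transform = c("log2p1", "none"),
                     min_group_size = 1L) {
  transform <- match.arg(transform)
  .validate_expression(expr)
  meta <- .as_metadata(meta)
  if (min_group_size < 1L) stop("'min_group_size' must be at least 1")

  unlabelled <- setdiff(colnames(expr), meta$sample_id)
  if (length(unlabelled) > 0L) {
    warning("dropping ", length(unlabelled),
            " sample(s) absent from metadata: ",
            paste(utils::head(unlabelled, 5L), collapse = ", "),
            if (length(unlabelled) > 5L) ", ..." else "")
    expr <- expr[, setdiff(colnames(expr), unlabelled), drop = FALSE]
  }
  orphan <- setdiff(meta$sample_id, colnames(expr))
  if (length(orphan) > 0L)
    warning(length(orphan), " metadata sample(s) have no expression data")
  meta <- meta[meta$sample_id %in% colnames(expr), , drop = FALSE]
  if (nrow(meta) == 0L) stop("no labelled samples remain")

  tx <- .apply_transform(expr, transform)
  sizes <- table(meta$label)
  keep <- names(sizes)[sizes >= min_group_size]
  drop <- setdiff(names(sizes), keep)
  if (length(keep) == 0L)
    stop("no tissue group reaches min_group_size = ", min_group_size)
  if (length(drop) > 0L)
    message("excluding ", length(drop), " group(s) below min_group_size: ",
            paste(drop, collapse = ", "))
  keep <- sort(keep)

  codes <- t(vapply(keep, function(tissue) {
    ids <- meta$sample_id[meta$label == tissue]
    apply(tx[, ids, drop = FALSE], 1L, stats::median)
  }, numeric(nrow(tx))))
  dimnames(codes) <- list(keep, rownames(expr))

  group_sizes <- as.integer(sizes[keep])
  names(group_sizes) <- keep
  structure(list(
    codes       = codes,
    transform   = transform,
    group_sizes = group_sizes,
    gene_ids    = rownames(expr),
    tissue_ids  = keep,
    n_samples   = sum(group_sizes)
  ), class = "hox_code")
}

#' @export
print.hox_code <- function(x, ...) {
  cat("Tissue HOX codes\n")
  cat(sprintf("  %d tissues x %d genes, from %d labelled samples (transform: %s)\n",
              length(x$tissue_ids), length(x$gene_ids), x$n_samples, x$transform))
  cat("  tissues:", paste(utils::head(x$tissue_ids, 6L), collapse = ", "),
      if (length(x$tissue_ids) > 6L) "..." else "", "\n")
  invisible(x)
}

#' @export
coef.hox_code <- function(object, ...) object$codes

#' @export
summary.hox_code <- function(object, ...) {
  rng <- apply(object$codes, 1L, range)
  out <- data.frame(
    tissue   = object$tissue_ids,
    n        = object$group_sizes[object$tissue_ids],
    code_min = rng[1L, ],
    code_max = rng[2L, ],
    row.names = NULL
  )
  structure(list(table = out, transform = object$transform,
                 n_genes = length(object$gene_ids)),
            class = "summary.hox_code")
}

#' @export
print.summary.hox_code <- function(x, ...) {
  cat(sprintf("HOX code table over %d genes (transform: %s)\n\n",
              x$n_genes, x$transform))
  print(x$table, row.names = FALSE, digits = 4L)
  invisible(x)
}

#' Simulate samples from fitted HOX codes
#'
#' Draws `nsim` synthetic samples per tissue by adding Gaussian noise to
#' each tissue's code on the transformed scale and mapping back to the
#' abundance scale (for `"log2p1"` codes, `2^x - 1` truncated at zero).
#'
#' @param object A fitted [hox_code()] object.
#' @param nsim Samples per tissue.
#' @param seed Integer seed (required; the global RNG stream is left
#'   untouched).
#' @param noise_sd Noise standard deviation on the code scale.
#' @param ... Unused.
#' @return A list with `expression` (genes x samples matrix) and
#'   `metadata` (`sample_id`, `label`).
#' @export
simulate.hox_code <- function(object, nsim = 1L, seed, noise_sd = 0.25, ...) {
  if (missing(seed)) stop("'seed' is required")
  if (nsim < 1L) stop("'nsim' must be at least 1")
  .with_seed(seed, {
    G <- length(object$gene_ids)
    cols <- list(); labels <- character(0L)
    for (tissue in object$tissue_ids) {
      for (k in seq_len(nsim)) {
        prof <- object$codes[tissue, ] + stats::rnorm(G, 0, noise_sd)
        val <- if (object$transform == "log2p1") pmax(2^prof - 1, 0) else pmax(prof, 0)
        cols[[length(cols) + 1L]] <- val
        labels <- c(labels, tissue)
      }
    }
    expr <- do.call(cbind, cols)
    ids <- paste0(labels, "_sim",
                  stats::ave(seq_along(labels), labels, FUN = seq_along))
    dimnames(expr) <- list(object$gene_ids, ids)
    list(expression = expr,
         metadata = data.frame(sample_id = ids, label = labels,
                               stringsAsFactors = FALSE))
  })
}

#' Validate HOX codes by within-group median self-correlation
#'
#' For every pair (sample group t, code u), computes the median over the
#' samples labelled t of the Pearson correlation between the sample's
#' transformed HOX profile and code u. The diagonal of the resulting
#' matrix measures how strongly each tissue correlates with its own
#' code; with well-separated tissue profiles the diagonal entry is the
#' row maximum. Note the validation is circular by construction (samples
#' are scored against codes they contributed to) unless
#' `leave_one_out = TRUE`, which rebuilds the code without the scored
#' sample before correlating.
#'
#' @param object A fitted [hox_code()] object.
#' @param expr Genes-by-samples matrix on the same gene set as the codes.
#' @param meta Sample metadata (see [hox_code()]).
#' @param leave_one_out Rebuild each code without the scored sample
#'   (default `FALSE`).
#' @return A tissues-by-tissues numeric matrix in `[-1, 1]`; rows are
#'   sample groups, columns are codes. A code tissue with no labelled
#'   samples yields an `NA` row with a warning.
#' @export
validate_hox_codes <- function(object, expr, meta, leave_one_out = FALSE) {
  stopifnot(inherits(object, "hox_code"))
  .validate_expression(expr)
  meta <- .as_metadata(meta)
  if (!identical(rownames(expr), object$gene_ids))
    stop("gene set of 'expr' does not match the fitted codes")
  tissues <- object$tissue_ids
  tx <- .apply_transform(expr, object$transform)
  out <- matrix(NA_real_, length(tissues), length(tissues),
                dimnames = list(tissues, tissues))
  for (t in tissues) {
    ids <- intersect(meta$sample_id[meta$label == t], colnames(expr))
    if (length(ids) == 0L) {
      warning("no labelled samples for tissue '", t, "'; row left missing")
      next
    }
    for (u in tissues) {
      r <- vapply(ids, function(s) {
        code <- if (leave_one_out && u == t && length(ids) > 1L) {
          apply(tx[, setdiff(ids, s), drop = FALSE], 1L, stats::median)
        } else object$codes[u, ]
        pearson_r(tx[, s], code)
      }, numeric(1L))
      out[t, u] <- stats::median(r, na.rm = TRUE)
    }
  }
  out
}
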