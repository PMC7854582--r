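# Internal helpers shared across the package.

# Expression transform applied before medians and correlations.
.apply_transform <- function(x, transform = c("log2p1", "none")) {
  transform <- match.arg(transform)
  if (transform == "log2p1") log2(x + 1) else x
}

# Validate a genes x samples expression matrix. Values must be finite and
# non-negative; gene ids unique after normalization; at least 1 x 1.
.validate_expression <- function(m, what = "expression matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    stop(what, " must be a numeric matrix (genes in rows, samples in columns)")
  if (nrow(m) < 1L || ncol(m) < 1L)
    stop(what, " must have at least one gene and one sample")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(what, " must carry gene row names and sample column names")
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop(sprintf("negative value (%g) at gene '%s', sample '%s'",
                 m[neg[1L, , drop = FALSE]],
                 rownames(m)[neg[1L, 1L]], colnames(m)[neg[1L, 2L]]))
  norm <- .normalize_gene_ids(rownames(m))
  if (anyDuplicated(norm))
    stop("duplicate gene identifiers after case normalization: ",
         paste(unique(norm[duplicated(norm)]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  invisible(m)
}

# Coerce sample metadata to a canonical two-column data.frame
# (sample_id, label). Accepts a data.frame whose first two columns are
# id and label, or a named character vector.
.as_metadata <- function(meta) {
  if (is.data.frame(meta)) {
    if (ncol(meta) < 2L)
      stop("metadata must have at least two columns: sample id and label")
    out <- data.frame(sample_id = as.character(meta[[1L]]),
                      label = as.character(meta[[2L]]),
                      stringsAsFactors = FALSE)
  } else if (is.character(meta) && !is.null(names(meta))) {
    out <- data.frame(sample_id = names(meta), label = unname(meta),
                      stringsAsFactors = FALSE)
  } else {
    stop("metadata must be a data.frame (sample_id, label) or a named character vector")
  }
  if (any(!nzchar(out$sample_id)) || anyNA(out$sample_id))
    stop("metadata contains empty sample identifiers")
  if (any(!nzchar(out$label)) || anyNA(out$label))
    stop("metadata contains empty group labels")
  if (anyDuplicated(out$sample_id))
    stop("duplicate sample identifiers in metadata: ",
         paste(unique(out$sample_id[duplicated(out$sample_id)]), collapse = ", "))
  out
}

# Run code under a fixed, portable RNG state and restore the caller's
# stream afterwards. All simulation in the package goes through this so
# a given seed yields the same cohort on every platform.
.with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}
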