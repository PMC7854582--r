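#' Pearson correlation with the conventions used throughout the package
#'
#' Standard sample Pearson correlation, requiring vectors of equal
#' length of at least 3 with all values finite. If either vector has
#' zero variance the correlation is undefined and `NA` is returned
#' rather than an error, so cohort-level scoring never aborts on one
#' degenerate sample.
#'
#' @param x,y Numeric vectors.
#' @return The correlation coefficient in `[-1, 1]`, or `NA_real_`.
#' @examples
#' pearson_r(1:3, 3:1)      # -1
#' pearson_r(c(5, 5, 5), 1:3)  # NA: zero variance
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("'x' and 'y' must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Score samples against a HOX code table
#'
#' Computes, for every sample, the Pearson correlation between its
#' transformed HOX expression profile and each tissue's code. This is
#' the "correlation score" used to read off tissue identity: a sample
#' retaining its lineage correlates strongly (conventionally r > 0.3)
#' with its tissue's code.
#'
#' @param object A fitted [hox_code()] object.
#' @param expr Genes-by-samples matrix over exactly the fitted gene set
#'   (any row order; rows are matched by identifier).
#' @return A samples-by-tissues numeric matrix of correlations in
#'   `[-1, 1]`. Samples whose transformed profile has zero variance get
#'   a fully `NA` row with a warning.
#' @seealso [classify_lineage()], [predict.hox_code()]
#' @export
score_hox_samples <- function(object, expr) {
  stopifnot(inherits(object, "hox_code"))
  .validate_expression(expr)
  rn <- .normalize_gene_ids(rownames(expr))
  idx <- match(object$gene_ids, rn)
  if (anyNA(idx))
    stop("expression matrix is missing fitted gene(s): ",
         paste(object$gene_ids[is.na(idx)], collapse = ", "))
  if (length(rn) != length(object$gene_ids))
    stop("expression matrix carries genes outside the fitted gene set; ",
         "subset it first (see subset_hox_genes)")
  tx <- .apply_transform(expr[idx, , drop = FALSE], object$transform)
  scores <- matrix(NA_real_, ncol(tx), length(object$tissue_ids),
                   dimnames = list(colnames(tx), object$tissue_ids))
  degenerate <- character(0L)
  for (s in colnames(tx)) {
    v <- tx[, s]
    if (stats::sd(v) == 0) { degenerate <- c(degenerate, s); next }
    scores[s, ] <- vapply(object$tissue_ids,
                          function(u) pearson_r(v, object$codes[u, ]),
                          numeric(1L))
  }
  if (length(degenerate) > 0L)
    warning("zero-variance profile(s), scores set to NA: ",
            paste(degenerate, collapse = ", "))
  scores
}

#' Classify lineage identity from a score matrix
#'
#' Implements the lineage-keep / lineage-switch call: a sample keeps its
#' lineage when its correlation with its home tissue's code is strictly
#' greater than the threshold (default 0.3). Otherwise, if some other
#' tissue's code exceeds the threshold the sample has switched to
#' another identity; if no code does, the sample has lost its identity
#' without gaining a new one (`switched_no_identity`) — the signature of
#' anaplastic trans-differentiation such as neuroendocrine prostate
#' cancer.
#'
#' Samples without a home label are reported by best-matching tissue:
#' exactly one tissue over threshold is called `kept` (a single clear
#' identity), two or more are `ambiguous`, none is
#' `switched_no_identity`. A fully missing score row yields `undefined`.
#' Ties for the best tissue break lexicographically by tissue label, so
#' output is deterministic.
#'
#' @param scores Samples-by-tissues score matrix from
#'   [score_hox_samples()].
#' @param meta Optional metadata giving each sample's home tissue label;
#'   labels must exist among the score columns. Samples absent from
#'   `meta` are treated as unlabelled.
#' @param threshold Correlation cutoff in (-1, 1); calls use strict
#'   `>`.
#' @return A data.frame with one row per sample: `sample_id`,
#'   `home_tissue`, `home_score`, `best_tissue`, `best_score`, `call`
#'   (factor with levels kept, switched_to_other, switched_no_identity,
#'   ambiguous, undefined) and `threshold`.
#' @export
classify_lineage <- function(scores, meta = NULL, threshold = 0.3) {
  if (!is.matrix(scores) || !is.numeric(scores))
    stop("'scores' must be a numeric samples-by-tissues matrix")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= -1 || threshold >= 1)
    stop("'threshold' must lie strictly inside (-1, 1)")
  tissues <- colnames(scores)
  home <- rep(NA_character_, nrow(scores))
  names(home) <- rownames(scores)
  if (!is.null(meta)) {
    meta <- .as_metadata(meta)
    known <- intersect(meta$sample_id, rownames(scores))
    lab <- meta$label[match(known, meta$sample_id)]
    bad <- setdiff(unique(lab), tissues)
    if (length(bad) > 0L)
      stop("home tissue(s) not present in score matrix: ",
           paste(bad, collapse = ", "))
    home[known] <- lab
  }
  levels_call <- c("kept", "switched_to_other", "switched_no_identity",
                   "ambiguous", "undefined")
  out <- lapply(rownames(scores), function(s) {
    r <- scores[s, ]
    h <- home[[s]]
    if (all(is.na(r))) {
      return(data.frame(sample_id = s, home_tissue = h,
                        home_score = NA_real_, best_tissue = NA_character_,
                        best_score = NA_real_, call = "undefined",
                        stringsAsFactors = FALSE))
    }
    ord <- order(-r, tissues, na.last = TRUE)
    best_tissue <- tissues[ord[1L]]
    best_score <- r[[ord[1L]]]
    over <- tissues[!is.na(r) & r > threshold]
    if (!is.na(h)) {
      hs <- r[[h]]
      call <- if (!is.na(hs) && hs > threshold) "kept"
      else if (length(setdiff(over, h)) > 0L) "switched_to_other"
      else "switched_no_identity"
    } else {
      hs <- NA_real_
      call <- if (length(over) >= 2L) "ambiguous"
      else if (length(over) == 1L) "kept"
      else "switched_no_identity"
    }
    data.frame(sample_id = s, home_tissue = h, home_score = hs,
               best_tissue = best_tissue, best_score = best_score,
               call = call, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$call <- factor(out$call, levels = levels_call)
  out$threshold <- threshold
  rownames(out) <- NULL
  out
}

#' Per-group contingency of lineage calls
#'
#' Tabulates, for each sample group, how many samples received each
#' lineage call and the fraction called `kept`; this is the shape of the
#' headline cohort statement "13 of 15 samples switched".
#'
#' @param calls Data.frame from [classify_lineage()].
#' @param meta Metadata mapping every call's sample to a group label
#'   (may differ from the home labels used for classification, e.g.
#'   AdPCa/NEPCa phenotype groups).
#' @return A data.frame with one row per group: `group`, `n`, one count
#'   column per call level, and `fraction_kept`.
#' @export
summarize_lineage_calls <- function(calls, meta) {
  if (!is.data.frame(calls) || nrow(calls) == 0L)
    stop("'calls' must be a non-empty data.frame of lineage calls")
  meta <- .as_metadata(meta)
  missing <- setdiff(calls$sample_id, meta$sample_id)
  if (length(missing) > 0L)
    stop("sample(s) without a group label: ", paste(missing, collapse = ", "))
  group <- meta$label[match(calls$sample_id, meta$sample_id)]
  tab <- table(group, factor(calls$call, levels = levels(calls$call)))
  out <- data.frame(group = rownames(tab), n = as.integer(rowSums(tab)),
                    stringsAsFactors = FALSE)
  for (lev in colnames(tab)) out[[lev]] <- as.integer(tab[, lev])
  out$fraction_kept <- out$kept / out$n
  rownames(out) <- NULL
  out[order(out$group), , drop = FALSE]
}

#' Score and classify new samples against fitted HOX codes
#'
#' @param object A fitted [hox_code()] object.
#' @param newdata Genes-by-samples expression matrix over the fitted
#'   gene set.
#' @param type `"scores"` for the samples-by-tissues correlation matrix,
#'   `"calls"` for lineage classifications.
#' @param meta Optional home-tissue metadata, used when
#'   `type = "calls"`.
#' @param threshold Correlation cutoff for `type = "calls"`.
#' @param ... Unused.
#' @return A score matrix or a call data.frame; see
#'   [score_hox_samples()] and [classify_lineage()].
#' @examples
#' sim <- simulate_hox_cohort(n_tissues = 4, samples_per_tissue = 5, seed = 1)
#' fit <- hox_code(sim$expression, sim$metadata)
#' head(predict(fit, sim$expression, type = "calls", meta = sim$metadata))
#' @export
predict.hox_code <- function(object, newdata, type = c("scores", "calls"),
                             meta = NULL, threshold = 0.3, ...) {
  type <- match.arg(type)
  scores <- score_hox_samples(object, newdata)
  if (type == "scores") return(scores)
  classify_lineage(scores, meta = meta, threshold = threshold)
}

#' Heatmap of a fitted code table
#'
#' @param x A fitted [hox_code()] object.
#' @param ... Passed to [hox_heatmap()] (e.g. `path`, `order`).
#' @return The heatmap grob, invisibly.
#' @export
plot.hox_code <- function(x, ...) {
  hox_heatmap(x$codes, symmetric = FALSE, ...)
}
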