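#' Semiquantitative immunohistochemistry H-score
#'
#' The H-score summarizes an IHC staining distribution over the four
#' conventional intensity levels (0 = negative, 1 = weak, 2 = moderate,
#' 3 = strong) as `1*pct1 + 2*pct2 + 3*pct3`, where `pct_i` is the
#' percentage of cells staining at level i. The score ranges from 0
#' (all cells negative) to 300 (all cells strong).
#'
#' @param pct A numeric vector of 4 percentages `(pct0, pct1, pct2,
#'   pct3)`, or a 4-column matrix/data.frame with one specimen per row.
#'   Each percentage must be non-negative and each row must sum to 100
#'   within +/-0.5.
#' @return A numeric H-score in `[0, 300]` (one per row).
#' @examples
#' h_score(c(0, 50, 50, 0))   # 150
#' h_score(c(100, 0, 0, 0))   # 0
#' @export
h_score <- function(pct) {
  m <- if (is.null(dim(pct))) matrix(as.numeric(pct), nrow = 1L)
       else as.matrix(pct)
  if (ncol(m) != 4L)
    stop("expected 4 intensity-level percentages (levels 0-3)")
  if (!is.numeric(m) || anyNA(m) || any(!is.finite(m)))
    stop("percentages must be finite numbers")
  if (any(m < 0)) stop("negative percentage")
  sums <- rowSums(m)
  off <- which(abs(sums - 100) > 0.5)
  if (length(off) > 0L)
    stop(sprintf("percentages must sum to 100 +/- 0.5 (row %d sums to %g)",
                 off[1L], sums[off[1L]]))
  pmin(pmax(m %*% c(0, 1, 2, 3), 0), 300)[, 1L]
}

# Default ordinal grade scale: benign hyperplasia below all Gleason scores.
.grade_levels <- c("BPH", "GS6", "GS7", "GS8", "GS9", "GS10")

#' Spearman correlation of H-score against ordinal tumor grade
#'
#' Ranks H-scores and grades (average ranks on ties) and reports the
#' Spearman correlation with a two-sided p-value from the large-sample
#' t approximation. Grades are mapped to an ordinal scale; the default
#' places benign prostatic hyperplasia below Gleason scores 6-10
#' (`BPH < GS6 < GS7 < GS8 < GS9 < GS10`).
#'
#' @param h_scores Numeric vector of H-scores.
#' @param grades Character/factor vector of grade labels (levels taken
#'   from `grade_levels`) or an already-ordinal numeric vector.
#'   Ungraded (`NA`) records are dropped.
#' @param grade_levels Ordered grade labels, lowest first.
#' @return A list with `rho`, `p_value` and `n` (records used). If all
#'   grades are identical, `rho` and `p_value` are `NA`.
#' @examples
#' spearman_grade_correlation(c(10, 40, 90), c("BPH", "GS6", "GS8"))
#' @export
spearman_grade_correlation <- function(h_scores, grades,
                                       grade_levels = .grade_levels) {
  if (length(h_scores) != length(grades))
    stop("'h_scores' and 'grades' must have equal length")
  if (is.numeric(grades)) {
    ord <- as.numeric(grades)
  } else {
    g <- as.character(grades)
    bad <- setdiff(unique(g[!is.na(g)]), grade_levels)
    if (length(bad) > 0L)
      stop("unknown grade label(s): ", paste(bad, collapse = ", "))
    ord <- as.numeric(factor(g, levels = grade_levels))
  }
  keep <- !is.na(ord) & !is.na(h_scores)
  h <- as.numeric(h_scores[keep]); ord <- ord[keep]
  if (length(h) < 3L) stop("need at least 3 graded records")
  if (length(unique(ord)) == 1L || length(unique(h)) == 1L)
    return(list(rho = NA_real_, p_value = NA_real_, n = length(h)))
  ct <- suppressWarnings(
    stats::cor.test(h, ord, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(h))
}
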