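make_meta <- function(ids, labels) {
  data.frame(sample_id = ids, label = labels, stringsAsFactors = FALSE)
}

test_that("codes are per-group medians on the requested scale", {
  genes <- c("HOXA1", "HOXB13", "HOXD9")
  # one-sample group: code equals the sample vector under transform = none
  m1 <- matrix(c(4, 7, 0), 3, 1, dimnames = list(genes, "s1"))
  fit1 <- hox_code(m1, make_meta("s1", "prostate"), transform = "none")
  expect_identical(unname(fit1$codes["prostate", ]), c(4, 7, 0))

  # odd group: median of {1, 5, 100} is 5
  m3 <- matrix(c(1, 0, 0, 5, 0, 0, 100, 0, 0), 3, 3,
               dimnames = list(genes, paste0("s", 1:3)))
  fit3 <- hox_code(m3, make_meta(paste0("s", 1:3), "skin"), transform = "none")
  expect_identical(unname(fit3$codes["skin", "HOXA1"]), 5)

  # even group under log2p1: median of log2({0,1,3,7}+1) = mean(log2(2), log2(4)) = 1.5
  m4 <- matrix(c(0, 1, 3, 7, rep(1, 8)), 3, 4, byrow = TRUE,
               dimnames = list(genes, paste0("s", 1:4)))
  fit4 <- hox_code(m4, make_meta(paste0("s", 1:4), "lung"), transform = "log2p1")
  expect_equal(unname(fit4$codes["lung", "HOXA1"]), 1.5)
})

test_that("fitting is invariant to sample-column and metadata-row permutations", {
  m <- hox_expr(n_samples = 9L, seed = 11L)
  meta <- make_meta(colnames(m), rep(c("lung", "skin", "liver"), each = 3L))
  fit <- hox_code(m, meta)

  set.seed(12)
  perm <- sample(ncol(m))
  fit_perm <- hox_code(m[, perm], meta[sample(nrow(meta)), ])
  expect_identical(fit_perm$codes, fit$codes)
  expect_identical(fit_perm$group_sizes, fit$group_sizes)
})

test_that("the median makes codes robust to a strict minority of outliers", {
  m <- hox_expr(n_samples = 5L, seed = 13L)
  m[] <- round(m)
  m <- m[, rep(1L, 5L)]  # five identical samples
  colnames(m) <- paste0("s", 1:5)
  meta <- make_meta(colnames(m), "prostate")
  base <- hox_code(m, meta, transform = "none")

  poisoned <- m
  poisoned[, c("s2", "s4")] <- 1e9  # 2 of 5: strict minority
  fit <- hox_code(poisoned, meta, transform = "none")
  expect_identical(fit$codes, base$codes)
})

test_that("groups below min_group_size are excluded, erroring when none remain", {
  m <- hox_expr(n_samples = 4L, seed = 14L)
  meta <- make_meta(colnames(m), c("lung", "lung", "lung", "skin"))
  expect_message(fit <- hox_code(m, meta, min_group_size = 2L), "skin")
  expect_identical(fit$tissue_ids, "lung")
  expect_error(suppressMessages(hox_code(m, meta, min_group_size = 10L)),
               "min_group_size")
})

test_that("sample/metadata mismatches warn without aborting", {
  m <- hox_expr(n_samples = 3L, seed = 15L)
  meta_missing <- make_meta(c("S1", "S2"), c("lung", "lung"))
  expect_warning(fit <- hox_code(m, meta_missing), "absent from metadata")
  expect_identical(fit$n_samples, 2L)

  meta_extra <- make_meta(c(colnames(m), "ghost"), rep("lung", 4L))
  expect_warning(hox_code(m, meta_extra), "no expression data")
})

test_that("validation diagonal is 1 for samples regenerated exactly from codes", {
  m <- hox_expr(n_samples = 6L, seed = 16L)
  meta <- make_meta(colnames(m), rep(c("lung", "skin"), each = 3L))
  fit <- hox_code(m, meta)
  # regenerate one pseudo-sample per tissue by inverting the transform
  pseudo <- t(fit$codes)
  pseudo <- 2^pseudo - 1
  colnames(pseudo) <- paste0(fit$tissue_ids, "_p")
  vmeta <- make_meta(colnames(pseudo), fit$tissue_ids)
  val <- validate_hox_codes(fit, pseudo, vmeta)
  expect_equal(unname(diag(val)), rep(1, 2), tolerance = 1e-12)
  expect_true(all(val >= -1 & val <= 1, na.rm = TRUE))
})

test_that("well-separated synthetic tissues put the validation diagonal on top", {
  sim <- simulate_hox_cohort(n_tissues = 6L, samples_per_tissue = 5L, seed = 17)
  fit <- hox_code(sim$expression, sim$metadata)
  val <- validate_hox_codes(fit, sim$expression, sim$metadata)
  for (t in rownames(val))
    expect_identical(colnames(val)[which.max(val[t, ])], t)
})

test_that("identical tissue groups yield equal codes and symmetric validation", {
  m <- hox_expr(n_samples = 3L, seed = 18L)
  twin <- cbind(m, m)
  colnames(twin) <- paste0("S", 1:6)
  meta <- make_meta(colnames(twin), rep(c("alpha", "beta"), each = 3L))
  fit <- hox_code(twin, meta)
  expect_identical(unname(fit$codes["alpha", ]), unname(fit$codes["beta", ]))
  val <- validate_hox_codes(fit, twin, meta)
  expect_equal(val["alpha", ], val["beta", ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a code tissue with no labelled samples gives a missing row and warning", {
  m <- hox_expr(n_samples = 4L, seed = 19L)
  meta <- make_meta(colnames(m), rep(c("lung", "skin"), each = 2L))
  fit <- hox_code(m, meta)
  meta2 <- make_meta(colnames(m), rep("lung", 4L))
  expect_warning(val <- validate_hox_codes(fit, m, meta2), "skin")
  expect_true(all(is.na(val["skin", ])))
})

test_that("print, summary and coef expose the fit", {
  sim <- simulate_hox_cohort(n_tissues = 3L, samples_per_tissue = 4L, seed = 20)
  fit <- hox_code(sim$expression, sim$metadata)
  expect_output(print(fit), "3 tissues x 39 genes")
  expect_identical(coef(fit), fit$codes)
  s <- summary(fit)
  expect_s3_class(s, "summary.hox_code")
  expect_identical(s$table$n, unname(fit$group_sizes))
})
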