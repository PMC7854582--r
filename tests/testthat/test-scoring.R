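test_that("pearson_r matches the textbook formula and its edge conventions", {
  expect_identical(pearson_r(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_identical(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  # direct evaluation: sum(dx*dy) = 9, sum(dx^2) = 5, sum(dy^2) = 19
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 4, 4, 8)), 9 / sqrt(95),
               tolerance = 1e-15)
  expect_identical(pearson_r(c(5, 5, 5), c(1, 2, 3)), NA_real_)
  expect_error(pearson_r(1:3, 1:4), "equal length")
  expect_error(pearson_r(1:2, 2:3), "at least 3")
  expect_error(pearson_r(c(1, NA, 3), c(1, 2, 3)), "finite")
})

test_that("pearson_r is invariant under positive affine maps and negated by reflection", {
  for (i in 1:25) {
    set.seed(100 + i)
    x <- rnorm(10); y <- rnorm(10)
    r <- pearson_r(x, y)
    a <- runif(1, 0.1, 5); b <- runif(1, -10, 10)
    expect_equal(pearson_r(a * x + b, y), r, tolerance = 1e-12)
    expect_equal(pearson_r(-a * x + b, y), -r, tolerance = 1e-12)
    expect_equal(r, brute_pearson(x, y), tolerance = 1e-12)
  }
})

scored_fixture <- function(seed = 30L) {
  sim <- simulate_hox_cohort(n_tissues = 4L, samples_per_tissue = 5L, seed = seed)
  fit <- hox_code(sim$expression, sim$metadata)
  list(sim = sim, fit = fit)
}

test_that("samples equal to a code score 1.0 for that tissue", {
  fx <- scored_fixture()
  pseudo <- 2^t(fx$fit$codes) - 1   # invert log2p1
  colnames(pseudo) <- paste0(fx$fit$tissue_ids, "_p")
  sc <- score_hox_samples(fx$fit, pseudo)
  expect_equal(unname(diag(sc)), rep(1, 4), tolerance = 1e-12)
  expect_true(all(sc >= -1 & sc <= 1))
})

test_that("generated samples score highest against their own tissue's code", {
  fx <- scored_fixture()
  sc <- score_hox_samples(fx$fit, fx$sim$expression)
  argmax <- colnames(sc)[apply(sc, 1L, which.max)]
  expect_identical(argmax,
                   fx$sim$metadata$label[match(rownames(sc),
                                               fx$sim$metadata$sample_id)])
})

test_that("zero-variance samples get a missing score row, not an error", {
  fx <- scored_fixture()
  flat <- matrix(5, nrow = 39, ncol = 1,
                 dimnames = list(fx$fit$gene_ids, "flat"))
  expect_warning(sc <- score_hox_samples(fx$fit, flat), "zero-variance")
  expect_true(all(is.na(sc["flat", ])))
})

test_that("scoring demands the fitted gene set", {
  fx <- scored_fixture()
  m <- fx$sim$expression
  expect_error(score_hox_samples(fx$fit, m[-1, , drop = FALSE]), "missing")
  extra <- rbind(m, OTHER1 = 1)
  expect_error(score_hox_samples(fx$fit, extra), "outside the fitted gene set")
})

test_that("lineage calls follow the strict > threshold rule", {
  sc <- matrix(c(0.85, 0.10, 0.30, 0.20,   # prostate column
                 0.10, 0.10, 0.10, 0.45),  # skin column
               4, 2, dimnames = list(paste0("s", 1:4), c("prostate", "skin")))
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     label = rep("prostate", 4))
  calls <- classify_lineage(sc, meta, threshold = 0.3)
  expect_identical(as.character(calls$call),
                   c("kept",                  # 0.85 > 0.3
                     "switched_no_identity",  # nothing over
                     "switched_no_identity",  # exactly 0.3 is NOT kept
                     "switched_to_other"))    # skin 0.45
  expect_identical(calls$best_tissue[4], "skin")
  expect_identical(calls$home_score[1], 0.85)
})

test_that("unlabelled samples collapse to best-tissue reporting", {
  sc <- matrix(c(0.6, 0.1, 0.5, 0.2,
                 0.4, 0.2, 0.1, 0.1),
               4, 2, dimnames = list(paste0("u", 1:4), c("lung", "skin")))
  calls <- classify_lineage(sc, meta = NULL, threshold = 0.3)
  expect_identical(as.character(calls$call),
                   c("ambiguous",             # two tissues over
                     "switched_no_identity",  # none over
                     "kept",                  # one clear identity
                     "switched_no_identity"))
  expect_true(all(is.na(calls$home_tissue)))
})

test_that("missing rows are undefined and ties break lexicographically", {
  sc <- matrix(c(NA, 0.5, NA, 0.5), 2, 2,
               dimnames = list(c("gone", "tie"), c("b_tissue", "a_tissue")))
  calls <- classify_lineage(sc, threshold = 0.3)
  expect_identical(as.character(calls$call[calls$sample_id == "gone"]),
                   "undefined")
  expect_identical(calls$best_tissue[calls$sample_id == "tie"], "a_tissue")
})

test_that("classification is invariant to sample order and rejects bad thresholds", {
  fx <- scored_fixture()
  sc <- score_hox_samples(fx$fit, fx$sim$expression)
  c1 <- classify_lineage(sc, fx$sim$metadata)
  set.seed(31)
  perm <- sample(nrow(sc))
  c2 <- classify_lineage(sc[perm, ], fx$sim$metadata)
  c2 <- c2[match(c1$sample_id, c2$sample_id), ]
  rownames(c2) <- NULL
  expect_identical(c1, c2)
  expect_error(classify_lineage(sc, threshold = 1), "threshold")
  expect_error(classify_lineage(sc, fx$sim$metadata[1:2, ] |>
                                  transform(label = "nosuch")),
               "not present")
})

test_that("call summaries count the cohort-style fractions", {
  calls <- data.frame(
    sample_id = paste0("s", 1:15),
    call = factor(c(rep("switched_no_identity", 13), rep("kept", 2)),
                  levels = c("kept", "switched_to_other",
                             "switched_no_identity", "ambiguous", "undefined")),
    stringsAsFactors = FALSE)
  meta <- data.frame(sample_id = paste0("s", 1:15), label = "NEPCa")
  tab <- summarize_lineage_calls(calls, meta)
  expect_identical(tab$n, 15L)
  expect_equal(tab$fraction_kept, 2 / 15)
  expect_identical(tab$switched_no_identity, 13L)

  all_kept <- calls; all_kept$call[] <- "kept"
  expect_equal(summarize_lineage_calls(all_kept, meta)$fraction_kept, 1)

  expect_error(summarize_lineage_calls(calls[0, ], meta), "non-empty")
  expect_error(summarize_lineage_calls(calls, meta[1:3, ]),
               "without a group label")
})

test_that("predict dispatches to scores and calls", {
  fx <- scored_fixture()
  sc <- predict(fx$fit, fx$sim$expression)
  expect_identical(sc, score_hox_samples(fx$fit, fx$sim$expression))
  calls <- predict(fx$fit, fx$sim$expression, type = "calls",
                   meta = fx$sim$metadata)
  expect_identical(calls,
                   classify_lineage(sc, fx$sim$metadata, threshold = 0.3))
})
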