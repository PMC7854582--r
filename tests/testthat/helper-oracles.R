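# Independent brute-force oracles used to cross-check the package's
# statistics. These deliberately avoid stats::cor / stats::rank and spell
# out the textbook formulas.

brute_pearson <- function(x, y) {
  dx <- x - sum(x) / length(x)
  dy <- y - sum(y) / length(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Average ranks with explicit tie handling (no call to rank()).
brute_avg_rank <- function(x) {
  o <- order(x)
  sx <- x[o]
  r <- numeric(length(x))
  i <- 1L
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && sx[j + 1L] == sx[i]) j <- j + 1L
    r[o[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}

brute_spearman <- function(x, y) brute_pearson(brute_avg_rank(x), brute_avg_rank(y))

# Small random expression matrix with valid dimnames.
rand_expr <- function(n_genes = 6L, n_samples = 4L, seed = 1L) {
  set.seed(seed)
  m <- matrix(stats::runif(n_genes * n_samples, 0, 1000), n_genes, n_samples)
  dimnames(m) <- list(paste0("G", seq_len(n_genes)),
                      paste0("S", seq_len(n_samples)))
  m
}

# Expression matrix whose rows are the full HOX gene set (+ optional extras).
hox_expr <- function(n_samples = 4L, seed = 1L, extra_genes = 0L) {
  gs <- hoxcode::hox_genes()$symbol
  genes <- c(gs, if (extra_genes > 0L) paste0("OTHER", seq_len(extra_genes)))
  set.seed(seed)
  m <- matrix(stats::runif(length(genes) * n_samples, 0, 1000),
              length(genes), n_samples)
  dimnames(m) <- list(genes, paste0("S", seq_len(n_samples)))
  m
}
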