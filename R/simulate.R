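# Default tissue labels for simulated cohorts: 24 anatomic sites in the
# style of cell-line compendium annotations.
.default_tissues <- c(
  "autonomic_ganglia", "biliary_tract", "bone", "breast",
  "central_nervous_system", "endometrium", "haematopoietic_and_lymphoid",
  "kidney", "large_intestine", "liver", "lung", "oesophagus", "ovary",
  "pancreas", "pleura", "prostate", "salivary_gland", "skin",
  "small_intestine", "soft_tissue", "stomach", "thyroid",
  "upper_aerodigestive_tract", "urinary_tract"
)

#' Simulate a multi-tissue expression cohort with known HOX archetypes
#'
#' Generates the statistical structure the HOX-code pipeline assumes:
#' each tissue has a fixed archetype profile on the log2 scale (entries
#' i.i.d. uniform on `[0, archetype_max]`), and each sample is its
#' tissue's archetype plus per-gene Gaussian noise, mapped back to the
#' abundance scale as `2^x - 1` truncated at zero (so the package's
#' default `log2p1` transform recovers the log-scale profile).
#' "Lineage-switch" samples instead draw a fresh random archetype of
#' their own, decorrelating them from their labelled tissue.
#'
#' Output is bit-identical for identical arguments and seed; the
#' caller's RNG stream is untouched.
#'
#' @param n_tissues Number of tissues (default 24; up to 24 named
#'   anatomic-site labels are used, then generic labels).
#' @param samples_per_tissue Samples per tissue: a single count
#'   (default 8) or a vector of length `n_tissues`.
#' @param noise_sd Per-gene noise standard deviation on the log2 scale
#'   (default 0.25).
#' @param switch_fraction Fraction of each tissue's samples generated as
#'   lineage switches, a scalar or per-tissue vector in `[0, 1]`
#'   (default 0). Counts are rounded per tissue.
#' @param archetype_max Upper bound of the uniform archetype draw on the
#'   log2 scale (default 12, spanning the dynamic range of FPKM-like
#'   data).
#' @param genes Gene identifiers (default the 39 HOX symbols).
#' @param tissues Optional tissue labels of length `n_tissues`.
#' @param seed Integer seed (required).
#' @return A list: `expression` (genes x samples matrix),
#'   `metadata` (`sample_id`, `label`), `truth` (`sample_id`, `tissue`,
#'   `is_switch`) and `archetypes` (tissues x genes log2-scale matrix).
#' @examples
#' sim <- simulate_hox_cohort(n_tissues = 3, samples_per_tissue = 4, seed = 7)
#' dim(sim$expression)   # 39 x 12
#' @export
simulate_hox_cohort <- function(n_tissues = 24L, samples_per_tissue = 8L,
                                noise_sd = 0.25, switch_fraction = 0,
                                archetype_max = 12, genes = hox_genes()$symbol,
                                tissues = NULL, seed) {
  if (missing(seed)) stop("'seed' is required")
  if (n_tissues < 2L) stop("'n_tissues' must be at least 2")
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop("'noise_sd' must be > 0")
  if (any(switch_fraction < 0 | switch_fraction > 1))
    stop("'switch_fraction' must lie in [0, 1]")
  n_per <- rep_len(as.integer(samples_per_tissue), n_tissues)
  if (any(n_per < 1L)) stop("'samples_per_tissue' must be at least 1")
  frac <- rep_len(switch_fraction, n_tissues)
  if (is.null(tissues)) {
    tissues <- if (n_tissues <= length(.default_tissues))
      .default_tissues[seq_len(n_tissues)]
    else c(.default_tissues,
           sprintf("tissue%02d", seq_len(n_tissues - length(.default_tissues))))
  }
  if (length(tissues) != n_tissues || anyDuplicated(tissues))
    stop("'tissues' must give ", n_tissues, " unique labels")
  genes <- .normalize_gene_ids(genes)
  G <- length(genes)

  .with_seed(seed, {
    archetypes <- matrix(stats::runif(n_tissues * G, 0, archetype_max),
                         n_tissues, G, byrow = TRUE,
                         dimnames = list(tissues, genes))
    cols <- vector("list", sum(n_per))
    ids <- character(sum(n_per)); labels <- character(sum(n_per))
    is_switch <- logical(sum(n_per))
    k <- 0L
    for (t in seq_len(n_tissues)) {
      n_switch <- as.integer(round(frac[t] * n_per[t]))
      for (j in seq_len(n_per[t])) {
        k <- k + 1L
        sw <- j <= n_switch
        base <- if (sw) stats::runif(G, 0, archetype_max) else archetypes[t, ]
        lp <- base + stats::rnorm(G, 0, noise_sd)
        cols[[k]] <- pmax(2^lp - 1, 0)
        ids[k] <- sprintf("%s_s%02d", tissues[t], j)
        labels[k] <- tissues[t]
        is_switch[k] <- sw
      }
    }
    expr <- do.call(cbind, cols)
    dimnames(expr) <- list(genes, ids)
    list(
      expression = expr,
      metadata   = data.frame(sample_id = ids, label = labels,
                              stringsAsFactors = FALSE),
      truth      = data.frame(sample_id = ids, tissue = labels,
                              is_switch = is_switch, stringsAsFactors = FALSE),
      archetypes = archetypes
    )
  })
}

#' Simulate an adenocarcinoma vs neuroendocrine contrast cohort
#'
#' Emulates a two-group prostate cohort: both groups share a prostate
#' archetype on the log2 scale, and the second group additionally
#' carries planted per-gene shifts (e.g. HOXB13 down by 4 log2 units;
#' HOXB3/B5/B6/B7 up by 2), plus the usual Gaussian noise. Default
#' group sizes are 34 adenocarcinoma (AdPCa) vs 15 neuroendocrine
#' (NEPCa) samples, the size of the reference clinical cohort.
#'
#' @param n_adpca,n_nepca Group sizes (defaults 34 and 15).
#' @param shifts Named numeric vector of log2-scale shifts applied to
#'   the NEPCa group; names must be gene identifiers in `genes`. Must
#'   be non-empty.
#' @param noise_sd Per-gene noise SD on the log2 scale (default 0.25).
#' @param archetype_max Upper bound of the uniform archetype draw
#'   (default 12).
#' @param genes Gene identifiers (default the 39 HOX symbols).
#' @param seed Integer seed (required).
#' @return A list: `expression`, `metadata` (labels `"AdPCa"` /
#'   `"NEPCa"`) and `archetype` (the shared log2-scale prostate
#'   profile).
#' @examples
#' sim <- simulate_nepca_contrast(shifts = c(HOXB13 = -4), seed = 3)
#' table(sim$metadata$label)
#' @export
simulate_nepca_contrast <- function(n_adpca = 34L, n_nepca = 15L, shifts,
                                    noise_sd = 0.25, archetype_max = 12,
                                    genes = hox_genes()$symbol, seed) {
  if (missing(seed)) stop("'seed' is required")
  if (missing(shifts) || length(shifts) == 0L)
    stop("'shifts' must be a non-empty named numeric vector")
  if (is.null(names(shifts)) || any(!nzchar(names(shifts))))
    stop("'shifts' must be named by gene identifier")
  if (n_adpca < 2L || n_nepca < 2L) stop("both groups need at least 2 samples")
  genes <- .normalize_gene_ids(genes)
  shift_genes <- .normalize_gene_ids(names(shifts))
  unknown <- setdiff(shift_genes, genes)
  if (length(unknown) > 0L)
    stop("shift gene(s) not in the gene set: ", paste(unknown, collapse = ", "))
  G <- length(genes)
  shift_vec <- stats::setNames(numeric(G), genes)
  shift_vec[shift_genes] <- as.numeric(shifts)

  .with_seed(seed, {
    archetype <- stats::setNames(stats::runif(G, 0, archetype_max), genes)
    draw <- function(center, n) {
      vapply(seq_len(n), function(j)
        pmax(2^(center + stats::rnorm(G, 0, noise_sd)) - 1, 0), numeric(G))
    }
    expr_a <- draw(archetype, n_adpca)
    expr_b <- draw(archetype + shift_vec, n_nepca)
    ids <- c(sprintf("AdPCa_s%02d", seq_len(n_adpca)),
             sprintf("NEPCa_s%02d", seq_len(n_nepca)))
    expr <- cbind(expr_a, expr_b)
    dimnames(expr) <- list(genes, ids)
    list(
      expression = expr,
      metadata = data.frame(
        sample_id = ids,
        label = rep(c("AdPCa", "NEPCa"), c(n_adpca, n_nepca)),
        stringsAsFactors = FALSE),
      archetype = archetype
    )
  })
}

#' Simulate an IHC H-score table over ordinal tumor grades
#'
#' Draws specimens with grades uniform over
#' `BPH < GS6 < GS7 < GS8 < GS9 < GS10` and staining-intensity
#' percentage distributions from a Dirichlet-like model: intensity-level
#' shape parameters `(4, 3, 2, 1)` tilted by
#' `exp(trend * level * g / 5)`, where `g` is the 0-5 ordinal grade. A
#' positive `trend` shifts staining mass toward strong intensity in
#' high-grade specimens, producing a positive expected H-score/grade
#' association; `trend = 0` makes H-score independent of grade.
#'
#' @param n Number of specimens (at least 3).
#' @param trend Association strength (0 = none; 1 is a strong positive
#'   trend with Spearman rho around 0.85 at these settings).
#' @param seed Integer seed (required).
#' @return A data.frame with columns `specimen_id`, `pct0`-`pct3`,
#'   `h_score` and `grade` (factor on the default ordinal scale).
#' @examples
#' tab <- simulate_hscore_table(n = 5, trend = 1, seed = 2)
#' tab$h_score
#' @export
simulate_hscore_table <- function(n, trend = 0, seed) {
  if (missing(seed)) stop("'seed' is required")
  if (!is.numeric(n) || n < 3L) stop("'n' must be at least 3")
  n <- as.integer(n)
  .with_seed(seed, {
    g <- sample(0:5, n, replace = TRUE)
    base <- c(4, 3, 2, 1)
    pct <- t(vapply(seq_len(n), function(i) {
      shape <- base * exp(trend * (0:3) * g[i] / 5)
      draw <- stats::rgamma(4L, shape = shape, rate = 1)
      100 * draw / sum(draw)
    }, numeric(4L)))
    colnames(pct) <- paste0("pct", 0:3)
    out <- data.frame(specimen_id = sprintf("spec%03d", seq_len(n)), pct,
                      stringsAsFactors = FALSE)
    out$h_score <- h_score(pct)
    out$grade <- factor(.grade_levels[g + 1L], levels = .grade_levels)
    out
  })
}
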