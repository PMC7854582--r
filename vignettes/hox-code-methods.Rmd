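---
title: "HOX codes: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HOX codes: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoxcode)
```

## The model

`hoxcode` implements a nearest-centroid-style identity classifier over
the 39 human HOX genes. Tissue identity during development is encoded by
which HOX genes a region expresses; the package operationalizes a
tissue's "HOX code" as the per-gene **median** expression of its
labelled samples, and a sample's identity as its **Pearson correlation**
with each code over the 39-gene panel.

The assumptions are deliberately light:

* abundance units (FPKM or similar) are consistent across the samples
  being compared — no cross-cohort normalization is attempted;
* the HOX panel is informative for the tissues involved, i.e. tissues
  differ in their HOX profiles;
* within a tissue, samples scatter around a common profile, so that the
  median is a sensible centroid and a correlation near 1 with the own
  code is expected.

Classification uses a single correlation threshold, default 0.3, with a
strict inequality: a sample *keeps* its lineage when its home-tissue
score is `> 0.3`. "Low or negative" correlation is implemented as the
complement (`<= 0.3`); no second cutoff is introduced. For samples
failing their home code, a best-scoring other tissue above the threshold
yields `switched_to_other`, otherwise `switched_no_identity` — the
operational encoding of a tumor that has lost its identity without
acquiring a new one.

## Tunable parameters

| Parameter | Default | Units / scale | Why |
|---|---|---|---|
| `transform` | `"log2p1"` | log2(x+1) of abundance | Raw-scale Pearson over FPKM is dominated by the single most expressed gene (HOXB13 in prostate); the log scale weights the panel more evenly. `"none"` is provided for the literal raw-scale reading. |
| `threshold` | 0.3 | Pearson r | The conventional identity cutoff for this method; strict `>`. |
| `min_group_size` | 1 | samples | Tissues with few lines (prostate has 8 in the motivating compendium) still receive codes; raise it to demand more support. |
| `alpha` | 0.05 | raw p | Per-gene significance flag for two-group contrasts; BH q-values are always reported alongside but do not drive the flag. |
| `var_equal` | `FALSE` | — | Welch's t-test by default: cohort sizes here are typically unbalanced (e.g. 34 vs 15), where the pooled-variance test is anti-conservative under variance heterogeneity. |
| `noise_sd` (generator) | 0.25 | log2 units | A modest within-tissue dispersion relative to archetypes spanning 0–12 log2 units; identity recovery is essentially perfect here and degrades as noise grows. |

Whether the original analyses log-transformed before the median and the
correlation, and whether the validation heatmap used leave-one-out
scoring, is not derivable from the method's published description; the
package defaults to the log scale (for the robustness reason above) and
to *in-sample* validation (`leave_one_out = FALSE`), documenting both as
choices rather than asserting them as the source's. Leave-one-out
scoring is available in `validate_hox_codes()` for a non-circular check.

## Decisions where the design was open

* **Even-size medians** are the arithmetic mean of the two middle
  values — the standard convention.
* **Ties** for the best-matching tissue break lexicographically by
  tissue label, so output never depends on column order.
* **Unlabelled samples**: with no home tissue there is no keep/switch
  dichotomy. The package reports the best tissue and calls the sample
  `kept` when exactly one code passes the threshold (a single clear
  identity), `ambiguous` when several pass, `switched_no_identity` when
  none does.
* **Degenerate profiles** (zero variance across the panel, e.g. an
  all-zero sample) produce `NA` scores and an `undefined` call with a
  warning, never an exception — a cohort run should not abort on one
  broken sample. Likewise `pearson_r()` returns `NA` on zero-variance
  input rather than raising.
* **Degenerate genes in contrasts**: zero variance in both groups with
  equal means gives `t = 0, p = 1`; with unequal means, `t = ±Inf,
  p = 0`. Both are deterministic rather than errors.
* **Gene matching** is case-insensitive with separators stripped and a
  small legacy-alias map (old `HOX1F`-style symbols), because public
  expression exports vary; a strict policy requiring all 39 genes and a
  tolerant `intersect` policy (minimum 10 genes, else error) are both
  offered.
* **Grade ordering** for the H-score statistics places benign
  hyperplasia below all Gleason scores
  (`BPH < GS6 < GS7 < GS8 < GS9 < GS10`), and the four-level 0–3
  staining-intensity scale is the universal H-score convention. Whether
  a published Gleason axis should be read as 6–10 integers or as
  sub-pattern categories (3+4 vs 4+3) is not decidable here; the
  package accepts any pre-mapped numeric ordinal for such cases.

## What the synthetic generator emulates — and what it does not

`simulate_hox_cohort()` draws, per tissue, an archetype vector with
i.i.d. uniform entries on [0, 12] log2 units; a sample is its tissue's
archetype plus per-gene Gaussian noise (`noise_sd`), mapped to the
abundance scale as `2^x − 1` truncated at zero. Lineage-switch samples
draw a *fresh* archetype of their own, decorrelating them from their
label. `simulate_nepca_contrast()` shares one prostate archetype between
two groups and adds planted log2 shifts (the center is deliberately not
clamped at zero; only abundances are truncated, so a strong negative
shift on a low-expressed gene saturates at zero expression exactly as it
would in FPKM data). `simulate_hscore_table()` draws staining
percentages from a Dirichlet-like model with shapes
`(4, 3, 2, 1) · exp(trend · level · grade/5)`, so `trend = 0` makes
H-score independent of grade and `trend = 1` produces a strong positive
monotone association.

This emulates: well-separated tissue centroids, log-normal-style
within-tissue dispersion, variable group sizes, decorrelated switch
samples, planted differential patterns, and valid simplex-distributed
IHC records. It does **not** emulate: count noise and library-size
effects, batch or platform differences between cohorts, correlated
genes within HOX clusters, partial lineage switches, or tissues with
genuinely similar HOX programs. Passing tests therefore demonstrate
correctness of the *procedure* under its assumptions, not performance
on any real cohort; on real data, tissues with near-identical HOX codes
will blur both the validation diagonal and the switch calls.

One structural property of the generator is worth knowing when reading
switch-group results: a fresh random 39-gene archetype has roughly a 3%
chance of exceeding r = 0.3 against any *single* unrelated code, so
against a panel of 24 codes the chance that *some* foreign code passes
is near one half. A fully-switched group is therefore reliably not
`kept` (its home score is null-distributed), but its calls split close
to evenly between `switched_no_identity` and `switched_to_other`, and
the modal call can go either way in small groups. This is a property of
random archetypes and a 24-way panel, not of the classifier.

## Numerical and reproducibility choices

* All table output renders doubles with `%.17g`, so TSV artifacts
  round-trip bit-exactly and pipeline reruns are byte-identical.
* Every simulator takes a mandatory `seed`, uses a fixed RNG kind
  (Mersenne-Twister / inversion / rejection sampling), and restores the
  caller's RNG stream, so results are reproducible across platforms and
  never depend on hidden global state.
* Validation and scoring are exact up to floating point: samples
  regenerated from a code correlate with it at 1 within 1e-12.
* Heatmaps use a fixed symmetric [-1, 1] blue–white–red scale for
  correlation matrices, grey for missing cells, and either the matrix's
  own ordering (default, reproducible) or opt-in average-linkage
  hierarchical clustering on Euclidean distance.

The test suite and the acceptance script run at deliberately modest
problem sizes chosen to exercise every property while keeping the whole
suite fast: the flagship cohort is 24 tissues × 8 samples over the
39-gene panel; differential-pattern recovery uses 100 seeded replicates
of a 34-vs-15 contrast; the null calibration uses 200 replicates of
1000 genes × 20 samples; H-score checks use up to 500 specimens.

## Known limitations

* The method is a correlation-to-centroid classifier; it cannot
  distinguish "mixed identity" from "no identity", and its threshold is
  a global constant rather than tissue-calibrated.
* Validation is in-sample by default (codes are scored against the
  samples that built them), which overstates self-consistency for small
  groups; use `leave_one_out = TRUE` for an honest check.
* Headline counts from the motivating clinical cohorts (e.g. 31/34
  adenocarcinomas keeping the prostate code, 13/15 neuroendocrine
  tumors losing it, or an H-score/Gleason Spearman rho of 0.348) depend
  on controlled-access or unpublished per-specimen data; the package
  reproduces the *operations* that yield such counts, and its tests
  verify them on synthetic cohorts only.
* No batch correction, cross-platform harmonization, meta-analysis
  across cohorts, or single-cell-specific handling is included.
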