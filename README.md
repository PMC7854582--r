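# hoxcode

Tissue-of-origin "HOX codes" and lineage-identity scoring for bulk
expression data.

The 39 human HOX genes (clusters A–D, paralogs 1–13) pattern the body
axes during development, and their combinatorial expression marks adult
tissue identity. `hoxcode` turns that observation into a simple,
auditable classifier for studying lineage plasticity in cancer —
in particular the trans-differentiation of prostate adenocarcinoma
(AdPCa) into neuroendocrine prostate cancer (NEPCa), which loses the
prostatic HOX program (most prominently HOXB13) without acquiring any
other tissue's.

It is aimed at cancer-transcriptomics analysts who have a gene × sample
abundance matrix (FPKM or comparable) and tissue/phenotype labels, and
want a nearest-centroid-style identity readout they can inspect gene by
gene.

## The method

For each tissue *t* with labelled samples, the **HOX code** is the
per-gene median expression over the group, taken (by default) on the
log2(x+1) scale:

```
code_t[g] = median over samples s in t of log2(x[g, s] + 1)
```

A sample *s* is scored against every code by the Pearson correlation
over the 39 HOX genes:

```
r(s, t) = cor(log2(x[, s] + 1), code_t)
```

and classified at a correlation threshold (default r > 0.3, strict):

* **kept** — its home tissue's score exceeds the threshold;
* **switched_to_other** — home fails, but some other tissue passes;
* **switched_no_identity** — no tissue passes (identity lost without a
  replacement, the anaplastic NEPCa signature);
* **ambiguous / undefined** — unlabelled samples matching several codes,
  or degenerate (zero-variance) profiles.

Around that core the package provides per-gene Welch t-tests with
Benjamini–Hochberg q-values for two-group contrasts (e.g. AdPCa vs
NEPCa), the semiquantitative IHC H-score
(`1·pct1 + 2·pct2 + 3·pct3`, range 0–300) with Spearman correlation
against ordinal tumor grade, TSV/CSV/GCT input and output, correlation
heatmaps, and a fully seeded synthetic-cohort generator so every stage
is testable without external downloads.

## Worked example

```r
library(hoxcode)

sim <- simulate_hox_cohort(n_tissues = 6, samples_per_tissue = 5, seed = 42)
fit <- hox_code(sim$expression, sim$metadata)
fit
#> Tissue HOX codes
#>   6 tissues x 39 genes, from 30 labelled samples (transform: log2p1)
#>   tissues: autonomic_ganglia, biliary_tract, bone, breast, ...

round(predict(fit, sim$expression)[1:3, 1:4], 3)
#>                       autonomic_ganglia biliary_tract   bone breast
#> autonomic_ganglia_s01             0.998        -0.088  0.004 -0.041
#> autonomic_ganglia_s02             0.998        -0.093 -0.031 -0.043
#> autonomic_ganglia_s03             0.999        -0.077 -0.017 -0.059

calls <- predict(fit, sim$expression, type = "calls", meta = sim$metadata)
head(calls[, c("sample_id", "home_score", "call")], 3)
#>               sample_id home_score call
#> 1 autonomic_ganglia_s01  0.9984383 kept
#> 2 autonomic_ganglia_s02  0.9980300 kept
#> 3 autonomic_ganglia_s03  0.9985881 kept

summarize_lineage_calls(calls, sim$metadata)[1:2, c("group", "n", "kept", "fraction_kept")]
#>               group n kept fraction_kept
#> 1 autonomic_ganglia 5    5             1
#> 2     biliary_tract 5    5             1
```

Each score row is a sample's correlation with every tissue's code; with
well-separated tissue profiles and modest noise, every sample correlates
near 1 with its own tissue and near 0 elsewhere, so all calls are
`kept`. `run_hox_pipeline()` runs the same chain from files on disk and
writes `codes.tsv`, `validation.tsv`, `scores.tsv`, `calls.tsv`,
`summary.tsv` and heatmaps into an output directory.

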