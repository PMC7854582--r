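#' Correlation heatmap of a score, validation or code matrix
#'
#' Renders a matrix as a heatmap. Correlation matrices
#' (`symmetric = TRUE`, the default) use a blue-white-red palette
#' symmetric about 0 and spanning `[-1, 1]`; missing cells are drawn in
#' grey. Row/column order is either the matrix's own (`"fixed"`,
#' reproducible) or average-linkage hierarchical clustering on Euclidean
#' distance (`"cluster"`).
#'
#' @param m Non-empty numeric matrix with dimnames.
#' @param path Optional output file; the device is chosen by extension
#'   (`.png`, `.pdf` or `.svg`). `NULL` draws on the current device.
#' @param order `"fixed"` or `"cluster"`.
#' @param symmetric Use the symmetric `[-1, 1]` correlation palette.
#' @param width,height Device size in inches.
#' @param ... Passed on to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
hox_heatmap <- function(m, path = NULL, order = c("fixed", "cluster"),
                        symmetric = TRUE, width = 7, height = 7, ...) {
  order <- match.arg(order)
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) < 1L || ncol(m) < 1L)
    stop("'m' must be a non-empty numeric matrix")
  cluster_rows <- cluster_cols <- FALSE
  if (order == "cluster") {
    fill <- function(x) { x[!is.finite(x)] <- 0; x }
    cluster_rows <- if (nrow(m) > 1L)
      stats::hclust(stats::dist(fill(m)), method = "average") else FALSE
    cluster_cols <- if (ncol(m) > 1L)
      stats::hclust(stats::dist(t(fill(m))), method = "average") else FALSE
  }
  args <- list(mat = m, cluster_rows = cluster_rows,
               cluster_cols = cluster_cols, na_col = "grey80",
               silent = TRUE, ...)
  if (symmetric) {
    args$breaks <- seq(-1, 1, length.out = 101L)
    args$color <- grDevices::colorRampPalette(
      c("#2166AC", "#F7F7F7", "#B2182B"))(100L)
  }
  ph <- do.call(pheatmap::pheatmap, args)
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    dev <- switch(ext,
                  png = function() grDevices::png(path, width = width,
                                                  height = height, units = "in",
                                                  res = 150),
                  pdf = function() grDevices::pdf(path, width = width,
                                                  height = height),
                  svg = function() grDevices::svg(path, width = width,
                                                  height = height),
                  stop("unsupported image extension: '", ext,
                       "' (use png, pdf or svg)"))
    dev()
    on.exit(grDevices::dev.off())
    grid::grid.newpage()
    grid::grid.draw(ph$gtable)
  } else {
    grid::grid.newpage()
    grid::grid.draw(ph$gtable)
  }
  invisible(ph)
}

#' Run the full HOX-code pipeline on an expression cohort
#'
#' Executes the complete analysis in one call: restrict the matrix to
#' the HOX gene set, fit per-tissue codes, validate them by within-group
#' median self-correlation, score every sample against every code,
#' classify lineage identity at the correlation threshold, and summarize
#' calls per group. All tables are written as TSV; writing is
#' deterministic, so identical inputs give byte-identical artifacts.
#'
#' @param expr Expression matrix or path to one (TSV/CSV/GCT).
#' @param meta Sample metadata (data.frame, named vector, or path to a
#'   two-column TSV).
#' @param out_dir Output directory, created if needed.
#' @param transform,threshold,min_group_size See [hox_code()] and
#'   [classify_lineage()].
#' @param gene_policy Passed to [subset_hox_genes()] (default
#'   `"intersect"`).
#' @param heatmaps Also render `heatmap_validation.png` and
#'   `heatmap_scores.png`.
#' @return Invisibly, a list with the fitted `code` object, `validation`
#'   and `scores` matrices, `calls`, `summary` and the artifact paths.
#'   Artifacts: `codes.tsv`, `validation.tsv`, `scores.tsv`,
#'   `calls.tsv`, `summary.tsv`, `run_log.txt` (+ heatmaps).
#' @examples
#' sim <- simulate_hox_cohort(n_tissues = 3, samples_per_tissue = 4, seed = 5)
#' out <- run_hox_pipeline(sim$expression, sim$metadata,
#'                         out_dir = tempfile(), heatmaps = FALSE)
#' out$summary
#' @export
run_hox_pipeline <- function(expr, meta, out_dir,
                             transform = c("log2p1", "none"), threshold = 0.3,
                             min_group_size = 1L,
                             gene_policy = c("intersect", "strict"),
                             heatmaps = TRUE) {
  transform <- match.arg(transform)
  gene_policy <- match.arg(gene_policy)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  expr <- stage("read_expression",
                if (is.character(expr)) read_expression(expr) else {
                  .validate_expression(expr); expr })
  meta <- stage("read_metadata",
                if (is.character(meta) && length(meta) == 1L && file.exists(meta))
                  read_sample_metadata(meta) else .as_metadata(meta))
  expr <- stage("subset_genes", subset_hox_genes(expr, policy = gene_policy))
  fit <- stage("build_codes",
               hox_code(expr, meta, transform = transform,
                        min_group_size = min_group_size))
  validation <- stage("validate_codes", validate_hox_codes(fit, expr, meta))
  scores <- stage("score_samples", score_hox_samples(fit, expr))
  calls <- stage("classify", classify_lineage(scores, meta = meta,
                                              threshold = threshold))
  summary_tab <- stage("summarize", summarize_lineage_calls(calls, meta))

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- file.path(out_dir, c(codes = "codes.tsv",
                                validation = "validation.tsv",
                                scores = "scores.tsv", calls = "calls.tsv",
                                summary = "summary.tsv", log = "run_log.txt"))
  names(paths) <- c("codes", "validation", "scores", "calls", "summary", "log")
  stage("write_artifacts", {
    write_labelled_table(fit$codes, paths[["codes"]])
    write_labelled_table(validation, paths[["validation"]])
    write_labelled_table(scores, paths[["scores"]])
    .write_calls_tsv(calls, paths[["calls"]])
    .write_df_tsv(summary_tab, paths[["summary"]])
    writeLines(c(
      sprintf("hoxcode version: %s",
              as.character(utils::packageVersion("hoxcode"))),
      sprintf("transform: %s", transform),
      sprintf("threshold: %g", threshold),
      sprintf("min_group_size: %d", as.integer(min_group_size)),
      sprintf("gene_policy: %s", gene_policy),
      sprintf("n_genes: %d", nrow(expr)),
      sprintf("n_samples: %d", ncol(expr)),
      sprintf("n_tissues: %d", length(fit$tissue_ids))
    ), paths[["log"]])
  })
  if (heatmaps) stage("render_heatmaps", {
    hox_heatmap(validation, file.path(out_dir, "heatmap_validation.png"))
    hox_heatmap(scores, file.path(out_dir, "heatmap_scores.png"))
    paths <- c(paths,
               heatmap_validation = file.path(out_dir, "heatmap_validation.png"),
               heatmap_scores = file.path(out_dir, "heatmap_scores.png"))
  })
  invisible(list(code = fit, validation = validation, scores = scores,
                 calls = calls, summary = summary_tab, paths = paths))
}

# Deterministic TSV writers for the call and summary tables.
.write_calls_tsv <- function(calls, path) {
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  lines <- c(paste(c("sample_id", "home_tissue", "home_score", "best_tissue",
                     "best_score", "call"), collapse = "\t"),
             vapply(seq_len(nrow(calls)), function(i)
               paste(c(calls$sample_id[i],
                       ifelse(is.na(calls$home_tissue[i]), "NA",
                              calls$home_tissue[i]),
                       fmt(calls$home_score[i]),
                       ifelse(is.na(calls$best_tissue[i]), "NA",
                              calls$best_tissue[i]),
                       fmt(calls$best_score[i]),
                       as.character(calls$call[i])), collapse = "\t"), ""))
  writeLines(lines, path)
}

.write_df_tsv <- function(df, path) {
  cell <- function(x) {
    if (is.numeric(x) && !is.integer(x)) ifelse(is.na(x), "NA", sprintf("%.17g", x))
    else as.character(x)
  }
  body <- do.call(paste, c(lapply(df, cell), sep = "\t"))
  writeLines(c(paste(names(df), collapse = "\t"), body), path)
}
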