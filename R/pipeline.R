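#' End-to-end pipeline orchestration
#'
#' `run_pipeline()` chains the stages — load and align, moderated DEG
#' filter, greedy information-theoretic selection, panel evaluation — and
#' writes every stage's output plus a machine-readable JSON report. Logging
#' (per-stage timing and counts) goes to stderr; result files carry no
#' timestamps, so identical inputs and config produce byte-identical
#' reports.
#'
#' @name pipeline_cli
NULL

#' Build and validate a pipeline configuration
#'
#' Defaults reproduce the standard DEG criterion (`|logFC| > 1`,
#' `adj.P < 0.05`) with JMI selection on 4 equal-frequency bins.
#'
#' @param expression path to the expression TSV.
#' @param phenotype path to the phenotype TSV.
#' @param out_dir output directory (created if absent).
#' @param k panel size (required).
#' @param logfc_threshold,alpha DEG filter thresholds.
#' @param criterion `"jmi"` or `"mrmr"`.
#' @param n_bins discretization bins.
#' @param seed integer seed for any stochastic evaluation step.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(expression, phenotype, out_dir, k,
                            logfc_threshold = 1, alpha = 0.05,
                            criterion = c("jmi", "mrmr"), n_bins = 4L,
                            seed = 1L) {
  criterion <- match.arg(criterion)
  stopifnot(is.character(expression), is.character(phenotype),
            k >= 1, logfc_threshold >= 0, alpha > 0, alpha < 1, n_bins >= 2)
  structure(list(expression = expression, phenotype = phenotype,
                 out_dir = out_dir, k = as.integer(k),
                 logfc_threshold = logfc_threshold, alpha = alpha,
                 criterion = criterion, n_bins = as.integer(n_bins),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full discovery pipeline
#'
#' Stages: read + align inputs, [deg_table()] + [filter_degs()],
#' [greedy_select()] on the DEG submatrix, [evaluate_panel()]. Outputs in
#' `config$out_dir`: `deg.tsv`, `selection.tsv`, `evaluation.tsv`,
#' `report.json`. If no gene passes the DEG filter the pipeline terminates
#' cleanly with an empty panel; if `k` exceeds the DEG count it is capped
#' (recorded in the report).
#'
#' @param config a [pipeline_config()].
#' @return the report, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]

  mat <- read_expression_tsv(config$expression)
  ann <- read_phenotype_tsv(config$phenotype)
  al <- align_samples(mat, ann)
  mat <- al$matrix; ann <- al$annotations
  labels <- ann$class
  tum <- as_class_labels(labels)
  stage_log("load", "%d genes x %d samples (%d tumor, %d normal), %.1fs",
            nrow(mat), ncol(mat), sum(tum), sum(!tum),
            proc.time()[["elapsed"]] - t0)

  deg <- deg_table(mat, labels, config$logfc_threshold, config$alpha)
  write_tsv(deg, file.path(config$out_dir, "deg.tsv"))
  degs <- filter_degs(deg, config$logfc_threshold, config$alpha)
  stage_log("deg", "%d of %d genes pass |logFC| > %g and adj.P < %g",
            length(degs), nrow(deg), config$logfc_threshold, config$alpha)

  report <- list(
    config = unclass(config),
    counts = list(n_genes_input = nrow(mat), n_samples = ncol(mat),
                  n_tumor = sum(tum), n_normal = sum(!tum),
                  n_degs = length(degs),
                  n_failed_filter = nrow(mat) - length(degs)))

  if (length(degs) == 0L) {
    stage_log("select", "no DEGs: terminating with empty panel")
    report$panel <- character(0)
    report$k_effective <- 0L
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }

  k_eff <- min(config$k, length(degs))
  if (k_eff < config$k) {
    stage_log("select", "k capped at %d (only %d DEGs)", k_eff, length(degs))
  }
  trace <- greedy_select(mat[degs, , drop = FALSE], labels, k_eff,
                         criterion = config$criterion, n_bins = config$n_bins,
                         store_scores = FALSE)
  write_tsv(trace$steps, file.path(config$out_dir, "selection.tsv"))
  panel <- trace$steps$gene
  stage_log("select", "panel of %d genes by %s: %s", k_eff,
            toupper(config$criterion), paste(panel, collapse = ", "))

  ev <- evaluate_panel(mat, ann, panel)
  write_tsv(ev$per_gene, file.path(config$out_dir, "evaluation.tsv"))
  stage_log("evaluate", "median AUC %.3f; panel cluster purity %s",
            stats::median(ev$per_gene$auc),
            ifelse(is.na(ev$purity), "NA", sprintf("%.3f", ev$purity)))

  report$panel <- panel
  report$k_effective <- k_eff
  report$selection <- trace$steps
  report$evaluation <- ev$per_gene
  report$cluster_purity <- ev$purity
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_log("done", "outputs in %s (%.1fs total)", config$out_dir,
            proc.time()[["elapsed"]] - t0)
  invisible(report)
}

#' The published 11-gene stomach-adenocarcinoma panel
#'
#' The 11 gene symbols reported as a tumor-vs-normal signature for stomach
#' adenocarcinoma (ten up-regulated plus the down-regulated STX12), shipped
#' as a fixture so [evaluate_panel()] can be pointed at any user-supplied
#' cohort that uses gene symbols. No data download is attempted.
#'
#' @return character vector of 11 gene symbols.
#' @export
stad_panel_genes <- function() {
  readLines(system.file("extdata", "stad_panel_11.txt", package = "jmipanel"))
}
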