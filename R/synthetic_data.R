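#' Synthetic two-class cohorts with planted structure
#'
#' The generator emulates the statistical structure the analysis assumes on a
#' log2-normalized expression matrix: Gaussian per-gene noise around a
#' gene-specific baseline, a subset of informative genes whose tumor mean is
#' shifted by a planted log2 effect (signs alternating up/down, mirroring a
#' signature that mixes up- and down-regulated markers), and redundant
#' duplicate genes correlated with their informative parent at a target
#' correlation. [attach_stage_and_survival()] then layers tumor stages with a
#' planted monotone expression trend and exponential survival whose log
#' hazard increases with a planted gene's expression. All randomness is fixed
#' by a single seed: the same call is bit-identical.
#'
#' @name synthetic_data
NULL

#' Generate a synthetic two-class cohort
#'
#' Null genes are baseline + `N(0, noise_sd^2)` identically in both classes.
#' Each informative gene `i` gets its tumor mean shifted by
#' `(-1)^(i-1) * effect_size`. Each redundant duplicate is built from its
#' parent's standardized profile as `rho * z_parent + sqrt(1-rho^2) * eps`,
#' rescaled to the parent's spread and re-centred on its own baseline, so its
#' population correlation with the parent is exactly `redundancy_rho` (and it
#' inherits an attenuated class effect, i.e. duplicates also pass a
#' fold-change filter — the situation redundancy-aware selection must cope
#' with).
#'
#' @param n_genes total number of genes.
#' @param n_tumor,n_normal samples per class (each >= 1).
#' @param n_informative number of genes with a planted class effect.
#' @param n_redundant_per redundant duplicates planted per informative gene.
#' @param effect_size planted mean shift, log2 units.
#' @param redundancy_rho target duplicate-parent correlation, in [0, 1).
#' @param noise_sd per-gene noise SD, log2 units.
#' @param seed integer seed fixing all randomness.
#' @return list with `matrix` (expression), `annotations` (phenotype
#'   data.frame) and `truth` (a `ground_truth` list: `informative_genes`,
#'   `redundant_map` named parent-by-duplicate, `stage_trend_genes`,
#'   `survival_genes`, and the generating parameters).
#' @export
generate_cohort <- function(n_genes, n_tumor, n_normal, n_informative,
                            n_redundant_per = 0L, effect_size = 2,
                            redundancy_rho = 0.95, noise_sd = 1, seed) {
  stopifnot(n_genes >= 1, n_tumor >= 1, n_normal >= 1, n_informative >= 1,
            n_redundant_per >= 0, noise_sd > 0,
            redundancy_rho >= 0, redundancy_rho < 1)
  n_planted <- n_informative * (1L + n_redundant_per)
  if (n_planted > n_genes) {
    stop(sprintf("infeasible counts: %d informative genes with %d duplicates each exceed n_genes = %d",
                 n_informative, n_redundant_per, n_genes))
  }
  set.seed(as.integer(seed))

  n <- n_tumor + n_normal
  wd <- max(3L, nchar(as.character(max(n_tumor, n_normal))))
  sample_ids <- c(sprintf(paste0("T%0", wd, "d"), seq_len(n_tumor)),
                  sprintf(paste0("N%0", wd, "d"), seq_len(n_normal)))
  is_tumor <- c(rep(TRUE, n_tumor), rep(FALSE, n_normal))

  inf_ids <- sprintf("INF%03d", seq_len(n_informative))
  dup_ids <- character(0)
  dup_parent <- character(0)
  if (n_redundant_per > 0) {
    for (i in seq_len(n_informative)) {
      ids <- sprintf("DUP%03d_%d", i, seq_len(n_redundant_per))
      dup_ids <- c(dup_ids, ids)
      dup_parent <- c(dup_parent, rep(inf_ids[i], n_redundant_per))
    }
  }
  null_ids <- sprintf("NUL%05d", seq_len(n_genes - n_planted))
  gene_ids <- c(inf_ids, dup_ids, null_ids)

  baseline <- stats::runif(n_genes, min = 4, max = 12)
  m <- baseline + matrix(stats::rnorm(n_genes * n, sd = noise_sd), n_genes, n)
  dimnames(m) <- list(gene_ids, sample_ids)

  signs <- rep_len(c(1, -1), n_informative)
  for (i in seq_len(n_informative)) {
    m[inf_ids[i], is_tumor] <- m[inf_ids[i], is_tumor] + signs[i] * effect_size
  }
  # duplicates drawn after the class shift so they inherit (attenuated) effect
  for (k in seq_along(dup_ids)) {
    p <- m[dup_parent[k], ]
    z <- (p - mean(p)) / stats::sd(p)
    eps <- stats::rnorm(n)
    zd <- redundancy_rho * z + sqrt(1 - redundancy_rho^2) * eps
    m[dup_ids[k], ] <- baseline[match(dup_ids[k], gene_ids)] + stats::sd(p) * zd
  }

  annotations <- data.frame(
    sample_id = sample_ids,
    class = ifelse(is_tumor, "tumor", "normal"),
    stage = NA_character_, os_time = NA_real_, os_event = NA_real_,
    stringsAsFactors = FALSE)

  truth <- structure(list(
    informative_genes = inf_ids,
    redundant_map = stats::setNames(dup_parent, dup_ids),
    stage_trend_genes = character(0),
    survival_genes = character(0),
    effect_size = effect_size, noise_sd = noise_sd,
    redundancy_rho = redundancy_rho, effect_signs = stats::setNames(signs, inf_ids)),
    class = "ground_truth")

  list(matrix = m, annotations = annotations, truth = truth)
}

#' Plant tumor stages and expression-linked survival
#'
#' Tumor samples are assigned stages I--IV by a multinomial draw with fixed
#' probabilities (defaults follow a typical stomach-adenocarcinoma stage
#' distribution). The first `n_stage_genes` informative genes receive an
#' additive increment of `stage_delta * (stage - 1)` in the staged tumor
#' samples, making their population stage means strictly increasing.
#' Survival times for tumor samples are exponential with log hazard
#' `log_hr` per standard deviation of the mean standardized expression of
#' the planted survival genes (so `log_hr = 0` is an exact survival null);
#' censoring is independent uniform on `[0, censor_max_days]`.
#'
#' Note the expression matrix itself is modified (the stage trend is an
#' expression feature), so the matrix, annotations and updated ground truth
#' are all returned.
#'
#' @param matrix expression matrix from [generate_cohort()].
#' @param annotations matching phenotype data.frame.
#' @param truth `ground_truth` from [generate_cohort()].
#' @param seed integer seed.
#' @param n_stage_genes,n_survival_genes how many informative genes receive a
#'   stage trend / survival link (stage genes are taken from the start of the
#'   informative list, survival genes from the end; they may overlap only if
#'   the informative pool is too small, which is an error).
#' @param stage_delta per-stage additive increment, log2 units.
#' @param stage_probs stage I--IV probabilities (summing to 1).
#' @param log_hr log hazard ratio per SD of planted-gene expression.
#' @param baseline_median_days median survival at average expression, days.
#' @param censor_max_days upper bound of the uniform censoring time, days
#'   (0 censors everything at time 0).
#' @return list with updated `matrix`, `annotations` and `truth`.
#' @export
attach_stage_and_survival <- function(matrix, annotations, truth, seed,
                                      n_stage_genes = 2L,
                                      n_survival_genes = 3L,
                                      stage_delta = 0.5,
                                      stage_probs = c(I = 0.138, II = 0.324,
                                                      III = 0.438, IV = 0.100),
                                      log_hr = log(2),
                                      baseline_median_days = 500,
                                      censor_max_days = 2000) {
  validate_expression_matrix(matrix)
  stopifnot(length(stage_probs) == 4L, all(stage_probs >= 0),
            n_stage_genes >= 0, n_survival_genes >= 0,
            baseline_median_days > 0, censor_max_days >= 0)
  tum <- annotations$class == "tumor"
  if (!any(tum)) stop("no tumor samples to stage")
  n_inf <- length(truth$informative_genes)
  if (n_stage_genes + n_survival_genes > n_inf) {
    stop("not enough informative genes to host disjoint stage and survival effects")
  }
  set.seed(as.integer(seed))

  stages <- c("I", "II", "III", "IV")
  drawn <- sample(stages, sum(tum), replace = TRUE,
                  prob = stage_probs / sum(stage_probs))
  annotations$stage[tum] <- drawn

  stage_genes <- utils::head(truth$informative_genes, n_stage_genes)
  stage_idx <- match(drawn, stages) - 1L
  for (g in stage_genes) {
    matrix[g, tum] <- matrix[g, tum] + stage_delta * stage_idx
  }

  surv_genes <- utils::tail(truth$informative_genes, n_survival_genes)
  n_tum <- sum(tum)
  zbar <- if (length(surv_genes) > 0) {
    zs <- t(scale(t(matrix[surv_genes, tum, drop = FALSE])))
    colMeans(zs)
  } else rep(0, n_tum)
  rate <- (log(2) / baseline_median_days) * exp(log_hr * zbar)
  death <- stats::rexp(n_tum, rate = rate)
  cens <- stats::runif(n_tum, min = 0, max = censor_max_days)
  annotations$os_time[tum] <- pmin(death, cens)
  annotations$os_event[tum] <- as.numeric(death <= cens)

  truth$stage_trend_genes <- stage_genes
  truth$survival_genes <- surv_genes
  list(matrix = matrix, annotations = annotations, truth = truth)
}
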