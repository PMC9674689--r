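#' Panel evaluation: ROC/AUC, cluster purity, stage trends, survival
#'
#' Downstream assessments of a candidate panel: per-gene diagnostic AUC via
#' the rank (Mann-Whitney) statistic, a deterministic two-cluster separation
#' purity standing in for t-SNE/heatmap figures, monotone stage-trend
#' screening on stage means, and Kaplan-Meier / log-rank comparison of
#' median-split expression groups.
#'
#' @name evaluation
NULL

#' ROC AUC by rank statistic
#'
#' `AUC = P(score_tumor > score_normal) + 0.5 * P(tie)`, computed from
#' midranks. Orientation is fixed tumor-positive (no auto-flip): a marker
#' lower in tumors scores below 0.5. Use `max(auc, 1 - auc)` for the
#' orientation-free value some ROC tools report.
#'
#' @param scores numeric score per sample (e.g. one gene's expression).
#' @param labels class labels per sample.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  tum <- as_class_labels(labels)
  if (length(scores) != length(tum)) stop("one score per sample required")
  n1 <- sum(tum); n2 <- sum(!tum)
  if (n1 == 0L || n2 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[tum]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Two-cluster separation purity of a panel
#'
#' Rows (genes) are standardized, samples are clustered by average-linkage
#' agglomeration on Euclidean distance, the tree is cut at 2 clusters, and
#' purity is the best achievable agreement between the 2 clusters and the 2
#' class labels (hence always >= 0.5). A deterministic, quantitative proxy
#' for "how cleanly does the panel separate tumor from normal".
#'
#' @param matrix expression matrix restricted to the panel's genes.
#' @param labels class labels per sample (>= 2 samples per class).
#' @return purity in `[0.5, 1]`.
#' @export
cluster_purity <- function(matrix, labels) {
  validate_expression_matrix(matrix)
  tum <- as_class_labels(labels)
  if (sum(tum) < 2L || sum(!tum) < 2L) stop("need at least 2 samples per class")
  z <- matrix
  for (i in seq_len(nrow(z))) {
    s <- stats::sd(z[i, ])
    z[i, ] <- if (s > 0) (z[i, ] - mean(z[i, ])) / s else 0
  }
  hc <- stats::hclust(stats::dist(t(z)), method = "average")
  cl <- stats::cutree(hc, k = 2L)
  acc <- mean((cl == 1L) == tum)
  max(acc, 1 - acc)
}

#' Compute stage means of one gene
#'
#' Means over tumor samples with known stage only; a stage with no samples
#' yields `NaN`.
#'
#' @param values expression of one gene per sample.
#' @param stages stage strings `"I".."IV"` per sample (`NA` = unknown).
#' @return named numeric vector of length 4 (stages I--IV).
#' @export
stage_means <- function(values, stages) {
  if (length(values) != length(stages)) stop("one stage per sample required")
  vapply(c("I", "II", "III", "IV"),
         function(s) mean(values[!is.na(stages) & stages == s]),
         numeric(1L))
}

#' Monotone stage-trend screen
#'
#' Flags a gene whose four stage means move consistently with stage
#' progression: monotone non-decreasing or non-increasing across I to IV.
#'
#' @param stage_means numeric vector of 4 finite stage means (I--IV).
#' @return list with `monotone` (logical), `direction` (`"increasing"`,
#'   `"decreasing"` or `NA`) and `means` (the input).
#' @export
stage_trend_monotone <- function(stage_means) {
  if (length(stage_means) != 4L || any(!is.finite(stage_means))) {
    stop("need 4 finite stage means (I-IV)")
  }
  d <- diff(stage_means)
  up <- all(d >= 0); down <- all(d <= 0)
  list(monotone = up || down,
       direction = if (up) "increasing" else if (down) "decreasing" else NA_character_,
       means = stage_means)
}

#' Median split of expression into high/low
#'
#' `high` means strictly above the sample median; values at the median go to
#' `low`, so an all-constant input is all `low`.
#'
#' @param values numeric vector, length >= 2.
#' @return factor with levels `low`, `high`.
#' @export
median_split <- function(values) {
  if (length(values) < 2L) stop("need at least 2 samples")
  factor(ifelse(values > stats::median(values), "high", "low"),
         levels = c("low", "high"))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times follow-up times (days), non-negative.
#' @param events event indicator per sample (1 = death, 0 = censored).
#' @return a `km_fit` data.frame over the distinct observed times: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv` (non-increasing, starts from 1;
#'   identically 1 if everything is censored).
#' @export
km_estimate <- function(times, events) {
  if (length(times) != length(events)) stop("times and events must align")
  if (anyNA(times) || anyNA(events)) stop("missing survival data")
  if (any(times < 0)) stop("negative survival time")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  ut <- sort(unique(times))
  n_risk <- vapply(ut, function(u) sum(times >= u), numeric(1L))
  n_event <- vapply(ut, function(u) sum(times == u & events == 1), numeric(1L))
  n_censor <- vapply(ut, function(u) sum(times == u & events == 0), numeric(1L))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, surv = surv, row.names = NULL),
            class = c("km_fit", "data.frame"))
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank: at each distinct event time the group-1 event
#' count is compared with its hypergeometric expectation, variances
#' accumulate, and the statistic `(O - E)^2 / V` is referred to
#' chi-square(1).
#'
#' @param times follow-up times, non-negative.
#' @param events 0/1 event indicators.
#' @param groups two-level grouping per sample (factor/character/logical).
#' @return list with `chisq`, `p`, `observed` and `expected` (length-2, per
#'   group in factor-level order).
#' @export
logrank_test <- function(times, events, groups) {
  if (length(unique(c(length(times), length(events), length(groups)))) != 1L) {
    stop("times, events and groups must align")
  }
  g <- as.factor(groups)
  if (nlevels(droplevels(g)) != 2L) stop("exactly two non-empty groups required")
  g <- droplevels(g)
  if (sum(events == 1) == 0L) stop("no events: log-rank statistic undefined")
  g1 <- g == levels(g)[1L]
  ut <- sort(unique(times[events == 1]))
  O1 <- 0; E1 <- 0; V <- 0; Otot <- 0
  for (u in ut) {
    at <- times >= u
    n <- sum(at); n1 <- sum(at & g1)
    d <- sum(times == u & events == 1)
    d1 <- sum(times == u & events == 1 & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    Otot <- Otot + d
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- if (V > 0) (O1 - E1)^2 / V else 0
  list(chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = stats::setNames(c(O1, Otot - O1), levels(g)),
       expected = stats::setNames(c(E1, Otot - E1), levels(g)))
}

#' Kaplan-Meier fit per group plus log-rank comparison
#'
#' @inheritParams logrank_test
#' @return a `survival_fit`: list with `fits` (one [km_estimate()] per group
#'   level) and `logrank` (the [logrank_test()] result).
#' @export
survival_fit <- function(times, events, groups) {
  g <- droplevels(as.factor(groups))
  fits <- lapply(levels(g), function(lv) km_estimate(times[g == lv], events[g == lv]))
  names(fits) <- levels(g)
  structure(list(fits = fits, logrank = logrank_test(times, events, g)),
            class = "survival_fit")
}

#' Evaluate a gene panel on an annotated cohort
#'
#' Per gene: AUC in the fixed tumor-positive orientation and the
#' orientation-free `max(AUC, 1-AUC)`; if stages are available, the four
#' tumor stage means and the monotone-trend flag; if survival is available,
#' the log-rank p-value of the median-split (high vs low expression, tumor
#' samples only). Panel-level: two-cluster purity (requires >= 2 samples per
#' class).
#'
#' @param matrix expression matrix containing at least the panel's genes.
#' @param annotations phenotype data.frame aligned to `matrix` columns.
#' @param genes character vector of panel gene ids.
#' @return list with `per_gene` (data.frame) and `purity` (scalar or `NA` if
#'   not computable).
#' @export
evaluate_panel <- function(matrix, annotations, genes) {
  validate_expression_matrix(matrix)
  missing_g <- setdiff(genes, rownames(matrix))
  if (length(missing_g) > 0) {
    stop("panel gene(s) absent from matrix: ", paste(missing_g, collapse = ", "))
  }
  if (!identical(colnames(matrix), annotations$sample_id)) {
    stop("annotations must be aligned to matrix columns (see align_samples)")
  }
  labels <- annotations$class
  tum <- as_class_labels(labels)

  has_stage <- any(!is.na(annotations$stage[tum]))
  surv_ok <- tum & !is.na(annotations$os_time) & !is.na(annotations$os_event)
  has_surv <- sum(annotations$os_event[surv_ok] == 1) > 0 && sum(surv_ok) >= 4

  rows <- lapply(genes, function(g) {
    x <- matrix[g, ]
    auc <- roc_auc(x, labels)
    row <- data.frame(gene = g, auc = auc, auc_oriented = max(auc, 1 - auc),
                      stringsAsFactors = FALSE)
    if (has_stage) {
      sm <- stage_means(x[tum], annotations$stage[tum])
      row$stage_mean_I <- sm[["I"]]; row$stage_mean_II <- sm[["II"]]
      row$stage_mean_III <- sm[["III"]]; row$stage_mean_IV <- sm[["IV"]]
      row$stage_monotone <- if (all(is.finite(sm))) stage_trend_monotone(sm)$monotone else NA
    }
    if (has_surv) {
      split <- median_split(x[surv_ok])
      row$logrank_p <- if (nlevels(droplevels(split)) == 2L) {
        logrank_test(annotations$os_time[surv_ok],
                     annotations$os_event[surv_ok], split)$p
      } else NA_real_
    }
    row
  })
  per_gene <- do.call(rbind, rows)

  purity <- if (sum(tum) >= 2 && sum(!tum) >= 2) {
    cluster_purity(matrix[genes, , drop = FALSE], labels)
  } else NA_real_
  list(per_gene = per_gene, purity = purity)
}
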