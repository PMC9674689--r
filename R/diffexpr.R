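#' Moderated two-group differential expression
#'
#' Re-implements the differential-expression path the pipeline's first filter
#' exercises: a per-gene two-group linear model (which for a tumor-vs-normal
#' contrast reduces to a difference of group means with a pooled variance),
#' empirical-Bayes moderation of the per-gene variances by a scaled
#' inverse-chi-square prior fitted by method of moments on log variances,
#' moderated t-statistics with augmented degrees of freedom,
#' Benjamini-Hochberg adjustment, and the DEG filter
#' `|logFC| > 1 & adj.P < 0.05` (both inequalities strict).
#'
#' @name diffexpr
NULL

#' Fit the two-group model per gene
#'
#' @param matrix expression matrix (genes x samples, log2 scale).
#' @param labels class labels per sample (see [as_class_labels()]).
#' @return data.frame with columns `gene`, `logFC` (tumor mean minus normal
#'   mean), `s2` (pooled within-group variance) and `df` (residual degrees of
#'   freedom, `n1 + n2 - 2`), with attributes `n1` (tumor) and `n2` (normal).
#' @export
fit_two_group <- function(matrix, labels) {
  validate_expression_matrix(matrix)
  tum <- as_class_labels(labels)
  if (length(tum) != ncol(matrix)) stop("one label per sample required")
  n1 <- sum(tum); n2 <- sum(!tum)
  if (n1 < 2L || n2 < 2L) {
    stop("each class needs at least 2 samples (variance undefined otherwise)")
  }
  x1 <- matrix[, tum, drop = FALSE]
  x2 <- matrix[, !tum, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  d <- n1 + n2 - 2L
  out <- data.frame(gene = rownames(matrix), logFC = m1 - m2,
                    s2 = ss / d, df = d,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n1") <- n1
  attr(out, "n2") <- n2
  out
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Assumes `s2 ~ s02 * F(df, d0)` and estimates the prior `(d0, s02)` by
#' matching the mean and variance of `log(s2)` to their theoretical values
#' through digamma/trigamma identities. Genes with `s2 = 0` are excluded
#' from the moment fit but still receive a posterior variance. When the
#' observed spread of log variances is no larger than pure chi-square
#' sampling noise, the prior degrees of freedom are infinite and every
#' posterior variance collapses to the common (mean) variance.
#'
#' @param s2 per-gene pooled variances.
#' @param df residual degrees of freedom (scalar, shared by all genes).
#' @return list with `prior_df` (`d0`, possibly `Inf`), `prior_var` (`s02`)
#'   and `post_var` (per-gene posterior variances
#'   `(d0*s02 + df*s2) / (d0 + df)`).
#' @export
ebayes_moderate <- function(s2, df) {
  stopifnot(length(df) == 1L, df >= 1, all(s2 >= 0))
  ok <- s2 > 0
  if (sum(ok) < 2L) stop("need at least two genes with positive variance")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    post <- (d0 * s02 + df * s2) / (d0 + df)
  } else {
    d0 <- Inf
    s02 <- mean(s2[ok])
    post <- rep(s02, length(s2))
  }
  list(prior_df = d0, prior_var = s02, post_var = post)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted values are the cumulative minimum, from the largest p downward,
#' of `p_(i) * m / i`, capped at 1 and returned in the original order.
#'
#' @param p raw p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

#' Full moderated differential-expression table
#'
#' Runs [fit_two_group()], [ebayes_moderate()] (unless an explicit prior is
#' supplied, e.g. `prior_df = 0` for the unmoderated pooled t), computes
#' moderated t-statistics `logFC / sqrt(post_var * (1/n1 + 1/n2))` on
#' `df + d0` degrees of freedom, two-sided p-values, BH adjustment, and the
#' pass flag. Genes with zero variance in both groups and zero logFC get
#' `p_raw = 1` (the 0/0 case carries no evidence either way).
#'
#' @param matrix expression matrix.
#' @param labels class labels per sample.
#' @param logfc_threshold log2 fold-change threshold (strict `>`), default 1.
#' @param alpha adjusted-p threshold (strict `<`), default 0.05.
#' @param prior_df,prior_var optional explicit prior, overriding the
#'   empirical-Bayes fit (`prior_df = 0` recovers the ordinary pooled t).
#' @return a `deg_table` data.frame: `gene`, `logFC`, `t_mod`, `df_total`,
#'   `p_raw`, `p_adj`, `pass`; prior and thresholds stored as attributes.
#' @export
deg_table <- function(matrix, labels, logfc_threshold = 1, alpha = 0.05,
                      prior_df = NULL, prior_var = NULL) {
  fit <- fit_two_group(matrix, labels)
  n1 <- attr(fit, "n1"); n2 <- attr(fit, "n2")
  d <- fit$df[1L]
  if (is.null(prior_df)) {
    eb <- ebayes_moderate(fit$s2, d)
    d0 <- eb$prior_df; s02 <- eb$prior_var; post <- eb$post_var
  } else {
    d0 <- prior_df
    s02 <- if (is.null(prior_var)) NA_real_ else prior_var
    post <- if (d0 == 0) fit$s2
            else if (is.infinite(d0)) rep(s02, nrow(fit))
            else (d0 * s02 + d * fit$s2) / (d0 + d)
  }
  se <- sqrt(post * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, fit$logFC / se,
                  ifelse(fit$logFC == 0, 0, sign(fit$logFC) * Inf))
  df_total <- d + d0
  p_raw <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p_raw[se == 0 & fit$logFC == 0] <- 1
  p_adj <- bh_adjust(p_raw)
  out <- data.frame(gene = fit$gene, logFC = fit$logFC, t_mod = t_mod,
                    df_total = df_total, p_raw = p_raw, p_adj = p_adj,
                    pass = abs(fit$logFC) > logfc_threshold & p_adj < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s02
  attr(out, "logfc_threshold") <- logfc_threshold
  attr(out, "alpha") <- alpha
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Extract the DEG set from a table
#'
#' Exactly the genes with `|logFC| > logfc_threshold` and
#' `p_adj < alpha`, both strict, re-evaluated from the table columns.
#'
#' @param table a `deg_table`.
#' @param logfc_threshold,alpha filter thresholds (defaults match the
#'   standard criterion `|logFC| > 1`, `adj.P < 0.05`).
#' @return character vector of passing gene ids, in table order.
#' @export
filter_degs <- function(table, logfc_threshold = 1, alpha = 0.05) {
  stopifnot(all(c("gene", "logFC", "p_adj") %in% colnames(table)))
  table$gene[abs(table$logFC) > logfc_threshold & table$p_adj < alpha]
}
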