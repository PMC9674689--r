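test_that("roc_auc equals the rank statistic, tumor-positive orientation", {
  labels <- c("tumor", "tumor", "normal", "normal")
  expect_equal(roc_auc(c(10, 9, 1, 2), labels), 1)
  expect_equal(roc_auc(c(3, 5, 1, 4), labels), 0.75)   # 3 of 4 pairs concordant
  # identical score multisets in both classes: exactly 0.5 by exchangeability
  expect_equal(roc_auc(c(1, 2, 1, 2), labels), 0.5)
  # a marker lower in tumors scores below 0.5 (no auto-flip)
  expect_lt(roc_auc(c(1, 2, 9, 10), labels), 0.5)
  expect_error(roc_auc(1:3, rep("tumor", 3)), "both classes")
})

test_that("roc_auc invariants: complement and monotone transforms", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    labels <- sample(c("tumor", "normal"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    x <- rnorm(n)
    a <- roc_auc(x, labels)
    expect_equal(a + roc_auc(-x, labels), 1)
    expect_equal(roc_auc(exp(2 * x) + 5, labels), a)   # strictly increasing map
  }
})

test_that("cluster_purity separates what is separable", {
  set.seed(22)
  n <- 40
  labels <- rep(c("tumor", "normal"), each = n / 2)
  m <- matrix(rnorm(5 * n), 5, n) + 10
  m[, labels == "tumor"] <- m[, labels == "tumor"] + 10   # 10 noise-SD gap
  dimnames(m) <- list(sprintf("g%d", 1:5), sprintf("s%d", 1:n))
  expect_equal(cluster_purity(m, labels), 1)

  # labels shuffled independently of the data: purity near the 0.5 baseline
  purities <- replicate(200, cluster_purity(m, sample(labels)))
  expect_lt(mean(purities), 0.68)
  expect_gte(min(purities), 0.5)
})

test_that("a single informative gene drives high purity (20 seeds)", {
  purities <- vapply(1:20, function(seed) {
    set.seed(seed)
    n <- 200
    labels <- rep(c("tumor", "normal"), each = n / 2)
    g <- rnorm(n) + ifelse(labels == "tumor", 3, 0)
    m <- matrix(g, 1, n, dimnames = list("g1", sprintf("s%d", 1:n)))
    cluster_purity(m, labels)
  }, numeric(1))
  expect_gt(mean(purities), 0.9)
})

test_that("stage trend flags monotone mean progressions", {
  up <- stage_trend_monotone(c(12.10, 12.16, 12.27, 12.40))
  expect_true(up$monotone); expect_equal(up$direction, "increasing")
  expect_true(stage_trend_monotone(c(8.36, 8.57, 8.58, 8.59))$monotone)
  down <- stage_trend_monotone(c(4, 3, 2, 2))
  expect_true(down$monotone); expect_equal(down$direction, "decreasing")
  expect_false(stage_trend_monotone(c(1, 3, 2, 4))$monotone)
  expect_error(stage_trend_monotone(c(1, 2, 3)), "4 finite")
})

test_that("stage_means uses only known-stage samples", {
  v <- c(1, 2, 3, 4, 100)
  st <- c("I", "II", "III", "IV", NA)
  expect_equal(stage_means(v, st), c(I = 1, II = 2, III = 3, IV = 4))
  expect_true(is.nan(stage_means(v, c("I", "I", "II", "II", NA))[["III"]]))
})

test_that("median_split sends median ties to low", {
  expect_equal(as.character(median_split(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(as.character(median_split(c(5, 5, 5))), rep("low", 3))
  expect_equal(as.character(median_split(c(5, 1, 5, 2))),
               c("high", "low", "high", "low"))
})

test_that("km_estimate reproduces hand product-limit results", {
  # deaths at 1, 2, 3, no censoring: empirical survival 2/3, 1/3, 0
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # all censored: flat at 1
  expect_equal(km_estimate(c(5, 8, 2), c(0, 0, 0))$surv, rep(1, 3))
  # mixed worked example 1+, 2, 3+, 4
  km2 <- km_estimate(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(km2$surv[km2$time == 2], 2 / 3)
  expect_equal(km2$surv[km2$time == 4], 0)
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("km_estimate agrees with survival::survfit and the hand oracle", {
  skip_if_not_installed("survival")
  set.seed(23)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    times <- round(rexp(n, 1 / 100)) + sample(0:3, n, replace = TRUE)
    events <- rbinom(n, 1, 0.7)
    if (sum(events) == 0) next
    km <- km_estimate(times, events)
    expect_equal(km$surv, oracle_km(times, events), tolerance = 1e-12)
    sf <- survival::survfit(survival::Surv(times, events) ~ 1)
    expect_equal(km$surv[match(sf$time, km$time)], sf$surv, tolerance = 1e-12)
  }
  # without censoring the KM equals the empirical survival function
  t2 <- c(3, 1, 4, 1, 5, 9, 2, 6)
  km3 <- km_estimate(t2, rep(1, 8))
  expect_equal(km3$surv, vapply(km3$time, function(u) mean(t2 > u), numeric(1)))
})

test_that("logrank_test matches survdiff and its degenerate cases", {
  # two groups holding identical copies of the same data: O = E exactly
  times <- c(1, 2, 3, 4, 1, 2, 3, 4)
  events <- c(1, 0, 1, 1, 1, 0, 1, 1)
  groups <- rep(c("a", "b"), each = 4)
  lr <- logrank_test(times, events, groups)
  expect_equal(lr$chisq, 0)
  expect_equal(lr$p, 1)

  expect_error(logrank_test(c(1, 2), c(0, 0), c("a", "b")), "no events")
  expect_error(logrank_test(1:3, c(1, 1, 1), rep("a", 3)), "two non-empty")

  skip_if_not_installed("survival")
  set.seed(24)
  for (i in 1:10) {
    n <- 40
    times <- rexp(n, 1 / 50)
    events <- rbinom(n, 1, 0.8)
    groups <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(groups)) < 2 || sum(events) == 0) next
    lr <- logrank_test(times, events, groups)
    sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
    expect_equal(lr$chisq, sd$chisq, tolerance = 1e-10)
  }

  # strictly earlier deaths in one group: decisive at large n
  n <- 100
  lr2 <- logrank_test(c(rexp(n, 1 / 20), rexp(n, 1 / 200)),
                      rep(1, 2 * n), rep(c("a", "b"), each = n))
  expect_lt(lr2$p, 0.01)
})

test_that("survival_fit bundles per-group KM and the log-rank comparison", {
  times <- c(5, 10, 15, 20, 3, 6, 9, 12)
  events <- c(1, 1, 0, 1, 1, 1, 1, 0)
  groups <- rep(c("high", "low"), each = 4)
  sf <- survival_fit(times, events, groups)
  expect_named(sf$fits, c("high", "low"))
  for (f in sf$fits) {
    expect_true(all(diff(f$surv) <= 1e-12))       # non-increasing
    expect_true(all(diff(f$n_risk) <= 0))
    expect_lte(f$surv[1], 1)
  }
  expect_equal(sf$logrank$chisq,
               logrank_test(times, events, groups)$chisq)
})

test_that("evaluate_panel assembles per-gene metrics and purity", {
  co <- generate_cohort(40, 60, 60, 4, effect_size = 3, seed = 31)
  full <- attach_stage_and_survival(co$matrix, co$annotations, co$truth,
                                    seed = 32, n_stage_genes = 2,
                                    n_survival_genes = 2)
  ev <- evaluate_panel(full$matrix, full$annotations,
                       full$truth$informative_genes)
  expect_equal(ev$per_gene$gene, full$truth$informative_genes)
  expect_true(all(ev$per_gene$auc_oriented >= 0.5))
  expect_true(all(ev$per_gene$auc_oriented >= ev$per_gene$auc - 1e-12))
  expect_true(all(c("stage_monotone", "logrank_p") %in% colnames(ev$per_gene)))
  expect_gt(ev$purity, 0.9)   # effect 3 on 4 genes separates cleanly
  expect_error(evaluate_panel(full$matrix, full$annotations, "NOPE"), "NOPE")
})
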