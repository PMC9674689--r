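test_that("step scores follow their defining formulas", {
  x <- rep(c(0L, 1L), each = 10)
  c <- c(rep(0L, 8), rep(1L, 2), rep(1L, 8), rep(0L, 2))  # noisy copy of x

  # empty S: both criteria fall back to marginal relevance
  expect_equal(mrmr_score(x, list(), c), mutual_information(x, c))
  expect_equal(jmi_score(x, list(), c), mutual_information(x, c))

  # candidate identical to the sole selected feature
  expect_equal(mrmr_score(x, list(x), c),
               mutual_information(x, c) - entropy(x))   # I(f;C) - H(f)
  expect_equal(jmi_score(x, list(x), c), mutual_information(x, c))

  # three-feature case composed from oracle MI values
  set.seed(11)
  f1 <- rand_codes(24, 3); f2 <- rand_codes(24, 3); f3 <- rand_codes(24, 3)
  cc <- rand_codes(24, 2)
  expect_equal(mrmr_score(f1, list(f2, f3), cc),
               oracle_mi(f1, cc) - mean(c(oracle_mi(f1, f2), oracle_mi(f1, f3))),
               tolerance = 1e-12)
  expect_equal(jmi_score(f1, list(f2, f3), cc),
               oracle_jmi(f1, f2, cc) + oracle_jmi(f1, f3, cc),
               tolerance = 1e-12)
})

test_that("JMI scores are non-negative; mRMR penalty can win", {
  set.seed(12)
  for (i in 1:20) {
    cand <- rand_codes(30, 3)
    sel <- list(rand_codes(30, 3), rand_codes(30, 3))
    cc <- rand_codes(30, 2)
    expect_gte(jmi_score(cand, sel, cc), -1e-12)
  }
  # a candidate identical to a selected feature but useless for C
  x <- rep(c(0L, 1L), 10)
  c_ind <- rep(c(0L, 0L, 1L, 1L), 5)      # balanced, independent of x
  expect_lt(mrmr_score(x, list(x), c_ind), 0)
})

test_that("greedy trace equals exhaustive per-step argmax (both criteria)", {
  m <- toy_matrix(10, 24, seed = 13)
  labels <- toy_labels(24)
  cl <- as.integer(labels == "tumor")
  disc <- lapply(seq_len(nrow(m)), function(i) as.vector(discretize(m[i, ], 4)))
  names(disc) <- rownames(m)
  for (crit in c("jmi", "mrmr")) {
    tr <- greedy_select(m, labels, k = 6, criterion = crit)
    or <- oracle_greedy(disc, cl, k = 6, criterion = crit)
    expect_equal(tr$steps$gene, or$gene, label = crit)
    expect_equal(tr$steps$score, or$score, tolerance = 1e-12, label = crit)
  }
})

test_that("stored candidate scores confirm each step's optimality", {
  m <- toy_matrix(8, 20, seed = 14)
  tr <- greedy_select(m, toy_labels(20), k = 5, criterion = "jmi")
  for (s in seq_along(tr$candidate_scores)) {
    scores <- tr$candidate_scores[[s]]
    expect_equal(unname(max(scores)), tr$steps$score[s])
    expect_true(all(scores <= tr$steps$score[s] + 1e-12))
  }
})

test_that("ties break by ascending gene id and k is validated", {
  # two identical genes: the lexicographically smaller id must win step 1
  m <- rbind(b_gene = c(1, 2, 3, 4, 5, 6, 7, 8),
             a_gene = c(1, 2, 3, 4, 5, 6, 7, 8),
             z_gene = c(8, 1, 7, 2, 6, 3, 5, 4))
  colnames(m) <- sprintf("s%d", 1:8)
  labels <- rep(c("tumor", "normal"), each = 4)
  tr <- greedy_select(m, labels, k = 2, criterion = "jmi", n_bins = 2)
  expect_equal(tr$steps$gene[1], "a_gene")
  expect_error(greedy_select(m, labels, k = 4), "exceeds")
  expect_error(greedy_select(m, labels, k = 0), "at least 1")
})

test_that("selection is invariant to gene row order (up to exact ties)", {
  m <- toy_matrix(9, 30, seed = 15)
  labels <- toy_labels(30)
  perm <- sample(nrow(m))
  a <- greedy_select(m, labels, k = 4)
  b <- greedy_select(m[perm, , drop = FALSE], labels, k = 4)
  expect_equal(a$steps$gene, b$steps$gene)
  expect_equal(a$steps$score, b$steps$score)
})

test_that("XOR synergy: JMI picks the partner with zero marginal relevance", {
  # c = x XOR y, perfectly balanced; z is balanced noise independent of
  # everything, so every step-1 relevance is exactly 0 and the documented
  # tie-break (ascending id) selects x first. Step 2 is the defining case:
  # y carries 1 bit jointly with x, z carries none.
  cell <- function(x, y) {
    z <- rep(c(0, 1), each = 2)      # balanced within each (x,y,c) cell
    data.frame(x = x, y = y, c = as.integer(xor(x, y)), z = z)
  }
  d <- do.call(rbind, list(cell(0, 0), cell(0, 1), cell(1, 0), cell(1, 1)))
  m <- rbind(a_x = d$x, b_y = d$y, c_z = d$z)
  colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  labels <- ifelse(d$c == 1, "tumor", "normal")

  expect_equal(mutual_information(d$y, d$c), 0)        # zero marginal relevance
  tr <- greedy_select(m, labels, k = 2, criterion = "jmi", n_bins = 2)
  expect_equal(tr$steps$gene, c("a_x", "b_y"))
  expect_equal(tr$steps$score[2], 1)                   # the full H(C) = 1 bit
  expect_equal(unname(tr$candidate_scores[[2]]["c_z"]), 0)
})

test_that("JMI avoids duplicating a selected parent", {
  # planted pair {A, B} plus a near-copy A' of A: k = 2 under JMI must take
  # the complementary gene B, not the duplicate
  set.seed(16)
  wins <- 0
  for (rep_i in 1:20) {
    n <- 300
    labels <- rep(c("tumor", "normal"), each = n)
    a <- rnorm(2 * n) + ifelse(labels == "tumor", 2, 0)
    b <- rnorm(2 * n) + ifelse(labels == "tumor", -2, 0)
    aprime <- 0.95 * scale(a)[, 1] + sqrt(1 - 0.95^2) * rnorm(2 * n)
    m <- rbind(A = a, B = b, Aprime = aprime)
    colnames(m) <- sprintf("s%d", seq_len(2 * n))
    tr <- greedy_select(m, labels, k = 2, criterion = "jmi")
    if (setequal(tr$steps$gene, c("A", "B"))) wins <- wins + 1
  }
  expect_equal(wins, 20)
})
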