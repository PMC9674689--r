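# Independent oracles, kept deliberately naive: explicit loops over
# contingency tables, sort-and-slice binning, hand product-limit. They never
# share code with the implementation they check.

oracle_entropy <- function(x) {
  h <- 0
  for (v in unique(x)) {
    p <- sum(x == v) / length(x)
    h <- h - p * log2(p)
  }
  h
}

# I(X;Y) by direct sum over the joint table: sum p log2(p / (px py))
oracle_mi <- function(x, y) {
  n <- length(x)
  total <- 0
  for (a in unique(x)) {
    for (b in unique(y)) {
      p <- sum(x == a & y == b) / n
      if (p > 0) {
        px <- sum(x == a) / n
        py <- sum(y == b) / n
        total <- total + p * log2(p / (px * py))
      }
    }
  }
  total
}

# I(X,Y;C) by triple loop over the (X,Y) x C table
oracle_jmi <- function(x, y, c) {
  n <- length(x)
  total <- 0
  for (a in unique(x)) {
    for (b in unique(y)) {
      for (k in unique(c)) {
        p <- sum(x == a & y == b & c == k) / n
        if (p > 0) {
          pxy <- sum(x == a & y == b) / n
          pc <- sum(c == k) / n
          total <- total + p * log2(p / (pxy * pc))
        }
      }
    }
  }
  total
}

# equal-frequency binning by sorting and slicing into B contiguous blocks,
# ties kept in original order, mapped back to input positions
oracle_discretize <- function(values, n_bins) {
  n <- length(values)
  ord <- order(values)            # stable: ties stay in input order
  block <- rep(seq_len(n_bins) - 1L, each = ceiling(n / n_bins))[seq_len(n)]
  codes <- integer(n)
  codes[ord] <- block
  codes
}

# exhaustive greedy re-evaluation built only on the oracle MI functions
oracle_greedy <- function(disc, cl, k, criterion) {
  genes <- names(disc)
  selected <- character(0)
  out <- data.frame(step = integer(0), gene = character(0), score = numeric(0))
  for (step in seq_len(k)) {
    remaining <- setdiff(genes, selected)
    scores <- sapply(remaining, function(g) {
      if (step == 1L) {
        oracle_mi(disc[[g]], cl)
      } else if (criterion == "jmi") {
        sum(sapply(selected, function(s) oracle_jmi(disc[[g]], disc[[s]], cl)))
      } else {
        oracle_mi(disc[[g]], cl) -
          mean(sapply(selected, function(s) oracle_mi(disc[[g]], disc[[s]])))
      }
    })
    best <- sort(remaining[scores >= max(scores) - 1e-12], method = "radix")[1L]
    selected <- c(selected, best)
    out <- rbind(out, data.frame(step = step, gene = best,
                                 score = unname(scores[best])))
  }
  out
}

# hand product-limit estimator over distinct times
oracle_km <- function(times, events) {
  s <- 1
  out <- numeric(0)
  for (u in sort(unique(times))) {
    at_risk <- sum(times >= u)
    d <- sum(times == u & events == 1)
    s <- s * (1 - d / at_risk)
    out <- c(out, s)
  }
  out
}

rand_codes <- function(n, n_bins) sample.int(n_bins, n, replace = TRUE) - 1L

# small deterministic expression fixture
toy_matrix <- function(n_genes = 6, n_samples = 8, seed = 42) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, mean = 8), n_genes, n_samples)
  dimnames(m) <- list(sprintf("G%02d", seq_len(n_genes)),
                      sprintf("S%02d", seq_len(n_samples)))
  m
}

toy_labels <- function(n_samples = 8) {
  rep(c("tumor", "normal"), length.out = n_samples)
}
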