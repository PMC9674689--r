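#' Plug-in information estimates on discretized expression
#'
#' The selection criteria need `I(f; C)`, `I(f_i; f_s)` and the joint
#' `I(f_i, f_s; C)` on continuous log-expression. Features are discretized
#' by equal-frequency binning (default 4 bins) and all quantities are
#' plug-in (maximum-likelihood) estimates in bits. The binary class variable
#' is used as-is. Criterion rankings are invariant to the log base and to
#' any relabelling of bin codes.
#'
#' @name infotheory
NULL

#' Equal-frequency discretization
#'
#' Samples are ranked (ties broken by original position, so the result is
#' deterministic) and split into `n_bins` contiguous rank blocks of equal
#' size, i.e. bin edges at the empirical `k/B` quantiles. A constant vector
#' maps to a single code 0: it carries no information and spreading ties
#' across bins would fabricate some.
#'
#' @param values finite numeric vector.
#' @param n_bins number of bins, >= 2.
#' @return integer codes in `0 .. n_bins-1`, with attribute `n_bins`.
#' @export
discretize <- function(values, n_bins = 4L) {
  stopifnot(n_bins >= 2L, length(values) >= 1L)
  if (anyNA(values) || any(!is.finite(values))) stop("values must be finite")
  n <- length(values)
  if (length(unique(values)) == 1L) {
    codes <- integer(n)
  } else {
    r <- rank(values, ties.method = "first")
    codes <- as.integer(floor((r - 1) * n_bins / n))
  }
  structure(codes, n_bins = as.integer(n_bins))
}

code_probs <- function(x) {
  as.numeric(table(as.vector(x))) / length(x)
}

#' Plug-in entropy in bits
#'
#' `H(X) = -sum p * log2 p` over observed codes, with `0 log 0 = 0`.
#'
#' @param x integer code vector (any discrete labels work).
#' @return entropy in bits.
#' @export
entropy <- function(x) {
  if (length(x) == 0L) stop("empty input")
  p <- code_probs(x)
  -sum(p * log2(p))
}

pair_codes <- function(x, y) {
  # product alphabet; actual label values are irrelevant to entropies
  as.integer(interaction(as.vector(x), as.vector(y), drop = TRUE)) - 1L
}

#' Plug-in mutual information in bits
#'
#' `I(X;Y) = H(X) + H(Y) - H(X,Y)`. Symmetric; non-negative up to floating
#' error; at most `min(H(X), H(Y))`.
#'
#' @param x,y equal-length discrete code vectors.
#' @return mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  entropy(x) + entropy(y) - entropy(pair_codes(x, y))
}

#' Joint (pairwise) mutual information with a class
#'
#' `I(X,Y;C)`: the information the pair `(X, Y)` carries about `C`, computed
#' as the mutual information between the product-alphabet pairing of `X` and
#' `Y` and `C`. Captures synergy (e.g. XOR) invisible to the marginal
#' relevances `I(X;C)`, `I(Y;C)`.
#'
#' @param x,y,c equal-length discrete code vectors; `c` is the class.
#' @return joint mutual information in bits.
#' @export
joint_mutual_information <- function(x, y, c) {
  if (length(x) != length(y) || length(x) != length(c)) stop("length mismatch")
  mutual_information(pair_codes(x, y), c)
}
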