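#' Normalize class labels to a tumor indicator
#'
#' Accepts a character vector or factor with values `"tumor"`/`"normal"`
#' (case-insensitive), or a logical vector (`TRUE` = tumor), and returns a
#' logical tumor indicator. Anything else is an error: the selection and
#' evaluation stages are defined for a two-class tumor-vs-normal contrast
#' and silently recoding arbitrary labels would hide phenotype-file bugs.
#'
#' @param labels character, factor or logical vector, one entry per sample.
#' @return logical vector, `TRUE` for tumor samples.
#' @keywords internal
as_class_labels <- function(labels) {
  if (is.logical(labels)) {
    if (anyNA(labels)) stop("class labels must not contain NA")
    return(labels)
  }
  x <- tolower(as.character(labels))
  bad <- setdiff(unique(x), c("tumor", "normal"))
  if (length(bad) > 0 || anyNA(labels)) {
    stop("invalid class label(s): ",
         paste(unique(c(bad, if (anyNA(labels)) NA)), collapse = ", "),
         " (expected 'tumor' or 'normal')")
  }
  x == "tumor"
}

# Locale-independent sort for deterministic tie-breaking on gene ids.
sort_c <- function(x) sort(x, method = "radix")

#' Inverse of the trigamma function
#'
#' Newton iteration on `trigamma(y) = x`, used by the method-of-moments fit
#' of the variance prior. Monotone decreasing, so the iteration started at
#' `0.5 + 1/x` converges quickly for all practical inputs.
#'
#' @param x positive numeric scalar (a trigamma value).
#' @return `y` such that `trigamma(y) = x`.
#' @keywords internal
trigamma_inverse <- function(x) {
  stopifnot(length(x) == 1L, is.finite(x))
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in seq_len(50L)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}
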