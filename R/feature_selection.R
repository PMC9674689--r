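#' Greedy information-theoretic panel selection
#'
#' Forward selection over a (typically DEG-filtered) expression matrix under
#' two step criteria. With `S` the already-selected set and `C` the class:
#'
#' * mRMR: `alpha(f_i) = I(f_i; C) - (1/|S|) * sum_{f_s in S} I(f_i; f_s)` —
#'   marginal relevance minus average pairwise redundancy.
#' * JMI:  `alpha(f_i) = sum_{f_s in S} I(f_i, f_s; C)` — summed joint
#'   information with each selected feature about the class, which rewards
#'   complementary features and ignores redundancy that adds nothing about
#'   `C`.
#'
#' Both criteria degenerate at the first step (the sum over `S` is empty),
#' so step 1 selects `argmax I(f; C)` under either criterion — the standard
#' convention in the information-theoretic selection literature. Ties are
#' broken by ascending gene id in C-locale order, so selection is a pure
#' function of `(matrix, labels, k, criterion, n_bins)`.
#'
#' @name feature_selection
NULL

#' mRMR step score
#'
#' @param candidate discretized candidate feature (code vector).
#' @param selected list of discretized already-selected features (may be
#'   empty, in which case the score is the plain relevance `I(f;C)`).
#' @param class discretized class vector.
#' @return score in bits (may be negative: the redundancy penalty can exceed
#'   the relevance).
#' @export
mrmr_score <- function(candidate, selected, class) {
  rel <- mutual_information(candidate, class)
  if (length(selected) == 0L) return(rel)
  red <- vapply(selected, function(s) mutual_information(candidate, s),
                numeric(1L))
  rel - mean(red)
}

#' JMI step score
#'
#' @inheritParams mrmr_score
#' @return score in bits (non-negative). With empty `selected` the score is
#'   the relevance `I(f;C)` (shared first-step convention).
#' @export
jmi_score <- function(candidate, selected, class) {
  if (length(selected) == 0L) return(mutual_information(candidate, class))
  sum(vapply(selected,
             function(s) joint_mutual_information(candidate, s, class),
             numeric(1L)))
}

#' Greedy forward selection of a gene panel
#'
#' Discretizes each gene once ([discretize()]), then at each step picks the
#' remaining gene maximizing the chosen criterion, recording the winning
#' score and (optionally) every candidate's score for audit.
#'
#' @param matrix expression matrix (rows = candidate genes, typically the
#'   DEG-filtered submatrix).
#' @param labels class labels per sample.
#' @param k panel size, `1 <= k <= nrow(matrix)`.
#' @param criterion `"jmi"` (default) or `"mrmr"`.
#' @param n_bins discretization bins, default 4.
#' @param store_scores keep each step's full candidate score vector
#'   (default `TRUE`).
#' @return a `selection_trace`: list with `steps` (data.frame `step`, `gene`,
#'   `score`), `candidate_scores` (list of named score vectors, or `NULL`),
#'   `criterion`, `n_bins`.
#' @export
greedy_select <- function(matrix, labels, k, criterion = c("jmi", "mrmr"),
                          n_bins = 4L, store_scores = TRUE) {
  validate_expression_matrix(matrix)
  criterion <- match.arg(criterion)
  genes <- rownames(matrix)
  if (k < 1L) stop("k must be at least 1")
  if (k > length(genes)) {
    stop(sprintf("k = %d exceeds the number of candidate genes (%d)",
                 k, length(genes)))
  }
  tum <- as_class_labels(labels)
  if (length(tum) != ncol(matrix)) stop("one label per sample required")
  cl <- as.integer(tum)
  disc <- lapply(seq_len(nrow(matrix)),
                 function(i) discretize(matrix[i, ], n_bins = n_bins))
  names(disc) <- genes

  selected <- character(0)
  steps <- data.frame(step = integer(0), gene = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  cand_scores <- if (store_scores) vector("list", k) else NULL

  for (step in seq_len(k)) {
    remaining <- setdiff(genes, selected)
    scorer <- if (step == 1L) {
      function(g) mutual_information(disc[[g]], cl)
    } else if (criterion == "jmi") {
      function(g) jmi_score(disc[[g]], disc[selected], cl)
    } else {
      function(g) mrmr_score(disc[[g]], disc[selected], cl)
    }
    scores <- vapply(remaining, scorer, numeric(1L))
    best <- sort_c(remaining[scores == max(scores)])[1L]
    selected <- c(selected, best)
    steps <- rbind(steps, data.frame(step = step, gene = best,
                                     score = scores[[best]],
                                     stringsAsFactors = FALSE))
    if (store_scores) cand_scores[[step]] <- scores
  }

  structure(list(steps = steps, candidate_scores = cand_scores,
                 criterion = criterion, n_bins = as.integer(n_bins)),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("Greedy %s selection trace (%d bins):\n",
              toupper(x$criterion), x$n_bins))
  print(x$steps, row.names = FALSE)
  invisible(x)
}
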