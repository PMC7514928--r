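# Per-sample classifier combination and evaluation, plus the
# confusion-matrix rank-likelihood and independence diagnostics.

#' Convert classifier scores to a rank vector
#'
#' The highest score receives rank 1.  Ties are broken deterministically in
#' favour of the smaller class index, so the result is always a total order.
#'
#' @param scores a finite numeric vector, one score per class.
#' @return an integer permutation of `1..K`.
#' @examples
#' scores_to_ranks(c(0.7, 0.2, 0.1))  # 1 2 3
#' @export
scores_to_ranks <- function(scores) {
  if (anyNA(scores) || any(!is.finite(scores))) {
    rf_validation_error("scores must be finite and non-missing")
  }
  as.integer(rank(-scores, ties.method = "first"))
}

#' Construct a batch of per-sample ensemble rankings
#'
#' A sample batch holds, for each of `n` observations, the `K x M` rank
#' matrix produced by the `M` classifiers, together with optional true
#' labels and the designated positive class for FPR/FNR evaluation.
#'
#' @param rank_tensor a `K x M x n` integer array; slice `[, , i]` must
#'   satisfy the rank-matrix invariants.
#' @param true_labels optional length-`n` integer vector of true class
#'   indices in `1..K`.
#' @param positive_class optional class index designated "positive" (e.g.
#'   the atypical-cell class in a cytology screen).
#' @param class_labels optional `K` class names.
#' @param classifier_labels optional `M` classifier names.
#' @return an object of class `sample_batch`.
#' @export
sample_batch <- function(rank_tensor, true_labels = NULL, positive_class = NULL,
                         class_labels = NULL, classifier_labels = NULL) {
  d <- dim(rank_tensor)
  if (length(d) != 3L) rf_validation_error("rank_tensor must be a K x M x n array")
  K <- d[1L]; M <- d[2L]; n <- d[3L]
  if (is.null(class_labels)) class_labels <- paste0("C", seq_len(K))
  if (is.null(classifier_labels)) classifier_labels <- paste0("K", seq_len(M))
  for (i in seq_len(n)) {
    for (k in seq_len(M)) {
      msg <- permutation_problem(rank_tensor[, k, i])
      if (!is.null(msg)) {
        rf_validation_error(sprintf("sample %d, classifier %d: %s", i, k, msg))
      }
    }
  }
  if (!is.null(true_labels)) {
    if (length(true_labels) != n) rf_validation_error("true_labels length != n")
    if (anyNA(true_labels) || any(true_labels < 1L | true_labels > K)) {
      rf_validation_error("true_labels must be class indices in 1..K")
    }
    true_labels <- as.integer(true_labels)
  }
  if (!is.null(positive_class)) {
    positive_class <- as.integer(positive_class)
    if (positive_class < 1L || positive_class > K) {
      rf_validation_error("positive_class must be a class index in 1..K")
    }
  }
  storage.mode(rank_tensor) <- "integer"
  structure(list(ranks = rank_tensor, n = n, K = K, M = M,
                 true_labels = true_labels, positive_class = positive_class,
                 class_labels = class_labels, classifier_labels = classifier_labels),
            class = "sample_batch")
}

#' @export
print.sample_batch <- function(x, ...) {
  cat(sprintf("Sample batch: %d samples, %d classes, %d classifiers%s\n",
              x$n, x$K, x$M,
              if (is.null(x$true_labels)) " (unlabeled)" else " (labeled)"))
  invisible(x)
}

#' Extract one sample's rank matrix from a batch
#' @param batch a [sample_batch()].
#' @param i sample index.
#' @return a [rank_matrix()].
#' @export
batch_rank_matrix <- function(batch, i) {
  rank_matrix(batch$ranks[, , i],
              class_labels = batch$class_labels,
              classifier_labels = batch$classifier_labels)
}

#' Combine a batch of ensemble rankings into class decisions
#'
#' For each sample, computes the exact consensus ranking of its `M`
#' classifier rankings under the chosen metric and predicts the class with
#' consensus rank 1 — the combination map from individual rankings to a
#' final decision.  Each sample is solved independently.
#'
#' @param batch a [sample_batch()].
#' @param metric `"disagreement"` or `"condorcet"`.
#' @param keep_results if `TRUE`, the per-sample `consensus_result` objects
#'   are returned too (slower on large batches only in memory, not time).
#' @return a list with `predictions` (length-`n` integer class indices),
#'   `tiebreak` (logical, whether the sample's consensus needed the
#'   deterministic tie-break) and, if requested, `results`.
#' @export
combine_batch <- function(batch, metric = c("disagreement", "condorcet"),
                          keep_results = FALSE) {
  metric <- match.arg(metric)
  stopifnot(inherits(batch, "sample_batch"))
  solver <- if (metric == "disagreement") solve_disagreement else solve_condorcet
  predictions <- integer(batch$n)
  tiebreak <- logical(batch$n)
  results <- if (keep_results) vector("list", batch$n) else NULL
  for (i in seq_len(batch$n)) {
    res <- solver(batch_rank_matrix(batch, i))
    predictions[i] <- which(res$ranks == 1L)
    tiebreak[i] <- isTRUE(res$tiebreak_applied)
    if (keep_results) results[[i]] <- res
  }
  out <- list(predictions = predictions, tiebreak = tiebreak)
  if (keep_results) out$results <- results
  out
}

#' Evaluate predictions against true labels
#'
#' Computes the overall error rate and, relative to a designated positive
#' class, the false positive rate `FPR = FP / N` (negatives predicted
#' positive over all negatives) and the false negative rate `FNR = FN / P`
#' (positives predicted non-positive over all positives).  When there are no
#' negatives (or no positives) the corresponding rate is reported as `NA`,
#' never as 0 — in screening applications these two rates carry asymmetric
#' risk and must not be silently conflated.
#'
#' @param predictions,true_labels equal-length integer class-index vectors.
#' @param positive_class the class index counted as "positive".
#' @return an `evaluation_report`: list with `error_rate`, `fpr`, `fnr`,
#'   `n_evaluated`.
#' @export
evaluate_predictions <- function(predictions, true_labels, positive_class) {
  if (length(predictions) != length(true_labels)) {
    rf_validation_error("predictions and true_labels must have equal length")
  }
  keep <- !is.na(true_labels)
  predictions <- predictions[keep]
  true_labels <- true_labels[keep]
  n <- length(true_labels)
  if (n == 0L) rf_validation_error("no labeled samples to evaluate")
  err <- mean(predictions != true_labels)
  pos <- true_labels == positive_class
  P <- sum(pos)
  N <- n - P
  fpr <- if (N > 0L) sum(predictions[!pos] == positive_class) / N else NA_real_
  fnr <- if (P > 0L) sum(predictions[pos] != positive_class) / P else NA_real_
  structure(list(error_rate = err, fpr = fpr, fnr = fnr, n_evaluated = n),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d labeled samples: error rate %.4f, FPR %s, FNR %s\n",
              x$n_evaluated, x$error_rate,
              if (is.na(x$fpr)) "undefined (no negatives)" else sprintf("%.4f", x$fpr),
              if (is.na(x$fnr)) "undefined (no positives)" else sprintf("%.4f", x$fnr)))
  invisible(x)
}

#' Rank likelihoods from a confusion matrix
#'
#' From a confusion matrix whose entry `(j, k)` counts how many times true
#' class `j` was ranked `k`-th by a classifier, estimates the conditional
#' rank likelihoods `p(rank = k | class = j) = n[j, k] / n[j, .]`.  These
#' are diagnostics of individual classifier behaviour, not a fusion rule:
#' at prediction time the true class is unknown, so the confusion matrix
#' cannot itself drive the combination.
#'
#' @param counts a `K x K` matrix of non-negative counts (rows: true
#'   classes, columns: rank positions).
#' @return a row-stochastic `K x K` numeric matrix.
#' @export
rank_likelihoods <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) rf_validation_error("confusion counts must be non-negative")
  marg <- rowSums(counts)
  zero <- which(marg == 0)
  if (length(zero)) {
    rf_validation_error(sprintf(
      "zero row marginal for class%s %s: likelihoods undefined",
      if (length(zero) > 1L) "es" else "", paste(zero, collapse = ", ")))
  }
  sweep(counts, 1L, marg, "/")
}

#' Empirical deviation from pairwise decision independence
#'
#' Two classifiers are independent when their joint decision distribution
#' factorises: `p(u1 = j, u2 = l) = p(u1 = j) p(u2 = l)` for all class
#' pairs.  This returns the largest absolute gap between the empirical
#' joint and the product of the empirical marginals.  0 indicates empirical
#' factorisation; for two perfectly correlated binary deciders over
#' equiprobable classes the gap is 0.25.  Note that accurate classifiers
#' are necessarily dependent in this marginal sense: for a binary problem
#' with equiprobable classes the marginal decision probability is 1/2
#' whatever the accuracy (see [marginal_decision_probability()]), so a
#' factorising joint would force the classifiers to be random.
#'
#' @param decisions_a,decisions_b equal-length vectors of decided class
#'   indices.
#' @return a number in `[0, 1]`.
#' @export
pairwise_independence_gap <- function(decisions_a, decisions_b) {
  if (length(decisions_a) != length(decisions_b)) {
    rf_validation_error("decision streams must have equal length")
  }
  n <- length(decisions_a)
  if (n < 1L) rf_validation_error("need at least one decision")
  lev <- sort(unique(c(decisions_a, decisions_b)))
  a <- factor(decisions_a, levels = lev)
  b <- factor(decisions_b, levels = lev)
  joint <- table(a, b) / n
  prod <- outer(table(a) / n, table(b) / n)
  max(abs(joint - prod))
}

#' Marginal decision probability of a symmetric binary classifier
#'
#' For a binary problem with class priors `priors` and a classifier whose
#' correct-classification probability is `alpha` for both classes, the total
#' probability rule gives `p(u = c1) = alpha * p(c1) + (1 - alpha) * p(c2)`.
#' With equiprobable classes this is 1/2 for every `alpha` — the marginal
#' output distribution carries no information about accuracy, which is why
#' unconditional independence is the wrong notion for useful ensembles.
#'
#' @param alpha correct-classification probability in `[0, 1]`.
#' @param priors length-2 prior vector summing to 1.
#' @return `p(u = c1)`.
#' @export
marginal_decision_probability <- function(alpha, priors = c(0.5, 0.5)) {
  if (length(priors) != 2L || abs(sum(priors) - 1) > 1e-12 || any(priors < 0)) {
    rf_validation_error("priors must be a length-2 simplex vector")
  }
  if (alpha < 0 || alpha > 1) rf_validation_error("alpha must lie in [0, 1]")
  alpha * priors[1L] + (1 - alpha) * priors[2L]
}
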