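# Core types: rank matrices and their three equivalent representations
# (rank vector, permutation matrix, pairwise-preference matrix), plus the
# position and pair tallies that the consensus solvers consume.

#' Classed error helpers
#'
#' Validation problems signal a condition of class `rankfuse_validation_error`;
#' problem sizes beyond an exact solver's ceiling signal
#' `rankfuse_capability_error`.  The command-line wrapper maps these to exit
#' codes 2 and 3.
#' @noRd
rf_validation_error <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("rankfuse_validation_error", "rankfuse_error")))
}

#' @noRd
rf_capability_error <- function(msg) {
  stop(errorCondition(msg, class = c("rankfuse_capability_error", "rankfuse_error")))
}

#' Check that a vector is a permutation of 1..K
#'
#' Returns `NULL` when valid, otherwise a message naming the duplicated and
#' missing rank values (used so file readers can prepend coordinates).
#' @noRd
permutation_problem <- function(r) {
  K <- length(r)
  if (K < 1L) return("empty rank vector")
  if (anyNA(r)) return("missing (NA) rank values")
  if (!is.numeric(r) || any(r != as.integer(r))) return("non-integer rank values")
  r <- as.integer(r)
  if (!setequal(r, seq_len(K))) {
    dup <- sort(unique(r[duplicated(r)]))
    mis <- setdiff(seq_len(K), r)
    return(sprintf(
      "not a permutation of 1..%d (duplicated rank%s: %s; missing rank%s: %s)",
      K,
      if (length(dup) == 1L) "" else "s", paste(dup, collapse = ", "),
      if (length(mis) == 1L) "" else "s",
      if (length(mis)) paste(mis, collapse = ", ") else "none"))
  }
  NULL
}

#' Assert that a vector is a permutation of 1..K
#' @noRd
assert_permutation <- function(r, what = "rank vector") {
  msg <- permutation_problem(r)
  if (!is.null(msg)) rf_validation_error(paste0(what, ": ", msg))
  invisible(as.integer(r))
}

#' Construct a validated rank matrix
#'
#' A rank matrix holds the total order rankings that `M` classifiers assign to
#' `K` classes: entry `(i, k)` is the rank given to class `i` by classifier
#' `k`, and every column must be a permutation of `1..K` (rank 1 = most
#' likely).  Ties and partial rankings are rejected.
#'
#' @param ranks a `K x M` integer matrix, one column per classifier.
#' @param class_labels optional character vector of `K` class names
#'   (defaults to existing rownames or `C1..CK`).
#' @param classifier_labels optional character vector of `M` classifier names
#'   (defaults to existing colnames or `K1..KM`).
#' @return an object of class `rank_matrix`: the integer matrix with class and
#'   classifier labels as dimnames.
#' @examples
#' R <- rank_matrix(cbind(c(1, 2, 3), c(2, 1, 3)))
#' tally_positions(R)
#' @export
rank_matrix <- function(ranks, class_labels = NULL, classifier_labels = NULL) {
  ranks <- as.matrix(ranks)
  K <- nrow(ranks)
  M <- ncol(ranks)
  if (K < 2L) rf_validation_error("a rank matrix needs at least 2 classes")
  if (M < 1L) rf_validation_error("a rank matrix needs at least 1 classifier")
  if (is.null(class_labels)) {
    class_labels <- rownames(ranks)
    if (is.null(class_labels)) class_labels <- paste0("C", seq_len(K))
  }
  if (is.null(classifier_labels)) {
    classifier_labels <- colnames(ranks)
    if (is.null(classifier_labels)) classifier_labels <- paste0("K", seq_len(M))
  }
  if (length(class_labels) != K) rf_validation_error("class_labels length != K")
  if (length(classifier_labels) != M) rf_validation_error("classifier_labels length != M")
  if (anyDuplicated(class_labels)) rf_validation_error("duplicated class labels")
  for (k in seq_len(M)) {
    msg <- permutation_problem(ranks[, k])
    if (!is.null(msg)) {
      rf_validation_error(sprintf("column %d (classifier '%s'): %s",
                                  k, classifier_labels[k], msg))
    }
  }
  storage.mode(ranks) <- "integer"
  dimnames(ranks) <- list(as.character(class_labels), as.character(classifier_labels))
  structure(ranks, class = c("rank_matrix", "matrix", "array"))
}

#' @export
print.rank_matrix <- function(x, ...) {
  cat(sprintf("Rank matrix: %d classes x %d classifiers (rank 1 = most likely)\n",
              nrow(x), ncol(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Number of classes / classifiers of a rank matrix
#' @param R a `rank_matrix`.
#' @return an integer.
#' @export
n_classes <- function(R) nrow(R)

#' @rdname n_classes
#' @export
n_classifiers <- function(R) ncol(R)

#' Convert a rank vector to its permutation matrix
#'
#' The permutation matrix `P` of a ranking has `P[i, j] = 1` exactly when
#' class `i` occupies position `j` (i.e. has rank `j`).
#'
#' @param r a permutation of `1..K`.
#' @return a `K x K` binary integer matrix with unit row and column sums.
#' @seealso [permutation_matrix_to_ranks()] for the inverse.
#' @export
ranks_to_permutation_matrix <- function(r) {
  r <- assert_permutation(r)
  K <- length(r)
  P <- matrix(0L, K, K)
  P[cbind(seq_len(K), r)] <- 1L
  P
}

#' Recover the rank vector from a permutation matrix
#'
#' Inverts [ranks_to_permutation_matrix()]: `r_i = sum_j j * P[i, j]`.
#'
#' @param P a `K x K` binary matrix with unit row and column sums.
#' @return an integer permutation of `1..K`.
#' @export
permutation_matrix_to_ranks <- function(P) {
  P <- as.matrix(P)
  K <- nrow(P)
  if (ncol(P) != K) rf_validation_error("permutation matrix must be square")
  if (!all(P %in% c(0L, 1L))) rf_validation_error("permutation matrix entries must be 0/1")
  if (any(rowSums(P) != 1L) || any(colSums(P) != 1L)) {
    rf_validation_error("permutation matrix rows and columns must each sum to 1")
  }
  as.integer(P %*% seq_len(K))
}

#' Convert a rank vector to its pairwise-preference matrix
#'
#' `Y[i, j] = 1` exactly when the ranking prefers class `i` to class `j`
#' (`r_i < r_j`).  For a total order Y is antisymmetric off the diagonal
#' (`Y[i,j] + Y[j,i] = 1`) and transitive, and its entries sum to
#' `K(K-1)/2`.
#'
#' @param r a permutation of `1..K`.
#' @return a `K x K` binary integer matrix with zero diagonal.
#' @export
ranks_to_pair_matrix <- function(r) {
  r <- assert_permutation(r)
  Y <- outer(r, r, "<")
  storage.mode(Y) <- "integer"
  Y
}

#' Tally class positions across an ensemble
#'
#' Builds the position tally `pi`: `pi[i, j]` is the number of classifiers
#' that place class `i` at position `j`.  Because every classifier fills each
#' position exactly once, every row and every column of `pi` sums to `M`.
#' The assignment cost used by the disagreement consensus is `M - pi`.
#'
#' @param R a [rank_matrix()].
#' @return a `K x K` integer matrix of class `position_tally`, with the
#'   classifier count attached as attribute `M`.
#' @export
tally_positions <- function(R) {
  R <- as_rank_matrix(R)
  K <- nrow(R)
  M <- ncol(R)
  pi <- matrix(0L, K, K, dimnames = list(rownames(R), paste0("pos", seq_len(K))))
  for (k in seq_len(M)) {
    idx <- cbind(seq_len(K), R[, k])
    pi[idx] <- pi[idx] + 1L
  }
  structure(pi, M = M, class = c("position_tally", "matrix", "array"))
}

#' Tally pairwise preferences across an ensemble
#'
#' Builds the pair tally `delta`: `delta[i, j]` is the number of classifiers
#' preferring class `i` to class `j` (ranking `i` before `j`).  For total
#' orders `delta[i, j] + delta[j, i] = M` off the diagonal and the entries sum
#' to `M * K * (K - 1) / 2`.  This matrix is the input of the Condorcet
#' (linear ordering) consensus problem.
#'
#' @param R a [rank_matrix()].
#' @return a `K x K` integer matrix of class `pair_tally`, with the classifier
#'   count attached as attribute `M`.
#' @export
tally_pairs <- function(R) {
  R <- as_rank_matrix(R)
  K <- nrow(R)
  M <- ncol(R)
  delta <- matrix(0L, K, K, dimnames = list(rownames(R), rownames(R)))
  for (k in seq_len(M)) {
    delta <- delta + ranks_to_pair_matrix(R[, k])
  }
  structure(delta, M = M, class = c("pair_tally", "matrix", "array"))
}

#' @export
print.position_tally <- function(x, ...) {
  cat(sprintf("Position tally (M = %d classifiers): pi[i, j] = #classifiers placing class i at position j\n",
              attr(x, "M")))
  print(matrix(x, nrow(x), dimnames = dimnames(x)), ...)
  invisible(x)
}

#' @export
print.pair_tally <- function(x, ...) {
  cat(sprintf("Pair tally (M = %d classifiers): delta[i, j] = #classifiers preferring class i to class j\n",
              attr(x, "M")))
  print(matrix(x, nrow(x), dimnames = dimnames(x)), ...)
  invisible(x)
}

#' Coerce to a rank matrix
#' @noRd
as_rank_matrix <- function(R) {
  if (inherits(R, "rank_matrix")) R else rank_matrix(R)
}

#' Consensus result container
#' @noRd
consensus_result <- function(ranks, objective, metric, class_labels,
                             optimum_count_hint = NA_integer_,
                             tiebreak_applied = FALSE) {
  ranks <- as.integer(ranks)
  names(ranks) <- class_labels
  structure(
    list(ranks = ranks, objective = objective, metric = metric,
         optimum_count_hint = optimum_count_hint,
         tiebreak_applied = tiebreak_applied),
    class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus ranking (%s metric), objective = %s\n",
              x$metric, format(x$objective)))
  print(x$ranks)
  if (!is.na(x$optimum_count_hint) && x$optimum_count_hint > 1L) {
    cat(sprintf("%d optimal orders exist; deterministic tie-break %s\n",
                x$optimum_count_hint,
                if (isTRUE(x$tiebreak_applied)) "applied" else "not needed"))
  }
  invisible(x)
}

#' Enumerate all permutations of 1..K
#'
#' Rows are permutations, in lexicographic order.  Used by the exhaustive
#' consensus backend and by the test oracles.  Intended for small `K`
#' (`K <= 9` is practical).
#'
#' @param K number of elements.
#' @return a `K! x K` integer matrix.
#' @export
all_permutations <- function(K) {
  K <- as.integer(K)
  if (K < 1L) rf_validation_error("K must be >= 1")
  if (K > 9L) rf_capability_error(sprintf("refusing to enumerate %d! permutations (K = %d > 9)", K, K))
  if (K == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(K - 1L)
  n <- nrow(sub)
  out <- matrix(0L, n * K, K)
  for (v in seq_len(K)) {
    rows <- (v - 1L) * n + seq_len(n)
    out[rows, 1L] <- v
    rest <- sub
    rest[rest >= v] <- rest[rest >= v] + 1L
    out[rows, -1L] <- rest
  }
  out
}

#' Evaluate .Random.seed-preserving seeded code
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}
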