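# Inter-ranking distances and the two consensus objective functions.
#
# Both distances count rather than measure and return exact integers:
# the disagreement distance is Hamming distance on the position vectors,
# the Condorcet distance is Kendall tau (number of discordant pairs).

#' Disagreement distance between two rankings
#'
#' Counts the classes placed at different positions by the two rankings
#' (Hamming distance on rank vectors).  The value is 0 iff `r == s` and can
#' never be 1 for permutations.
#'
#' @param r,s permutations of `1..K`.
#' @return a non-negative integer in `{0, 2, 3, ..., K}`.
#' @export
disagreement_distance <- function(r, s) {
  r <- assert_permutation(r)
  s <- assert_permutation(s, "second rank vector")
  if (length(r) != length(s)) rf_validation_error("rank vectors have different lengths")
  sum(r != s)
}

#' Condorcet distance between two rankings
#'
#' Counts the class pairs on whose relative order the two rankings disagree
#' (Kendall tau distance).  Maximum is `K(K-1)/2`, attained at full reversal.
#'
#' @param r,s permutations of `1..K`.
#' @return a non-negative integer.
#' @export
condorcet_distance <- function(r, s) {
  r <- assert_permutation(r)
  s <- assert_permutation(s, "second rank vector")
  if (length(r) != length(s)) rf_validation_error("rank vectors have different lengths")
  dr <- outer(r, r, "<")
  ds <- outer(s, s, "<")
  sum(dr & !ds)
}

#' Disagreement consensus objective
#'
#' `phi_d(r) = sum_k f_d(r, r^(k))`, the total disagreement between a
#' candidate ranking and every column of the rank matrix.  Computed through
#' the position tally as `sum_ij (M - pi[i, j]) * x[i, j]`, i.e.
#' `K * M - sum_i pi[i, r_i]`, which is linear in the candidate's
#' permutation matrix — the objective of the assignment formulation.
#'
#' @param r a candidate permutation of `1..K`.
#' @param R a [rank_matrix()] (or coercible) with the same number of classes.
#' @return a non-negative integer.
#' @export
phi_disagreement <- function(r, R) {
  R <- as_rank_matrix(R)
  r <- assert_permutation(r)
  if (length(r) != nrow(R)) rf_validation_error("candidate length != number of classes")
  pi <- tally_positions(R)
  phi_disagreement_from_tally(r, pi)
}

#' @noRd
phi_disagreement_from_tally <- function(r, pi) {
  K <- nrow(pi)
  M <- attr(pi, "M")
  as.integer(K * M - sum(pi[cbind(seq_len(K), r)]))
}

#' Condorcet consensus objective
#'
#' `phi_C(r) = sum_k f_C(r, r^(k))`, the total Kendall tau distance between a
#' candidate ranking and every column.  Equals `theta - sum_ij delta[i, j] *
#' y[i, j]` where `delta` is the pair tally, `y` the candidate's
#' pairwise-preference matrix and `theta = M * K * (K - 1) / 2` — so
#' minimising `phi_C` is the linear ordering problem of maximising the
#' pairwise vote score `sum delta[i, j] y[i, j]`.
#'
#' @inheritParams phi_disagreement
#' @return a non-negative integer.
#' @export
phi_condorcet <- function(r, R) {
  R <- as_rank_matrix(R)
  r <- assert_permutation(r)
  if (length(r) != nrow(R)) rf_validation_error("candidate length != number of classes")
  delta <- tally_pairs(R)
  phi_condorcet_from_tally(r, delta)
}

#' @noRd
condorcet_theta <- function(delta) {
  K <- nrow(delta)
  M <- attr(delta, "M")
  # theta = (M*K*(K-1)/2 + sum(delta)) / 2; for total orders sum(delta) equals
  # M*K*(K-1)/2, so theta is the integer M*K*(K-1)/2.  Kept in the two-term
  # form so the identity is explicit.
  s <- (M * K * (K - 1L)) %/% 2L + sum(delta)
  stopifnot(s %% 2L == 0L)
  s %/% 2L
}

#' @noRd
condorcet_score <- function(r, delta) {
  y <- outer(r, r, "<")
  sum(delta[y])
}

#' @noRd
phi_condorcet_from_tally <- function(r, delta) {
  as.integer(condorcet_theta(delta) - condorcet_score(r, delta))
}
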