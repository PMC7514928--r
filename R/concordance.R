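# Conjunction coefficients: agreement statistics for a classifier ensemble,
# analogous to Kendall's W.  Both coefficients equal 1 exactly when all M
# classifiers produce the identical ranking.  Numerators are integer-exact;
# the single division happens last.

#' Condorcet conjunction coefficient
#'
#' Quantifies ensemble agreement from the pair tally:
#' `I_C = 4 * sum_ij delta[i,j] * (delta[i,j] - 1) / (M (M-1) K (K-1)) - 1`.
#' Equals 1 iff all classifiers produce the identical ranking; its attainable
#' lower bound depends on the parity of `M` (see [ic_bounds()]).
#'
#' @param x a `pair_tally` from [tally_pairs()], or a [rank_matrix()] (the
#'   tally is then computed internally).
#' @return a `concordance_report`: list with `metric`, `coefficient`, `M`,
#'   `K`, `lower_bound`, `upper_bound`.
#' @examples
#' R <- rank_matrix(cbind(c(1, 2, 3), c(1, 2, 3)))
#' conjunction_condorcet(R)$coefficient  # unanimous ensemble: 1
#' @export
conjunction_condorcet <- function(x) {
  delta <- if (inherits(x, "pair_tally")) x else tally_pairs(as_rank_matrix(x))
  M <- attr(delta, "M")
  K <- nrow(delta)
  if (M < 2L) rf_validation_error("the conjunction coefficient is undefined for M < 2 classifiers")
  num <- sum(delta * (delta - 1L))  # integer-exact
  coef <- 4 * num / (as.numeric(M) * (M - 1L) * K * (K - 1L)) - 1
  b <- ic_bounds(M, K)
  concordance_report("condorcet", coef, M, K, b$lower, 1)
}

#' Disagreement conjunction coefficient
#'
#' Positional agreement statistic built from the position tally:
#' `I_d = sum_ij pi[i,j] * (pi[i,j] - 1) / (K M (M-1))` — the probability
#' that two distinct classifiers drawn at random agree on the position of a
#' random class.  Lies in `[0, 1]`: 1 iff all rankings are identical, 0 iff
#' no (class, position) cell receives two votes (e.g. cyclic-shift
#' ensembles with `M <= K`).
#'
#' @param x a `position_tally` from [tally_positions()], or a
#'   [rank_matrix()].
#' @return a `concordance_report` (see [conjunction_condorcet()]).
#' @export
conjunction_disagreement <- function(x) {
  pi <- if (inherits(x, "position_tally")) x else tally_positions(as_rank_matrix(x))
  M <- attr(pi, "M")
  K <- nrow(pi)
  if (M < 2L) rf_validation_error("the conjunction coefficient is undefined for M < 2 classifiers")
  num <- sum(pi * (pi - 1L))
  coef <- num / (as.numeric(K) * M * (M - 1L))
  concordance_report("disagreement", coef, M, K, 0, 1)
}

#' @noRd
concordance_report <- function(metric, coefficient, M, K, lower, upper) {
  structure(list(metric = metric, coefficient = coefficient, M = M, K = K,
                 lower_bound = lower, upper_bound = upper),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Conjunction coefficient (%s metric): %.6f  [attainable interval %.4f, %g]  (M = %d, K = %d)\n",
              x$metric, x$coefficient, x$lower_bound, x$upper_bound, x$M, x$K))
  invisible(x)
}

#' Attainable interval of the Condorcet conjunction coefficient
#'
#' The upper endpoint is always 1 (unanimity).  The lower endpoint is
#' attained by the most balanced pair tally a profile of total orders can
#' produce: every `delta[i, j]` as close to `M/2` as possible, giving
#' `-1/(M-1)` when `M` is even and `-1/M` when `M` is odd.  The interval is
#' classically printed with the opposite parity assignment; exhaustive
#' enumeration over all profiles (see the package tests) supports the
#' assignment returned here, so both readings are exposed and a discrepancy
#' flag is raised.
#'
#' @param M number of classifiers (>= 2).
#' @param K number of classes (>= 2).
#' @return list with `lower`, `upper` (the enumeration-backed attainable
#'   interval), `printed_lower` (the classically printed parity assignment) and
#'   `parity_discrepancy` (TRUE when the two disagree).
#' @export
ic_bounds <- function(M, K) {
  M <- as.integer(M); K <- as.integer(K)
  if (M < 2L || K < 2L) rf_validation_error("ic_bounds requires M >= 2 and K >= 2")
  lower <- if (M %% 2L == 0L) -1 / (M - 1) else -1 / M
  printed_lower <- if (M %% 2L == 0L) -1 / M else -1 / (M - 1)
  list(lower = lower, upper = 1,
       printed_lower = printed_lower,
       parity_discrepancy = !isTRUE(all.equal(lower, printed_lower)))
}

#' Exhaustively enumerate the Condorcet coefficient over all profiles
#'
#' Evaluates `I_C` for every one of the `(K!)^M` profiles of `M` total
#' orders on `K` classes.  Feasible only for tiny `M`, `K`; used to validate
#' the attainable interval in [ic_bounds()].
#'
#' @param M,K ensemble dimensions (the enumeration size `(K!)^M` must stay
#'   below 10^7).
#' @return a numeric vector of `(K!)^M` coefficients (one per profile).
#' @export
enumerate_ic_profiles <- function(M, K) {
  M <- as.integer(M); K <- as.integer(K)
  if (M < 2L || K < 2L) rf_validation_error("requires M >= 2 and K >= 2")
  perms <- all_permutations(K)
  np <- nrow(perms)
  if (np^M > 1e7) rf_capability_error("profile space too large to enumerate")
  idx <- rep(1L, M)
  out <- numeric(np^M)
  # precompute each permutation's preference matrix, flattened
  Ys <- lapply(seq_len(np), function(i) ranks_to_pair_matrix(perms[i, ]))
  pos <- 1L
  repeat {
    delta <- Reduce(`+`, Ys[idx])
    num <- sum(delta * (delta - 1L))
    out[pos] <- 4 * num / (as.numeric(M) * (M - 1L) * K * (K - 1L)) - 1
    pos <- pos + 1L
    j <- M
    while (j >= 1L) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= np) break
      idx[j] <- 1L
      j <- j - 1L
    }
    if (j < 1L) break
  }
  out
}

#' Exhaustively enumerate the disagreement coefficient over all profiles
#'
#' Same enumeration as [enumerate_ic_profiles()] for `I_d`.
#' @inheritParams enumerate_ic_profiles
#' @return a numeric vector of `(K!)^M` coefficients.
#' @export
enumerate_id_profiles <- function(M, K) {
  M <- as.integer(M); K <- as.integer(K)
  if (M < 2L || K < 2L) rf_validation_error("requires M >= 2 and K >= 2")
  perms <- all_permutations(K)
  np <- nrow(perms)
  if (np^M > 1e7) rf_capability_error("profile space too large to enumerate")
  Ps <- lapply(seq_len(np), function(i) ranks_to_permutation_matrix(perms[i, ]))
  idx <- rep(1L, M)
  out <- numeric(np^M)
  pos <- 1L
  repeat {
    pi <- Reduce(`+`, Ps[idx])
    out[pos] <- sum(pi * (pi - 1L)) / (as.numeric(K) * M * (M - 1L))
    pos <- pos + 1L
    j <- M
    while (j >= 1L) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= np) break
      idx[j] <- 1L
      j <- j - 1L
    }
    if (j < 1L) break
  }
  out
}
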