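# Globally optimal consensus solvers.
#
# Disagreement metric: the constraint set of the binary program is the
# assignment polytope, so despite its binary-programming appearance the
# problem is solved exactly in polynomial time as a linear assignment on
# cost M - pi (Jonker-Volgenant shortest augmenting path).
#
# Condorcet metric: a genuine linear ordering problem (NP-hard in general).
# Solved exactly by exhaustive search for K <= 8 and by branch-and-bound
# over prefix orders with the admissible bound sum(max(delta_ij, delta_ji))
# on unresolved pairs for 8 < K <= 15; larger K raises a capability error.

# ceiling for exhaustive permutation enumeration
.EXHAUSTIVE_K <- 8L
# ceiling for the branch-and-bound linear ordering solver
.BNB_K <- 15L
# cap on optima collected for tie-breaking / enumeration
.OPTIMA_CAP <- 4096L

#' Solve a linear assignment problem
#'
#' Minimises `sum_i cost[i, p(i)]` over permutations `p` by the
#' Jonker-Volgenant shortest augmenting path algorithm (O(n^3)).
#'
#' @param cost a square numeric cost matrix.
#' @return a list with `assignment` (column chosen for each row) and
#'   `value` (the minimal total cost).
#' @keywords internal
#' @export
lap_solve <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  if (ncol(cost) != n) rf_validation_error("cost matrix must be square")
  if (n == 1L) return(list(assignment = 1L, value = cost[1L, 1L]))
  v0 <- n + 1L  # virtual column
  u <- numeric(n)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)        # p[j] = row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[v0] <- i
    j0 <- v0
    minv <- rep(Inf, n + 1L)
    used <- logical(n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      free <- which(!used[seq_len(n)])
      if (length(free)) {
        cur <- cost[i0, free] - u[i0] - v[free]
        upd <- cur < minv[free]
        if (any(upd)) {
          minv[free[upd]] <- cur[upd]
          way[free[upd]] <- j0
        }
        jbest <- which.min(minv[free])
        delta <- minv[free[jbest]]
        j1 <- free[jbest]
      }
      usedj <- which(used)
      u[p[usedj]] <- u[p[usedj]] + delta
      v[usedj] <- v[usedj] - delta
      notused <- which(!used)
      minv[notused] <- minv[notused] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == v0) break
    }
  }
  assignment <- integer(n)
  assignment[p[seq_len(n)]] <- seq_len(n)
  list(assignment = assignment,
       value = sum(cost[cbind(seq_len(n), assignment)]))
}

#' Lexicographically smallest optimal assignment
#'
#' Fixes rows one at a time to the smallest column that still admits an
#' optimal completion (verified by re-solving the reduced problem).
#' @noRd
lap_solve_lex <- function(cost) {
  n <- nrow(cost)
  best <- lap_solve(cost)$value
  fixed <- integer(n)
  rows <- seq_len(n)
  cols <- seq_len(n)
  spent <- 0
  for (i in seq_len(n)) {
    rows_left <- rows[-seq_len(i)]
    for (j in cols[!(cols %in% fixed)]) {
      cand <- spent + cost[i, j]
      rest <- if (length(rows_left)) {
        sub <- cost[rows_left, setdiff(cols, c(fixed[seq_len(i - 1L)], j)), drop = FALSE]
        lap_solve(sub)$value
      } else 0
      if (isTRUE(all.equal(cand + rest, best)) || cand + rest <= best + 1e-9) {
        fixed[i] <- j
        spent <- cand
        break
      }
    }
    if (fixed[i] == 0L) stop("internal error: no optimal completion found")
  }
  list(assignment = fixed, value = best)
}

#' Disagreement-distance consensus
#'
#' Finds the total order minimising the summed disagreement distance to all
#' `M` classifier rankings, by solving the assignment problem with cost
#' `M - pi` (`pi` the position tally) to global optimality.  Ties between
#' optimal orders are broken deterministically by the lexicographically
#' smallest rank vector.
#'
#' @param R a [rank_matrix()] or coercible matrix.
#' @return a `consensus_result`: the consensus rank vector (named by class),
#'   the minimised objective `phi_d`, the metric name, a count of optimal
#'   orders when cheaply available (`NA` otherwise), and whether a tie-break
#'   was needed.
#' @examples
#' R <- rank_matrix(cbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3)))
#' solve_disagreement(R)
#' @export
solve_disagreement <- function(R) {
  R <- as_rank_matrix(R)
  K <- nrow(R)
  pi <- tally_positions(R)
  M <- ncol(R)
  cost <- matrix(as.numeric(M) - pi, K, K)
  sol <- lap_solve_lex(cost)
  # count optima exactly when enumeration is cheap
  count <- NA_integer_
  tie <- FALSE
  if (K <= .EXHAUSTIVE_K) {
    perms <- all_permutations(K)
    vals <- K * M - tally_score_all(perms, pi)
    count <- sum(vals == min(vals))
    tie <- count > 1L
  }
  consensus_result(sol$assignment, as.integer(round(sol$value)),
                   "disagreement", rownames(R),
                   optimum_count_hint = count, tiebreak_applied = tie)
}

#' phi_d-style score of many candidate permutations against a tally
#' @noRd
tally_score_all <- function(perms, pi) {
  K <- ncol(perms)
  s <- numeric(nrow(perms))
  for (i in seq_len(K)) s <- s + pi[cbind(rep.int(i, nrow(perms)), perms[, i])]
  s
}

#' Condorcet vote score of many candidate permutations against a pair tally
#' @noRd
condorcet_score_all <- function(perms, delta) {
  K <- ncol(perms)
  s <- numeric(nrow(perms))
  for (i in seq_len(K - 1L)) {
    for (j in (i + 1L):K) {
      less <- perms[, i] < perms[, j]
      s <- s + ifelse(less, delta[i, j], delta[j, i])
    }
  }
  s
}

#' All orderings attaining the maximal Condorcet vote score
#'
#' Branch-and-bound over prefix orderings (class chosen for the next-best
#' position), pruning with the admissible bound that every unresolved pair
#' contributes max(delta_ij, delta_ji).  Collects every optimal order up to
#' `cap`.
#' @return list(score, orders = matrix of rank vectors, capped = logical)
#' @noRd
condorcet_branch_bound <- function(delta, cap = .OPTIMA_CAP) {
  K <- nrow(delta)
  pairmax <- pmax(delta, t(delta))
  best <- -Inf
  acc <- list()
  capped <- FALSE
  # greedy initial incumbent: order classes by row sums of delta (Borda-like)
  greedy <- order(-rowSums(delta))
  g_ranks <- integer(K); g_ranks[greedy] <- seq_len(K)
  best <- condorcet_score(g_ranks, delta)
  recurse <- function(prefix, remaining, score, bound_rest) {
    # bound_rest: max achievable among pairs fully inside `remaining`
    if (score + bound_rest < best) return()
    if (!length(remaining)) {
      if (score > best) { best <<- score; acc <<- list() }
      if (score == best) {
        if (length(acc) < cap) acc[[length(acc) + 1L]] <<- prefix
        else capped <<- TRUE
      }
      return()
    }
    for (cls in remaining) {
      rest <- remaining[remaining != cls]
      gain <- sum(delta[cls, rest])  # cls beats everything placed later
      new_bound <- bound_rest - sum(pairmax[cls, rest])  # pairs fully inside rest
      if (score + gain + new_bound >= best) {
        recurse(c(prefix, cls), rest, score + gain, new_bound)
      }
    }
  }
  total_bound <- sum(pairmax[upper.tri(pairmax)])
  recurse(integer(0), seq_len(K), 0, total_bound)
  orders <- do.call(rbind, acc)
  # convert orderings (sequence of classes, best first) to rank vectors
  ranks <- t(apply(orders, 1L, function(o) { r <- integer(K); r[o] <- seq_len(K); r }))
  list(score = best, ranks = ranks, capped = capped)
}

#' Condorcet-distance consensus
#'
#' Finds the total order maximising the pairwise vote score
#' `sum delta[i, j] y[i, j]` (equivalently minimising the summed Kendall tau
#' distance `phi_C`) to global optimality.  Backends: exhaustive enumeration
#' for `K <= 8`, branch-and-bound for `8 < K <= 15`; larger problems raise a
#' capability error rather than falling back to a heuristic.
#'
#' When several orders are optimal (majority-tied class pairs), the tie is
#' broken deterministically: first by the larger disagreement-metric vote
#' score `sum pi[i, r_i]` (how many classifiers voted each class into exactly
#' its consensus position), then by the lexicographically smallest rank
#' vector.
#'
#' @param R a [rank_matrix()] or coercible matrix.
#' @param backend `"auto"` picks by problem size; `"bruteforce"` and `"bnb"`
#'   force a backend (subject to their size ceilings).
#' @return a `consensus_result` with objective `phi_C(r*)`.
#' @export
solve_condorcet <- function(R, backend = c("auto", "bruteforce", "bnb")) {
  backend <- match.arg(backend)
  R <- as_rank_matrix(R)
  K <- nrow(R)
  delta <- tally_pairs(R)
  if (backend == "auto") backend <- if (K <= .EXHAUSTIVE_K) "bruteforce" else "bnb"
  if (backend == "bruteforce" && K > .EXHAUSTIVE_K) {
    rf_capability_error(sprintf(
      "exhaustive Condorcet backend is limited to K <= %d (got K = %d)", .EXHAUSTIVE_K, K))
  }
  if (K > .BNB_K) {
    rf_capability_error(sprintf(
      "exact Condorcet solver is limited to K <= %d classes (got K = %d); no ILP backend is available",
      .BNB_K, K))
  }
  if (backend == "bruteforce") {
    perms <- all_permutations(K)
    sc <- condorcet_score_all(perms, delta)
    best <- max(sc)
    opt <- perms[sc == best, , drop = FALSE]
    count <- nrow(opt)
    capped <- FALSE
  } else {
    bb <- condorcet_branch_bound(delta)
    best <- bb$score
    opt <- bb$ranks
    count <- if (bb$capped) NA_integer_ else nrow(opt)
    capped <- bb$capped
  }
  tie <- is.na(count) || count > 1L
  r <- if (nrow(opt) == 1L) opt[1L, ] else pick_condorcet_tiebreak(opt, tally_positions(R))
  consensus_result(r, as.integer(condorcet_theta(delta) - best),
                   "condorcet", rownames(R),
                   optimum_count_hint = count, tiebreak_applied = tie)
}

#' Among optimal orders: max vote score, then lexicographically smallest
#' @noRd
pick_condorcet_tiebreak <- function(opt, pi) {
  vs <- tally_score_all(opt, pi)
  opt <- opt[vs == max(vs), , drop = FALSE]
  if (nrow(opt) == 1L) return(opt[1L, ])
  opt[do.call(order, as.data.frame(opt))[1L], ]
}

#' Enumerate all optimal consensus orders
#'
#' Exhaustively lists every permutation attaining the optimal objective under
#' the chosen metric, in lexicographic order of rank vectors, up to `cap`
#' entries.  Makes tie-breaking auditable: the two solvers may return
#' different rankings, and either problem may have several optima.
#'
#' @param R a [rank_matrix()] or coercible matrix with `K <= 8` classes.
#' @param metric `"disagreement"` or `"condorcet"`.
#' @param cap maximum number of optima to return.
#' @return an integer matrix, one optimal rank vector per row (columns named
#'   by class).
#' @export
enumerate_optima <- function(R, metric = c("disagreement", "condorcet"), cap = 100L) {
  metric <- match.arg(metric)
  R <- as_rank_matrix(R)
  K <- nrow(R)
  if (K > .EXHAUSTIVE_K) {
    rf_capability_error(sprintf("enumerate_optima requires K <= %d (got K = %d)", .EXHAUSTIVE_K, K))
  }
  perms <- all_permutations(K)
  if (metric == "disagreement") {
    pi <- tally_positions(R)
    vals <- nrow(R) * ncol(R) - tally_score_all(perms, pi)
    opt <- perms[vals == min(vals), , drop = FALSE]
  } else {
    delta <- tally_pairs(R)
    sc <- condorcet_score_all(perms, delta)
    opt <- perms[sc == max(sc), , drop = FALSE]
  }
  opt <- opt[do.call(order, as.data.frame(opt)), , drop = FALSE]
  opt <- opt[seq_len(min(nrow(opt), cap)), , drop = FALSE]
  colnames(opt) <- rownames(R)
  opt
}
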