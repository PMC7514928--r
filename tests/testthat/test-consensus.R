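# Exact consensus solvers.

test_that("assignment solver matches exhaustive search on random costs", {
  set.seed(301)
  for (t in 1:40) {
    K <- sample(2:6, 1)
    cost <- matrix(sample(0:9, K * K, replace = TRUE), K)
    perms <- all_permutations(K)
    vals <- apply(perms, 1L, function(p) sum(cost[cbind(1:K, p)]))
    expect_equal(lap_solve(cost)$value, min(vals))
  }
})

test_that("worked example: both printed consensus columns are reproduced", {
  R <- table2_matrix()
  d <- solve_disagreement(R)
  expect_identical(unname(d$ranks), c(3L, 2L, 1L, 4L, 5L, 6L, 7L, 8L, 10L, 9L))
  expect_identical(d$optimum_count_hint, NA_integer_)  # K = 10 > enumeration ceiling
  co <- solve_condorcet(R)
  expect_identical(unname(co$ranks), c(3L, 2L, 1L, 4L, 6L, 5L, 7L, 8L, 10L, 9L))
  expect_true(co$tiebreak_applied)
  # the two metrics disagree exactly on the positions of digits 4 and 5
  expect_identical(which(d$ranks != co$ranks), c(`4` = 5L, `5` = 6L))
  # objectives agree with the distance-sum definition
  expect_identical(d$objective, phi_disagreement(d$ranks, R))
  expect_identical(co$objective, phi_condorcet(co$ranks, R))
})

test_that("unanimous ensembles return their common ranking with known objectives", {
  set.seed(302)
  r <- sample.int(7)
  R <- rank_matrix(replicate(3, r))
  d <- solve_disagreement(R)
  expect_identical(unname(d$ranks), r)
  expect_identical(d$objective, 0L)
  expect_identical(d$optimum_count_hint, 1L)
  co <- solve_condorcet(R)
  expect_identical(unname(co$ranks), r)
  expect_identical(co$objective, 0L)
  # max vote score at a unanimous profile is M * K(K-1)/2
  delta <- tally_pairs(R)
  expect_identical(sum(delta * ranks_to_pair_matrix(r)), (3L * 7L * 6L) %/% 2L)
})

test_that("both solvers match the exhaustive distance-sum oracle", {
  set.seed(303)
  for (t in 1:60) {
    K <- sample(2:6, 1); M <- sample(2:7, 1)
    R <- random_rank_matrix(K, M)
    od <- oracle_consensus(R, oracle_disagreement)
    oc <- oracle_consensus(R, oracle_condorcet)
    d <- solve_disagreement(R)
    expect_identical(d$objective, as.integer(od$objective))
    expect_true(any(apply(od$optima, 1L, identical, y = unname(d$ranks))))
    co <- solve_condorcet(R)
    expect_identical(co$objective, as.integer(oc$objective))
    expect_true(any(apply(oc$optima, 1L, identical, y = unname(co$ranks))))
  }
})

test_that("branch-and-bound backend agrees with exhaustive enumeration", {
  set.seed(304)
  for (t in 1:25) {
    K <- sample(4:8, 1); M <- sample(2:6, 1)
    R <- random_rank_matrix(K, M)
    a <- solve_condorcet(R, backend = "bruteforce")
    b <- solve_condorcet(R, backend = "bnb")
    expect_identical(a$objective, b$objective)
    expect_identical(a$ranks, b$ranks)
  }
  # K above the exhaustive ceiling runs on branch-and-bound transparently
  R <- random_rank_matrix(11, 5)
  expect_s3_class(solve_condorcet(R), "consensus_result")
})

test_that("problem sizes above the exact ceiling raise a capability error", {
  R <- random_rank_matrix(16, 3)
  expect_error(solve_condorcet(R), class = "rankfuse_capability_error")
  expect_error(enumerate_optima(random_rank_matrix(9, 2), "condorcet"),
               class = "rankfuse_capability_error")
})

test_that("enumerate_optima lists all optima in lexicographic order", {
  r <- sample.int(5)
  R <- rank_matrix(replicate(4, r))
  for (m in c("disagreement", "condorcet")) {
    opt <- enumerate_optima(R, m)
    expect_identical(nrow(opt), 1L)
    expect_identical(unname(opt[1L, ]), r)
  }
  # two reversed voters: every order is condorcet-optimal; cap=1 gives identity
  R2 <- rank_matrix(cbind(1:3, 3:1))
  opt2 <- enumerate_optima(R2, "condorcet")
  expect_identical(nrow(opt2), 6L)
  expect_identical(unname(enumerate_optima(R2, "condorcet", cap = 1L)[1L, ]), 1:3)
  # a majority-tied adjacent pair yields exactly the two swapped optima
  R3 <- rank_matrix(cbind(c(1, 2, 3), c(2, 1, 3), c(1, 2, 3), c(2, 1, 3)))
  opt3 <- enumerate_optima(R3, "condorcet")
  expect_identical(nrow(opt3), 2L)
  expect_identical(unname(opt3[1L, ]), c(1L, 2L, 3L))
  expect_identical(unname(opt3[2L, ]), c(2L, 1L, 3L))
})

test_that("duplicating all columns preserves optima and doubles objectives", {
  set.seed(305)
  R <- random_rank_matrix(6, 4)
  R2 <- rank_matrix(cbind(unclass(R), unclass(R)))
  for (solver in list(solve_disagreement, solve_condorcet)) {
    a <- solver(R); b <- solver(R2)
    expect_identical(unname(a$ranks), unname(b$ranks))
    expect_identical(b$objective, 2L * a$objective)
  }
})

test_that("relabeling classes permutes the consensus consistently", {
  set.seed(306)
  R <- random_rank_matrix(6, 5)
  sigma <- sample.int(6)
  Rp <- rank_matrix(unclass(R)[sigma, ])
  inv <- integer(6); inv[sigma] <- seq_len(6)
  a <- solve_disagreement(R); b <- solve_disagreement(Rp)
  expect_identical(b$objective, a$objective)
  # mapped back, the relabeled optimum attains the original optimal objective
  expect_identical(phi_disagreement(unname(b$ranks)[inv], R), a$objective)
  ac <- solve_condorcet(R); bc <- solve_condorcet(Rp)
  expect_identical(bc$objective, ac$objective)
  expect_identical(phi_condorcet(unname(bc$ranks)[inv], R), ac$objective)
})
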