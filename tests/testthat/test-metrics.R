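# Distances and consensus objectives.

test_that("disagreement distance counts differing positions", {
  expect_identical(disagreement_distance(1:4, 1:4), 0L)
  expect_identical(disagreement_distance(c(1, 2, 3), c(2, 1, 3)), 2L)
  expect_error(disagreement_distance(1:3, 1:4), class = "rankfuse_validation_error")
  set.seed(201)
  for (t in 1:50) {
    K <- sample(2:8, 1)
    r <- sample.int(K); s <- sample.int(K)
    expect_identical(disagreement_distance(r, s), oracle_disagreement(r, s))
  }
})

test_that("condorcet distance equals the discordant-pair count", {
  expect_identical(condorcet_distance(1:5, 1:5), 0L)
  expect_identical(condorcet_distance(1:4, 4:1), 6L)  # K(K-1)/2 at full reversal
  expect_error(condorcet_distance(1:3, 1:4), class = "rankfuse_validation_error")
  set.seed(202)
  for (t in 1:50) {
    K <- sample(2:8, 1)
    r <- sample.int(K); s <- sample.int(K)
    expect_identical(condorcet_distance(r, s), oracle_condorcet(r, s))
  }
})

test_that("both distances are metrics on the permutation group", {
  # exhaustive for K <= 4, random triples for larger K
  for (K in 2:4) {
    perms <- all_permutations(K)
    n <- nrow(perms)
    for (a in 1:n) for (b in 1:n) {
      r <- perms[a, ]; s <- perms[b, ]
      fd <- disagreement_distance(r, s); fc <- condorcet_distance(r, s)
      expect_true(fd >= 0 && fc >= 0)
      expect_identical(fd == 0L, a == b)
      expect_identical(fc == 0L, a == b)
      expect_identical(fd, disagreement_distance(s, r))
      expect_identical(fc, condorcet_distance(s, r))
    }
  }
  set.seed(203)
  for (t in 1:200) {
    K <- sample(3:8, 1)
    r <- sample.int(K); s <- sample.int(K); u <- sample.int(K)
    expect_lte(disagreement_distance(r, u),
               disagreement_distance(r, s) + disagreement_distance(s, u))
    expect_lte(condorcet_distance(r, u),
               condorcet_distance(r, s) + condorcet_distance(s, u))
  }
})

test_that("phi objectives equal the distance sums and their tally identities", {
  set.seed(204)
  for (t in 1:40) {
    K <- sample(2:8, 1); M <- sample(1:7, 1)
    R <- random_rank_matrix(K, M)
    r <- sample.int(K)
    # direct distance-sum oracle
    expect_identical(phi_disagreement(r, R), oracle_phi(r, R, oracle_disagreement))
    expect_identical(phi_condorcet(r, R), oracle_phi(r, R, oracle_condorcet))
    # permutation-matrix identity: sum_ij (M - pi_ij) x_ij
    pi <- tally_positions(R)
    x <- ranks_to_permutation_matrix(r)
    expect_identical(phi_disagreement(r, R), as.integer(sum((M - pi) * x)))
    # linear ordering identity: theta - sum_ij delta_ij y_ij
    delta <- tally_pairs(R)
    theta <- M * K * (K - 1) / 2
    y <- ranks_to_pair_matrix(r)
    expect_identical(phi_condorcet(r, R), as.integer(theta - sum(delta * y)))
  }
})

test_that("phi is zero at a unanimous ensemble and invariant under class relabeling", {
  r <- sample.int(6)
  R <- rank_matrix(replicate(4, r))
  expect_identical(phi_disagreement(r, R), 0L)
  expect_identical(phi_condorcet(r, R), 0L)
  set.seed(205)
  R2 <- random_rank_matrix(5, 4)
  cand <- sample.int(5)
  sigma <- sample.int(5)
  R2p <- rank_matrix(unclass(R2)[sigma, ])
  expect_identical(phi_disagreement(cand[sigma], R2p), phi_disagreement(cand, R2))
  expect_identical(phi_condorcet(cand[sigma], R2p), phi_condorcet(cand, R2))
})

test_that("inequality chain f_d <= sum|r_i - s_i| <= 2 f_C holds", {
  # exhaustive pairs for K <= 4
  for (K in 2:4) {
    perms <- all_permutations(K)
    for (a in seq_len(nrow(perms))) for (b in seq_len(nrow(perms))) {
      r <- perms[a, ]; s <- perms[b, ]
      mid <- sum(abs(r - s))
      expect_lte(disagreement_distance(r, s), mid)
      expect_lte(mid, 2L * condorcet_distance(r, s))
    }
  }
  # the one-line summary f_d <= f_C fails on an adjacent transposition
  expect_gt(disagreement_distance(c(1, 2, 3), c(2, 1, 3)),
            condorcet_distance(c(1, 2, 3), c(2, 1, 3)))
})
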