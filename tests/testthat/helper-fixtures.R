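# Shared fixtures and independent oracles for the test suite.
# The oracles deliberately avoid the tally-based identities used by the
# implementation: distances are recomputed elementwise / pairwise, and
# optima are found by exhaustive search over the distance-sum objectives.

# The 10-digit x 4-classifier worked example shipped with the package.
table2_matrix <- function() {
  read_rank_matrix(system.file("extdata", "mnist_digit_ranks.tsv",
                               package = "rankfuse"))
}

random_rank_matrix <- function(K, M) {
  rank_matrix(replicate(M, sample.int(K)))
}

# Hamming distance on rank vectors, written directly from the definition
# sum_i sgn|r_i - s_i|.
oracle_disagreement <- function(r, s) as.integer(sum(sign(abs(r - s))))

# Discordant-pair count by explicit double loop.
oracle_condorcet <- function(r, s) {
  K <- length(r)
  d <- 0L
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
    if (sign(r[i] - r[j]) != sign(s[i] - s[j])) d <- d + 1L
  }
  d
}

# Objective of a candidate as the plain sum of distances to every column.
oracle_phi <- function(r, R, dist) as.integer(sum(apply(unclass(R), 2L, dist, r = r)))

# Exhaustive minimiser of the distance-sum objective over all K! orders.
oracle_consensus <- function(R, dist) {
  perms <- all_permutations(nrow(R))
  vals <- apply(perms, 1L, function(p) oracle_phi(p, R, dist))
  list(objective = min(vals), optima = perms[vals == min(vals), , drop = FALSE])
}
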