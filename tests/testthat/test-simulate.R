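# Mallows sampler and ensemble simulator.

test_that("large dispersion collapses the Mallows model onto its center", {
  center <- c(3L, 1L, 4L, 2L, 5L)
  R <- sample_mallows(center, dispersion = 50, count = 20, seed = 601)
  expect_true(all(unclass(R) == center))
})

test_that("zero dispersion gives uniform permutations", {
  R <- sample_mallows(1:3, dispersion = 0, count = 6000, seed = 602)
  key <- apply(unclass(R), 2L, paste, collapse = "")
  freq <- table(key)
  expect_identical(length(freq), 6L)
  # binomial 3-sigma band around 1/6
  p <- 1 / 6
  tol <- 3 * sqrt(p * (1 - p) / 6000)
  expect_true(all(abs(freq / 6000 - p) < tol))
})

test_that("expected distance to the center is non-increasing in dispersion", {
  center <- 1:6
  mean_dist <- function(disp, seed) {
    R <- sample_mallows(center, disp, count = 300, seed = seed)
    mean(apply(unclass(R), 2L, condorcet_distance, r = center))
  }
  d0 <- mean_dist(0, 603)
  d1 <- mean_dist(1, 603)
  d2 <- mean_dist(3, 603)
  expect_gt(d0, d1)
  expect_gt(d1, d2)
})

test_that("the sampler rejects invalid parameters and preserves RNG state", {
  expect_error(sample_mallows(1:4, -1, 5), class = "rankfuse_validation_error")
  expect_error(sample_mallows(c(1, 1, 2), 1, 5), class = "rankfuse_validation_error")
  set.seed(604)
  before <- .Random.seed
  invisible(sample_mallows(1:5, 1, 3, seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("simulated batches validate and are reproducible bit-for-bit", {
  cfg <- simulation_config(K = 3, M = 5, n = 40, seed = 605, accuracy = 0.8)
  b1 <- simulate_ensemble(cfg)
  b2 <- simulate_ensemble(cfg)
  expect_identical(b1$ranks, b2$ranks)
  expect_identical(b1$true_labels, b2$true_labels)
  expect_s3_class(batch_rank_matrix(b1, 7), "rank_matrix")
  # score model too
  cfgs <- simulation_config(K = 4, M = 3, n = 20, seed = 606, accuracy = 2,
                            class_priors = rep(0.25, 4), model = "score",
                            dependence = 0.5)
  bs <- simulate_ensemble(cfgs)
  expect_identical(simulate_ensemble(cfgs)$ranks, bs$ranks)
})

test_that("highly accurate independent classifiers yield zero pipeline error", {
  cfg <- simulation_config(K = 3, M = 5, n = 30, seed = 607,
                           accuracy = 50, dependence = 0)
  b <- simulate_ensemble(cfg)
  # every classifier ranks the true class first
  tops <- apply(b$ranks, c(2, 3), which.min)
  expect_true(all(t(tops) == b$true_labels))
  comb <- combine_batch(b, "condorcet")
  ev <- evaluate_predictions(comb$predictions, b$true_labels, b$positive_class)
  expect_equal(ev$error_rate, 0)
})

test_that("default priors emulate a rare-positive screening mix", {
  cfg <- simulation_config(n = 4000, M = 3, seed = 608, accuracy = 1)
  expect_equal(cfg$class_priors, c(0.81, 0.02, 0.17))
  b <- simulate_ensemble(cfg)
  shares <- tabulate(b$true_labels, 3) / b$n
  expect_gt(shares[2], 0)       # the rare class is present...
  expect_lt(shares[2], 0.05)    # ...but rare (prior 0.02)
  expect_gt(shares[1], 0.7)
})

test_that("dependence induces correlated classifier errors", {
  mk <- function(dep) {
    cfg <- simulation_config(K = 3, M = 2, n = 400, seed = 609,
                             accuracy = 1.2, dependence = dep,
                             class_priors = rep(1 / 3, 3))
    b <- simulate_ensemble(cfg)
    tops <- apply(b$ranks, c(2, 3), which.min)
    pairwise_independence_gap(tops[1, ], tops[2, ])
  }
  expect_gt(mk(0.9), mk(0))
})

test_that("the size sweep composes simulate + combine + evaluate", {
  cfg <- simulation_config(K = 3, M = 3, n = 25, seed = 610, accuracy = 0.9)
  tab <- accuracy_vs_ensemble_size(cfg, sizes = c(3L, 7L), metric = "condorcet")
  expect_identical(tab$M, c(3L, 7L))
  expect_true(all(tab$error_rate >= 0 & tab$error_rate <= 1))
  expect_true(all(tab$coefficient >= -1 & tab$coefficient <= 1))
  # single-size sweep equals the direct composition with the same seed
  cfg1 <- cfg; cfg1$M <- 3L
  b <- simulate_ensemble(cfg1)
  ev <- evaluate_predictions(combine_batch(b, "condorcet")$predictions,
                             b$true_labels, b$positive_class)
  expect_equal(tab$error_rate[1], ev$error_rate)
  # unanimity limit: coefficient 1 at huge accuracy
  cfg_hi <- simulation_config(K = 3, M = 4, n = 10, seed = 611, accuracy = 50)
  tab_hi <- accuracy_vs_ensemble_size(cfg_hi, sizes = 4L, metric = "condorcet")
  expect_equal(tab_hi$coefficient, 1)
})

test_that("consensus recovers the Mallows center as the ensemble grows", {
  center <- c(2L, 4L, 1L, 5L, 3L)
  recov <- function(M, reps, seed0) {
    mean(vapply(seq_len(reps), function(rep) {
      R <- sample_mallows(center, dispersion = 0.5, count = M, seed = seed0 + rep)
      identical(unname(solve_condorcet(R)$ranks), center)
    }, logical(1)))
  }
  expect_gt(recov(25, 40, 61200), recov(3, 40, 61300) - 0.05)
  expect_gte(recov(101, 40, 61400), 0.95)
})
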