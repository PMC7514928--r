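# Simulator of classifier-ensemble rank data with controlled accuracy,
# inter-classifier dependence, and class imbalance.  Rankings are drawn from
# a Mallows model by the repeated-insertion construction (an exact sampler),
# or from a Gaussian score model passed through scores_to_ranks().

#' Simulation configuration
#'
#' Bundles and validates the parameters of [simulate_ensemble()].  Defaults
#' emulate a cervical-cytology-style screening setting: three classes
#' (normal / atypical / debris) with a rare positive class (atypical prior
#' 0.02), a moderately sized ensemble of weak classifiers, and independent
#' errors.
#'
#' @param K number of classes (>= 2).
#' @param M number of classifiers (>= 1).
#' @param n number of samples.
#' @param class_priors length-`K` simplex vector of class frequencies.
#' @param accuracy concentration parameter: Mallows dispersion (model
#'   `"mallows"`) or Gaussian score margin (model `"score"`); larger means
#'   more accurate classifiers, 0 means uninformative.
#' @param dependence shared-noise weight in `[0, 1]`; 0 gives conditionally
#'   independent classifiers, larger values induce correlated errors.
#' @param seed integer seed; every draw from this configuration is
#'   reproducible bit-for-bit.
#' @param model `"mallows"` or `"score"`.
#' @param positive_class index of the class treated as positive for
#'   FPR/FNR evaluation (defaults to 2, the rare class under the default
#'   priors).
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(K = 3L, M = 9L, n = 500L,
                              class_priors = c(0.81, 0.02, 0.17),
                              accuracy = 1.0, dependence = 0,
                              seed = 1L, model = c("mallows", "score"),
                              positive_class = 2L) {
  model <- match.arg(model)
  K <- as.integer(K); M <- as.integer(M); n <- as.integer(n)
  if (K < 2L) rf_validation_error("K must be >= 2")
  if (M < 1L) rf_validation_error("M must be >= 1")
  if (n < 1L) rf_validation_error("n must be >= 1")
  if (length(class_priors) != K || any(class_priors < 0) ||
      abs(sum(class_priors) - 1) > 1e-9) {
    rf_validation_error("class_priors must be a length-K simplex vector")
  }
  if (accuracy < 0) rf_validation_error("accuracy must be >= 0")
  if (dependence < 0 || dependence > 1) rf_validation_error("dependence must lie in [0, 1]")
  positive_class <- as.integer(positive_class)
  if (positive_class < 1L || positive_class > K) {
    rf_validation_error("positive_class must be a class index in 1..K")
  }
  structure(list(K = K, M = M, n = n, class_priors = as.numeric(class_priors),
                 accuracy = accuracy, dependence = dependence,
                 seed = as.integer(seed), model = model,
                 positive_class = positive_class),
            class = "simulation_config")
}

#' Draw rankings from a Mallows model
#'
#' Samples `count` independent rankings with probability proportional to
#' `exp(-dispersion * d_C(r, center))`, `d_C` the Condorcet (Kendall tau)
#' distance, via the repeated-insertion construction: item `i` of the
#' center's ordering is inserted at position `j <= i` with probability
#' proportional to `exp(-dispersion * (i - j))`.  `dispersion = 0` gives
#' uniform permutations; large dispersion concentrates on the center.
#'
#' @param center a permutation of `1..K` (rank 1 = most preferred).
#' @param dispersion non-negative concentration parameter.
#' @param count number of rankings to draw.
#' @param seed optional integer seed (the caller's RNG state is preserved).
#' @return a [rank_matrix()] with `count` columns.
#' @export
sample_mallows <- function(center, dispersion, count, seed = NULL) {
  center <- assert_permutation(center, "center")
  if (dispersion < 0) rf_validation_error("dispersion must be >= 0")
  count <- as.integer(count)
  if (count < 1L) rf_validation_error("count must be >= 1")
  with_seed(seed, {
    K <- length(center)
    ordering <- order(center)  # class indices, most preferred first
    q <- exp(-dispersion)
    out <- matrix(0L, K, count)
    for (s in seq_len(count)) {
      lst <- integer(0)
      for (i in seq_len(K)) {
        w <- q ^ ((i - 1L):0)  # insertion at position j has weight q^(i-j)
        j <- sample.int(i, 1L, prob = w)
        lst <- append(lst, ordering[i], after = j - 1L)
      }
      r <- integer(K)
      r[lst] <- seq_len(K)
      out[, s] <- r
    }
    rank_matrix(out)
  })
}

#' Center ranking for a given true class
#'
#' The true class gets rank 1; the remaining classes follow in canonical
#' (index) order.  Fixing this secondary order makes center-recovery
#' experiments well defined.
#' @noRd
center_for_class <- function(true_class, K) {
  ordering <- c(true_class, setdiff(seq_len(K), true_class))
  r <- integer(K)
  r[ordering] <- seq_len(K)
  r
}

#' Simulate a classifier-ensemble batch
#'
#' For each sample: the true class is drawn from `class_priors`; each of the
#' `M` classifiers produces a ranking drawn from the chosen noise model
#' centered on an ordering that ranks the true class first.  With
#' `dependence > 0`, a per-sample shared noise component is mixed into all
#' classifiers, inducing the correlated errors typical of real ensembles
#' (most members fail on the same hard samples): under the Mallows model
#' each classifier adopts a shared noisy ranking with probability
#' `dependence`; under the score model the Gaussian score noise has
#' correlation `dependence` across classifiers.
#'
#' @param cfg a [simulation_config()].
#' @return a [sample_batch()] with true labels and the configured positive
#'   class attached.
#' @export
simulate_ensemble <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    K <- cfg$K; M <- cfg$M; n <- cfg$n
    tensor <- array(0L, dim = c(K, M, n))
    truth <- sample.int(K, n, replace = TRUE, prob = cfg$class_priors)
    for (i in seq_len(n)) {
      center <- center_for_class(truth[i], K)
      if (cfg$model == "mallows") {
        shared <- as.integer(sample_mallows(center, cfg$accuracy, 1L)[, 1L])
        own <- sample_mallows(center, cfg$accuracy, M)
        use_shared <- stats::runif(M) < cfg$dependence
        for (k in seq_len(M)) {
          tensor[, k, i] <- if (use_shared[k]) shared else own[, k]
        }
      } else {
        mu <- ifelse(seq_len(K) == truth[i], cfg$accuracy, 0)
        shared_noise <- stats::rnorm(K)
        for (k in seq_len(M)) {
          eps <- sqrt(cfg$dependence) * shared_noise +
            sqrt(1 - cfg$dependence) * stats::rnorm(K)
          tensor[, k, i] <- scores_to_ranks(mu + eps)
        }
      }
    }
    sample_batch(tensor, true_labels = truth,
                 positive_class = cfg$positive_class)
  })
}

#' Ensemble accuracy as a function of ensemble size
#'
#' For each ensemble size in `sizes`, simulates a fresh batch (same
#' configuration except `M`), combines it with the chosen consensus metric,
#' evaluates against the true labels, and records the ensemble agreement
#' coefficient averaged over samples.
#'
#' @param cfg a [simulation_config()]; its `M` is overridden by each entry
#'   of `sizes`.
#' @param sizes ascending integer vector of ensemble sizes.
#' @param metric `"disagreement"` or `"condorcet"`.
#' @return a data.frame with columns `M`, `error_rate`, `fpr`, `fnr`,
#'   `coefficient` (mean per-sample conjunction coefficient for the chosen
#'   metric; `NA` when `M < 2`).
#' @export
accuracy_vs_ensemble_size <- function(cfg, sizes,
                                      metric = c("disagreement", "condorcet")) {
  metric <- match.arg(metric)
  stopifnot(inherits(cfg, "simulation_config"))
  sizes <- as.integer(sizes)
  if (is.unsorted(sizes)) rf_validation_error("sizes must be ascending")
  rows <- lapply(seq_along(sizes), function(s) {
    m <- sizes[s]
    cfg_m <- cfg
    cfg_m$M <- m
    cfg_m$seed <- cfg$seed + s - 1L
    batch <- simulate_ensemble(cfg_m)
    comb <- combine_batch(batch, metric)
    ev <- evaluate_predictions(comb$predictions, batch$true_labels,
                               batch$positive_class)
    coefficient <- if (m >= 2L) {
      mean(vapply(seq_len(batch$n), function(i) {
        R <- batch_rank_matrix(batch, i)
        if (metric == "condorcet") conjunction_condorcet(R)$coefficient
        else conjunction_disagreement(R)$coefficient
      }, numeric(1)))
    } else NA_real_
    data.frame(M = m, error_rate = ev$error_rate, fpr = ev$fpr, fnr = ev$fnr,
               coefficient = coefficient)
  })
  do.call(rbind, rows)
}
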