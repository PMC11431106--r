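make_ens <- function(eta, n_bins = 1000, seed = 1, theta = 0) {
  to_spike_times(sample_pattern(law_of(eta, eta, theta), n_bins, seed = seed), 16)
}

test_that("segmenting splits the window evenly and loses no spikes", {
  s <- make_ens(0.3, 500, seed = 4)
  segs <- segment_ensemble(s, 50)
  expect_equal(attr(segs, "period_length") * 50, 16, tolerance = 1e-9)
  for (i in 1:2) {
    rebuilt <- unlist(lapply(seq_along(segs), function(p) {
      segs[[p]][[i]] + (p - 1) * attr(segs, "period_length")
    }))
    expect_equal(rebuilt, s[[i]], tolerance = 1e-9)
  }
})

test_that("Wasserstein segment distance matches hand values and the CDF oracle", {
  expect_equal(wasserstein_distance(c(1, 2, 3), c(1, 2, 3), 10), 0)
  expect_equal(wasserstein_distance(c(2), c(5), 10), 3) # unit-mass matching
  expect_equal(wasserstein_distance(numeric(0), numeric(0), 10), 0)
  expect_equal(wasserstein_distance(numeric(0), c(1, 2), 10), 10)
  set.seed(19)
  for (i in 1:20) {
    a <- sort(stats::runif(sample(1:6, 1), 0, 8))
    b <- sort(stats::runif(sample(1:6, 1), 0, 8))
    d <- wasserstein_distance(a, b, 8)
    expect_equal(d, wasserstein_distance(b, a, 8), tolerance = 1e-12)
    expect_equal(d, oracle_w1_cdf(a, b, 8, n_grid = 2e5), tolerance = 1e-3)
  }
})

test_that("estimated MI is exact for identical patterns and bounded above", {
  cfg <- estimator_config(n_periods = 50, h = 3)
  s <- make_ens(0.3, 1000, seed = 21)
  expect_equal(estimated_mi(s, s, cfg), log(50 / 3), tolerance = 1e-12)
  expect_equal(estimated_mi(s, s, estimator_config(n_periods = 20, h = 5)),
               log(20 / 5), tolerance = 1e-12)
  set.seed(2)
  for (i in 1:10) {
    a <- make_ens(0.3, 400, seed = 300 + i)
    b <- make_ens(0.3, 400, seed = 400 + i)
    v <- estimated_mi(a, b, cfg)
    expect_lte(v, log(50^2 / 9) + 1e-12)
    expect_equal(v, estimated_mi(b, a, cfg), tolerance = 1e-12) # exact symmetry
  }
})

test_that("estimated MI on independent patterns sits at its permutation-null level", {
  # the estimator is biased; independence is judged against the null formed
  # by decoupling the period pairing (circular shifts of one pattern)
  cfg <- estimator_config(n_periods = 50, h = 3)
  vals <- vapply(1:20, function(i) {
    estimated_mi(make_ens(0.3, 1000, seed = 500 + i),
                 make_ens(0.3, 1000, seed = 600 + i), cfg)
  }, numeric(1))
  null_vals <- vapply(1:20, function(i) {
    a <- make_ens(0.3, 1000, seed = 500 + i)
    b <- make_ens(0.3, 1000, seed = 600 + i)
    shift <- function(s, dt, tau) {
      spike_ensemble(lapply(s, function(x) sort((x + dt) %% tau)), tau)
    }
    estimated_mi(a, shift(b, 8, 16), cfg)
  }, numeric(1))
  se <- sqrt(stats::var(vals) / 20 + stats::var(null_vals) / 20)
  expect_lt(abs(mean(vals) - mean(null_vals)), 2 * se)
  # destroying the period pairing of an identical pair collapses the
  # estimate from log(N/h) toward the independent level
  s <- make_ens(0.3, 1000, seed = 77)
  shifted <- spike_ensemble(lapply(s, function(x) sort((x + 8) %% 16)), 16)
  expect_lt(estimated_mi(s, shifted, cfg), log(50 / 3) - 0.5)
})

test_that("estimated MI increases with within-pair dependence", {
  cfg <- estimator_config(n_periods = 50, h = 3)
  indep <- vapply(1:20, function(i) {
    estimated_mi(make_ens(0.4, 600, seed = 700 + i),
                 make_ens(0.4, 600, seed = 800 + i), cfg)
  }, numeric(1))
  ident <- vapply(1:20, function(i) {
    s <- make_ens(0.4, 600, seed = 900 + i)
    estimated_mi(s, s, cfg)
  }, numeric(1))
  expect_gt(mean(ident), mean(indep))
})

test_that("estimator sensitivity to its tuning parameters stays finite and ordered", {
  s <- make_ens(0.35, 600, seed = 42)
  for (N in c(20, 50, 100)) {
    for (h in c(1, 3, 5)) {
      cfg <- estimator_config(n_periods = N, h = h)
      v <- estimated_mi(s, s, cfg)
      expect_equal(v, log(N / h), tolerance = 1e-12)
    }
  }
  expect_error(estimator_config(n_periods = 10, h = 10), "h < n_periods")
})

test_that("transfer entropy detects a lagged copy and is directional", {
  set.seed(6)
  src <- stats::rbinom(1e4, 1, 0.5)
  tgt <- c(0L, src[-1e4]) # target = source lagged by one bin
  te_fwd <- transfer_entropy(src, tgt, estimator_config(k = 1))
  expect_equal(te_fwd, 1, tolerance = 0.02) # one fair bit per bin
  te_bwd <- transfer_entropy(tgt, src, estimator_config(k = 1))
  expect_gt(te_fwd, te_bwd + 0.5)
  expect_error(transfer_entropy(src[1:1], tgt[1:1]), "history")
})

test_that("transfer entropy is a non-negative plug-in estimate matching its permutation bias", {
  set.seed(8)
  vals <- numeric(20); nulls <- numeric(20)
  for (i in 1:20) {
    a <- stats::rbinom(2000, 1, 0.4)
    b <- stats::rbinom(2000, 1, 0.4)
    vals[i] <- transfer_entropy(a, b)
    nulls[i] <- transfer_entropy(sample(a), b) # permutation bias oracle
    expect_gte(vals[i], 0)
  }
  se <- sqrt(stats::var(vals) / 20 + stats::var(nulls) / 20)
  expect_lt(abs(mean(vals) - mean(nulls)), 2 * se)
  # patterns (matrices) are accepted and joint states are used
  p1 <- sample_pattern(joint_law(0.25, 0.25, 0.25, 0.25), 500, seed = 1)
  p2 <- sample_pattern(joint_law(0.25, 0.25, 0.25, 0.25), 500, seed = 2)
  expect_gte(transfer_entropy(p1, p2), 0)
})

test_that("redundancy reduces to the identical-pattern MI for a duplicated neuron", {
  cfg <- estimator_config(n_periods = 50, h = 3)
  s <- make_ens(0.3, 800, seed = 33)
  dup <- spike_ensemble(list(s[[1]], s[[1]]), 16)
  expect_equal(redundancy(dup, cfg), log(50 / 3), tolerance = 1e-12)
  # invariant under neuron relabeling
  swapped <- spike_ensemble(list(s[[2]], s[[1]]), 16)
  expect_equal(redundancy(s, cfg), redundancy(swapped, cfg), tolerance = 1e-12)
  expect_error(redundancy(spike_ensemble(list(c(1, 2)), 16), cfg), "2 neurons")
})

test_that("redundancy reduction vanishes for identical patterns and flips sign on swap", {
  cfg <- estimator_config(n_periods = 50, h = 3)
  s <- make_ens(0.3, 800, seed = 44)
  expect_equal(redundancy_reduction(s, s, cfg)$value, 0)
  t2 <- make_ens(0.3, 800, seed = 45, theta = 1.5)
  fwd <- redundancy_reduction(s, t2, cfg)
  bwd <- redundancy_reduction(t2, s, cfg)
  expect_true(fwd$valid && bwd$valid)
  expect_equal(fwd$value, -bwd$value, tolerance = 1e-12)
})
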