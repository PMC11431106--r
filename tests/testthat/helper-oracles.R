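# Independent oracles used across the suite. Each re-derives a quantity by
# brute force so the implementation under test never checks itself.

# KL divergence between two joint laws by direct summation over the four
# outcomes.
kl_div <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  keep <- p > 0
  sum(p[keep] * log(p[keep] / q[keep]))
}

# Rejection-sampled strictly interior joint law.
random_interior_law <- function(min_q = 0.02) {
  repeat {
    q <- stats::rexp(4)
    q <- q / sum(q)
    if (min(q) > min_q) return(joint_law(q[1], q[2], q[3], q[4]))
  }
}

# Brute-force SPIKE dissimilarity integral between two single-neuron trains:
# scalar evaluation of the profile straight from the defining quantities
# (preceding/following spikes, instantaneous ISIs, nearest-spike distances)
# on a dense midpoint grid.
oracle_spike_similarity <- function(a, b, tau, n_grid = 2e5) {
  sa <- c(0, a, tau); sb <- c(0, b, tau)
  tm <- (seq_len(n_grid) - 0.5) * tau / n_grid
  prof <- vapply(tm, function(t) {
    tPa <- max(sa[sa <= t]); tFa <- min(sa[sa > t])
    tPb <- max(sb[sb <= t]); tFb <- min(sb[sb > t])
    ia <- tFa - tPa; ib <- tFb - tPb
    Sa <- (min(abs(tPa - sb)) * (tFa - t) + min(abs(tFa - sb)) * (t - tPa)) / ia
    Sb <- (min(abs(tPb - sa)) * (tFb - t) + min(abs(tFb - sa)) * (t - tPb)) / ib
    (Sa * ib + Sb * ia) / (2 * ((ia + ib) / 2)^2)
  }, numeric(1))
  1 - mean(prof)
}

# 1-Wasserstein distance between two nonempty spike lists via the CDF
# difference integral on a dense time grid (independent of the
# quantile-function route used by the implementation).
oracle_w1_cdf <- function(a, b, period_length, n_grid = 2e5) {
  tm <- (seq_len(n_grid) - 0.5) * period_length / n_grid
  Fa <- vapply(tm, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(tm, function(t) mean(b <= t), numeric(1))
  sum(abs(Fa - Fb)) * period_length / n_grid
}
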