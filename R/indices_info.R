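# Information-theoretic measures: nearest-neighbour estimated mutual
# information over Wasserstein spike distances, plug-in transfer entropy on
# binarized bins, and relative redundancy reduction.

#' Estimator configuration
#'
#' Tuning parameters for the information-theoretic measures.
#'
#' @param n_periods Number of equal-duration periods each pattern is cut
#'   into for the mutual-information estimator (default 50).
#' @param h Integer smoothing parameter of the nearest-neighbour estimator;
#'   must satisfy `1 <= h < n_periods` (default 3).
#' @param k Transfer-entropy history length in bins (default 1).
#' @param mi_log_base Logarithm base for the mutual-information estimate
#'   (default `exp(1)`, i.e. nats); transfer entropy is always reported in
#'   bits.
#' @return An `estimator_config`.
#' @export
estimator_config <- function(n_periods = 50, h = 3, k = 1,
                             mi_log_base = exp(1)) {
  n_periods <- as.integer(n_periods); h <- as.integer(h); k <- as.integer(k)
  if (h < 1 || h >= n_periods) rlang::abort("require 1 <= h < n_periods")
  if (k < 1) rlang::abort("k must be >= 1")
  structure(list(n_periods = n_periods, h = h, k = k,
                 mi_log_base = mi_log_base),
            class = "estimator_config")
}

#' @export
print.estimator_config <- function(x, ...) {
  cat("<estimator_config> n_periods =", x$n_periods, " h =", x$h,
      " k =", x$k, " mi_log_base =", format(x$mi_log_base), "\n")
  invisible(x)
}

#' Cut a spike-train ensemble into equal periods
#'
#' Splits the window `[0, tau]` into `n_periods` consecutive periods and
#' re-references each period's spike times to the period start. Spikes
#' exactly on a boundary belong to the earlier period.
#'
#' @param x A [spike_ensemble()].
#' @param n_periods Number of periods.
#' @return A list of `n_periods` elements, each a list of per-neuron spike
#'   vectors, with attributes `period_length` and `n_neurons`.
#' @export
segment_ensemble <- function(x, n_periods) {
  tau <- attr(x, "tau")
  plen <- tau / n_periods
  segs <- lapply(seq_len(n_periods), function(p) {
    lo <- (p - 1) * plen; hi <- p * plen
    lapply(x, function(s) s[s > lo & s <= hi] - lo)
  })
  # spikes exactly at 0 go to the first period
  segs[[1]] <- lapply(seq_along(x), function(i) {
    s <- x[[i]]
    s[s <= plen]
  })
  structure(segs, period_length = plen, n_neurons = length(x))
}

#' Wasserstein distance between two period spike lists
#'
#' The 1-Wasserstein (earth mover's) distance between the empirical measures
#' that place mass `1/n` on each spike of a period. For equal counts this is
#' the mean absolute difference of the sorted times; for unequal counts the
#' quantile-function integral is used. An empty period against a non-empty
#' one is assigned the maximal displacement, i.e. the period length; two
#' empty periods are at distance 0.
#'
#' @param a,b Sorted numeric vectors of spike times within one period.
#' @param period_length Period duration (ms), the empty-vs-nonempty distance.
#' @return Scalar distance in ms.
#' @export
wasserstein_distance <- function(a, b, period_length) {
  na <- length(a); nb <- length(b)
  if (na == 0 && nb == 0) return(0)
  if (na == 0 || nb == 0) return(period_length)
  if (na == nb) return(mean(abs(a - b)))
  # quantile-function integral of the two empirical measures
  u <- sort(unique(c(seq_len(na - 1) / na, seq_len(nb - 1) / nb)))
  edges <- c(0, u, 1)
  widths <- diff(edges)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  qa <- a[ceiling(mids * na)]
  qb <- b[ceiling(mids * nb)]
  sum(widths * abs(qa - qb))
}

# Per-neuron N x N matrices of pairwise segment Wasserstein distances.
segment_distance_matrices <- function(x, n_periods) {
  segs <- segment_ensemble(x, n_periods)
  plen <- attr(segs, "period_length")
  nn <- attr(segs, "n_neurons")
  lapply(seq_len(nn), function(i) {
    per <- lapply(segs, `[[`, i)
    D <- matrix(0, n_periods, n_periods)
    for (p in seq_len(n_periods - 1)) {
      for (q in (p + 1):n_periods) {
        D[p, q] <- D[q, p] <- wasserstein_distance(per[[p]], per[[q]], plen)
      }
    }
    D
  })
}

sum_matrices <- function(mats) Reduce(`+`, mats)

# Nearest-neighbour MI estimate from two per-pattern segment distance
# tables. For each period i the h-1 nearest other periods are found in each
# pattern (ties broken by period index), the self pair always counts, and
# the average of log(N * C_i / h^2) is returned.
mi_from_matrices <- function(D1, D2, h, log_base = exp(1)) {
  N <- nrow(D1)
  idx <- seq_len(N)
  C <- vapply(idx, function(i) {
    if (h == 1) return(1)
    d1 <- D1[i, ]; d1[i] <- Inf
    d2 <- D2[i, ]; d2[i] <- Inf
    A <- order(d1, idx)[seq_len(h - 1)]
    B <- order(d2, idx)[seq_len(h - 1)]
    length(intersect(A, B)) + 1
  }, numeric(1))
  mean(log(N * C / h^2)) / log(log_base)
}

#' Estimated mutual information between two patterns
#'
#' Nearest-neighbour (Kozachenko-Leonenko-style) estimate: each pattern is
#' cut into `n_periods` equal periods, pairwise Wasserstein distances
#' between periods are computed within each pattern (summed over neurons for
#' multi-neuron ensembles), and for each period `i` the count `C_i` of
#' periods lying strictly within the `h`-th-nearest-neighbour radius in
#' *both* patterns jointly estimates the local dependence. The estimate is
#' `mean(log(N C_i / h^2))`.
#'
#' Ties in the discrete distances are broken deterministically by period
#' index, and the self pair is always counted, so `C_i >= 1`, the estimator
#' is exactly symmetric in its arguments, and identical patterns give
#' exactly `log(N / h)`. The estimator is biased (the spec of Eq.-type
#' nearest-neighbour counts with a guaranteed self pair cannot average to 0
#' for independent patterns); compare against a permutation null when an
#' absolute reference is needed.
#'
#' @param t1,t2 [spike_ensemble()]s on the same window.
#' @param cfg An [estimator_config()].
#' @return Scalar estimate in `mi_log_base` units (nats by default).
#' @export
estimated_mi <- function(t1, t2, cfg = estimator_config()) {
  if (cfg$n_periods < 2) rlang::abort("need at least 2 periods")
  D1 <- sum_matrices(segment_distance_matrices(t1, cfg$n_periods))
  D2 <- sum_matrices(segment_distance_matrices(t2, cfg$n_periods))
  mi_from_matrices(D1, D2, cfg$h, cfg$mi_log_base)
}

# Encode each time bin of a pattern as an integer state (0..2^n_neurons - 1).
encode_states <- function(x) {
  x <- as.matrix(x)
  as.integer(colSums(x * 2^(seq_len(nrow(x)) - 1)))
}

plugin_entropy <- function(codes) {
  p <- tabulate(codes + 1L)
  p <- p[p > 0] / length(codes)
  -sum(p * log2(p))
}

# Integer code of k consecutive states ending at t-1, in base `base`.
history_codes <- function(s, k, base) {
  n <- length(s)
  out <- integer(n - k)
  for (j in seq_len(k)) {
    out <- out * base + s[(k - j + 1):(n - j)][seq_len(n - k)]
  }
  out
}

#' Transfer entropy between binarized patterns
#'
#' Plug-in estimate, in bits, of the directional information flow from a
#' source pattern to a target pattern:
#' `H(target_t | target history) - H(target_t | target history, source
#' history)`, with histories of `k` bins and per-bin states encoding the
#' joint activity of all neurons in each pattern. Equivalently the plug-in
#' conditional mutual information between the target's current state and the
#' source's history given the target's own history, hence always
#' non-negative and asymmetric in its arguments.
#'
#' @param source,target [binary_pattern()]s (or 0/1 vectors) with the same
#'   number of bins, `> k`.
#' @param cfg An [estimator_config()]; only `k` is used.
#' @return Transfer entropy in bits.
#' @export
transfer_entropy <- function(source, target, cfg = estimator_config()) {
  k <- cfg$k
  s <- if (is.matrix(source)) encode_states(source) else as.integer(source)
  y <- if (is.matrix(target)) encode_states(target) else as.integer(target)
  if (length(s) != length(y)) rlang::abort("patterns must share n_bins")
  n <- length(y)
  if (n <= k) rlang::abort("n_bins must exceed the history length k")
  base_s <- max(s) + 1L; base_y <- max(y) + 1L
  cur <- y[(k + 1):n]
  yh <- history_codes(y, k, base_y)
  sh <- history_codes(s, k, base_s)
  # H(cur|yh) - H(cur|yh, sh) via joint plug-in entropies
  by <- max(yh) + 1L; bs <- max(sh) + 1L; bc <- max(cur) + 1L
  h_yh <- plugin_entropy(yh)
  h_cur_yh <- plugin_entropy(cur + bc * yh)
  h_yh_sh <- plugin_entropy(yh + by * sh)
  h_cur_yh_sh <- plugin_entropy(cur + bc * (yh + by * sh))
  (h_cur_yh - h_yh) - (h_cur_yh_sh - h_yh_sh)
}

#' Redundancy of a multi-neuron pattern
#'
#' The minimum, over neurons `i`, of the estimated mutual information
#' between neuron `i`'s train and the rest of the ensemble: the part of the
#' signal most plausibly duplicated elsewhere.
#'
#' @param x A [spike_ensemble()] with at least 2 neurons.
#' @param cfg An [estimator_config()].
#' @return Scalar redundancy in `mi_log_base` units.
#' @export
redundancy <- function(x, cfg = estimator_config()) {
  if (length(x) < 2) rlang::abort("redundancy needs at least 2 neurons")
  mats <- segment_distance_matrices(x, cfg$n_periods)
  redundancy_from_matrices(mats, cfg)
}

redundancy_from_matrices <- function(mats, cfg) {
  vals <- vapply(seq_along(mats), function(i) {
    rest <- sum_matrices(mats[-i])
    mi_from_matrices(rest, mats[[i]], cfg$h, cfg$mi_log_base)
  }, numeric(1))
  min(vals)
}

#' Relative redundancy reduction between two patterns
#'
#' `(R(T1) - R(T2)) / MI(T1, T2)`: how much redundancy is removed between
#' the control and comparison pattern, relative to the information the two
#' patterns share. Antisymmetric in its arguments (the denominator is
#' symmetric under this estimator).
#'
#' @param t1,t2 [spike_ensemble()]s with at least 2 neurons each.
#' @param cfg An [estimator_config()].
#' @return An [index_value()]; invalid when the mutual information between
#'   the patterns is zero.
#' @export
redundancy_reduction <- function(t1, t2, cfg = estimator_config()) {
  m1 <- segment_distance_matrices(t1, cfg$n_periods)
  m2 <- segment_distance_matrices(t2, cfg$n_periods)
  denom <- mi_from_matrices(sum_matrices(m1), sum_matrices(m2), cfg$h,
                            cfg$mi_log_base)
  if (denom == 0) return(index_value("redundancy_reduction", NA, valid = FALSE))
  r1 <- redundancy_from_matrices(m1, cfg)
  r2 <- redundancy_from_matrices(m2, cfg)
  index_value("redundancy_reduction", (r1 - r2) / denom)
}
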