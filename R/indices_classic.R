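# Non-information-theoretic similarity indices on vectorized binary patterns
# and spike-time ensembles.

#' Index value record
#'
#' Wraps an index result with its name and a validity flag. Indices that are
#' mathematically undefined for a given input (zero variance, zero norm,
#' zero denominator) return `valid = FALSE` with `value = NA` instead of
#' propagating NaN; sweep aggregation excludes such trials.
#'
#' @param name Index name.
#' @param value Scalar value (NA when invalid).
#' @param valid Logical validity flag.
#' @export
index_value <- function(name, value, valid = TRUE) {
  structure(list(name = name, value = if (valid) value else NA_real_,
                 valid = isTRUE(valid)),
            class = "index_value")
}

#' @export
print.index_value <- function(x, ...) {
  cat("<index_value>", x$name, "=",
      if (x$valid) format(x$value) else "NA (undefined)", "\n")
  invisible(x)
}

as_bits <- function(x) {
  if (inherits(x, "binary_pattern")) vectorize_pattern(x) else as.numeric(x)
}

#' Pearson correlation between two binary pattern vectors
#'
#' Sample-moment form: `(<xy> - <x><y>) / sqrt((<x^2> - <x>^2)(<y^2> - <y>^2))`
#' with expectations taken as plain means over entries.
#'
#' @param x1,x2 Binary vectors (or [binary_pattern()]s, which are
#'   vectorized) of equal length, at least 2.
#' @return An [index_value()]; invalid when either vector has zero variance.
#' @export
index_pearson <- function(x1, x2) {
  x1 <- as_bits(x1); x2 <- as_bits(x2)
  stopifnot(length(x1) == length(x2), length(x1) >= 2)
  v1 <- mean(x1^2) - mean(x1)^2
  v2 <- mean(x2^2) - mean(x2)^2
  if (v1 <= 0 || v2 <= 0) return(index_value("pearson", NA, valid = FALSE))
  index_value("pearson", (mean(x1 * x2) - mean(x1) * mean(x2)) / sqrt(v1 * v2))
}

#' Cosine similarity between two binary pattern vectors
#'
#' Normalized dot product `x1 . x2 / (||x1|| ||x2||)`.
#'
#' @inheritParams index_pearson
#' @return An [index_value()]; invalid when either vector has zero norm.
#' @export
index_cosine <- function(x1, x2) {
  x1 <- as_bits(x1); x2 <- as_bits(x2)
  stopifnot(length(x1) == length(x2))
  n1 <- sqrt(sum(x1^2)); n2 <- sqrt(sum(x2^2))
  if (n1 == 0 || n2 == 0) return(index_value("cosine", NA, valid = FALSE))
  index_value("cosine", sum(x1 * x2) / (n1 * n2))
}

#' Scaling factor between two binary pattern vectors
#'
#' Ratio of Euclidean norms `||x1|| / ||x2||`; complements the cosine
#' similarity, which ignores norm.
#'
#' @inheritParams index_pearson
#' @return An [index_value()]; invalid when `x2` has zero norm.
#' @export
index_scaling <- function(x1, x2) {
  x1 <- as_bits(x1); x2 <- as_bits(x2)
  stopifnot(length(x1) == length(x2))
  n2 <- sqrt(sum(x2^2))
  if (n2 == 0) return(index_value("scaling_factor", NA, valid = FALSE))
  index_value("scaling_factor", sqrt(sum(x1^2)) / n2)
}

#' Bin-wise Hamming distance between two binary patterns
#'
#' Mean absolute bit difference over all neuron-bin cells; permanently
#' inactive rows are kept in the average.
#'
#' @param p1,p2 [binary_pattern()]s (or matrices) of matching shape.
#' @return An [index_value()] in `[0, 1]`.
#' @export
index_hamming <- function(p1, p2) {
  p1 <- as.matrix(p1); p2 <- as.matrix(p2)
  if (!all(dim(p1) == dim(p2))) rlang::abort("patterns must have matching shapes")
  index_value("hamming", mean(abs(p1 - p2)))
}

# Distance from each value in v to its nearest point of the sorted vector s.
nearest_dist <- function(v, s) {
  j <- findInterval(v, s)
  lo <- ifelse(j >= 1, v - s[pmax(j, 1)], Inf)
  hi <- ifelse(j < length(s), s[pmin(j + 1, length(s))] - v, Inf)
  pmin(lo, hi)
}

# Kreuz dissimilarity profile D(t) between two single-neuron trains at the
# (sorted, spike-free) evaluation times t. Auxiliary spikes at 0 and tau on
# both trains anchor the edge intervals.
kreuz_profile <- function(a, b, tau, t) {
  sa <- c(0, a, tau)
  sb <- c(0, b, tau)
  ia <- findInterval(t, sa); ib <- findInterval(t, sb)
  tP_a <- sa[ia]; tF_a <- sa[ia + 1]
  tP_b <- sb[ib]; tF_b <- sb[ib + 1]
  isi_a <- tF_a - tP_a; isi_b <- tF_b - tP_b
  xP_a <- t - tP_a; xF_a <- tF_a - t
  xP_b <- t - tP_b; xF_b <- tF_b - t
  dtP_a <- nearest_dist(tP_a, sb); dtF_a <- nearest_dist(tF_a, sb)
  dtP_b <- nearest_dist(tP_b, sa); dtF_b <- nearest_dist(tF_b, sa)
  S_a <- (dtP_a * xF_a + dtF_a * xP_a) / isi_a
  S_b <- (dtP_b * xF_b + dtF_b * xP_b) / isi_b
  (S_a * isi_b + S_b * isi_a) / (2 * ((isi_a + isi_b) / 2)^2)
}

#' SPIKE similarity between two spike-train ensembles
#'
#' For each neuron, one minus the time average over `[0, tau]` of the Kreuz
#' bivariate dissimilarity profile `D(t)` between that neuron's trains in the
#' two patterns, averaged across neurons. `D(t)` weights the distances from
#' each train's preceding/following spikes to the nearest spike of the other
#' train by the local inter-spike intervals. Auxiliary spikes at `t = 0` and
#' `t = tau` on both trains anchor the profile at the window edges; two
#' silent trains therefore compare as identical. Identical ensembles give
#' exactly 1.
#'
#' The time integral uses the midpoint rule on a uniform grid (`n_grid`
#' points), which never lands exactly on a spike time, where `D` is
#' non-smooth.
#'
#' @param t1,t2 [spike_ensemble()]s sharing `tau` and neuron count.
#' @param n_grid Midpoint-rule grid size (default 16000, i.e. 16 points per
#'   bin of a 1000-bin pattern).
#' @return An [index_value()] in `[0, 1]`.
#' @export
index_spike <- function(t1, t2, n_grid = 16000) {
  tau <- attr(t1, "tau")
  if (!identical(tau, attr(t2, "tau")) || length(t1) != length(t2)) {
    rlang::abort("ensembles must share tau and neuron count")
  }
  tm <- (seq_len(n_grid) - 0.5) * tau / n_grid
  per_neuron <- vapply(seq_along(t1), function(i) {
    1 - mean(kreuz_profile(t1[[i]], t2[[i]], tau, tm))
  }, numeric(1))
  index_value("spike", mean(per_neuron))
}
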