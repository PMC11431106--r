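# Two-neuron statistical manifold: joint law, mixed coordinates (eta1, eta2,
# theta), Fisher information and infinitesimal squared distances.

#' Joint law of a two-neuron system
#'
#' Constructs the joint probability law of a pair of binary neurons for one
#' time bin. `q_mn` is the probability that neuron 1 is in state `m` and
#' neuron 2 in state `n` (1 = active, 0 = silent).
#'
#' @param q00,q10,q01,q11 Outcome probabilities; each in `[0, 1]` and summing
#'   to 1 (within `1e-12`).
#' @return A `joint_law` object: a named numeric vector of the four outcome
#'   probabilities.
#' @examples
#' joint_law(0.25, 0.25, 0.25, 0.25)
#' law_of(coords(0.5, 0.1, 0)) # independent neurons, q11 = eta1 * eta2
#' @seealso [theta_of()], [etas_of()], [law_of()]
#' @export
joint_law <- function(q00, q10, q01, q11) {
  q <- c(q00 = q00, q10 = q10, q01 = q01, q11 = q11)
  stopifnot(is.numeric(q), length(q) == 4, !anyNA(q))
  if (any(q < 0) || any(q > 1)) {
    rlang::abort("all outcome probabilities must lie in [0, 1]")
  }
  if (abs(sum(q) - 1) > 1e-12) {
    rlang::abort(sprintf("outcome probabilities must sum to 1 (got %.15f)", sum(q)))
  }
  structure(q, class = "joint_law")
}

#' @export
print.joint_law <- function(x, ...) {
  cat("<joint_law>  q00 =", format(x[["q00"]]), " q10 =", format(x[["q10"]]),
      " q01 =", format(x[["q01"]]), " q11 =", format(x[["q11"]]), "\n")
  cat("  eta1 =", format(x[["q10"]] + x[["q11"]]),
      " eta2 =", format(x[["q01"]] + x[["q11"]]), "\n")
  invisible(x)
}

#' Mixed coordinates on the two-neuron manifold
#'
#' The manifold of two-neuron joint laws is three dimensional. The mixed
#' coordinate system used throughout this package is `(eta1, eta2, theta)`:
#' the marginal firing probability per bin of each neuron, and the
#' log-odds-ratio `theta = log(q11 q00 / (q10 q01))` measuring within-ensemble
#' correlation. `(eta1, eta2)` and `theta` are mutually orthogonal under the
#' Fisher metric, so each can be varied without moving the other.
#'
#' @param eta1,eta2 Marginal firing probabilities, strictly inside `(0, 1)`.
#' @param theta Log-odds-ratio correlation; any finite real. 0 means the two
#'   neurons fire independently.
#' @return A `coords` object (named numeric vector).
#' @export
coords <- function(eta1, eta2, theta = 0) {
  xi <- c(eta1 = eta1, eta2 = eta2, theta = theta)
  stopifnot(is.numeric(xi), length(xi) == 3, !anyNA(xi))
  if (eta1 <= 0 || eta1 >= 1 || eta2 <= 0 || eta2 >= 1) {
    rlang::abort("eta1 and eta2 must lie strictly inside (0, 1)")
  }
  if (!is.finite(theta)) {
    rlang::abort("theta must be finite")
  }
  structure(xi, class = "coords")
}

#' @export
print.coords <- function(x, ...) {
  cat("<coords>  eta1 =", format(x[["eta1"]]), " eta2 =", format(x[["eta2"]]),
      " theta =", format(x[["theta"]]), "\n")
  invisible(x)
}

#' Tangent step in mixed coordinates
#'
#' @param d_eta1,d_eta2,d_theta Coordinate increments.
#' @return A named numeric vector of length 3.
#' @export
tangent_step <- function(d_eta1 = 0, d_eta2 = 0, d_theta = 0) {
  c(d_eta1 = d_eta1, d_eta2 = d_eta2, d_theta = d_theta)
}

as_law <- function(q) {
  if (inherits(q, "joint_law")) return(q)
  if (is.numeric(q) && length(q) == 4) return(joint_law(q[[1]], q[[2]], q[[3]], q[[4]]))
  rlang::abort("expected a joint_law or a numeric vector (q00, q10, q01, q11)")
}

#' Correlation coordinate of a joint law
#'
#' The within-ensemble correlation `theta = log(q11 q00 / (q10 q01))`: zero
#' for independent neurons, diverging to `-Inf` as the neurons become
#' maximally anti-correlated (q00, q11 -> 0) and to `+Inf` as they become
#' maximally correlated (q10, q01 -> 0).
#'
#' @param q A [joint_law()] with all four probabilities strictly positive.
#' @return The log-odds-ratio (a scalar).
#' @export
theta_of <- function(q) {
  q <- as_law(q)
  if (any(q == 0)) {
    sign <- if (q[["q11"]] == 0 || q[["q00"]] == 0) "-Inf" else "+Inf"
    rlang::abort(paste0("theta undefined (infinite): diverges to ", sign))
  }
  log(q[["q11"]] * q[["q00"]] / (q[["q10"]] * q[["q01"]]))
}

#' Marginal firing probabilities of a joint law
#'
#' @param q A [joint_law()].
#' @return Named numeric vector `c(eta1, eta2)` with `eta1 = q10 + q11`,
#'   `eta2 = q01 + q11`.
#' @export
etas_of <- function(q) {
  q <- as_law(q)
  c(eta1 = q[["q10"]] + q[["q11"]], eta2 = q[["q01"]] + q[["q11"]])
}

# Feasible interval for q11 at fixed marginals (Frechet bounds).
q11_bounds <- function(eta1, eta2) {
  c(lo = max(0, eta1 + eta2 - 1), hi = min(eta1, eta2))
}

#' Joint law implied by mixed coordinates
#'
#' Inverts the coordinate map: given `(eta1, eta2, theta)` solves for the
#' coincidence probability `q11` the equation
#' `exp(theta) (eta1 - q11)(eta2 - q11) = q11 (1 - eta1 - eta2 + q11)`,
#' a quadratic in `q11` with a unique root inside the Frechet interval
#' `[max(0, eta1 + eta2 - 1), min(eta1, eta2)]` (theta is strictly increasing
#' in `q11`), then fills in the remaining outcome probabilities from the
#' marginals. At `theta = 0` this reduces to independence, `q11 = eta1 eta2`.
#'
#' @param xi A [coords()] object, or `eta1` when all three coordinates are
#'   given positionally.
#' @param eta2,theta Optional positional coordinates when `xi` is numeric.
#' @return A [joint_law()].
#' @export
law_of <- function(xi, eta2 = NULL, theta = NULL) {
  if (!inherits(xi, "coords")) {
    xi <- coords(xi, eta2, if (is.null(theta)) 0 else theta)
  }
  eta1 <- xi[["eta1"]]; eta2 <- xi[["eta2"]]; theta <- xi[["theta"]]
  b <- q11_bounds(eta1, eta2)
  A <- exp(theta)
  if (abs(theta) < 1e-12) {
    q11 <- eta1 * eta2
  } else {
    # (A-1) q^2 - [(A-1)(eta1+eta2) + 1] q + A eta1 eta2 = 0
    a2 <- A - 1
    a1 <- -((A - 1) * (eta1 + eta2) + 1)
    a0 <- A * eta1 * eta2
    disc <- a1 * a1 - 4 * a2 * a0
    q11 <- NA_real_
    if (is.finite(disc) && disc >= 0) {
      # numerically stable pair of roots
      s <- -(a1 + sign(a1) * sqrt(disc)) / 2
      roots <- c(s / a2, a0 / s)
      inside <- roots >= b[["lo"]] - 1e-12 & roots <= b[["hi"]] + 1e-12
      if (any(inside)) q11 <- roots[inside][1]
    }
    if (!is.finite(q11)) {
      # bisection on the monotone map q11 -> theta(q11)
      f <- function(q) {
        log(q) + log(1 - eta1 - eta2 + q) - log(eta1 - q) - log(eta2 - q) - theta
      }
      eps <- 1e-14
      lo <- b[["lo"]] + eps; hi <- b[["hi"]] - eps
      if (!(f(lo) < 0 && f(hi) > 0)) {
        rlang::abort("infeasible coordinates: no root in the Frechet interval")
      }
      q11 <- stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
    }
  }
  q11 <- min(max(q11, b[["lo"]]), b[["hi"]])
  q10 <- eta1 - q11
  q01 <- eta2 - q11
  q00 <- 1 - q10 - q01 - q11
  q <- pmax(c(q00, q10, q01, q11), 0)
  q <- q / sum(q)
  joint_law(q[1], q[2], q[3], q[4])
}

#' Log-probability of an outcome under mixed coordinates
#'
#' Evaluates the log-linear expansion
#' `log p(x) = x1 log(q10/q00) + x2 log(q01/q00) + theta x1 x2 + log q00`,
#' which coincides with the direct lookup `log q_{x1 x2}` of the implied law.
#'
#' @param x Binary outcome, a length-2 vector `c(x1, x2)` with entries 0/1.
#' @param xi A [coords()] object.
#' @return Scalar log-probability; `-Inf` for a zero-probability outcome.
#' @export
log_prob <- function(x, xi) {
  stopifnot(length(x) == 2, all(x %in% c(0, 1)))
  q <- law_of(xi)
  lp <- x[1] * (log(q[["q10"]]) - log(q[["q00"]])) +
    x[2] * (log(q[["q01"]]) - log(q[["q00"]])) +
    xi[["theta"]] * x[1] * x[2] +
    log(q[["q00"]])
  unname(lp)
}

coord_names <- c("eta1", "eta2", "theta")

#' Fisher information matrix in mixed coordinates
#'
#' Computes the 3x3 Fisher information matrix `g(xi_i, xi_j)` at a point of
#' the manifold: the expectation, over the four joint outcomes weighted by
#' their probabilities, of the product of score functions
#' `L(xi_i) = d log p / d xi_i`. Scores are obtained by central finite
#' differences (step `1e-6`) through the coordinate-to-law map, so only the
#' derivative is numeric -- the expectation is exact. In these coordinates
#' the marginal-rate directions are orthogonal to the correlation direction:
#' `g(eta1, theta) = g(eta2, theta) = 0`.
#'
#' @param xi A [coords()] object, strictly interior (all implied outcome
#'   probabilities and both marginals at least `1e-4` from their bounds).
#' @param step Finite-difference step for the scores.
#' @return A symmetric positive semi-definite `fisher_matrix` (3x3, ordered
#'   `eta1, eta2, theta`).
#' @export
fisher_information <- function(xi, step = 1e-6) {
  stopifnot(inherits(xi, "coords"))
  q <- law_of(xi)
  if (min(q) < 1e-4 ||
      min(xi[["eta1"]], 1 - xi[["eta1"]], xi[["eta2"]], 1 - xi[["eta2"]]) < 1e-4) {
    rlang::abort("ill-conditioned near boundary")
  }
  outcomes <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  w <- c(q[["q00"]], q[["q10"]], q[["q01"]], q[["q11"]])
  # scores[k, i] = d log p(x_k) / d xi_i
  scores <- matrix(0, 4, 3)
  for (i in 1:3) {
    up <- unclass(xi); up[i] <- up[i] + step
    dn <- unclass(xi); dn[i] <- dn[i] - step
    cu <- coords(up[[1]], up[[2]], up[[3]]); cd <- coords(dn[[1]], dn[[2]], dn[[3]])
    for (k in 1:4) {
      scores[k, i] <- (log_prob(outcomes[k, ], cu) - log_prob(outcomes[k, ], cd)) / (2 * step)
    }
  }
  G <- crossprod(scores, scores * w)
  G <- (G + t(G)) / 2
  dimnames(G) <- list(coord_names, coord_names)
  structure(G, class = c("fisher_matrix", class(G)))
}

#' @export
print.fisher_matrix <- function(x, ...) {
  cat("<fisher_matrix> metric components g(xi_i, xi_j):\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Squared infinitesimal distance between nearby laws
#'
#' The quadratic form `ds^2 = sum_ij g(xi_i, xi_j) d xi_i d xi_j` of a
#' tangent step against the Fisher matrix at `c`. Because `(eta1, eta2)` and
#' `theta` are orthogonal, a pure `d_theta` step gives
#' `g(theta, theta) d_theta^2`, and a pure `d_eta2` step gives
#' `g(eta2, eta2) d_eta2^2`. To first order `ds^2` equals twice the
#' Kullback-Leibler divergence between the laws at `xi` and `xi + d`.
#'
#' @param xi A [coords()] object.
#' @param d A [tangent_step()] (or numeric length-3 vector of increments).
#' @return Scalar squared distance.
#' @export
squared_distance <- function(xi, d) {
  stopifnot(is.numeric(d), length(d) == 3)
  target <- unclass(xi) + as.numeric(d)
  if (target[1] <= 0 || target[1] >= 1 || target[2] <= 0 || target[2] >= 1 ||
      !is.finite(target[3])) {
    rlang::abort("step leaves manifold")
  }
  G <- fisher_information(xi)
  drop(t(as.numeric(d)) %*% unclass(G) %*% as.numeric(d))
}

#' Serialize laws and coordinates as flat JSON
#'
#' @param x A [joint_law()] or [coords()] object.
#' @return A JSON string with keys `q00,q10,q01,q11` or `eta1,eta2,theta`.
#' @export
as_json <- function(x) {
  jsonlite::toJSON(as.list(unclass(x)), auto_unbox = TRUE, digits = NA)
}

#' Deserialize a joint law from flat JSON
#'
#' @param txt JSON string or path to a JSON file.
#' @return A [joint_law()].
#' @export
law_from_json <- function(txt) {
  v <- jsonlite::fromJSON(txt)
  joint_law(v$q00, v$q10, v$q01, v$q11)
}

#' Deserialize coordinates from flat JSON
#'
#' @param txt JSON string or path to a JSON file.
#' @return A [coords()].
#' @export
coords_from_json <- function(txt) {
  v <- jsonlite::fromJSON(txt)
  coords(v$eta1, v$eta2, v$theta)
}
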