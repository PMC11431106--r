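# Binary firing patterns: categorical sampling from a joint law, spike-time
# representations, text I/O, and construction of the control/comparison
# sweep pairs.

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seed for (grid point, trial, role); role 0 = control,
# 1 = comparison. Kept below 2^31 so it is a valid integer seed.
child_seed <- function(master, point, trial, role = 0) {
  as.integer((as.double(master) + 1000003 * point + 7919 * trial + 500009 * role) %%
               2147483647)
}

#' Sample a binary firing pattern from a joint law
#'
#' Draws `n_bins` i.i.d. time bins from the categorical distribution over the
#' four joint outcomes `{00, 10, 01, 11}` and records each neuron's activity
#' as a row of bits.
#'
#' @param q A [joint_law()].
#' @param n_bins Number of time bins (columns); positive integer.
#' @param seed Optional integer seed; the same seed always reproduces the
#'   same pattern, and the caller's RNG state is left untouched.
#' @return A `binary_pattern`: an integer matrix with 2 rows (neurons) and
#'   `n_bins` columns.
#' @export
sample_pattern <- function(q, n_bins, seed = NULL) {
  q <- as_law(q)
  if (length(n_bins) != 1 || n_bins <= 0) {
    rlang::abort("n_bins must be a positive integer")
  }
  n_bins <- as.integer(n_bins)
  code <- with_seed(seed, {
    sample.int(4L, n_bins, replace = TRUE, prob = as.numeric(q))
  })
  x <- rbind(as.integer(code == 2L | code == 4L),
             as.integer(code == 3L | code == 4L))
  binary_pattern(x)
}

#' Construct a binary pattern from a 0/1 matrix
#'
#' @param x Matrix of 0/1 with neurons as rows and time bins as columns.
#' @return A `binary_pattern`.
#' @export
binary_pattern <- function(x) {
  x <- as.matrix(x)
  if (!all(x %in% c(0L, 1L))) rlang::abort("pattern entries must be 0 or 1")
  if (ncol(x) < 1) rlang::abort("pattern needs at least one time bin")
  storage.mode(x) <- "integer"
  dimnames(x) <- list(paste0("neuron", seq_len(nrow(x))), NULL)
  structure(x, class = c("binary_pattern", "matrix", "array"))
}

#' @export
print.binary_pattern <- function(x, ...) {
  cat("<binary_pattern> ", nrow(x), "neurons x", ncol(x), "bins;",
      "active bins per neuron:", paste(rowSums(x), collapse = ", "), "\n")
  invisible(x)
}

#' Vectorize a binary pattern
#'
#' Flattens the pattern matrix neuron by neuron:
#' `(x_11, ..., x_1Nbins, x_21, ..., x_2Nbins, ...)`, the form on which the
#' vector-based indices (Pearson, cosine, scaling factor) operate.
#'
#' @param p A [binary_pattern()].
#' @return Integer vector of length `n_neurons * n_bins`.
#' @export
vectorize_pattern <- function(p) {
  as.integer(t(p))
}

#' Convert a binary pattern to spike times
#'
#' Each active bin contributes one spike time for its neuron within the
#' observation window `[0, tau]`. By default spikes sit at bin centers
#' (`(j - 1/2) tau / n_bins` for bin `j`), making trains symmetric under time
#' reversal of the pattern; `placement = "left"` uses the bin's left edge.
#'
#' @param p A [binary_pattern()].
#' @param tau Observation window length in ms (default 16).
#' @param placement `"center"` (default) or `"left"`.
#' @return A [spike_ensemble()].
#' @export
to_spike_times <- function(p, tau = 16, placement = c("center", "left")) {
  placement <- match.arg(placement)
  if (tau <= 0) rlang::abort("tau must be positive")
  w <- tau / ncol(p)
  off <- if (placement == "center") 0.5 else 0
  trains <- lapply(seq_len(nrow(p)), function(i) {
    (which(p[i, ] == 1L) - 1 + off) * w
  })
  spike_ensemble(trains, tau)
}

#' Spike-train ensemble
#'
#' An ensemble of per-neuron spike-time lists on a common observation window
#' `[0, tau]`.
#'
#' @param trains List of numeric vectors of strictly increasing spike times
#'   (ms), all within `[0, tau]`.
#' @param tau Window length in ms.
#' @return A `spike_ensemble` (list of trains with a `tau` attribute).
#' @export
spike_ensemble <- function(trains, tau = 16) {
  stopifnot(is.list(trains), tau > 0)
  trains <- lapply(trains, as.numeric)
  ok <- vapply(trains, function(s) {
    length(s) == 0 || (all(diff(s) > 0) && s[1] >= 0 && s[length(s)] <= tau)
  }, logical(1))
  if (!all(ok)) {
    rlang::abort("each train must be strictly increasing within [0, tau]")
  }
  structure(trains, tau = tau, class = "spike_ensemble")
}

#' @export
print.spike_ensemble <- function(x, ...) {
  cat("<spike_ensemble> ", length(x), "neurons on [0,", attr(x, "tau"), "] ms;",
      "spike counts:", paste(lengths(x), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read spike trains as plain text
#'
#' One line per neuron, whitespace-separated ascending spike times in ms;
#' an empty line denotes a silent neuron.
#'
#' @param x A [spike_ensemble()].
#' @param path File path.
#' @return `write_spike_trains()` returns `path` invisibly;
#'   `read_spike_trains()` returns a [spike_ensemble()].
#' @export
write_spike_trains <- function(x, path) {
  lines <- vapply(x, function(s) paste(format(s, trim = TRUE, digits = 15),
                                       collapse = " "), character(1))
  lines[lengths(x) == 0] <- ""
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_spike_trains
#' @param tau Window length in ms assumed for the file.
#' @export
read_spike_trains <- function(path, tau = 16) {
  lines <- readLines(path)
  trains <- lapply(lines, function(l) {
    s <- strsplit(trimws(l), "\\s+")[[1]]
    as.numeric(s[nzchar(s)])
  })
  spike_ensemble(trains, tau)
}

#' Write / read a binary pattern as CSV
#'
#' Plain 0/1 CSV with neurons as rows, no header.
#'
#' @param p A [binary_pattern()].
#' @param path File path.
#' @export
write_pattern_csv <- function(p, path) {
  utils::write.table(unclass(p), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_pattern_csv
#' @export
read_pattern_csv <- function(path) {
  binary_pattern(as.matrix(utils::read.table(path, sep = ",", header = FALSE)))
}

new_sweep_spec <- function(kind, eta1, eta2, control, grid, n_bins, n_trials,
                           seed, tau) {
  structure(list(kind = kind, eta1 = eta1, eta2 = eta2, control = control,
                 grid = grid, n_bins = as.integer(n_bins),
                 n_trials = as.integer(n_trials), seed = as.integer(seed),
                 tau = tau),
            class = "sweep_spec")
}

#' @export
print.sweep_spec <- function(x, ...) {
  cat("<sweep_spec> kind =", x$kind, " eta1 =", x$eta1, " eta2 =", x$eta2,
      "\n  ", nrow(x$grid), "grid points;", x$n_trials, "trials x", x$n_bins,
      "bins on [0,", x$tau, "] ms; seed =", x$seed, "\n")
  invisible(x)
}

#' Correlation (d-theta) sweep specification
#'
#' Builds the control/comparison pairs for the correlation experiment: both
#' neurons keep the same marginal rates (`eta2 = 1 - eta1`, so the system's
#' overall rate is fixed), while the coincidence probability `q11` is moved
#' across its feasible range. Shifting `q00` and `q11` up by `dq11` and
#' `q10`, `q01` down by the same amount leaves the marginals untouched and
#' changes only the correlation coordinate, so the comparison law is
#' `p(x; eta1, 1 - eta1, dtheta)` against the independent control
#' `p(x; eta1, 1 - eta1, 0)`. Comparisons span `q11` from `1e-2` (nearly
#' maximally anti-correlated; under `eta1 + eta2 = 1`, `q00 = q11`
#' automatically) to `eta1 - 1e-2` (nearly maximally correlated,
#' `q10 = 1e-2`).
#'
#' @param eta1 Marginal rate of neuron 1, in `(0.02, 0.5]` (the convention
#'   `eta2 >= eta1` requires `eta1 <= 0.5`).
#' @param grid_size Number of grid points; `q11` values are evenly spaced in
#'   `[1e-2, eta1 - 1e-2]`.
#' @param q11_grid Optional explicit grid of comparison `q11` values
#'   (overrides `grid_size`); must stay inside `[1e-2, eta1 - 1e-2]`.
#' @param n_bins Bins per sampled pattern (default 1000).
#' @param n_trials Control/comparison pattern pairs per grid point
#'   (default 10).
#' @param seed Master seed for the sweep; per-trial child seeds are derived
#'   deterministically from it.
#' @param tau Observation window (ms).
#' @return A `sweep_spec` whose `grid` is a tibble with the comparison law
#'   and its `dtheta` per point.
#' @export
build_dtheta_sweep <- function(eta1 = 0.5, grid_size = 21, q11_grid = NULL,
                               n_bins = 1000, n_trials = 10, seed = 1,
                               tau = 16) {
  if (eta1 > 0.5) rlang::abort("eta1 must be <= 0.5 so that eta2 = 1 - eta1 >= eta1")
  if (eta1 <= 0.02) rlang::abort("eta1 too small: the q11 range [1e-2, eta1 - 1e-2] is empty")
  eta2 <- 1 - eta1
  if (is.null(q11_grid)) {
    q11_grid <- seq(1e-2, eta1 - 1e-2, length.out = grid_size)
  }
  if (any(q11_grid < 1e-2 - 1e-12) || any(q11_grid > eta1 - 1e-2 + 1e-12)) {
    rlang::abort("q11 grid point escapes [1e-2, eta1 - 1e-2]")
  }
  control <- law_of(eta1, eta2, 0)
  theta0 <- theta_of(control) # 0 up to roundoff
  grid <- purrr::map_dfr(q11_grid, function(q11) {
    # under eta1 + eta2 = 1 the four-way dq11 shift gives q00 = q11
    law <- joint_law(q11, eta1 - q11, eta2 - q11, q11)
    tibble::tibble(q11 = q11, dtheta = theta_of(law) - theta0,
                   q00 = law[["q00"]], q10 = law[["q10"]],
                   q01 = law[["q01"]], q11_law = law[["q11"]])
  })
  grid$increment <- grid$dtheta
  new_sweep_spec("dtheta", eta1, eta2, control, grid, n_bins, n_trials, seed, tau)
}

#' Firing-rate (d-eta2) sweep specification
#'
#' Builds the control/comparison pairs for the rate experiment: the two
#' neurons fire independently (`theta = 0`, so `q11 = eta1 * eta2`), neuron 1
#' keeps marginal rate `eta1`, and neuron 2's rate is raised from the
#' baseline 0.1 by `deta2`. Control is `p(x; eta1, 0.1, 0)`, comparison
#' `p(x; eta1, 0.1 + deta2, 0)`.
#'
#' @param eta1 Marginal rate of neuron 1, in `(0, 1)`.
#' @param deta2_grid Increments for neuron 2's rate; `0.1 + deta2` must stay
#'   below 1. Default: 17 values evenly spaced in `[0, 0.8]`.
#' @inheritParams build_dtheta_sweep
#' @return A `sweep_spec`.
#' @export
build_deta2_sweep <- function(eta1 = 0.5,
                              deta2_grid = seq(0, 0.8, length.out = 17),
                              n_bins = 1000, n_trials = 10, seed = 1,
                              tau = 16) {
  if (any(0.1 + deta2_grid >= 1) || any(0.1 + deta2_grid <= 0)) {
    rlang::abort("infeasible deta2: 0.1 + deta2 must lie in (0, 1)")
  }
  control <- law_of(eta1, 0.1, 0)
  grid <- purrr::map_dfr(deta2_grid, function(de) {
    law <- law_of(eta1, 0.1 + de, 0)
    tibble::tibble(deta2 = de, eta2 = 0.1 + de,
                   q00 = law[["q00"]], q10 = law[["q10"]],
                   q01 = law[["q01"]], q11_law = law[["q11"]])
  })
  grid$increment <- grid$deta2
  new_sweep_spec("deta2", eta1, 0.1, control, grid, n_bins, n_trials, seed, tau)
}

grid_law <- function(spec, i) {
  g <- spec$grid[i, ]
  joint_law(g$q00, g$q10, g$q01, g$q11_law)
}

#' Serialize / deserialize a sweep specification as JSON
#'
#' @param spec A `sweep_spec`.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @export
sweep_spec_to_json <- function(spec, path = NULL) {
  payload <- list(kind = spec$kind, eta1 = spec$eta1, n_bins = spec$n_bins,
                  n_trials = spec$n_trials, seed = spec$seed, tau = spec$tau,
                  grid = if (spec$kind == "dtheta") spec$grid$q11 else spec$grid$deta2)
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname sweep_spec_to_json
#' @param txt JSON string or path to a JSON file.
#' @export
sweep_spec_from_json <- function(txt) {
  v <- jsonlite::fromJSON(txt)
  if (v$kind == "dtheta") {
    build_dtheta_sweep(eta1 = v$eta1, q11_grid = v$grid, n_bins = v$n_bins,
                       n_trials = v$n_trials, seed = v$seed, tau = v$tau)
  } else if (v$kind == "deta2") {
    build_deta2_sweep(eta1 = v$eta1, deta2_grid = v$grid, n_bins = v$n_bins,
                      n_trials = v$n_trials, seed = v$seed, tau = v$tau)
  } else {
    rlang::abort(sprintf("unknown sweep kind '%s'", v$kind))
  }
}
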