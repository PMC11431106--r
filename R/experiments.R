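# Sweep experiments: apply the eight indices to sampled control/comparison
# pattern pairs across a grid of coordinate increments and aggregate
# mean +/- SEM over trials.

all_indices <- c("pearson", "cosine", "scaling_factor", "hamming", "spike",
                 "mi", "te", "redundancy_reduction")

#' All eight indices on one control/comparison pattern pair
#'
#' Computes the requested indices on a pair of binary patterns: the
#' vector-based indices on the vectorized patterns, the Hamming distance on
#' the pattern matrices, and the spike-time indices on the bin-center
#' spike-train representations. Mutual information, transfer entropy and
#' redundancy reduction share one set of segment distance tables per
#' pattern.
#'
#' @param control,comparison [binary_pattern()]s of matching shape.
#' @param cfg An [estimator_config()].
#' @param tau Observation window (ms) for the spike-time representations.
#' @param indices Character vector naming the indices to compute (subset of
#'   `pearson, cosine, scaling_factor, hamming, spike, mi, te,
#'   redundancy_reduction`).
#' @param spike_grid Midpoint-rule grid size for the SPIKE similarity;
#'   default 16 points per bin.
#' @return One-row tibble with a `<index>` value column and `<index>_valid`
#'   flag per requested index.
#' @export
pattern_indices <- function(control, comparison, cfg = estimator_config(),
                            tau = 16, indices = all_indices,
                            spike_grid = 16 * ncol(control)) {
  indices <- match.arg(indices, all_indices, several.ok = TRUE)
  out <- list()
  put <- function(iv) {
    out[[iv$name]] <<- iv$value
    out[[paste0(iv$name, "_valid")]] <<- iv$valid
  }
  if (any(indices %in% c("pearson", "cosine", "scaling_factor"))) {
    v1 <- vectorize_pattern(control); v2 <- vectorize_pattern(comparison)
    if ("pearson" %in% indices) put(index_pearson(v1, v2))
    if ("cosine" %in% indices) put(index_cosine(v1, v2))
    if ("scaling_factor" %in% indices) put(index_scaling(v1, v2))
  }
  if ("hamming" %in% indices) put(index_hamming(control, comparison))
  need_trains <- any(indices %in% c("spike", "mi", "redundancy_reduction"))
  if (need_trains) {
    s1 <- to_spike_times(control, tau)
    s2 <- to_spike_times(comparison, tau)
    if ("spike" %in% indices) put(index_spike(s1, s2, n_grid = spike_grid))
    if (any(indices %in% c("mi", "redundancy_reduction"))) {
      m1 <- segment_distance_matrices(s1, cfg$n_periods)
      m2 <- segment_distance_matrices(s2, cfg$n_periods)
      joint <- mi_from_matrices(sum_matrices(m1), sum_matrices(m2), cfg$h,
                                cfg$mi_log_base)
      if ("mi" %in% indices) put(index_value("mi", joint))
      if ("redundancy_reduction" %in% indices) {
        if (joint == 0) {
          put(index_value("redundancy_reduction", NA, valid = FALSE))
        } else {
          r1 <- redundancy_from_matrices(m1, cfg)
          r2 <- redundancy_from_matrices(m2, cfg)
          put(index_value("redundancy_reduction", (r1 - r2) / joint))
        }
      }
    }
  }
  if ("te" %in% indices) {
    put(index_value("te", transfer_entropy(control, comparison, cfg)))
  }
  tibble::as_tibble(out)
}

#' Run a sweep experiment
#'
#' For every grid point of the sweep, draws `n_trials` independent
#' control/comparison pattern pairs (the control is re-sampled each trial,
#' so trial-to-trial variability enters both members of the pair), computes
#' the requested indices on each pair, and aggregates mean, SEM and the
#' number of valid trials per index. Fully deterministic given the sweep's
#' master seed: each (grid point, trial, member) gets a derived child seed.
#'
#' @param spec A sweep specification from [build_dtheta_sweep()] or
#'   [build_deta2_sweep()].
#' @param cfg An [estimator_config()].
#' @param indices Indices to compute (see [pattern_indices()]).
#' @return A `sweep_result`: a tibble with one row per grid point, columns
#'   `kind`, `eta1`, `increment`, and `<index>_mean`, `<index>_sem`,
#'   `<index>_n` per index, carrying the provenance (seed, n_bins, n_trials,
#'   estimator config) as attributes.
#' @export
run_sweep <- function(spec, cfg = estimator_config(), indices = all_indices) {
  stopifnot(inherits(spec, "sweep_spec"))
  indices <- match.arg(indices, all_indices, several.ok = TRUE)
  n_invalid <- 0L
  rows <- purrr::map_dfr(seq_len(nrow(spec$grid)), function(i) {
    comp_law <- grid_law(spec, i)
    trials <- purrr::map_dfr(seq_len(spec$n_trials), function(tr) {
      control <- sample_pattern(spec$control, spec$n_bins,
                                seed = child_seed(spec$seed, i, tr, 0))
      comparison <- sample_pattern(comp_law, spec$n_bins,
                                   seed = child_seed(spec$seed, i, tr, 1))
      pattern_indices(control, comparison, cfg = cfg, tau = spec$tau,
                      indices = indices)
    })
    agg <- list(kind = spec$kind, eta1 = spec$eta1,
                increment = spec$grid$increment[i])
    for (ix in indices) {
      v <- trials[[ix]][trials[[paste0(ix, "_valid")]]]
      n_invalid <<- n_invalid + sum(!trials[[paste0(ix, "_valid")]])
      agg[[paste0(ix, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      agg[[paste0(ix, "_sem")]] <- if (length(v) > 1) {
        stats::sd(v) / sqrt(length(v))
      } else {
        NA_real_
      }
      agg[[paste0(ix, "_n")]] <- length(v)
    }
    tibble::as_tibble(agg)
  })
  if (n_invalid > 0) {
    rlang::warn(sprintf("%d invalid index trials excluded from sweep averages",
                        n_invalid))
  }
  structure(rows,
            class = c("sweep_result", class(rows)),
            indices = indices,
            provenance = list(kind = spec$kind, eta1 = spec$eta1,
                              seed = spec$seed, n_bins = spec$n_bins,
                              n_trials = spec$n_trials, tau = spec$tau,
                              cfg = unclass(cfg), n_invalid = n_invalid))
}

#' Write sweep results to CSV with a JSON provenance sidecar
#'
#' The CSV holds one row per grid point (numbers printed at full double
#' precision); a `.json` sidecar next to it records the provenance (sweep
#' kind, seed, sizes, estimator config) so results round-trip through
#' [read_results()].
#'
#' @param r A `sweep_result`.
#' @param path CSV path; the sidecar replaces the extension with `.json`.
#' @return `path`, invisibly.
#' @export
write_results <- function(r, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    rlang::abort(sprintf("directory '%s' does not exist", dir))
  }
  df <- as.data.frame(r)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = TRUE)
  sidecar <- paste0(sub("\\.[^./]*$", "", path), ".json")
  meta <- attr(r, "provenance")
  meta$indices <- attr(r, "indices")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read sweep results written by [write_results()]
#'
#' @param path CSV path.
#' @return A `sweep_result` tibble with provenance restored.
#' @export
read_results <- function(path) {
  df <- utils::read.table(path, sep = ",", header = TRUE,
                          stringsAsFactors = FALSE)
  num <- setdiff(names(df), "kind")
  df[num] <- lapply(df[num], as.numeric)
  intcols <- grep("_n$", names(df), value = TRUE)
  df[intcols] <- lapply(df[intcols], as.integer)
  sidecar <- paste0(sub("\\.[^./]*$", "", path), ".json")
  meta <- jsonlite::fromJSON(sidecar)
  indices <- meta$indices
  meta$indices <- NULL
  meta$cfg <- as.list(meta$cfg)
  out <- tibble::as_tibble(df)
  structure(out, class = c("sweep_result", class(out)),
            indices = indices, provenance = meta)
}

#' Monotone-trend summary of a sweep result
#'
#' For each index, the Spearman rank correlation between the per-point mean
#' and the coordinate increment, with a two-sided permutation p-value
#' (permuting the grid order). A rank correlation of +1/-1 flags a strictly
#' monotone response; an index that does not respond to the increment shows
#' a small correlation with a non-significant p-value.
#'
#' @param r A `sweep_result` with at least 3 grid points.
#' @param n_perm Number of permutations (default 2000).
#' @param seed Seed for the permutation draw.
#' @return A tibble with columns `index`, `rank_correlation`, `p_value`,
#'   `n_points`, `defined` (`FALSE` when the index column is constant, in
#'   which case the correlation is undefined).
#' @export
summarize_trends <- function(r, n_perm = 2000, seed = 1) {
  if (nrow(r) < 3) rlang::abort("need at least 3 grid points")
  indices <- attr(r, "indices")
  inc <- r$increment
  with_seed(seed, {
    purrr::map_dfr(indices, function(ix) {
      m <- r[[paste0(ix, "_mean")]]
      ok <- is.finite(m)
      if (sum(ok) < 3 || stats::sd(m[ok]) == 0) {
        return(tibble::tibble(index = ix, rank_correlation = NA_real_,
                              p_value = NA_real_, n_points = sum(ok),
                              defined = FALSE))
      }
      rho <- stats::cor(inc[ok], m[ok], method = "spearman")
      perm <- vapply(seq_len(n_perm), function(b) {
        stats::cor(inc[ok], sample(m[ok]), method = "spearman")
      }, numeric(1))
      p <- (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
      tibble::tibble(index = ix, rank_correlation = rho, p_value = p,
                     n_points = sum(ok), defined = TRUE)
    })
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a sweep result into long format
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return A tibble with one row per (grid point, index): `kind`, `eta1`,
#'   `increment`, `index`, `mean`, `sem`, `n_valid`.
#' @export
tidy.sweep_result <- function(x, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(x),
    cols = -c("kind", "eta1", "increment"),
    names_to = c("index", ".value"),
    names_pattern = "(.*)_(mean|sem|n)$"
  )
  dplyr::rename(long, n_valid = "n")
}

#' One-row summary of a sweep result
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return A tibble with the sweep kind, base coordinates, sizes, seed and
#'   the number of invalid trials excluded.
#' @export
glance.sweep_result <- function(x, ...) {
  p <- attr(x, "provenance")
  tibble::tibble(kind = p$kind, eta1 = p$eta1, n_points = nrow(x),
                 n_trials = p$n_trials, n_bins = p$n_bins, tau = p$tau,
                 seed = p$seed, n_invalid = p$n_invalid)
}

#' Plot a sweep result
#'
#' Mean +/- SEM of each index against the coordinate increment, one panel
#' per index.
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, ...) {
  long <- tidy(object)
  xlab <- if (unique(long$kind) == "dtheta") "dθ" else "dη2"
  ggplot2::ggplot(long, ggplot2::aes(x = .data$increment, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem),
                             size = 0.25) +
    ggplot2::geom_line(linewidth = 0.3, alpha = 0.6) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = xlab, y = "index value (mean ± SEM)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
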