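#' Assign a reference-rhythm phase to each spike
#'
#' For every spike falling inside one of the supplied episode windows, the
#' instantaneous phase of the reference rhythm (whisking or theta) at the
#' spike time is obtained by linear interpolation of the unwrapped phase and
#' re-wrapped. Spikes outside the windows (or outside phase coverage) are
#' dropped, with counts reported.
#'
#' @param spikes A [spike_train].
#' @param phase A `phase_series`.
#' @param windows Data frame of episode windows (`start_s`, `end_s`), e.g.
#'   from [segment_episodes()]; NULL uses the full phase coverage.
#' @param method `"linear"` (interpolate unwrapped phase) or `"nearest"`
#'   (phase of the nearest sample).
#' @return List with `phases` (radians, one per used spike), `spike_times_s`,
#'   `n_dropped`.
#' @export
assign_spike_phases <- function(spikes, phase, windows = NULL,
                                method = c("linear", "nearest")) {
  method <- match.arg(method)
  t_sp <- spikes$spike_times_s
  t0 <- phase$start_time_s
  t1 <- t0 + (length(phase$phases) - 1) / phase$sample_rate_hz
  keep <- t_sp >= t0 & t_sp <= t1
  if (!is.null(windows) && nrow(windows)) {
    o <- order(windows$start_s)
    starts <- windows$start_s[o]; ends <- windows$end_s[o]
    if (any(starts[-1] < ends[-length(ends)])) {
      # overlapping windows: fall back to the per-window scan
      in_any <- rep(FALSE, length(t_sp))
      for (i in seq_along(starts))
        in_any <- in_any | (t_sp >= starts[i] & t_sp < ends[i])
    } else {
      idx <- findInterval(t_sp, starts)
      in_any <- idx >= 1 & t_sp < ends[pmax(idx, 1)]
    }
    keep <- keep & in_any
  }
  used <- t_sp[keep]
  if (!length(used))
    return(list(phases = numeric(0), spike_times_s = used,
                n_dropped = length(t_sp)))
  phi <- if (method == "linear") {
    phase_at_times(phase, used)
  } else {
    idx <- pmin(pmax(round((used - t0) * phase$sample_rate_hz) + 1, 1),
                length(phase$phases))
    phase$phases[idx]
  }
  list(phases = phi, spike_times_s = used, n_dropped = length(t_sp) - length(used))
}

#' Pooled spike-phase histogram
#'
#' 36-bin (10 degree) probability histogram of spike phases, with the
#' circular-mean arrow (angle = circular mean, length = von Mises
#' concentration). The shuffle control destroys the spike-phase relationship
#' by assigning each spike a phase drawn at random from the supplied phase
#' pool (the within-window phase samples), which preserves any residual
#' phase-occupancy bias rather than assuming a uniform cycle.
#'
#' @param phases Spike phases in radians.
#' @param shuffle_control Build the shuffled control histogram as well.
#' @param phase_pool Phase sample pool for the control (defaults to the spike
#'   phases themselves).
#' @param n_bins Number of bins (36 = 10 degrees).
#' @param seed Optional RNG seed for the control.
#' @return Object of class `phase_histogram`: `bin_edges`, `bin_centers`,
#'   `probabilities`, `mean_angle_rad`, `kappa`, `n`, `rayleigh_p`, and
#'   optionally `control` (a `phase_histogram`).
#' @export
pooled_phase_histogram <- function(phases, shuffle_control = FALSE,
                                   phase_pool = NULL, n_bins = 36,
                                   seed = NULL) {
  if (!length(phases)) stop("pooled_phase_histogram: no spike phases")
  if (!is.null(seed)) set.seed(seed)
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  counts <- tabulate(findInterval(phases, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  fit <- if (length(phases) >= 10) fit_von_mises(phases) else NULL
  rt <- if (length(phases) >= 2) rayleigh_test(phases) else NULL
  out <- structure(list(
    bin_edges = edges, bin_centers = (edges[-1] + edges[-(n_bins + 1)]) / 2,
    probabilities = counts / sum(counts),
    mean_angle_rad = circ_mean(phases),
    kappa = if (!is.null(fit)) fit$kappa else NA_real_,
    n = length(phases),
    rayleigh_p = if (!is.null(rt)) rt$p else NA_real_),
    class = "phase_histogram")
  if (shuffle_control) {
    pool <- if (is.null(phase_pool)) phases else phase_pool
    shuffled <- sample(pool, length(phases), replace = TRUE)
    out$control <- pooled_phase_histogram(shuffled, shuffle_control = FALSE,
                                          n_bins = n_bins)
  }
  out
}

#' @export
print.phase_histogram <- function(x, ...) {
  cat(sprintf("<phase_histogram> %d spikes in %d bins; mean %.2f rad, kappa %.3f, Rayleigh p = %.3g\n",
              x$n, length(x$probabilities), x$mean_angle_rad, x$kappa,
              x$rayleigh_p))
  invisible(x)
}

#' @export
plot.phase_histogram <- function(x, main = "spike phase distribution", ...) {
  th <- x$bin_centers
  r <- x$probabilities
  graphics::plot(c(-1, 1) * max(r) * 1.2, c(-1, 1) * max(r) * 1.2,
                 type = "n", asp = 1, xlab = "", ylab = "", main = main,
                 axes = FALSE)
  for (i in seq_along(th)) {
    a <- seq(x$bin_edges[i], x$bin_edges[i + 1], length.out = 8)
    graphics::polygon(c(0, r[i] * cos(a), 0), c(0, r[i] * sin(a), 0),
                      border = "black", col = "grey85")
  }
  graphics::arrows(0, 0, 0.9 * max(r) * cos(x$mean_angle_rad) * min(x$kappa, 1),
                   0.9 * max(r) * sin(x$mean_angle_rad) * min(x$kappa, 1),
                   length = 0.08, lwd = 2)
  invisible(x)
}

#' Equal-sample bootstrap of phase-locking statistics across conditions
#'
#' The mean resultant length, and with it the Rayleigh Z and the fitted
#' concentration kappa, depend on sample size, so conditions with different
#' spike counts cannot be compared directly. This bootstrap resamples each
#' condition's spike-phase pool to the size of the smallest condition
#' (without replacement) for `n_iter` iterations, computing Z and kappa in
#' each, and reports the medians per condition.
#'
#' @param condition_phase_sets Named list of phase vectors, one per condition.
#' @param n_iter Bootstrap iterations.
#' @param min_spikes Conditions with fewer spikes are excluded (flagged).
#' @param seed Optional RNG seed.
#' @return List with `resample_size`, `median_Z`, `median_kappa`
#'   (named per condition), `excluded`, `n_iter`.
#' @export
bootstrap_equal_size <- function(condition_phase_sets, n_iter = 500,
                                 min_spikes = 10, seed = NULL) {
  if (length(condition_phase_sets) < 2)
    stop("bootstrap_equal_size: need >= 2 conditions")
  if (!is.null(seed)) set.seed(seed)
  sizes <- lengths(condition_phase_sets)
  excluded <- names(condition_phase_sets)[sizes < min_spikes]
  keep <- condition_phase_sets[sizes >= min_spikes]
  if (length(keep) < 2)
    stop("bootstrap_equal_size: fewer than 2 conditions with enough spikes")
  n_common <- min(lengths(keep))
  med_Z <- med_k <- stats::setNames(numeric(length(keep)), names(keep))
  for (cn in names(keep)) {
    ph <- keep[[cn]]
    Zs <- ks <- numeric(n_iter)
    for (i in seq_len(n_iter)) {
      sub <- ph[sample.int(length(ph), n_common)]
      r <- circ_r(sub)
      Zs[i] <- 2 * n_common * r^2
      ks[i] <- fit_von_mises_kappa(r)
    }
    med_Z[cn] <- stats::median(Zs)
    med_k[cn] <- stats::median(ks)
  }
  list(resample_size = n_common, median_Z = med_Z, median_kappa = med_k,
       excluded = excluded, n_iter = n_iter)
}

# kappa from a resultant length alone (the bootstrap inner loop does not need
# the full fit object)
fit_von_mises_kappa <- function(r, kappa_max = 1e3) {
  if (r < 1e-8) return(0)
  if (r >= 1 - 1e-9) return(kappa_max)
  f <- function(k) bessel_ratio_A1(k) - r
  upper <- 2
  while (f(upper) < 0 && upper < kappa_max) upper <- upper * 2
  upper <- min(upper, kappa_max)
  if (f(upper) < 0) return(kappa_max)
  stats::uniroot(f, c(0, upper), tol = 1e-10)$root
}

#' Population summary of per-neuron phase preference
#'
#' Applies the spike-count inclusion rule (neurons with fewer than
#' `min_spikes` spikes in the condition are excluded unless their Rayleigh
#' test is significant), flags per-neuron significance (Rayleigh p < alpha),
#' and summarizes the population: Rayleigh test across the included neurons'
#' preferred phases, mean preferred direction, the concentration of preferred
#' phases, and the proportion of significantly locked neurons.
#'
#' @param fits List of [fit_von_mises()] objects (one per neuron).
#' @param min_spikes Inclusion threshold on the spike count.
#' @param alpha Per-neuron Rayleigh significance level.
#' @param locked_only Population statistics computed over significantly
#'   locked neurons only (as opposed to all included neurons).
#' @return List of class `population_phase_summary`.
#' @export
population_phase_summary <- function(fits, min_spikes = 1000, alpha = 0.05,
                                     locked_only = TRUE) {
  sig <- vapply(fits, function(f) f$p_value < alpha, logical(1))
  ns <- vapply(fits, `[[`, numeric(1), "n")
  included <- ns >= min_spikes | sig
  if (!any(included)) {
    return(structure(list(n_neurons = length(fits), n_included = 0,
                          empty = TRUE),
                     class = "population_phase_summary"))
  }
  use <- if (locked_only) included & sig else included
  prefs <- vapply(fits[use], `[[`, numeric(1), "theta_mean")
  pop <- if (sum(use) >= 2) rayleigh_test(prefs) else NULL
  structure(list(
    n_neurons = length(fits),
    n_included = sum(included),
    n_locked = sum(sig & included),
    prop_locked = sum(sig & included) / sum(included),
    preferred_phases = prefs,
    mean_direction_rad = if (length(prefs)) circ_mean(prefs) else NA_real_,
    concentration_kappa = if (length(prefs) >= 10)
      fit_von_mises(prefs)$kappa else NA_real_,
    population_rayleigh_p = if (!is.null(pop)) pop$p else NA_real_,
    empty = FALSE),
    class = "population_phase_summary")
}

#' @export
print.population_phase_summary <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("population phase summary: no neurons passed the inclusion rule\n")
    return(invisible(x))
  }
  cat(sprintf("population phase summary: %d/%d neurons included, %d locked (%.0f%%)\n",
              x$n_included, x$n_neurons, x$n_locked, 100 * x$prop_locked))
  cat(sprintf("  mean preferred phase %.2f rad; population Rayleigh p = %.3g\n",
              x$mean_direction_rad, x$population_rayleigh_p))
  invisible(x)
}
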