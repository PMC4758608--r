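#' Run the full analysis pipeline on a session
#'
#' Orchestrates the complete analysis: band-pass filtering and Hilbert phase
#' extraction (with rank-based bias correction) for LFP and whisking, episode
#' segmentation, per-trial PSI over approach/touch windows with the bootstrap
#' chance level, phase-delay statistics, PSI/behavior statistics, episode
#' power spectra with baseline normalization and theta peaks, and per-unit
#' spike phase-locking statistics relative to theta.
#'
#' @param x A `sim_config` (the session is generated), a `tw_session`, or a
#'   path to a session directory (see [read_session()]).
#' @param seed Seed for all resampling stages (chance level, randomization
#'   tests, shuffle controls). When `x` is a `sim_config` with `seed = NULL`,
#'   this seed also drives generation.
#' @param psi_win_s PSI window length (s).
#' @param n_psi_shuffles Shuffle sets for the PSI chance level.
#' @param n_randomization Iterations for the behavior randomization test.
#' @param spectra,spikes Logical switches for the spectral and spike-phase
#'   stages.
#' @return Object of class `tw_analysis`.
#' @export
run_pipeline <- function(x, seed = 1, psi_win_s = 0.25, n_psi_shuffles = 2000,
                         n_randomization = 10000, spectra = TRUE,
                         spikes = TRUE) {
  if (inherits(x, "sim_config")) {
    if (is.null(x$seed)) x$seed <- seed
    session <- gen_session(x)
  } else if (inherits(x, "tw_session")) {
    session <- x
  } else if (is.character(x)) {
    session <- read_session(x)
  } else stop("run_pipeline: x must be a sim_config, tw_session, or path")
  set.seed(seed)

  episodes <- segment_episodes(session$events)
  theta <- psi_bias_correct(instantaneous_phase(bandpass_theta(session$lfp)))
  whisk <- psi_bias_correct(instantaneous_phase(bandpass_theta(session$whisking)))

  ## PSI stage
  psi_tab <- trial_psi_table(theta, whisk, session$events, win_s = psi_win_s)
  touch_windows <- collect_psi_windows(theta, whisk, session$events,
                                       "touch", win_s = psi_win_s)
  chance <- psi_chance_level(touch_windows, n_shuffles = n_psi_shuffles)
  delay <- list(
    approach = try_or_null(phase_delay_stats(psi_tab$delay_approach_rad,
                                             psi_tab$psi_approach,
                                             chance$chance_level)),
    touch = try_or_null(phase_delay_stats(psi_tab$delay_touch_rad,
                                          psi_tab$psi_touch,
                                          chance$chance_level)))
  durations <- session$events$contact_offset_s - session$events$contact_onset_s
  metrics <- trial_metrics(psi_tab, durations, session$events$correct)
  behavior <- psi_behavior_tests(metrics, n_randomization = n_randomization)

  ## spectral stage
  spectra_out <- NULL
  if (spectra) {
    spectra_out <- episode_spectra_report(session$lfp, episodes)
  }

  ## spike-phase stage
  spikes_out <- NULL
  if (spikes && length(session$spikes)) {
    spikes_out <- spike_phase_report(session$spikes, theta, episodes,
                                     session$events)
  }

  structure(list(
    events = session$events, episodes = episodes,
    psi = list(trial_table = psi_tab, chance = chance, delay = delay,
               mean_psi_approach = mean(psi_tab$psi_approach),
               mean_psi_touch = mean(psi_tab$psi_touch)),
    metrics = metrics, behavior = behavior,
    spectra = spectra_out, spikes = spikes_out,
    truth = session$truth,
    provenance = list(seed = seed, psi_win_s = psi_win_s,
                      n_psi_shuffles = n_psi_shuffles,
                      n_randomization = n_randomization,
                      package_version = as.character(utils::packageVersion("thetawhisk")))),
    class = "tw_analysis")
}

try_or_null <- function(expr) {
  tryCatch(expr, error = function(e) NULL)
}

# per-episode LFP spectra, baseline normalization, theta peaks
episode_spectra_report <- function(lfp, episodes, f_range = c(4, 20)) {
  fs <- lfp$sample_rate_hz
  ep_names <- c("baseline", "approach", "touch", "reward")
  ests <- list()
  for (ep in ep_names) {
    w <- episodes[episodes$label == ep, ]
    if (!nrow(w)) next
    segs <- lapply(seq_len(nrow(w)), function(i)
      extract_window(lfp, w[i, ]))
    # touch windows vary in duration: use the standard first 500 ms where
    # available, dropping shorter touches (all fixed windows are 500 ms)
    len <- round(0.5 * fs)
    segs <- lapply(segs, function(s) if (length(s) >= len) s[seq_len(len)] else NULL)
    segs <- segs[!vapply(segs, is.null, logical(1))]
    if (length(segs) < 2) next
    ests[[ep]] <- episode_spectrum(segs, fs, f_range = f_range)
  }
  normalized <- NULL
  peaks <- NULL
  if (!is.null(ests$baseline)) {
    normalized <- lapply(ests, normalize_power,
                         baseline_estimate = ests$baseline)
    peaks <- lapply(ests, function(e) peak_theta_frequency(e)$value_hz)
  }
  list(estimates = ests, normalized = normalized, peaks = peaks)
}

# per-unit von Mises fits per condition + population summaries
spike_phase_report <- function(spike_list, theta_phase, episodes, events,
                               min_spikes = 1000) {
  conds <- list(
    waiting = waiting_windows(events),
    approach = episodes[episodes$label == "approach", ],
    touch = episodes[episodes$label == "touch", ])
  per_unit <- lapply(spike_list, function(sp) {
    lapply(conds, function(w) {
      if (!nrow(w)) return(NULL)
      ph <- assign_spike_phases(sp, theta_phase, w)$phases
      if (length(ph) < 10) return(NULL)
      fit_von_mises(ph)
    })
  })
  names(per_unit) <- vapply(spike_list, `[[`, character(1), "unit_id")
  population <- lapply(c("waiting", "approach", "touch"), function(cn) {
    fits <- Filter(Negate(is.null), lapply(per_unit, `[[`, cn))
    if (!length(fits)) return(NULL)
    population_phase_summary(fits, min_spikes = min_spikes)
  })
  names(population) <- c("waiting", "approach", "touch")
  pooled <- lapply(c("waiting", "approach", "touch"), function(cn) {
    phs <- unlist(lapply(seq_along(spike_list), function(i) {
      f <- per_unit[[i]][[cn]]
      if (is.null(f) || f$p_value >= 0.05) return(NULL)
      assign_spike_phases(spike_list[[i]], theta_phase, conds[[cn]])$phases
    }))
    if (length(phs) < 10) return(NULL)
    pooled_phase_histogram(phs, shuffle_control = TRUE,
                           phase_pool = theta_phase$phases)
  })
  names(pooled) <- c("waiting", "approach", "touch")
  list(per_unit = per_unit, population = population, pooled = pooled)
}

#' @export
print.tw_analysis <- function(x, ...) {
  cat(sprintf("<tw_analysis> %d trials\n", nrow(x$events)))
  cat(sprintf("  mean PSI: approach %.3f, touch %.3f; chance level %.3f (%s)\n",
              x$psi$mean_psi_approach, x$psi$mean_psi_touch,
              x$psi$chance$chance_level,
              if (x$psi$chance$exceeds) "observed above chance" else "not above chance"))
  if (!is.null(x$behavior$correlation$overall))
    cat(sprintf("  PSI change vs speed: r = %.3f, p = %.2g\n",
                x$behavior$correlation$overall$r,
                x$behavior$correlation$overall$p))
  if (!is.null(x$spectra$peaks))
    cat("  theta peaks (Hz):",
        paste(sprintf("%s %.2f", names(x$spectra$peaks),
                      unlist(x$spectra$peaks)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.tw_analysis <- function(object, ...) {
  print(object)
  cat("\nBehavior statistics:\n")
  print(object$behavior)
  if (!is.null(object$spikes)) {
    cat("\nSpike phase locking (theta reference):\n")
    for (cn in names(object$spikes$population)) {
      p <- object$spikes$population[[cn]]
      if (is.null(p) || isTRUE(p$empty)) next
      cat(sprintf("  %s: %d/%d units locked\n", cn, p$n_locked, p$n_included))
    }
  }
  invisible(object)
}

#' @export
plot.tw_analysis <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  if (!is.null(x$spectra$normalized)) {
    cols <- c(baseline = "grey40", approach = "steelblue",
              touch = "forestgreen", reward = "grey70")
    first <- TRUE
    for (ep in names(x$spectra$normalized)) {
      e <- x$spectra$normalized[[ep]]
      if (first) {
        graphics::plot(e$frequencies_hz, e$power, type = "l",
                       col = cols[[ep]], xlab = "frequency (Hz)",
                       ylab = "normalized power", main = "episode spectra")
        first <- FALSE
      } else graphics::lines(e$frequencies_hz, e$power, col = cols[[ep]])
    }
    graphics::legend("topright", legend = names(x$spectra$normalized),
                     col = cols[names(x$spectra$normalized)], lty = 1, cex = 0.8)
  }
  graphics::hist(x$psi$chance$shuffled_psi, breaks = 30,
                 main = "PSI chance distribution", xlab = "shuffle-set mean PSI")
  graphics::abline(v = x$psi$chance$observed_mean, col = "red", lwd = 2)
  graphics::abline(v = x$psi$chance$chance_level, col = "blue", lty = 2)
  invisible(x)
}
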