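#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic-session generator.
#' Defaults encode the recording and task conditions the analysis is designed
#' for: LFP digitized at 2 kHz, whisking tracked at 1,000 frames/s, theta and
#' whisking rhythms inside the 5-12 Hz band (theta near 8 Hz, whisking near
#' 10 Hz during palpation), touch episodes of 540 +/- 224 ms, and coupling
#' between the rhythms that steps up during approach and touch.
#'
#' @param duration_s Duration for free-running signal generation
#'   ([gen_coupled_pair()]); trial-structured sessions derive their duration
#'   from `n_trials`.
#' @param lfp_rate_hz,whisk_rate_hz Sampling rates (samples/s).
#' @param f_theta_hz,f_whisk_hz Oscillator center frequencies (5-12 Hz).
#' @param phase_noise_sd Phase-diffusion intensity, rad/sqrt(s).
#' @param coupling_eps Base coupling strength (1/s, >= 0) of the sine pull of
#'   theta phase on whisking phase; per-episode multipliers scale it.
#' @param coupling_lag_rad Target phase delay (theta minus whisking) toward
#'   which the coupling pulls.
#' @param episode_gains List with numeric vectors `amplitude` and `coupling`,
#'   each with entries `baseline`, `approach`, `touch`, `other`: stepwise
#'   multipliers applied within the corresponding episode.
#' @param theta_amp_uV,whisk_amp_deg Oscillation amplitudes.
#' @param whisk_offset_deg Whisker set-point angle.
#' @param lfp_noise_sd_uV SD of the additive 1/f (pink) LFP background.
#' @param whisk_noise_sd_deg SD of the additive white whisking noise.
#' @param kappa_gen,theta_gen von Mises concentration and mean phase of spike
#'   modulation relative to theta phase.
#' @param base_rate_hz Mean firing rate of each simulated unit.
#' @param n_units Number of simulated units per session.
#' @param n_trials Number of trials in a session.
#' @param touch_dur_mean_s,touch_dur_sd_s Touch-duration distribution.
#' @param turn_dur_mean_s,turn_dur_sd_s Turn-duration distribution.
#' @param iti_gap_s Extra inter-trial gap appended after each trial's reward
#'   tail. The task's inter-trial intervals are long (several seconds while
#'   the bridge is withdrawn); the generator compresses them to keep sessions
#'   compact while leaving a pre-trial waiting span long enough for
#'   waiting-period spike analyses.
#' @param behavior_r_target Planted Pearson correlation between PSI change
#'   (touch minus approach) and normalized trial duration.
#' @param p_correct_link List with `base_rate` (session-mean probability of a
#'   correct choice) and `psi_effect` (planted difference in mean PSI-touch,
#'   correct minus incorrect trials; 0 = flat link).
#' @param seed RNG seed (integer) or NULL to use the current RNG state.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(duration_s = 100,
                       lfp_rate_hz = 2000,
                       whisk_rate_hz = 1000,
                       f_theta_hz = 8,
                       f_whisk_hz = 10,
                       phase_noise_sd = 3,
                       coupling_eps = 30,
                       coupling_lag_rad = 1.63,
                       episode_gains = list(
                         amplitude = c(baseline = 1, approach = 1.5,
                                       touch = 1.6, other = 0.9),
                         coupling = c(baseline = 0.05, approach = 0.8,
                                      touch = 1, other = 0.05)),
                       theta_amp_uV = 100,
                       whisk_amp_deg = 15,
                       whisk_offset_deg = 90,
                       lfp_noise_sd_uV = 30,
                       whisk_noise_sd_deg = 1.5,
                       kappa_gen = 0.5,
                       theta_gen = 2.9,
                       base_rate_hz = 10,
                       n_units = 3,
                       n_trials = 100,
                       touch_dur_mean_s = 0.54,
                       touch_dur_sd_s = 0.224,
                       turn_dur_mean_s = 0.26,
                       turn_dur_sd_s = 0.15,
                       iti_gap_s = 2.6,
                       behavior_r_target = 0.146,
                       p_correct_link = list(base_rate = 0.78, psi_effect = 0.05),
                       seed = NULL) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  num_fields <- c("duration_s", "lfp_rate_hz", "whisk_rate_hz", "f_theta_hz",
                  "f_whisk_hz", "phase_noise_sd", "coupling_eps",
                  "coupling_lag_rad", "theta_amp_uV", "whisk_amp_deg",
                  "whisk_offset_deg", "lfp_noise_sd_uV", "whisk_noise_sd_deg",
                  "kappa_gen", "theta_gen", "base_rate_hz", "n_units",
                  "n_trials", "touch_dur_mean_s", "touch_dur_sd_s",
                  "turn_dur_mean_s", "turn_dur_sd_s", "iti_gap_s",
                  "behavior_r_target")
  for (f in num_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop(sprintf("sim_config: field '%s' must be a finite number", f))
  }
  if (cfg$duration_s <= 0 || cfg$lfp_rate_hz <= 0 || cfg$whisk_rate_hz <= 0 ||
      cfg$base_rate_hz <= 0)
    stop("sim_config: durations and rates must be positive")
  if (cfg$coupling_eps < 0) stop("sim_config: coupling_eps must be >= 0")
  if (cfg$kappa_gen < 0) stop("sim_config: kappa_gen must be >= 0")
  if (cfg$f_theta_hz < 5 || cfg$f_theta_hz > 12 ||
      cfg$f_whisk_hz < 5 || cfg$f_whisk_hz > 12)
    stop("sim_config: center frequencies must lie in the 5-12 Hz band")
  if (cfg$n_trials < 1) stop("sim_config: n_trials must be >= 1")
  if (abs(cfg$behavior_r_target) >= 1)
    stop("sim_config: |behavior_r_target| must be < 1")
  eg <- cfg$episode_gains
  if (!is.list(eg) || !all(c("amplitude", "coupling") %in% names(eg)))
    stop("sim_config: episode_gains must list 'amplitude' and 'coupling' vectors")
  for (g in c("amplitude", "coupling")) {
    if (!all(c("baseline", "approach", "touch", "other") %in% names(eg[[g]])))
      stop(sprintf("sim_config: episode_gains$%s needs baseline/approach/touch/other entries", g))
    if (!all(is.finite(eg[[g]])) || any(eg[[g]] < 0))
      stop(sprintf("sim_config: episode_gains$%s must be finite and >= 0", g))
  }
  pl <- cfg$p_correct_link
  if (!is.list(pl) || !all(c("base_rate", "psi_effect") %in% names(pl)))
    stop("sim_config: p_correct_link must list 'base_rate' and 'psi_effect'")
  if (pl$base_rate <= 0 || pl$base_rate >= 1)
    stop("sim_config: p_correct_link$base_rate must be in (0, 1)")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  oscillators: theta %g Hz / whisking %g Hz, noise %g rad/sqrt(s)\n",
              x$f_theta_hz, x$f_whisk_hz, x$phase_noise_sd))
  cat(sprintf("  coupling: eps = %g /s, lag = %g rad (gains: %s)\n",
              x$coupling_eps, x$coupling_lag_rad,
              paste(sprintf("%s=%g", names(x$episode_gains$coupling),
                            x$episode_gains$coupling), collapse = " ")))
  cat(sprintf("  trials: %d, touch %g +/- %g s; spikes: %d units @ %g Hz, kappa %g\n",
              x$n_trials, x$touch_dur_mean_s, x$touch_dur_sd_s, x$n_units,
              x$base_rate_hz, x$kappa_gen))
  cat(sprintf("  seed: %s\n", if (is.null(x$seed)) "NULL" else x$seed))
  invisible(x)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Fields not present in the file keep their [sim_config()] defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (!is.null(vals$episode_gains))
    vals$episode_gains <- lapply(vals$episode_gains, unlist)
  if (!is.null(vals$p_correct_link))
    vals$p_correct_link <- as.list(vals$p_correct_link)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown))
    stop("read_sim_config: unknown field(s): ", paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}
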