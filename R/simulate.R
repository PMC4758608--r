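## Synthetic session generation: coupled phase oscillators, von Mises
## phase-locked Poisson spike trains, and trial outcomes with planted effect
## sizes. All randomness flows through R's RNG so a seed makes every output
## bit-identical.

# 1/f ("pink") background noise, unit variance, via FFT amplitude shaping
pink_noise <- function(n) {
  if (n < 2) return(stats::rnorm(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))          # avoid the DC singularity
  f <- pmin(f, n - f + 1)            # fold to two-sided frequencies
  W <- W / sqrt(f)
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x <- x - mean(x)
  x / stats::sd(x)
}

# integrate coupled phases at the LFP rate; eps may be a scalar or a
# per-sample vector; returns phase matrix and final state
integrate_pair <- function(n, cfg, eps, phi0 = NULL) {
  if (is.null(phi0)) phi0 <- stats::runif(2, -pi, pi)
  if (length(eps) == 1) eps <- rep(eps, n)
  ph <- integrate_coupled_phases(n, 1 / cfg$lfp_rate_hz, cfg$f_theta_hz,
                                 cfg$f_whisk_hz, eps, cfg$phase_noise_sd,
                                 cfg$coupling_lag_rad, phi0[1], phi0[2])
  ph
}

# waveforms from phases: LFP with pink background, whisking with white noise;
# amp may be scalar or per-sample multiplier for the theta amplitude
waveforms_from_phases <- function(ph, cfg, amp = 1) {
  n <- nrow(ph)
  lfp <- cfg$theta_amp_uV * amp * cos(ph[, 1]) +
    cfg$lfp_noise_sd_uV * pink_noise(n)
  ratio <- cfg$lfp_rate_hz / cfg$whisk_rate_hz
  idx <- if (abs(ratio - round(ratio)) < 1e-9 && ratio >= 1) {
    seq(1, n, by = round(ratio))
  } else {
    round(seq(1, n, length.out = max(1, floor(n / ratio))))
  }
  whisk <- cfg$whisk_offset_deg + cfg$whisk_amp_deg * cos(ph[idx, 2]) +
    cfg$whisk_noise_sd_deg * stats::rnorm(length(idx))
  list(lfp = lfp, whisk = whisk, whisk_idx = idx)
}

#' Generate a coupled theta/whisking signal pair
#'
#' Simulates two noisy narrow-band oscillations, a theta-like LFP trace and a
#' whisking-like angle trace, whose phases evolve as
#' `dphi_x = 2 pi f_theta dt + noise` and
#' `dphi_y = 2 pi f_whisk dt + eps sin(phi_x - phi_y - lag) dt + noise`
#' (unidirectional Kuramoto-style pull on the whisking phase). The LFP carries
#' an additive 1/f background; the whisking trace carries white noise.
#'
#' @param config A [sim_config()]. `duration_s`, the rates, frequencies,
#'   `phase_noise_sd`, `coupling_eps` and `coupling_lag_rad` are used.
#' @param return_phases Also return the generating (ground-truth) phases.
#'
#' @return List with `lfp` and `whisking` ([continuous_signal]s); when
#'   `return_phases = TRUE` also `phase_theta` and `phase_whisk` (numeric,
#'   at the respective signal rates).
#' @export
gen_coupled_pair <- function(config, return_phases = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- round(config$duration_s * config$lfp_rate_hz)
  ph <- integrate_pair(n, config, config$coupling_eps)
  wf <- waveforms_from_phases(ph, config)
  out <- list(
    lfp = continuous_signal(wf$lfp, config$lfp_rate_hz, 0, "lfp", "uV"),
    whisking = continuous_signal(wf$whisk, config$whisk_rate_hz, 0,
                                 "whisking", "degrees")
  )
  if (return_phases) {
    out$phase_theta <- wrap_phase(ph[, 1])
    out$phase_whisk <- wrap_phase(ph[wf$whisk_idx, 2])  # at the whisking rate
  }
  out
}

#' Generate a phase-locked Poisson spike train
#'
#' Inhomogeneous Poisson process with intensity
#' `lambda(t) = base_rate * exp(kappa * cos(phi(t) - theta)) / I0(kappa)`,
#' sampled exactly by thinning (the intensity is bounded). When the phase
#' advances uniformly, the spike-phase distribution is von
#' Mises(`theta_gen`, `kappa_gen`) and the mean rate is exactly `base_rate_hz`.
#'
#' @param phase A `phase_series`, or a list with `phases`, `sample_rate_hz`,
#'   `start_time_s`.
#' @param kappa_gen Concentration of the modulation (>= 0).
#' @param theta_gen Preferred phase (radians).
#' @param base_rate_hz Mean firing rate (> 0).
#' @param unit_id Unit label for the returned train.
#' @param seed Optional RNG seed.
#'
#' @return A [spike_train].
#' @export
gen_phase_locked_spikes <- function(phase, kappa_gen, theta_gen, base_rate_hz,
                                    unit_id = "unit1", seed = NULL) {
  if (kappa_gen < 0) stop("kappa_gen must be >= 0")
  if (base_rate_hz <= 0) stop("base_rate_hz must be > 0")
  if (!is.null(seed)) set.seed(seed)
  dur <- (length(phase$phases) - 1) / phase$sample_rate_hz  # covered span
  if (dur < 1 / 5)  # less than one cycle of the slowest in-band rhythm
    warning("gen_phase_locked_spikes: phase series shorter than one cycle")
  i0s <- besselI(kappa_gen, 0, expon.scaled = TRUE)  # I0(k) * exp(-k)
  lambda_max <- base_rate_hz / i0s
  n_cand <- stats::rpois(1, lambda_max * dur)
  if (n_cand == 0) return(spike_train(numeric(0), unit_id))
  t0 <- phase$start_time_s
  cand <- sort(stats::runif(n_cand, t0, t0 + dur))
  phi <- phase_at_times(phase, cand)
  accept <- stats::runif(n_cand) < exp(kappa_gen * (cos(phi - theta_gen) - 1))
  spike_train(cand[accept], unit_id)
}

#' Plant a behavioral link into per-trial PSI values
#'
#' Constructs touch durations as a linear function of the within-trial PSI
#' change (touch minus approach) plus Gaussian noise calibrated so the Pearson
#' correlation between PSI change and normalized trial duration (per-rat
#' maximum duration minus single-trial duration) equals `r_target` in
#' expectation. Correct/incorrect flags are Bernoulli draws from a logistic
#' link on PSI-touch whose intercept and slope are solved so that the expected
#' proportion correct equals `p_correct_link$base_rate` and the expected
#' difference in mean PSI-touch between correct and incorrect trials equals
#' `p_correct_link$psi_effect` (`psi_effect = 0` gives a flat link).
#'
#' @param trial_psi Data frame with one row per trial and columns
#'   `psi_approach` and `psi_touch`.
#' @param r_target Planted correlation, |r| < 1.
#' @param p_correct_link List with `base_rate` and `psi_effect`.
#' @param dur_mean_s,dur_sd_s Mean and SD of the touch-duration distribution.
#' @param dur_range_s Durations are clamped to this closed interval.
#' @param seed Optional RNG seed.
#'
#' @return Data frame with `touch_duration_s` and `correct` per trial, plus
#'   attribute `link` recording the solved logistic coefficients.
#' @export
plant_behavioral_link <- function(trial_psi, r_target, p_correct_link,
                                  dur_mean_s = 0.54, dur_sd_s = 0.224,
                                  dur_range_s = c(0.155, 1.995), seed = NULL) {
  if (abs(r_target) >= 1) stop("plant_behavioral_link: |r_target| must be < 1")
  stopifnot(all(c("psi_approach", "psi_touch") %in% names(trial_psi)))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(trial_psi)
  x <- trial_psi$psi_touch - trial_psi$psi_approach
  sx <- stats::sd(x)
  z <- if (sx > 0) (x - mean(x)) / sx else rep(0, n)
  # normalized duration (higher = faster trial) with planted correlation
  nd <- r_target * z + sqrt(1 - r_target^2) * stats::rnorm(n)
  dur <- pmin(pmax(dur_mean_s - dur_sd_s * nd, dur_range_s[1]), dur_range_s[2])

  xt <- trial_psi$psi_touch - mean(trial_psi$psi_touch)
  link <- solve_correct_link(xt, p_correct_link$base_rate,
                             p_correct_link$psi_effect)
  p <- stats::plogis(link["a"] + link["b"] * xt)
  correct <- stats::runif(n) < p
  out <- data.frame(touch_duration_s = dur, correct = correct)
  attr(out, "link") <- link
  out
}

# solve logistic intercept/slope so E[correct] = base_rate and the expected
# correct-minus-incorrect difference in x equals effect
solve_correct_link <- function(x, base_rate, effect) {
  a_for_b <- function(b) {
    stats::uniroot(function(a) mean(stats::plogis(a + b * x)) - base_rate,
                   c(-20, 20), tol = 1e-10)$root
  }
  exp_diff <- function(b) {
    p <- stats::plogis(a_for_b(b) + b * x)
    sum(x * p) / sum(p) - sum(x * (1 - p)) / sum(1 - p)
  }
  if (effect == 0 || stats::sd(x) == 0)
    return(c(a = stats::qlogis(base_rate), b = 0))
  hi <- 1
  while (exp_diff(hi) < effect && hi < 512) hi <- hi * 2
  if (exp_diff(hi) < effect) {
    warning("plant_behavioral_link: requested psi_effect not attainable for this PSI sample; using the maximum attainable")
    return(c(a = a_for_b(hi), b = hi))
  }
  b <- stats::uniroot(function(b) exp_diff(b) - effect, c(0, hi), tol = 1e-8)$root
  c(a = a_for_b(b), b = b)
}

# ---- trial-structured session ------------------------------------------------

# fixed within-trial layout (seconds relative to block start)
TRIAL_PRE_S <- 3.2        # signal before contact onset (covers baseline)
TRIAL_GAIN_TOUCH_S <- 0.5 # touch-level coupling applies to this post-onset span
TRIAL_TAIL_S <- 0.7       # margin after reward end
PSI_WIN_S <- 0.25         # analysis window length for trial PSI

# eps/amp per-sample vectors for the first (analysis-core) part of a block
block_gain_vectors <- function(n_core, cfg) {
  fs <- cfg$lfp_rate_hz
  g <- cfg$episode_gains
  eps <- rep(cfg$coupling_eps * g$coupling[["baseline"]], n_core)
  amp <- rep(g$amplitude[["baseline"]], n_core)
  i_app <- (round((TRIAL_PRE_S - 0.5) * fs) + 1):round(TRIAL_PRE_S * fs)
  i_tch <- (round(TRIAL_PRE_S * fs) + 1):round((TRIAL_PRE_S + TRIAL_GAIN_TOUCH_S) * fs)
  eps[i_app] <- cfg$coupling_eps * g$coupling[["approach"]]
  eps[i_tch] <- cfg$coupling_eps * g$coupling[["touch"]]
  amp[i_app] <- g$amplitude[["approach"]]
  amp[i_tch] <- g$amplitude[["touch"]]
  list(eps = eps, amp = amp)
}

window_psi_from_phases <- function(ph, i0, i1) {
  th <- ph[i0:i1, 1] - ph[i0:i1, 2]
  sqrt(mean(cos(th))^2 + mean(sin(th))^2)
}

#' Generate a complete synthetic session
#'
#' Simulates `n_trials` trials of the tactile discrimination task with known
#' ground truth. Each trial is an independent block: coupled theta/whisking
#' phases are integrated with stepwise episode gains (coupling and theta
#' amplitude boosted during approach and the first 500 ms of touch), the
#' trial's realized PSI is measured on 250 ms windows flanking contact onset
#' from the generating phases, touch durations and correct flags are then
#' planted through [plant_behavioral_link()], and the block is extended
#' through turn and reward. Spike trains phase-locked to the generating theta
#' phase are added per unit.
#'
#' @param config A [sim_config()].
#' @return An object of class `tw_session`: list with `lfp`, `whisking`
#'   ([continuous_signal]s), `spikes` (list of [spike_train]s), `events`
#'   ([trial_events] table) and `truth` (per-trial generating record plus
#'   session-level parameters).
#' @export
gen_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  fs <- cfg$lfp_rate_hz
  n_tr <- cfg$n_trials
  core_len_s <- TRIAL_PRE_S + 1.0
  n_core <- round(core_len_s * fs)
  n_core <- max(1, round(fs / cfg$whisk_rate_hz)) *
    ceiling(n_core / max(1, round(fs / cfg$whisk_rate_hz)))
  if (TRIAL_PRE_S < 3)
    stop("gen_session: trial layout too short for the baseline window")
  gains <- block_gain_vectors(n_core, cfg)

  # pass 1: analysis cores. The realized PSI of each trial is measured from
  # the emitted waveforms with the same band-pass + Hilbert route the
  # analysis uses, so the planted behavioral link acts on the observable
  # synchronization, not on the latent generating phases.
  cores <- vector("list", n_tr)
  core_wf <- vector("list", n_tr)
  states <- matrix(0, n_tr, 2)
  psi_app <- psi_tch <- psi_app_true <- psi_tch_true <- numeric(n_tr)
  i_on <- round(TRIAL_PRE_S * fs)
  nw <- round(PSI_WIN_S * fs)
  app_win <- list(start_s = TRIAL_PRE_S - PSI_WIN_S, end_s = TRIAL_PRE_S)
  tch_win <- list(start_s = TRIAL_PRE_S, end_s = TRIAL_PRE_S + PSI_WIN_S)
  for (k in seq_len(n_tr)) {
    ph <- integrate_pair(n_core, cfg, gains$eps)
    cores[[k]] <- ph
    states[k, ] <- ph[n_core, ]
    psi_app_true[k] <- window_psi_from_phases(ph, i_on - nw + 1, i_on)
    psi_tch_true[k] <- window_psi_from_phases(ph, i_on + 1, i_on + nw)
    wf <- waveforms_from_phases(ph, cfg, amp = gains$amp)
    core_wf[[k]] <- wf
    th_ph <- instantaneous_phase(bandpass_theta(
      continuous_signal(wf$lfp, fs, 0, "lfp", "uV")))
    wh_ph <- instantaneous_phase(bandpass_theta(
      continuous_signal(wf$whisk, cfg$whisk_rate_hz, 0, "whisking", "degrees")))
    psi_app[k] <- compute_psi(th_ph, wh_ph, app_win)$psi
    psi_tch[k] <- compute_psi(th_ph, wh_ph, tch_win)$psi
  }

  # plant outcomes from realized (measured) PSI
  planted <- plant_behavioral_link(
    data.frame(psi_approach = psi_app, psi_touch = psi_tch),
    cfg$behavior_r_target, cfg$p_correct_link,
    dur_mean_s = cfg$touch_dur_mean_s, dur_sd_s = cfg$touch_dur_sd_s)
  turn_dur <- pmax(0.05, stats::rnorm(n_tr, cfg$turn_dur_mean_s, cfg$turn_dur_sd_s))

  # pass 2: extend blocks through turn/reward, build waveforms and events
  eps_base <- cfg$coupling_eps * cfg$episode_gains$coupling[["baseline"]]
  g_other <- cfg$episode_gains$amplitude[["other"]]
  lfp_parts <- whisk_parts <- vector("list", n_tr)
  theta_phase_parts <- vector("list", n_tr)
  block_start <- numeric(n_tr)
  t_cursor <- 0
  onset <- offset <- arrival <- rew_end <- numeric(n_tr)
  ratio <- max(1, round(fs / cfg$whisk_rate_hz))
  for (k in seq_len(n_tr)) {
    dur <- planted$touch_duration_s[k]
    block_len_s <- TRIAL_PRE_S + dur + turn_dur[k] + 0.5 + TRIAL_TAIL_S +
      cfg$iti_gap_s
    # block length padded to a multiple of the LFP/whisking rate ratio so the
    # whisking sample grid stays aligned across concatenated blocks
    n_blk <- ratio * ceiling(round(block_len_s * fs) / ratio)
    n_ext <- max(0, n_blk - n_core)
    lfp_k <- core_wf[[k]]$lfp
    whisk_k <- core_wf[[k]]$whisk
    ph_k <- cores[[k]][, 1]
    if (n_ext > 0) {
      ph2 <- integrate_pair(n_ext + 1, cfg, eps_base, phi0 = states[k, ])
      ext <- ph2[-1, , drop = FALSE]
      wf2 <- waveforms_from_phases(ext, cfg, amp = g_other)
      lfp_k <- c(lfp_k, wf2$lfp)
      whisk_k <- c(whisk_k, wf2$whisk)
      ph_k <- c(ph_k, ext[, 1])
    }
    lfp_parts[[k]] <- lfp_k
    whisk_parts[[k]] <- whisk_k
    theta_phase_parts[[k]] <- ph_k
    block_start[k] <- t_cursor
    onset[k] <- t_cursor + TRIAL_PRE_S
    offset[k] <- onset[k] + dur
    arrival[k] <- offset[k] + turn_dur[k]
    rew_end[k] <- arrival[k] + 0.5
    t_cursor <- t_cursor + length(lfp_k) / fs
  }

  lfp <- continuous_signal(unlist(lfp_parts), fs, 0, "lfp", "uV")
  whisking <- continuous_signal(unlist(whisk_parts), cfg$whisk_rate_hz, 0,
                                "whisking", "degrees")

  texture <- sample(c("S1", "S3"), n_tr, replace = TRUE)
  side_of <- c(S1 = "right", S3 = "left")
  choice <- ifelse(planted$correct, side_of[texture],
                   ifelse(side_of[texture] == "right", "left", "right"))
  events <- trial_events(data.frame(
    trial_id = seq_len(n_tr),
    contact_onset_s = onset, contact_offset_s = offset,
    spout_arrival_s = arrival, reward_end_s = rew_end,
    texture_id = texture, choice_side = unname(choice),
    correct = planted$correct, stringsAsFactors = FALSE))

  # spikes phase-locked to the generating theta phase of the whole session
  theta_phase <- structure(
    list(phases = wrap_phase(unlist(theta_phase_parts)), sample_rate_hz = fs,
         start_time_s = 0, band = c(5, 12), bias_corrected = FALSE),
    class = "phase_series")
  spikes <- lapply(seq_len(cfg$n_units), function(u) {
    gen_phase_locked_spikes(theta_phase, cfg$kappa_gen, cfg$theta_gen,
                            cfg$base_rate_hz, unit_id = sprintf("unit%02d", u))
  })

  truth <- list(
    per_trial = data.frame(
      trial_id = seq_len(n_tr),
      psi_approach_true = psi_app_true, psi_touch_true = psi_tch_true,
      psi_approach_meas = psi_app, psi_touch_meas = psi_tch,
      touch_duration_s = planted$touch_duration_s,
      turn_duration_s = turn_dur, correct = planted$correct),
    config = cfg, link = attr(planted, "link"),
    eps_schedule = cfg$coupling_eps * cfg$episode_gains$coupling)

  structure(list(lfp = lfp, whisking = whisking, spikes = spikes,
                 events = events, truth = truth),
            class = "tw_session")
}

#' @export
print.tw_session <- function(x, ...) {
  cat(sprintf("<tw_session> %d trials, %d unit(s)%s\n", nrow(x$events),
              length(x$spikes),
              if (!is.null(x$truth)) ", synthetic (truth attached)" else ""))
  print(x$lfp)
  print(x$whisking)
  invisible(x)
}
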