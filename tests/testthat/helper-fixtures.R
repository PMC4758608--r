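# shared fixtures, built in code at test time

tone_signal <- function(freq_hz, fs = 2000, dur_s = 5, amp = 1, noise_sd = 0,
                        phase0 = 0, label = "lfp") {
  t <- (0:(round(dur_s * fs) - 1)) / fs
  x <- amp * cos(2 * pi * freq_hz * t + phase0)
  if (noise_sd > 0) x <- x + rnorm(length(x), 0, noise_sd)
  continuous_signal(x, fs, 0, label, if (label == "lfp") "uV" else "degrees")
}

# minimal well-formed event table: trials spaced widely enough for baselines
make_events <- function(n = 5, first_onset = 10, spacing = 8,
                        touch_dur = 0.54, turn_dur = 0.76) {
  onset <- first_onset + (seq_len(n) - 1) * spacing
  trial_events(data.frame(
    trial_id = seq_len(n),
    contact_onset_s = onset,
    contact_offset_s = onset + touch_dur,
    spout_arrival_s = onset + touch_dur + turn_dur,
    reward_end_s = onset + touch_dur + turn_dur + 0.5,
    texture_id = rep(c("S1", "S3"), length.out = n),
    choice_side = rep(c("right", "left"), length.out = n),
    correct = rep(TRUE, n), stringsAsFactors = FALSE))
}

# a uniformly advancing phase series (ideal oscillator) at a given rate
ramp_phase <- function(freq_hz, fs = 1000, dur_s = 10) {
  structure(list(
    phases = thetawhisk:::wrap_phase(2 * pi * freq_hz * (0:(round(dur_s * fs) - 1)) / fs),
    sample_rate_hz = fs, start_time_s = 0, band = c(5, 12),
    bias_corrected = FALSE), class = "phase_series")
}

expect_wrapped_equal <- function(a, b, tol = 1e-6) {
  d <- atan2(sin(a - b), cos(a - b))
  expect_lt(max(abs(d)), tol)
}
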