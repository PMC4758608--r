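#' Zero-phase theta-band filtering
#'
#' Band-passes a signal in the theta range with a zero-phase (forward-backward)
#' Butterworth filter, order 4 per pass. Zero-phase filtering preserves the
#' timing of oscillation peaks, which matters because instantaneous phase is
#' extracted downstream.
#'
#' @param signal A [continuous_signal].
#' @param band Two-element numeric, pass band in Hz (default 5-12).
#' @param order Butterworth order per pass.
#' @return A [continuous_signal] of the same length and rate.
#' @export
bandpass_theta <- function(signal, band = c(5, 12), order = 4) {
  stopifnot(inherits(signal, "continuous_signal"))
  fs <- signal$sample_rate_hz
  if (fs <= 2 * band[2])
    stop("bandpass_theta: sample rate must exceed twice the band top")
  # ~3 time constants of the band-edge transient
  min_len <- ceiling(3 * fs / band[1])
  if (length(signal$samples) < min_len)
    stop("bandpass_theta: signal too short for stable band-pass filtering")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  filtered <- signal::filtfilt(bf, signal$samples)
  out <- signal
  out$samples <- as.numeric(filtered)
  attr(out, "band") <- band
  out
}

# analytic signal via FFT (padded to the next power of two for speed)
analytic_signal <- function(x) {
  n <- length(x)
  nfft <- 2^ceiling(log2(n))
  xp <- c(x, rep(0, nfft - n))
  X <- stats::fft(xp)
  h <- numeric(nfft)
  h[1] <- 1
  if (nfft %% 2 == 0) {
    h[nfft / 2 + 1] <- 1
    h[2:(nfft / 2)] <- 2
  } else {
    h[2:((nfft + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / nfft
  z[seq_len(n)]
}

#' Instantaneous phase via the Hilbert transform
#'
#' Computes the analytic signal of a band-passed trace and returns the angle,
#' wrapped to (-pi, pi]. Convention: phase 0 at signal maxima, +/- pi at
#' minima; for a whisking angle trace with protraction = increasing angle,
#' phase 0 is peak protraction. Edge effects of the transform are reduced by
#' reflect-padding 1 s at each end; analysis windows should stay >= 0.25 s
#' away from the signal edges.
#'
#' @param filtered A band-passed [continuous_signal] (see [bandpass_theta()]).
#' @return An object of class `phase_series`: list with `phases` (radians,
#'   wrapped), `sample_rate_hz`, `start_time_s`, `band`, `bias_corrected`.
#' @export
instantaneous_phase <- function(filtered) {
  stopifnot(inherits(filtered, "continuous_signal"))
  x <- filtered$samples
  if (stats::sd(x) == 0)
    stop("instantaneous_phase: constant input has undefined phase")
  fs <- filtered$sample_rate_hz
  pad <- min(round(fs), length(x) - 1)
  xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(length(x) - pad):(length(x) - 1)]))
  z <- analytic_signal(xp)[(pad + 1):(pad + length(x))]
  band <- attr(filtered, "band")
  structure(
    list(phases = wrap_phase(Arg(z)), sample_rate_hz = fs,
         start_time_s = filtered$start_time_s,
         band = if (is.null(band)) c(5, 12) else band,
         bias_corrected = FALSE),
    class = "phase_series"
  )
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series> %d samples @ %g Hz, band %g-%g Hz%s\n",
              length(x$phases), x$sample_rate_hz, x$band[1], x$band[2],
              if (isTRUE(x$bias_corrected)) ", bias-corrected" else ""))
  invisible(x)
}

phase_unwrap <- function(phi) {
  d <- diff(phi)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(phi[1], d))
}

# linear interpolation of a phase series at arbitrary times, done on the
# unwrapped phase and re-wrapped (wrapped-phase interpolation would be wrong
# near the +/- pi boundary); works on corrected series too, since the bias
# map is a monotone circular bijection and the series stays a valid phase
# evolution
phase_at_times <- function(phase, times) {
  fs <- phase$sample_rate_hz
  n <- length(phase$phases)
  t0 <- phase$start_time_s
  if (any(times < t0 - 1e-9) || any(times > t0 + (n - 1) / fs + 1e-9))
    stop("phase_at_times: requested times outside phase coverage")
  # unwrap only the slice spanning the requested times
  i0 <- max(1L, floor((min(times) - t0) * fs) - 1L)
  i1 <- min(n, ceiling((max(times) - t0) * fs) + 2L)
  idx <- i0:i1
  ts <- t0 + (idx - 1) / fs
  uw <- phase_unwrap(phase$phases[idx])
  wrap_phase(stats::approx(ts, uw, xout = times, rule = 2)$y)
}

# rank-based uniformizing transform Psi(phi) = 2*pi*F(phi) - pi, stored as an
# interpolation map so it can also be applied to phases obtained by
# interpolation (e.g., at spike times)
make_bias_map <- function(phases, knots = 2048) {
  s <- sort.int(phases, method = "quick")
  n <- length(s)
  if (n > knots) {
    idx <- unique(round(seq(1, n, length.out = knots)))
    x <- s[idx]; y <- idx / n
  } else {
    x <- s; y <- seq_len(n) / n
  }
  keep <- !duplicated(x)
  list(x = c(-pi, x[keep], pi), y = c(0, y[keep], 1))
}

apply_bias_map <- function(phi, map) {
  wrap_phase(2 * pi * stats::approx(map$x, map$y, xout = phi, rule = 2,
                                    ties = "ordered")$y - pi)
}

#' Rank-based phase bias correction
#'
#' Asymmetric oscillation wave shape biases Hilbert phases: some phases are
#' occupied more than others, which inflates phase-locking statistics. This
#' correction tests the session-wide phase distribution for uniformity
#' (Rayleigh test, alpha = 0.05) and, if non-uniform, remaps phases through
#' the rank transform Psi(phi) = 2*pi*F(phi) - pi, where F is the session
#' empirical CDF of phase. The output distribution is uniform by construction.
#' If the distribution is already uniform (or `force = FALSE` and the test
#' does not reject), the series is returned unchanged with
#' `bias_corrected = FALSE`.
#'
#' @param phase A `phase_series` (see [instantaneous_phase()]), or a bare
#'   numeric vector of phases.
#' @param alpha Rayleigh significance level that triggers the correction.
#' @param force Apply the transform unconditionally.
#' @return Same type as the input, with corrected phases and a stored
#'   correction map; a `bias_corrected` flag records whether the transform was
#'   applied. With fewer than 100 phase samples the correction is skipped with
#'   a warning.
#' @export
psi_bias_correct <- function(phase, alpha = 0.05, force = FALSE) {
  bare <- !inherits(phase, "phase_series")
  phases <- if (bare) as.numeric(phase) else phase$phases
  if (length(phases) < 100) {
    warning("psi_bias_correct: fewer than 100 phase samples; correction skipped")
    return(phase)
  }
  # Rayleigh on (at most) 1e5 evenly thinned samples: the test statistic is
  # about the distribution, not the sample size of the series
  test_sample <- if (length(phases) > 1e5)
    phases[round(seq(1, length(phases), length.out = 1e5))] else phases
  needed <- force || rayleigh_test(test_sample)$p < alpha
  if (!needed) return(phase)
  map <- make_bias_map(phases)
  corrected <- apply_bias_map(phases, map)
  if (bare) return(corrected)
  phase$phases <- corrected
  phase$bias_corrected <- TRUE
  attr(phase, "bias_map") <- map
  phase
}
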