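## Spectral estimation: adaptive multitaper spectrogram (window length 8/f,
## Slepian tapers), Hanning-taper episode spectra on the 4-20 Hz grid,
## baseline normalization, theta peak frequency, and trial-shuffle
## randomization tests with Bonferroni correction.

# Discrete prolate spheroidal sequences via the symmetric tridiagonal
# formulation (diagonal ((N-1-2i)/2)^2 cos(2 pi W), off-diagonal i(N-i)/2);
# the top K eigenvectors are the tapers, normalized to unit energy.
dpss_tapers <- function(n, nw = 2, k = 3) {
  if (k >= n) stop("dpss_tapers: need k < n")
  W <- nw / n
  i <- 0:(n - 1)
  d <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * W)
  e <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  diag(A) <- d
  A[cbind(1:(n - 1), 2:n)] <- e
  A[cbind(2:n, 1:(n - 1))] <- e
  eg <- eigen(A, symmetric = TRUE)
  tapers <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tj <- tapers[, j]
    tj <- tj / sqrt(sum(tj^2))
    if (sum(tj) < 0) tj <- -tj          # fix arbitrary eigenvector sign
    tapers[, j] <- tj
  }
  tapers
}

# low-pass + integer-factor decimation used before spectrogram estimation
decimate_signal <- function(signal, target_fs = 200) {
  fs <- signal$sample_rate_hz
  fac <- round(fs / target_fs)
  if (fac <= 1) return(signal)
  if (abs(fs / fac - target_fs) > 1e-6)
    fac <- max(1, floor(fs / target_fs))
  bf <- signal::butter(4, (0.4 * fs / fac) / (fs / 2), type = "low")
  y <- signal::filtfilt(bf, signal$samples)
  out <- signal
  out$samples <- y[seq(1, length(y), by = fac)]
  out$sample_rate_hz <- fs / fac
  out
}

#' Adaptive multitaper spectrogram around contact onset
#'
#' Time-frequency power for the period extending `t_range` around each
#' trial's contact onset, using an adaptive sliding window eight cycles long
#' (window duration 8/f at frequency f) multiplied by Slepian tapers, averaged
#' across trials and normalized to the pre-contact baseline (2.5-3 s before
#' first contact). The signal is low-pass decimated internally; the analysis
#' band (4-20 Hz) is far below the decimated Nyquist.
#'
#' @param signal A [continuous_signal].
#' @param onsets_s Numeric vector of contact-onset times (one per trial).
#' @param f_grid_hz Frequency grid (Hz).
#' @param t_range_s Time range around onset (seconds).
#' @param step_s Time step of the spectrogram.
#' @param n_tapers,nw Number of Slepian tapers and time-bandwidth product.
#' @param baseline_window_s Baseline interval, relative to onset, used for
#'   normalization.
#' @param normalization `"ratio"` (power / mean baseline power per frequency)
#'   or `"db_diff"` (10 log10 power minus 10 log10 baseline power).
#' @return List of class `tw_spectrogram`: `times_s`, `frequencies_hz`,
#'   `power` (frequency x time, normalized), `raw_power`, `n_trials`,
#'   `dropped_trials`.
#' @export
spectrogram_adaptive <- function(signal, onsets_s, f_grid_hz = seq(4, 20, 0.5),
                                 t_range_s = c(-3, 3), step_s = 0.05,
                                 n_tapers = 3, nw = 2,
                                 baseline_window_s = c(-3, -2.5),
                                 normalization = c("ratio", "db_diff")) {
  normalization <- match.arg(normalization)
  sig <- decimate_signal(signal)
  fs <- sig$sample_rate_hz
  x <- sig$samples
  max_halfwin <- 0.5 * 8 / min(f_grid_hz)
  lo_need <- t_range_s[1] - max_halfwin
  hi_need <- t_range_s[2] + max_halfwin
  t0 <- sig$start_time_s
  t_end <- signal_end_time(sig)
  ok <- (onsets_s + lo_need >= t0) & (onsets_s + hi_need <= t_end)
  if (!all(ok))
    warning(sprintf("spectrogram_adaptive: dropping %d trial(s) without full coverage",
                    sum(!ok)))
  onsets <- onsets_s[ok]
  if (!length(onsets)) stop("spectrogram_adaptive: no trial has full signal coverage")
  times <- seq(t_range_s[1], t_range_s[2], by = step_s)
  centers <- round(outer(onsets, times, "+") * fs - t0 * fs) + 1  # trial x time
  P <- matrix(0, length(f_grid_hz), length(times))
  for (fi in seq_along(f_grid_hz)) {
    f <- f_grid_hz[fi]
    L <- round(8 / f * fs)
    tap <- dpss_tapers(L, nw, n_tapers)
    offs <- seq_len(L) - 1 - floor(L / 2)
    wmat <- tap * exp(-2i * pi * f * (seq_len(L) - 1) / fs)  # L x K complex
    idx <- outer(as.vector(centers), offs, "+")
    segs <- matrix(x[idx], nrow = nrow(idx))
    Z <- segs %*% wmat
    pw <- rowMeans(Mod(Z)^2) * 2 / fs
    P[fi, ] <- colMeans(matrix(pw, nrow = length(onsets)))
  }
  base_cols <- times >= baseline_window_s[1] & times <= baseline_window_s[2]
  base <- rowMeans(P[, base_cols, drop = FALSE])
  norm <- if (normalization == "ratio") P / base
          else 10 * log10(P) - 10 * log10(base)
  structure(list(times_s = times, frequencies_hz = f_grid_hz, power = norm,
                 raw_power = P, normalization = normalization,
                 n_trials = length(onsets), dropped_trials = sum(!ok)),
            class = "tw_spectrogram")
}

as_window_matrix <- function(windows) {
  if (is.matrix(windows)) return(windows)
  lens <- lengths(windows)
  if (length(unique(lens)) != 1)
    stop("episode windows must all have equal length")
  do.call(rbind, windows)
}

#' Episode power spectra (Hanning taper)
#'
#' Per-window periodograms of equal-length episode segments multiplied by a
#' Hanning taper, zero-padded to a refined frequency grid, reported on
#' `f_range` (4-20 Hz by default). Power is one-sided PSD
#' (2 |X|^2 / (fs * sum(w^2))).
#'
#' @param windows Matrix (windows x samples) or list of equal-length vectors.
#' @param fs Sampling rate of the window samples (Hz).
#' @param f_range Reported frequency range (Hz).
#' @param df_hz Frequency spacing after zero padding (0.25 Hz default, the
#'   resolution at which theta peak frequencies are reported).
#' @param demean Remove each window's mean before tapering.
#' @return List of class `spectral_estimate`: `frequencies_hz`, `power`
#'   (mean across windows), `per_window` (windows x frequency), `taper`,
#'   `normalization`, `n`.
#' @export
episode_spectrum <- function(windows, fs, f_range = c(4, 20), df_hz = 0.25,
                             demean = TRUE) {
  W <- as_window_matrix(windows)
  n <- ncol(W)
  if (n < 2) stop("episode_spectrum: windows too short")
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))  # Hanning
  if (demean) W <- W - rowMeans(W)
  Wt <- W * rep(w, each = nrow(W))
  nfft <- max(n, round(fs / df_hz))
  pad <- matrix(0, nrow(W), nfft - n)
  X <- t(stats::mvfft(t(cbind(Wt, pad))))
  freqs <- (0:(nfft - 1)) * fs / nfft
  keep <- freqs >= f_range[1] & freqs <= f_range[2] & freqs <= fs / 2
  pw <- 2 * Mod(X[, keep, drop = FALSE])^2 / (fs * sum(w^2))
  structure(list(frequencies_hz = freqs[keep], power = colMeans(pw),
                 per_window = pw, taper = "hanning", normalization = "raw",
                 n = nrow(W)),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate> %d windows, %g-%g Hz (%d bins), taper %s, %s\n",
              x$n, min(x$frequencies_hz), max(x$frequencies_hz),
              length(x$frequencies_hz), x$taper, x$normalization))
  invisible(x)
}

#' Baseline normalization of an episode spectrum
#'
#' Normalizes an episode's log power by the baseline theta-floor reference:
#' each frequency's 10 log10(power) is divided by the baseline's
#' 10 log10(power at 4 Hz).
#'
#' @param estimate,baseline_estimate `spectral_estimate`s on grids that
#'   include 4 Hz (the baseline's).
#' @return A `spectral_estimate` with `normalization = "baseline_4hz_log"`.
#' @export
normalize_power <- function(estimate, baseline_estimate) {
  i4 <- which.min(abs(baseline_estimate$frequencies_hz - 4))
  if (abs(baseline_estimate$frequencies_hz[i4] - 4) > 0.126)
    stop("normalize_power: baseline grid has no 4 Hz bin")
  p4 <- baseline_estimate$power[i4]
  if (!is.finite(p4) || p4 <= 0)
    stop("normalize_power: non-positive baseline power at 4 Hz")
  ref <- 10 * log10(p4)
  if (ref == 0) stop("normalize_power: baseline 4 Hz log-power is zero")
  out <- estimate
  out$power <- 10 * log10(estimate$power) / ref
  out$per_window <- 10 * log10(estimate$per_window) / ref
  out$normalization <- "baseline_4hz_log"
  out
}

#' Grand average of per-subject spectra
#'
#' @param estimates List of `spectral_estimate`s (one per subject) on a
#'   common frequency grid.
#' @return List with `frequencies_hz`, `mean`, `sd`, `n_subjects`.
#' @export
grand_average_spectra <- function(estimates) {
  M <- do.call(rbind, lapply(estimates, `[[`, "power"))
  list(frequencies_hz = estimates[[1]]$frequencies_hz,
       mean = colMeans(M), sd = apply(M, 2, stats::sd),
       n_subjects = length(estimates))
}

#' Peak theta frequency of a spectrum
#'
#' Maximum of the power spectrum within the theta band. Exact ties across the
#' whole band are broken toward the lowest frequency and flagged.
#'
#' @param estimate A `spectral_estimate` whose grid covers the band.
#' @param band Theta band (Hz).
#' @return List with `value_hz`, `band`, `tie` flag.
#' @export
peak_theta_frequency <- function(estimate, band = c(5, 12)) {
  f <- estimate$frequencies_hz
  in_band <- f >= band[1] & f <= band[2]
  if (!any(in_band)) stop("peak_theta_frequency: grid does not cover the theta band")
  p <- estimate$power[in_band]
  fb <- f[in_band]
  tie <- length(unique(p)) == 1
  list(value_hz = fb[which.max(p)], band = band, tie = tie)
}

#' One-way ANOVA on per-subject peak frequencies across episodes
#'
#' @param peaks Data frame with columns `subject`, `episode`, `peak_hz`.
#' @return List with the per-episode mean +/- SD table, the `aov` fit, its
#'   p-value, and Tukey multiple comparisons.
#' @export
peak_frequency_anova <- function(peaks) {
  stopifnot(all(c("subject", "episode", "peak_hz") %in% names(peaks)))
  peaks$episode <- factor(peaks$episode)
  fit <- stats::aov(peak_hz ~ episode, data = peaks)
  tab <- do.call(rbind, lapply(split(peaks$peak_hz, peaks$episode), function(v)
    data.frame(mean_hz = mean(v), sd_hz = stats::sd(v), n = length(v))))
  list(summary = tab,
       fit = fit,
       p_value = summary(fit)[[1]][["Pr(>F)"]][1],
       tukey = stats::TukeyHSD(fit))
}

#' Trial-shuffle randomization test of spectral power differences
#'
#' Tests, per frequency, whether mean power differs between two groups of
#' episode windows by shuffling window-to-group assignment. The statistic is
#' the difference of group-mean power; the two-sided p-value is the add-one
#' rank of |observed| among |shuffled|, and the significance mask applies a
#' Bonferroni correction across frequencies.
#'
#' @param windows_A,windows_B Window matrices/lists for the two groups (equal
#'   sample length, same sampling rate).
#' @param fs Sampling rate (Hz).
#' @param n_shuffles Number of shuffles (a warning is raised below 100).
#' @param alpha Family-wise significance level.
#' @param seed Optional RNG seed.
#' @param df_hz Frequency spacing of the test grid. The default is coarser
#'   (0.5 Hz) than the episode-spectrum default: with a Bonferroni correction
#'   over F frequencies the smallest attainable add-one p is
#'   1/(n_shuffles + 1), so the grid must satisfy F < alpha * (n_shuffles + 1)
#'   for significance to be reachable at all.
#' @param ... Passed to [episode_spectrum()].
#' @return List with `frequencies_hz`, `observed_diff`, `p_values`,
#'   `significant` (Bonferroni mask), `alpha`, `n_shuffles`.
#' @export
power_randomization_test <- function(windows_A, windows_B, fs,
                                     n_shuffles = 1000, alpha = 0.05,
                                     seed = NULL, df_hz = 0.5, ...) {
  if (n_shuffles < 100)
    warning("power_randomization_test: fewer than 100 shuffles gives unstable p-values")
  if (!is.null(seed)) set.seed(seed)
  A <- as_window_matrix(windows_A); B <- as_window_matrix(windows_B)
  if (nrow(A) < 2 || nrow(B) < 2)
    stop("power_randomization_test: need >= 2 windows per group")
  if (ncol(A) != ncol(B)) stop("episode windows must all have equal length")
  specA <- episode_spectrum(A, fs, df_hz = df_hz, ...)
  specB <- episode_spectrum(B, fs, df_hz = df_hz, ...)
  P <- rbind(specA$per_window, specB$per_window)  # (nA+nB) x F
  nA <- nrow(A); nTot <- nrow(P)
  obs <- colMeans(specA$per_window) - colMeans(specB$per_window)
  # each shuffle = random re-assignment of windows to groups of size nA/nB;
  # realized as an indicator-matrix product for speed
  Ind <- matrix(0, n_shuffles, nTot)
  for (s in seq_len(n_shuffles)) Ind[s, sample.int(nTot, nA)] <- 1
  sumA <- Ind %*% P
  sumB <- matrix(colSums(P), n_shuffles, ncol(P), byrow = TRUE) - sumA
  null_diff <- sumA / nA - sumB / (nTot - nA)
  exceed <- colSums(abs(null_diff) >= matrix(abs(obs), n_shuffles,
                                             ncol(P), byrow = TRUE))
  p <- (1 + exceed) / (n_shuffles + 1)
  list(frequencies_hz = specA$frequencies_hz, observed_diff = obs,
       p_values = p, significant = p < alpha / length(p),
       alpha = alpha, n_shuffles = n_shuffles)
}
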