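# episode spectra, spectrogram, baseline normalization, shuffle tests

make_tone_windows <- function(n_win, freq, fs = 2000, len_s = 0.5, amp = 1,
                              noise_sd = 0.1) {
  t <- (0:(round(len_s * fs) - 1)) / fs
  do.call(rbind, lapply(seq_len(n_win), function(i)
    amp * cos(2 * pi * freq * t + runif(1, 0, 2 * pi)) +
      rnorm(length(t), 0, noise_sd)))
}

test_that("episode spectrum recovers a known tone and rejects bad input", {
  set.seed(1)
  W <- make_tone_windows(30, 8, noise_sd = 0.1)  # SNR 10
  est <- episode_spectrum(W, fs = 2000)
  pk <- peak_theta_frequency(est)
  expect_lt(abs(pk$value_hz - 8), 0.25 + 1e-9)
  expect_false(pk$tie)

  expect_error(episode_spectrum(list(rnorm(100), rnorm(99)), fs = 2000),
               "equal length")
  # zero signal gives zero power
  z <- episode_spectrum(matrix(0, 3, 1000), fs = 2000)
  expect_true(all(z$power == 0))
})

test_that("white-noise spectra are flat and satisfy Parseval on average", {
  set.seed(2)
  W <- matrix(rnorm(200 * 1000), 200)
  est <- episode_spectrum(W, fs = 2000)
  expect_lt(max(est$power) / min(est$power), 1.5)

  # total periodogram power over the full band tracks window variance
  full <- episode_spectrum(W, fs = 2000, f_range = c(0, 1000), df_hz = 2)
  df <- diff(full$frequencies_hz[1:2])
  tot <- mean(rowSums(full$per_window)) * df
  expect_lt(abs(tot / mean(apply(W, 1, var)) - 1), 0.05)
})

test_that("peak frequency estimator is unbiased on- and off-grid", {
  set.seed(3)
  on_grid <- episode_spectrum(make_tone_windows(5, 8, noise_sd = 0), fs = 2000)
  expect_equal(peak_theta_frequency(on_grid)$value_hz, 8)
  off <- episode_spectrum(make_tone_windows(5, 8.1, noise_sd = 0), fs = 2000)
  expect_lt(abs(peak_theta_frequency(off)$value_hz - 8.1), 0.125 + 1e-9)
  # all-equal power ties break to the lowest in-band frequency, flagged
  flat <- list(frequencies_hz = seq(4, 20, 0.25), power = rep(1, 65))
  class(flat) <- "spectral_estimate"
  pk <- peak_theta_frequency(flat)
  expect_true(pk$tie)
  expect_equal(pk$value_hz, 5)
})

test_that("baseline normalization follows the 4 Hz log-power rule", {
  f <- seq(4, 20, 0.25)
  base <- structure(list(frequencies_hz = f, power = rep(100, length(f)),
                         per_window = matrix(100, 2, length(f)),
                         taper = "hanning", normalization = "raw", n = 2),
                    class = "spectral_estimate")
  # episode power equal to the baseline 4 Hz power everywhere -> exactly 1
  norm <- normalize_power(base, base)
  expect_true(all(abs(norm$power - 1) < 1e-12))
  bad <- base; bad$power[1] <- 0
  expect_error(normalize_power(base, bad), "non-positive")

  # a planted theta boost shows up above the baseline curve in-band
  # (microvolt-scale amplitudes: the log-power normalization needs a
  # positive 4 Hz reference)
  set.seed(4)
  noise_b <- matrix(rnorm(30 * 1000, 0, 100), 30)
  t <- (0:999) / 2000
  boost <- noise_b + 200 * matrix(cos(outer(runif(30, 0, 2 * pi), 2 * pi * 8 * t, "+")),
                                  30, 1000)
  eb <- episode_spectrum(noise_b, 2000)
  et <- episode_spectrum(boost, 2000)
  nb <- normalize_power(eb, eb); nt <- normalize_power(et, eb)
  in_band <- nb$frequencies_hz >= 7 & nb$frequencies_hz <= 9
  expect_true(all(nt$power[in_band] > nb$power[in_band]))
})

test_that("adaptive spectrogram: stationary ridge, 8-cycle window, chirp tracking", {
  set.seed(5)
  fs <- 2000
  sig <- tone_signal(8, fs = fs, dur_s = 40, noise_sd = 0.05)
  onsets <- c(10, 20, 30)
  # ridge location uses the single concentration-optimal taper: averaging
  # several tapers estimates band-averaged power (bandwidth ~ f/4 at NW = 2),
  # which flat-tops the ridge by design
  sg <- spectrogram_adaptive(sig, onsets, step_s = 0.25, n_tapers = 1)
  ridge <- sg$frequencies_hz[apply(sg$raw_power, 2, which.max)]
  expect_true(all(abs(ridge - 8) <= 0.5 + 1e-9))  # within one 0.5 Hz bin

  # linear chirp 6 -> 12 Hz over 6 s: ridge tracks instantaneous frequency
  tt <- (0:(12 * fs - 1)) / fs
  inst_f <- function(t) 6 + (12 - 6) * pmin(pmax(t - 3, 0), 6) / 6
  phase <- 2 * pi * cumsum(inst_f(tt)) / fs
  chirp <- continuous_signal(cos(phase) + rnorm(length(tt), 0, 0.02), fs,
                             0, "lfp", "uV")
  sgc <- spectrogram_adaptive(chirp, 6, step_s = 0.25, n_tapers = 1)
  sel <- sgc$times_s >= -2 & sgc$times_s <= 2
  ridge_c <- sgc$frequencies_hz[apply(sgc$raw_power[, sel], 2, which.max)]
  expected <- inst_f(6 + sgc$times_s[sel])
  expect_lt(max(abs(ridge_c - expected)), 0.5 + 1e-9)

  # trials without full coverage are dropped with a warning
  expect_warning(spectrogram_adaptive(sig, c(2, 20), step_s = 0.5), "dropping")
})

test_that("power randomization test flags planted differences and only those", {
  # group size chosen so the in-band (2x tone power) effect is overwhelming
  # while Hanning-window leakage of the 8 Hz tone toward the 4-5 Hz bins
  # stays below the detection floor (a 500 ms Hanning mainlobe spans +-4 Hz)
  set.seed(6)
  A <- make_tone_windows(30, 8, amp = sqrt(2), noise_sd = 1)
  B <- make_tone_windows(30, 8, amp = 1, noise_sd = 1)
  res <- power_randomization_test(A, B, fs = 2000, n_shuffles = 1000)
  in_band <- res$frequencies_hz >= 5 & res$frequencies_hz <= 12
  expect_true(any(res$significant[in_band]))
  expect_false(any(res$significant[!in_band]))

  # identical groups cannot be significant at any frequency
  same <- power_randomization_test(A, A, fs = 2000, n_shuffles = 200)
  expect_true(all(same$p_values == 1))
  expect_warning(power_randomization_test(A, B, fs = 2000, n_shuffles = 50),
                 "unstable")
})

test_that("shuffle p-values are uniform under the null", {
  set.seed(7)
  fs <- 200
  ps <- replicate(200, {
    A <- matrix(rnorm(10 * 100), 10)
    B <- matrix(rnorm(10 * 100), 10)
    res <- power_randomization_test(A, B, fs = fs, n_shuffles = 199)
    res$p_values[sample(length(res$p_values), 1)]
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("slepian tapers are orthonormal and concentrated", {
  tap <- thetawhisk:::dpss_tapers(256, nw = 2, k = 3)
  G <- crossprod(tap)
  expect_equal(G, diag(3), tolerance = 1e-8)
  # leading taper concentrates energy in the central half of the window
  central <- sum(tap[65:192, 1]^2)
  expect_gt(central, 0.9)
})
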