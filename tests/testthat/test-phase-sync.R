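# band-pass filtering, Hilbert phase, bias correction, PSI

test_that("theta band-pass passes 8 Hz and rejects 2 Hz, with zero phase", {
  tone8 <- tone_signal(8, fs = 1000, dur_s = 10)
  f8 <- bandpass_theta(tone8)
  mid <- 2001:8000
  expect_lt(abs(max(f8$samples[mid]) - 1), 0.05)  # amplitude within 5%

  tone2 <- tone_signal(2, fs = 1000, dur_s = 10)
  f2 <- bandpass_theta(tone2)
  atten_db <- 20 * log10(max(abs(f2$samples[mid])) / 1)
  expect_lt(atten_db, -20)

  # zero-phase: filtered peaks coincide with input peaks (to one sample)
  pk_in <- which(diff(sign(diff(tone8$samples[mid]))) < 0) + 1
  pk_out <- which(diff(sign(diff(f8$samples[mid]))) < 0) + 1
  expect_lte(max(abs(pk_in - pk_out)), 1)

  expect_error(bandpass_theta(tone_signal(8, fs = 10, dur_s = 2)),
               "sample rate")
  expect_error(bandpass_theta(tone_signal(8, fs = 1000, dur_s = 0.2)),
               "too short")
})

test_that("instantaneous phase follows the cosine convention", {
  fs <- 1000
  cosg <- bandpass_theta(tone_signal(8, fs = fs, dur_s = 10))
  ph <- instantaneous_phase(cosg)
  mid <- 2001:8000
  peaks <- mid[which(diff(sign(diff(cosg$samples[mid]))) < 0) + 1]
  expect_lt(max(abs(ph$phases[peaks])), 0.06)  # phase ~ 0 at maxima

  # sine lags cosine by pi/2
  t <- (0:9999) / fs
  sing <- continuous_signal(sin(2 * pi * 8 * t), fs, 0, "lfp", "uV")
  phs <- instantaneous_phase(bandpass_theta(sing))
  d <- atan2(sin(ph$phases[mid] - phs$phases[mid]),
             cos(ph$phases[mid] - phs$phases[mid]))
  expect_lt(abs(mean(d) - pi / 2), 0.05)

  # unwrapped slope of an 8 Hz tone is 2*pi*8 rad/s to 0.1%
  uw <- thetawhisk:::phase_unwrap(ph$phases[mid])
  slope <- (uw[length(uw)] - uw[1]) / ((length(uw) - 1) / fs)
  expect_lt(abs(slope - 2 * pi * 8) / (2 * pi * 8), 0.001)

  expect_error(instantaneous_phase(continuous_signal(rep(1, 1000), 1000)),
               "constant")
})

test_that("rank-based bias correction uniformizes skewed phase distributions", {
  # evenly spaced grid under a forced transform moves each point < 2*pi/n
  n <- 1000
  grid <- -pi + 2 * pi * (seq_len(n) - 1) / n
  out <- psi_bias_correct(grid, force = TRUE)
  expect_lte(max(abs(out - grid)), 2 * pi / n + 1e-9)

  # n = 4 forced: outputs land on the quarter grid
  out4 <- suppressWarnings(psi_bias_correct(c(-2, -1, 0.5, 2)))
  expect_equal(sort(out4), c(-2, -1, 0.5, 2))  # < 100 samples: skipped
  expect_warning(psi_bias_correct(c(-2, -1, 0.5, 2)), "skipped")

  # von Mises-skewed phases become Rayleigh-uniform
  set.seed(11)
  skewed <- rvonmises(5000, 0, 1)
  expect_lt(rayleigh_test(skewed)$p, 1e-6)
  fixed <- psi_bias_correct(skewed)
  expect_gt(rayleigh_test(fixed)$p, 0.05)

  # already-uniform phases are left alone
  unif <- runif(5000, -pi, pi)
  expect_identical(psi_bias_correct(unif), unif)
})

test_that("PSI identities hold exactly", {
  # constant phase difference of 1 rad
  x <- runif(100, -pi, pi)
  r1 <- compute_psi(thetawhisk:::wrap_phase(x + 1), x)
  expect_equal(r1$psi, 1, tolerance = 1e-12)
  expect_equal(r1$mean_delay_rad, 1, tolerance = 1e-9)

  # four symmetric phase differences cancel
  r0 <- compute_psi(c(0, pi / 2, pi, 3 * pi / 2), rep(0, 4))
  expect_lt(r0$psi, 1e-12)

  # PSI(x, x) = 1 for any series paired with itself
  set.seed(2)
  z <- runif(57, -pi, pi)
  expect_equal(compute_psi(z, z)$psi, 1, tolerance = 1e-12)

  expect_error(compute_psi(1, 1), "< 2 samples")
})

test_that("PSI matches brute-force summation and is rotation invariant", {
  set.seed(3)
  for (rep in 1:25) {
    n <- sample(2:20, 1)
    x <- runif(n, -pi, pi); y <- runif(n, -pi, pi)
    got <- compute_psi(x, y)
    th <- x - y
    brute <- sqrt((sum(cos(th)) / n)^2 + (sum(sin(th)) / n)^2)
    expect_equal(got$psi, brute, tolerance = 1e-12)
    # global rotation leaves PSI unchanged and shifts the mean delay
    c0 <- runif(1, -pi, pi)
    rot <- compute_psi(thetawhisk:::wrap_phase(x + c0), y)
    expect_equal(rot$psi, got$psi, tolerance = 1e-12)
    expect_wrapped_equal(rot$mean_delay_rad, got$mean_delay_rad + c0, 1e-9)
  }
})

test_that("PSI of iid uniform phase differences follows the random-walk scale", {
  set.seed(4)
  vals <- replicate(300, compute_psi(runif(500, -pi, pi), rep(0, 500))$psi)
  expect_lt(abs(mean(vals) - sqrt(pi / (4 * 500))), 0.006)
})

test_that("windowed PSI interpolates across different sampling rates", {
  # identical underlying oscillation sampled at 2 kHz and 1 kHz: PSI ~ 1
  fs_x <- 2000; fs_y <- 1000
  px <- ramp_phase(8, fs = fs_x, dur_s = 4)
  py <- ramp_phase(8, fs = fs_y, dur_s = 4)
  r <- compute_psi(px, py, list(start_s = 1, end_s = 1.25))
  expect_equal(r$n_samples, 500)
  expect_gt(r$psi, 0.999)
  expect_lt(abs(r$mean_delay_rad), 0.01)
})

test_that("chance level separates coupled from uncoupled sessions", {
  gen_trials <- function(eps, n_tr, seed) {
    set.seed(seed)
    cfg <- sim_config(duration_s = 1, coupling_eps = eps, seed = NULL)
    rows <- lapply(seq_len(n_tr), function(i) {
      p <- gen_coupled_pair(cfg, return_phases = TRUE)
      list(x = p$phase_theta[seq(1001, 1500, by = 2)],
           y = p$phase_whisk[501:750])
    })
    list(phi_x = do.call(rbind, lapply(rows, `[[`, "x")),
         phi_y = do.call(rbind, lapply(rows, `[[`, "y")))
  }
  coupled <- gen_trials(30, 20, 71)
  ch <- psi_chance_level(coupled, n_shuffles = 500)
  expect_true(ch$exceeds)
  expect_gte(ch$chance_level, min(ch$shuffled_psi))
  expect_lte(ch$chance_level, max(ch$shuffled_psi))
  expect_error(psi_chance_level(list(phi_x = coupled$phi_x[1:5, ],
                                     phi_y = coupled$phi_y[1:5, ])),
               ">= 10 trials")
})

test_that("pairwise PSI matrix agrees with direct evaluation", {
  set.seed(5)
  phix <- matrix(runif(60, -pi, pi), 4)
  phiy <- matrix(runif(60, -pi, pi), 4)
  M <- thetawhisk:::psi_pairwise_matrix(phix, phiy)
  for (i in 1:4) for (j in 1:4)
    expect_equal(M[i, j], compute_psi(phix[i, ], phiy[j, ])$psi,
                 tolerance = 1e-12)
})

test_that("phase delay statistics behave at the extremes", {
  all_same <- rep(1.3, 50)
  st <- phase_delay_stats(all_same)
  expect_lt(st$rayleigh_p, 1e-6)
  expect_equal(st$circular_mean_rad, 1.3, tolerance = 1e-9)

  set.seed(6)
  rej <- replicate(200, phase_delay_stats(runif(50, -pi, pi))$rayleigh_p < 0.05)
  expect_lt(mean(rej), 0.11)
  expect_error(phase_delay_stats(1:3), "fewer than 5")
  # significance filtering drops low-PSI trials
  st2 <- phase_delay_stats(c(rep(1, 10), rep(-2, 10)),
                           psi = c(rep(0.9, 10), rep(0.1, 10)),
                           psi_threshold = 0.5)
  expect_equal(st2$n, 10)
  expect_equal(st2$circular_mean_rad, 1, tolerance = 1e-9)
})
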