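# circular statistics: Rayleigh test, von Mises fits, pooled and per-neuron
# analyses, equal-sample bootstrap, proportion tests

test_that("Rayleigh statistic and p follow the closed forms", {
  r10 <- rayleigh_test(rep(0.7, 10))
  expect_equal(r10$Z, 20, tolerance = 1e-12)
  expect_equal(r10$p, exp(-10), tolerance = 1e-15)

  r4 <- rayleigh_test(c(0, pi / 2, pi, 3 * pi / 2))
  expect_lt(r4$Z, 1e-12)
  expect_equal(r4$p, 1, tolerance = 1e-9)

  # p = exp(-Z/2) equals the chi-squared(2) survival function
  set.seed(1)
  for (i in 1:20) {
    rt <- rayleigh_test(runif(sample(5:200, 1), -pi, pi))
    expect_equal(rt$p, stats::pchisq(rt$Z, 2, lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_equal(rt$Z, 2 * rt$n * rt$r^2, tolerance = 1e-12)
  }
  expect_error(rayleigh_test(0.3), "at least 2")
})

test_that("r, circular mean and Z match direct summation on tiny samples", {
  set.seed(2)
  for (i in 1:20) {
    n <- sample(2:12, 1)
    ph <- runif(n, -pi, pi)
    C <- sum(cos(ph)); S <- sum(sin(ph))
    expect_equal(circ_r(ph), sqrt(C^2 + S^2) / n, tolerance = 1e-12)
    expect_equal(circ_mean(ph), atan2(S, C), tolerance = 1e-12)
    expect_equal(rayleigh_test(ph)$Z, 2 * (C^2 + S^2) / n, tolerance = 1e-10)
  }
})

test_that("von Mises fitting is consistent and handles degeneracy", {
  set.seed(3)
  u <- fit_von_mises(runif(10000, -pi, pi))
  expect_lt(u$kappa, 0.05)

  vm <- fit_von_mises(rvonmises(10000, pi / 2, 2))
  expect_lt(abs(vm$theta_mean - pi / 2), 0.05)
  expect_lt(abs(vm$kappa - 2), 0.15)

  deg <- fit_von_mises(rep(1.1, 20))
  expect_true(deg$degenerate)
  expect_equal(deg$kappa, 1e3)
  expect_error(fit_von_mises(runif(5, -pi, pi)), "at least 10")

  # kappa estimator bias shrinks with n across concentrations
  for (k in c(0.3, 1, 3)) {
    fit <- fit_von_mises(rvonmises(1e5, 0, k))
    expect_lt(abs(fit$kappa - k), 0.05)
  }
})

test_that("spike phases follow the signal convention at peaks and troughs", {
  fs <- 2000
  sig <- bandpass_theta(tone_signal(8, fs = fs, dur_s = 4))
  ph <- instantaneous_phase(sig)
  # spikes exactly at a peak (t = k/8 s) and a trough (t = (k + 0.5)/8 s)
  peaks <- spike_train(c(1, 1.5, 2))
  troughs <- spike_train(c(1.0625, 1.5625, 2.0625))
  php <- assign_spike_phases(peaks, ph)$phases
  pht <- assign_spike_phases(troughs, ph)$phases
  expect_lt(max(abs(php)), 0.05)
  expect_lt(max(abs(abs(pht) - pi)), 0.1)
  # spikes outside coverage are dropped and counted
  far <- spike_train(c(1, 100))
  res <- assign_spike_phases(far, ph)
  expect_equal(res$n_dropped, 1)
  # nearest-sample assignment stays close to interpolation
  near <- assign_spike_phases(peaks, ph, method = "nearest")$phases
  expect_lt(max(abs(near - php)), 0.05)
})

test_that("window filtering keeps only in-window spikes", {
  ph <- ramp_phase(8, fs = 1000, dur_s = 20)
  sp <- spike_train(seq(0.5, 19.5, by = 0.1))
  w <- data.frame(start_s = c(2, 10), end_s = c(3, 11))
  res <- assign_spike_phases(sp, ph, w)
  expect_true(all(res$spike_times_s >= 2 & res$spike_times_s < 11))
  expect_true(all((res$spike_times_s < 3) | (res$spike_times_s >= 10)))
})

test_that("pooled histogram normalizes, recovers the arrow, and its control is flat", {
  set.seed(4)
  ph <- rvonmises(12000, 3.5 - 2 * pi, 1)  # mean near the wrap boundary
  h <- pooled_phase_histogram(ph)
  expect_equal(sum(h$probabilities), 1, tolerance = 1e-12)
  expect_length(h$probabilities, 36)
  expect_lt(abs(atan2(sin(h$mean_angle_rad - 3.5), cos(h$mean_angle_rad - 3.5))),
            0.1)
  nonsig <- replicate(40, {
    hh <- pooled_phase_histogram(rvonmises(500, 0, 2), shuffle_control = TRUE,
                                 phase_pool = runif(5000, -pi, pi))
    hh$control$rayleigh_p > 0.05
  })
  expect_gte(mean(nonsig), 0.8)
  expect_error(pooled_phase_histogram(numeric(0)), "no spike phases")
})

test_that("equal-sample bootstrap uses the minimum size and exposes kappa's n-dependence", {
  set.seed(5)
  sets <- list(a = rvonmises(5000, 0, 1), b = rvonmises(2000, 0, 1))
  bs <- bootstrap_equal_size(sets, n_iter = 100)
  expect_equal(bs$resample_size, 2000)
  expect_lt(abs(bs$median_kappa[["a"]] - bs$median_kappa[["b"]]), 0.1)

  # uniform phases: fitted kappa inflates at small n and shrinks with n
  u <- runif(20000, -pi, pi)
  small <- bootstrap_equal_size(list(a = u[1:100], b = u[101:200]), n_iter = 200)
  large <- bootstrap_equal_size(list(a = u[1:10000], b = u[10001:20000]),
                                n_iter = 200)
  expect_gt(min(small$median_kappa), max(large$median_kappa))

  tiny <- list(a = rvonmises(5, 0, 1), b = rvonmises(2000, 0, 1),
               c = rvonmises(3000, 0, 1))
  bs2 <- bootstrap_equal_size(tiny, n_iter = 50)
  expect_equal(bs2$excluded, "a")
})

test_that("population summary applies the inclusion rule and clusters preferences", {
  set.seed(6)
  aligned <- lapply(1:20, function(i) fit_von_mises(rvonmises(2000, 2.2, 1.5)))
  pop <- population_phase_summary(aligned)
  expect_lt(pop$population_rayleigh_p, 1e-4)
  expect_lt(abs(pop$mean_direction_rad - 2.2), 0.1)
  expect_equal(pop$n_included, 20)

  # uniformly distributed preferred phases: population test stays quiet
  quiet <- replicate(30, {
    fits <- lapply(runif(12, -pi, pi), function(th)
      fit_von_mises(rvonmises(2000, th, 2)))
    population_phase_summary(fits)$population_rayleigh_p > 0.05
  })
  expect_gte(mean(quiet), 0.8)

  # inclusion: small-sample neurons stay only if significantly locked
  sparse_sig <- fit_von_mises(rvonmises(200, 0, 2))      # locked, small n
  sparse_uni <- fit_von_mises(runif(200, -pi, pi))       # unlocked, small n
  big_uni <- fit_von_mises(runif(2000, -pi, pi))         # unlocked, big n
  pop2 <- population_phase_summary(list(sparse_sig, sparse_uni, big_uni),
                                   min_spikes = 1000)
  expect_equal(pop2$n_included, 2)
  empty <- population_phase_summary(list(sparse_uni), min_spikes = 1000)
  expect_true(empty$empty)
})

test_that("proportion arithmetic matches hand computation", {
  # 37 locked out of 136 is 27%
  expect_equal(round(100 * 37 / 136), 27)
  z <- two_proportion_ztest(50, 100, 50, 100)
  expect_equal(z$z, 0)
  expect_equal(z$p, 1)
  expect_error(two_proportion_ztest(0, 10, 0, 12), "pooled proportion")
  expect_error(two_proportion_ztest(10, 10, 12, 12), "pooled proportion")
})
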