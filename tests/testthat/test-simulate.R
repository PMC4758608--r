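# synthetic-data generator: determinism, oscillator behavior, spike trains,
# planted behavioral effects

test_that("sim_config rejects invalid parameter combinations", {
  expect_error(sim_config(f_theta_hz = 3), "5-12")
  expect_error(sim_config(f_whisk_hz = 14), "5-12")
  expect_error(sim_config(coupling_eps = -1), "coupling_eps")
  expect_error(sim_config(kappa_gen = -0.5), "kappa_gen")
  expect_error(sim_config(phase_noise_sd = NaN), "finite")
  expect_error(sim_config(behavior_r_target = 1.2), "r_target")
  expect_error(sim_config(n_trials = 0), "n_trials")
  expect_error(sim_config(p_correct_link = list(base_rate = 1.5, psi_effect = 0)),
               "base_rate")
})

test_that("identical config and seed give bit-identical output", {
  cfg <- sim_config(duration_s = 3, seed = 123)
  a <- gen_coupled_pair(cfg)
  b <- gen_coupled_pair(cfg)
  expect_identical(a$lfp$samples, b$lfp$samples)
  expect_identical(a$whisking$samples, b$whisking$samples)

  cfg2 <- sim_config(n_trials = 4, n_units = 1, base_rate_hz = 4, seed = 9)
  s1 <- gen_session(cfg2)
  s2 <- gen_session(cfg2)
  expect_identical(s1$lfp$samples, s2$lfp$samples)
  expect_identical(s1$spikes[[1]]$spike_times_s, s2$spikes[[1]]$spike_times_s)
  expect_identical(as.data.frame(s1$events), as.data.frame(s2$events))
})

test_that("uncoupled oscillators with distinct frequencies stay incoherent", {
  cfg <- sim_config(duration_s = 100, coupling_eps = 0, f_theta_hz = 8,
                    f_whisk_hz = 10, seed = 2)
  p <- gen_coupled_pair(cfg, return_phases = TRUE)
  th <- p$phase_theta[seq(1, length(p$phase_theta), by = 2)]
  full <- compute_psi(th, p$phase_whisk)
  # mean resultant length of a long incoherent record is near zero (the
  # random-walk scale is sqrt(pi / (4 N)) for iid samples; drift makes it
  # smaller still)
  expect_lt(full$psi, 0.1)
})

test_that("strong coupling at matched frequencies locks phase at the target lag", {
  cfg <- sim_config(duration_s = 30, coupling_eps = 40, phase_noise_sd = 0.5,
                    f_theta_hz = 8, f_whisk_hz = 8, coupling_lag_rad = 1.2,
                    seed = 3)
  p <- gen_coupled_pair(cfg, return_phases = TRUE)
  i <- (10 * 2000):(30 * 2000 - 1)          # skip the entrainment transient
  th <- p$phase_theta[i][seq(1, length(i), by = 2)]
  wh <- p$phase_whisk[(i[1] + 1) %/% 2 + seq_along(th) - 1]
  r <- compute_psi(th, wh)
  expect_gt(r$psi, 0.95)
  expect_lt(abs(r$mean_delay_rad - 1.2), 0.1)
})

test_that("non-finite generator parameters are rejected", {
  expect_error(sim_config(coupling_eps = Inf), "finite")
})

test_that("phase-locked spikes have the expected rate and phase law", {
  # kappa = 0: homogeneous Poisson at base rate
  ph <- ramp_phase(8, fs = 1000, dur_s = 100)
  sp <- gen_phase_locked_spikes(ph, 0, 0, base_rate_hz = 5, seed = 4)
  n <- length(sp$spike_times_s)
  expect_lt(abs(n - 500), 3 * sqrt(500))

  # kappa = 2: von Mises phase distribution, parameters recovered
  sp2 <- gen_phase_locked_spikes(ph, 2, pi, base_rate_hz = 120, seed = 5)
  phases <- assign_spike_phases(sp2, ph)$phases
  expect_gt(length(phases), 10000)
  fit <- fit_von_mises(phases)
  expect_lt(abs(atan2(sin(fit$theta_mean - pi), cos(fit$theta_mean - pi))), 0.05)
  expect_lt(abs(fit$kappa - 2), 0.15)
})

test_that("spike phases pass a chi-squared test against the generating law", {
  ph <- ramp_phase(8, fs = 1000, dur_s = 120)
  kappa <- 1.2; theta <- 0.7
  sp <- gen_phase_locked_spikes(ph, kappa, theta, base_rate_hz = 100, seed = 6)
  phases <- assign_spike_phases(sp, ph)$phases
  expect_gt(length(phases), 10000)
  edges <- seq(-pi, pi, length.out = 37)
  obs <- tabulate(findInterval(phases, edges, rightmost.closed = TRUE), 36)
  pr <- vapply(seq_len(36), function(i)
    stats::integrate(dvonmises, edges[i], edges[i + 1], theta = theta,
                     kappa = kappa)$value, numeric(1))
  gof <- suppressWarnings(stats::chisq.test(obs, p = pr / sum(pr)))
  expect_gt(gof$p.value, 0.01)
})

test_that("kappa = 0 spike trains trigger the Rayleigh test at the nominal rate", {
  ph <- ramp_phase(8, fs = 500, dur_s = 60)
  set.seed(8)
  rej <- replicate(100, {
    sp <- gen_phase_locked_spikes(ph, 0, 0, base_rate_hz = 10)
    rayleigh_test(assign_spike_phases(sp, ph)$phases)$p < 0.05
  })
  expect_lt(mean(rej), 0.12)
  expect_gte(mean(rej), 0)
})

test_that("gen_session produces a valid schedule with the planted structure", {
  cfg <- sim_config(n_trials = 40, seed = 14)
  ses <- gen_session(cfg)
  ev <- ses$events
  expect_true(all(ev$contact_onset_s < ev$contact_offset_s))
  expect_true(all(ev$contact_offset_s <= ev$spout_arrival_s))
  expect_true(all(ev$spout_arrival_s <= ev$reward_end_s))
  # coupling boosted in touch relative to approach shows up in realized PSI
  tr <- ses$truth$per_trial
  expect_gt(mean(tr$psi_touch_meas), mean(tr$psi_approach_meas))
  # signals cover every event window
  expect_gte(min(ev$contact_onset_s) - 3, ses$lfp$start_time_s)
  expect_lte(max(ev$reward_end_s), ses$lfp$start_time_s +
               length(ses$lfp$samples) / ses$lfp$sample_rate_hz)
})

test_that("plant_behavioral_link hits the target correlation in expectation", {
  set.seed(42)
  devs <- replicate(20, {
    n <- 915
    psi <- data.frame(psi_approach = pmin(pmax(rnorm(n, 0.85, 0.1), 0), 1),
                      psi_touch = pmin(pmax(rnorm(n, 0.88, 0.1), 0), 1))
    pl <- plant_behavioral_link(psi, 0.146, list(base_rate = 0.78, psi_effect = 0.05))
    d <- pl$touch_duration_s
    cor(psi$psi_touch - psi$psi_approach, max(d) - d) - 0.146
  })
  expect_lt(mean(abs(devs)), 2 / sqrt(915))
})

test_that("a null behavioral link plants nothing", {
  set.seed(43)
  n <- 915
  rs <- replicate(40, {
    psi <- data.frame(psi_approach = rnorm(n, 0.85, 0.1),
                      psi_touch = rnorm(n, 0.88, 0.1))
    pl <- plant_behavioral_link(psi, 0, list(base_rate = 0.78, psi_effect = 0))
    d <- pl$touch_duration_s
    cor(psi$psi_touch - psi$psi_approach, max(d) - d)
  })
  expect_gte(mean(abs(rs) < 0.07), 0.9)
  # flat link: no planted correct/incorrect PSI difference
  diffs <- replicate(20, {
    psi <- data.frame(psi_approach = rnorm(n, 0.85, 0.1),
                      psi_touch = rnorm(n, 0.88, 0.1))
    pl <- plant_behavioral_link(psi, 0, list(base_rate = 0.78, psi_effect = 0))
    mean(psi$psi_touch[pl$correct]) - mean(psi$psi_touch[!pl$correct])
  })
  expect_lt(abs(mean(diffs)), 0.01)
  expect_error(plant_behavioral_link(
    data.frame(psi_approach = 1:5 / 10, psi_touch = 1:5 / 10), 1.0,
    list(base_rate = 0.5, psi_effect = 0)), "r_target")
})
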