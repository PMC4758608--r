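## Phase Synchronization Index and its trial-level statistics.
##
## PSI = sqrt(<cos theta_xy>^2 + <sin theta_xy>^2), the mean resultant length
## of the instantaneous phase difference theta_xy = n*phi_x - m*phi_y (1:1
## locking by default). 0 = no synchronization, 1 = constant phase difference.

psi_of_theta <- function(theta) {
  c(psi = sqrt(mean(cos(theta))^2 + mean(sin(theta))^2),
    mean_delay = wrap_phase(atan2(mean(sin(theta)), mean(cos(theta)))))
}

#' Phase Synchronization Index over a window
#'
#' Computes the PSI and circular-mean phase delay (theta-phase minus
#' whisking-phase) of two phase series over an episode window. Phase
#' differences are taken at the sample times of `phase_x`; when the two series
#' have different sampling rates, `phase_y` is evaluated at those times by
#' linear interpolation of its unwrapped phase. Only 1:1 locking is of
#' interest for rhythms sharing the theta band, but the `n:m` generalization
#' is provided.
#'
#' @param phase_x,phase_y `phase_series` objects, or bare numeric phase
#'   vectors of equal length (then `window` is ignored).
#' @param window List/row with `start_s`, `end_s`; the window is half-open
#'   \[start, end).
#' @param n,m Locking ratio (1:1 default).
#' @return Object of class `psi_result`: list with `psi`, `mean_delay_rad`,
#'   `n_samples`, `label`, `trial_id`.
#' @export
compute_psi <- function(phase_x, phase_y, window = NULL, n = 1, m = 1) {
  if (is.numeric(phase_x)) {
    if (!is.numeric(phase_y) || length(phase_x) != length(phase_y))
      stop("compute_psi: bare phase vectors must be numeric and equal length")
    if (length(phase_x) < 2) stop("compute_psi: window with < 2 samples")
    th <- n * phase_x - m * phase_y
    ps <- psi_of_theta(th)
    return(structure(list(psi = unname(ps["psi"]),
                          mean_delay_rad = unname(ps["mean_delay"]),
                          n_samples = length(phase_x),
                          label = NA_character_, trial_id = NA),
                     class = "psi_result"))
  }
  stopifnot(inherits(phase_x, "phase_series"), inherits(phase_y, "phase_series"))
  if (is.null(window)) stop("compute_psi: a window is required for phase series")
  fs <- phase_x$sample_rate_hz
  i0 <- ceiling((window$start_s - phase_x$start_time_s) * fs - 1e-9) + 1
  i1 <- ceiling((window$end_s - phase_x$start_time_s) * fs - 1e-9)  # end-exclusive
  if (i1 - i0 + 1 < 2) stop("compute_psi: window with < 2 samples")
  if (i0 < 1 || i1 > length(phase_x$phases))
    stop("compute_psi: window outside phase_x coverage")
  px <- phase_x$phases[i0:i1]
  tx <- phase_x$start_time_s + ((i0:i1) - 1) / fs
  py <- if (abs(phase_y$sample_rate_hz - fs) < 1e-9 &&
            abs(phase_y$start_time_s - phase_x$start_time_s) < 1e-12) {
    phase_y$phases[i0:i1]
  } else {
    phase_at_times(phase_y, tx)
  }
  th <- n * px - m * py
  ps <- psi_of_theta(th)
  structure(list(psi = unname(ps["psi"]), mean_delay_rad = unname(ps["mean_delay"]),
                 n_samples = length(px),
                 label = if (!is.null(window$label)) window$label else NA_character_,
                 trial_id = if (!is.null(window$trial_id)) window$trial_id else NA),
            class = "psi_result")
}

#' @export
print.psi_result <- function(x, ...) {
  cat(sprintf("PSI = %.4f, mean delay = %.3f rad (n = %d%s)\n", x$psi,
              x$mean_delay_rad, x$n_samples,
              if (!is.na(x$label)) paste0(", ", x$label) else ""))
  invisible(x)
}

#' Per-trial PSI over approach and touch windows
#'
#' For every trial, computes the PSI over a common-length window ending at
#' contact onset (approach) and one starting at contact onset (touch); the
#' length is `min(win_s, touch duration)` per trial.
#'
#' @param phase_theta,phase_whisk `phase_series` for the band-passed LFP and
#'   whisking signals.
#' @param events A [trial_events] table.
#' @param win_s Target window length in seconds (250 ms default).
#' @return Data frame with per-trial `psi_approach`, `psi_touch`,
#'   `delay_approach_rad`, `delay_touch_rad`, `win_s_used`.
#' @export
trial_psi_table <- function(phase_theta, phase_whisk, events, win_s = 0.25) {
  ev <- as.data.frame(events)
  res <- lapply(seq_len(nrow(ev)), function(i) {
    on <- ev$contact_onset_s[i]
    L <- min(win_s, ev$contact_offset_s[i] - on)
    app <- compute_psi(phase_theta, phase_whisk,
                       list(start_s = on - L, end_s = on))
    tch <- compute_psi(phase_theta, phase_whisk,
                       list(start_s = on, end_s = on + L))
    data.frame(trial_id = ev$trial_id[i], psi_approach = app$psi,
               psi_touch = tch$psi, delay_approach_rad = app$mean_delay_rad,
               delay_touch_rad = tch$mean_delay_rad, win_s_used = L)
  })
  do.call(rbind, res)
}

# full pairwise PSI matrix between trial phase windows (equal length L):
# M[i, j] = PSI(phi_x of trial i, phi_y of trial j); done with four real
# matrix products so BLAS carries the load
psi_pairwise_matrix <- function(phix, phiy) {
  L <- ncol(phix)
  cx <- cos(phix); sx <- sin(phix)
  cy <- cos(phiy); sy <- sin(phiy)
  C <- cx %*% t(cy) + sx %*% t(sy)
  S <- sx %*% t(cy) - cx %*% t(sy)
  sqrt(C^2 + S^2) / L
}

#' Bootstrap chance level for trial-mean PSI
#'
#' Builds the distribution of session-mean PSI expected for unsynchronized
#' signals by shuffling the trial pairing: each of `n_shuffles` sets pairs the
#' theta phase of trial i with the whisking phase of a different trial
#' (a random derangement), and the mean PSI of the set is recorded. The
#' chance level is the upper bound of the 95% interval of those set means —
#' by default the 97.5th percentile of the shuffle distribution; the
#' mean + 1.96 SD alternative is available via `method`.
#'
#' @param trial_pairs List with matrices `phi_x` and `phi_y` (trials x
#'   samples: one equal-length phase window per trial), e.g. from
#'   [collect_psi_windows()]; >= 10 trials required.
#' @param n_shuffles Number of shuffle sets.
#' @param method `"percentile"` or `"mean_sd"`.
#' @param seed Optional RNG seed.
#' @return Object of class `shuffle_null`: list with `shuffled_psi` (set
#'   means), `chance_level`, `observed_mean`, `exceeds` flag, `n_shuffles`,
#'   `n_trials`.
#' @export
psi_chance_level <- function(trial_pairs, n_shuffles = 2000,
                             method = c("percentile", "mean_sd"), seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  phix <- trial_pairs$phi_x; phiy <- trial_pairs$phi_y
  stopifnot(is.matrix(phix), is.matrix(phiy), all(dim(phix) == dim(phiy)))
  n <- nrow(phix)
  if (n < 10) stop("psi_chance_level: need >= 10 trials")
  M <- psi_pairwise_matrix(phix, phiy)
  observed <- mean(diag(M))
  rows <- seq_len(n)
  set_means <- vapply(seq_len(n_shuffles), function(s) {
    repeat {
      perm <- sample.int(n)
      if (!any(perm == rows)) break
    }
    mean(M[cbind(rows, perm)])
  }, numeric(1))
  chance <- if (method == "percentile") unname(stats::quantile(set_means, 0.975))
            else mean(set_means) + 1.96 * stats::sd(set_means)
  structure(list(shuffled_psi = set_means, chance_level = chance,
                 observed_mean = observed, exceeds = observed > chance,
                 n_shuffles = n_shuffles, n_trials = n, method = method),
            class = "shuffle_null")
}

#' @export
print.shuffle_null <- function(x, ...) {
  cat(sprintf("PSI chance level (%d shuffle sets, %d trials, %s): %.4f\n",
              x$n_shuffles, x$n_trials, x$method, x$chance_level))
  cat(sprintf("observed mean PSI = %.4f (%s chance level)\n", x$observed_mean,
              if (x$exceeds) "exceeds" else "within"))
  invisible(x)
}

#' Collect equal-length per-trial phase windows
#'
#' Extracts, per trial, the theta and whisking phase samples of one episode
#' window (approach or touch, relative to contact onset) as matrices suitable
#' for [psi_chance_level()]. Trials whose touch episode is shorter than the
#' full window are dropped (with a count in the result) so that all rows have
#' equal length.
#'
#' @param phase_theta,phase_whisk `phase_series` objects.
#' @param events A [trial_events] table.
#' @param episode `"touch"` or `"approach"`.
#' @param win_s Window length (s).
#' @return List with `phi_x`, `phi_y` (trials x samples), `trial_id`,
#'   `n_dropped`.
#' @export
collect_psi_windows <- function(phase_theta, phase_whisk, events,
                                episode = c("touch", "approach"), win_s = 0.25) {
  episode <- match.arg(episode)
  ev <- as.data.frame(events)
  full <- (ev$contact_offset_s - ev$contact_onset_s) >= win_s
  ev_use <- ev[full, ]
  fs <- phase_theta$sample_rate_hz
  L <- round(win_s * fs)
  get_rows <- function(on) {
    win <- if (episode == "touch") list(start_s = on, end_s = on + win_s)
           else list(start_s = on - win_s, end_s = on)
    i0 <- ceiling((win$start_s - phase_theta$start_time_s) * fs - 1e-9) + 1
    idx <- i0:(i0 + L - 1)
    tx <- phase_theta$start_time_s + (idx - 1) / fs
    list(x = phase_theta$phases[idx], y = phase_at_times(phase_whisk, tx))
  }
  rows <- lapply(ev_use$contact_onset_s, get_rows)
  list(phi_x = do.call(rbind, lapply(rows, `[[`, "x")),
       phi_y = do.call(rbind, lapply(rows, `[[`, "y")),
       trial_id = ev_use$trial_id, n_dropped = sum(!full))
}

#' Phase-delay statistics across trials
#'
#' Rayleigh test of the per-trial mean phase delays (theta minus whisking),
#' optionally restricted to trials whose PSI exceeds a significance level
#' (e.g., the bootstrap chance level).
#'
#' @param delays_rad Per-trial circular-mean phase delays.
#' @param psi Optional per-trial PSI values for filtering.
#' @param psi_threshold Keep trials with `psi > psi_threshold` (NULL = all).
#' @return List with `circular_mean_rad`, `rayleigh_p`, `rayleigh_Z`, `n`.
#' @export
phase_delay_stats <- function(delays_rad, psi = NULL, psi_threshold = NULL) {
  if (!is.null(psi_threshold)) {
    if (is.null(psi)) stop("phase_delay_stats: psi values needed for filtering")
    delays_rad <- delays_rad[psi > psi_threshold]
  }
  if (length(delays_rad) < 5)
    stop("phase_delay_stats: fewer than 5 trials after filtering")
  rt <- rayleigh_test(delays_rad)
  list(circular_mean_rad = rt$mean_phase, rayleigh_p = rt$p,
       rayleigh_Z = rt$Z, n = rt$n)
}

#' Trial-level PSI/behavior metrics
#'
#' Builds the per-trial metrics table: PSI change (touch minus approach),
#' normalized trial duration (per-rat maximum duration minus the trial's
#' touch duration, so speedier trials score higher), duration groups (fast /
#' intermediate / slow, cut at the per-rat mean +/- 0.4 SD of touch duration),
#' PSI-approach and PSI-touch groups (low / intermediate / high, cut at the
#' mean +/- 0.5 SD), and exclusion flags for outlier durations (shorter than
#' 0.15 s or longer than 2 s). Group statistics are computed on non-excluded
#' trials.
#'
#' @param trial_psi Data frame with `trial_id`, `psi_approach`, `psi_touch`
#'   (e.g. from [trial_psi_table()]).
#' @param touch_duration_s Per-trial touch durations.
#' @param correct Per-trial logical correct flags.
#' @param rat Per-trial rat/subject identifier (single rat by default).
#' @return Data frame of class `trial_metrics`.
#' @export
trial_metrics <- function(trial_psi, touch_duration_s, correct,
                          rat = rep(1L, nrow(trial_psi))) {
  n <- nrow(trial_psi)
  stopifnot(length(touch_duration_s) == n, length(correct) == n)
  excluded <- touch_duration_s < 0.15 | touch_duration_s > 2
  m <- data.frame(trial_id = trial_psi$trial_id, rat = rat,
                  psi_approach = trial_psi$psi_approach,
                  psi_touch = trial_psi$psi_touch,
                  psi_change = trial_psi$psi_touch - trial_psi$psi_approach,
                  touch_duration_s = touch_duration_s,
                  correct = as.logical(correct), excluded = excluded)
  m$normalized_duration <- NA_real_
  m$duration_group <- NA_character_
  for (r in unique(rat)) {
    i <- rat == r & !excluded
    if (!any(i)) stop("trial_metrics: no usable trials for rat ", r)
    dmax <- max(touch_duration_s[i])
    m$normalized_duration[rat == r] <- dmax - touch_duration_s[rat == r]
    mu <- mean(touch_duration_s[i]); sdev <- stats::sd(touch_duration_s[i])
    cuts <- c(mu - 0.4 * sdev, mu + 0.4 * sdev)
    g <- ifelse(touch_duration_s < cuts[1], "fast",
                ifelse(touch_duration_s > cuts[2], "slow", "intermediate"))
    m$duration_group[rat == r] <- g[rat == r]
  }
  grp3 <- function(v) {
    mu <- mean(v[!excluded]); sdev <- stats::sd(v[!excluded])
    ifelse(v < mu - 0.5 * sdev, "low",
           ifelse(v > mu + 0.5 * sdev, "high", "intermediate"))
  }
  m$psi_approach_group <- grp3(m$psi_approach)
  m$psi_touch_group <- grp3(m$psi_touch)
  m$duration_group[excluded] <- NA_character_
  class(m) <- c("trial_metrics", "data.frame")
  m
}

# two-sample randomization test on a difference of group means (add-one p)
randomization_diff_test <- function(values, in_group1, n_iter = 10000,
                                    alternative = c("two.sided", "greater"),
                                    seed = NULL) {
  alternative <- match.arg(alternative)
  if (!is.null(seed)) set.seed(seed)
  n <- length(values); n1 <- sum(in_group1)
  stopifnot(n1 >= 1, n1 < n)
  tot <- sum(values)
  obs <- mean(values[in_group1]) - mean(values[!in_group1])
  null_diff <- vapply(seq_len(n_iter), function(i) {
    s1 <- sum(values[sample.int(n, n1)])
    s1 / n1 - (tot - s1) / (n - n1)
  }, numeric(1))
  p <- if (alternative == "two.sided")
    (1 + sum(abs(null_diff) >= abs(obs))) / (n_iter + 1)
  else
    (1 + sum(null_diff >= obs)) / (n_iter + 1)
  list(observed_diff = obs, p_value = p, n_iter = n_iter,
       alternative = alternative)
}

#' PSI-versus-behavior statistics
#'
#' Computes the trial-level statistics relating phase synchronization to task
#' performance: (a) Pearson correlation between PSI change and normalized
#' trial duration — on correct trials (`overall`), on all non-excluded trials
#' (`all_trials`), and conditional on PSI-approach and PSI-touch groups
#' (correct trials); (b) Wilcoxon signed-rank tests on paired
#' (PSI-approach, PSI-touch) within each duration group; (c) a two-sample
#' randomization test (difference of group-mean PSI-touch, label shuffling)
#' between correct and incorrect trials; (d) one-tail t tests on PSI change
#' for correct versus incorrect trials and between duration groups.
#' Comparisons with fewer than `min_n` trials per group are skipped and
#' flagged.
#'
#' @param metrics A [trial_metrics()] table.
#' @param n_randomization Iterations for the randomization test.
#' @param min_n Minimum trials per group.
#' @param seed Optional RNG seed.
#' @return List of class `psi_behavior_report`.
#' @export
psi_behavior_tests <- function(metrics, n_randomization = 10000, min_n = 3,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- metrics[!metrics$excluded, ]
  if (nrow(m) < 10) stop("psi_behavior_tests: fewer than 10 usable trials")
  mc <- m[m$correct, ]
  skipped <- character(0)

  cor_block <- function(d, label) {
    if (nrow(d) < max(min_n, 3) ||
        stats::sd(d$psi_change) == 0 || stats::sd(d$normalized_duration) == 0) {
      skipped <<- c(skipped, label)
      return(NULL)
    }
    ct <- stats::cor.test(d$psi_change, d$normalized_duration)
    list(n = nrow(d), r = unname(ct$estimate), p = ct$p.value)
  }
  correlation <- list(overall = cor_block(mc, "correlation:overall"),
                      all_trials = cor_block(m, "correlation:all-trials"))
  for (g in c("low", "intermediate", "high")) {
    correlation[[paste0("psi_approach_", g)]] <-
      cor_block(mc[mc$psi_approach_group == g, ], paste0("correlation:approach-", g))
    correlation[[paste0("psi_touch_", g)]] <-
      cor_block(mc[mc$psi_touch_group == g, ], paste0("correlation:touch-", g))
  }

  wilcoxon <- list()
  for (g in c("fast", "intermediate", "slow")) {
    d <- mc[!is.na(mc$duration_group) & mc$duration_group == g, ]
    if (nrow(d) < min_n) {
      skipped <- c(skipped, paste0("wilcoxon:", g))
      wilcoxon[[g]] <- NULL
      next
    }
    if (all(d$psi_touch == d$psi_approach)) {
      wilcoxon[[g]] <- list(n = nrow(d), p = 1, note = "no nonzero differences")
    } else {
      wt <- suppressWarnings(stats::wilcox.test(d$psi_touch, d$psi_approach,
                                                paired = TRUE, exact = FALSE))
      wilcoxon[[g]] <- list(n = nrow(d), p = wt$p.value,
                            mean_change = mean(d$psi_change))
    }
  }

  randomization <- NULL
  if (sum(m$correct) >= min_n && sum(!m$correct) >= min_n) {
    randomization <- randomization_diff_test(m$psi_touch, m$correct,
                                             n_iter = n_randomization)
    randomization$mean_correct <- mean(m$psi_touch[m$correct])
    randomization$mean_incorrect <- mean(m$psi_touch[!m$correct])
  } else skipped <- c(skipped, "randomization:correct-vs-incorrect")

  ttests <- list()
  if (sum(m$correct) >= min_n && sum(!m$correct) >= min_n) {
    tt <- stats::t.test(m$psi_change[m$correct], m$psi_change[!m$correct],
                        alternative = "greater")
    ttests$correct_vs_incorrect <- list(
      t = unname(tt$statistic), p = tt$p.value,
      mean_correct = mean(m$psi_change[m$correct]),
      mean_incorrect = mean(m$psi_change[!m$correct]))
  } else skipped <- c(skipped, "ttest:correct-vs-incorrect")
  pairs <- list(c("fast", "intermediate"), c("intermediate", "slow"),
                c("fast", "slow"))
  for (pr in pairs) {
    a <- mc$psi_change[!is.na(mc$duration_group) & mc$duration_group == pr[1]]
    b <- mc$psi_change[!is.na(mc$duration_group) & mc$duration_group == pr[2]]
    key <- paste(pr, collapse = "_vs_")
    if (length(a) >= min_n && length(b) >= min_n) {
      tt <- stats::t.test(a, b, alternative = "greater")
      ttests[[key]] <- list(t = unname(tt$statistic), p = tt$p.value)
    } else skipped <- c(skipped, paste0("ttest:", key))
  }

  structure(list(correlation = correlation, wilcoxon = wilcoxon,
                 randomization = randomization, ttests = ttests,
                 n_trials = nrow(m), n_correct = sum(m$correct),
                 skipped = skipped),
            class = "psi_behavior_report")
}

#' @export
print.psi_behavior_report <- function(x, ...) {
  cat(sprintf("PSI/behavior report: %d trials (%d correct)\n",
              x$n_trials, x$n_correct))
  if (!is.null(x$correlation$overall))
    cat(sprintf("  PSI change vs normalized duration: r = %.3f, p = %.2g (n = %d)\n",
                x$correlation$overall$r, x$correlation$overall$p,
                x$correlation$overall$n))
  if (!is.null(x$randomization))
    cat(sprintf("  PSI-touch correct %.3f vs incorrect %.3f: randomization p = %.4f\n",
                x$randomization$mean_correct, x$randomization$mean_incorrect,
                x$randomization$p_value))
  for (g in names(x$wilcoxon))
    cat(sprintf("  %s trials: mean PSI change %.3f, Wilcoxon p = %.3g (n = %d)\n",
                g, x$wilcoxon[[g]]$mean_change %||% NA, x$wilcoxon[[g]]$p,
                x$wilcoxon[[g]]$n))
  if (length(x$skipped))
    cat("  skipped:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
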