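#' Segment trials into behavioral episode windows
#'
#' Derives the labeled analysis windows from the per-trial event table,
#' following the task's episode definitions: per trial,
#' baseline = \[onset - 3.0, onset - 2.5\] (the interval 2.5 to 3 s before
#' first contact), approach = \[onset - 0.5, onset), touch = \[onset, offset\],
#' turn = (offset, spout_arrival\], reward = \[spout_arrival,
#' spout_arrival + 0.5\]. Baseline, approach and reward have fixed length
#' (`analysis_len_s`, 500 ms by default, close to the 540 ms mean touch
#' duration); touch and turn take their measured lengths. Trials that start
#' too close to the session start for a baseline window lose only that window,
#' with a warning. The turn episode is segmented but excluded from spectral
#' and PSI analyses.
#'
#' @param events A [trial_events] table.
#' @param analysis_len_s Standard fixed window length in seconds.
#' @param session_start_s Earliest usable signal time (baseline windows
#'   reaching before it are omitted).
#' @return Data frame of class `episode_windows` with columns `label`,
#'   `start_s`, `end_s`, `trial_id`.
#' @export
segment_episodes <- function(events, analysis_len_s = 0.5, session_start_s = 0) {
  events <- trial_events(as.data.frame(events))
  o <- order(events$contact_onset_s)
  ev <- events[o, ]
  if (nrow(ev) > 1 && any(ev$contact_onset_s[-1] < ev$reward_end_s[-nrow(ev)]))
    stop("segment_episodes: overlapping trials")
  L <- analysis_len_s
  per_trial <- function(i) {
    on <- ev$contact_onset_s[i]; off <- ev$contact_offset_s[i]
    arr <- ev$spout_arrival_s[i]; id <- ev$trial_id[i]
    w <- data.frame(
      label = c("baseline", "approach", "touch", "turn", "reward"),
      start_s = c(on - 3.0, on - L, on, off, arr),
      end_s = c(on - 2.5, on, off, arr, arr + L),
      trial_id = id, stringsAsFactors = FALSE)
    if (on - 3.0 < session_start_s) {
      warning(sprintf("trial %s: too close to session start; baseline omitted", id))
      w <- w[w$label != "baseline", ]
    }
    w <- w[w$end_s > w$start_s, ]  # zero-length turn (offset == arrival) dropped
    w
  }
  out <- do.call(rbind, lapply(seq_len(nrow(ev)), per_trial))
  rownames(out) <- NULL
  class(out) <- c("episode_windows", "data.frame")
  out
}

#' Waiting-period windows tiled over inter-trial intervals
#'
#' The pre-trial waiting period (rat waiting for the bridge and texture to be
#' presented) has no instrumented boundaries, so windows are taken as
#' fixed-length segments tiled over the intervals between trials, keeping a
#' configurable guard distance away from the previous trial's reward end and
#' the next trial's baseline start.
#'
#' @param events A [trial_events] table.
#' @param len_s Window length (500 ms default, matching the task windows).
#' @param guard_s Minimum distance from flanking trial events.
#' @return Data frame with columns `label` (`"waiting"`), `start_s`, `end_s`,
#'   `trial_id` (the upcoming trial).
#' @export
waiting_windows <- function(events, len_s = 0.5, guard_s = 1) {
  ev <- as.data.frame(events)
  ev <- ev[order(ev$contact_onset_s), ]
  out <- list()
  for (i in 2:max(2, nrow(ev))) {
    if (i > nrow(ev)) break
    lo <- ev$reward_end_s[i - 1] + guard_s
    hi <- ev$contact_onset_s[i] - 3.0 - guard_s
    k <- floor((hi - lo) / len_s)
    if (k < 1) next
    starts <- lo + (seq_len(k) - 1) * len_s
    out[[length(out) + 1]] <- data.frame(
      label = "waiting", start_s = starts, end_s = starts + len_s,
      trial_id = ev$trial_id[i], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(label = character(0), start_s = numeric(0),
                      end_s = numeric(0), trial_id = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Shuffle test of behavioral performance
#'
#' Simulates chance-level percent correct by shuffling texture labels across
#' trials; each shuffle re-scores the session against the fixed
#' texture-to-side rule implied by the observed correct choices. The p-value
#' uses the add-one rule:
#' p = (1 + #\{shuffled >= observed\}) / (n_shuffles + 1).
#'
#' @param texture_ids Per-trial texture labels (>= 2 distinct values).
#' @param choices Per-trial chosen sides.
#' @param rule Named character vector mapping texture to the rewarded side. If
#'   NULL, the majority choice per texture among the trials is used.
#' @param n_shuffles Number of label shuffles.
#' @param seed Optional RNG seed.
#' @return List with `percent_correct`, `p_value` and the shuffle
#'   distribution `null_percent`.
#' @export
performance_randomization_test <- function(texture_ids, choices, rule = NULL,
                                           n_shuffles = 500, seed = NULL) {
  if (length(texture_ids) != length(choices))
    stop("performance_randomization_test: label/choice lengths differ")
  if (length(unique(texture_ids)) < 2)
    stop("performance_randomization_test: need >= 2 distinct textures")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rule)) {
    rule <- vapply(split(as.character(choices), as.character(texture_ids)),
                   function(ch) names(sort(table(ch), decreasing = TRUE))[1],
                   character(1))
  }
  score <- function(tex) mean(rule[as.character(tex)] == as.character(choices))
  observed <- score(texture_ids)
  null_pc <- replicate(n_shuffles, score(sample(texture_ids)))
  p <- (1 + sum(null_pc >= observed)) / (n_shuffles + 1)
  list(percent_correct = 100 * observed, p_value = p,
       null_percent = 100 * null_pc)
}
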