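#' Uniformly sampled continuous signal
#'
#' Container for a uniformly sampled real-valued trace: a hippocampal LFP
#' channel (microvolts) or a whisker mean-angle trace (degrees).
#'
#' @param samples Numeric vector of samples; all values must be finite.
#' @param sample_rate_hz Sampling rate in samples/s (> 0).
#' @param start_time_s Session-relative time of the first sample, in seconds.
#' @param label Signal label, `"lfp"` or `"whisking"`.
#' @param units Physical units, `"uV"` or `"degrees"`.
#'
#' @return An object of class `continuous_signal`.
#' @export
continuous_signal <- function(samples, sample_rate_hz, start_time_s = 0,
                              label = c("lfp", "whisking"),
                              units = c("uV", "degrees")) {
  label <- match.arg(label)
  units <- match.arg(units)
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("signal must contain at least one sample")
  if (!all(is.finite(samples))) stop("signal samples must all be finite")
  sample_rate_hz <- as.numeric(sample_rate_hz)
  start_time_s <- as.numeric(start_time_s)
  if (!is.finite(sample_rate_hz) || sample_rate_hz <= 0)
    stop("sample_rate_hz must be a positive finite number")
  structure(
    list(samples = samples, sample_rate_hz = sample_rate_hz,
         start_time_s = start_time_s, label = label, units = units),
    class = "continuous_signal"
  )
}

#' @export
print.continuous_signal <- function(x, ...) {
  cat(sprintf("<continuous_signal '%s'> %d samples @ %g Hz, t = [%.3f, %.3f] s (%s)\n",
              x$label, length(x$samples), x$sample_rate_hz, x$start_time_s,
              signal_end_time(x), x$units))
  invisible(x)
}

#' @export
length.continuous_signal <- function(x) length(x$samples)

signal_end_time <- function(signal) {
  signal$start_time_s + length(signal$samples) / signal$sample_rate_hz
}

signal_times <- function(signal) {
  signal$start_time_s + (seq_along(signal$samples) - 1) / signal$sample_rate_hz
}

#' Spike train of one unit
#'
#' @param spike_times_s Numeric vector of spike times in seconds, sorted
#'   ascending (non-decreasing).
#' @param unit_id Identifier of the unit.
#' @param session_id Optional session identifier.
#'
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(spike_times_s, unit_id = "unit1", session_id = NA_character_) {
  spike_times_s <- as.numeric(spike_times_s)
  if (is.unsorted(spike_times_s)) stop("spike times must be sorted ascending")
  if (anyNA(spike_times_s) || (length(spike_times_s) && !all(is.finite(spike_times_s))))
    stop("spike times must be finite")
  structure(list(spike_times_s = spike_times_s, unit_id = as.character(unit_id),
                 session_id = session_id),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train '%s'> %d spikes", x$unit_id, length(x$spike_times_s)))
  if (length(x$spike_times_s))
    cat(sprintf(" in [%.3f, %.3f] s", min(x$spike_times_s), max(x$spike_times_s)))
  cat("\n")
  invisible(x)
}

#' Per-trial behavioral event table
#'
#' Validates a per-trial event table: first-contact onset, final-contact
#' offset, arrival at the reward spout, end of reward consumption, the texture
#' presented, the side chosen and whether the choice was correct.
#'
#' @param df A data.frame with columns `trial_id`, `contact_onset_s`,
#'   `contact_offset_s`, `spout_arrival_s`, `reward_end_s`, `texture_id`,
#'   `choice_side`, `correct`.
#'
#' @return The validated data.frame with class `trial_events`.
#' @export
trial_events <- function(df) {
  required <- c("trial_id", "contact_onset_s", "contact_offset_s",
                "spout_arrival_s", "reward_end_s", "texture_id",
                "choice_side", "correct")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("trial_events: missing required column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$trial_id)) stop("trial_events: trial_id values must be unique")
  bad <- !(df$contact_onset_s < df$contact_offset_s &
             df$contact_offset_s <= df$spout_arrival_s &
             df$spout_arrival_s <= df$reward_end_s)
  if (any(bad))
    stop(sprintf("trial_events: event ordering violated (need onset < offset <= spout_arrival <= reward_end) in trial(s) %s",
                 paste(utils::head(df$trial_id[bad], 5), collapse = ", ")))
  df$correct <- as.logical(df$correct)
  class(df) <- c("trial_events", "data.frame")
  df
}

#' Extract the samples of a signal inside an episode window
#'
#' Returns samples at the signal's native rate with the window start inclusive
#' and end exclusive, so a window of duration `d` yields `round(d * rate)`
#' samples.
#'
#' @param signal A [continuous_signal].
#' @param window An episode window (see [segment_episodes()]), or any list with
#'   `start_s` and `end_s` fields.
#'
#' @return Numeric vector of samples.
#' @export
extract_window <- function(signal, window) {
  stopifnot(inherits(signal, "continuous_signal"))
  fs <- signal$sample_rate_hz
  i0 <- round((window$start_s - signal$start_time_s) * fs) + 1
  n <- round((window$end_s - window$start_s) * fs)
  if (n < 1) stop("extract_window: window shorter than one sample")
  if (i0 < 1 || (i0 + n - 1) > length(signal$samples))
    stop(sprintf("extract_window: window [%.3f, %.3f] outside signal extent [%.3f, %.3f]",
                 window$start_s, window$end_s, signal$start_time_s, signal_end_time(signal)))
  signal$samples[i0:(i0 + n - 1)]
}
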