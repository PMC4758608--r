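## Plain-text session container: one directory per session holding
##   lfp.csv       sample column + header comment-free metadata in meta.json
##   whisking.csv  same layout
##   spikes_<unit>.csv  one column of spike times (one file per unit)
##   events.csv    the trial-events table
##   meta.json     sample rates, start times, labels, units
## Numbers are written with full double precision (17 significant digits) so a
## write/read round trip reproduces every array exactly.

fmt_full <- function(x) sprintf("%.17g", x)

#' Write a session bundle to a directory of CSV/JSON files
#'
#' @param bundle A `tw_session` (see [gen_session()]) or any list with `lfp`,
#'   `whisking`, `spikes`, `events` components.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(bundle, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    lfp = bundle$lfp[c("sample_rate_hz", "start_time_s", "label", "units")],
    whisking = bundle$whisking[c("sample_rate_hz", "start_time_s", "label", "units")],
    units = vapply(bundle$spikes, function(s) s$unit_id, character(1))
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c("sample", fmt_full(bundle$lfp$samples)),
             file.path(path, "lfp.csv"))
  writeLines(c("sample", fmt_full(bundle$whisking$samples)),
             file.path(path, "whisking.csv"))
  for (s in bundle$spikes) {
    writeLines(c("spike_time_s", fmt_full(s$spike_times_s)),
               file.path(path, sprintf("spikes_%s.csv", s$unit_id)))
  }
  ev <- as.data.frame(bundle$events)
  for (col in c("contact_onset_s", "contact_offset_s", "spout_arrival_s", "reward_end_s"))
    ev[[col]] <- fmt_full(ev[[col]])
  utils::write.csv(ev, file.path(path, "events.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a session bundle from a directory of CSV/JSON files
#'
#' Validates the layout written by [write_session()]: missing components and
#' invariant violations (non-monotone spike times, bad event ordering) are
#' reported as errors naming the offending field. A session with no
#' `spikes_*.csv` files is valid and yields an empty unit list.
#'
#' @param path Session directory.
#' @return A `tw_session` (without a `truth` record).
#' @export
read_session <- function(path) {
  need <- c("meta.json", "lfp.csv", "whisking.csv", "events.csv")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop("read_session: missing required file(s): ", paste(missing, collapse = ", "))
  meta <- jsonlite::fromJSON(file.path(path, "meta.json"))
  read_sig <- function(file, m, label, units) {
    lines <- readLines(file.path(path, file))
    if (lines[1] != "sample")
      stop(sprintf("read_session: %s: expected header 'sample'", file))
    continuous_signal(as.numeric(lines[-1]), m$sample_rate_hz, m$start_time_s,
                      label, units)
  }
  lfp <- read_sig("lfp.csv", meta$lfp, "lfp", "uV")
  whisking <- read_sig("whisking.csv", meta$whisking, "whisking", "degrees")
  unit_ids <- as.character(unlist(meta$units))
  spikes <- lapply(unit_ids, function(u) {
    f <- file.path(path, sprintf("spikes_%s.csv", u))
    if (!file.exists(f))
      stop("read_session: missing spike file for unit ", u)
    times <- as.numeric(readLines(f)[-1])
    if (is.unsorted(times))
      stop("read_session: spikes_", u, ": spike times not sorted ascending")
    spike_train(times, u)
  })
  ev <- utils::read.csv(file.path(path, "events.csv"), stringsAsFactors = FALSE)
  events <- trial_events(ev)
  structure(list(lfp = lfp, whisking = whisking, spikes = spikes,
                 events = events, truth = NULL),
            class = "tw_session")
}
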