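#' Write a recording to a directory
#'
#' The on-disk dialect is one CSV per channel (`<name>.csv` with header
#' `time_s,value`) plus a `session.json` sidecar holding the participant
#' id, per-channel unit and sampling rate, the baseline interval, the
#' stimulus events and the self-reports. Everything is plain UTF-8 text,
#' so recordings diff cleanly and read from any language.
#'
#' @param rec A [recording()].
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, path) {
  if (!inherits(rec, "physio_recording")) abort("`rec` must be a recording")
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok || !dir.exists(path)) stopf("cannot create directory '%s'", path)
  for (ch in rec$channels) {
    f <- file.path(path, paste0(ch$name, ".csv"))
    readr::write_csv(tibble(time_s = channel_times(ch), value = ch$samples), f)
  }
  meta <- list(
    participant_id = rec$participant_id,
    channels = lapply(rec$channels, function(ch)
      list(name = ch$name, unit = ch$unit, rate_hz = ch$rate_hz,
           t0_s = ch$t0_s)),
    baseline_interval = rec$baseline_interval,
    events = rec$events,
    self_reports = rec$self_reports
  )
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' Channel sampling rates and units are taken from `session.json`, never
#' inferred from the CSV time columns; the time column is still checked
#' for monotonicity.
#'
#' @param path Directory produced by [write_recording()].
#' @return A [recording()].
#' @export
read_recording <- function(path) {
  sess_path <- file.path(path, "session.json")
  if (!file.exists(sess_path))
    stopf("no session.json under '%s'", path)
  meta <- jsonlite::read_json(sess_path, simplifyVector = TRUE)
  chans <- list()
  specs <- meta$channels
  # channels may arrive as a named list of lists or a data frame
  if (is.data.frame(specs)) specs <- split(specs, seq_len(nrow(specs)))
  for (spec in specs) {
    spec <- as.list(spec)
    f <- file.path(path, paste0(spec$name, ".csv"))
    if (!file.exists(f))
      stopf("missing channel file for channel '%s' ('%s')", spec$name, f)
    df <- readr::read_csv(f, col_types = readr::cols(
      time_s = readr::col_double(), value = readr::col_double()))
    if (nrow(df) > 1 && any(diff(df$time_s) <= 0))
      stopf("non-monotone time column in channel '%s'", spec$name)
    chans[[spec$name]] <- channel_signal(spec$name, spec$unit, spec$rate_hz,
                                         df$value, spec$t0_s %||% 0)
  }
  ev <- if (is.null(meta$events) || length(meta$events) == 0) empty_events()
        else as_tibble(meta$events)
  sr <- if (is.null(meta$self_reports) || length(meta$self_reports) == 0)
          empty_reports() else as_tibble(meta$self_reports)
  recording(meta$participant_id, chans,
            baseline_interval = unlist(meta$baseline_interval),
            events = ev, self_reports = sr)
}
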