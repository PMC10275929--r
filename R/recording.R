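#' Construct a single physiological channel
#'
#' A channel is an evenly sampled real-valued signal with a physical unit
#' and a start time expressed in seconds from session start.
#'
#' @param name Channel identifier, one of `"gsr"`, `"ecg"`, `"resp_rate"`
#'   (other names are allowed for derived streams).
#' @param unit Physical unit string (e.g. `"uS"`, `"mV"`, `"breaths/min"`).
#' @param rate_hz Sampling frequency in Hz (> 0).
#' @param samples Numeric vector of samples; must be finite.
#' @param t0_s Time of the first sample in seconds from session start.
#' @return An object of class `physio_channel`.
#' @export
channel_signal <- function(name, unit, rate_hz, samples, t0_s = 0) {
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    abort("`rate_hz` must be a single positive number.")
  samples <- as.numeric(samples)
  if (length(samples) && !all(is.finite(samples)))
    stopf("channel '%s' contains non-finite samples", name)
  structure(
    list(name = name, unit = unit, rate_hz = rate_hz,
         samples = samples, t0_s = as.numeric(t0_s)),
    class = "physio_channel"
  )
}

#' @export
print.physio_channel <- function(x, ...) {
  cat(sprintf("<physio_channel> %s [%s] %.6g Hz, %d samples, %.2f-%.2f s\n",
              x$name, x$unit, x$rate_hz, length(x$samples),
              x$t0_s, channel_end(x)))
  invisible(x)
}

channel_times <- function(ch) ch$t0_s + (seq_along(ch$samples) - 1) / ch$rate_hz

channel_end <- function(ch) ch$t0_s + length(ch$samples) / ch$rate_hz

#' Construct a multichannel physiological recording
#'
#' Bundles a participant's synchronously recorded channels (skin
#' conductance, electrocardiogram, respiration rate) with the stimulus
#' schedule, the rest-baseline interval and the self-reported affect
#' ratings.
#'
#' @param participant_id Participant identifier string.
#' @param channels Named list of [channel_signal()] objects; must cover
#'   `gsr`, `ecg` and `resp_rate`.
#' @param baseline_interval Numeric `c(start_s, end_s)` of the rest period.
#' @param events Tibble of stimulus events with columns `image_id`,
#'   `iaps_valence_raw`, `iaps_arousal_raw` (both on the 1-9 rating scale),
#'   `onset_s`, `duration_s`, `cluster_quadrant`.
#' @param self_reports Tibble with columns `image_id`, `sam_valence`,
#'   `sam_arousal` (integers 1-9) and `response_time_s`.
#' @return An object of class `physio_recording`.
#' @export
recording <- function(participant_id, channels, baseline_interval = NULL,
                      events = empty_events(), self_reports = empty_reports()) {
  rec <- structure(
    list(participant_id = participant_id,
         channels = channels,
         baseline_interval = if (is.null(baseline_interval)) NULL
                             else as.numeric(baseline_interval),
         events = as_tibble(events),
         self_reports = as_tibble(self_reports)),
    class = "physio_recording"
  )
  validate_recording(rec)
}

empty_events <- function() {
  tibble(image_id = character(), iaps_valence_raw = numeric(),
         iaps_arousal_raw = numeric(), onset_s = numeric(),
         duration_s = numeric(), cluster_quadrant = character())
}

empty_reports <- function() {
  tibble(image_id = character(), sam_valence = integer(),
         sam_arousal = integer(), response_time_s = numeric())
}

validate_recording <- function(rec) {
  if (!all(c("gsr", "ecg", "resp_rate") %in% names(rec$channels)))
    abort("recording must contain 'gsr', 'ecg' and 'resp_rate' channels")
  for (ch in rec$channels) {
    if (!inherits(ch, "physio_channel"))
      abort("all channels must be physio_channel objects")
  }
  ev <- rec$events
  if (nrow(ev)) {
    bad_v <- ev$iaps_valence_raw < 1 | ev$iaps_valence_raw > 9
    bad_a <- ev$iaps_arousal_raw < 1 | ev$iaps_arousal_raw > 9
    if (any(bad_v | bad_a))
      stopf("IAPS ratings outside [1, 9] for image(s): %s",
            paste(ev$image_id[bad_v | bad_a], collapse = ", "))
    ev <- ev[order(ev$onset_s), ]
    if (nrow(ev) > 1 &&
        any(ev$onset_s[-1] < (ev$onset_s + ev$duration_s)[-nrow(ev)] - 1e-9))
      abort("stimulus events overlap")
    if (any(ev$duration_s <= 0)) abort("event durations must be positive")
  }
  sr <- rec$self_reports
  if (nrow(sr)) {
    if (any(sr$sam_valence < 1 | sr$sam_valence > 9 |
            sr$sam_arousal < 1 | sr$sam_arousal > 9))
      abort("SAM ratings outside [1, 9]")
    orphan <- setdiff(sr$image_id, ev$image_id)
    if (length(orphan))
      stopf("self-report(s) without a matching event: %s",
            paste(orphan, collapse = ", "))
  }
  if (!is.null(rec$baseline_interval)) {
    bi <- rec$baseline_interval
    if (length(bi) != 2L || bi[1] >= bi[2])
      abort("baseline_interval must be c(start_s, end_s) with start < end")
    if (nrow(ev) && bi[2] > min(ev$onset_s) + 1e-9)
      abort("baseline_interval must precede the first stimulus onset")
  }
  rec
}

#' @export
print.physio_recording <- function(x, ...) {
  cat(sprintf("<physio_recording> participant %s\n", x$participant_id))
  for (ch in x$channels)
    cat(sprintf("  %-10s %8.6g Hz  %8d samples  [%s]\n",
                ch$name, ch$rate_hz, length(ch$samples), ch$unit))
  if (!is.null(x$baseline_interval))
    cat(sprintf("  baseline   %.1f-%.1f s\n",
                x$baseline_interval[1], x$baseline_interval[2]))
  cat(sprintf("  %d stimulus events, %d self-reports\n",
              nrow(x$events), nrow(x$self_reports)))
  invisible(x)
}

recording_span <- function(rec) {
  starts <- vapply(rec$channels, function(ch) ch$t0_s, numeric(1))
  ends <- vapply(rec$channels, channel_end, numeric(1))
  c(max(starts), min(ends))
}

#' Crop a recording to a time interval
#'
#' All channels are cropped to the half-open interval `[start_s, end_s)`
#' and times are rebased so the slice starts at 0. Events falling outside
#' the interval are dropped (their self-reports with them); the baseline
#' interval is intersected with the slice.
#'
#' @param rec A [recording()].
#' @param start_s,end_s Interval bounds in seconds, `start_s < end_s`.
#' @return A `physio_recording` covering the requested interval.
#' @export
slice_segment <- function(rec, start_s, end_s) {
  if (!inherits(rec, "physio_recording")) abort("`rec` must be a recording")
  if (start_s >= end_s) abort("`start_s` must be smaller than `end_s`")
  chans <- lapply(rec$channels, function(ch) {
    t <- channel_times(ch)
    keep <- t >= start_s - 1e-9 & t < end_s - 1e-9
    idx <- which(keep)
    samples <- ch$samples[idx]
    t0 <- if (length(idx)) t[idx[1]] - start_s else 0
    channel_signal(ch$name, ch$unit, ch$rate_hz, samples, t0)
  })
  ev <- rec$events
  if (nrow(ev)) {
    keep <- ev$onset_s >= start_s - 1e-9 &
      (ev$onset_s + ev$duration_s) <= end_s + 1e-9
    ev <- ev[keep, ]
    ev$onset_s <- ev$onset_s - start_s
  }
  sr <- rec$self_reports
  if (nrow(sr)) sr <- sr[sr$image_id %in% ev$image_id, ]
  bi <- rec$baseline_interval
  if (!is.null(bi)) {
    bi <- c(max(bi[1], start_s), min(bi[2], end_s)) - start_s
    if (bi[1] >= bi[2]) bi <- NULL
  }
  structure(
    list(participant_id = rec$participant_id, channels = chans,
         baseline_interval = bi, events = ev, self_reports = sr),
    class = "physio_recording"
  )
}
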