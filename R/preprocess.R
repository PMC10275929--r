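#' Zero-phase Butterworth filtering
#'
#' Designs an order-`order` Butterworth filter and applies it forward and
#' backward ([signal::filtfilt()]), so the output has no phase lag and the
#' effective attenuation at the cutoff is two passes of -3 dB (amplitude
#' ratio 0.5).
#'
#' @param x Numeric signal.
#' @param rate_hz Sampling frequency in Hz.
#' @param cutoff_hz Cutoff frequency in Hz; must lie in `(0, rate_hz/2)`.
#' @param mode `"lowpass"` or `"highpass"`.
#' @param order Filter order (default 4).
#' @return Filtered signal, same length as `x`.
#' @examples
#' t <- seq(0, 10, by = 1 / 100)
#' y <- butterworth_filter(sin(2 * pi * 2 * t), 100, 5, "lowpass")
#' @export
butterworth_filter <- function(x, rate_hz, cutoff_hz,
                               mode = c("lowpass", "highpass"), order = 4) {
  mode <- match.arg(mode)
  if (cutoff_hz <= 0 || cutoff_hz >= rate_hz / 2)
    stopf("cutoff (%g Hz) must lie strictly between 0 and Nyquist (%g Hz)",
          cutoff_hz, rate_hz / 2)
  if (length(x) < 3 * order)
    stopf("signal too short for order-%d filtering (need >= %d samples)",
          order, 3 * order)
  bt <- signal::butter(order, cutoff_hz / (rate_hz / 2),
                       type = if (mode == "lowpass") "low" else "high")
  # transient length scales with 1/cutoff, so pad accordingly
  pad <- ceiling(3 * rate_hz / cutoff_hz)
  padded_filtfilt(bt, x, pad)
}

# forward-backward filtering with odd-reflection end padding, so the
# filter state is consistent with the signal level and slope at both ends
# (signal::filtfilt starts from zero state, which leaves long transients
# at low cutoffs)
padded_filtfilt <- function(filt, x, pad) {
  n <- length(x)
  pad <- max(1L, min(n - 1L, as.integer(pad)))
  head_pad <- 2 * x[1] - x[(pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
  ext <- c(head_pad, x, tail_pad)
  dc <- sum(filt$b) / sum(filt$a)
  # run each pass relative to its first sample so the zero initial state
  # matches a constant input exactly (the DC transient vanishes)
  one_pass <- function(z) {
    as.numeric(signal::filter(filt, z - z[1])) + z[1] * dc
  }
  y <- one_pass(ext)
  y <- rev(one_pass(rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Decompose a skin-conductance signal into tonic and phasic components
#'
#' The raw conductance is denoised with a 5 Hz zero-phase low-pass
#' Butterworth filter, then split with a complementary pair at 0.1 Hz:
#' the slow skin conductance level (SCL) is the 0.1 Hz low-pass of the
#' denoised signal, and the fast skin conductance response (SCR) is its
#' 0.1 Hz high-pass. The two components reconstruct the denoised signal
#' up to the leakage of the complementary pair.
#'
#' @param gsr A [channel_signal()] in microsiemens, or a numeric vector
#'   (then `rate_hz` must be given).
#' @param rate_hz Sampling rate when `gsr` is a bare vector.
#' @param denoise_hz,split_hz Low-pass denoise cutoff and tonic/phasic
#'   split cutoff, in Hz.
#' @param order Butterworth order used for all three filters.
#' @return An object of class `gsr_decomposition`: list with `scl`, `scr`
#'   (numeric, equal length), `rate_hz` and `t0_s`.
#' @export
decompose_gsr <- function(gsr, rate_hz = NULL, denoise_hz = 5,
                          split_hz = 0.1, order = 4) {
  if (inherits(gsr, "physio_channel")) {
    x <- gsr$samples
    rate_hz <- gsr$rate_hz
    t0 <- gsr$t0_s
  } else {
    if (is.null(rate_hz)) abort("`rate_hz` required for a bare numeric signal")
    x <- as.numeric(gsr)
    t0 <- 0
  }
  den <- butterworth_filter(x, rate_hz, denoise_hz, "lowpass", order)
  scl <- butterworth_filter(den, rate_hz, split_hz, "lowpass", order)
  scr <- butterworth_filter(den, rate_hz, split_hz, "highpass", order)
  structure(list(scl = scl, scr = scr, denoised = den,
                 rate_hz = rate_hz, t0_s = t0),
            class = "gsr_decomposition")
}

#' @export
print.gsr_decomposition <- function(x, ...) {
  cat(sprintf("<gsr_decomposition> %d samples at %.6g Hz (SCL + SCR)\n",
              length(x$scl), x$rate_hz))
  invisible(x)
}

sync_grid <- function(start_s, end_s, rate_hz) {
  n <- floor((end_s - start_s) * rate_hz + 1e-9)
  start_s + (seq_len(n) - 1) / rate_hz
}

#' Resample all channels of a recording onto a shared grid
#'
#' Channels are linearly interpolated onto a common `rate_hz` grid over
#' the intersection of their time spans. Linear interpolation is exact for
#' affine signals and appropriate for the slowly varying level-type
#' streams resampled here; beat detection on the electrocardiogram is run
#' at the native rate *before* synchronization (see
#' [preprocess_recording()]).
#'
#' @param rec A [recording()].
#' @param rate_hz Target shared rate (default 36.5 Hz).
#' @return A `physio_recording` whose channels share one grid.
#' @export
synchronize <- function(rec, rate_hz = 36.5) {
  if (!inherits(rec, "physio_recording")) abort("`rec` must be a recording")
  span <- recording_span(rec)
  if (span[1] >= span[2]) abort("channels have no common time span")
  grid <- sync_grid(span[1], span[2], rate_hz)
  chans <- lapply(rec$channels, function(ch) {
    y <- approx(channel_times(ch), ch$samples, xout = grid, rule = 2)$y
    channel_signal(ch$name, ch$unit, rate_hz, y, grid[1])
  })
  out <- rec
  out$channels <- chans
  out
}

#' Preprocess a recording into synchronized analysis streams
#'
#' Runs the full preprocessing chain: tonic/phasic decomposition of the
#' skin conductance at its native rate, R-peak detection on the native
#' 250 Hz electrocardiogram followed by inter-beat-interval validation and
#' instantaneous heart-rate computation, then linear resampling of the
#' SCL/SCR/respiration streams and piecewise-constant resampling of the
#' heart rate onto a shared grid (36.5 Hz by default), and finally
#' baseline normalization (subtraction of each level stream's mean over
#' the rest interval from SCL, heart rate and respiration rate; the
#' phasic SCR is zero-mean by construction and is left untouched).
#'
#' @param rec A [recording()] with `gsr`, `ecg`, `resp_rate` channels.
#' @param sync_rate_hz Shared grid rate in Hz.
#' @param normalize Apply baseline normalization (default `TRUE`). Set to
#'   `FALSE` explicitly to skip it when no baseline interval exists.
#' @return An object of class `affect_streams`: the grid-aligned streams
#'   tibble (`time_s`, `scl`, `scr`, `hr`, `rr`), the validated
#'   inter-beat-interval series, and the event/self-report metadata.
#' @export
preprocess_recording <- function(rec, sync_rate_hz = 36.5, normalize = TRUE) {
  if (!inherits(rec, "physio_recording")) abort("`rec` must be a recording")
  dec <- decompose_gsr(rec$channels$gsr)
  beats <- detect_r_peaks(rec$channels$ecg)
  ibi <- ibi_series(beats)
  hr <- instantaneous_hr(ibi)

  span <- recording_span(rec)
  grid <- sync_grid(span[1], span[2], sync_rate_hz)
  gsr_t <- channel_times(rec$channels$gsr)
  rr_ch <- rec$channels$resp_rate
  streams <- tibble(
    time_s = grid,
    scl = approx(gsr_t, dec$scl, xout = grid, rule = 2)$y,
    scr = approx(gsr_t, dec$scr, xout = grid, rule = 2)$y,
    hr = if (nrow(hr) >= 2)
           approx(hr$time_s, hr$hr_bpm, xout = grid,
                  method = "constant", rule = 2)$y
         else if (nrow(hr) == 1) rep(hr$hr_bpm, length(grid))
         else rep(NA_real_, length(grid)),
    rr = approx(channel_times(rr_ch), rr_ch$samples, xout = grid, rule = 2)$y
  )
  out <- structure(
    list(participant_id = rec$participant_id,
         streams = streams, rate_hz = sync_rate_hz, ibi = ibi,
         baseline_interval = rec$baseline_interval,
         events = rec$events, self_reports = rec$self_reports,
         normalized = FALSE),
    class = "affect_streams"
  )
  if (normalize) out <- baseline_normalize(out)
  out
}

#' @export
print.affect_streams <- function(x, ...) {
  cat(sprintf(
    "<affect_streams> participant %s: %d grid samples at %.6g Hz, %d beats%s\n",
    x$participant_id, nrow(x$streams), x$rate_hz,
    length(x$ibi$beat_times_s),
    if (x$normalized) ", baseline-normalized" else ""))
  invisible(x)
}

#' Subtract the rest-baseline mean from the level-type streams
#'
#' Inter-subject offsets live in level signals; the scalar mean of each of
#' the SCL, heart-rate and respiration-rate streams over the baseline
#' interval is subtracted from that stream. The phasic SCR stream and the
#' event/report metadata are unchanged.
#'
#' @param x An `affect_streams` object from [preprocess_recording()].
#' @return The normalized `affect_streams` object.
#' @export
baseline_normalize <- function(x) {
  if (!inherits(x, "affect_streams"))
    abort("`x` must be an affect_streams object (see preprocess_recording)")
  bi <- x$baseline_interval
  if (is.null(bi))
    abort(paste("no baseline interval in this recording; pass",
                "`normalize = FALSE` to preprocess_recording() to skip",
                "normalization explicitly"))
  if (bi[2] - bi[1] < 30)
    stopf("baseline interval is %.1f s; need >= 30 s for a stable mean",
          bi[2] - bi[1])
  inb <- x$streams$time_s >= bi[1] & x$streams$time_s < bi[2]
  if (!any(inb)) abort("baseline interval contains no grid samples")
  for (col in c("scl", "hr", "rr")) {
    x$streams[[col]] <- x$streams[[col]] - mean(x$streams[[col]][inb])
  }
  x$normalized <- TRUE
  x
}
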