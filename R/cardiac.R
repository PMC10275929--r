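#' Detect R peaks in an electrocardiogram
#'
#' Energy-based detector: the ECG is band-passed to 5-15 Hz where the QRS
#' complex concentrates its power, squared, and smoothed with a 150 ms
#' moving average; local maxima of the smoothed energy above an adaptive
#' threshold are candidate beats, a 250 ms refractory period suppresses
#' double detections, and each candidate is refined to the local maximum
#' of the raw ECG within +/- 75 ms.
#'
#' @param ecg A [channel_signal()] at >= 100 Hz, or numeric vector with
#'   `rate_hz` supplied.
#' @param rate_hz Sampling rate when `ecg` is a bare vector.
#' @param refractory_s Minimum spacing between accepted beats (s).
#' @return Numeric vector of beat times in seconds (session clock).
#' @export
detect_r_peaks <- function(ecg, rate_hz = NULL, refractory_s = 0.25) {
  if (inherits(ecg, "physio_channel")) {
    x <- ecg$samples; rate_hz <- ecg$rate_hz; t0 <- ecg$t0_s
  } else {
    if (is.null(rate_hz)) abort("`rate_hz` required for a bare numeric signal")
    x <- as.numeric(ecg); t0 <- 0
  }
  if (rate_hz < 100) stopf("ECG rate %.6g Hz too low; need >= 100 Hz", rate_hz)
  if (length(x) < 2 * rate_hz) abort("ECG shorter than 2 s")

  bp <- signal::butter(3, c(5, 15) / (rate_hz / 2), type = "pass")
  e <- padded_filtfilt(bp, x, pad = round(rate_hz))^2
  w <- max(3L, round(0.15 * rate_hz))
  e <- as.numeric(stats::filter(e, rep(1 / w, w), sides = 2))
  e[is.na(e)] <- 0

  thr <- 0.2 * quantile(e, 0.99, names = FALSE)
  if (!is.finite(thr) || thr <= 1e-12) return(numeric(0))
  n <- length(e)
  loc <- which(e[2:(n - 1)] > e[1:(n - 2)] & e[2:(n - 1)] >= e[3:n] &
                 e[2:(n - 1)] > thr) + 1L
  if (!length(loc)) return(numeric(0))

  # refractory pass on the energy peaks: within the dead time keep the larger
  ref_n <- refractory_s * rate_hz
  kept <- loc[1]
  for (i in loc[-1]) {
    last <- kept[length(kept)]
    if (i - last >= ref_n) kept <- c(kept, i)
    else if (e[i] > e[last]) kept[length(kept)] <- i
  }

  # refine each beat to the raw-ECG maximum in a +/- 75 ms neighbourhood
  half <- round(0.075 * rate_hz)
  half <- as.integer(half)
  refined <- vapply(as.integer(kept), function(i) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  if (length(refined) > 1) {
    ok <- c(TRUE, diff(refined) >= ref_n)
    refined <- refined[ok]
  }
  t0 + (refined - 1) / rate_hz
}

#' Build a validated inter-beat-interval series
#'
#' Successive differences of the beat times in milliseconds;
#' physiologically implausible intervals (outside `(min_ms, max_ms)`,
#' default 200-3000 ms) are discarded before any variability statistic is
#' computed.
#'
#' @param beat_times_s Strictly increasing beat instants in seconds.
#' @param min_ms,max_ms Open validity bounds in milliseconds.
#' @return Object of class `ibi_series`: `beat_times_s`, `intervals_ms`
#'   and `interval_times_s` (the second beat of each kept interval).
#' @export
ibi_series <- function(beat_times_s, min_ms = 200, max_ms = 3000) {
  beat_times_s <- as.numeric(beat_times_s)
  if (is.unsorted(beat_times_s, strictly = TRUE))
    abort("beat times must be strictly increasing")
  iv <- diff(beat_times_s) * 1000
  t2 <- beat_times_s[-1]
  keep <- iv > min_ms & iv < max_ms
  structure(list(beat_times_s = beat_times_s,
                 intervals_ms = iv[keep],
                 interval_times_s = t2[keep]),
            class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("<ibi_series> %d beats, %d valid intervals (mean %.0f ms)\n",
              length(x$beat_times_s), length(x$intervals_ms),
              if (length(x$intervals_ms)) mean(x$intervals_ms) else NA))
  invisible(x)
}

#' Instantaneous heart rate from an inter-beat-interval series
#'
#' Each valid interval of `ibi` yields one rate sample
#' `60000 / interval_ms` in beats per minute, timestamped at the second
#' beat of the interval. The series is held piecewise constant when
#' resampled onto the analysis grid.
#'
#' @param ibi An [ibi_series()].
#' @return Tibble with `time_s` and `hr_bpm`; zero rows with < 2 beats.
#' @export
instantaneous_hr <- function(ibi) {
  if (!inherits(ibi, "ibi_series")) abort("`ibi` must be an ibi_series")
  if (!length(ibi$intervals_ms))
    return(tibble(time_s = numeric(), hr_bpm = numeric()))
  tibble(time_s = ibi$interval_times_s, hr_bpm = 60000 / ibi$intervals_ms)
}

#' Time-domain heart-rate-variability statistics
#'
#' `sdnn()` is the population standard deviation of the interval sequence
#' in milliseconds; `rmssd()` is the root mean square of successive
#' interval differences. Both return `NA` below their minimum length
#' (2 and 3 intervals respectively).
#'
#' @param intervals_ms Numeric vector of inter-beat intervals (ms).
#' @return A single value in milliseconds, or `NA_real_`.
#' @examples
#' sdnn(c(800, 810, 790)) # sqrt(200/3) = 8.165
#' rmssd(c(800, 810, 790)) # sqrt((100 + 400)/2) = 15.811
#' @export
sdnn <- function(intervals_ms) {
  if (length(intervals_ms) < 2L) return(NA_real_)
  pop_sd(intervals_ms)
}

#' @rdname sdnn
#' @export
rmssd <- function(intervals_ms) {
  if (length(intervals_ms) < 3L) return(NA_real_)
  sqrt(mean(diff(intervals_ms)^2))
}
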