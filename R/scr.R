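#' Detect phasic skin-conductance-response peaks
#'
#' A peak is a local maximum of the SCR signal whose rise from the
#' preceding local minimum strictly exceeds `threshold_uS`; the peak
#' amplitude is that rise. The default 0.03 uS sits at the midpoint of
#' the 0.01-0.05 uS range conventionally used for electrodermal event
#' detection.
#'
#' @param scr Phasic skin-conductance signal (uS), e.g. the `scr`
#'   component of [decompose_gsr()].
#' @param rate_hz Sampling rate of `scr` in Hz.
#' @param threshold_uS Minimum rise in uS (strict inequality).
#' @param t0_s Time of the first sample (s).
#' @return Tibble with `time_s` (peak instant) and `amplitude_uS` (rise
#'   from the preceding minimum); zero rows when nothing crosses the
#'   threshold.
#' @export
detect_scr_peaks <- function(scr, rate_hz, threshold_uS = 0.03, t0_s = 0) {
  x <- as.numeric(scr)
  n <- length(x)
  if (n < 3) return(tibble(time_s = numeric(), amplitude_uS = numeric()))
  d <- diff(x)
  maxima <- which(d[-(n - 1)] > 0 & d[-1] <= 0) + 1L
  minima <- which(d[-(n - 1)] < 0 & d[-1] >= 0) + 1L
  if (!length(maxima)) return(tibble(time_s = numeric(), amplitude_uS = numeric()))
  # preceding local minimum for each maximum; signal start if none
  prev_min <- findInterval(maxima - 1L, minima)
  min_idx <- ifelse(prev_min > 0, minima[pmax(prev_min, 1L)], 1L)
  rise <- x[maxima] - x[min_idx]
  keep <- rise > threshold_uS
  tibble(time_s = t0_s + (maxima[keep] - 1) / rate_hz,
         amplitude_uS = rise[keep])
}
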