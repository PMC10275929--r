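#' Tile non-overlapping analysis windows over the stimulus events
#'
#' Windows of `window_s` seconds are tiled from each image onset across
#' the presentation; blank slides, self-assessment gaps and the rest
#' baseline are excluded. Each window carries the image id and the
#' quadrant label derived from the image's rescaled ratings.
#'
#' @param prep An `affect_streams` object (or a raw [recording()], whose
#'   events are used directly).
#' @param window_s Window length in seconds (default 0.5).
#' @return Tibble with `image_id`, `quadrant`, `window_start_s`,
#'   `window_end_s`.
#' @export
window_schedule <- function(prep, window_s = 0.5) {
  ev <- prep$events
  if (!nrow(ev))
    return(tibble(image_id = character(), quadrant = character(),
                  window_start_s = numeric(), window_end_s = numeric()))
  quad <- assign_quadrant(rescale_rating(ev$iaps_valence_raw),
                          rescale_rating(ev$iaps_arousal_raw))
  out <- lapply(seq_len(nrow(ev)), function(i) {
    nw <- floor(ev$duration_s[i] / window_s + 1e-9)
    starts <- ev$onset_s[i] + window_s * (seq_len(nw) - 1)
    tibble(image_id = ev$image_id[i], quadrant = quad[i],
           window_start_s = starts, window_end_s = starts + window_s)
  })
  bind_rows(out)
}

#' Extract the 23 physiological features on analysis windows
#'
#' For every window: mean, population standard deviation, min, max and
#' max-min of the tonic skin conductance (SCL), the phasic component
#' (SCR), and the instantaneous heart rate; mean first and second SCL
#' derivatives (uS/s, uS/s^2); the number and amplitude statistics of SCR
#' peaks falling in the window; running SDNN and RMSSD of the inter-beat
#' intervals over a trailing buffer ending at the window end (15 s by
#' default, one image presentation); and the mean respiration rate.
#' Windows not fully covered by the streams, or whose interval buffer
#' holds too few beats, are skipped (their count is reported in the
#' `skipped` attribute).
#'
#' @param prep An `affect_streams` object from [preprocess_recording()].
#' @param windows Window tibble as from [window_schedule()]; defaults to
#'   the schedule tiled over the recording's image events.
#' @param window_s Window length used when `windows` is `NULL`.
#' @param features Character vector of feature names to compute (default
#'   all 23). Unrequested feature groups are not computed, which the
#'   per-window estimation-time measurement relies on.
#' @param hrv_buffer_s Length of the trailing inter-beat-interval buffer
#'   feeding `sDNN_mean`/`rMSSD_mean`.
#' @param scr_threshold_uS Peak-detection threshold passed to
#'   [detect_scr_peaks()].
#' @return Tibble with one row per retained window: `participant_id`,
#'   `image_id`, `quadrant`, `window_start_s`, `window_end_s` and the
#'   requested feature columns.
#' @export
extract_features <- function(prep, windows = NULL, window_s = 0.5,
                             features = feature_names(),
                             hrv_buffer_s = 15, scr_threshold_uS = 0.03) {
  if (!inherits(prep, "affect_streams"))
    abort("`prep` must come from preprocess_recording()")
  bad <- setdiff(features, feature_names())
  if (length(bad))
    stopf("unknown feature name(s): %s", paste(bad, collapse = ", "))
  if (is.null(windows)) windows <- window_schedule(prep, window_s)
  if (!nrow(windows)) return(empty_feature_table(features))

  st <- prep$streams
  t <- st$time_s
  rate <- prep$rate_hz
  eps <- 1e-9

  need <- function(f) any(f %in% features)
  need_scl <- need(feature_names("scl"))
  need_scr <- need(c("SCR_mean", "SCR_std", "SCR_min", "SCR_max",
                     "SCR_max_minus_min"))
  need_pk <- need(c("N_peaks", "PA_mean", "PA_std"))
  need_hr <- need(c("HR_mean", "HR_std", "HR_min", "HR_max",
                    "HR_max_minus_min"))
  need_hrv <- need(c("sDNN_mean", "rMSSD_mean"))
  need_rr <- need("RR_mean")

  pk <- if (need_pk)
    detect_scr_peaks(st$scr, rate, threshold_uS = scr_threshold_uS,
                     t0_s = t[1])
  else NULL

  if (need_hrv) {
    x <- prep$ibi$intervals_ms
    b2 <- prep$ibi$interval_times_s
    C1 <- c(0, cumsum(x)); C2 <- c(0, cumsum(x^2))
    D <- c(0, cumsum(diff(x)^2))
  }

  i1 <- findInterval(windows$window_start_s - eps, t) + 1L
  i2 <- findInterval(windows$window_end_s - eps, t)
  covered <- windows$window_start_s >= t[1] - eps &
    windows$window_end_s <= t[length(t)] + 1 / rate + eps &
    (i2 - i1) >= 2L

  rows <- vector("list", nrow(windows))
  n_short <- sum(!covered)
  n_hrv <- 0L
  for (w in seq_len(nrow(windows))) {
    if (!covered[w]) next
    a <- i1[w]; b <- i2[w]
    v <- c()
    if (need_scl) {
      s <- st$scl[a:b]
      v <- c(v, SCL_mean = mean(s), SCL_std = pop_sd(s), SCL_min = min(s),
             SCL_max = max(s), SCL_max_minus_min = max(s) - min(s),
             SCL_dot = mean(diff(s)) * rate,
             SCL_ddot = mean(diff(s, differences = 2)) * rate^2)
    }
    if (need_scr) {
      s <- st$scr[a:b]
      v <- c(v, SCR_mean = mean(s), SCR_std = pop_sd(s), SCR_min = min(s),
             SCR_max = max(s), SCR_max_minus_min = max(s) - min(s))
    }
    if (need_pk) {
      inw <- pk$time_s >= windows$window_start_s[w] - eps &
        pk$time_s < windows$window_end_s[w] - eps
      amps <- pk$amplitude_uS[inw]
      v <- c(v, N_peaks = length(amps),
             PA_mean = if (length(amps)) mean(amps) else 0,
             PA_std = if (length(amps)) pop_sd(amps) else 0)
    }
    if (need_hr) {
      s <- st$hr[a:b]
      v <- c(v, HR_mean = mean(s), HR_std = pop_sd(s), HR_min = min(s),
             HR_max = max(s), HR_max_minus_min = max(s) - min(s))
    }
    if (need_hrv) {
      we <- windows$window_end_s[w]
      j2 <- findInterval(we + eps, b2)
      j1 <- findInterval(we - hrv_buffer_s + eps, b2) + 1L
      nb <- j2 - j1 + 1L
      if (nb < 3L) { n_hrv <- n_hrv + 1L; next }
      mu <- (C1[j2 + 1] - C1[j1]) / nb
      v <- c(v,
             sDNN_mean = sqrt(max(0, (C2[j2 + 1] - C2[j1]) / nb - mu^2)),
             rMSSD_mean = sqrt((D[j2] - D[j1]) / (j2 - j1)))
    }
    if (need_rr) v <- c(v, RR_mean = mean(st$rr[a:b]))
    rows[[w]] <- v
  }
  keep <- !vapply(rows, is.null, logical(1))
  skipped <- c(uncovered = n_short, short_ibi_buffer = n_hrv)
  if (any(skipped > 0))
    message(sprintf("extract_features: skipped %d window(s) (%d uncovered, %d with short IBI buffer)",
                    sum(skipped), n_short, n_hrv))
  if (!any(keep)) {
    out <- empty_feature_table(features)
    attr(out, "skipped") <- skipped
    return(out)
  }
  mat <- do.call(rbind, rows[keep])
  out <- bind_cols(
    tibble(participant_id = prep$participant_id %||% NA_character_),
    windows[keep, c("image_id", "quadrant", "window_start_s", "window_end_s")],
    as_tibble(mat)[, features, drop = FALSE]
  )
  attr(out, "skipped") <- skipped
  out
}

empty_feature_table <- function(features) {
  out <- tibble(participant_id = character(), image_id = character(),
                quadrant = character(), window_start_s = numeric(),
                window_end_s = numeric())
  for (f in features) out[[f]] <- numeric()
  out
}

#' Extract the feature vector of a single 0.5-s window
#'
#' Convenience wrapper around [extract_features()] for one window.
#'
#' @param prep An `affect_streams` object.
#' @param window Numeric `c(start_s, end_s)`.
#' @inheritParams extract_features
#' @return One-row tibble with the requested feature values.
#' @export
extract_window_features <- function(prep, window,
                                    features = feature_names(), ...) {
  if (length(window) != 2L || window[2] <= window[1])
    abort("`window` must be c(start_s, end_s) with start < end")
  w <- tibble(image_id = NA_character_, quadrant = NA_character_,
              window_start_s = window[1], window_end_s = window[2])
  out <- extract_features(prep, windows = w, features = features, ...)
  if (!nrow(out))
    abort("window is not fully covered by the preprocessed streams")
  out
}
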