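#' Per-quadrant physiological effect specification
#'
#' Defines how each affective quadrant modulates the generated signals,
#' relative to the rest/neutral condition: tonic skin-conductance level
#' offset and within-image slope, phasic event rate and mean amplitude,
#' mean heart-rate offset, the standard deviation of the inter-beat
#' intervals, the ratio of successive-difference variability to that
#' standard deviation, and the respiration-rate offset. The default
#' specification encodes the usual arousal/valence physiology: high
#' arousal raises tonic conductance, its slope, heart rate and
#' respiration rate and suppresses beat-to-beat variability, with
#' valence-signed asymmetries on the heart-rate and conductance offsets;
#' phasic SCR statistics receive no systematic class effect.
#'
#' @param overrides Optional tibble with a `quadrant` column and any of
#'   the effect columns, replacing the default rows.
#' @return Tibble with one row per quadrant and columns `quadrant`,
#'   `scl_level` (uS), `scl_slope` (uS/s), `scr_rate` (events/min),
#'   `scr_amp_mean` (uS), `hr_mean` (bpm), `ibi_sdnn` (ms),
#'   `ibi_rmssd_factor`, `rr` (breaths/min).
#' @export
default_effect_spec <- function(overrides = NULL) {
  spec <- tibble(
    quadrant = c("HAHV", "HALV", "LALV", "LAHV", "N"),
    scl_level = c(0.90, 0.55, 0.10, 0.30, 0),
    scl_slope = c(0.030, 0.020, 0.000, 0.007, 0),
    scr_rate = c(3, 3, 3, 3, 3),
    scr_amp_mean = c(0.30, 0.30, 0.30, 0.30, 0.30),
    hr_mean = c(10, 4, -4, -8, 0),
    ibi_sdnn = c(28, 32, 50, 56, 42),
    ibi_rmssd_factor = c(0.7, 0.7, 0.7, 0.7, 0.7),
    rr = c(3.5, 2.5, 0.2, 1.0, 0)
  )
  if (!is.null(overrides)) {
    for (i in seq_len(nrow(overrides))) {
      row <- match(overrides$quadrant[i], spec$quadrant)
      for (col in setdiff(names(overrides), "quadrant"))
        spec[row, col] <- overrides[[col]][i]
    }
  }
  spec
}

#' Null effect specification (no affect modulation)
#'
#' All offsets zero and identical variability in every quadrant; feature
#' distributions are then class-independent and classifiers should sit
#' at chance level.
#'
#' @return Effect tibble as in [default_effect_spec()].
#' @export
null_effect_spec <- function() {
  default_effect_spec(tibble(
    quadrant = c("HAHV", "HALV", "LALV", "LAHV", "N"),
    scl_level = 0, scl_slope = 0, hr_mean = 0, ibi_sdnn = 42, rr = 0
  ))
}

#' Draw the stimulation schedule of one session
#'
#' Emulates the picture-viewing protocol: a 4-minute rest baseline, then
#' two passes over the cluster order LAHV, HALV, HAHV, LALV, N with 5
#' images per cluster (50 images in total); every image is preceded by a
#' 5-s blank slide, shown for 15 s and followed by a self-assessment gap
#' drawn around 8.7 s. Each image receives synthetic database ratings
#' drawn uniformly inside its quadrant's region of the rescaled plane
#' (outside the neutral box for non-neutral clusters).
#'
#' @param seed Integer seed.
#' @param images_per_cluster Images per cluster (default 5; smaller
#'   values give scaled-down sessions for quick experiments).
#' @param baseline_s Rest-baseline duration (s).
#' @param image_s,blank_s Image and blank durations (s).
#' @param sam_gap_mean_s,sam_gap_sd_s Self-assessment gap distribution.
#' @return List with `events` (stimulus tibble), `baseline_interval` and
#'   `duration_s`.
#' @export
default_protocol <- function(seed = 1, images_per_cluster = 5,
                             baseline_s = 240, image_s = 15, blank_s = 5,
                             sam_gap_mean_s = 8.7, sam_gap_sd_s = 1.5) {
  withr::with_seed(seed, {
    order <- c("LAHV", "HALV", "HAHV", "LALV", "N")
    rows <- list()
    t <- baseline_s
    i_img <- 0L
    for (pass in 1:2) {
      for (q in order) {
        for (i in seq_len(images_per_cluster)) {
          i_img <- i_img + 1L
          t <- t + blank_s
          r <- draw_quadrant_rating(q)
          rows[[i_img]] <- tibble(
            image_id = sprintf("img%03d_%s", i_img, q),
            iaps_valence_raw = r[1] + 5, iaps_arousal_raw = r[2] + 5,
            onset_s = t, duration_s = image_s, cluster_quadrant = q)
          t <- t + image_s + max(3, rnorm(1, sam_gap_mean_s, sam_gap_sd_s))
        }
      }
    }
    list(events = bind_rows(rows),
         baseline_interval = c(0, baseline_s),
         duration_s = t + 2)
  })
}

# uniform draw of a rescaled (valence, arousal) point inside quadrant `q`,
# outside the neutral box for the four affective quadrants
draw_quadrant_rating <- function(q) {
  if (q == "N") return(runif(2, -1, 1))
  repeat {
    v <- switch(q, HAHV = , LAHV = runif(1, 0, 4), runif(1, -4, 0))
    a <- switch(q, HAHV = , HALV = runif(1, 0, 4), runif(1, -4, 0))
    if (!(abs(v) <= 1 && abs(a) <= 1)) return(c(v, a))
  }
}

#' Draw inter-subject baseline parameters
#'
#' @param seed Integer seed.
#' @return List with `baseline_scl` (uS, uniform 2-10), `baseline_hr`
#'   (bpm, 60-80), `baseline_rr` (breaths/min, 12-18) and per-channel
#'   effect gain multipliers (uniform 0.7-1.3).
#' @export
subject_params <- function(seed = 1) {
  withr::with_seed(seed, list(
    baseline_scl = runif(1, 2, 10),
    baseline_hr = runif(1, 60, 80),
    baseline_rr = runif(1, 12, 18),
    gain_scl = runif(1, 0.7, 1.3),
    gain_hr = runif(1, 0.7, 1.3),
    gain_rr = runif(1, 0.7, 1.3),
    seed = seed
  ))
}

# attack/release envelope of one stimulus on time grid tt; the "smooth"
# shape is a C1 raised-cosine attack with exponential release, slow enough
# that an event-locked tonic response stays below the 0.1 Hz tonic/phasic
# split (its energy lives at the cluster timescale once responses of
# consecutive same-cluster images stack)
event_envelope <- function(tt, onset, offset, tau_on, tau_off,
                           shape = c("exp", "smooth")) {
  shape <- match.arg(shape)
  env <- numeric(length(tt))
  during <- tt >= onset & tt <= offset
  after <- tt > offset
  if (shape == "exp") {
    env[during] <- 1 - exp(-(tt[during] - onset) / tau_on)
    peak <- 1 - exp(-(offset - onset) / tau_on)
  } else {
    x <- pmin(tt[during] - onset, tau_on) / tau_on
    env[during] <- (1 - cos(pi * x)) / 2
    peak <- (1 - cos(pi * min((offset - onset) / tau_on, 1))) / 2
  }
  env[after] <- peak * exp(-(tt[after] - offset) / tau_off)
  env
}

# sum of per-event effects on grid tt; value_by_q named per quadrant
event_effect_track <- function(tt, events, value_by_q, tau_on, tau_off,
                               slope_by_q = NULL, shape = "exp") {
  out <- numeric(length(tt))
  for (i in seq_len(nrow(events))) {
    on <- events$onset_s[i]
    off <- on + events$duration_s[i]
    idx <- which(tt >= on & tt <= off + 6 * tau_off)
    if (!length(idx)) next
    env <- event_envelope(tt[idx], on, off, tau_on, tau_off, shape)
    q <- events$cluster_quadrant[i]
    out[idx] <- out[idx] + value_by_q[[q]] * env
    if (!is.null(slope_by_q) && slope_by_q[[q]] != 0) {
      ramp <- pmin(pmax(tt[idx] - on, 0), off - on)
      out[idx] <- out[idx] + slope_by_q[[q]] * ramp * env
    }
  }
  out
}

# piecewise-linear slow noise with knots every `knot_s` seconds
slow_noise <- function(tt, knot_s, sd) {
  kx <- seq(tt[1], tt[length(tt)] + knot_s, by = knot_s)
  ky <- rnorm(length(kx), 0, sd)
  approx(kx, ky, xout = tt, rule = 2)$y
}

#' Simulate one participant's recording
#'
#' Renders affect-modulated channels under the stimulation protocol:
#' skin conductance at 51.2 Hz (tonic baseline + slow drift + per-image
#' level/slope responses + a Poisson train of phasic responses with
#' 0.75 s rise / 2 s decay kinetics and exponentially distributed
#' amplitudes + Gaussian noise), an ECG at 250 Hz rendered as a train of
#' Gaussian R bumps driven by an AR(1) inter-beat-interval process whose
#' mean follows the target heart rate and whose spread follows the
#' quadrant's `ibi_sdnn`, and a respiration-rate channel at 25 Hz.
#' Self-reports are the true ratings plus integer rounding noise of
#' +/- 1 per axis, with a 10% chance of a diagonal (both-axes) flip to
#' exercise the consistency filter.
#'
#' @param params Subject baseline parameters from [subject_params()].
#' @param protocol Stimulation schedule from [default_protocol()].
#' @param effects Effect tibble, see [default_effect_spec()].
#' @param seed Integer seed for all signal noise.
#' @param participant_id Identifier stored in the recording.
#' @param gsr_rate_hz,ecg_rate_hz,rr_rate_hz Channel sampling rates.
#' @param scl_drift_sd Amplitude (uS) of the slow tonic drift.
#' @param gsr_noise_sd Sensor noise of the conductance channel (uS).
#' @param scl_attack_s,scl_release_s Raised-cosine attack span and
#'   exponential release constant of the tonic response (s).
#' @param rr_noise_sd,rr_noise_knot_s Breath-scale respiration-rate
#'   variability: knot standard deviation (breaths/min) and spacing (s).
#' @return A [recording()] with ground-truth labels in its events.
#' @export
simulate_subject <- function(params, protocol,
                             effects = default_effect_spec(), seed = 1,
                             participant_id = "S01",
                             gsr_rate_hz = 51.2, ecg_rate_hz = 250,
                             rr_rate_hz = 25, scl_drift_sd = 0.01,
                             gsr_noise_sd = 0.015,
                             scl_attack_s = 12, scl_release_s = 30,
                             rr_noise_sd = 0.25, rr_noise_knot_s = 8) {
  ev <- protocol$events
  dur <- protocol$duration_s
  by_q <- function(col) stats::setNames(effects[[col]], effects$quadrant)
  withr::with_seed(seed, {
    ## --- skin conductance ------------------------------------------------
    tg <- seq(0, dur, by = 1 / gsr_rate_hz)
    scl <- params$baseline_scl +
      slow_noise(tg, 60, scl_drift_sd) +
      params$gain_scl *
        event_effect_track(tg, ev, by_q("scl_level"), scl_attack_s,
                           scl_release_s, slope_by_q = by_q("scl_slope"),
                           shape = "smooth")
    scr_rate_min <- effects$scr_rate[effects$quadrant == "N"]
    n_scr <- rpois(1, scr_rate_min * dur / 60)
    scr <- numeric(length(tg))
    if (n_scr > 0) {
      onsets <- sort(runif(n_scr, 0, dur - 1))
      amps <- rexp(n_scr, 1 / effects$scr_amp_mean[effects$quadrant == "N"])
      kt <- seq(0, 10, by = 1 / gsr_rate_hz)
      kern <- exp(-kt / 2) - exp(-kt / 0.75)
      kern <- kern / max(kern)
      for (i in seq_len(n_scr)) {
        i0 <- floor(onsets[i] * gsr_rate_hz) + 1
        idx <- i0:min(length(tg), i0 + length(kern) - 1)
        scr[idx] <- scr[idx] + amps[i] * kern[seq_along(idx)]
      }
    }
    gsr <- scl + scr + rnorm(length(tg), 0, gsr_noise_sd)

    ## --- cardiac ---------------------------------------------------------
    cg_rate <- 20
    tc <- seq(0, dur, by = 1 / cg_rate)
    hr_track <- params$baseline_hr +
      params$gain_hr * event_effect_track(tc, ev, by_q("hr_mean"), 1.5, 3)
    rest_sdnn <- effects$ibi_sdnn[effects$quadrant == "N"]
    sdnn_track <- rest_sdnn +
      event_effect_track(tc, ev, by_q("ibi_sdnn") - rest_sdnn, 1.5, 3)
    fac <- mean(effects$ibi_rmssd_factor)
    rho <- max(0, min(0.999, 1 - fac^2 / 2))
    beats <- numeric(ceiling(dur / 0.3))
    nb <- 0L
    t <- 0.2
    u <- rnorm(1)
    while (t < dur) {
      nb <- nb + 1L
      beats[nb] <- t
      i <- min(length(tc), floor(t * cg_rate) + 1)
      mean_ibi <- 60 / max(40, hr_track[i])
      u <- rho * u + sqrt(1 - rho^2) * rnorm(1)
      ibi <- mean_ibi + (sdnn_track[i] / 1000) * u
      t <- t + min(2.5, max(0.3, ibi))
    }
    beats <- beats[seq_len(nb)]
    n_ecg <- floor(dur * ecg_rate_hz) + 1
    te <- (seq_len(n_ecg) - 1) / ecg_rate_hz
    ecg <- 0.05 * sin(2 * pi * 0.25 * te + runif(1, 0, 2 * pi)) +
      rnorm(n_ecg, 0, 0.01)
    rel <- -10:10
    bump <- exp(-(rel / ecg_rate_hz)^2 / (2 * 0.01^2))
    centers <- round(beats * ecg_rate_hz) + 1
    amps <- 1 + rnorm(nb, 0, 0.05)
    idx <- rep(centers, each = length(rel)) + rel
    val <- as.vector(t(outer(amps, bump)))
    ok <- idx >= 1 & idx <= n_ecg
    ecg[idx[ok]] <- ecg[idx[ok]] + val[ok]

    ## --- respiration rate ------------------------------------------------
    tr <- seq(0, dur, by = 1 / rr_rate_hz)
    rr <- params$baseline_rr +
      params$gain_rr * event_effect_track(tr, ev, by_q("rr"), 2, 4) +
      slow_noise(tr, rr_noise_knot_s, rr_noise_sd) + rnorm(length(tr), 0, 0.05)

    ## --- self-reports ----------------------------------------------------
    v <- ev$iaps_valence_raw - 5
    a <- ev$iaps_arousal_raw - 5
    flip <- runif(nrow(ev)) < 0.10
    v[flip] <- -v[flip]; a[flip] <- -a[flip]
    jitter <- function(x) pmin(9, pmax(1, round(x + 5) +
      sample(c(-1L, 0L, 1L), length(x), TRUE, prob = c(0.2, 0.6, 0.2))))
    reports <- tibble(
      image_id = ev$image_id,
      sam_valence = as.integer(jitter(v)),
      sam_arousal = as.integer(jitter(a)),
      response_time_s = pmax(2, rnorm(nrow(ev), 8.7, 1.5))
    )

    recording(
      participant_id,
      channels = list(
        gsr = channel_signal("gsr", "uS", gsr_rate_hz, gsr, 0),
        ecg = channel_signal("ecg", "mV", ecg_rate_hz, ecg, 0),
        resp_rate = channel_signal("resp_rate", "breaths/min", rr_rate_hz,
                                   rr, 0)
      ),
      baseline_interval = protocol$baseline_interval,
      events = ev, self_reports = reports
    )
  })
}

#' Simulate a cohort of participants
#'
#' Each subject gets independent baseline parameters, an independent
#' schedule draw and independent signal noise, all derived
#' reproducibly from the master seed. Identical master seeds give
#' identical cohorts.
#'
#' @param n_subjects Number of participants (default 20).
#' @param seed Master seed.
#' @param effects Effect tibble shared by the cohort.
#' @param images_per_cluster Images per cluster (see
#'   [default_protocol()]).
#' @param dir Optional directory: each recording is also written there
#'   via [write_recording()] under its participant id.
#' @param ... Passed on to [simulate_subject()].
#' @return List of [recording()] objects named by participant id.
#' @export
simulate_cohort <- function(n_subjects = 20, seed = 1,
                            effects = default_effect_spec(),
                            images_per_cluster = 5, dir = NULL, ...) {
  if (n_subjects < 1) abort("`n_subjects` must be >= 1")
  seeds <- withr::with_seed(seed,
    matrix(sample.int(.Machine$integer.max, 3 * n_subjects), ncol = 3))
  out <- vector("list", n_subjects)
  ids <- sprintf("S%02d", seq_len(n_subjects))
  for (i in seq_len(n_subjects)) {
    proto <- default_protocol(seed = seeds[i, 1],
                              images_per_cluster = images_per_cluster)
    params <- subject_params(seed = seeds[i, 2])
    out[[i]] <- simulate_subject(params, proto, effects = effects,
                                 seed = seeds[i, 3],
                                 participant_id = ids[i], ...)
    if (!is.null(dir)) write_recording(out[[i]], file.path(dir, ids[i]))
  }
  stats::setNames(out, ids)
}
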