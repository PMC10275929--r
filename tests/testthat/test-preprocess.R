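test_that("butterworth filter has unit DC gain and blocks DC in highpass", {
  x <- rep(3.7, 1000)
  expect_equal(butterworth_filter(x, 100, 5, "lowpass"), x, tolerance = 1e-8)
  hp <- butterworth_filter(x, 100, 5, "highpass")
  expect_lt(max(abs(hp)), 1e-6 * 3.7)
})

test_that("zero-phase lowpass attenuates the cutoff sinusoid to ~0.5", {
  fs <- 100; fc <- 5
  t <- seq(0, 60, by = 1 / fs)
  y <- butterworth_filter(sin(2 * pi * fc * t), fs, fc, "lowpass", order = 4)
  mid <- y[2000:4000]
  expect_equal(max(abs(mid)), 0.5, tolerance = 0.01)
})

test_that("filtering is linear", {
  withr::with_seed(5, {
    x <- rnorm(2000); y <- rnorm(2000)
  })
  a <- 2.5; b <- -1.3
  lhs <- butterworth_filter(a * x + b * y, 100, 8, "lowpass")
  rhs <- a * butterworth_filter(x, 100, 8, "lowpass") +
    b * butterworth_filter(y, 100, 8, "lowpass")
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-8)
})

test_that("filter argument errors are raised", {
  expect_error(butterworth_filter(rnorm(100), 100, 50, "lowpass"), "Nyquist")
  expect_error(butterworth_filter(rnorm(100), 100, 60, "lowpass"), "Nyquist")
  expect_error(butterworth_filter(rnorm(5), 100, 5, "lowpass"), "short")
})

test_that("tonic/phasic decomposition separates slow and fast bands", {
  rate <- 51.2
  t <- seq(0, 120, by = 1 / rate)

  # constant signal: all level, no phasic
  d0 <- decompose_gsr(rep(5, length(t)), rate_hz = rate)
  expect_equal(d0$scl, rep(5, length(t)), tolerance = 1e-6)
  expect_lt(max(abs(d0$scr)), 1e-6)

  # 1 Hz ripple on a 5 uS level
  x <- 5 + 0.5 * sin(2 * pi * 1.0 * t)
  d1 <- decompose_gsr(x, rate_hz = rate)
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  expect_equal(mean(d1$scl[mid]), 5, tolerance = 0.02)
  expect_lt(max(abs(d1$scl[mid] - 5)), 0.02)
  expect_equal(max(d1$scr[mid]), 0.5, tolerance = 0.025)
  expect_equal(d1$scr[mid], (x - 5)[mid], tolerance = 0.05)

  # slow ramp is tonic: phasic residue stays below 0.05 uS
  ramp <- 2 + 0.01 * t
  d2 <- decompose_gsr(ramp, rate_hz = rate)
  expect_lt(max(abs(d2$scr[mid])), 0.05)
})

test_that("decomposition conserves the denoised signal", {
  rate <- 51.2
  t <- seq(0, 120, by = 1 / rate)
  withr::with_seed(8, {
    x <- 5 + 0.4 * sin(2 * pi * 0.5 * t) + 0.2 * sin(2 * pi * 0.02 * t)
  })
  d <- decompose_gsr(x, rate_hz = rate)
  resid <- (d$scl + d$scr) - d$denoised
  expect_lt(sqrt(mean(resid^2)) / sqrt(mean(d$denoised^2)), 0.05)
})

two_channel_recording <- function(f_gsr, f_rr, dur = 10) {
  tg <- seq(0, dur - 1 / 51.2, by = 1 / 51.2)
  tr <- seq(0, dur - 1 / 25, by = 1 / 25)
  te <- seq(0, dur - 1 / 250, by = 1 / 250)
  recording("P1", channels = list(
    gsr = channel_signal("gsr", "uS", 51.2, f_gsr(tg)),
    ecg = channel_signal("ecg", "mV", 250, rep(0, length(te))),
    resp_rate = channel_signal("resp_rate", "breaths/min", 25, f_rr(tr))))
}

test_that("synchronize resamples onto the shared 36.5 Hz grid", {
  rec <- two_channel_recording(function(t) rep(2, length(t)),
                               function(t) rep(14, length(t)))
  sync <- synchronize(rec)
  # floor(10 x 36.5) grid samples over a 10-s common span
  expect_equal(length(sync$channels$gsr$samples), 365)
  expect_equal(length(sync$channels$resp_rate$samples), 365)
  expect_equal(unique(sync$channels$gsr$samples), 2)

  # linear interpolation is exact for affine signals
  rec2 <- two_channel_recording(function(t) 1 + 0.3 * t,
                                function(t) 10 + 0.1 * t)
  sync2 <- synchronize(rec2)
  grid <- physioaffect:::channel_times(sync2$channels$gsr)
  expect_equal(sync2$channels$gsr$samples, 1 + 0.3 * grid,
               tolerance = 1e-9)

  # idempotent at the same rate
  sync3 <- synchronize(sync2)
  expect_equal(sync3$channels$gsr$samples, sync2$channels$gsr$samples,
               tolerance = 1e-9)
})

test_that("baseline normalization subtracts the rest mean from level streams", {
  prep <- small_prep()
  bi <- prep$baseline_interval
  inb <- prep$streams$time_s >= bi[1] & prep$streams$time_s < bi[2]
  # after normalization the baseline-segment mean of each level stream is 0
  for (col in c("scl", "hr", "rr"))
    expect_equal(mean(prep$streams[[col]][inb]), 0, tolerance = 1e-9)

  # arithmetic: a later value sitting 0.7 above the baseline mean maps to 0.7
  raw <- preprocess_recording(small_recording(), normalize = FALSE)
  mu <- mean(raw$streams$scl[inb])
  expect_equal(prep$streams$scl, raw$streams$scl - mu, tolerance = 1e-9)

  # missing baseline interval instructs to skip explicitly
  rec2 <- small_recording()
  rec2$baseline_interval <- NULL
  expect_error(preprocess_recording(rec2), "normalize = FALSE")
  expect_silent(preprocess_recording(rec2, normalize = FALSE))

  # too-short baseline
  rec3 <- small_recording()
  rec3$baseline_interval <- c(0, 20)
  expect_error(preprocess_recording(rec3), ">= 30 s")
})
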