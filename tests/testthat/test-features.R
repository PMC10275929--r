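test_that("SCR peak detection applies the strict rise threshold", {
  rate <- 51.2
  t <- seq(0, 30, by = 1 / rate)
  bump <- function(at, amp) amp * exp(-(t - at)^2 / (2 * 0.5^2))
  x <- bump(5, 0.05) + bump(15, 0.02) + bump(25, 0.10)
  pk <- detect_scr_peaks(x, rate)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$amplitude_uS, c(0.05, 0.10), tolerance = 1e-3)
  expect_equal(pk$time_s, c(5, 25), tolerance = 0.1)

  expect_equal(nrow(detect_scr_peaks(rep(0, 1000), rate)), 0)

  # a rise of exactly 0.03 uS is NOT a peak (strict inequality)
  tri <- c(seq(0, 0.03, length.out = 50), seq(0.03, 0, length.out = 50))
  expect_equal(nrow(detect_scr_peaks(tri, rate)), 0)
  tri2 <- tri * (0.031 / 0.03)
  expect_equal(nrow(detect_scr_peaks(tri2, rate)), 1)
})

test_that("the extractor emits exactly the 23 named features", {
  fx <- small_features()
  expect_true(all(feature_names() %in% names(fx)))
  expect_length(feature_names(), 23)
  expect_length(feature_names("gsr"), 15)
  expect_length(feature_names("cardiac"), 7)
  expect_length(feature_names("respiratory"), 1)
  vals <- as.matrix(fx[, feature_names()])
  expect_true(all(is.finite(vals)))
  # a scaled session with 20 images x 30 windows per image
  expect_equal(nrow(fx), 600)
})

test_that("feature invariants hold on every extracted window", {
  fx <- small_features()
  for (g in c("SCL", "SCR", "HR")) {
    expect_true(all(fx[[paste0(g, "_max")]] >= fx[[paste0(g, "_min")]]))
    expect_equal(fx[[paste0(g, "_max_minus_min")]],
                 fx[[paste0(g, "_max")]] - fx[[paste0(g, "_min")]],
                 tolerance = 1e-12)
    expect_true(all(fx[[paste0(g, "_std")]] >= 0))
  }
  expect_true(all(fx$N_peaks >= 0 & fx$N_peaks == round(fx$N_peaks)))
  none <- fx$N_peaks == 0
  expect_true(all(fx$PA_mean[none] == 0 & fx$PA_std[none] == 0))
  expect_true(all(fx$sDNN_mean >= 0 & fx$rMSSD_mean >= 0))
})

test_that("a constant SCL window has zero spread and derivatives", {
  prep <- small_prep()
  prep$streams$scl <- rep(2, nrow(prep$streams))
  fv <- extract_window_features(prep, c(300, 300.5))
  expect_equal(fv$SCL_mean, 2)
  expect_equal(fv$SCL_std, 0)
  expect_equal(fv$SCL_max_minus_min, 0)
  expect_equal(fv$SCL_dot, 0)
  expect_equal(fv$SCL_ddot, 0)
})

test_that("a single in-window SCR rise gives N_peaks 1 with PA_std 0", {
  prep <- small_prep()
  t <- prep$streams$time_s
  prep$streams$scr <- 0.05 * exp(-(t - 300.25)^2 / (2 * 0.1^2))
  fv <- extract_window_features(prep, c(300, 300.5))
  expect_equal(fv$N_peaks, 1)
  expect_equal(fv$PA_mean, 0.05, tolerance = 1e-3)
  expect_equal(fv$PA_std, 0)
})

test_that("adding a constant to SCL shifts location features only", {
  prep <- small_prep()
  base <- extract_window_features(prep, c(305, 305.5))
  prep2 <- prep
  prep2$streams$scl <- prep2$streams$scl + 1.5
  shifted <- extract_window_features(prep2, c(305, 305.5))
  for (f in c("SCL_mean", "SCL_min", "SCL_max"))
    expect_equal(shifted[[f]], base[[f]] + 1.5, tolerance = 1e-9)
  for (f in c("SCL_std", "SCL_dot", "SCL_ddot", "SCL_max_minus_min"))
    expect_equal(shifted[[f]], base[[f]], tolerance = 1e-9)
})

test_that("windows in a flat rest segment have near-zero spread features", {
  # null-effect subject: baseline segment is level + noise only
  proto <- default_protocol(seed = 21, images_per_cluster = 2)
  eff <- null_effect_spec()
  eff$scr_rate <- 0 # no spontaneous phasic events either
  rec <- simulate_subject(subject_params(22), proto, effects = eff,
                          seed = 23)
  prep <- preprocess_recording(rec)
  w <- tibble::tibble(image_id = "rest", quadrant = "N",
                      window_start_s = seq(60, 120, by = 0.5))
  w$window_end_s <- w$window_start_s + 0.5
  fx <- suppressMessages(extract_features(prep, windows = w))
  expect_lt(max(fx$SCL_std), 0.02)
  expect_lt(max(abs(fx$SCR_mean)), 0.05)
  expect_equal(sum(fx$N_peaks), 0)
})

test_that("uncovered windows are skipped with a reported reason", {
  prep <- small_prep()
  w <- tibble::tibble(image_id = "x", quadrant = "N",
                      window_start_s = c(250, 1e6),
                      window_end_s = c(250.5, 1e6 + 0.5))
  expect_message(fx <- extract_features(prep, windows = w), "skipped")
  expect_equal(nrow(fx), 1)
  expect_error(extract_window_features(prep, c(1e6, 1e6 + 0.5)))
  expect_error(extract_window_features(prep, c(10, 9)), "start < end")
  expect_error(extract_features(prep, features = "bogus"), "unknown feature")
})
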