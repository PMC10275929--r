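test_that("the default protocol reproduces the session structure", {
  proto <- default_protocol(seed = 5)
  ev <- proto$events
  expect_equal(nrow(ev), 50)
  order5 <- c("LAHV", "HALV", "HAHV", "LALV", "N")
  expect_equal(ev$cluster_quadrant[!duplicated(ev$cluster_quadrant) |
                                     c(FALSE, diff(match(ev$cluster_quadrant,
                                                         order5)) != 0)][1:10],
               rep(order5, 2))
  expect_equal(proto$baseline_interval, c(0, 240))
  expect_true(all(ev$onset_s >= 240))
  expect_true(all(diff(ev$onset_s) >= 15 + 5)) # image + blank at least
  expect_equal(unique(ev$duration_s), 15)
})

test_that("synthetic ratings land inside their cluster's quadrant region", {
  proto <- default_protocol(seed = 6)
  ev <- proto$events
  q <- assign_quadrant(rescale_rating(ev$iaps_valence_raw),
                       rescale_rating(ev$iaps_arousal_raw))
  expect_equal(q, ev$cluster_quadrant)
  hahv <- ev[ev$cluster_quadrant == "HAHV", ]
  expect_true(all(rescale_rating(hahv$iaps_valence_raw) > 0))
  expect_true(all(rescale_rating(hahv$iaps_arousal_raw) > 0))
})

test_that("identical master seeds give identical cohorts", {
  a <- simulate_cohort(2, seed = 77, images_per_cluster = 1)
  b <- simulate_cohort(2, seed = 77, images_per_cluster = 1)
  expect_identical(names(a), names(b))
  for (id in names(a)) {
    expect_identical(a[[id]]$channels$gsr$samples,
                     b[[id]]$channels$gsr$samples)
    expect_identical(a[[id]]$channels$ecg$samples,
                     b[[id]]$channels$ecg$samples)
    expect_equal(as.data.frame(a[[id]]$events),
                 as.data.frame(b[[id]]$events))
  }
  c1 <- simulate_cohort(2, seed = 78, images_per_cluster = 1)
  expect_false(identical(a[[1]]$channels$gsr$samples,
                         c1[[1]]$channels$gsr$samples))
})

test_that("subject parameters stay in their documented ranges", {
  for (s in 1:20) {
    p <- subject_params(s)
    expect_true(p$baseline_scl >= 2 && p$baseline_scl <= 10)
    expect_true(p$baseline_hr >= 60 && p$baseline_hr <= 80)
    expect_true(p$baseline_rr >= 12 && p$baseline_rr <= 18)
    expect_true(all(c(p$gain_scl, p$gain_hr, p$gain_rr) >= 0.7))
    expect_true(all(c(p$gain_scl, p$gain_hr, p$gain_rr) <= 1.3))
  }
})

test_that("the realized IBI spread matches the specified SDNN within 20%", {
  # rest-only session (no events): the variability target is the N row
  proto <- list(events = physioaffect:::empty_events(),
                baseline_interval = c(0, 240), duration_s = 240)
  p <- subject_params(31)
  rec <- simulate_subject(p, proto, seed = 32)
  beats <- detect_r_peaks(rec$channels$ecg)
  expect_gt(length(beats), 200)
  realized <- sdnn(ibi_series(beats)$intervals_ms)
  target <- default_effect_spec()$ibi_sdnn[5] # N row
  expect_lt(abs(realized - target) / target, 0.2)
})

test_that("default effects raise tonic conductance under high arousal", {
  ok <- 0
  for (s in 1:6) {
    proto <- default_protocol(seed = 50 + s, images_per_cluster = 2)
    rec <- simulate_subject(subject_params(60 + s), proto, seed = 70 + s)
    prep <- preprocess_recording(rec)
    fx <- suppressMessages(extract_features(prep))
    ha <- fx$SCL_mean[fx$quadrant %in% c("HAHV", "HALV")]
    la <- fx$SCL_mean[fx$quadrant %in% c("LALV", "LAHV")]
    if (mean(ha) > mean(la)) ok <- ok + 1
  }
  expect_gte(ok, 5)
})

test_that("zero effects remove the class structure from tonic features", {
  pvals <- sapply(1:8, function(s) {
    proto <- default_protocol(seed = 80 + s, images_per_cluster = 2)
    rec <- simulate_subject(subject_params(90 + s), proto,
                            effects = null_effect_spec(), seed = 100 + s)
    prep <- preprocess_recording(rec)
    fx <- suppressMessages(extract_features(prep))
    # aggregate to image level first: windows within an image are correlated
    img <- stats::aggregate(SCL_mean ~ image_id + quadrant, fx, mean)
    ha <- img$SCL_mean[img$quadrant %in% c("HAHV", "HALV")]
    la <- img$SCL_mean[img$quadrant %in% c("LALV", "LAHV")]
    stats::t.test(ha, la)$p.value
  })
  expect_gte(sum(pvals > 0.01), 6)
})
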