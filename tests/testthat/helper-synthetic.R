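# Shared synthetic fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small single-subject recording (scaled protocol: 2 images per cluster)
small_recording <- function() {
  cached("small_recording", {
    proto <- default_protocol(seed = 401, images_per_cluster = 2)
    simulate_subject(subject_params(402), proto, seed = 403,
                     participant_id = "S01")
  })
}

small_prep <- function() {
  cached("small_prep", preprocess_recording(small_recording()))
}

small_features <- function() {
  cached("small_features",
         suppressMessages(extract_features(small_prep())))
}

# full-scale 20-subject cohort features + selection, used by the
# acceptance checks; built once (~1 min)
cohort_fixture <- function() {
  cached("cohort_fixture", {
    cfg <- study_config(seed = 1)
    cohort <- simulate_cohort(20, seed = 1)
    cf <- cohort_features(cohort, cfg)
    sel <- select_features(cf$features, cfg)
    list(cohort = cohort, features = cf$features, selection = sel,
         config = cfg)
  })
}

# synthetic ECG: Gaussian R bumps at given beat times
synth_ecg <- function(beat_times, dur, rate = 250, sigma = 0.010,
                      noise_sd = 0) {
  t <- seq(0, dur, by = 1 / rate)
  x <- numeric(length(t))
  for (b in beat_times) x <- x + exp(-(t - b)^2 / (2 * sigma^2))
  if (noise_sd > 0) x <- x + rnorm(length(t), 0, noise_sd)
  channel_signal("ecg", "mV", rate, x, 0)
}

# iid "planted signal" dataset: some features shift with the class, the
# rest are pure noise
planted_dataset <- function(seed, n_per_class = 40, shift = 2) {
  withr::with_seed(seed, {
    classes <- rep(c("a", "b", "c"), each = n_per_class)
    n <- length(classes)
    tibble::tibble(
      sig1 = rnorm(n) + shift * as.integer(factor(classes)),
      sig2 = rnorm(n) - shift * as.integer(factor(classes)),
      noise1 = rnorm(n),
      noise2 = runif(n),
      cls = classes
    )
  })
}
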