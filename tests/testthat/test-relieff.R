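test_that("hand-enumerated toy example gives W[A] = 1, W[B] = 0", {
  d <- tibble::tibble(A = c(0, 0, 1, 1), B = 1,
                      cls = c("a", "a", "b", "b"))
  w <- relieff(d, features = c("A", "B"), label_col = "cls", k = 1)
  expect_equal(w$weight[w$feature == "A"], 1.0)
  expect_equal(w$weight[w$feature == "B"], 0.0)
})

test_that("a class-independent duplicate pattern gets non-positive weight", {
  # feature value pattern identical in both classes
  d <- tibble::tibble(A = c(0, 1, 0, 1), cls = c("a", "a", "b", "b"))
  w <- relieff(d, features = "A", label_col = "cls", k = 1)
  expect_lte(w$weight, 0)
})

test_that("relieff equals the brute-force oracle on random datasets", {
  for (seed in 1:60) {
    case <- random_relieff_case(seed)
    d <- tibble::as_tibble(as.data.frame(case$X))
    d$cls <- case$y
    w <- relieff(d, features = colnames(case$X), label_col = "cls",
                 k = case$k)
    expect_equal(w$weight, unname(oracle_relieff(case$X, case$y, case$k)),
                 tolerance = 1e-9)
  }
})

test_that("weights are range-bounded and invariant to instance order", {
  case <- random_relieff_case(999)
  d <- tibble::as_tibble(as.data.frame(case$X))
  d$cls <- case$y
  w <- relieff(d, features = colnames(case$X), label_col = "cls", k = case$k)
  expect_true(all(w$weight >= -1 & w$weight <= 1))
  perm <- withr::with_seed(7, sample(nrow(d)))
  w2 <- relieff(d[perm, ], features = colnames(case$X), label_col = "cls",
                k = case$k)
  expect_equal(w$weight, w2$weight, tolerance = 1e-12)
})

test_that("degenerate inputs are handled per contract", {
  d <- tibble::tibble(A = 1, B = 2, cls = rep(c("a", "b"), each = 5))
  w <- relieff(d, features = c("A", "B"), label_col = "cls", k = 2)
  expect_equal(w$weight, c(0, 0))

  d2 <- tibble::tibble(A = rnorm(7), cls = c(rep("a", 5), "b", "b"))
  expect_error(relieff(d2, features = "A", label_col = "cls", k = 2), "'b'")
  expect_error(relieff(tibble::tibble(A = rnorm(5), cls = "a"),
                       features = "A", label_col = "cls", k = 1),
               "2 classes")
})

test_that("planted signals get positive weight, independent noise near zero", {
  reps <- lapply(1:50, function(s) {
    d <- planted_dataset(s, n_per_class = 20)
    relieff(d, features = c("sig1", "sig2", "noise1", "noise2"),
            label_col = "cls", k = 3)$weight
  })
  m <- colMeans(do.call(rbind, reps))
  expect_gt(m[1], 0.05) # deterministic monotone function of the class
  expect_gt(m[2], 0.05)
  expect_lte(m[3], 0.02) # label-independent
  expect_lte(m[4], 0.02)
})

test_that("the positive-weight set is stable across k on a planted dataset", {
  d <- planted_dataset(42, n_per_class = 40)
  rep <- weight_stability_report(d, features = c("sig1", "sig2", "noise1",
                                                 "noise2"),
                                 label_col = "cls")
  expect_equal(sort(unique(rep$k)), c(1, 3, 5, 10))
  expect_equal(nrow(rep), 4 * 4)
  sets <- positive_sets(rep)
  expect_length(sets, 4)
  expect_true(all(vapply(sets, function(s)
    identical(sort(s), sort(sets[[1]])), logical(1))))
  # a single k reproduces relieff directly
  w5 <- relieff(d, features = c("sig1", "sig2", "noise1", "noise2"),
                label_col = "cls", k = 5)
  expect_equal(rep$weight[rep$k == 5], w5$weight)
})

test_that("median-positive rule defines the optimal set", {
  long <- tibble::tibble(
    participant_id = rep(c("P1", "P2", "P3"), each = 2),
    feature = rep(c("f1", "f2"), 3),
    weight = c(0.10, -0.10, 0.20, 0.05, 0.05, -0.20))
  opt <- optimal_feature_set(long)
  expect_equal(opt$features, "f1")
  meds <- opt$medians
  expect_equal(meds$median_weight[meds$feature == "f1"], 0.10)
  expect_equal(meds$median_weight[meds$feature == "f2"], -0.10)
  expect_false(meds$selected[meds$feature == "f2"])

  # single participant: reduces to that participant's positive weights
  one <- long[long$participant_id == "P1", ]
  opt1 <- optimal_feature_set(one)
  expect_equal(opt1$features, "f1")

  expect_error(optimal_feature_set(
    tibble::tibble(participant_id = c("P1", "P2"),
                   feature = c("f1", "f2"), weight = c(1, 1))),
    "inconsistent")
})
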