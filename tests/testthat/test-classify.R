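two_clouds <- function(n = 60, sep = 4, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    SCL_mean = c(rnorm(n), rnorm(n) + sep),
    HR_mean = c(rnorm(n), rnorm(n) + sep),
    class_label = rep(c("low", "high"), each = n)))
}

test_that("LDA separates linearly separable clouds perfectly", {
  d <- two_clouds()
  m <- fit_affect_model(d, "LDA", features = c("SCL_mean", "HR_mean"))
  expect_equal(as.character(predict(m, d)), d$class_label)
})

test_that("1-NN reproduces its training labels", {
  d <- two_clouds(sep = 0.5)
  m <- fit_affect_model(d, "KNN", features = c("SCL_mean", "HR_mean"),
                        knn_k = 1)
  expect_equal(as.character(predict(m, d)), d$class_label)
})

test_that("the Gaussian SVM solves XOR where LDA cannot", {
  d <- withr::with_seed(12, {
    x <- runif(200, -1, 1); y <- runif(200, -1, 1)
    tibble::tibble(SCL_mean = x, HR_mean = y,
                   class_label = ifelse(x * y > 0, "a", "b"))
  })
  lda <- fit_affect_model(d, "LDA", features = c("SCL_mean", "HR_mean"))
  svg <- fit_affect_model(d, "SVM_GAUSSIAN",
                          features = c("SCL_mean", "HR_mean"))
  acc <- function(m) mean(predict(m, d) == d$class_label)
  expect_lt(acc(lda), 0.65)
  expect_gt(acc(svg), 0.9)
})

test_that("model guards reject unusable inputs", {
  d <- two_clouds(n = 3)
  expect_error(fit_affect_model(d, "KNN", features = c("SCL_mean"),
                                knn_k = 5), "knn_k")
  m <- fit_affect_model(two_clouds(), "LDA",
                        features = c("SCL_mean", "HR_mean"))
  expect_error(predict(m, tibble::tibble(SCL_mean = 1)), "HR_mean")
  expect_error(fit_affect_model(two_clouds(), "LDA", features = "nope"),
               "nope")
})

test_that("accuracy and macro-F match hand values and brute force", {
  conf <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
  expect_equal(confusion_accuracy(conf), 0.75)
  # precision 0.5, recall 1 -> F = 2/3
  conf2 <- matrix(c(1, 0, 1, 0), 2, byrow = TRUE,
                  dimnames = list(c("a", "b"), c("a", "b")))
  f_a <- 2 * 0.5 * 1 / (0.5 + 1)
  expect_equal(confusion_macro_f(conf2), mean(c(f_a, 0)))
  expect_equal(confusion_accuracy(diag(c(5, 7))), 1)
  expect_equal(confusion_macro_f(diag(c(5, 7))), 1)

  withr::with_seed(4, {
    truth <- sample(letters[1:3], 200, replace = TRUE)
    pred <- sample(letters[1:3], 200, replace = TRUE)
  })
  conf3 <- as.matrix(table(truth, pred))
  expect_equal(confusion_accuracy(conf3), oracle_accuracy(truth, pred))
  expect_equal(confusion_macro_f(conf3), oracle_macro_f(truth, pred))
})

test_that("evaluate_model agrees with direct recomputation", {
  d <- two_clouds(sep = 1.5)
  m <- fit_affect_model(d, "KNN", features = c("SCL_mean", "HR_mean"))
  test <- two_clouds(sep = 1.5, seed = 2)
  ev <- evaluate_model(m, test, problem = "HL_VALENCE", feature_set = "all")
  pred <- as.character(predict(m, test))
  expect_equal(ev$accuracy, oracle_accuracy(test$class_label, pred))
  expect_equal(ev$f_score, oracle_macro_f(test$class_label, pred))
  expect_equal(sum(ev$confusion), nrow(test))
  gl <- glance(ev)
  expect_equal(gl$accuracy, ev$accuracy)
  expect_equal(gl$problem, "HL_VALENCE")
})

test_that("pairwise ANOVA comparison applies the Bonferroni threshold", {
  acc <- tibble::tibble(
    algorithm = rep(c("KNN", "SVM_CUBIC", "SVM_GAUSSIAN", "LDA"), each = 5),
    accuracy = c(rnorm(5, 0.8, 0.01), rnorm(5, 0.8, 0.01),
                 rnorm(5, 0.79, 0.01), rnorm(5, 0.5, 0.01)))
  cmp <- compare_models(acc)
  expect_equal(cmp$n_comparisons, 6)
  expect_equal(cmp$p_threshold, 0.05 / 6)
  expect_equal(round(cmp$p_threshold, 3), 0.008)
  expect_equal(nrow(cmp$pairwise), 6)
  lda_rows <- cmp$pairwise$group1 == "LDA" | cmp$pairwise$group2 == "LDA"
  expect_true(all(cmp$pairwise$significant[lda_rows]))

  # two groups of identical constants: F = 0, not significant
  flat <- tibble::tibble(algorithm = rep(c("A", "B"), each = 3),
                         accuracy = 0.7)
  cmp0 <- compare_models(flat)
  expect_equal(cmp0$pairwise$f, 0)
  expect_equal(cmp0$pairwise$p_value, 1)
  expect_false(cmp0$pairwise$significant)

  # oracle check: groups [1,2,3] vs [4,5,6]
  g <- tibble::tibble(algorithm = rep(c("A", "B"), each = 3),
                      accuracy = c(1, 2, 3, 4, 5, 6))
  cmp1 <- compare_models(g)
  a <- stats::aov(accuracy ~ algorithm, data = g)
  f_oracle <- summary(a)[[1]]$`F value`[1]
  expect_equal(cmp1$pairwise$f, f_oracle, tolerance = 1e-9)
  expect_equal(cmp1$pairwise$f, 13.5, tolerance = 1e-9)

  expect_error(compare_models(g[1:3, ]), "2 groups")
})
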