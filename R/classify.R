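#' Fit an affective-state classifier on labeled windows
#'
#' Features are restricted to `features` and z-scored with training
#' statistics stored in the model. Algorithms: `KNN` (distance-based
#' nearest-neighbour vote), `SVM_CUBIC` and `SVM_GAUSSIAN` (maximum
#' margin with degree-3 polynomial / radial kernel, one-vs-one for
#' multi-class), `LDA` (shared-covariance linear discriminant).
#'
#' @param train Labeled window tibble with a `class_label` column.
#' @param algorithm One of `"KNN"`, `"SVM_CUBIC"`, `"SVM_GAUSSIAN"`,
#'   `"LDA"`.
#' @param features Feature columns to use (default: all 23 present).
#' @param knn_k Neighbours for KNN (default 5); every training class must
#'   have at least `knn_k` members.
#' @param svm_cost Box constraint for both SVMs (default 1).
#' @param svm_gamma Kernel coefficient; default `1/n_features` after
#'   z-scoring.
#' @param label_col Name of the label column.
#' @return An `affect_model` object with a [predict()] method.
#' @export
fit_affect_model <- function(train,
                             algorithm = c("KNN", "SVM_CUBIC",
                                           "SVM_GAUSSIAN", "LDA"),
                             features = NULL, knn_k = 5, svm_cost = 1,
                             svm_gamma = NULL, label_col = "class_label") {
  algorithm <- match.arg(algorithm)
  if (!nrow(train)) abort("empty training set")
  if (is.null(features)) features <- intersect(feature_names(), names(train))
  missing <- setdiff(features, names(train))
  if (length(missing))
    stopf("feature(s) missing from training data: %s",
          paste(missing, collapse = ", "))
  y <- factor(train[[label_col]])
  X <- as.matrix(train[, features, drop = FALSE])
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  Xz <- sweep(sweep(X, 2, center), 2, scale, "/")
  gamma <- svm_gamma %||% (1 / length(features))

  if (algorithm == "LDA") {
    # a feature that is (near-)constant within every class carries no
    # discriminant information and breaks the within-covariance estimate
    centered <- Xz - rowsum(Xz, y)[y, ] / as.vector(table(y))[as.integer(y)]
    keep <- sqrt(colMeans(centered^2)) > 1e-6
    if (!all(keep)) {
      features <- features[keep]
      center <- center[keep]; scale <- scale[keep]
      Xz <- Xz[, keep, drop = FALSE]
    }
  }

  fit <- switch(algorithm,
    KNN = {
      if (min(table(y)) < knn_k)
        stopf("a training class has fewer than knn_k = %d members", knn_k)
      list(x = Xz, y = y)
    },
    SVM_CUBIC = e1071::svm(Xz, y, kernel = "polynomial", degree = 3,
                           coef0 = 1, gamma = gamma, cost = svm_cost,
                           scale = FALSE),
    SVM_GAUSSIAN = e1071::svm(Xz, y, kernel = "radial", gamma = gamma,
                              cost = svm_cost, scale = FALSE),
    # related level statistics (e.g. SCL mean/min/max) are expected to be
    # nearly collinear; lda handles this, so its advisory warning is noise
    LDA = suppressWarnings(MASS::lda(Xz, grouping = y))
  )
  structure(
    list(algorithm = algorithm, features = features, center = center,
         scale = scale, fit = fit, knn_k = knn_k, levels = levels(y)),
    class = "affect_model"
  )
}

#' @export
print.affect_model <- function(x, ...) {
  cat(sprintf("<affect_model> %s on %d features, classes: %s\n",
              x$algorithm, length(x$features),
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Predict affective classes for new windows
#'
#' @param object An `affect_model`.
#' @param newdata Tibble containing the model's feature columns.
#' @param ... Unused.
#' @return Factor of predicted class labels.
#' @export
predict.affect_model <- function(object, newdata, ...) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing))
    stopf("feature(s) missing from test data: %s",
          paste(missing, collapse = ", "))
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  Xz <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  switch(object$algorithm,
    # distance ties in the neighbour vote are broken by class::knn through
    # the RNG; fix the seed so predictions are a pure function of the data
    KNN = withr::with_seed(1L,
      class::knn(object$fit$x, Xz, object$fit$y, k = object$knn_k)),
    SVM_CUBIC = ,
    SVM_GAUSSIAN = predict(object$fit, Xz),
    LDA = predict(object$fit, Xz)$class
  )
}

#' Accuracy and macro F-score from a confusion matrix
#'
#' Accuracy is the ratio of the main-diagonal sum to the total count;
#' the F-score is the unweighted (macro) mean over classes of the
#' harmonic mean of per-class precision and recall. Rows index the true
#' class, columns the predicted class.
#'
#' @param confusion Square numeric matrix (rows = truth, cols = predicted).
#' @return A single number.
#' @examples
#' confusion_accuracy(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)) # 0.75
#' @export
confusion_accuracy <- function(confusion) {
  sum(diag(confusion)) / sum(confusion)
}

#' @rdname confusion_accuracy
#' @export
confusion_macro_f <- function(confusion) {
  present <- rowSums(confusion) > 0
  f <- vapply(which(present), function(i) {
    tp <- confusion[i, i]
    prec <- if (sum(confusion[, i]) > 0) tp / sum(confusion[, i]) else 0
    rec <- tp / sum(confusion[i, ])
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  mean(f)
}

#' Evaluate a fitted model on held-out windows
#'
#' @param model An `affect_model`.
#' @param test Labeled window tibble (same schema as the training data).
#' @param problem Optional problem id recorded in the report.
#' @param feature_set Optional feature-set tag (e.g. `"all"`,
#'   `"optimal"`) recorded in the report.
#' @param label_col Name of the label column.
#' @return An `affect_eval` object: confusion matrix, accuracy, macro
#'   F-score and per-class precision/recall. Use [tidy()]/[glance()] for
#'   tabular access.
#' @export
evaluate_model <- function(model, test, problem = NA_character_,
                           feature_set = NA_character_,
                           label_col = "class_label") {
  if (!nrow(test)) abort("empty test set")
  truth <- factor(test[[label_col]], levels = model$levels)
  pred <- factor(predict(model, test), levels = model$levels)
  confusion <- as.matrix(table(truth = truth, predicted = pred))
  per_class <- tibble(
    class = model$levels,
    n = as.numeric(rowSums(confusion)),
    precision = vapply(seq_along(model$levels), function(i) {
      cs <- sum(confusion[, i])
      if (cs > 0) confusion[i, i] / cs else NA_real_
    }, numeric(1)),
    recall = vapply(seq_along(model$levels), function(i) {
      rs <- sum(confusion[i, ])
      if (rs > 0) confusion[i, i] / rs else NA_real_
    }, numeric(1))
  )
  structure(
    list(problem = problem, algorithm = model$algorithm,
         feature_set = feature_set, confusion = confusion,
         accuracy = confusion_accuracy(confusion),
         f_score = confusion_macro_f(confusion),
         per_class = per_class, n = nrow(test)),
    class = "affect_eval"
  )
}

#' @export
print.affect_eval <- function(x, ...) {
  cat(sprintf("<affect_eval> %s%s: accuracy %.3f, macro-F %.3f on %d windows\n",
              x$algorithm,
              if (!is.na(x$problem)) paste0(" / ", x$problem) else "",
              x$accuracy, x$f_score, x$n))
  print(x$confusion)
  invisible(x)
}

#' @method tidy affect_eval
#' @export
tidy.affect_eval <- function(x, ...) x$per_class

#' @method glance affect_eval
#' @export
glance.affect_eval <- function(x, ...) {
  tibble(problem = x$problem, algorithm = x$algorithm,
         feature_set = x$feature_set, accuracy = x$accuracy,
         f_score = x$f_score, n = x$n)
}

#' Measure per-window estimation time from raw signals
#'
#' Emulates the real-time path: for each 0.5-s window the raw channels
#' are sliced with a trailing context buffer, filtered and decomposed,
#' beats are detected, the model's features (and only those) are
#' extracted and the class is predicted; the wall-clock span of the
#' whole chain is the window's estimation time.
#'
#' @param model An `affect_model`.
#' @param rec The raw [recording()] the windows come from.
#' @param window_starts Window start times (s).
#' @param window_s Window length (s).
#' @param context_s Trailing raw-signal context sliced per window; must
#'   cover the inter-beat buffer feeding the running HRV features.
#' @return Tibble with `window_start_s` and `time_ms`.
#' @export
measure_estimation_time <- function(model, rec, window_starts,
                                    window_s = 0.5, context_s = 15) {
  margin <- 0.1 # keeps the final window on the resampled grid
  out <- vapply(window_starts, function(ws) {
    t0 <- proc.time()[["elapsed"]]
    slice <- slice_segment(rec, ws + window_s - context_s,
                           ws + window_s + margin)
    prep <- preprocess_recording(slice, normalize = FALSE)
    fv <- extract_window_features(
      prep, c(context_s - window_s, context_s),
      features = model$features, hrv_buffer_s = context_s - window_s)
    invisible(predict(model, fv))
    (proc.time()[["elapsed"]] - t0) * 1000
  }, numeric(1))
  tibble(window_start_s = window_starts, time_ms = out)
}

#' Pairwise one-way ANOVA comparison of per-participant accuracies
#'
#' For every pair of groups a one-way ANOVA F and p value is computed;
#' the significance threshold is Bonferroni-corrected,
#' `p_m = alpha / n_comparisons` (0.05/6 = 0.008 for four algorithms).
#' Pairs of identical constant groups report F = 0, p = 1.
#'
#' @param accuracies Tibble with one row per participant x group.
#' @param group_col,value_col Column names of the grouping factor and
#'   the response.
#' @param alpha Family-wise significance level (default 0.05).
#' @return A `model_comparison`: `pairwise` tibble (`group1`, `group2`,
#'   `f`, `p_value`, `significant`), `overall` one-way ANOVA across all
#'   groups, and `p_threshold`.
#' @export
compare_models <- function(accuracies, group_col = "algorithm",
                           value_col = "accuracy", alpha = 0.05) {
  g <- factor(accuracies[[group_col]])
  v <- accuracies[[value_col]]
  if (nlevels(g) < 2) abort("need at least 2 groups")
  if (any(table(g) < 2)) abort("every group needs at least 2 values")
  one_way <- function(vals, grp) {
    grp <- droplevels(grp)
    if (stats::var(vals) < 1e-300) return(c(f = 0, p = 1))
    ow <- stats::oneway.test(vals ~ grp, var.equal = TRUE)
    c(f = unname(ow$statistic), p = unname(ow$p.value))
  }
  pairs <- utils::combn(levels(g), 2)
  n_c <- ncol(pairs)
  p_m <- alpha / n_c
  rows <- apply(pairs, 2, function(pr) {
    sel <- g %in% pr
    st <- one_way(v[sel], g[sel])
    tibble(group1 = pr[1], group2 = pr[2], f = st[["f"]],
           p_value = st[["p"]], significant = st[["p"]] <= p_m)
  })
  ov <- one_way(v, g)
  structure(
    list(pairwise = bind_rows(rows),
         overall = tibble(f = ov[["f"]], p_value = ov[["p"]]),
         p_threshold = p_m, alpha = alpha, n_comparisons = n_c),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %d pairwise ANOVAs, threshold p <= %.3f\n",
              x$n_comparisons, x$p_threshold))
  print(as.data.frame(x$pairwise))
  invisible(x)
}

#' @method tidy model_comparison
#' @export
tidy.model_comparison <- function(x, ...) x$pairwise
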