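#' ReliefF feature weights for one participant's labeled windows
#'
#' Instance-based feature relevance. Features are range-normalized on the
#' supplied (training) data. For every evaluated instance the k nearest
#' hits (same class) and k nearest misses from each other class are found
#' under Manhattan distance in the normalized space; each feature's
#' weight is decreased by the mean hit difference and increased by the
#' prior-weighted mean miss difference:
#' \deqn{W_A \leftarrow W_A - \sum_j \frac{d(A, R_i, H_j)}{m k}
#'   + \sum_{C \ne cls(R_i)} \frac{P(C)}{1 - P(cls(R_i))}
#'     \sum_j \frac{d(A, R_i, M_j(C))}{m k}}
#' with \eqn{d(A, I_1, I_2) = |I_1[A] - I_2[A]| / (\max A - \min A)} and
#' empirical class priors. With range-normalized differences every weight
#' lies in `[-1, 1]`. Distance ties break deterministically toward the
#' lowest instance index, and zero-range features contribute zero
#' difference (weight 0).
#'
#' @param data Data frame/tibble of labeled instances.
#' @param features Feature column names (default: the 23 window features
#'   present in `data`).
#' @param label_col Name of the class-label column (default `"quadrant"`,
#'   falling back to `"class_label"` when absent).
#' @param k Number of neighbours per class (default 5). Every class must
#'   have more than `k` instances.
#' @param m Number of evaluated instances: `"all"` (default,
#'   deterministic and order-invariant) or an integer drawn without
#'   replacement under `seed`.
#' @param seed Seed for the instance draw when `m` is an integer.
#' @return A `relieff_weights` tibble with columns `feature`, `weight`
#'   and attributes `k`, `n`, `participant_id`.
#' @examples
#' d <- tibble::tibble(A = c(0, 0, 1, 1), B = 1, cls = c("a", "a", "b", "b"))
#' relieff(d, features = c("A", "B"), label_col = "cls", k = 1)
#' @export
relieff <- function(data, features = NULL, label_col = NULL, k = 5,
                    m = "all", seed = 1) {
  if (is.null(label_col))
    label_col <- if ("quadrant" %in% names(data)) "quadrant" else "class_label"
  if (!label_col %in% names(data))
    stopf("label column '%s' not found", label_col)
  if (is.null(features))
    features <- intersect(feature_names(), names(data))
  if (!length(features)) abort("no feature columns found")

  y <- as.character(data[[label_col]])
  X <- as.matrix(data[, features, drop = FALSE])
  storage.mode(X) <- "double"
  n <- nrow(X)
  classes <- sort(unique(y))
  if (length(classes) < 2L) abort("need at least 2 classes")
  counts <- table(factor(y, classes))
  low <- names(counts)[counts <= k]
  if (length(low))
    stopf("class '%s' has %d instance(s); ReliefF with k = %d needs > k per class",
          low[1], counts[[low[1]]], k)
  priors <- as.numeric(counts) / n
  names(priors) <- classes

  rng <- apply(X, 2, function(col) diff(range(col)))
  Xn <- X
  for (j in seq_along(rng))
    Xn[, j] <- if (rng[j] > 0) (X[, j] - min(X[, j])) / rng[j] else 0

  sampled <- if (identical(m, "all")) seq_len(n)
             else withr::with_seed(seed, sort(sample.int(n, min(m, n))))
  msize <- length(sampled)

  D <- as.matrix(stats::dist(Xn, method = "manhattan"))
  W <- numeric(length(features))
  for (cl in classes) {
    idx_c <- which(y == cl)
    Dc <- D[sampled, idx_c, drop = FALSE]
    own <- y[sampled] == cl
    if (any(own)) {
      # exclude self from its own class's neighbour pool
      self_col <- match(sampled[own], idx_c)
      Dc[cbind(which(own), self_col)] <- Inf
    }
    nbr <- matrix(0L, msize, k)
    for (r in seq_len(msize))
      nbr[r, ] <- idx_c[order(Dc[r, ])[seq_len(k)]]
    coef <- ifelse(own, -1, priors[cl] / (1 - priors[y[sampled]]))
    ii <- rep(sampled, times = k)
    jj <- as.vector(nbr)
    cc <- rep(coef, times = k)
    W <- W + colSums(abs(Xn[ii, , drop = FALSE] - Xn[jj, , drop = FALSE]) * cc)
  }
  out <- tibble(feature = features, weight = unname(W) / (msize * k))
  pid <- if ("participant_id" %in% names(data))
    unique(data[["participant_id"]]) else NA_character_
  structure(out, class = c("relieff_weights", class(out)),
            k = k, n = n, participant_id = pid)
}

#' @export
print.relieff_weights <- function(x, ...) {
  cat(sprintf("<relieff_weights> k = %d, %d instances\n",
              attr(x, "k"), attr(x, "n")))
  NextMethod()
}

#' @method tidy relieff_weights
#' @export
tidy.relieff_weights <- function(x, ...) {
  tibble(feature = x$feature, weight = x$weight, k = attr(x, "k"),
         participant_id = attr(x, "participant_id")[1])
}

#' ReliefF weights across several neighbourhood sizes
#'
#' Runs [relieff()] for each `k` and reports, per k, the weights and the
#' set of positive-weight features, to check that the selected set is
#' insensitive to k.
#'
#' @inheritParams relieff
#' @param k_values Integer vector of neighbour counts (default
#'   `c(1, 3, 5, 10)`).
#' @return A `relieff_stability` tibble with columns `k`, `feature`,
#'   `weight`, `positive`.
#' @export
weight_stability_report <- function(data, features = NULL, label_col = NULL,
                                    k_values = c(1, 3, 5, 10), ...) {
  rows <- lapply(k_values, function(kk) {
    w <- relieff(data, features = features, label_col = label_col,
                 k = kk, ...)
    tibble(k = kk, feature = w$feature, weight = w$weight,
           positive = w$weight > 0)
  })
  out <- bind_rows(rows)
  structure(out, class = c("relieff_stability", class(out)))
}

#' Positive-weight feature sets per k
#'
#' @param report A `relieff_stability` object.
#' @return Named list (one element per k) of positive-weight features.
#' @export
positive_sets <- function(report) {
  lapply(split(report, report$k),
         function(d) d$feature[d$positive])
}

#' Cross-participant optimal feature set (median-positive rule)
#'
#' Aggregates per-participant ReliefF weights by the per-feature median
#' across participants; the features with strictly positive median define
#' the global optimal set, ordered by descending median weight.
#'
#' @param weights A list of `relieff_weights`, or a long tibble with
#'   columns `participant_id`, `feature`, `weight`.
#' @return An `optimal_feature_set`: list with `features` (ordered
#'   character vector) and `medians` (tibble `feature`, `median_weight`,
#'   `selected`).
#' @export
optimal_feature_set <- function(weights) {
  long <- if (is.data.frame(weights)) as_tibble(weights)
          else bind_rows(lapply(weights, tidy))
  if (!all(c("feature", "weight") %in% names(long)))
    abort("weights must provide 'feature' and 'weight'")
  if ("participant_id" %in% names(long)) {
    cross <- table(long$participant_id, long$feature)
    if (any(cross != 1L))
      abort("participants report inconsistent feature sets")
  }
  per_feat <- split(long$weight, long$feature)
  if (length(unique(lengths(per_feat))) != 1L)
    abort("participants report inconsistent feature sets")
  med <- vapply(per_feat, median, numeric(1))
  ord <- order(-med, names(med))
  medians <- tibble(feature = names(med)[ord],
                    median_weight = unname(med)[ord],
                    selected = unname(med)[ord] > 0)
  structure(list(features = medians$feature[medians$selected],
                 medians = medians),
            class = "optimal_feature_set")
}

#' @export
print.optimal_feature_set <- function(x, ...) {
  cat(sprintf("<optimal_feature_set> %d of %d features with positive median weight:\n",
              length(x$features), nrow(x$medians)))
  cat(" ", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy optimal_feature_set
#' @export
tidy.optimal_feature_set <- function(x, ...) x$medians

#' @method glance optimal_feature_set
#' @export
glance.optimal_feature_set <- function(x, ...) {
  tibble(n_selected = length(x$features), n_features = nrow(x$medians))
}
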