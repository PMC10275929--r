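# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

# naive ReliefF: explicit loops over instances, classes and neighbours
oracle_relieff <- function(X, y, k) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  priors <- sapply(classes, function(cl) mean(y == cl))
  rng <- apply(X, 2, function(col) max(col) - min(col))
  mins <- apply(X, 2, min)
  norm1 <- function(v) {
    out <- numeric(p)
    for (j in 1:p) out[j] <- if (rng[j] > 0) (v[j] - mins[j]) / rng[j] else 0
    out
  }
  Xn <- t(apply(X, 1, norm1))
  manhattan <- function(a, b) sum(abs(Xn[a, ] - Xn[b, ]))
  W <- numeric(p)
  for (i in 1:n) {
    for (cl in classes) {
      cand <- setdiff(which(y == cl), i)
      dists <- sapply(cand, function(j) manhattan(i, j))
      nb <- cand[order(dists)[1:k]]
      dd <- numeric(p)
      for (j in nb) dd <- dd + abs(Xn[i, ] - Xn[j, ])
      if (cl == y[i]) W <- W - dd
      else W <- W + (priors[cl] / (1 - priors[y[i]])) * dd
    }
  }
  W / (n * k)
}

oracle_sdnn <- function(x) sqrt(mean((x - mean(x))^2))
oracle_rmssd <- function(x) {
  d <- x[-1] - x[-length(x)]
  sqrt(mean(d^2))
}

oracle_accuracy <- function(truth, pred) mean(truth == pred)
oracle_macro_f <- function(truth, pred) {
  classes <- sort(unique(truth))
  f <- sapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    prec <- if (sum(pred == cl) > 0) tp / sum(pred == cl) else 0
    rec <- tp / sum(truth == cl)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  })
  mean(f)
}

# random labeled dataset for ReliefF equivalence checks
random_relieff_case <- function(seed) {
  withr::with_seed(seed, {
    p <- sample(2:6, 1)
    n_cls <- sample(2:3, 1)
    k <- sample(1:2, 1)
    n <- sample((n_cls * (k + 1)):30, 1) # every class must have > k members
    repeat {
      y <- sample(letters[1:n_cls], n, replace = TRUE)
      if (length(unique(y)) == n_cls && min(table(y)) > k) break
    }
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", 1:p)))
    if (runif(1) < 0.3) X[, 1] <- 1 # zero-range feature
    list(X = X, y = y, k = k)
  })
}
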