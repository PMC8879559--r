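# Classification: k-nearest-neighbour and Gaussian naive Bayes, evaluated
# by stratified k-fold cross-validation. The correction rate is the
# percentage of trials assigned their true class; it is accumulated with a
# confusion matrix over all folds.

#' k-nearest-neighbour prediction
#'
#' Majority vote among the `k` Euclidean-nearest training rows. Ties are
#' broken deterministically: among the tied classes, the one whose member
#' is nearest to the query wins; any residual tie goes to the lowest class
#' id.
#'
#' @param train_features numeric matrix, training observations in rows.
#' @param train_labels integer labels, one per training row.
#' @param query numeric vector (one observation) or matrix of queries in
#'   rows.
#' @param k neighbourhood size, `1 <= k <= nrow(train_features)`.
#' @return integer vector of predicted labels, one per query row.
#' @export
knn_predict <- function(train_features, train_labels, query, k) {
  train_features <- as.matrix(train_features)
  if (is.vector(query)) query <- matrix(query, nrow = 1)
  query <- as.matrix(query)
  n <- nrow(train_features)
  if (k < 1 || k > n) stop("k must be between 1 and the training size ", n)
  if (!all(is.finite(train_features)) || !all(is.finite(query))) {
    stop("features must be finite")
  }
  train_labels <- as.integer(train_labels)
  vapply(seq_len(nrow(query)), function(i) {
    d2 <- rowSums(sweep(train_features, 2, query[i, ])^2)
    ord <- order(d2, train_labels)  # distance, then class id (stable)
    nb <- ord[seq_len(k)]
    votes <- table(train_labels[nb])
    top <- as.integer(names(votes)[votes == max(votes)])
    if (length(top) == 1) return(top)
    # tie: class whose nearest member (within the neighbourhood) is closest
    best_d <- vapply(top, function(cl) min(d2[nb][train_labels[nb] == cl]),
                     numeric(1))
    top[order(best_d, top)][1]
  }, integer(1))
}

#' Gaussian naive Bayes
#'
#' Class-conditionally independent Gaussian model per feature. Class
#' priors are the training frequencies. Zero within-class variances are
#' floored at `var_floor_rel` times the pooled global variance of the
#' feature (so degenerate features cannot produce infinite likelihoods).
#'
#' @param features numeric matrix, observations in rows.
#' @param labels integer class labels (>= 2 samples per class).
#' @param var_floor_rel relative variance floor (default 1e-9).
#' @return object of class `nb_model`.
#' @export
naive_bayes_fit <- function(features, labels, var_floor_rel = 1e-9) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  stopifnot(nrow(features) == length(labels))
  classes <- sort(unique(labels))
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2)) {
    stop("every class needs >= 2 samples for variance estimation")
  }
  global_var <- apply(features, 2, stats::var)
  floor_val <- pmax(var_floor_rel * global_var, .Machine$double.xmin)
  means <- t(vapply(classes, function(cl) {
    colMeans(features[labels == cl, , drop = FALSE])
  }, numeric(ncol(features))))
  vars <- t(vapply(classes, function(cl) {
    v <- apply(features[labels == cl, , drop = FALSE], 2, stats::var)
    pmax(v, floor_val)
  }, numeric(ncol(features))))
  structure(list(classes = classes, prior = as.numeric(counts) / sum(counts),
                 means = means, vars = vars),
            class = "nb_model")
}

#' @rdname naive_bayes_fit
#' @param model an `nb_model`.
#' @param query numeric vector or matrix of queries in rows.
#' @param type `"class"` (default) for labels, `"posterior"` for the
#'   normalized posterior probability matrix (rows sum to 1).
#' @return predicted labels, or a posterior matrix for
#'   `type = "posterior"`. Posterior ties break to the lowest class id.
#' @export
naive_bayes_predict <- function(model, query, type = c("class", "posterior")) {
  type <- match.arg(type)
  stopifnot(inherits(model, "nb_model"))
  if (is.vector(query)) query <- matrix(query, nrow = 1)
  query <- as.matrix(query)
  loglik <- vapply(seq_along(model$classes), function(ci) {
    mu <- model$means[ci, ]
    v <- model$vars[ci, ]
    rowSums(sweep(-0.5 * sweep(query, 2, mu)^2, 2, v, "/")) -
      0.5 * sum(log(2 * pi * v)) + log(model$prior[ci])
  }, numeric(nrow(query)))
  loglik <- matrix(loglik, nrow = nrow(query))
  if (type == "posterior") {
    mx <- apply(loglik, 1, max)
    p <- exp(loglik - mx)
    p <- p / rowSums(p)
    colnames(p) <- model$classes
    return(p)
  }
  # which.max takes the first maximum; classes are sorted ascending, so
  # ties resolve to the lowest class id
  model$classes[apply(loglik, 1, which.max)]
}

#' @export
print.nb_model <- function(x, ...) {
  cat("Gaussian naive Bayes: ", length(x$classes), " classes, ",
      ncol(x$means), " features\n", sep = "")
  invisible(x)
}

# stratified fold assignment: per class, seeded shuffle then round-robin
.stratified_folds <- function(labels, n_folds, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep(seq_len(n_folds), length.out = length(idx))
    }
  })
  fold
}

#' Cross-validated classification
#'
#' Stratified `n_folds`-fold cross-validation of a classifier on a feature
#' table. Folds are assigned per class from a seeded shuffle, so fold
#' class proportions match the overall proportions within one trial. The
#' correction rate is `R = N_tp / N_t * 100` (percentage of trials
#' classified into their true class), accumulated with the confusion
#' matrix over all folds.
#'
#' @param features a [feature_table()], or a numeric matrix (then `labels`
#'   must be given).
#' @param classifier `"knn"` or `"nb"`.
#' @param k neighbourhood size for KNN (ignored for `"nb"`).
#' @param n_folds number of folds (default 10; every class must have at
#'   least `n_folds` members).
#' @param seed seed for the fold shuffle.
#' @param labels class labels when `features` is a bare matrix.
#' @return object of class `cv_result`: `accuracy` (percent), `confusion`
#'   (true x predicted counts), `fold_accuracy`, `classifier`, `k`,
#'   `n_folds`, `seed`, `n_correct`, `n_total`.
#' @export
cross_validate <- function(features, classifier = c("knn", "nb"), k = 1,
                           n_folds = 10, seed = 1, labels = NULL) {
  classifier <- match.arg(classifier)
  if (inherits(features, "feature_table")) {
    labels <- features$labels
    x <- features$values
  } else {
    x <- as.matrix(features)
    if (is.null(labels)) stop("labels required for matrix input")
    labels <- as.integer(labels)
  }
  classes <- sort(unique(labels))
  min_count <- min(table(labels))
  if (min_count < n_folds) {
    stop("smallest class has ", min_count, " members; use n_folds <= ",
         min_count)
  }
  fold <- .stratified_folds(labels, n_folds, seed)
  pred <- integer(length(labels))
  fold_acc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    test_i <- which(fold == f)
    train_i <- which(fold != f)
    p <- if (classifier == "knn") {
      knn_predict(x[train_i, , drop = FALSE], labels[train_i],
                  x[test_i, , drop = FALSE], k = k)
    } else {
      m <- naive_bayes_fit(x[train_i, , drop = FALSE], labels[train_i])
      naive_bayes_predict(m, x[test_i, , drop = FALSE])
    }
    pred[test_i] <- p
    fold_acc[f] <- mean(p == labels[test_i]) * 100
  }
  conf <- table(factor(labels, levels = classes),
                factor(pred, levels = classes))
  dimnames(conf) <- list(true = classes, predicted = classes)
  n_correct <- sum(diag(conf))
  structure(list(accuracy = n_correct / length(labels) * 100,
                 confusion = unclass(conf), fold_accuracy = fold_acc,
                 classifier = classifier,
                 k = if (classifier == "knn") k else NA_integer_,
                 n_folds = n_folds, seed = seed,
                 n_correct = n_correct, n_total = length(labels)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result: ", x$classifier,
      if (x$classifier == "knn") paste0(" (k = ", x$k, ")"), ", ",
      x$n_folds, "-fold\n  correction rate: ",
      sprintf("%.2f%%", x$accuracy), " (", x$n_correct, "/", x$n_total,
      ")\n", sep = "")
  invisible(x)
}

#' Biased cross-correlation profile
#'
#' `R_xy(m) = (1/N) * sum_n x(n + m) y(n)` over lags
#' `-max_lag..max_lag` (biased normalization; out-of-range products are
#' zero). For `x == y` the profile peaks at lag 0 with value equal to the
#' signal energy divided by N.
#'
#' @param x,y numeric vectors of equal length.
#' @param max_lag largest lag magnitude (< length).
#' @return object of class `correlation_profile`: `lags`, `values`,
#'   `peak_lag`, `peak_value`.
#' @export
cross_correlation <- function(x, y, max_lag) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (max_lag >= n) stop("max_lag must be smaller than the signal length")
  lags <- (-max_lag):max_lag
  vals <- vapply(lags, function(m) {
    if (m >= 0) {
      sum(x[(1 + m):n] * y[1:(n - m)]) / n
    } else {
      sum(x[1:(n + m)] * y[(1 - m):n]) / n
    }
  }, numeric(1))
  peak <- which.max(abs(vals))
  structure(list(lags = lags, values = vals, peak_lag = lags[peak],
                 peak_value = vals[peak]),
            class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat("correlation_profile: lags ", min(x$lags), "..", max(x$lags),
      ", peak ", signif(x$peak_value, 4), " at lag ", x$peak_lag, "\n",
      sep = "")
  invisible(x)
}
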