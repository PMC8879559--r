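# Classifiers, cross-validation, cross-correlation.

test_that("KNN matches a brute-force oracle and breaks ties as documented", {
  set.seed(80)
  # exact-match query at k = 1
  x <- matrix(rnorm(40), 20)
  lab <- rep(1:4, 5)
  expect_equal(knn_predict(x, lab, x[7, ], k = 1), lab[7])

  # brute-force oracle over random cases
  for (case in 1:40) {
    tr <- matrix(rnorm(30 * 3), 30)
    lab <- sample(1:3, 30, replace = TRUE)
    q <- rnorm(3)
    for (k in c(1, 4, 7, 10)) {
      d <- sqrt(colSums((t(tr) - q)^2))
      nb <- order(d, lab)[1:k]
      votes <- table(lab[nb])
      top <- as.integer(names(votes)[votes == max(votes)])
      expected <- if (length(top) == 1) top else {
        nd <- vapply(top, function(cl) min(d[nb][lab[nb] == cl]), 1)
        top[order(nd, top)][1]
      }
      expect_identical(knn_predict(tr, lab, q, k = k), expected)
    }
  }

  # residual tie goes to the lowest class id: two classes, symmetric
  tr <- matrix(c(-1, 1), 2)
  expect_equal(knn_predict(tr, c(2L, 5L), 0, k = 2), 2L)

  expect_error(knn_predict(tr, c(1, 2), 0, k = 3), "between 1 and")
  expect_error(knn_predict(tr, c(1, 2), 0, k = 0), "between 1 and")
})

test_that("KNN with k = n_train predicts the modal class everywhere", {
  set.seed(81)
  x <- matrix(rnorm(22 * 2), 22)
  lab <- c(rep(1, 5), rep(2, 10), rep(3, 7))
  q <- matrix(rnorm(10 * 2), 10)
  expect_true(all(knn_predict(x, lab, q, k = 22) == 2))
})

test_that("naive Bayes separates distant classes and matches hand posterior", {
  set.seed(82)
  x <- rbind(matrix(rnorm(28, -10), 14), matrix(rnorm(28, 10), 14))
  lab <- rep(1:2, each = 14)
  m <- naive_bayes_fit(x, lab)
  expect_equal(naive_bayes_predict(m, c(-10, -10)), 1L)
  expect_equal(naive_bayes_predict(m, c(10, 10)), 2L)

  # hand-computed two-feature, two-class Gaussian posterior
  q <- c(1, -2)
  post <- naive_bayes_predict(m, q, type = "posterior")
  loglik <- vapply(1:2, function(ci) {
    sum(dnorm(q, m$means[ci, ], sqrt(m$vars[ci, ]), log = TRUE)) +
      log(m$prior[ci])
  }, 1)
  hand <- exp(loglik - max(loglik))
  hand <- hand / sum(hand)
  expect_equal(as.vector(post), hand, tolerance = 1e-9)
  expect_equal(sum(post), 1, tolerance = 1e-12)
})

test_that("naive Bayes ties break to the lowest class id", {
  # symmetric classes, equal priors, query at the midpoint
  x <- rbind(matrix(c(-2, -1, -1, -2), 2), matrix(c(1, 2, 2, 1), 2))
  x <- cbind(x, x)
  lab <- c(3L, 3L, 7L, 7L)
  m <- naive_bayes_fit(x, lab)
  expect_equal(naive_bayes_predict(m, rep(0, 4)), 3L)
})

test_that("naive Bayes agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(83)
  x <- matrix(rnorm(60 * 4), 60)
  x[1:30, 1] <- x[1:30, 1] + 2
  lab <- rep(1:2, each = 30)
  ours <- naive_bayes_fit(x, lab)
  theirs <- e1071::naiveBayes(x, factor(lab))
  q <- matrix(rnorm(20 * 4), 20)
  q[1:10, 1] <- q[1:10, 1] + 2
  p_ours <- naive_bayes_predict(ours, q)
  p_theirs <- as.integer(as.character(predict(theirs, q)))
  expect_equal(p_ours, p_theirs)
})

test_that("zero-variance features are floored, not fatal", {
  x <- cbind(rep(1, 8), rnorm(8))
  lab <- rep(1:2, each = 4)
  expect_no_error(m <- naive_bayes_fit(x, lab))
  expect_true(all(m$vars > 0))
  expect_error(naive_bayes_fit(x[c(1, 5), ], c(1, 2)), ">= 2 samples")
})

test_that("cross-validation is stratified, exhaustive and seeded", {
  set.seed(84)
  labels <- rep(1:6, each = 20)
  fold <- emgmpca:::.stratified_folds(labels, 10, seed = 2)
  expect_setequal(unique(fold), 1:10)
  # folds partition the data with exact per-class balance (20 = 2 x 10)
  for (f in 1:10) {
    expect_equal(as.vector(table(labels[fold == f])), rep(2, 6))
  }
  expect_identical(fold, emgmpca:::.stratified_folds(labels, 10, seed = 2))
})

test_that("separable clusters give perfect accuracy, permuted labels chance", {
  fx <- fix_separable_features(n_per_class = 20, sep = 50, seed = 85)
  res <- cross_validate(fx$x, "knn", k = 1, n_folds = 10, seed = 3,
                        labels = fx$labels)
  expect_equal(res$accuracy, 100)
  expect_equal(sum(diag(res$confusion)), res$n_total)

  # permuted labels: chance level 1/6 within 3 binomial SDs
  set.seed(86)
  perm <- sample(fx$labels)
  res_p <- cross_validate(fx$x, "knn", k = 1, n_folds = 10, seed = 3,
                          labels = perm)
  p0 <- 1 / 6
  band <- 3 * sqrt(p0 * (1 - p0) / length(perm)) * 100
  expect_lt(abs(res_p$accuracy - p0 * 100), band)

  # confusion-matrix row sums equal per-class counts
  expect_equal(rowSums(res_p$confusion),
               as.vector(table(perm)), ignore_attr = TRUE)

  # 25 rows leave the second class with only 5 members
  expect_error(cross_validate(fx$x[1:25, ], "knn", labels = fx$labels[1:25],
                              n_folds = 10), "n_folds")
})

test_that("accuracy is invariant under feature-column permutation", {
  fx <- fix_separable_features(n_per_class = 12, sep = 5, seed = 87)
  perm_cols <- sample(ncol(fx$x))
  for (clf in c("knn", "nb")) {
    a <- cross_validate(fx$x, clf, k = 4, n_folds = 6, seed = 5,
                        labels = fx$labels)$accuracy
    b <- cross_validate(fx$x[, perm_cols], clf, k = 4, n_folds = 6,
                        seed = 5, labels = fx$labels)$accuracy
    expect_equal(a, b)
  }
})

test_that("cross-correlation matches definition, shift and dense oracle", {
  # unit impulse: peak 1/N at lag 0
  x <- c(1, numeric(15))
  pr <- cross_correlation(x, x, 5)
  expect_equal(pr$peak_lag, 0)
  expect_equal(pr$peak_value, 1 / 16)
  expect_equal(pr$values[pr$lags != 0], numeric(10))

  # shift property under R_xy(m) = E{x(n+m) y(n)}: if y lags x by d
  # samples, y(n+d) aligns with x(n), so R_yx peaks at +d
  set.seed(88)
  base <- rnorm(400)
  d <- 7
  y <- c(numeric(d), base[1:(400 - d)])
  pr <- cross_correlation(y, base, 20)
  expect_equal(pr$peak_lag, d)

  # brute-force double-loop oracle
  a <- rnorm(64)
  b <- rnorm(64)
  pr <- cross_correlation(a, b, 10)
  oracle <- vapply(-10:10, function(m) {
    acc <- 0
    for (n in 1:64) {
      if (n + m >= 1 && n + m <= 64) acc <- acc + a[n + m] * b[n]
    }
    acc / 64
  }, 1)
  expect_equal(pr$values, oracle, tolerance = 1e-12)

  expect_error(cross_correlation(a, b[1:10], 5), "equal length")
  expect_error(cross_correlation(a, b, 64), "smaller")
})
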