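# Multiscale PCA: band decomposition, retention rule, monitoring
# statistics, scale relevance, and the denoiser.

test_that("band decomposition inverts exactly and handles zero input", {
  sig <- fix_signal(n = 1000, seed = 30)
  bands <- decompose_bands(sig, "sym4", 5)
  rec <- reconstruct_bands(bands)
  expect_equal(rec$samples, sig$samples, tolerance = 1e-10)

  z <- emg_signal(matrix(0, 2, 512), 500)
  bz <- decompose_bands(z, "sym4", 4)
  expect_true(all(bz$A == 0) && all(vapply(bz$D, function(d) all(d == 0),
                                           TRUE)))
})

test_that("retention rule keeps eigenvalues above the 5% fraction", {
  # columns with exact biased-covariance eigenvalues {10, 1, 0.1}:
  # threshold 0.05 * 11.1 = 0.555 -> k = 2
  n <- 64
  set.seed(31)
  Q <- qr.Q(qr(matrix(rnorm(n * 3), n)))  # orthonormal columns
  X <- Q %*% diag(sqrt(n * c(10, 1, 0.1)))
  X <- sweep(X, 2, colMeans(X))  # recenter: eigenvalues only approximate
  mod <- fit_pca_retain(X, retain_fraction = 0.05)
  ev <- sort(mod$eigenvalues, decreasing = TRUE)
  expect_equal(sum(ev > 0.05 * sum(ev)), 2)
  expect_equal(mod$k, 2)

  # identity covariance, 2 channels: equal eigenvalues, both retained
  set.seed(32)
  Z <- matrix(rnorm(4000), ncol = 2)
  mod2 <- fit_pca_retain(Z)
  expect_equal(mod2$k, 2)

  # eigenvectors match a dense eigendecomposition oracle up to sign
  set.seed(33)
  Y <- matrix(rnorm(300), ncol = 3)
  mod3 <- fit_pca_retain(Y)
  C <- crossprod(sweep(Y, 2, colMeans(Y))) / nrow(Y)
  oracle <- eigen(C, symmetric = TRUE)
  for (j in 1:3) {
    expect_equal(abs(sum(mod3$loadings[, j] * oracle$vectors[, j])), 1,
                 tolerance = 1e-9)
  }
  expect_equal(mod3$eigenvalues, oracle$values, tolerance = 1e-9)

  expect_warning(fit_pca_retain(matrix(1, 10, 2)), "constant")
})

test_that("T-squared matches its defining formula and boundary cases", {
  set.seed(34)
  X <- matrix(rnorm(500 * 4), ncol = 4)
  mod <- fit_pca_retain(X, retain_fraction = 0)
  # model mean has T2 = 0
  expect_equal(t2_statistic(mod$mean, mod), 0, tolerance = 1e-12)
  # centered row sqrt(lambda_j) p_j has T2 = 1
  for (j in seq_len(mod$k)) {
    row <- mod$mean + sqrt(mod$eigenvalues[j]) * mod$loadings[, j]
    expect_equal(t2_statistic(row, mod), 1, tolerance = 1e-9)
  }
  # brute-force oracle: explicit score/eigenvalue sum
  t2 <- t2_statistic(X, mod)
  xc <- sweep(X, 2, mod$mean)
  oracle <- apply(xc, 1, function(r) {
    s <- as.vector(r %*% mod$loadings[, seq_len(mod$k)])
    sum(s^2 / mod$eigenvalues[seq_len(mod$k)])
  })
  expect_equal(t2, oracle, tolerance = 1e-10)
})

test_that("T-squared control limit follows the F-quantile formula", {
  expect_equal(t2_control_limit(2, 100, 0.05),
               2 * 99 * 101 / (100 * 98) * qf(0.95, 2, 98),
               tolerance = 1e-12)
  # monotone in alpha; vanishes as alpha -> 1
  expect_gt(t2_control_limit(2, 100, 0.01), t2_control_limit(2, 100, 0.05))
  expect_lt(t2_control_limit(2, 100, 0.999), 0.01)
  expect_error(t2_control_limit(3, 3), "more observations")
})

test_that("SPE is the residual energy and vanishes on retained subspace", {
  set.seed(35)
  X <- matrix(rnorm(400 * 4), ncol = 4)
  mod <- fit_pca_retain(X, retain_fraction = 0)  # k = 4 = m_dim
  expect_equal(spe_statistic(X, mod), numeric(nrow(X)))
  expect_equal(spe_control_limit(mod), 0)

  mod$k <- 2L
  # rows inside the retained subspace have SPE = 0
  row <- mod$mean + 3 * mod$loadings[, 1] - 2 * mod$loadings[, 2]
  expect_equal(spe_statistic(row, mod), 0, tolerance = 1e-18)
  # residual direction contributes its squared norm
  row2 <- mod$mean + 2 * mod$loadings[, 4]
  expect_equal(spe_statistic(row2, mod), 4, tolerance = 1e-9)
  expect_gt(spe_control_limit(mod, 0.05), 0)
})

test_that("relevance factors flag burst-carrying scales only", {
  set.seed(36)
  sig <- emg_signal(matrix(rnorm(2 * 2048), 2), 500)
  bands <- decompose_bands(sig, "sym4", 4)
  models <- lapply(bands$D, fit_pca_retain)
  mu_noise <- relevance_factors(bands, models, alpha = 0.05,
                                exceed_fraction = 0.1)
  expect_true(all(mu_noise == 0))

  # burst loading both the retained and the residual subspace of scale 2
  # (three channels: anisotropic base + rows exceeding T2 and SPE jointly)
  sig3 <- emg_signal(matrix(rnorm(3 * 2048), 3), 500)
  b2 <- decompose_bands(sig3, "sym4", 4)
  n2 <- nrow(b2$D[[2]])
  b2$D[[2]] <- matrix(rnorm(n2 * 3), n2) %*% diag(c(3, 1, 0.7))
  idx <- 100:120
  b2$D[[2]][idx, 1] <- b2$D[[2]][idx, 1] + 20  # retained direction
  b2$D[[2]][idx, 3] <- b2$D[[2]][idx, 3] + 5   # residual direction
  models2 <- lapply(b2$D, fit_pca_retain)
  expect_lt(models2[[2]]$k, 3)  # residual subspace exists
  mu_burst <- relevance_factors(b2, models2, alpha = 0.05,
                                exceed_fraction = 0.005)
  expect_equal(mu_burst[2], 1L)
})

test_that("mpca_denoise passes degenerate inputs through sensibly", {
  z <- emg_signal(matrix(0, 2, 512), 500)
  expect_equal(suppressWarnings(mpca_denoise(z))$signal$samples, z$samples)

  one <- emg_signal(matrix(rnorm(512), 1), 500)
  expect_warning(res <- mpca_denoise(one), "single-channel")
  expect_identical(res$signal$samples, one$samples)
})

test_that("all-retained, all-relevant MPCA is the identity", {
  sig <- fix_signal(n = 1024, seed = 37)
  res <- mpca_denoise(sig, retain_fraction = 0, mu = rep(1L, 5))
  expect_equal(res$signal$samples, sig$samples, tolerance = 1e-8)
})

test_that("denoising improves SNR at 0 dB and approaches idempotence", {
  fx <- fix_clean_noisy(snr_db = 0, seed = 38)
  den1 <- mpca_denoise(fx$noisy)$signal
  mse_in <- mean((fx$noisy$samples - fx$clean)^2)
  mse_out <- mean((den1$samples - fx$clean)^2)
  expect_lt(mse_out, mse_in)

  # a second pass changes the signal less than the first did
  den2 <- mpca_denoise(den1)$signal
  d1 <- sum((den1$samples - fx$noisy$samples)^2)
  d2 <- sum((den2$samples - den1$samples)^2)
  expect_lt(d2, d1)
})

test_that("diagnostics table matches the decomposition geometry", {
  sig <- fix_signal(n = 1024, seed = 39)
  res <- mpca_denoise(sig, level = 4)
  diag_df <- mpca_diagnostics(res)
  expect_setequal(unique(diag_df$scale), 1:4)
  n_rows <- vapply(decompose_bands(sig, "sym4", 4)$D, nrow, 1L)
  expect_equal(as.vector(table(diag_df$scale)), as.vector(n_rows))
  expect_true(all(diag_df$t2 >= 0) && all(diag_df$spe >= 0))
})
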