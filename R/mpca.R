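# Multiscale PCA denoising.
#
# Each channel is decomposed with an orthogonal DWT; the coefficients of
# every scale are collected into a (coefficient x channel) matrix; each
# matrix is denoised by projecting onto its retained principal components
# and back; detail scales are then kept or zeroed by a relevance factor
# driven by Hotelling T-squared and SPE monitoring statistics against
# F-distribution and Jackson-Mudholkar control limits; finally the inverse
# DWT rebuilds the signal.

#' Per-channel wavelet band decomposition
#'
#' Decomposes every channel of a multi-channel signal to `level` scales and
#' collects the approximation and per-scale detail coefficients into
#' coefficient-by-channel matrices (`A_L`, `D_1..D_L`), the layout on which
#' the per-scale PCA operates.
#'
#' @param x an [emg_signal()] or channels x time matrix.
#' @param wavelet orthogonal wavelet name (default `"sym4"`, the
#'   least-asymmetric Daubechies family).
#' @param level decomposition depth L.
#' @param fs_hz sampling rate if `x` is a bare matrix.
#' @return object of class `wavelet_band_set`: list with `A` (matrix),
#'   `D` (list of matrices, `D[[l]]` = scale l, finest first), `wavelet`,
#'   `level`, `n`, `fs_hz`, `boundary`.
#' @export
decompose_bands <- function(x, wavelet = "sym4", level = 5, fs_hz = NULL) {
  if (inherits(x, "emg_signal")) {
    fs_hz <- x$fs_hz
    m <- x$samples
  } else {
    m <- as.matrix(x)
    if (is.null(fs_hz)) fs_hz <- NA_real_
  }
  per_ch <- lapply(seq_len(nrow(m)), function(ch) {
    dwt(m[ch, ], wavelet = wavelet, level = level)
  })
  A <- vapply(per_ch, function(cf) cf$a, numeric(length(per_ch[[1]]$a)))
  D <- lapply(seq_len(level), function(l) {
    vapply(per_ch, function(cf) cf$d[[l]],
           numeric(length(per_ch[[1]]$d[[l]])))
  })
  structure(list(A = as.matrix(A), D = lapply(D, as.matrix),
                 wavelet = wavelet, level = level, n = ncol(m),
                 fs_hz = fs_hz, boundary = "periodized"),
            class = "wavelet_band_set")
}

#' Rebuild a multi-channel signal from a wavelet band set
#'
#' Inverse of [decompose_bands()]: applies the inverse DWT channel by
#' channel. An untouched band set reproduces the original signal exactly up
#' to floating point.
#'
#' @param bands a `wavelet_band_set`.
#' @return an [emg_signal()] (or a matrix when `fs_hz` is unknown).
#' @export
reconstruct_bands <- function(bands) {
  stopifnot(inherits(bands, "wavelet_band_set"))
  n_ch <- ncol(bands$A)
  out <- matrix(0, n_ch, bands$n)
  for (ch in seq_len(n_ch)) {
    cf <- structure(list(a = bands$A[, ch],
                         d = lapply(bands$D, function(Dl) Dl[, ch]),
                         wavelet = bands$wavelet, level = bands$level,
                         n = bands$n, boundary = bands$boundary),
                    class = "dwt_coefficients")
    out[ch, ] <- idwt(cf)
  }
  if (is.na(bands$fs_hz)) out else emg_signal(out, bands$fs_hz)
}

#' @export
print.wavelet_band_set <- function(x, ...) {
  cat("wavelet_band_set (", x$wavelet, "), level ", x$level, ", ",
      ncol(x$A), " channel(s), signal length ", x$n, "\n", sep = "")
  invisible(x)
}

#' PCA with eigenvalue-fraction retention
#'
#' Eigendecomposition of the (biased, 1/n) column covariance of a
#' coefficient matrix, rows as observations. A component is retained when
#' its eigenvalue exceeds `retain_fraction` times the sum of all
#' eigenvalues (heuristic retention rule); at least one component is always
#' kept.
#'
#' @param x numeric matrix with >= 2 rows (observations) and columns as
#'   channels/variables.
#' @param retain_fraction eigenvalue-sum fraction threshold (default 0.05).
#' @return object of class `pca_model`: `mean`, `loadings` (orthonormal
#'   columns), `eigenvalues` (descending), `k` (retained count), `m_dim`.
#' @export
fit_pca_retain <- function(x, retain_fraction = 0.05) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows to estimate covariance")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  C <- crossprod(xc) / nrow(x)
  eig <- eigen(C, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  total <- sum(lambda)
  if (total <= 0) {
    warning("constant matrix: zero covariance; retaining one component")
    k <- 1L
  } else {
    k <- sum(lambda > retain_fraction * total)
    if (k < 1) k <- 1L
  }
  structure(list(mean = mu, loadings = eig$vectors, eigenvalues = lambda,
                 k = as.integer(k), m_dim = ncol(x), n_obs = nrow(x)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("pca_model: dim ", x$m_dim, ", retained k = ", x$k,
      ", eigenvalues: ", paste(signif(x$eigenvalues, 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Hotelling T-squared statistic
#'
#' Mahalanobis-type distance of each row in the retained principal
#' subspace: `T2 = sum_j (score_j^2 / lambda_j)` over the first k
#' components, after centering by the model mean.
#'
#' @param x numeric vector (one observation) or matrix of observations in
#'   rows.
#' @param model a [fit_pca_retain()] model.
#' @return numeric vector of nonnegative T-squared values, one per row.
#' @export
t2_statistic <- function(x, model) {
  stopifnot(inherits(model, "pca_model"))
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  k <- model$k
  lam <- model$eigenvalues[seq_len(k)]
  if (any(lam <= 0)) stop("retained eigenvalue is zero: rank-deficient model")
  xc <- sweep(x, 2, model$mean)
  scores <- xc %*% model$loadings[, seq_len(k), drop = FALSE]
  as.vector(scores^2 %*% (1 / lam))
}

#' T-squared control limit
#'
#' Upper control limit of the Hotelling T-squared statistic at significance
#' level alpha: `k (m-1)(m+1) / (m (m-k))` times the upper-alpha quantile
#' of the F distribution with `(k, m-k)` degrees of freedom, where `m` is
#' the number of observation rows the model was fitted on.
#'
#' @param k number of retained components (>= 1).
#' @param m number of observations (> k).
#' @param alpha significance level in (0, 1), default 0.05.
#' @return the control limit (positive scalar).
#' @export
t2_control_limit <- function(k, m, alpha = 0.05) {
  stopifnot(k >= 1, alpha > 0, alpha < 1)
  if (m <= k) stop("need more observations m than retained components k")
  k * (m - 1) * (m + 1) / (m * (m - k)) *
    stats::qf(1 - alpha, k, m - k)
}

#' Squared prediction error (SPE, Q statistic)
#'
#' Energy of each row's residual outside the retained principal subspace:
#' `SPE = || (I - P_k P_k') (x - mean) ||^2`. Identically zero when all
#' components are retained.
#'
#' @param x numeric vector or matrix of observations in rows.
#' @param model a [fit_pca_retain()] model.
#' @return numeric vector of nonnegative SPE values, one per row.
#' @export
spe_statistic <- function(x, model) {
  stopifnot(inherits(model, "pca_model"))
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  xc <- sweep(x, 2, model$mean)
  if (model$k >= model$m_dim) return(numeric(nrow(x)))
  Pk <- model$loadings[, seq_len(model$k), drop = FALSE]
  resid <- xc - (xc %*% Pk) %*% t(Pk)
  rowSums(resid^2)
}

#' SPE control limit (Jackson-Mudholkar)
#'
#' Normal-theory upper limit of the SPE statistic from the residual
#' eigenvalue moments `theta_n = sum_{j>k} lambda_j^n` (n = 1, 2, 3) and
#' `h = 1 - 2 theta1 theta3 / (3 theta2^2)`:
#' `SPE_alpha = theta1 * (C_alpha * sqrt(2 theta2 h^2) / theta1 + 1 +
#' theta2 h (h - 1) / theta1^2)^(1/h)`, with `C_alpha` the standard normal
#' upper-alpha deviate. When the residual subspace is empty the limit is
#' reported as 0 (SPE is then identically zero and scale relevance falls
#' back to the T-squared statistic alone).
#'
#' @param model a [fit_pca_retain()] model.
#' @param alpha significance level in (0, 1), default 0.05.
#' @return the control limit (nonnegative scalar).
#' @export
spe_control_limit <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "pca_model"), alpha > 0, alpha < 1)
  lam <- model$eigenvalues
  k <- model$k
  if (k >= model$m_dim) return(0)
  resid <- lam[(k + 1):model$m_dim]
  th1 <- sum(resid)
  th2 <- sum(resid^2)
  th3 <- sum(resid^3)
  if (th1 <= 0 || th2 <= 0) return(0)
  h <- 1 - 2 * th1 * th3 / (3 * th2^2)
  ca <- stats::qnorm(1 - alpha)
  th1 * (ca * sqrt(2 * th2 * h^2) / th1 + 1 +
           th2 * h * (h - 1) / th1^2)^(1 / h)
}

#' Relevance factors for wavelet scales
#'
#' For each detail scale, computes the per-row T-squared and SPE statistics
#' of the scale's coefficient matrix under its PCA model and flags the
#' scale as relevant (`mu = 1`) when the fraction of rows exceeding *both*
#' control limits is greater than `exceed_fraction`. Scales whose model
#' retains every component have a degenerate SPE; there the decision falls
#' back to the T-squared exceedance alone.
#'
#' @param bands a [decompose_bands()] band set.
#' @param models list of [fit_pca_retain()] models, one per detail scale
#'   (`models[[l]]` for `bands$D[[l]]`).
#' @param alpha significance level for both limits (default 0.05).
#' @param exceed_fraction minimum joint-exceedance fraction for relevance
#'   (default 0.05).
#' @return integer vector `mu` of 0/1 flags, one per detail scale, with
#'   attribute `detail` (a per-scale list of statistics and limits).
#' @export
relevance_factors <- function(bands, models, alpha = 0.05,
                              exceed_fraction = 0.05) {
  stopifnot(inherits(bands, "wavelet_band_set"),
            length(models) == bands$level)
  mu <- integer(bands$level)
  detail <- vector("list", bands$level)
  for (l in seq_len(bands$level)) {
    Dl <- bands$D[[l]]
    mod <- models[[l]]
    if (mod$eigenvalues[1] <= 0) {
      # constant scale (e.g. all-zero signal): nothing in control to flag
      mu[l] <- 0L
      detail[[l]] <- list(scale = l, t2 = numeric(nrow(Dl)),
                          spe = numeric(nrow(Dl)), t2_limit = Inf,
                          spe_limit = 0, exceed_fraction = 0, k = mod$k)
      next
    }
    t2 <- t2_statistic(Dl, mod)
    m <- nrow(Dl)
    tlim <- if (m > mod$k) t2_control_limit(mod$k, m, alpha) else Inf
    spe <- spe_statistic(Dl, mod)
    slim <- spe_control_limit(mod, alpha)
    if (mod$k >= mod$m_dim || slim <= 0) {
      frac <- mean(t2 > tlim)
    } else {
      frac <- mean(t2 > tlim & spe > slim)
    }
    mu[l] <- as.integer(frac > exceed_fraction)
    detail[[l]] <- list(scale = l, t2 = t2, spe = spe, t2_limit = tlim,
                        spe_limit = slim, exceed_fraction = frac,
                        k = mod$k)
  }
  attr(mu, "detail") <- detail
  mu
}

# project rows of X onto the retained components of its model and back
.pca_filter <- function(x, model) {
  xc <- sweep(x, 2, model$mean)
  Pk <- model$loadings[, seq_len(model$k), drop = FALSE]
  sweep((xc %*% Pk) %*% t(Pk), 2, model$mean, "+")
}

#' Multiscale PCA denoising
#'
#' The full denoiser: per-channel DWT to `level` scales; PCA filtering
#' (project onto retained components and back) of the approximation matrix
#' and of every detail matrix; relevance-factor selection of detail scales
#' via T-squared/SPE monitoring; reconstruction of the signal as the
#' approximation plus the relevant (PCA-filtered) details. The
#' approximation is always included.
#'
#' @param x an [emg_signal()] with >= 2 channels (a single channel is
#'   passed through unchanged with a warning, since cross-channel PCA is
#'   then meaningless).
#' @param wavelet orthogonal wavelet (default `"sym4"`).
#' @param level decomposition depth (default 5).
#' @param alpha significance level of both control limits (default 0.05).
#' @param retain_fraction eigenvalue retention threshold (default 0.05).
#' @param exceed_fraction joint-exceedance fraction for scale relevance
#'   (default 0.05).
#' @param mu optional integer vector of 0/1 overrides for the per-scale
#'   relevance decision (length `level`); bypasses the T-squared/SPE vote.
#' @return list of class `mpca_result`: `signal` (denoised
#'   [emg_signal()]), `stats` (per-scale monitoring detail, the `mu` flags,
#'   models, and parameters).
#' @export
mpca_denoise <- function(x, wavelet = "sym4", level = 5, alpha = 0.05,
                         retain_fraction = 0.05, exceed_fraction = 0.05,
                         mu = NULL) {
  stopifnot(inherits(x, "emg_signal"))
  if (n_channels(x) < 2) {
    warning("single-channel signal: cross-channel PCA not applicable; ",
            "returning input unchanged")
    return(structure(list(signal = x, stats = NULL), class = "mpca_result"))
  }
  bands <- decompose_bands(x, wavelet = wavelet, level = level)
  models <- lapply(bands$D, fit_pca_retain, retain_fraction = retain_fraction)
  model_A <- fit_pca_retain(bands$A, retain_fraction = retain_fraction)
  if (is.null(mu)) {
    mu <- relevance_factors(bands, models, alpha = alpha,
                            exceed_fraction = exceed_fraction)
  } else {
    stopifnot(length(mu) == level, all(mu %in% c(0L, 1L)))
    mu <- as.integer(mu)
  }
  den <- bands
  den$A <- .pca_filter(bands$A, model_A)
  for (l in seq_len(level)) {
    den$D[[l]] <- if (mu[l] == 1L) {
      .pca_filter(bands$D[[l]], models[[l]])
    } else {
      matrix(0, nrow(bands$D[[l]]), ncol(bands$D[[l]]))
    }
  }
  out <- reconstruct_bands(den)
  stats <- list(mu = as.integer(mu), detail = attr(mu, "detail"),
                models = models, model_A = model_A,
                wavelet = wavelet, level = level, alpha = alpha,
                retain_fraction = retain_fraction,
                exceed_fraction = exceed_fraction)
  structure(list(signal = out, stats = stats), class = "mpca_result")
}

#' @export
print.mpca_result <- function(x, ...) {
  cat("mpca_result\n")
  if (!is.null(x$stats)) {
    cat("  wavelet:", x$stats$wavelet, " level:", x$stats$level, "\n")
    cat("  scale relevance mu (fine -> coarse):",
        paste(x$stats$mu, collapse = " "), "\n")
  } else {
    cat("  pass-through (single channel)\n")
  }
  invisible(x)
}

#' Export monitoring diagnostics as a data frame
#'
#' Flattens the per-scale T-squared/SPE series and limits of an
#' [mpca_denoise()] result into a long-format data frame suitable for CSV
#' export.
#'
#' @param result an `mpca_result`.
#' @return data frame with columns `scale`, `row`, `t2`, `spe`,
#'   `t2_limit`, `spe_limit`, `mu`.
#' @export
mpca_diagnostics <- function(result) {
  stopifnot(inherits(result, "mpca_result"))
  if (is.null(result$stats)) return(data.frame())
  do.call(rbind, lapply(result$stats$detail, function(d) {
    data.frame(scale = d$scale, row = seq_along(d$t2), t2 = d$t2,
               spe = d$spe, t2_limit = d$t2_limit, spe_limit = d$spe_limit,
               mu = result$stats$mu[d$scale])
  }))
}
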