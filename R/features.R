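# The three ten-dimensional feature families:
#   arcoeff - order-10 autoregressive coefficients via Yule-Walker /
#             Levinson-Durbin (time-domain feature),
#   DWTF    - level-9 wavelet scale energies [E(ca9), E(cd9), ..., E(cd1)],
#   ICAF    - energies of FastICA components extracted from the trial
#             segmented into pseudo-channels.

#' Biased sample autocorrelation
#'
#' `r(k) = (1/N) * sum_n x(n) x(n-k)` for `k = 0..max_lag`. The biased
#' (1/N) normalization guarantees the Toeplitz autocorrelation matrix is
#' positive semidefinite, which the Levinson-Durbin recursion requires.
#'
#' @param x numeric vector.
#' @param max_lag largest lag (< length(x)).
#' @return numeric vector of length `max_lag + 1`, lags 0..max_lag.
#' @export
autocorrelation <- function(x, max_lag) {
  n <- length(x)
  if (max_lag >= n) stop("max_lag must be smaller than the signal length")
  vapply(0:max_lag, function(k) {
    sum(x[(k + 1):n] * x[1:(n - k)]) / n
  }, numeric(1))
}

#' Levinson-Durbin recursion
#'
#' Solves the order-p Yule-Walker system for the autoregressive model
#' `x(n) = sum_k a_k x(n-k) + w(n)` (regression-on-past sign convention)
#' given the autocorrelation sequence `r(0..p)`, in O(p^2) via reflection
#' coefficients. At every order m the prediction-error variance satisfies
#' `rho_m = rho_{m-1} (1 - k_m^2)` exactly; `|k_m| >= 1` signals a
#' non-positive-definite autocorrelation and raises an error naming the
#' failing order.
#'
#' @param r autocorrelation sequence, lags 0..p (length >= p + 1).
#' @param p model order (>= 1).
#' @return object of class `ar_model`: `order`, `coefficients` (a_1..a_p),
#'   `reflection` (k_1..k_p), `pev` (prediction-error variances
#'   rho_0..rho_p), `autocorrelation` (r(0..p)).
#' @export
levinson_durbin <- function(r, p = length(r) - 1) {
  stopifnot(p >= 1, length(r) >= p + 1)
  if (r[1] <= 0) stop("r(0) must be positive")
  # internal prediction-error convention: x(n) + sum b_k x(n-k) = e(n)
  b <- numeric(p)
  k_refl <- numeric(p)
  rho <- numeric(p + 1)
  rho[1] <- r[1]
  for (m in seq_len(p)) {
    acc <- r[m + 1]
    if (m > 1) acc <- acc + sum(b[seq_len(m - 1)] * r[m:2])
    km <- -acc / rho[m]
    if (abs(km) >= 1) {
      stop("autocorrelation sequence not positive definite: |k_", m,
           "| = ", signif(abs(km), 6), " >= 1 at order ", m)
    }
    b_new <- b
    b_new[m] <- km
    if (m > 1) {
      b_new[seq_len(m - 1)] <- b[seq_len(m - 1)] +
        km * rev(b[seq_len(m - 1)])
    }
    b <- b_new
    k_refl[m] <- km
    rho[m + 1] <- rho[m] * (1 - km^2)
  }
  structure(list(order = p, coefficients = -b, reflection = k_refl,
                 pev = rho, autocorrelation = r[seq_len(p + 1)]),
            class = "ar_model")
}

#' @export
print.ar_model <- function(x, ...) {
  cat("ar_model of order ", x$order, "\n  coefficients: ",
      paste(signif(x$coefficients, 4), collapse = ", "),
      "\n  prediction-error variance: ", signif(x$pev[x$order + 1], 6),
      "\n", sep = "")
  invisible(x)
}

# collapse a multi-channel trial to one series per the channel policy
.collapse_channels <- function(trial, channel_policy = c("mean", "first")) {
  channel_policy <- match.arg(channel_policy)
  m <- if (inherits(trial, "emg_signal")) trial$samples else
    .as_signal_matrix(trial)
  switch(channel_policy,
         mean = colMeans(m),
         first = m[1, ])
}

#' Autoregressive coefficient features
#'
#' Fits an order-p AR model to the trial by Yule-Walker/Levinson-Durbin
#' and returns the coefficient vector `a_1..a_p`. Channels are collapsed
#' according to `channel_policy` (default: averaged) before fitting. A
#' degenerate (constant) trial yields a zero vector with a warning. AR
#' coefficients are invariant to amplitude scaling of the trial.
#'
#' @param trial an [emg_signal()], matrix or vector.
#' @param p AR order (default 10).
#' @param channel_policy `"mean"` (average channels) or `"first"`.
#' @return numeric vector of length `p`.
#' @export
ar_features <- function(trial, p = 10, channel_policy = "mean") {
  x <- .collapse_channels(trial, channel_policy)
  if (length(x) <= p) stop("trial too short for lag-", p, " autocorrelation")
  r <- autocorrelation(x, p)
  if (r[1] <= .Machine$double.eps * length(x)) {
    warning("degenerate (constant) trial: returning zero AR coefficients")
    return(numeric(p))
  }
  levinson_durbin(r, p)$coefficients
}

#' Wavelet scale-energy features (DWTF)
#'
#' Level-9 DWT of the trial (db4 by default) and the energy (quadratic sum
#' of coefficients) of each scale, ordered
#' `[E(ca9), E(cd9), E(cd8), ..., E(cd1)]` — a 10-vector for `level = 9`.
#' For an orthogonal wavelet the energies sum to the signal energy
#' (Parseval). If the trial is too short for the requested depth, the
#' maximum feasible depth is used and the missing coarse entries are zero,
#' with a warning.
#'
#' @param trial an [emg_signal()], matrix or vector.
#' @param wavelet orthogonal wavelet (default `"db4"`).
#' @param level decomposition depth (default 9).
#' @param channel_policy `"mean"` or `"first"`.
#' @return numeric vector of length `level + 1`, all nonnegative.
#' @export
dwt_energy_features <- function(trial, wavelet = "db4", level = 9,
                                channel_policy = "mean") {
  x <- .collapse_channels(trial, channel_policy)
  max_level <- floor(log2(length(x)))
  use_level <- min(level, max_level)
  if (use_level < level) {
    warning("trial supports only ", use_level, " levels; ",
            "missing coarse energies set to 0")
  }
  cf <- dwt(x, wavelet = wavelet, level = use_level)
  e_a <- sum(cf$a^2)
  e_d <- vapply(cf$d, function(d) sum(d^2), numeric(1))  # fine -> coarse
  out <- numeric(level + 1)
  out[1] <- e_a
  # slots 2..(level+1) hold E(cd_level)..E(cd_1)
  out[1 + (level - seq_len(use_level) + 1)] <- e_d
  out
}

#' ICA component-energy features (ICAF)
#'
#' The trial is collapsed to one series, sliced into `n_segments` equal
#' non-overlapping segments treated as observation channels, and FastICA
#' extracts `n_features` components; the features are the per-component
#' weights (variance each component contributes to the observations),
#' sorted descending for a deterministic order. This construction produces
#' a fixed-length weight vector for the
#' independent components of a trial regardless of the number of physical
#' channels; it scales as the square of the trial amplitude.
#'
#' @param trial an [emg_signal()], matrix or vector.
#' @param n_features number of components / features (default 10).
#' @param n_segments number of segments (>= n_features, default 12).
#' @param seed integer seed for the FastICA initialization.
#' @param channel_policy `"mean"` or `"first"`.
#' @return numeric vector of length `n_features`, nonincreasing.
#' @export
ica_features <- function(trial, n_features = 10, n_segments = 12, seed = 1,
                         channel_policy = "mean") {
  stopifnot(n_segments >= n_features)
  x <- .collapse_channels(trial, channel_policy)
  seg_len <- length(x) %/% n_segments
  if (seg_len < 32) {
    stop("segments would have ", seg_len, " samples; need >= 32")
  }
  if (all(x == 0)) return(numeric(n_features))
  segs <- matrix(x[seq_len(seg_len * n_segments)], nrow = n_segments,
                 byrow = TRUE)
  model <- suppressWarnings(
    fastica(segs, n_components = n_features, seed = seed)
  )
  # weight of component j = variance it contributes to the observations:
  # sources are unit-variance after whitening, so that is the squared norm
  # of the j-th estimated mixing column
  w_j <- colSums(model$mixing^2)
  out <- numeric(n_features)
  out[seq_along(w_j)] <- sort(w_j, decreasing = TRUE)
  out
}

#' Extract all three feature families from a trial set
#'
#' Runs [ar_features()], [dwt_energy_features()] and [ica_features()] on
#' every trial and assembles three aligned [feature_table()]s. A trial
#' whose extraction fails in any family is dropped from all three tables
#' symmetrically (recorded in the returned `dropped` attribute).
#'
#' @param trialset an [emg_trialset()].
#' @param ar_order AR order (default 10).
#' @param dwt_wavelet,dwt_level DWTF parameters (default db4, level 9).
#' @param ica_n_features,ica_n_segments ICAF parameters (default 10, 12).
#' @param seed master seed; per-trial ICA seeds are derived from it.
#' @param channel_policy channel collapsing policy for all families.
#' @return named list of three `feature_table`s (`arcoeff`, `DWTF`,
#'   `ICAF`), with attribute `dropped` (indices of dropped trials).
#' @export
extract_all <- function(trialset, ar_order = 10, dwt_wavelet = "db4",
                        dwt_level = 9, ica_n_features = 10,
                        ica_n_segments = 12, seed = 1,
                        channel_policy = "mean") {
  stopifnot(inherits(trialset, "emg_trialset"), length(trialset) >= 1)
  n <- length(trialset)
  ar_m <- matrix(NA_real_, n, ar_order)
  dw_m <- matrix(NA_real_, n, dwt_level + 1)
  ic_m <- matrix(NA_real_, n, ica_n_features)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    tr <- trialset$trials[[i]]
    res <- tryCatch({
      list(ar = ar_features(tr, p = ar_order,
                            channel_policy = channel_policy),
           dw = dwt_energy_features(tr, wavelet = dwt_wavelet,
                                    level = dwt_level,
                                    channel_policy = channel_policy),
           ic = ica_features(tr, n_features = ica_n_features,
                             n_segments = ica_n_segments,
                             seed = derive_seed(seed, paste0("icaf_", i)),
                             channel_policy = channel_policy))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("trial ", i, " dropped: ", conditionMessage(res))
      ok[i] <- FALSE
    } else {
      ar_m[i, ] <- res$ar
      dw_m[i, ] <- res$dw
      ic_m[i, ] <- res$ic
    }
  }
  labels <- trialset$labels[ok]
  out <- list(
    arcoeff = feature_table(ar_m[ok, , drop = FALSE], "arcoeff", labels),
    DWTF = feature_table(dw_m[ok, , drop = FALSE], "DWTF", labels),
    ICAF = feature_table(ic_m[ok, , drop = FALSE], "ICAF", labels)
  )
  attr(out, "dropped") <- which(!ok)
  out
}
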