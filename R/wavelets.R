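# Orthogonal discrete wavelet transform with periodized boundaries.
#
# No wavelet package ships with this toolchain, so the filter banks and the
# pyramid algorithm are implemented here. Filters are standard orthonormal
# Daubechies ("dbN", extremal phase) and least-asymmetric ("symN", symlet)
# scaling coefficients; the quadrature mirror highpass is derived from the
# lowpass by the alternating-flip rule, so the per-level transform matrix is
# orthogonal and the transform conserves energy exactly.

# scaling (lowpass) filters in natural order; sum = sqrt(2)
.wavelet_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db1  = c(0.7071067811865476, 0.7071067811865476),
  db2  = c(0.48296291314453416, 0.8365163037378079,
           0.2241438680420134, -0.12940952255126037),
  db4  = c(0.2303778133088965, 0.7148465705529157,
           0.6308807679298589, -0.027983769416859854,
           -0.18703481171909309, 0.030841381835560764,
           0.0328830116668852, -0.010597401785069032),
  sym4 = c(0.0322231006040427, -0.012603967262037833,
           -0.09921954357684722, 0.29785779560527736,
           0.8037387518059161, 0.49761866763201545,
           -0.02963552764599851, -0.07576571478927333),
  sym8 = c(0.0018899503327594609, -0.0003029205147213668,
           -0.01495225833704823, 0.003808752013890615,
           0.049137179673607506, -0.027219029917056003,
           -0.05194583810770904, 0.3644418948353314,
           0.7771857517005235, 0.4813596512583722,
           -0.061273359067658524, -0.1432942383508097,
           0.007607487324917605, 0.03169508781149298,
           -0.0005421323317911481, -0.0033824159510061256)
)

#' Orthonormal wavelet filter pair
#'
#' Returns the lowpass (scaling) and highpass (wavelet) decomposition filters
#' of an orthogonal wavelet. The highpass is the alternating-flip quadrature
#' mirror of the lowpass, so shifts-by-two of the pair form an orthonormal
#' basis and the resulting transform is energy-preserving.
#'
#' @param wavelet filter name: one of `"haar"`, `"db1"`, `"db2"`, `"db4"`,
#'   `"sym4"`, `"sym8"`.
#' @return list with elements `h` (lowpass) and `g` (highpass), each a
#'   numeric vector of equal even length.
#' @export
wavelet_filter <- function(wavelet = "db4") {
  h <- .wavelet_filters[[tolower(wavelet)]]
  if (is.null(h)) {
    stop("unknown wavelet '", wavelet, "'; available: ",
         paste(names(.wavelet_filters), collapse = ", "))
  }
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  list(h = h, g = g)
}

# one periodized analysis step; x length must be even
.dwt_step <- function(x, h, g) {
  N <- length(x)
  L <- length(h)
  idx <- (outer(seq(0L, N - 2L, by = 2L), 0:(L - 1L), "+") %% N) + 1L
  X <- matrix(x[idx], nrow = N %/% 2L)
  list(a = as.vector(X %*% h), d = as.vector(X %*% g))
}

# one periodized synthesis step (transpose of the analysis step)
.idwt_step <- function(a, d, h, g) {
  N <- 2L * length(a)
  L <- length(h)
  x <- numeric(N)
  pos0 <- (outer(2L * (seq_along(a) - 1L), 0:(L - 1L), "+") %% N) + 1L
  contrib <- outer(a, h) + outer(d, g)
  for (j in seq_len(L)) {
    # accumulate column-wise; positions within a column are distinct
    x[pos0[, j]] <- x[pos0[, j]] + contrib[, j]
  }
  x
}

#' Discrete wavelet transform of a single channel
#'
#' Mallat pyramid decomposition with periodized boundary handling. The signal
#' is zero-padded at the end to the next multiple of `2^level`; padding adds
#' no energy, so the coefficient energy equals the signal energy (Parseval)
#' and [idwt()] reproduces the input exactly up to floating point.
#'
#' @param x numeric vector.
#' @param wavelet filter name, see [wavelet_filter()]. Default `"db4"`, the
#'   fourth-order Daubechies wavelet.
#' @param level decomposition depth (number of detail scales).
#' @return object of class `dwt_coefficients`: list with `a` (approximation
#'   at the deepest level), `d` (list of detail vectors, `d[[l]]` = scale l,
#'   finest is l = 1), `wavelet`, `level`, `n` (original length),
#'   `boundary = "periodized"`.
#' @seealso [idwt()], [decompose_bands()]
#' @export
dwt <- function(x, wavelet = "db4", level = 4) {
  stopifnot(is.numeric(x), level >= 1)
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  flt <- wavelet_filter(wavelet)
  n <- length(x)
  block <- 2^level
  max_level <- floor(log2(max(n, 1)))
  if (n < block) {
    stop("signal of length ", n, " too short for level ", level,
         "; maximum feasible level is ", max_level)
  }
  npad <- ceiling(n / block) * block
  xp <- c(x, numeric(npad - n))
  d <- vector("list", level)
  a <- xp
  for (l in seq_len(level)) {
    st <- .dwt_step(a, flt$h, flt$g)
    a <- st$a
    d[[l]] <- st$d
  }
  structure(list(a = a, d = d, wavelet = wavelet, level = level,
                 n = n, boundary = "periodized"),
            class = "dwt_coefficients")
}

#' Inverse discrete wavelet transform
#'
#' @param coeffs a `dwt_coefficients` object from [dwt()].
#' @return numeric vector of the original length.
#' @export
idwt <- function(coeffs) {
  stopifnot(inherits(coeffs, "dwt_coefficients"))
  flt <- wavelet_filter(coeffs$wavelet)
  a <- coeffs$a
  for (l in rev(seq_len(coeffs$level))) {
    a <- .idwt_step(a, coeffs$d[[l]], flt$h, flt$g)
  }
  a[seq_len(coeffs$n)]
}

#' @export
print.dwt_coefficients <- function(x, ...) {
  cat("Discrete wavelet transform (", x$wavelet, ", periodized)\n", sep = "")
  cat("  level:", x$level, " signal length:", x$n, "\n")
  cat("  approximation length:", length(x$a), "\n")
  cat("  detail lengths (fine -> coarse):",
      paste(vapply(x$d, length, 1L), collapse = ", "), "\n")
  invisible(x)
}

#' Continuous wavelet transform with L1 normalization
#'
#' Real Morlet continuous wavelet transform, computed by direct convolution
#' with kernels psi(t/a)/a (L1 normalization). Under this normalization the
#' expected power of transformed unit-variance white noise is inversely
#' proportional to the scale a, which [mpca_denoise()]'s scale-noise model
#' relies on; the log-log slope of mean power against scale is a diagnostic
#' for whiteness of the residual.
#'
#' @param x numeric vector.
#' @param scales numeric vector of scales in samples (> 1).
#' @param omega0 Morlet center frequency in radians (default 6).
#' @return matrix of coefficients, `length(scales)` rows x `length(x)`
#'   columns, with attribute `scales`.
#' @export
cwt_l1 <- function(x, scales, omega0 = 6) {
  stopifnot(is.numeric(x), all(scales > 0))
  n <- length(x)
  out <- matrix(0, nrow = length(scales), ncol = n)
  for (i in seq_along(scales)) {
    a <- scales[i]
    half <- ceiling(4 * a)
    t <- seq(-half, half)
    # real Morlet, L1-normalized: psi(t/a)/a
    psi <- exp(-(t / a)^2 / 2) * cos(omega0 * t / a) / a
    psi <- psi - mean(psi)  # enforce zero mean after truncation
    full <- convolve(x, rev(psi), type = "open")
    out[i, ] <- full[half + seq_len(n)]
  }
  attr(out, "scales") <- scales
  out
}
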