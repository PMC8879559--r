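# Blind source separation by the fixed-point (FastICA) algorithm:
# whitening followed by one-unit Newton iterations with tanh nonlinearity
# and Gram-Schmidt deflation. The model is x = A s with A square and
# invertible; ICA estimates an unmixing matrix w with s = w x, identified
# up to permutation and sign when at most one source is Gaussian.

#' Whiten a multichannel observation matrix
#'
#' Linear transform `Z = V (X - mean)` making the rows of `Z` uncorrelated
#' with unit variance, via eigendecomposition of the (biased) covariance.
#' Near-zero eigenvalues (rank deficiency) reduce the output dimension with
#' a warning.
#'
#' @param x numeric matrix, variables (channels) in rows, samples in
#'   columns.
#' @param rank_tol relative eigenvalue threshold below which a dimension is
#'   treated as null (default 1e-12).
#' @return list with `z` (whitened data, possibly fewer rows), `v`
#'   (whitening matrix), `v_inv` (its right inverse, un-whitening),
#'   `center` (row means).
#' @export
whiten <- function(x, rank_tol = 1e-12) {
  x <- as.matrix(x)
  if (ncol(x) < 2 * nrow(x)) {
    stop("need at least 2 observations per dimension to whiten")
  }
  center <- rowMeans(x)
  xc <- x - center
  C <- tcrossprod(xc) / ncol(x)
  eig <- eigen(C, symmetric = TRUE)
  keep <- eig$values > rank_tol * max(eig$values, 0)
  if (!any(keep)) stop("zero covariance: cannot whiten")
  if (sum(keep) < nrow(x)) {
    warning("rank-deficient covariance: reducing dimension from ",
            nrow(x), " to ", sum(keep))
  }
  E <- eig$vectors[, keep, drop = FALSE]
  d <- eig$values[keep]
  v <- diag(1 / sqrt(d), nrow = length(d)) %*% t(E)
  v_inv <- E %*% diag(sqrt(d), nrow = length(d))
  list(z = v %*% xc, v = v, v_inv = v_inv, center = center)
}

#' FastICA blind source separation
#'
#' One-unit fixed-point algorithm with deflation. Data are whitened
#' internally; each unmixing row `w` is initialized as a random unit vector
#' from the seeded generator and updated by the Newton step
#' `w' = E{z g(w'z)} - E{g'(w'z)} w` with `g(u) = tanh(a u)`, normalized to
#' unit length and Gram-Schmidt-decorrelated against previously found rows.
#' Convergence is declared when the old and new `w` point in the same
#' direction (`|<w, w_old>| > 1 - tol`).
#'
#' @param x numeric matrix, channels in rows, samples in columns.
#' @param n_components number of components to extract (defaults to the
#'   whitened rank; reduced to it with a warning when larger).
#' @param a slope of the tanh nonlinearity (default 1).
#' @param tol convergence tolerance on the direction cosine (default 1e-6).
#' @param max_iter maximum Newton iterations per component (default 200).
#' @param seed integer seed for the random initial vectors.
#' @return object of class `ica_model`: `w` (unmixing rows, in whitened
#'   space), `v`/`v_inv`/`center` (whitening), `unmixing` (`w %*% v`, maps
#'   raw data to sources), `mixing` (estimated mixing, pseudo-inverse),
#'   `sources` (component x sample matrix), `a`, `iterations`, `converged`
#'   (per component), `tol`, `seed`.
#' @export
fastica <- function(x, n_components = NULL, a = 1, tol = 1e-6,
                    max_iter = 200, seed = 1) {
  x <- as.matrix(x)
  wh <- whiten(x)
  z <- wh$z
  rank <- nrow(z)
  if (is.null(n_components)) n_components <- rank
  if (n_components > rank) {
    warning("n_components reduced to whitened rank ", rank)
    n_components <- rank
  }
  n <- ncol(z)
  W <- matrix(0, n_components, rank)
  iters <- integer(n_components)
  conv <- logical(n_components)
  with_seed(seed, {
    for (comp in seq_len(n_components)) {
      w <- stats::rnorm(rank)
      w <- w / sqrt(sum(w^2))
      if (comp > 1) {
        prev <- W[seq_len(comp - 1), , drop = FALSE]
        w <- w - as.vector(t(prev) %*% (prev %*% w))
        w <- w / sqrt(sum(w^2))
      }
      for (it in seq_len(max_iter)) {
        wu <- as.vector(w %*% z)
        gu <- tanh(a * wu)
        gpu <- a * (1 - gu^2)
        w_new <- as.vector(z %*% gu) / n - mean(gpu) * w
        if (comp > 1) {
          prev <- W[seq_len(comp - 1), , drop = FALSE]
          w_new <- w_new - as.vector(t(prev) %*% (prev %*% w_new))
        }
        nrm <- sqrt(sum(w_new^2))
        if (nrm < 1e-12) {
          # degenerate direction; re-draw
          w_new <- stats::rnorm(rank)
          w_new <- w_new / sqrt(sum(w_new^2))
        } else {
          w_new <- w_new / nrm
        }
        done <- abs(sum(w_new * w)) > 1 - tol
        w <- w_new
        if (done) break
      }
      iters[comp] <- it
      conv[comp] <- done
      W[comp, ] <- w
    }
  })
  if (!all(conv)) {
    warning(sum(!conv), " component(s) did not converge within ",
            max_iter, " iterations")
  }
  unmixing <- W %*% wh$v
  sources <- W %*% z
  structure(list(w = W, v = wh$v, v_inv = wh$v_inv, center = wh$center,
                 unmixing = unmixing, mixing = wh$v_inv %*% t(W),
                 sources = sources, a = a, iterations = iters,
                 converged = conv, tol = tol, seed = seed),
            class = "ica_model")
}

#' @export
print.ica_model <- function(x, ...) {
  cat("ica_model: ", nrow(x$w), " component(s), tanh slope a = ", x$a,
      "\n  iterations: ", paste(x$iterations, collapse = ", "),
      "  converged: ", paste(x$converged, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Amari performance index
#'
#' Permutation- and scale-invariant distance between an estimated unmixing
#' and the true mixing: with `P = unmixing %*% mixing`, the index averages
#' the normalized off-diagonal mass of the rows and columns of `|P|`. It is
#' 0 exactly when `P` is a scaled permutation matrix (perfect separation)
#' and grows towards 2(n-1)/... for random matrices; values below 0.05
#' indicate essentially perfect recovery.
#'
#' @param unmixing estimated unmixing matrix (maps observations to
#'   sources).
#' @param mixing true mixing matrix.
#' @return nonnegative scalar.
#' @export
amari_index <- function(unmixing, mixing) {
  P <- abs(as.matrix(unmixing) %*% as.matrix(mixing))
  n <- nrow(P)
  stopifnot(n == ncol(P))
  row_term <- sum(rowSums(P) / apply(P, 1, max) - 1)
  col_term <- sum(colSums(P) / apply(P, 2, max) - 1)
  (row_term + col_term) / (2 * n * (n - 1))
}
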