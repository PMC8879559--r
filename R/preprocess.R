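# Acquisition-side filtering: Butterworth band-limiting and a power-line
# notch, both applied forward-backward (zero phase) channel by channel.

.as_signal_matrix <- function(signal_or_matrix) {
  if (inherits(signal_or_matrix, "emg_signal")) signal_or_matrix$samples
  else if (is.vector(signal_or_matrix)) matrix(signal_or_matrix, nrow = 1)
  else as.matrix(signal_or_matrix)
}

.rewrap <- function(original, samples) {
  if (inherits(original, "emg_signal")) emg_signal(samples, original$fs_hz)
  else if (is.vector(original)) as.vector(samples)
  else samples
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering of every channel.
#' When `high_hz >= fs/2` a band-pass is infeasible (Nyquist), and the
#' filter degrades gracefully to a high-pass at `low_hz` with a message:
#' this preserves the intent of a "15-500 Hz" band at a 500 Hz sampling
#' rate, namely removing the sub-15 Hz firing-instability component.
#'
#' @param x an [emg_signal()], matrix (channels x time) or vector.
#' @param low_hz lower band edge (Hz), `0 < low_hz < fs/2`.
#' @param high_hz upper band edge (Hz).
#' @param order filter order (default 4).
#' @param fs_hz sampling rate; taken from `x` when it is an `emg_signal`.
#' @return filtered signal of the same type and shape as `x`.
#' @export
butterworth_bandpass <- function(x, low_hz, high_hz, order = 4,
                                 fs_hz = NULL) {
  if (inherits(x, "emg_signal")) fs_hz <- x$fs_hz
  if (is.null(fs_hz)) stop("fs_hz required for matrix/vector input")
  nyq <- fs_hz / 2
  if (low_hz <= 0 || low_hz >= nyq) {
    stop("low_hz must lie strictly between 0 and fs/2 = ", nyq)
  }
  if (high_hz >= nyq) {
    message("high_hz >= Nyquist (", nyq, " Hz); applying high-pass at ",
            low_hz, " Hz")
    flt <- signal::butter(order, low_hz / nyq, type = "high")
  } else {
    if (high_hz <= low_hz) stop("high_hz must exceed low_hz")
    flt <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  }
  m <- .as_signal_matrix(x)
  out <- t(apply(m, 1, function(ch) signal::filtfilt(flt, ch)))
  .rewrap(x, out)
}

#' Zero-phase notch (band-stop) filter
#'
#' Second-order Butterworth band-stop centered at `f0_hz` with bandwidth
#' `f0_hz / quality`, applied forward-backward per channel.
#'
#' @param x an [emg_signal()], matrix (channels x time) or vector.
#' @param f0_hz notch center frequency (Hz), `0 < f0_hz < fs/2`.
#' @param quality quality factor Q; bandwidth = f0/Q (default 30).
#' @param fs_hz sampling rate; taken from `x` when it is an `emg_signal`.
#' @return filtered signal of the same type and shape as `x`.
#' @export
notch <- function(x, f0_hz = 50, quality = 30, fs_hz = NULL) {
  if (inherits(x, "emg_signal")) fs_hz <- x$fs_hz
  if (is.null(fs_hz)) stop("fs_hz required for matrix/vector input")
  nyq <- fs_hz / 2
  if (f0_hz <= 0 || f0_hz >= nyq) {
    stop("f0_hz must lie strictly between 0 and fs/2 = ", nyq)
  }
  bw <- f0_hz / quality / 2
  edges <- c(max(f0_hz - bw, 1e-6), min(f0_hz + bw, nyq * (1 - 1e-9)))
  flt <- signal::butter(2, edges / nyq, type = "stop")
  m <- .as_signal_matrix(x)
  out <- t(apply(m, 1, function(ch) signal::filtfilt(flt, ch)))
  .rewrap(x, out)
}
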