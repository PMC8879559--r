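#' Multi-channel EMG signal
#'
#' Container for a sampled multi-channel signal: a channels x time numeric
#' matrix plus the sampling rate. All internal processing uses this
#' channels-in-rows orientation; the on-disk container stores channels as
#' columns (see [write_trialset()]).
#'
#' @param samples numeric matrix, channels x time, all finite.
#' @param fs_hz sampling rate in Hz (> 0).
#' @return object of class `emg_signal`.
#' @export
emg_signal <- function(samples, fs_hz) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (!all(is.finite(samples))) stop("samples contain non-finite values")
  if (nrow(samples) < 1 || ncol(samples) < 1) {
    stop("signal needs at least one channel and one sample")
  }
  stopifnot(is.numeric(fs_hz), length(fs_hz) == 1, fs_hz > 0)
  structure(list(samples = samples, fs_hz = fs_hz), class = "emg_signal")
}

#' @export
print.emg_signal <- function(x, ...) {
  cat("emg_signal: ", nrow(x$samples), " channel(s) x ", ncol(x$samples),
      " samples @ ", x$fs_hz, " Hz (",
      round(ncol(x$samples) / x$fs_hz, 3), " s)\n", sep = "")
  invisible(x)
}

#' Number of channels / samples of an EMG signal
#' @param x an `emg_signal`.
#' @return integer count.
#' @export
n_channels <- function(x) nrow(x$samples)

#' @rdname n_channels
#' @export
n_samples <- function(x) ncol(x$samples)

#' Labelled collection of EMG trials
#'
#' @param trials list of [emg_signal()] objects with a common sampling rate.
#' @param labels integer class labels, one per trial (class ids from a fixed
#'   known set, e.g. 1..6 for the six grasp movements).
#' @param subject_id subject identifier string.
#' @param repetition integer repetition index per trial (defaults to the
#'   within-class running count).
#' @return object of class `emg_trialset`.
#' @export
emg_trialset <- function(trials, labels, subject_id = "synthetic",
                         repetition = NULL) {
  stopifnot(is.list(trials), length(trials) >= 1)
  if (!all(vapply(trials, inherits, TRUE, "emg_signal"))) {
    stop("all trials must be emg_signal objects")
  }
  labels <- as.integer(labels)
  if (length(labels) != length(trials)) {
    stop("length(labels) must equal length(trials)")
  }
  fs <- unique(vapply(trials, function(tr) tr$fs_hz, 1))
  if (length(fs) != 1) stop("trials have inconsistent sampling rates")
  if (is.null(repetition)) {
    repetition <- stats::ave(seq_along(labels), labels, FUN = seq_along)
  }
  structure(list(trials = trials, labels = labels,
                 subject_id = subject_id,
                 repetition = as.integer(repetition), fs_hz = fs),
            class = "emg_trialset")
}

#' @export
print.emg_trialset <- function(x, ...) {
  tab <- table(x$labels)
  cat("emg_trialset: ", length(x$trials), " trials, subject '",
      x$subject_id, "', fs ", x$fs_hz, " Hz\n", sep = "")
  cat("  classes:", paste(sprintf("%s (n=%d)", names(tab), tab),
                          collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.emg_trialset <- function(x) length(x$trials)

#' Feature table
#'
#' n_trials x n_features numeric matrix tagged with the feature family and
#' the trial labels. Rows align with the originating trial set's order.
#'
#' @param values numeric matrix, trials in rows.
#' @param kind feature family: `"arcoeff"`, `"DWTF"` or `"ICAF"`.
#' @param labels integer class labels, one per row.
#' @return object of class `feature_table`.
#' @export
feature_table <- function(values, kind, labels) {
  stopifnot(is.matrix(values), nrow(values) == length(labels))
  if (!all(is.finite(values))) stop("feature table contains non-finite values")
  kind <- match.arg(kind, c("arcoeff", "DWTF", "ICAF"))
  cn <- switch(kind,
               arcoeff = paste0("ar", seq_len(ncol(values))),
               DWTF = c("ca9", paste0("cd", rev(seq_len(ncol(values) - 1)))),
               ICAF = paste0("ica", seq_len(ncol(values))))
  colnames(values) <- cn
  structure(list(values = values, kind = kind, labels = as.integer(labels)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table (", x$kind, "): ", nrow(x$values), " trials x ",
      ncol(x$values), " features, ", length(unique(x$labels)),
      " classes\n", sep = "")
  invisible(x)
}
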