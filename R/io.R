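# Reading and writing trial sets.
#
# Native container: one directory per subject holding one plain CSV per
# trial (channels as columns) plus manifest.json (labels, repetition,
# sampling rate, provenance, seed and a config echo). The UCI two-channel
# hand-grasp layout (MAT-v5, one trials-x-samples variable per movement
# and channel) is read by a small MAT-v5 parser implemented below, since
# no MAT reader ships with this toolchain.

#' Write a trial set to the native on-disk container
#'
#' Creates `path/` containing `trial_0001.csv`, ... (numeric matrices,
#' channels as columns, one row per time sample) and `manifest.json`
#' describing labels, repetitions, class names, sampling rate, provenance
#' and, for synthetic data, the generator seed and config echo.
#'
#' @param trialset an [emg_trialset()].
#' @param path output directory (created if missing).
#' @param class_names optional character names for the class ids.
#' @param provenance `"synthetic"` or `"UCI"`.
#' @param config optional [synth_config()] echoed into the manifest.
#' @return `path`, invisibly.
#' @export
write_trialset <- function(trialset, path, class_names = NULL,
                           provenance = "synthetic", config = NULL) {
  stopifnot(inherits(trialset, "emg_trialset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(trialset))
  for (i in seq_along(trialset$trials)) {
    files[i] <- sprintf("trial_%04d.csv", i)
    m <- t(trialset$trials[[i]]$samples)
    # 17 significant digits: doubles round-trip exactly through text
    fm <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
    utils::write.table(fm, file.path(path, files[i]),
                       sep = ",", row.names = FALSE, quote = FALSE,
                       col.names = paste0("ch", seq_len(ncol(m))))
  }
  manifest <- list(
    subject_id = trialset$subject_id,
    fs_hz = trialset$fs_hz,
    labels = trialset$labels,
    repetition = trialset$repetition,
    files = files,
    class_names = class_names,
    provenance = provenance,
    seed = if (!is.null(config)) config$seed,
    config = if (!is.null(config)) {
      cfg <- unclass(config)
      cfg$crosstalk_mixing <- NULL
      cfg
    }
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a trial set from the native container
#'
#' Inverse of [write_trialset()]: arrays and labels round-trip exactly
#' (CSV values are written at full precision). Trials are returned in
#' manifest order, which [write_trialset()] stores as (class, repetition).
#'
#' @param path directory written by [write_trialset()].
#' @return an [emg_trialset()].
#' @export
read_trialset <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json under ", path)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  trials <- lapply(mf$files, function(f) {
    m <- as.matrix(utils::read.csv(file.path(path, f)))
    emg_signal(unname(t(m)), mf$fs_hz)
  })
  emg_trialset(trials, mf$labels, subject_id = mf$subject_id,
               repetition = mf$repetition)
}

# ---------------------------------------------------------------------------
# Minimal MAT-v5 parser: numeric (real) matrices only, compressed or plain.

.mat5_numtype <- function(type) {
  switch(as.character(type),
         "1" = list(what = "integer", size = 1L, signed = TRUE),   # miINT8
         "2" = list(what = "integer", size = 1L, signed = FALSE),  # miUINT8
         "3" = list(what = "integer", size = 2L, signed = TRUE),   # miINT16
         "4" = list(what = "integer", size = 2L, signed = FALSE),  # miUINT16
         "5" = list(what = "integer", size = 4L, signed = TRUE),   # miINT32
         "6" = list(what = "integer", size = 4L, signed = FALSE),  # miUINT32
         "7" = list(what = "numeric", size = 4L, signed = TRUE),   # miSINGLE
         "9" = list(what = "numeric", size = 8L, signed = TRUE),   # miDOUBLE
         NULL)
}

# parse one data element starting at offset pos (1-based) in raw vector;
# returns list(type, bytes, next_pos)
.mat5_element <- function(raw, pos, endian) {
  tag <- readBin(raw[pos:(pos + 7L)], "integer", n = 2L, size = 4L,
                 endian = endian)
  type <- tag[1]
  nbytes <- tag[2]
  small <- bitwAnd(type, -65536L)  # upper 16 bits nonzero => small element
  if (small != 0L) {
    nbytes <- bitwShiftR(bitwAnd(type, -65536L), 16L)
    type <- bitwAnd(type, 65535L)
    data <- if (nbytes > 0) raw[(pos + 4L):(pos + 3L + nbytes)] else raw(0)
    return(list(type = type, bytes = data, next_pos = pos + 8L))
  }
  data <- if (nbytes > 0) raw[(pos + 8L):(pos + 7L + nbytes)] else raw(0)
  # elements are padded to 8-byte boundaries
  adv <- 8L + nbytes + ((8L - nbytes %% 8L) %% 8L)
  list(type = type, bytes = data, next_pos = pos + adv)
}

.mat5_read_numeric <- function(bytes, type, endian) {
  nt <- .mat5_numtype(type)
  if (is.null(nt)) stop("unsupported MAT data type ", type)
  n <- length(bytes) %/% nt$size
  # readBin only honours `signed` for 1- and 2-byte integers
  signed <- if (nt$size >= 4L) TRUE else nt$signed
  readBin(bytes, nt$what, n = n, size = nt$size, signed = signed,
          endian = endian)
}

# parse a miMATRIX payload -> list(name, data) or NULL for unsupported
.mat5_matrix <- function(bytes, endian) {
  pos <- 1L
  flags_el <- .mat5_element(bytes, pos, endian)
  pos <- flags_el$next_pos
  flags <- readBin(flags_el$bytes, "integer", n = 2L, size = 4L,
                   endian = endian)
  class_id <- bitwAnd(flags[1], 255L)
  complex_flag <- bitwAnd(bitwShiftR(flags[1], 8L), 8L) != 0L
  dims_el <- .mat5_element(bytes, pos, endian)
  pos <- dims_el$next_pos
  dims <- readBin(dims_el$bytes, "integer", n = length(dims_el$bytes) %/% 4L,
                  size = 4L, endian = endian)
  name_el <- .mat5_element(bytes, pos, endian)
  pos <- name_el$next_pos
  name <- rawToChar(name_el$bytes[name_el$bytes != as.raw(0)])
  if (!class_id %in% 6:13 || complex_flag || length(dims) != 2) {
    return(list(name = name, data = NULL))  # non-numeric/complex: skipped
  }
  data_el <- .mat5_element(bytes, pos, endian)
  vals <- .mat5_read_numeric(data_el$bytes, data_el$type, endian)
  if (length(vals) != prod(dims)) {
    stop("MAT variable '", name, "' is truncated: expected ", prod(dims),
         " values, found ", length(vals))
  }
  list(name = name, data = matrix(as.numeric(vals), dims[1], dims[2]))
}

#' Read numeric variables from a MAT-v5 file
#'
#' Minimal MAT-v5 (Level 5) reader covering what the UCI sEMG files
#' contain: real numeric 2-D matrices, stored plain or zlib-compressed.
#' Character/cell/struct variables are skipped.
#'
#' @param path MAT-v5 file path.
#' @return named list of numeric matrices.
#' @export
read_mat5 <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 128L) stop("not a MAT-v5 file: shorter than the header")
  endian_mark <- rawToChar(raw[127:128])
  endian <- if (endian_mark == "IM") "little"
  else if (endian_mark == "MI") "big"
  else stop("not a MAT-v5 file: bad endian indicator '", endian_mark, "'")
  out <- list()
  pos <- 129L
  n_total <- length(raw)
  while (pos + 7L <= n_total) {
    el <- .mat5_element(raw, pos, endian)
    if (el$next_pos - 8L > n_total + 1L) {
      stop("truncated MAT-v5 element at byte ", pos)
    }
    payload <- el$bytes
    type <- el$type
    if (type == 15L) {  # miCOMPRESSED: zlib stream wrapping one element
      payload <- memDecompress(payload, type = "gzip")
      inner <- .mat5_element(payload, 1L, endian)
      type <- inner$type
      payload <- inner$bytes
    }
    if (type == 14L) {  # miMATRIX
      mx <- .mat5_matrix(payload, endian)
      if (!is.null(mx$data)) out[[mx$name]] <- mx$data
    }
    pos <- el$next_pos
  }
  out
}

.uci_grasps <- c("spher", "tip", "palm", "lat", "cyl", "hook")

#' Read a UCI hand-grasp MAT file as a trial set
#'
#' Expects the two-channel, 500 Hz layout of the UCI "sEMG for Basic Hand
#' movements" collection: per movement class `<grasp>_ch1` and
#' `<grasp>_ch2` variables, each a trials x samples matrix, with the six
#' grasp names `r paste(emgmpca:::.uci_grasps, collapse = ", ")` (matched
#' case-insensitively). Class ids 1..6 follow that fixed order. Trials are
#' ordered by (class, repetition).
#'
#' @param path MAT-v5 file path.
#' @param fs_hz sampling rate (the collection uses 500 Hz).
#' @return an [emg_trialset()] with 2-channel trials.
#' @export
read_uci_mat <- function(path, fs_hz = 500) {
  vars <- read_mat5(path)
  lower <- tolower(names(vars))
  trials <- list()
  labels <- integer(0)
  reps <- integer(0)
  for (ci in seq_along(.uci_grasps)) {
    g <- .uci_grasps[ci]
    i1 <- which(startsWith(lower, g) & endsWith(lower, "ch1"))
    i2 <- which(startsWith(lower, g) & endsWith(lower, "ch2"))
    if (length(i1) != 1 || length(i2) != 1) {
      stop("class '", g, "' not found (need <grasp>_ch1/_ch2); ",
           "file contains: ", paste(names(vars), collapse = ", "))
    }
    m1 <- vars[[i1]]
    m2 <- vars[[i2]]
    if (!all(dim(m1) == dim(m2))) {
      stop("channel matrices of class '", g, "' differ in shape")
    }
    if (!all(is.finite(m1)) || !all(is.finite(m2))) {
      stop("non-finite samples in class '", g, "'")
    }
    for (tr in seq_len(nrow(m1))) {
      trials[[length(trials) + 1L]] <-
        emg_signal(rbind(m1[tr, ], m2[tr, ]), fs_hz)
      labels <- c(labels, ci)
      reps <- c(reps, tr)
    }
  }
  emg_trialset(trials, labels,
               subject_id = tools::file_path_sans_ext(basename(path)),
               repetition = reps)
}

# ---------------------------------------------------------------------------

#' Write experiment results to disk
#'
#' Emits `accuracies.csv` (one row per feature x classifier x k x arm
#' cell), one `confusion_<feature>_<classifier><k>_<arm>.csv` per cell,
#' and `summary.json` with the full accuracy grid.
#'
#' @param results an `experiment_result` from [run_experiment()], or a
#'   list with elements `accuracy` (data frame) and `confusion` (named
#'   list of matrices).
#' @param path output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  acc <- results$accuracy
  if (is.null(acc)) {
    acc <- data.frame(feature = character(), classifier = character(),
                      k = integer(), arm = character(),
                      accuracy = numeric())
  }
  utils::write.table(acc, file.path(path, "accuracies.csv"), sep = ",",
                     row.names = FALSE)
  for (nm in names(results$confusion)) {
    utils::write.table(results$confusion[[nm]],
                       file.path(path, paste0("confusion_", nm, ".csv")),
                       sep = ",", row.names = TRUE, col.names = NA)
  }
  jsonlite::write_json(list(accuracy = acc),
                       file.path(path, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
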