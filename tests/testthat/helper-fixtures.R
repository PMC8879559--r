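# Shared fixtures: small synthetic inputs built in code, and a byte-level
# MAT-v5 writer used to exercise the reader against independently
# constructed files (layout written directly from the format definition,
# not via the package's own parser).

fix_signal <- function(n = 1024, n_ch = 2, seed = 1, fs = 500) {
  set.seed(seed)
  emg_signal(matrix(rnorm(n_ch * n), n_ch), fs)
}

# clean two-channel low-frequency signal plus white noise at a given SNR
fix_clean_noisy <- function(n = 1500, fs = 500, snr_db = 0, seed = 1) {
  set.seed(seed)
  t <- (1:n) / fs
  shared <- sin(2 * pi * 8 * t) + 0.6 * sin(2 * pi * 3 * t + 1) +
    0.4 * sin(2 * pi * 17 * t)
  clean <- rbind(shared, 0.9 * shared + 0.2 * sin(2 * pi * 5 * t))
  p_sig <- mean(clean^2)
  noise_sd <- sqrt(p_sig / 10^(snr_db / 10))
  noisy <- clean + matrix(rnorm(2 * n, 0, noise_sd), 2)
  list(clean = clean, noisy = emg_signal(noisy, fs), noise_sd = noise_sd)
}

# valid autocorrelation sequence: from a random stable AR model's sample path
fix_valid_autocorr <- function(p, seed) {
  set.seed(seed)
  # partial autocorrelations in (-1, 1) guarantee a stationary model
  x <- generate_ar_process(c(0.3, -0.2), 4000, seed = seed)
  autocorrelation(x, p)
}

# --- byte-level MAT-v5 writer (uncompressed, mxDOUBLE matrices only) ------

mat5_tag <- function(type, nbytes) {
  writeBin(c(as.integer(type), as.integer(nbytes)), raw(), size = 4,
           endian = "little")
}

mat5_pad <- function(bytes) {
  pad <- (8 - length(bytes) %% 8) %% 8
  c(bytes, raw(pad))
}

mat5_matrix_element <- function(name, m) {
  flags <- c(mat5_tag(6, 8),
             writeBin(c(6L, 0L), raw(), size = 4, endian = "little"))
  dims <- c(mat5_tag(5, 8),
            writeBin(c(nrow(m), ncol(m)), raw(), size = 4,
                     endian = "little"))
  nm <- charToRaw(name)
  name_el <- mat5_pad(c(mat5_tag(1, length(nm)), nm))
  vals <- writeBin(as.numeric(m), raw(), size = 8, endian = "little")
  pr <- c(mat5_tag(9, length(vals)), vals)
  body <- c(flags, dims, name_el, pr)
  c(mat5_tag(14, length(body)), body)
}

write_mat5_fixture <- function(path, vars) {
  header <- charToRaw(sprintf("%-116s", "MATLAB 5.0 MAT-file, fixture"))
  header <- c(header, raw(8),
              writeBin(c(0L, 1L), raw(), size = 1),   # version 0x0100 LE
              charToRaw("IM"))
  body <- unlist(lapply(names(vars), function(nm) {
    mat5_matrix_element(nm, vars[[nm]])
  }))
  writeBin(c(header, body), path)
  invisible(path)
}

uci_fixture_vars <- function(n_trials = 3, n_samples = 64, seed = 7) {
  set.seed(seed)
  grasps <- c("spher", "tip", "palm", "lat", "cyl", "hook")
  vars <- list()
  for (g in grasps) {
    vars[[paste0(g, "_ch1")]] <- matrix(rnorm(n_trials * n_samples),
                                        n_trials)
    vars[[paste0(g, "_ch2")]] <- matrix(rnorm(n_trials * n_samples),
                                        n_trials)
  }
  vars
}

# well-separated 6-class Gaussian feature clusters
fix_separable_features <- function(n_per_class = 20, d = 10, sep = 50,
                                   seed = 1) {
  set.seed(seed)
  labels <- rep(1:6, each = n_per_class)
  centers <- matrix(rnorm(6 * d), 6) * sep
  x <- centers[labels, ] + matrix(rnorm(length(labels) * d),
                                  length(labels))
  list(x = x, labels = labels)
}
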