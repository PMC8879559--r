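# Synthetic EMG generator: MUAPT model, trial sets, AR processes, mixed
# sources.

test_that("generate_muapt handles degenerate and identity cases", {
  tpl <- muap_template(duration_ms = 12, fs_hz = 500)
  expect_equal(sum(tpl$waveform^2), 1, tolerance = 1e-9)

  # zero gain -> all-zero signal
  tr0 <- muap_train(tpl, firing_rate_hz = 20, jitter_sd_ms = 0, gain = 0)
  expect_equal(generate_muapt(tr0, 500, 1, seed = 1), numeric(500))

  # a single discharge at t = 0 with unit gain reproduces the template
  tr1 <- muap_train(tpl, firing_rate_hz = 0.05, jitter_sd_ms = 0, gain = 1)
  out <- generate_muapt(tr1, 500, 0.5, seed = 1)
  w <- tpl$waveform
  expect_equal(out[seq_along(w)], w, tolerance = 1e-12)
  expect_equal(out[-seq_along(w)], numeric(250 - length(w)))

  expect_error(muap_train(tpl, firing_rate_hz = 0), "positive")
  expect_error(generate_muapt(tr1, 500, -1), "positive")
})

test_that("discharge count matches rate x duration for a regular train", {
  tpl <- muap_template(duration_ms = 10, fs_hz = 500)
  tr <- muap_train(tpl, firing_rate_hz = 20, jitter_sd_ms = 0, gain = 1)
  out <- generate_muapt(tr, 500, 10, seed = 3)
  # templates are unit energy and non-overlapping at 20 Hz (25-sample ISI
  # vs 5-sample support), so total energy counts the discharges
  expect_equal(sum(out^2), 200, tolerance = 1)
})

test_that("trial sets have the documented shape and are deterministic", {
  cfg <- synth_config(duration_s = 1, seed = 42)
  ts1 <- generate_trialset(cfg, n_classes = 3, n_trials_per_class = 4)
  ts2 <- generate_trialset(cfg, n_classes = 3, n_trials_per_class = 4)
  expect_length(ts1, 12)
  expect_equal(ts1$labels, rep(1:3, each = 4))
  expect_true(all(vapply(ts1$trials, n_channels, 1L) == 2))
  expect_true(all(vapply(ts1$trials, n_samples, 1L) == 500))
  # bit-identical for the same config + seed
  expect_identical(
    lapply(ts1$trials, function(t) t$samples),
    lapply(ts2$trials, function(t) t$samples)
  )
  expect_identical(ts1$labels, ts2$labels)
})

test_that("trials with no motor units and no noise are identically zero", {
  cfg <- synth_config(n_motor_units = 0, noise_sd = 0, line_amp = 0,
                      baseline_amp = 0, duration_s = 0.5)
  ts <- generate_trialset(cfg, n_classes = 2, n_trials_per_class = 2)
  expect_true(all(vapply(ts$trials, function(t) all(t$samples == 0), TRUE)))
})

test_that("noise is additive: clean generation + noise stream = noisy generation", {
  cfg_noisy <- synth_config(duration_s = 0.5, seed = 9, noise_sd = 0.1)
  cfg_clean <- cfg_noisy
  cfg_clean$noise_sd <- 0
  cfg_clean$line_amp <- 0
  cfg_clean$baseline_amp <- 0
  ts_noisy <- generate_trialset(cfg_noisy, 2, 2)
  ts_clean <- generate_trialset(cfg_clean, 2, 2)
  n <- n_samples(ts_noisy$trials[[1]])
  for (i in seq_along(ts_noisy$trials)) {
    cls <- ts_noisy$labels[i]
    rep_i <- ts_noisy$repetition[i]
    noise <- emgmpca:::.trial_noise(
      cfg_noisy, n,
      derive_seed(cfg_noisy$seed, sprintf("trial_%d_%d_noise", cls, rep_i)))
    expect_equal(ts_clean$trials[[i]]$samples + noise,
                 ts_noisy$trials[[i]]$samples, tolerance = 1e-12)
  }
})

test_that("baseline instability is band-limited and the line is a pure tone", {
  cfg <- synth_config(duration_s = 4, seed = 5, noise_sd = 0, line_amp = 0,
                      baseline_amp = 1)
  noise <- emgmpca:::.trial_noise(cfg, 2000, 123)
  spec <- Mod(fft(noise[1, ]))^2
  freqs <- (seq_along(spec) - 1) * cfg$fs_hz / length(spec)
  in_band <- freqs <= 19 | freqs >= cfg$fs_hz - 19
  expect_gte(sum(spec[in_band]) / sum(spec), 0.95)

  cfg_line <- synth_config(duration_s = 4, seed = 5, noise_sd = 0,
                           baseline_amp = 0, line_amp = 1)
  tone <- emgmpca:::.trial_noise(cfg_line, 2000, 123)[1, ]
  spec <- Mod(fft(tone))^2
  peak_bin <- which.max(spec[2:1000]) + 1
  expect_equal(freqs[peak_bin], 50, tolerance = cfg$fs_hz / 2000)
  expect_gte(spec[peak_bin] + spec[length(spec) + 2 - peak_bin],
             0.999 * sum(spec))
})

test_that("trial energy grows linearly with non-overlapping motor units", {
  # identical, non-overlapping trains on separate channels sum in energy
  tpl <- muap_template(duration_ms = 8, fs_hz = 500)
  tr <- muap_train(tpl, firing_rate_hz = 10, jitter_sd_ms = 0, gain = 1)
  one <- generate_muapt(tr, 500, 2, seed = 1)
  for (m in c(2, 4)) {
    # m copies of the same train, shifted far apart in separate channels,
    # mixed with unit weights into one channel
    shifted <- vapply(seq_len(m), function(j) {
      c(numeric((j - 1) * 12), one)[seq_along(one)]
    }, numeric(length(one)))
    stacked <- rowSums(shifted)
    # trains offset by more than the template support do not overlap
    expect_equal(sum(stacked^2), m * sum(one^2), tolerance = 0.15 * m)
  }
})

test_that("AR process generator is stationary, reproducible and validated", {
  # degenerate AR(0): white noise with unit variance
  x <- generate_ar_process(numeric(0), 50000, noise_sd = 1, seed = 2)
  expect_equal(var(x), 1, tolerance = 0.03)

  # AR(1) theory: lag-1 autocorrelation equals the coefficient
  x <- generate_ar_process(0.5, 100000, seed = 4)
  r <- autocorrelation(x, 1)
  expect_equal(r[2] / r[1], 0.5, tolerance = 0.01)

  # reproducibility and zero-noise degeneracy
  expect_identical(generate_ar_process(0.5, 100, seed = 8),
                   generate_ar_process(0.5, 100, seed = 8))
  expect_equal(generate_ar_process(0.5, 100, noise_sd = 0, seed = 8),
               numeric(100))

  # instability is detected and reported with the root modulus
  expect_error(generate_ar_process(c(1.2), 100), "root modulus 1.200000")
  expect_error(generate_ar_process(c(0.9, 0.3), 100), "unstable")
})

test_that("mixed sources satisfy x = A s and identity mixing is transparent", {
  mx <- generate_mixed_sources(3, 500, mixing = diag(3), seed = 6)
  expect_identical(mx$observations, mx$sources)

  A <- matrix(c(1, 0.5, 0.2, 1.3, -0.4, 0.9, 0.1, 0.6, -1.1), 3)
  mx <- generate_mixed_sources(3, 500, mixing = A, seed = 6)
  expect_equal(mx$observations, A %*% mx$sources, tolerance = 1e-12)
  expect_error(generate_mixed_sources(2, 100, mixing = matrix(1, 2, 2)),
               "singular")
})
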