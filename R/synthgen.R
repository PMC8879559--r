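# Synthetic surface-EMG generator.
#
# The signal model is the classical additive one: each recorded channel is a
# superposition of motor-unit action-potential trains (MUAPTs) mixed across
# channels (crosstalk), plus additive white Gaussian instrumentation noise,
# a power-line tone, and a low-frequency (0-19 Hz) baseline-instability
# component emulating unstable motor-unit firing. Classes of a labelled
# trial set differ by a recruitment profile: per-motor-unit gains and firing
# rates, with class distinctness controlled by a separation parameter.

#' Motor unit action potential template
#'
#' A biphasic difference-of-Gaussians waveform, normalized to unit energy
#' (sum of squares = 1). The shape is a generic biphasic MUAP surrogate; the
#' physiological literature does not pin down a canonical analytic template,
#' and only duration and energy matter downstream.
#'
#' @param duration_ms support of the waveform in milliseconds.
#' @param fs_hz sampling rate used to discretize the template.
#' @param asymmetry relative offset of the negative lobe (0..1).
#' @return object of class `muap_template` with fields `waveform`
#'   (unit-energy numeric vector) and `duration_ms`.
#' @export
muap_template <- function(duration_ms = 12, fs_hz = 500, asymmetry = 0.35) {
  stopifnot(duration_ms > 0, fs_hz > 0)
  n <- max(3L, round(duration_ms / 1000 * fs_hz))
  t <- seq(0, 1, length.out = n)
  w <- exp(-((t - 0.4)^2) / (2 * 0.12^2)) -
    0.8 * exp(-((t - 0.4 - asymmetry * 0.5)^2) / (2 * 0.16^2))
  w <- w - mean(w)
  e <- sqrt(sum(w^2))
  if (e == 0) stop("degenerate template")
  structure(list(waveform = w / e, duration_ms = duration_ms),
            class = "muap_template")
}

#' Motor unit action potential train specification
#'
#' Discharges follow a renewal process: regular inter-discharge intervals of
#' `1/firing_rate_hz` seconds with independent Gaussian jitter. The mean
#' inter-discharge interval therefore equals `1/firing_rate_hz` up to
#' sampling error.
#'
#' @param template a [muap_template()].
#' @param firing_rate_hz mean discharge rate in Hz (> 0).
#' @param jitter_sd_ms standard deviation of interval jitter (ms, >= 0).
#' @param gain amplitude multiplier of the train.
#' @return object of class `muap_train`.
#' @export
muap_train <- function(template, firing_rate_hz, jitter_sd_ms = 2, gain = 1) {
  stopifnot(inherits(template, "muap_template"))
  if (!is.numeric(firing_rate_hz) || firing_rate_hz <= 0) {
    stop("firing_rate_hz must be positive")
  }
  stopifnot(jitter_sd_ms >= 0)
  structure(list(template = template, firing_rate_hz = firing_rate_hz,
                 jitter_sd_ms = jitter_sd_ms, gain = gain),
            class = "muap_train")
}

#' Simulate one motor unit action potential train
#'
#' Draws jittered discharge times over `[0, duration_s)`, builds the spike
#' train, and convolves it with the unit's template.
#'
#' @param train a [muap_train()].
#' @param fs_hz sampling rate in Hz.
#' @param duration_s signal duration in seconds (> 0).
#' @param seed integer seed; the draw is reproducible for a fixed seed.
#' @return numeric vector of `round(fs_hz * duration_s)` samples.
#' @export
generate_muapt <- function(train, fs_hz, duration_s, seed = 1) {
  stopifnot(inherits(train, "muap_train"))
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("duration_s must be positive")
  }
  stopifnot(fs_hz > 0)
  n <- round(fs_hz * duration_s)
  if (train$gain == 0) return(numeric(n))
  with_seed(seed, {
    isi <- 1 / train$firing_rate_hz
    n_max <- ceiling(duration_s / isi) + 5L
    jit <- stats::rnorm(n_max, 0, train$jitter_sd_ms / 1000)
    # renewal train anchored at t = 0: first discharge at 0, then
    # jittered regular intervals
    times <- cumsum(c(0, pmax(rep(isi, n_max) + jit, 1e-4)))
    times <- times[times >= 0 & times < duration_s]
    spikes <- numeric(n)
    idx <- floor(times * fs_hz) + 1L
    for (i in idx) spikes[i] <- spikes[i] + 1
    out <- .place_template(spikes, train$template$waveform)
    train$gain * out
  })
}

# convolve spike train with template, truncating at the end
.place_template <- function(spikes, w) {
  n <- length(spikes)
  full <- convolve(spikes, rev(w), type = "open")
  full[seq_len(n)]
}

#' Synthetic trial-set configuration
#'
#' Bundles every knob of the generator. Defaults mirror a two-channel,
#' 500 Hz grasp-classification recording setup: 6-second trials, a handful
#' of motor units with crosstalk mixing, 50 Hz line interference and
#' band-limited (0-19 Hz) baseline instability.
#'
#' @param n_channels number of recording channels (>= 1).
#' @param n_motor_units number of motor units (>= 0; 0 gives pure noise).
#' @param crosstalk_mixing n_channels x n_motor_units mixing matrix; default
#'   assigns each unit a primary channel with 0.35 bleed into the others.
#' @param fs_hz sampling rate (Hz).
#' @param duration_s trial length (s).
#' @param noise_sd standard deviation of the additive white noise.
#' @param line_hz power-line frequency (Hz).
#' @param line_amp amplitude of the line tone.
#' @param baseline_band_hz two-element band of the baseline instability
#'   component (Hz); its power is confined to this band by construction.
#' @param baseline_amp RMS amplitude of the baseline component.
#' @param seed integer seed governing template/recruitment draws.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_channels = 2, n_motor_units = 6,
                         crosstalk_mixing = NULL, fs_hz = 500,
                         duration_s = 6, noise_sd = 0.05,
                         line_hz = 50, line_amp = 0.02,
                         baseline_band_hz = c(0, 19), baseline_amp = 0.03,
                         seed = 1) {
  stopifnot(n_channels >= 1, n_motor_units >= 0, fs_hz > 0, duration_s > 0,
            noise_sd >= 0, line_amp >= 0, baseline_amp >= 0,
            length(baseline_band_hz) == 2,
            baseline_band_hz[1] >= 0,
            baseline_band_hz[2] > baseline_band_hz[1])
  if (is.null(crosstalk_mixing)) {
    crosstalk_mixing <- matrix(0.35, n_channels, max(n_motor_units, 1))
    if (n_motor_units > 0) {
      primary <- rep(seq_len(n_channels), length.out = n_motor_units)
      for (j in seq_len(n_motor_units)) crosstalk_mixing[primary[j], j] <- 1
    }
  }
  crosstalk_mixing <- as.matrix(crosstalk_mixing)
  if (n_motor_units > 0 &&
      (nrow(crosstalk_mixing) != n_channels ||
       ncol(crosstalk_mixing) != n_motor_units)) {
    stop("crosstalk_mixing must be n_channels x n_motor_units")
  }
  if (n_motor_units >= n_channels && n_motor_units > 0) {
    if (qr(crosstalk_mixing)$rank < n_channels) {
      warning("crosstalk mixing matrix is rank-deficient; ",
              "sources are not recoverable by ICA")
    }
  }
  structure(list(n_channels = n_channels, n_motor_units = n_motor_units,
                 crosstalk_mixing = crosstalk_mixing, fs_hz = fs_hz,
                 duration_s = duration_s, noise_sd = noise_sd,
                 line_hz = line_hz, line_amp = line_amp,
                 baseline_band_hz = baseline_band_hz,
                 baseline_amp = baseline_amp, seed = seed),
            class = "synth_config")
}

# additive noise for one trial: white + line tone + band-limited baseline.
# Drawn from its own seed so that signal and noise streams are separable
# (generating with noise_sd = 0 and adding this noise afterwards equals
# generating with noise included).
.trial_noise <- function(config, n, seed) {
  with_seed(seed, {
    noise <- matrix(stats::rnorm(config$n_channels * n, 0, config$noise_sd),
                    nrow = config$n_channels)
    tt <- (seq_len(n) - 1) / config$fs_hz
    for (ch in seq_len(config$n_channels)) {
      if (config$line_amp > 0) {
        phase <- stats::runif(1, 0, 2 * pi)
        noise[ch, ] <- noise[ch, ] +
          config$line_amp * sin(2 * pi * config$line_hz * tt + phase)
      }
      if (config$baseline_amp > 0) {
        noise[ch, ] <- noise[ch, ] +
          .bandlimited_noise(n, config$fs_hz, config$baseline_band_hz,
                             config$baseline_amp)
      }
    }
    noise
  })
}

# random signal with spectrum confined to [band[1], band[2]] Hz, given RMS;
# built in the frequency domain so the confinement is exact
.bandlimited_noise <- function(n, fs_hz, band, rms) {
  freqs <- seq(0, n - 1) * fs_hz / n
  spec <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
  keep <- (freqs > band[1] & freqs <= band[2]) |
    (freqs >= fs_hz - band[2] & freqs < fs_hz - band[1])
  spec[!keep] <- 0
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s * rms
}

# recruitment profile: per-class, per-unit gains and firing rates.
# Classes are spread on a gain/rate grid whose spacing scales with
# class_separation; separation 0 collapses all classes onto one profile.
.recruitment_profile <- function(n_classes, n_motor_units, class_separation,
                                 seed) {
  with_seed(seed, {
    base_gain <- stats::runif(n_motor_units, 0.8, 1.2)
    base_rate <- stats::runif(n_motor_units, 12, 22)
    lapply(seq_len(n_classes), function(cls) {
      phase <- 2 * pi * (cls - 1) / n_classes
      mod <- 1 + class_separation *
        sin(phase + 2 * pi * seq_len(n_motor_units) / n_motor_units)
      rate_mod <- 1 + 0.5 * class_separation *
        cos(phase + 2 * pi * seq_len(n_motor_units) / n_motor_units)
      list(gain = pmax(base_gain * mod, 0),
           rate = pmax(base_rate * rate_mod, 1))
    })
  })
}

#' Generate a labelled synthetic trial set
#'
#' Builds `n_classes * n_trials_per_class` trials. Motor-unit templates and
#' the class recruitment profiles are drawn once from `config$seed`; each
#' trial then draws its own discharge jitter and noise from seeds derived
#' deterministically from `config$seed` and the trial index, so the whole
#' set is bit-reproducible.
#'
#' @param config a [synth_config()].
#' @param n_classes number of movement classes (>= 2).
#' @param n_trials_per_class trials per class (>= 2).
#' @param class_separation nonnegative scalar scaling how distinct the class
#'   recruitment profiles are (0 = identical classes).
#' @return an [emg_trialset()], ordered by (class, repetition).
#' @export
generate_trialset <- function(config, n_classes = 6, n_trials_per_class = 30,
                              class_separation = 0.6) {
  stopifnot(inherits(config, "synth_config"))
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (n_trials_per_class < 2) stop("n_trials_per_class must be >= 2")
  n <- round(config$fs_hz * config$duration_s)
  templates <- with_seed(derive_seed(config$seed, "templates"), {
    lapply(seq_len(max(config$n_motor_units, 1)), function(j) {
      muap_template(duration_ms = stats::runif(1, 8, 16),
                    fs_hz = config$fs_hz)
    })
  })
  profiles <- .recruitment_profile(n_classes, config$n_motor_units,
                                   class_separation,
                                   derive_seed(config$seed, "recruitment"))
  trials <- list()
  labels <- integer(0)
  reps <- integer(0)
  for (cls in seq_len(n_classes)) {
    prof <- profiles[[cls]]
    for (rep_i in seq_len(n_trials_per_class)) {
      tag <- sprintf("trial_%d_%d", cls, rep_i)
      sig <- matrix(0, config$n_channels, n)
      if (config$n_motor_units > 0) {
        src <- matrix(0, config$n_motor_units, n)
        for (j in seq_len(config$n_motor_units)) {
          tr <- muap_train(templates[[j]], firing_rate_hz = prof$rate[j],
                           jitter_sd_ms = 2, gain = prof$gain[j])
          src[j, ] <- generate_muapt(
            tr, config$fs_hz, config$duration_s,
            seed = derive_seed(config$seed, paste0(tag, "_mu", j)))
        }
        sig <- config$crosstalk_mixing %*% src
      }
      sig <- sig + .trial_noise(config, n,
                                derive_seed(config$seed,
                                            paste0(tag, "_noise")))
      trials[[length(trials) + 1L]] <- emg_signal(sig, config$fs_hz)
      labels <- c(labels, cls)
      reps <- c(reps, rep_i)
    }
  }
  emg_trialset(trials, labels, subject_id = "synthetic", repetition = reps)
}

#' Simulate a stationary autoregressive process
#'
#' Simulates `x(n) = sum_k a_k x(n-k) + w(n)` with Gaussian innovations
#' (regression-on-past sign convention). Stability is checked via the
#' characteristic roots; a burn-in of `burn_in` samples (default `10 * p`)
#' is discarded so the returned series is effectively stationary.
#'
#' @param coeffs numeric vector `a_1..a_p` (may be empty for white noise).
#' @param n output length.
#' @param noise_sd innovation standard deviation.
#' @param seed integer seed.
#' @param burn_in samples to discard (default `10 * length(coeffs)`).
#' @return numeric vector of length `n`.
#' @export
generate_ar_process <- function(coeffs, n, noise_sd = 1, seed = 1,
                                burn_in = NULL) {
  p <- length(coeffs)
  stopifnot(n >= 1, noise_sd >= 0)
  if (p > 0) {
    # roots of z^p - a_1 z^(p-1) - ... - a_p
    rts <- polyroot(c(-rev(coeffs), 1))
    bad <- Mod(rts) >= 1 - 1e-12
    if (any(bad)) {
      stop(sprintf(
        "unstable AR coefficients: characteristic root modulus %.6f >= 1",
        max(Mod(rts))))
    }
  }
  if (is.null(burn_in)) burn_in <- 10L * p
  ntot <- n + burn_in
  with_seed(seed, {
    w <- stats::rnorm(ntot, 0, noise_sd)
    x <- if (p == 0) w else {
      as.numeric(stats::filter(w, coeffs, method = "recursive"))
    }
    x[(burn_in + 1):ntot]
  })
}

#' Generate linearly mixed non-Gaussian sources
#'
#' Draws `n_sources` independent non-Gaussian source series and returns both
#' the sources and their exact linear mixtures `x = A s` — the ground truth
#' for blind-source-separation recovery scoring.
#'
#' @param n_sources number of sources.
#' @param n_samples samples per source.
#' @param mixing square invertible mixing matrix `A`; default a random
#'   orthogonal matrix drawn from the seed.
#' @param source_family `"uniform"` (default) or `"laplace"`.
#' @param seed integer seed.
#' @return list with `sources` (n_sources x n_samples), `observations`
#'   (`mixing %*% sources`), and `mixing`.
#' @export
generate_mixed_sources <- function(n_sources, n_samples, mixing = NULL,
                                   source_family = c("uniform", "laplace"),
                                   seed = 1) {
  source_family <- match.arg(source_family)
  stopifnot(n_sources >= 1, n_samples >= 1)
  with_seed(seed, {
    if (is.null(mixing)) {
      mixing <- qr.Q(qr(matrix(stats::rnorm(n_sources^2), n_sources)))
    }
    mixing <- as.matrix(mixing)
    stopifnot(nrow(mixing) == n_sources, ncol(mixing) == n_sources)
    if (abs(det(mixing)) < 1e-12) stop("mixing matrix is singular")
    s <- switch(source_family,
                uniform = matrix(stats::runif(n_sources * n_samples,
                                              -sqrt(3), sqrt(3)),
                                 nrow = n_sources),
                laplace = {
                  u <- stats::runif(n_sources * n_samples, -0.5, 0.5)
                  matrix(-sign(u) * log(1 - 2 * abs(u)) / sqrt(2),
                         nrow = n_sources)
                })
    list(sources = s, observations = mixing %*% s, mixing = mixing)
  })
}
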