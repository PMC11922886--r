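# Synthetic multichannel EEG forward model. Each trial is the sum of a
# stimulus-locked harmonic response, 1/f^gamma background noise, and
# band-limited theta/alpha/beta components whose power drifts linearly over
# the four tasks of a block. The generator's job is to reproduce the
# session structure and the statistical features the downstream analyses
# assume, not biophysical realism.

#' Session layout
#'
#' Structure of a recording campaign: subjects x brightness levels x
#' stimulation frequencies (tasks) x trials, six parieto-occipital channels
#' sampled at 1200 Hz, 5-s trials flanked by a 1-s cue and a 1-s gray
#' screen, one block per paradigm. With the defaults a trial holds
#' `1200 * 5 = 6000` samples per channel.
#'
#' @param n_subjects Number of subjects (default 10).
#' @param brightness_levels Brightness level labels.
#' @param frequencies_hz Stimulation frequencies; task `i` uses frequency `i`.
#' @param trials_per_run Trials per run (default 20).
#' @param channels Channel labels.
#' @param sampling_rate_hz Sampling rate in Hz (default 1200).
#' @param trial_seconds,cue_seconds,gray_seconds Trial, cue and inter-trial
#'   gray-screen durations in seconds.
#' @param blocks Paradigm labels, one block each.
#' @return Object of class `session_layout`.
#' @export
session_layout <- function(n_subjects = 10,
                           brightness_levels = c("low", "medium", "high"),
                           frequencies_hz = c(3, 3.5, 4, 4.5),
                           trials_per_run = 20,
                           channels = c("Po3", "Poz", "Po4", "O1", "Oz", "O2"),
                           sampling_rate_hz = 1200,
                           trial_seconds = 5,
                           cue_seconds = 1,
                           gray_seconds = 1,
                           blocks = c("bimodal", "single_motion", "single_color")) {
  brightness_levels <- unlist(brightness_levels)
  frequencies_hz <- unlist(frequencies_hz)
  channels <- unlist(channels)
  blocks <- unlist(blocks)
  if (n_subjects < 1 || trials_per_run < 1) {
    .err("layout counts must be positive", "ssmvep_domain_error")
  }
  samples <- sampling_rate_hz * trial_seconds
  if (abs(samples - round(samples)) > 1e-9) {
    .err("trial_seconds * sampling_rate_hz must be an integer",
         "ssmvep_domain_error")
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    brightness_levels = brightness_levels,
    frequencies_hz = frequencies_hz,
    trials_per_run = as.integer(trials_per_run),
    channels = channels,
    n_channels = length(channels),
    sampling_rate_hz = sampling_rate_hz,
    trial_seconds = trial_seconds,
    cue_seconds = cue_seconds,
    gray_seconds = gray_seconds,
    blocks = blocks,
    tasks_per_block = length(frequencies_hz),
    samples_per_trial = as.integer(round(samples))
  ), class = "session_layout")
}

#' @export
print.session_layout <- function(x, ...) {
  cat(sprintf(
    "session_layout: %d subjects x %d brightness x %d tasks x %d trials, %d ch x %d samples @ %g Hz, blocks: %s\n",
    x$n_subjects, length(x$brightness_levels), x$tasks_per_block,
    x$trials_per_run, x$n_channels, x$samples_per_trial, x$sampling_rate_hz,
    paste(x$blocks, collapse = ", ")))
  invisible(x)
}

#' Response model for the synthetic EEG generator
#'
#' @param harmonic_amplitudes Amplitudes (microvolt) of the stimulus-locked
#'   response at harmonics 1..H. Default `c(1, 0.4)`: a clear fundamental
#'   with a visible second harmonic.
#' @param paradigm_gain Named multipliers per paradigm; the default ordering
#'   bimodal > single_motion > single_color encodes the calibration that
#'   bimodal stimulation evokes the strongest response.
#' @param brightness_gain Named multipliers per brightness level (medium
#'   strongest by default).
#' @param channel_gains Per-channel gains on the evoked response.
#' @param phase Phase (radians) per harmonic, recycled to H.
#' @param noise_exponent Spectral slope gamma of the 1/f^gamma background.
#' @param noise_scale Standard deviation (microvolt) of the background noise.
#' @param band_powers Named powers (microvolt^2) of the band-limited
#'   theta/alpha/beta components; the alpha component doubles as the
#'   posterior alpha rhythm.
#' @param band_drift_slopes Named per-task fractional power change of each
#'   band component: power at task `k` is `P * (1 + slope * (k - 1))`.
#' @param subject_sigma Log-normal sigma of the multiplicative inter-subject
#'   response-amplitude factor.
#' @return Object of class `response_model`.
#' @export
response_model <- function(harmonic_amplitudes = c(1, 0.4),
                           paradigm_gain = c(bimodal = 1, single_motion = 0.75,
                                             single_color = 0.6),
                           brightness_gain = c(low = 0.85, medium = 1,
                                               high = 0.9),
                           channel_gains = c(1, 1.1, 1, 0.9, 1.05, 0.95),
                           phase = c(0, pi / 4),
                           noise_exponent = 1,
                           noise_scale = 1,
                           band_powers = c(theta = 2, alpha = 3, beta = 1),
                           band_drift_slopes = c(theta = 0, alpha = 0, beta = 0),
                           subject_sigma = 0.3) {
  # accept list-valued arguments (e.g. from YAML configs)
  harmonic_amplitudes <- unlist(harmonic_amplitudes)
  paradigm_gain <- unlist(paradigm_gain)
  brightness_gain <- unlist(brightness_gain)
  channel_gains <- unlist(channel_gains)
  phase <- unlist(phase)
  band_powers <- unlist(band_powers)
  band_drift_slopes <- unlist(band_drift_slopes)
  if (any(harmonic_amplitudes < 0) || noise_scale < 0 || any(band_powers < 0)) {
    .err("amplitudes and powers must be non-negative", "ssmvep_domain_error")
  }
  H <- length(harmonic_amplitudes)
  structure(list(
    harmonic_amplitudes = harmonic_amplitudes,
    paradigm_gain = paradigm_gain,
    brightness_gain = brightness_gain,
    channel_gains = channel_gains,
    phase = rep_len(phase, H),
    noise_exponent = noise_exponent,
    noise_scale = noise_scale,
    band_powers = band_powers,
    band_drift_slopes = band_drift_slopes,
    subject_sigma = subject_sigma
  ), class = "response_model")
}

# Conventional clinical band edges, shared with the workload module.
.default_bands <- list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))

# Run expr with a private RNG state seeded by `seed`.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stable integer hash of a master seed plus index coordinates, < 2^31.
.derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.double(master) %% 2147483647
  for (v in idx) {
    h <- (h * 69069 + as.double(v) * 2654435761) %% 2147483647
  }
  as.integer(h)
}

# Squared DFT shaping weights for 1/f^gamma noise on an N-point grid
# (flat below 1 Hz to keep the spectrum integrable).
.one_over_f_weights2 <- function(n, fs, gamma) {
  k <- seq_len(n %/% 2 - 1L)
  f <- k * fs / n
  pmax(f, 1)^(-gamma)
}

# Hermitian-spectrum Gaussian noise with squared spectral weights w2
# (length n/2 - 1) scaled to total variance `power`.
.shaped_noise <- function(n, w2, power) {
  if (power <= 0 || all(w2 == 0)) return(numeric(n))
  half <- n %/% 2 - 1L
  z <- complex(real = stats::rnorm(half), imaginary = stats::rnorm(half))
  X <- complex(length.out = n)
  X[2:(half + 1L)] <- sqrt(w2) * z
  X[n:(n - half + 1L)] <- Conj(X[2:(half + 1L)])
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x * sqrt(power) / sqrt(4 * sum(w2) / n^2)
}

.band_indicator2 <- function(n, fs, band) {
  k <- seq_len(n %/% 2 - 1L)
  f <- k * fs / n
  as.numeric(f >= band[[1L]] & f < band[[2L]])
}

# Expected power of the 1/f background falling inside `band`.
.background_band_power <- function(model, layout, band) {
  n <- layout$samples_per_trial
  w2 <- .one_over_f_weights2(n, layout$sampling_rate_hz, model$noise_exponent)
  ind <- .band_indicator2(n, layout$sampling_rate_hz, band)
  model$noise_scale^2 * sum(w2 * ind) / sum(w2)
}

#' Analytic band power of the generative model
#'
#' Expected power (microvolt^2, per channel) that the model places inside a
#' frequency band at a given task index: the band-limited component (with
#' its task drift applied) plus the share of the 1/f background falling in
#' the band. Evoked-response harmonics are not included.
#'
#' @param model A [response_model()].
#' @param layout A [session_layout()].
#' @param band `c(low, high)` in Hz, or a band name `"theta"`, `"alpha"`,
#'   `"beta"`.
#' @param task_index Task position 1..4 (applies the drift slope).
#' @return Expected power in the band.
#' @export
analytic_band_power <- function(model, layout, band, task_index = 1) {
  if (is.character(band)) {
    nm <- band
    band <- .default_bands[[nm]]
  } else {
    nm <- NULL
  }
  bg <- .background_band_power(model, layout, band)
  comp <- 0
  for (b in names(model$band_powers)) {
    bb <- .default_bands[[b]]
    ov <- c(max(band[[1L]], bb[[1L]]), min(band[[2L]], bb[[2L]]))
    if (ov[[2L]] <= ov[[1L]]) next
    drift <- 1 + model$band_drift_slopes[[b]] * (task_index - 1)
    frac <- (ov[[2L]] - ov[[1L]]) / (bb[[2L]] - bb[[1L]])
    comp <- comp + model$band_powers[[b]] * max(drift, 0) * frac
  }
  bg + comp
}

#' Analytic signal and noise powers of a generated trial
#'
#' Closed-form per-channel powers implied by the model: evoked power
#' `sum_h (A_h * gain)^2 / 2` over the harmonics inside the analysis band,
#' and total non-evoked (background + band component) power in the band.
#' Used as the ground truth when validating the SNR estimator.
#'
#' @inheritParams analytic_band_power
#' @param frequency_hz Stimulation frequency.
#' @param paradigm Paradigm label (applies `paradigm_gain`).
#' @param band Analysis band `c(low, high)` in Hz.
#' @param n_harmonics Harmonics included as signal.
#' @param brightness Brightness level label.
#' @return List with `signal_power`, `noise_power`, `snr_db`, each averaged
#'   over channels.
#' @export
analytic_trial_snr <- function(model, layout, frequency_hz,
                               paradigm = "bimodal", band = c(1, 45),
                               n_harmonics = 4, brightness = "medium") {
  g <- model$paradigm_gain[[paradigm]] * model$brightness_gain[[brightness]]
  H <- length(model$harmonic_amplitudes)
  sig <- 0
  for (h in seq_len(min(H, n_harmonics))) {
    fh <- h * frequency_hz
    if (fh >= band[[1L]] && fh < band[[2L]] &&
        fh <= layout$sampling_rate_hz / 2) {
      sig <- sig + mean((model$harmonic_amplitudes[[h]] * g *
                           model$channel_gains)^2) / 2
    }
  }
  noise <- analytic_band_power(model, layout, band, task_index = 1)
  list(signal_power = sig, noise_power = noise,
       snr_db = 10 * log10(sig / noise))
}

#' Generate one synthetic EEG trial
#'
#' One trial of `n_channels x samples_per_trial` samples: stimulus-locked
#' harmonics plus 1/f background plus band-limited theta/alpha/beta
#' components, deterministic given `seed`.
#'
#' @inheritParams analytic_trial_snr
#' @param seed Integer seed for this trial.
#' @param task_index Task position (drives band-power drifts).
#' @param subject_gain Multiplicative subject factor (1 = average subject).
#' @return Matrix `n_channels x samples_per_trial` (microvolt).
#' @export
generate_trial <- function(layout, model, frequency_hz,
                           paradigm = "bimodal", seed = 1,
                           task_index = 1, subject_gain = 1,
                           brightness = "medium") {
  if (!frequency_hz %in% layout$frequencies_hz && frequency_hz <= 0) {
    .err("frequency_hz must be positive", "ssmvep_domain_error")
  }
  n <- layout$samples_per_trial
  fs <- layout$sampling_rate_hz
  tt <- (seq_len(n) - 1L) / fs
  g <- model$paradigm_gain[[paradigm]] * model$brightness_gain[[brightness]] *
    subject_gain
  chg <- rep_len(model$channel_gains, layout$n_channels)

  sig <- numeric(n)
  for (h in seq_along(model$harmonic_amplitudes)) {
    sig <- sig + model$harmonic_amplitudes[[h]] *
      sin(2 * pi * h * frequency_hz * tt + model$phase[[h]])
  }
  x <- outer(chg * g, sig)

  .with_seed(seed, {
    w2_bg <- .one_over_f_weights2(n, fs, model$noise_exponent)
    for (c_i in seq_len(layout$n_channels)) {
      row <- .shaped_noise(n, w2_bg, model$noise_scale^2)
      for (b in names(model$band_powers)) {
        drift <- 1 + model$band_drift_slopes[[b]] * (task_index - 1)
        p <- model$band_powers[[b]] * max(drift, 0)
        row <- row + .shaped_noise(n, .band_indicator2(n, fs, .default_bands[[b]]), p)
      }
      x[c_i, ] <- x[c_i, ] + row
    }
  })
  dimnames(x) <- list(layout$channels, NULL)
  x
}

#' Trial tensor container
#'
#' Holds a stack of EEG trials (`n_trials x n_channels x n_samples`)
#' together with a label table (one row per trial: subject, paradigm,
#' brightness, frequency, task and trial indices) and sampling metadata.
#'
#' @param data 3-d numeric array, trials x channels x samples.
#' @param info Data frame with one row per trial.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param channels Channel labels.
#' @return Object of class `trial_tensor`.
#' @export
trial_tensor <- function(data, info, sampling_rate_hz, channels = NULL) {
  if (length(dim(data)) != 3L) .err("data must be a 3-d array",
                                    "ssmvep_domain_error")
  if (nrow(info) != dim(data)[[1L]]) {
    .err("info must have one row per trial", "ssmvep_domain_error")
  }
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[[2L]]))
  structure(list(data = data, info = info,
                 sampling_rate_hz = sampling_rate_hz,
                 channels = channels),
            class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("trial_tensor: %d trials x %d channels x %d samples @ %g Hz\n",
              d[[1L]], d[[2L]], d[[3L]], x$sampling_rate_hz))
  if (nrow(x$info) > 0) {
    for (col in c("subject", "paradigm", "brightness", "frequency_hz")) {
      if (col %in% names(x$info)) {
        cat(sprintf("  %s: %s\n", col,
                    paste(unique(x$info[[col]]), collapse = ", ")))
      }
    }
  }
  invisible(x)
}

#' Subset a trial tensor by trial
#' @param x A `trial_tensor`.
#' @param i Trial indices or logical mask.
#' @param ... Unused.
#' @export
`[.trial_tensor` <- function(x, i, ...) {
  trial_tensor(x$data[i, , , drop = FALSE], x$info[i, , drop = FALSE],
               x$sampling_rate_hz, x$channels)
}

#' Generate a full synthetic session
#'
#' Iterates subjects x blocks (paradigms) x brightness levels x tasks
#' (frequencies) x trials, deriving one stable seed per trial from the
#' master seed, applying per-subject log-normal response factors and
#' per-task band-power drifts.
#'
#' @inheritParams generate_trial
#' @param seed Master seed; every trial's seed is a stable hash of the
#'   master seed and its (subject, block, brightness, task, trial) indices.
#' @param paradigms,brightness_levels Optional subsets of the layout's
#'   blocks/brightness levels, to generate partial sessions.
#' @return A [trial_tensor()] with full label metadata.
#' @export
generate_session <- function(layout, model, seed = 1,
                             paradigms = layout$blocks,
                             brightness_levels = layout$brightness_levels) {
  n_trials <- layout$n_subjects * length(paradigms) *
    length(brightness_levels) * layout$tasks_per_block * layout$trials_per_run
  data <- array(0, dim = c(n_trials, layout$n_channels,
                           layout$samples_per_trial))
  info <- data.frame(
    subject = integer(n_trials), paradigm = character(n_trials),
    brightness = character(n_trials), task = integer(n_trials),
    frequency_hz = numeric(n_trials), trial = integer(n_trials),
    area_ratio_C = numeric(n_trials),
    stringsAsFactors = FALSE
  )
  subj_gain <- .with_seed(.derive_seed(seed, 0L), {
    exp(model$subject_sigma * stats::rnorm(layout$n_subjects))
  })
  row <- 0L
  for (s in seq_len(layout$n_subjects)) {
    for (b in seq_along(paradigms)) {
      for (br in seq_along(brightness_levels)) {
        for (task in seq_len(layout$tasks_per_block)) {
          for (tr in seq_len(layout$trials_per_run)) {
            row <- row + 1L
            trial_seed <- .derive_seed(seed, s, b, br, task, tr)
            data[row, , ] <- generate_trial(
              layout, model, layout$frequencies_hz[[task]],
              paradigm = paradigms[[b]], seed = trial_seed,
              task_index = task, subject_gain = subj_gain[[s]],
              brightness = brightness_levels[[br]])
            info$subject[[row]] <- s
            info$paradigm[[row]] <- paradigms[[b]]
            info$brightness[[row]] <- brightness_levels[[br]]
            info$task[[row]] <- task
            info$frequency_hz[[row]] <- layout$frequencies_hz[[task]]
            info$trial[[row]] <- tr
            info$area_ratio_C[[row]] <- 0.6
          }
        }
      }
    }
  }
  trial_tensor(data, info, layout$sampling_rate_hz, layout$channels)
}
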