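# Shared fixture builders: reduced-scale layouts and models so tests run in
# seconds while keeping the structure of the full study design.

tiny_layout <- function(n_subjects = 1, trials_per_run = 10,
                        sampling_rate_hz = 300, trial_seconds = 2) {
  session_layout(n_subjects = n_subjects, trials_per_run = trials_per_run,
                 sampling_rate_hz = sampling_rate_hz,
                 trial_seconds = trial_seconds)
}

noiseless_model <- function(...) {
  response_model(noise_scale = 0, band_powers = c(theta = 0, alpha = 0,
                                                  beta = 0),
                 subject_sigma = 0, ...)
}

# Moderate-SNR model: responses recognisable but not saturated.
moderate_model <- function(noise_scale = 3, ...) {
  response_model(noise_scale = noise_scale,
                 band_powers = c(theta = noise_scale^2 / 4,
                                 alpha = noise_scale^2 / 3,
                                 beta = noise_scale^2 / 8),
                 subject_sigma = 0.2, ...)
}

# Bind two trial arrays along the trial axis.
abind_simple <- function(a, b) {
  out <- array(0, c(dim(a)[[1L]] + dim(b)[[1L]], dim(a)[-1L]))
  out[seq_len(dim(a)[[1L]]), , ] <- a
  out[dim(a)[[1L]] + seq_len(dim(b)[[1L]]), , ] <- b
  out
}

# Averaged Welch PSD over the trials of a tensor (channel-averaged).
averaged_psd <- function(tensor, window_seconds = 2) {
  n_tr <- dim(tensor$data)[[1L]]
  acc <- NULL
  for (i in seq_len(n_tr)) {
    sp <- welch_psd(tensor$data[i, , ], tensor$sampling_rate_hz,
                    window_seconds = window_seconds)
    acc <- if (is.null(acc)) sp$values / n_tr else acc + sp$values / n_tr
  }
  sp$values <- acc
  sp
}
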