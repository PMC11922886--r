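# Spectral analyses: Welch power spectral density, harmonic SNR, and FFT
# amplitude spectra of trial averages.

#' Welch power spectral density
#'
#' Averaged modified periodograms: Hann-windowed, mean-removed, overlapping
#' segments, one-sided density normalisation (`sum(values) * resolution_hz`
#' equals the signal variance for stationary inputs). Matrix input is
#' treated as channels x samples and the per-channel densities are averaged
#' (per-channel values are retained in `values_by_channel`).
#'
#' @param x Numeric vector, or channels x samples matrix.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param window_seconds Segment length in seconds (default 2: 0.5 Hz
#'   resolution, enough to resolve 3 from 3.5 Hz).
#' @param overlap Fractional segment overlap (default 0.5).
#' @return Object of class `spectrum_result` with `freqs_hz`, `values`
#'   (density, microvolt^2/Hz), `kind = "welch_psd"`, `resolution_hz`, and
#'   the window's equivalent noise bandwidth `enbw_bins` used for harmonic
#'   power readings.
#' @export
welch_psd <- function(x, sampling_rate_hz, window_seconds = 2,
                      overlap = 0.5) {
  m <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  n <- ncol(m)
  L <- as.integer(round(window_seconds * sampling_rate_hz))
  if (L > n) .err("window longer than the signal", "ssmvep_spectral_error")
  if (L < 8L) .err("window too short", "ssmvep_spectral_error")
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(L) - 1L) / L))  # periodic Hann
  U <- sum(w^2)
  half <- L %/% 2
  scale <- 1 / (sampling_rate_hz * U)

  psd <- matrix(0, nrow(m), half + 1L)
  for (ch in seq_len(nrow(m))) {
    acc <- numeric(half + 1L)
    for (s in starts) {
      seg <- m[ch, s:(s + L - 1L)]
      seg <- (seg - mean(seg)) * w
      X <- stats::fft(seg)[1:(half + 1L)]
      acc <- acc + Mod(X)^2
    }
    p <- acc / length(starts) * scale
    p[2:half] <- 2 * p[2:half]  # one-sided (DC and Nyquist unscaled)
    psd[ch, ] <- p
  }
  values <- colMeans(psd)
  structure(list(
    freqs_hz = (0:half) * sampling_rate_hz / L,
    values = values,
    values_by_channel = psd,
    kind = "welch_psd",
    resolution_hz = sampling_rate_hz / L,
    enbw_bins = L * U / sum(w)^2,
    sampling_rate_hz = sampling_rate_hz,
    n_segments = length(starts)
  ), class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("spectrum_result (%s): %d bins, 0-%g Hz at %g Hz resolution\n",
              x$kind, length(x$freqs_hz), max(x$freqs_hz), x$resolution_hz))
  invisible(x)
}

#' Harmonic signal-to-noise ratio from a PSD
#'
#' Signal power is the summed power at the bins nearest the first
#' `n_harmonics` multiples of the stimulation frequency; noise power is the
#' remaining power in the analysis band; the ratio is reported in dB,
#' `10 log10(signal / noise)`. Harmonic bin readings are converted from
#' density to sinusoid power with the window's equivalent-noise-bandwidth
#' factor (a bin-centred sinusoid of amplitude A then reads exactly A^2/2),
#' and by default the local noise floor (flanking bins) is subtracted from
#' each harmonic reading so the estimate stays unbiased when the response is
#' weak. Harmonics above the Nyquist frequency or outside the analysis band
#' are dropped with a note.
#'
#' @param psd A `spectrum_result` from [welch_psd()].
#' @param stimulus_freq_hz Stimulation frequency in Hz.
#' @param n_harmonics Number of harmonics summed as signal (default 4).
#' @param band Analysis band `c(low, high)` in Hz for the noise total
#'   (default 1-45 Hz, below the powerline notch).
#' @param correct_noise_floor Subtract the local noise-floor estimate from
#'   each harmonic power reading (default `TRUE`).
#' @return Object of class `snr_result` with `snr_db`, `signal_power`,
#'   `noise_power`, the harmonic frequencies used, and an `infinite` flag
#'   for the degenerate pure-signal case.
#' @export
compute_snr <- function(psd, stimulus_freq_hz, n_harmonics = 4,
                        band = c(1, 45), correct_noise_floor = TRUE) {
  if (!inherits(psd, "spectrum_result") || psd$kind != "welch_psd") {
    .err("psd must be a welch_psd spectrum_result", "ssmvep_domain_error")
  }
  fr <- psd$freqs_hz
  df <- psd$resolution_hz
  nyq <- psd$sampling_rate_hz / 2
  harm <- (1:n_harmonics) * stimulus_freq_hz
  usable <- harm <= nyq & harm >= band[[1L]] & harm <= band[[2L]]
  if (any(!usable)) {
    message(sprintf("dropping %d harmonic(s) outside the analysis band",
                    sum(!usable)))
  }
  harm <- harm[usable]
  if (length(harm) == 0L) {
    .err("no usable harmonics in the analysis band", "ssmvep_spectral_error")
  }
  bins <- vapply(harm, function(f) which.min(abs(fr - f)), integer(1))

  in_band <- which(fr >= band[[1L]] & fr <= band[[2L]])
  total <- sum(psd$values[in_band]) * df

  harm_power <- numeric(length(bins))
  for (i in seq_along(bins)) {
    b <- bins[[i]]
    p <- psd$values[[b]] * df * psd$enbw_bins
    if (correct_noise_floor) {
      neigh <- setdiff(intersect((b - 4L):(b + 4L), in_band),
                       unlist(lapply(bins, function(x) (x - 1L):(x + 1L))))
      if (length(neigh) > 0L) {
        p <- p - mean(psd$values[neigh]) * df * psd$enbw_bins
      }
    }
    harm_power[[i]] <- max(p, 0)
  }
  signal <- sum(harm_power)
  noise <- total - signal
  infinite <- noise <= 0
  snr_db <- if (infinite) Inf else 10 * log10(signal / noise)
  structure(list(
    stimulus_freq_hz = stimulus_freq_hz,
    n_harmonics = n_harmonics,
    harmonics_used = harm,
    harmonic_power = harm_power,
    snr_db = snr_db,
    signal_power = signal,
    noise_power = noise,
    band = band,
    infinite = infinite
  ), class = "snr_result")
}

#' @export
print.snr_result <- function(x, ...) {
  cat(sprintf("snr_result: %g Hz, %d harmonic(s) [%s], SNR = %.2f dB\n",
              x$stimulus_freq_hz, length(x$harmonics_used),
              paste(x$harmonics_used, collapse = ", "), x$snr_db))
  invisible(x)
}

#' FFT amplitude spectrum of an averaged response
#'
#' One-sided amplitude spectrum `2 |X_k| / N` of a trial-averaged response
#' (apply the `fft_2_40` preset first when mirroring the evaluation chain);
#' a 5-s average gives a 0.2 Hz grid, placing all study frequencies exactly
#' on grid points. Matrix input averages the per-channel amplitude spectra.
#'
#' @param avg Averaged response: vector or channels x samples matrix.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @return A `spectrum_result` with `kind = "fft_amplitude"`.
#' @export
fft_amplitude_spectrum <- function(avg, sampling_rate_hz) {
  m <- if (is.matrix(avg)) avg else matrix(avg, nrow = 1L)
  n <- ncol(m)
  half <- n %/% 2
  amp <- matrix(0, nrow(m), half + 1L)
  for (ch in seq_len(nrow(m))) {
    X <- stats::fft(m[ch, ] - mean(m[ch, ]))[1:(half + 1L)]
    a <- Mod(X) / n
    a[2:half] <- 2 * a[2:half]
    amp[ch, ] <- a
  }
  structure(list(
    freqs_hz = (0:half) * sampling_rate_hz / n,
    values = colMeans(amp),
    values_by_channel = amp,
    kind = "fft_amplitude",
    resolution_hz = sampling_rate_hz / n,
    sampling_rate_hz = sampling_rate_hz
  ), class = "spectrum_result")
}

#' Locate spectral peaks near candidate frequencies
#'
#' For each candidate, returns the grid frequency with maximal value within
#' `tol_hz` of the candidate.
#'
#' @param spec A `spectrum_result`.
#' @param candidates Candidate frequencies in Hz.
#' @param tol_hz Search half-width (default 0.5 Hz).
#' @return Data frame with `candidate_hz`, `peak_hz`, `value`.
#' @export
find_spectral_peaks <- function(spec, candidates, tol_hz = 0.5) {
  out <- data.frame(candidate_hz = candidates, peak_hz = NA_real_,
                    value = NA_real_)
  for (i in seq_along(candidates)) {
    sel <- which(abs(spec$freqs_hz - candidates[[i]]) <= tol_hz + 1e-9)
    if (length(sel) == 0L) next
    top <- sel[[which.max(spec$values[sel])]]
    out$peak_hz[[i]] <- spec$freqs_hz[[top]]
    out$value[[i]] <- spec$values[[top]]
  }
  out
}

#' Export a spectrum as CSV (freq, value)
#' @param spec A `spectrum_result`.
#' @param path Output CSV path.
#' @export
write_spectrum_csv <- function(spec, path) {
  utils::write.csv(data.frame(freq_hz = spec$freqs_hz, value = spec$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export an SNR result as a JSON summary
#' @param snr An `snr_result` (or list of them).
#' @param path Output JSON path.
#' @export
write_snr_json <- function(snr, path) {
  as_lst <- function(s) list(freq = s$stimulus_freq_hz, snr_db = s$snr_db,
                             harmonics_used = s$harmonics_used)
  lst <- if (inherits(snr, "snr_result")) as_lst(snr) else lapply(snr, as_lst)
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
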