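# Welch PSD, harmonic SNR and FFT amplitude spectra.

test_that("Welch PSD satisfies Parseval and is flat for white noise", {
  set.seed(2)
  fs <- 300
  x <- rnorm(6000)
  sp <- welch_psd(x, fs)
  expect_true(all(sp$values >= 0))
  expect_equal(sp$resolution_hz, fs / (2 * fs))
  expect_lt(abs(sum(sp$values) * sp$resolution_hz - var(x)) / var(x), 0.05)
  # flat within estimation error: compare lower and upper half-band power
  mid <- length(sp$values) %/% 2
  p1 <- mean(sp$values[2:mid]); p2 <- mean(sp$values[(mid + 1):(2 * mid - 1)])
  expect_lt(abs(p1 - p2) / p1, 0.15)
  expect_error(welch_psd(rnorm(100), fs, window_seconds = 2),
               class = "ssmvep_spectral_error")
})

test_that("a bin-centred sinusoid reads A^2/2 and spectra superpose", {
  fs <- 300
  tt <- (0:5999) / fs
  A1 <- 2; A2 <- 0.7
  x1 <- A1 * sin(2 * pi * 10 * tt)
  x2 <- A2 * sin(2 * pi * 21 * tt)
  peak_power <- function(sp, f) {
    b <- which.min(abs(sp$freqs_hz - f))
    sp$values[[b]] * sp$resolution_hz * sp$enbw_bins
  }
  sp1 <- welch_psd(x1, fs)
  expect_equal(peak_power(sp1, 10), A1^2 / 2, tolerance = 1e-6)
  sp12 <- welch_psd(x1 + x2, fs)
  expect_equal(peak_power(sp12, 10), A1^2 / 2, tolerance = 1e-3)
  expect_equal(peak_power(sp12, 21), A2^2 / 2, tolerance = 1e-3)
})

test_that("SNR recovers an analytic sinusoid-in-noise construction", {
  lay <- session_layout(n_subjects = 1)
  f0 <- 4
  mod <- response_model(harmonic_amplitudes = sqrt(2), phase = 0,
                        channel_gains = rep(1, 6), noise_scale = 1,
                        band_powers = c(theta = 0, alpha = 0, beta = 0),
                        subject_sigma = 0)
  truth <- analytic_trial_snr(mod, lay, f0, n_harmonics = 4)
  acc <- NULL
  for (i in 1:40) {
    sp <- welch_psd(generate_trial(lay, mod, f0, seed = i), 1200)
    acc <- if (is.null(acc)) sp$values / 40 else acc + sp$values / 40
  }
  sp$values <- acc
  est <- compute_snr(sp, f0, n_harmonics = 4)
  expect_lt(abs(est$snr_db - truth$snr_db), 1)
  expect_equal(est$snr_db,
               10 * log10(est$signal_power / est$noise_power))
})

test_that("doubling the signal amplitude raises SNR by about 6 dB", {
  fs <- 300
  tt <- (0:5999) / fs
  set.seed(4)
  noise <- apply_filter_chain(rnorm(6000, sd = 2), "fft_2_40", fs)
  snr_for <- function(A) {
    xs <- A * sin(2 * pi * 8 * tt) + noise
    compute_snr(welch_psd(xs, fs), 8, n_harmonics = 1, band = c(2, 40))$snr_db
  }
  expect_equal(snr_for(2) - snr_for(1), 10 * log10(4), tolerance = 0.5)
})

test_that("harmonic bookkeeping adds exactly the 2f bin's power", {
  fs <- 300
  tt <- (0:5999) / fs
  set.seed(5)
  x <- sin(2 * pi * 6 * tt) + 0.5 * sin(2 * pi * 12 * tt) + rnorm(6000, sd = 0.5)
  sp <- welch_psd(x, fs)
  s1 <- compute_snr(sp, 6, n_harmonics = 1)
  s2 <- compute_snr(sp, 6, n_harmonics = 2)
  expect_equal(s2$signal_power - s1$signal_power, s2$harmonic_power[[2L]])
  expect_gt(s2$snr_db, s1$snr_db)
  # harmonics above the analysis band are dropped with a note
  expect_message(compute_snr(sp, 40, n_harmonics = 4), "dropping")
})

test_that("a pure-signal spectrum yields a flagged infinite SNR", {
  sp <- structure(list(
    freqs_hz = seq(0, 150, by = 0.5),
    values = numeric(301), kind = "welch_psd", resolution_hz = 0.5,
    enbw_bins = 1.5, sampling_rate_hz = 300), class = "spectrum_result")
  sp$values[[which.min(abs(sp$freqs_hz - 4))]] <- 10
  res <- compute_snr(sp, 4, n_harmonics = 1, correct_noise_floor = FALSE)
  expect_true(res$infinite)
  expect_identical(res$snr_db, Inf)
})

test_that("FFT spectra localise fundamentals and harmonics on the grid", {
  lay <- session_layout(n_subjects = 1, trials_per_run = 10)
  mod <- moderate_model(noise_scale = 1.5)
  tens <- generate_session(lay, mod, seed = 12, paradigms = "bimodal",
                           brightness_levels = "medium")
  t3 <- tens[tens$info$frequency_hz == 3]
  avg <- average_trials(apply_filter_chain(t3, "fft_2_40"))
  sp <- fft_amplitude_spectrum(avg, 1200)
  expect_equal(sp$resolution_hz, 0.2)
  pk <- find_spectral_peaks(sp, c(3, 6))
  expect_equal(pk$peak_hz, c(3, 6))   # fundamental and second harmonic
})

test_that("stronger paradigm gain yields larger fundamental amplitude", {
  lay <- tiny_layout(trials_per_run = 8, sampling_rate_hz = 300,
                     trial_seconds = 2)
  mod <- moderate_model(noise_scale = 2)
  tens <- generate_session(lay, mod, seed = 13,
                           brightness_levels = "medium")
  amp_at <- function(par) {
    sub <- tens[tens$info$paradigm == par & tens$info$frequency_hz == 4]
    sp <- fft_amplitude_spectrum(average_trials(sub), 300)
    sp$values[[which.min(abs(sp$freqs_hz - 4))]]
  }
  a <- vapply(c("bimodal", "single_motion", "single_color"), amp_at,
              numeric(1))
  expect_true(a[[1L]] > a[[2L]] && a[[2L]] > a[[3L]])
})

test_that("spectra export to CSV and SNR to JSON", {
  sp <- welch_psd(rnorm(1200), 300)
  p1 <- tempfile(fileext = ".csv")
  write_spectrum_csv(sp, p1)
  back <- utils::read.csv(p1)
  expect_equal(back$freq_hz, sp$freqs_hz)
  x <- sin(2 * pi * 5 * (0:1199) / 300) + rnorm(1200, sd = 0.3)
  snr <- compute_snr(welch_psd(x, 300), 5, n_harmonics = 2)
  p2 <- tempfile(fileext = ".json")
  write_snr_json(snr, p2)
  parsed <- jsonlite::read_json(p2, simplifyVector = TRUE)
  expect_equal(parsed$snr_db, snr$snr_db)
})
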