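# Filtering chain, epoching, averaging, and the EDF round trip.

test_that("the filter chain is linear and passes zero", {
  fs <- 1200
  zero <- matrix(0, 2, 1200)
  expect_equal(apply_filter_chain(zero, "acq", fs), zero)
  set.seed(1)
  x <- rnorm(1200); y <- rnorm(1200)
  fx <- apply_filter_chain(x, "acq", fs)
  fy <- apply_filter_chain(y, "acq", fs)
  fxy <- apply_filter_chain(2 * x - 3 * y, "acq", fs)
  expect_equal(fxy, 2 * fx - 3 * fy, tolerance = 1e-10)
})

test_that("the notch removes 50 Hz and the band-pass keeps 10 Hz", {
  fs <- 1200
  tt <- (0:5999) / fs
  x50 <- sin(2 * pi * 50 * tt)
  y50 <- apply_filter_chain(x50, "acq", fs)
  expect_lt(sqrt(mean(y50^2)) / sqrt(mean(x50^2)), 0.10)
  x10 <- sin(2 * pi * 10 * tt)
  y10 <- apply_filter_chain(x10, list(filter_spec("band_pass", 8, c(2, 100))),
                            fs)
  expect_lt(abs(sqrt(mean(y10^2)) / sqrt(mean(x10^2)) - 1), 0.05)
  # 50 Hz sits in the stop band of the notch alone too
  yn <- apply_filter_chain(x50, list(filter_spec("notch", 4, c(48, 52))), fs)
  expect_lt(sqrt(mean(yn^2)) / sqrt(mean(x50^2)), 0.10)
})

test_that("chain presets exist and band edges are validated", {
  expect_length(filter_preset("acq"), 2L)
  expect_equal(filter_preset("avg_1_30")[[1L]]$band_hz, c(1, 30))
  expect_equal(filter_preset("fft_2_40")[[1L]]$band_hz, c(2, 40))
  expect_error(filter_spec("band_pass", 4, c(30, 10)),
               class = "ssmvep_domain_error")
  # edge at Nyquist rejected at application time
  expect_error(apply_filter_chain(rnorm(100),
                                  list(filter_spec("band_pass", 4, c(2, 160))),
                                  300),
               class = "ssmvep_filter_error")
})

test_that("EDF round trip preserves signals to quantisation accuracy", {
  set.seed(3)
  fs <- 300
  x <- matrix(rnorm(4 * fs * 2, sd = 20), nrow = 4)
  rownames(x) <- c("Po3", "Poz", "Po4", "O1")
  path <- tempfile(fileext = ".edf")
  write_edf(x, fs, path)
  back <- read_edf(path)
  expect_equal(back$sampling_rate_hz, fs)
  expect_equal(back$channels, rownames(x))
  qstep <- apply(x, 1L, function(r) (max(r) - min(r)) / 65535)
  for (i in 1:4) {
    expect_lt(max(abs(back$data[i, ] - x[i, ])), qstep[[i]] * 0.51 + 1e-4)
  }
})

test_that("a session written to EDF re-epochs to the original trials", {
  lay <- tiny_layout(trials_per_run = 3, sampling_rate_hz = 300,
                     trial_seconds = 2)
  tens <- generate_session(lay, moderate_model(), seed = 6,
                           paradigms = "bimodal",
                           brightness_levels = "medium")
  dir <- tempfile("edf_")
  files <- write_session_edf(tens, lay, dir)
  expect_true(file.exists(file.path(dir, "events.csv")))
  rec <- read_edf(files$file[[1L]])
  rec$events <- utils::read.csv(file.path(dir, "events.csv"))
  epo <- epoch_trials(rec, trial_seconds = lay$trial_seconds)
  # epoch count conserved
  expect_equal(dim(epo$data)[[1L]], dim(tens$data)[[1L]])
  # samples equal up to 16-bit quantisation of the channel range
  rng <- max(tens$data) - min(tens$data)
  expect_lt(max(abs(epo$data - tens$data)), rng / 65535 + 1e-4)
  expect_equal(epo$info$frequency_hz, tens$info$frequency_hz)
})

test_that("epoching covers [t, t+5) and handles bad events", {
  fs <- 100
  rec <- list(data = matrix(seq_len(3 * fs * 15), nrow = 3, byrow = TRUE),
              sampling_rate_hz = fs, channels = c("a", "b", "c"))
  ev <- data.frame(onset_sec = c(1, 7), label = c("x", "y"))
  epo <- epoch_trials(rec, ev, trial_seconds = 5)
  expect_equal(dim(epo$data), c(2L, 3L, 500L))
  # epoch starts exactly at the onset sample
  expect_equal(epo$data[1L, 1L, 1L], rec$data[1L, fs * 1 + 1L])
  expect_equal(epo$info$label, c("x", "y"))
  # overlapping events are an error
  expect_error(epoch_trials(rec, data.frame(onset_sec = c(1, 3)),
                            trial_seconds = 5),
               class = "ssmvep_epoch_error")
  # an epoch running past the end is dropped with a warning
  expect_warning(
    epo2 <- epoch_trials(rec, data.frame(onset_sec = c(1, 10.8)),
                         trial_seconds = 5),
    "dropped")
  expect_equal(dim(epo2$data)[[1L]], 1L)
})

test_that("trial averaging behaves like a mean and suppresses noise", {
  lay <- tiny_layout(trials_per_run = 1, sampling_rate_hz = 300,
                     trial_seconds = 1)
  one <- generate_session(lay, moderate_model(), seed = 8,
                          paradigms = "bimodal", brightness_levels = "medium")
  one4 <- one[one$info$task == 1]
  expect_equal(average_trials(one4), one4$data[1L, , ],
               ignore_attr = TRUE)
  # exact cancellation
  x <- one4$data
  both <- trial_tensor(abind_simple(x, -x), rbind(one4$info, one4$info),
                       300, one4$channels)
  expect_equal(max(abs(average_trials(both))), 0)
  # 100 noise-only trials: residual RMS ~ single-trial RMS / 10
  set.seed(11)
  noise <- array(rnorm(100 * 2 * 400), c(100, 2, 400))
  nt <- trial_tensor(noise, data.frame(i = 1:100), 100)
  resid_rms <- sqrt(mean(average_trials(nt)^2))
  single_rms <- sqrt(mean(noise[1L, , ]^2))
  expect_lt(abs(resid_rms - single_rms / 10) / (single_rms / 10), 0.2)
  # grouped averaging keeps one row per group
  g <- average_trials(one, by = c("task"))
  expect_equal(dim(g$data)[[1L]], 4L)
  expect_error(average_trials(one[integer(0)]),
               class = "ssmvep_domain_error")
})
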