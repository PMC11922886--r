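# Frequency recognition: CCA and the compact CNN.

test_that("CCA references have the declared shape and near-orthogonality", {
  refs <- cca_references(c(3, 3.5, 4, 4.5), 300, 300, n_harmonics = 4)
  expect_length(refs$refs, 4L)
  expect_equal(dim(refs$refs[[1L]]), c(8L, 300L))
  # cross-frequency reference correlation small over a 1-s window
  r34 <- abs(cor(refs$refs[["3"]][1L, ], refs$refs[["4"]][1L, ]))
  expect_lt(r34, 0.05)
})

test_that("CCA matches cancor and a generalized-eigen oracle", {
  set.seed(17)
  for (rep_i in 1:5) {
    X <- matrix(rnorm(4 * 200), 4)
    Y <- matrix(rnorm(6 * 200), 6)
    Y[1L, ] <- Y[1L, ] + 0.7 * X[2L, ]
    got <- canonical_correlations(X, Y)
    # oracle 1: QR-based cancor
    want1 <- stats::cancor(t(X), t(Y))$cor
    expect_equal(got[seq_along(want1)], want1, tolerance = 1e-8)
    # oracle 2: eigenvalues of Sxx^-1 Sxy Syy^-1 Syx are squared correlations
    Xc <- X - rowMeans(X); Yc <- Y - rowMeans(Y)
    Sxx <- Xc %*% t(Xc); Syy <- Yc %*% t(Yc); Sxy <- Xc %*% t(Yc)
    M <- solve(Sxx) %*% Sxy %*% solve(Syy) %*% t(Sxy)
    want2 <- sqrt(sort(Re(eigen(M)$values), decreasing = TRUE))
    expect_equal(got, want2[seq_along(got)], tolerance = 1e-8)
  }
})

test_that("noiseless trials are classified perfectly with correlation ~1", {
  lay <- tiny_layout(sampling_rate_hz = 300, trial_seconds = 2)
  mod <- noiseless_model()
  tr <- generate_trial(lay, mod, 3.5, seed = 1)
  refs <- cca_references(c(3, 3.5, 4, 4.5), ncol(tr), 300)
  res <- cca_classify(tr, refs)
  expect_equal(res$predicted_hz, 3.5)
  expect_gt(res$correlations[["3.5"]], 0.999)
  expect_true(all(res$correlations >= 0 & res$correlations <= 1))
  # segment shorter than a period of the lowest frequency is rejected
  expect_error(cca_classify(tr[, 1:80], refs),
               class = "ssmvep_segment_error")
})

test_that("pure-noise segments classify at 4-class chance", {
  set.seed(18)
  refs <- cca_references(c(3, 3.5, 4, 4.5), 250, 250)
  hits <- 0L
  n_seg <- 400L
  for (i in seq_len(n_seg)) {
    seg <- matrix(rnorm(6 * 250), 6)
    hits <- hits + (cca_classify(seg, refs)$predicted_hz == 3)
  }
  ci <- 1.96 * sqrt(0.25 * 0.75 / n_seg)
  expect_lt(abs(hits / n_seg - 0.25), ci + 0.02)
})

test_that("the CNN spec applies the half-sampling-rate kernel rule", {
  expect_equal(compact_cnn_spec(1200)$temporal_kernel, 600L)
  expect_equal(compact_cnn_spec(300)$temporal_kernel, 150L)
  expect_equal(compact_cnn_spec(250)$temporal_kernel, 125L)
  sp <- compact_cnn_spec(300, n_channels = 6)
  expect_equal(sp$n_channels, 6L)   # depthwise kernel spans all channels
})

test_that("CNN training is deterministic and softmax rows sum to 1", {
  lay <- tiny_layout(trials_per_run = 6, sampling_rate_hz = 300,
                     trial_seconds = 1)
  tens <- generate_session(lay, moderate_model(noise_scale = 1), seed = 19,
                           paradigms = "bimodal", brightness_levels = "medium")
  spec <- compact_cnn_spec(300, n_epochs = 6, batch_size = 8, patience = 6)
  a <- train_compact_cnn(tens, spec, seed = 5)
  b <- train_compact_cnn(tens, spec, seed = 5)
  expect_identical(a$params, b$params)
  expect_identical(predict(a, tens), predict(b, tens))
  pr <- predict(a, tens, type = "prob")
  expect_equal(rowSums(pr), rep(1, nrow(pr)))
  # training loss decreases on separable data
  expect_lt(tail(a$loss_history, 1), a$loss_history[[1L]])
  # a missing class is an error
  sub <- tens[tens$info$frequency_hz != 3]
  expect_error(train_compact_cnn(sub, spec, seed = 5),
               class = "ssmvep_class_error")
})

test_that("the CNN separates high-SNR synthetic classes", {
  lay <- tiny_layout(trials_per_run = 16, sampling_rate_hz = 300,
                     trial_seconds = 1)
  tens <- generate_session(lay, moderate_model(noise_scale = 1), seed = 20,
                           paradigms = "bimodal", brightness_levels = "medium")
  spec <- compact_cnn_spec(300, n_epochs = 30, batch_size = 16, patience = 6)
  tr <- tens$info$trial <= 12
  net <- train_compact_cnn(tens[tr], spec, seed = 7)
  acc <- mean(predict(net, tens[!tr]) == tens$info$frequency_hz[!tr])
  expect_gte(acc, 0.9)
})

test_that("decimation preserves the evoked response and rescales the rule", {
  lay <- session_layout(n_subjects = 1, trials_per_run = 2)
  tens <- generate_session(lay, noiseless_model(), seed = 1,
                           paradigms = "bimodal", brightness_levels = "medium")
  dec <- decimate_tensor(tens, 4)
  expect_equal(dec$sampling_rate_hz, 300)
  expect_equal(dim(dec$data)[[3L]], 1500L)
  # a 4 Hz component survives decimation with its amplitude intact
  sp <- fft_amplitude_spectrum(dec$data[1L, , ], 300)
  pk <- find_spectral_peaks(sp, 4)
  sp0 <- fft_amplitude_spectrum(tens$data[1L, , ], 1200)
  pk0 <- find_spectral_peaks(sp0, 4)
  expect_equal(pk$value, pk0$value, tolerance = 0.02)
  expect_equal(compact_cnn_spec(dec$sampling_rate_hz)$temporal_kernel, 150L)
})

test_that("accuracy grows with segment length and tracks paradigm gain", {
  lay <- tiny_layout(n_subjects = 3, trials_per_run = 10,
                     sampling_rate_hz = 300, trial_seconds = 2)
  tens <- generate_session(lay, moderate_model(noise_scale = 4), seed = 11,
                           paradigms = "bimodal", brightness_levels = "medium")
  sw <- sweep_segment_length(tens, c(0.5, 1, 1.5, 2), method = "cca")
  expect_gte(cor(sw$length_s, sw$accuracy, method = "spearman"), 0.8)
  expect_error(sweep_segment_length(tens, 3, method = "cca"),
               class = "ssmvep_segment_error")
  # noiseless full-length trials: perfect accuracy
  tens0 <- generate_session(tiny_layout(trials_per_run = 2),
                            noiseless_model(), seed = 2,
                            paradigms = "bimodal",
                            brightness_levels = "medium")
  sw0 <- sweep_segment_length(tens0, 2, method = "cca")
  expect_equal(sw0$accuracy, 1)
})
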