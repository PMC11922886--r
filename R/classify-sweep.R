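# Segment-length accuracy sweeps and cross-validated evaluation.

# Zero-phase 8th-order Butterworth low-pass, for anti-aliasing.
.lowpass_zp <- function(x, fs, cutoff_hz, order = 8) {
  .filtfilt_sos(x, .butter_sos("low_pass", order, cutoff_hz, fs))
}

#' Decimate a trial tensor
#'
#' Anti-alias low-pass (zero-phase Butterworth at 80% of the new Nyquist)
#' followed by subsampling. Used to run the compact CNN economically: the
#' temporal-kernel rule `L = floor(fs / 2)` is re-applied at the decimated
#' rate.
#'
#' @param tensor A [trial_tensor()].
#' @param factor Integer decimation factor (default 4: 1200 -> 300 Hz).
#' @return The decimated `trial_tensor`.
#' @export
decimate_tensor <- function(tensor, factor = 4) {
  factor <- as.integer(factor)
  fs <- tensor$sampling_rate_hz
  fs_new <- fs / factor
  cutoff <- 0.8 * fs_new / 2
  d <- dim(tensor$data)
  keep <- seq(1L, d[[3L]], by = factor)
  out <- array(0, c(d[[1L]], d[[2L]], length(keep)))
  for (i in seq_len(d[[1L]])) {
    for (c_i in seq_len(d[[2L]])) {
      out[i, c_i, ] <- .lowpass_zp(tensor$data[i, c_i, ], fs, cutoff)[keep]
    }
  }
  trial_tensor(out, tensor$info, fs_new, tensor$channels)
}

# Stratified fold assignment: trials of each class spread evenly over folds.
.stratified_folds <- function(y, folds, seed) {
  .with_seed(seed, {
    assign_f <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      assign_f[idx] <- rep_len(seq_len(folds), length(idx))
    }
    assign_f
  })
}

#' Cross-validated compact-CNN accuracy
#'
#' Per-subject stratified k-fold cross-validation over trials: for each
#' subject and fold, the network is trained on the remaining folds and
#' scored on the held-out fold.
#'
#' @param tensor A [trial_tensor()] with `subject` and `frequency_hz`
#'   labels.
#' @param spec A [compact_cnn_spec()] (built from the tensor if `NULL`).
#' @param folds Number of folds (default 5).
#' @param seed Seed controlling fold assignment and training.
#' @return Data frame with one row per subject x fold and its accuracy.
#' @export
cnn_crossval <- function(tensor, spec = NULL, folds = 5, seed = 1) {
  subjects <- unique(tensor$info$subject)
  out <- NULL
  for (s in subjects) {
    sub <- tensor[tensor$info$subject == s]
    y <- sub$info$frequency_hz
    fold_of <- .stratified_folds(y, folds, .derive_seed(seed, s))
    for (k in seq_len(folds)) {
      train <- sub[fold_of != k]
      test <- sub[fold_of == k]
      if (dim(test$data)[[1L]] == 0L) next
      net <- train_compact_cnn(train, spec, seed = .derive_seed(seed, s, k))
      acc <- mean(predict(net, test) == test$info$frequency_hz)
      out <- rbind(out, data.frame(subject = s, fold = k, accuracy = acc))
    }
  }
  out
}

#' Accuracy versus data segment length
#'
#' Evaluates classification accuracy for truncated trial segments of the
#' requested lengths, per subject, by CCA (no training) or by the compact
#' CNN (cross-validated). On synthetic data at fixed SNR the accuracy curve
#' is non-decreasing in segment length up to sampling noise.
#'
#' @param tensor A [trial_tensor()].
#' @param lengths_s Segment lengths in seconds.
#' @param method `"cca"` or `"cnn"`.
#' @param folds CNN cross-validation folds (default 2 for sweep economy).
#' @param spec Optional [compact_cnn_spec()] template; its
#'   `sampling_rate_hz` must match the tensor.
#' @param seed Seed for CNN training.
#' @param n_harmonics CCA reference harmonics.
#' @return Data frame with `length_s`, `method`, per-subject mean accuracy
#'   (`accuracy`) and its between-subject SD (`sd`).
#' @export
sweep_segment_length <- function(tensor, lengths_s, method = c("cca", "cnn"),
                                 folds = 2, spec = NULL, seed = 1,
                                 n_harmonics = 4) {
  method <- match.arg(method)
  fs <- tensor$sampling_rate_hz
  max_s <- dim(tensor$data)[[3L]] / fs
  if (any(lengths_s > max_s + 1e-9)) {
    .err("segment length exceeds the trial duration", "ssmvep_segment_error")
  }
  out <- NULL
  for (len in lengths_s) {
    n <- as.integer(round(len * fs))
    cut <- trial_tensor(tensor$data[, , seq_len(n), drop = FALSE],
                        tensor$info, fs, tensor$channels)
    if (method == "cca") {
      ev <- evaluate_cca(cut, n_harmonics = n_harmonics)
      accs <- if (is.null(ev$by_subject)) ev$accuracy else ev$by_subject
    } else {
      sp <- spec
      cv <- cnn_crossval(cut, sp, folds = folds, seed = seed)
      accs <- tapply(cv$accuracy, cv$subject, mean)
    }
    out <- rbind(out, data.frame(
      length_s = len, method = method,
      accuracy = mean(accs),
      sd = if (length(accs) > 1L) stats::sd(accs) else 0))
  }
  out
}
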