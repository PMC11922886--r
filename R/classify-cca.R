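# Frequency recognition by canonical correlation analysis: EEG segments are
# correlated against sine/cosine reference sets at each candidate frequency
# and its harmonics; the predicted frequency maximises the top canonical
# correlation.

#' Sinusoidal reference set for CCA frequency recognition
#'
#' For each candidate frequency, a `2 * n_harmonics x n_samples` matrix of
#' sine/cosine pairs at harmonics 1..H sampled at the trial rate. Distinct
#' frequencies' references are near-orthogonal over windows of a second or
#' more.
#'
#' @param frequencies_hz Candidate stimulation frequencies.
#' @param n_samples Segment length in samples.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param n_harmonics Harmonics per frequency (default 4, matching the SNR
#'   harmonic count).
#' @return Object of class `reference_set`.
#' @export
cca_references <- function(frequencies_hz, n_samples, sampling_rate_hz,
                           n_harmonics = 4) {
  tt <- (seq_len(n_samples) - 1L) / sampling_rate_hz
  refs <- lapply(frequencies_hz, function(f) {
    rows <- lapply(seq_len(n_harmonics), function(h) {
      rbind(sin(2 * pi * h * f * tt), cos(2 * pi * h * f * tt))
    })
    do.call(rbind, rows)
  })
  names(refs) <- as.character(frequencies_hz)
  structure(list(refs = refs, frequencies_hz = frequencies_hz,
                 sampling_rate_hz = sampling_rate_hz,
                 n_harmonics = n_harmonics, n_samples = n_samples),
            class = "reference_set")
}

#' Canonical correlations between two multivariate time series
#'
#' Computes the canonical correlations of `X` (variables x samples) and `Y`
#' via the singular values of the whitened cross-covariance
#' `Sxx^-1/2 Sxy Syy^-1/2`; dimensions with negligible variance are dropped
#' from the whitening (pseudo-inverse).
#'
#' @param X,Y Matrices with variables in rows and matching sample counts.
#' @return Vector of canonical correlations in `[0, 1]`, decreasing.
#' @export
canonical_correlations <- function(X, Y) {
  if (ncol(X) != ncol(Y)) .err("X and Y must have the same sample count",
                               "ssmvep_domain_error")
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  whiten <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    keep <- e$values > max(e$values) * 1e-10
    e$vectors[, keep, drop = FALSE] %*%
      diag(1 / sqrt(e$values[keep]), sum(keep)) %*%
      t(e$vectors[, keep, drop = FALSE])
  }
  n <- ncol(Xc)
  Sxx <- Xc %*% t(Xc) / n
  Syy <- Yc %*% t(Yc) / n
  Sxy <- Xc %*% t(Yc) / n
  M <- whiten(Sxx) %*% Sxy %*% whiten(Syy)
  pmin(pmax(svd(M)$d, 0), 1)
}

#' Classify a segment by CCA
#'
#' @param segment EEG segment, channels x samples.
#' @param refs A [cca_references()] set whose `n_samples` matches the
#'   segment (references are truncated/rebuilt if longer segments were
#'   prepared).
#' @return List with `predicted_hz`, `correlations` (named per candidate,
#'   each the top canonical correlation), and `tie` flag. Ties are broken
#'   toward the lowest frequency.
#' @export
cca_classify <- function(segment, refs) {
  if (!inherits(refs, "reference_set")) {
    .err("refs must be a reference_set", "ssmvep_domain_error")
  }
  n <- ncol(segment)
  min_f <- min(refs$frequencies_hz)
  if (n < refs$sampling_rate_hz / min_f) {
    .err("segment shorter than one period of the lowest frequency",
         "ssmvep_segment_error")
  }
  rho <- vapply(refs$refs, function(Y) {
    canonical_correlations(segment, Y[, seq_len(n), drop = FALSE])[[1L]]
  }, numeric(1))
  top <- which(rho >= max(rho) - 1e-12)
  tie <- length(top) > 1L
  if (tie) {
    message("canonical-correlation tie broken toward the lowest frequency")
    top <- top[[which.min(refs$frequencies_hz[top])]]
  }
  list(predicted_hz = refs$frequencies_hz[[top[[1L]]]],
       correlations = rho, tie = tie)
}

#' CCA accuracy over a trial tensor
#'
#' Classifies every trial (optionally truncated to `segment_seconds`)
#' against references built from the frequencies present in the labels.
#'
#' @param tensor A [trial_tensor()] with a `frequency_hz` label column.
#' @param segment_seconds Segment length in seconds; `NULL` uses the whole
#'   trial.
#' @param n_harmonics Reference harmonics.
#' @return List with overall `accuracy`, `predicted` vector, and
#'   `by_subject` accuracies.
#' @export
evaluate_cca <- function(tensor, segment_seconds = NULL, n_harmonics = 4) {
  fs <- tensor$sampling_rate_hz
  n_full <- dim(tensor$data)[[3L]]
  n <- if (is.null(segment_seconds)) n_full else
    min(n_full, as.integer(round(segment_seconds * fs)))
  freqs <- sort(unique(tensor$info$frequency_hz))
  refs <- cca_references(freqs, n, fs, n_harmonics)
  n_tr <- dim(tensor$data)[[1L]]
  pred <- numeric(n_tr)
  for (i in seq_len(n_tr)) {
    seg <- tensor$data[i, , seq_len(n), drop = FALSE]
    dim(seg) <- dim(seg)[-1L]
    pred[[i]] <- cca_classify(seg, refs)$predicted_hz
  }
  correct <- pred == tensor$info$frequency_hz
  by_subject <- if ("subject" %in% names(tensor$info)) {
    tapply(correct, tensor$info$subject, mean)
  } else NULL
  list(accuracy = mean(correct), predicted = pred, by_subject = by_subject)
}
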