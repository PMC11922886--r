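# Filtering chain and epoching. Butterworth filters are designed
# analytically (prototype poles + band transform + bilinear transform) and
# realised as a cascade of second-order sections applied forward-backward
# (zero phase). Single-polynomial transfer functions of these designs are
# numerically unstable at 8th order for the band-edge/sampling-rate ratios
# used here; the biquad cascade is stable at any order.

#' Butterworth filter specification
#'
#' @param kind `"band_pass"` or `"notch"` (band-stop).
#' @param order Butterworth order of the analog prototype.
#' @param band_hz `c(low, high)` corner frequencies in Hz (-3 dB points).
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("band_pass", "notch"), order, band_hz) {
  kind <- match.arg(kind)
  if (length(band_hz) != 2L || band_hz[[1L]] <= 0 ||
      band_hz[[2L]] <= band_hz[[1L]]) {
    .err("band_hz must satisfy 0 < low < high", "ssmvep_domain_error")
  }
  if (order < 1 || order != round(order)) {
    .err("order must be a positive integer", "ssmvep_domain_error")
  }
  structure(list(kind = kind, order = as.integer(order),
                 band_hz = as.numeric(band_hz)),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("filter_spec: %s Butterworth order %d, %g-%g Hz\n",
              x$kind, x$order, x$band_hz[[1L]], x$band_hz[[2L]]))
  invisible(x)
}

#' Named filter-chain presets
#'
#' `"acq"`: the acquisition chain (8th-order 2-100 Hz band-pass plus
#' 4th-order 48-52 Hz powerline notch). `"avg_1_30"`: 1-30 Hz band-pass
#' applied before trial averaging. `"fft_2_40"`: 4th-order 2-40 Hz
#' band-pass applied before FFT amplitude spectra.
#'
#' @param name Preset name.
#' @return List of [filter_spec()]s.
#' @export
filter_preset <- function(name = c("acq", "avg_1_30", "fft_2_40")) {
  switch(match.arg(name),
    acq = list(filter_spec("band_pass", 8, c(2, 100)),
               filter_spec("notch", 4, c(48, 52))),
    avg_1_30 = list(filter_spec("band_pass", 4, c(1, 30))),
    fft_2_40 = list(filter_spec("band_pass", 4, c(2, 40))))
}

# Analog Butterworth prototype poles (stable half-plane), order n.
.butter_proto <- function(n) {
  exp(1i * pi * (2 * seq_len(n) + n - 1) / (2 * n))
}

# Second-order sections (rows: b0 b1 b2 a1 a2) for a Butterworth design via
# prewarped band transform and bilinear transform. type: "band_pass",
# "band_stop" or "low_pass" (band_hz then holds the single cutoff).
.butter_sos <- function(type, order, band_hz, fs) {
  k2 <- 2 * fs
  bilinear <- function(s) (1 + s / k2) / (1 - s / k2)
  proto <- .butter_proto(order)

  sections <- list()
  add_pole_pair <- function(z1, z2, num) {
    # biquad with digital poles z1, z2 and numerator coefficients num
    sections[[length(sections) + 1L]] <<- c(
      num,
      -Re(z1 + z2), Re(z1 * z2))
  }

  if (type == "low_pass") {
    W <- k2 * tan(pi * band_hz[[1L]] / fs)
    poles <- bilinear(W * proto)
    i <- 1L
    while (i <= order) {
      if (abs(Im(proto[[i]])) < 1e-9) {
        z <- poles[[i]]
        sections[[length(sections) + 1L]] <- c(1, 1, 0, -Re(z), 0)
        i <- i + 1L
      } else {
        add_pole_pair(poles[[i]], Conj(poles[[i]]), c(1, 2, 1))
        i <- i + 2L
      }
    }
    z_ref <- 1 + 0i  # unit gain at DC
  } else {
    Wl <- k2 * tan(pi * band_hz[[1L]] / fs)
    Wh <- k2 * tan(pi * band_hz[[2L]] / fs)
    W0 <- sqrt(Wl * Wh)
    B <- Wh - Wl
    th0 <- 2 * atan(W0 / k2)
    for (i in seq_len(order)) {
      p <- proto[[i]]
      if (Im(p) < -1e-9) next  # conjugates handled with their partner
      if (type == "band_pass") {
        disc <- sqrt((B * p)^2 - 4 * W0^2)
        s_pair <- c((B * p + disc) / 2, (B * p - disc) / 2)
        num <- c(1, 0, -1)  # zeros at z = +1 and z = -1
      } else {
        disc <- sqrt(B^2 - 4 * p^2 * W0^2)
        s_pair <- c((B + disc) / (2 * p), (B - disc) / (2 * p))
        num <- c(1, -2 * cos(th0), 1)  # zero pair on the unit circle at W0
      }
      zd <- bilinear(s_pair)
      if (abs(Im(p)) < 1e-9) {
        # real prototype pole: its two transformed poles form one section
        add_pole_pair(zd[[1L]], zd[[2L]], num)
      } else {
        add_pole_pair(zd[[1L]], Conj(zd[[1L]]), num)
        add_pole_pair(zd[[2L]], Conj(zd[[2L]]), num)
      }
    }
    z_ref <- if (type == "band_stop") 1 + 0i else exp(1i * th0)
  }

  sos <- do.call(rbind, sections)
  # normalise overall gain at the reference frequency
  h <- 1 + 0i
  zi1 <- 1 / z_ref; zi2 <- zi1^2
  for (r in seq_len(nrow(sos))) {
    h <- h * (sos[r, 1L] + sos[r, 2L] * zi1 + sos[r, 3L] * zi2) /
      (1 + sos[r, 4L] * zi1 + sos[r, 5L] * zi2)
  }
  sos[1L, 1:3] <- sos[1L, 1:3] / Mod(h)
  sos
}

.sos_filter <- function(x, sos) {
  for (r in seq_len(nrow(sos))) {
    u <- stats::filter(c(0, 0, x), sos[r, 1:3], method = "convolution",
                       sides = 1L)[-(1:2)]
    x <- as.numeric(stats::filter(u, -sos[r, 4:5], method = "recursive"))
  }
  x
}

# Zero-phase (forward-backward) filtering through a biquad cascade, with
# odd edge extension to suppress start-up transients.
.filtfilt_sos <- function(x, sos) {
  n <- length(x)
  padlen <- min(n - 1L, 3000L)
  left <- 2 * x[[1L]] - x[(padlen + 1L):2L]
  right <- 2 * x[[n]] - x[(n - 1L):(n - padlen)]
  ext <- c(left, x, right)
  y <- .sos_filter(ext, sos)
  y <- rev(.sos_filter(rev(y), sos))
  y[(padlen + 1L):(padlen + n)]
}

.spec_sos <- function(spec, fs) {
  type <- if (spec$kind == "notch") "band_stop" else spec$kind
  .butter_sos(type, spec$order, spec$band_hz, fs)
}

#' Apply a zero-phase filter chain
#'
#' Filters every channel of the input with the cascaded squared-magnitude
#' Butterworth response of `specs` (zero phase: no latency shift, so evoked
#' responses stay aligned for averaging).
#'
#' @param x A [trial_tensor()], a channels x samples matrix, or a vector.
#' @param specs A [filter_spec()], a list of them, or a [filter_preset()]
#'   name.
#' @param sampling_rate_hz Required when `x` is not a `trial_tensor`.
#' @return The filtered object, same shape as the input.
#' @export
apply_filter_chain <- function(x, specs, sampling_rate_hz = NULL) {
  if (is.character(specs)) specs <- filter_preset(specs)
  if (inherits(specs, "filter_spec")) specs <- list(specs)
  fs <- if (inherits(x, "trial_tensor")) x$sampling_rate_hz else sampling_rate_hz
  if (is.null(fs)) .err("sampling_rate_hz is required", "ssmvep_domain_error")
  for (sp in specs) {
    if (sp$band_hz[[2L]] >= fs / 2) {
      .err("filter band edge at or above Nyquist", "ssmvep_filter_error")
    }
  }
  sos_list <- lapply(specs, .spec_sos, fs = fs)
  run <- function(v) {
    for (sos in sos_list) v <- .filtfilt_sos(v, sos)
    v
  }
  if (inherits(x, "trial_tensor")) {
    out <- x
    for (i in seq_len(dim(x$data)[[1L]])) {
      for (c_i in seq_len(dim(x$data)[[2L]])) {
        out$data[i, c_i, ] <- run(x$data[i, c_i, ])
      }
    }
    out
  } else if (is.matrix(x)) {
    t(apply(x, 1L, run))
  } else {
    run(x)
  }
}

#' Epoch a continuous recording into trials
#'
#' Cuts a `[t, t + trial_seconds)` epoch at each event onset; cue and gray
#' intervals fall outside the epochs by construction. Epochs extending past
#' the end of the recording are dropped with a warning; overlapping events
#' are an error.
#'
#' @param recording List with `data` (channels x samples),
#'   `sampling_rate_hz`, optionally `channels` (as returned by [read_edf()]
#'   or [session_to_recording()]).
#' @param events Data frame with `onset_sec` plus any label columns; taken
#'   from `recording$events` when omitted.
#' @param trial_seconds Epoch duration (default 5).
#' @return A [trial_tensor()] whose `info` carries the event labels.
#' @export
epoch_trials <- function(recording, events = recording$events,
                         trial_seconds = 5) {
  fs <- recording$sampling_rate_hz
  n_s <- as.integer(round(trial_seconds * fs))
  if (is.null(events) || nrow(events) == 0L) {
    .err("no events to epoch", "ssmvep_domain_error")
  }
  onsets <- sort(events$onset_sec)
  if (any(diff(onsets) < trial_seconds - 1e-9)) {
    .err("overlapping events: inter-onset interval shorter than the epoch",
         "ssmvep_epoch_error")
  }
  total <- ncol(recording$data)
  start <- as.integer(round(events$onset_sec * fs))
  keep <- start + n_s <= total
  if (any(!keep)) {
    warning(sprintf("dropped %d epoch(s) extending past the recording end",
                    sum(!keep)))
  }
  events <- events[keep, , drop = FALSE]
  start <- start[keep]
  if (nrow(events) == 0L) .err("all epochs dropped", "ssmvep_epoch_error")
  data <- array(0, dim = c(nrow(events), nrow(recording$data), n_s))
  for (i in seq_along(start)) {
    data[i, , ] <- recording$data[, (start[[i]] + 1L):(start[[i]] + n_s)]
  }
  info <- events[, setdiff(names(events), "onset_sec"), drop = FALSE]
  rownames(info) <- NULL
  trial_tensor(data, info, fs,
               recording$channels %||% rownames(recording$data))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Average trials
#'
#' Mean over the trial axis, optionally per group. Averaging `N`
#' independent noise trials reduces the noise RMS by about `1/sqrt(N)`
#' while leaving the phase-locked evoked response untouched.
#'
#' @param tensor A [trial_tensor()].
#' @param by Character vector of `info` columns to group by; `NULL`
#'   averages everything into one channels x samples matrix.
#' @return A matrix (ungrouped), or a `trial_tensor` with one averaged
#'   entry per group and `info` reduced to the grouping keys plus `n_trials`.
#' @export
average_trials <- function(tensor, by = NULL) {
  n_tr <- dim(tensor$data)[[1L]]
  if (n_tr == 0L) .err("empty trial group", "ssmvep_domain_error")
  if (is.null(by)) {
    m <- apply(tensor$data, c(2L, 3L), mean)
    rownames(m) <- tensor$channels
    return(m)
  }
  if (!all(by %in% names(tensor$info))) {
    .err("grouping columns missing from info", "ssmvep_domain_error")
  }
  key <- interaction(tensor$info[, by, drop = FALSE], drop = TRUE)
  groups <- levels(key)
  data <- array(0, dim = c(length(groups), dim(tensor$data)[[2L]],
                           dim(tensor$data)[[3L]]))
  info <- NULL
  for (g in seq_along(groups)) {
    sel <- which(key == groups[[g]])
    data[g, , ] <- apply(tensor$data[sel, , , drop = FALSE], c(2L, 3L), mean)
    row <- tensor$info[sel[[1L]], by, drop = FALSE]
    row$n_trials <- length(sel)
    info <- rbind(info, row)
  }
  rownames(info) <- NULL
  trial_tensor(data, info, tensor$sampling_rate_hz, tensor$channels)
}
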