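# Minimal European Data Format (EDF) writer/reader for continuous
# multichannel recordings: ASCII header, 16-bit little-endian samples, one
# 1-second data record per signal per second. Covers exactly what the
# synthetic-session exporter emits (no annotations, no discontinuities).

.edf_pad <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  formatC(s, width = -width, flag = " ")
}

.edf_num <- function(x, width) {
  s <- formatC(x, digits = 7, format = "g", width = -1)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  .edf_pad(s, width)
}

#' Write a continuous recording to an EDF file
#'
#' Samples are quantised to 16 bits over each channel's physical range, the
#' standard EDF encoding; the round-trip error is bounded by half a
#' quantisation step, `(max - min) / 65535 / 2` per channel.
#'
#' @param data Numeric matrix, channels x samples (microvolt).
#' @param sampling_rate_hz Sampling rate; the recording must span a whole
#'   number of seconds.
#' @param path Output file path.
#' @param channels Channel labels (default from rownames).
#' @return Invisibly, `path`.
#' @export
write_edf <- function(data, sampling_rate_hz, path, channels = rownames(data)) {
  if (!is.matrix(data)) .err("data must be a channels x samples matrix",
                             "ssmvep_domain_error")
  ns <- nrow(data)
  n_samp <- ncol(data)
  spr <- as.integer(round(sampling_rate_hz))
  n_rec <- n_samp / spr
  if (abs(n_rec - round(n_rec)) > 1e-9) {
    .err("recording must span a whole number of seconds", "ssmvep_domain_error")
  }
  n_rec <- as.integer(round(n_rec))
  if (is.null(channels)) channels <- paste0("ch", seq_len(ns))

  pmin <- apply(data, 1L, min)
  pmax <- apply(data, 1L, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad("synthetic SSMVEP subject", 80),
    .edf_pad("synthetic SSMVEP session", 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (1 + ns), 8),
    .edf_pad("", 44),
    .edf_pad(n_rec, 8),
    .edf_pad("1", 8),
    .edf_pad(ns, 4),
    paste(vapply(channels, .edf_pad, "", 16), collapse = ""),
    paste(rep(.edf_pad("", 80), ns), collapse = ""),
    paste(rep(.edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(pmin, .edf_num, "", 8), collapse = ""),
    paste(vapply(pmax, .edf_num, "", 8), collapse = ""),
    paste(rep(.edf_pad(-32768, 8), ns), collapse = ""),
    paste(rep(.edf_pad(32767, 8), ns), collapse = ""),
    paste(rep(.edf_pad("", 80), ns), collapse = ""),
    paste(rep(.edf_pad(spr, 8), ns), collapse = ""),
    paste(rep(.edf_pad("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)

  # Physical-range values written in the header are truncated to 8 ASCII
  # chars; use the parsed-back values for quantisation so the round trip is
  # consistent.
  pmin_h <- as.numeric(vapply(pmin, .edf_num, "", 8))
  pmax_h <- as.numeric(vapply(pmax, .edf_num, "", 8))

  dig <- matrix(0L, ns, n_samp)
  for (i in seq_len(ns)) {
    scale <- 65535 / (pmax_h[[i]] - pmin_h[[i]])
    d <- round((pmin(pmax(data[i, ], pmin_h[[i]]), pmax_h[[i]]) - pmin_h[[i]]) *
                 scale) - 32768
    dig[i, ] <- as.integer(pmin(pmax(d, -32768), 32767))
  }
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @return List with `data` (channels x samples matrix), `sampling_rate_hz`
#'   and `channels`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)

  data <- matrix(0, ns, n_rec * spr[[1L]])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[[i]], size = 2L, signed = TRUE,
                   endian = "little")
      phys <- pmin[[i]] + (d - dmin[[i]]) * (pmax[[i]] - pmin[[i]]) /
        (dmax[[i]] - dmin[[i]])
      data[i, ((r - 1L) * spr[[i]] + 1L):(r * spr[[i]])] <- phys
    }
  }
  rownames(data) <- labels
  list(data = data, sampling_rate_hz = spr[[1L]] / rec_dur,
       channels = labels)
}

#' Flatten a trial tensor into a continuous recording with events
#'
#' Reassembles the session timeline one trial at a time: a cue interval, the
#' 5-s trial, then a gray-screen interval (cue and gray carry only weak
#' background noise). Returns the continuous multichannel signal plus an
#' event table marking each trial onset, the layout expected by
#' [epoch_trials()].
#'
#' @param tensor A [trial_tensor()].
#' @param layout The [session_layout()] that produced it.
#' @return List with `data` (channels x samples), `sampling_rate_hz`,
#'   `channels` and `events` (data frame with `onset_sec` and the trial
#'   labels).
#' @export
session_to_recording <- function(tensor, layout) {
  fs <- tensor$sampling_rate_hz
  n_tr <- dim(tensor$data)[[1L]]
  n_ch <- dim(tensor$data)[[2L]]
  n_s <- dim(tensor$data)[[3L]]
  cue <- as.integer(round(layout$cue_seconds * fs))
  gray <- as.integer(round(layout$gray_seconds * fs))
  step <- cue + n_s + gray
  data <- matrix(0, n_ch, n_tr * step)
  onset <- numeric(n_tr)
  for (i in seq_len(n_tr)) {
    s0 <- (i - 1L) * step + cue
    data[, (s0 + 1L):(s0 + n_s)] <- tensor$data[i, , ]
    onset[[i]] <- s0 / fs
  }
  rownames(data) <- tensor$channels
  events <- cbind(data.frame(onset_sec = onset), tensor$info)
  list(data = data, sampling_rate_hz = fs, channels = tensor$channels,
       events = events)
}

#' Write a session to EDF files with a sidecar label table
#'
#' One EDF file per subject and paradigm block plus one CSV table of trial
#' events across all files.
#'
#' @inheritParams session_to_recording
#' @param dir Output directory.
#' @return Invisibly, a data frame listing the files written.
#' @export
write_session_edf <- function(tensor, layout, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  info <- tensor$info
  keys <- unique(info[, c("subject", "paradigm")])
  files <- character(nrow(keys))
  all_events <- list()
  for (k in seq_len(nrow(keys))) {
    sel <- info$subject == keys$subject[[k]] &
      info$paradigm == keys$paradigm[[k]]
    rec <- session_to_recording(tensor[sel], layout)
    files[[k]] <- file.path(dir, sprintf("sub-%02d_%s.edf",
                                         keys$subject[[k]],
                                         keys$paradigm[[k]]))
    write_edf(rec$data, rec$sampling_rate_hz, files[[k]], rec$channels)
    ev <- rec$events
    ev$file <- basename(files[[k]])
    all_events[[k]] <- ev
  }
  events <- do.call(rbind, all_events)
  utils::write.csv(events, file.path(dir, "events.csv"), row.names = FALSE)
  invisible(data.frame(file = files, subject = keys$subject,
                       paradigm = keys$paradigm))
}
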