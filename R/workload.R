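# Bandpower-ratio workload and fatigue metrics. Cognitive load is tracked
# by the theta/alpha power ratio and fatigue by (theta + alpha)/beta; both
# are fitted linearly over the four tasks of a block and summarised by the
# variation extent, the percent relative difference between the fitted
# values at task 4 and task 1.

#' Band-integrated powers per subject, paradigm and task
#'
#' Integrates the Welch PSD of every trial over the theta (4-8 Hz), alpha
#' (8-13 Hz) and beta (13-30 Hz) bands (channel-averaged), then averages
#' trials within each subject x paradigm x task cell and forms the
#' theta/alpha cognitive-load ratio and the (theta+alpha)/beta fatigue
#' ratio.
#'
#' @param tensor A [trial_tensor()] whose `info` has `subject`, `paradigm`
#'   and `task` columns.
#' @param bands Named list of band edges in Hz.
#' @param window_seconds Welch segment length (default 2).
#' @return Object of class `bandpower_series`: a data frame with one row
#'   per subject x paradigm x task.
#' @export
bandpowers <- function(tensor, bands = list(theta = c(4, 8),
                                            alpha = c(8, 13),
                                            beta = c(13, 30)),
                       window_seconds = 2) {
  fs <- tensor$sampling_rate_hz
  for (b in bands) {
    if (b[[2L]] > fs / 2) {
      .err("band extends beyond the spectrum", "ssmvep_domain_error")
    }
  }
  need <- c("subject", "paradigm", "task")
  if (!all(need %in% names(tensor$info))) {
    .err("info must carry subject, paradigm and task labels",
         "ssmvep_domain_error")
  }
  n_tr <- dim(tensor$data)[[1L]]
  pw <- matrix(0, n_tr, length(bands),
               dimnames = list(NULL, names(bands)))
  for (i in seq_len(n_tr)) {
    spec <- welch_psd(tensor$data[i, , ], fs, window_seconds = window_seconds)
    for (b in names(bands)) {
      sel <- spec$freqs_hz >= bands[[b]][[1L]] &
        spec$freqs_hz < bands[[b]][[2L]]
      pw[i, b] <- sum(spec$values[sel]) * spec$resolution_hz
    }
  }
  df <- cbind(tensor$info[, need], as.data.frame(pw))
  agg <- stats::aggregate(df[, names(bands)],
                          by = df[, need], FUN = mean)
  agg <- agg[order(agg$subject, agg$paradigm, agg$task), ]
  rownames(agg) <- NULL
  agg$load_ratio <- agg$theta / agg$alpha
  agg$fatigue_ratio <- (agg$theta + agg$alpha) / agg$beta
  names(agg)[names(agg) %in% names(bands)] <-
    paste0(names(bands), "_power")
  structure(agg, class = c("bandpower_series", "data.frame"),
            bands = bands)
}

.fit_extent <- function(task, ratio, eps_frac = 1e-6) {
  if (length(unique(task)) < 2L) {
    .err("need at least 2 distinct task points to fit a trend",
         "ssmvep_domain_error")
  }
  fit <- stats::lm.fit(cbind(1, task), ratio)
  b <- fit$coefficients
  f1 <- b[[1L]] + b[[2L]] * min(task)
  f4 <- b[[1L]] + b[[2L]] * max(task)
  extent <- if (abs(f1) < eps_frac * abs(mean(ratio))) {
    NA_real_  # denominator guard: extent undefined near a zero baseline
  } else {
    100 * (f4 - f1) / abs(f1)
  }
  c(slope = b[[2L]], intercept = b[[1L]], fit_first = f1, fit_last = f4,
    extent_pct = extent)
}

#' Task trend and variation extent of the workload/fatigue ratios
#'
#' Fits a least-squares line over the task index (1..4) to each subject's
#' load and fatigue ratios within each paradigm and reports the variation
#' extent `100 * (fit(4) - fit(1)) / |fit(1)|`. Extents are computed on raw
#' ratio values; per-subject z-scored ratios are attached separately for
#' cross-subject comparison (relative differences of z-scores are
#' ill-defined near zero).
#'
#' @param series A [bandpowers()] result.
#' @return Object of class `fatigue_report`: data frame with one row per
#'   subject x paradigm x metric (`load`, `fatigue`) carrying slope,
#'   intercept, fitted endpoints and `extent_pct`; the z-scored ratio table
#'   is in `attr(, "normalized")`.
#' @export
ratio_trend <- function(series) {
  if (!inherits(series, "bandpower_series")) {
    .err("series must come from bandpowers()", "ssmvep_domain_error")
  }
  out <- NULL
  norm <- series
  for (metric in c("load", "fatigue")) {
    col <- paste0(metric, "_ratio")
    keys <- unique(series[, c("subject", "paradigm")])
    for (k in seq_len(nrow(keys))) {
      sel <- series$subject == keys$subject[[k]] &
        series$paradigm == keys$paradigm[[k]]
      v <- .fit_extent(series$task[sel], series[[col]][sel])
      out <- rbind(out, data.frame(
        subject = keys$subject[[k]], paradigm = keys$paradigm[[k]],
        metric = metric, slope = v[["slope"]],
        intercept = v[["intercept"]], fit_first = v[["fit_first"]],
        fit_last = v[["fit_last"]], extent_pct = v[["extent_pct"]]))
      # per-subject normalisation for cross-subject comparability
      z <- series[[col]][sel]
      norm[[col]][sel] <- (z - mean(z)) / stats::sd(z)
    }
  }
  rownames(out) <- NULL
  structure(out, class = c("fatigue_report", "data.frame"),
            normalized = norm)
}

#' @export
print.fatigue_report <- function(x, ...) {
  cat("fatigue_report: variation extents (%) by paradigm\n")
  agg <- stats::aggregate(extent_pct ~ paradigm + metric,
                          data = as.data.frame(x), FUN = mean)
  print(format(agg, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Export a fatigue report as CSV
#'
#' One row per subject x paradigm x metric with the fitted line and the
#' variation extent, the layout used for the study-style extent tables.
#'
#' @param report A `fatigue_report`.
#' @param path Output CSV path.
#' @export
write_fatigue_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
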