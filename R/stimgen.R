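# Newton's-rings stimulus synthesis: ring geometry with a controlled
# band/background area ratio, equal-luminance red/green colour modulation,
# and rendered frame sequences for the bimodal, single-motion and
# single-colour paradigms.

.err <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ssmvep_error", "error")))
}

#' Outer radii of a Newton's-rings pattern
#'
#' The rings' outer radii form an arithmetic sequence: ring `i` of `n` has
#' outer radius `(2i - 1) * r_max / (2n)`, so the rings sit at the midpoints
#' of `n` equal radial cells of `[0, r_max]` and the outermost radius is
#' `(2n - 1) * r_max / (2n) < r_max`.
#'
#' @param n_rings Number of rings (positive integer).
#' @param r_max Maximum radius of the pattern scale, in pixels.
#' @return Numeric vector of `n_rings` strictly increasing radii.
#' @export
compute_outer_radii <- function(n_rings, r_max) {
  if (length(n_rings) != 1L || !is.finite(n_rings) || n_rings < 1 ||
      n_rings != round(n_rings)) {
    .err("n_rings must be a positive integer", "ssmvep_domain_error")
  }
  if (length(r_max) != 1L || !is.finite(r_max) || r_max <= 0) {
    .err("r_max must be positive", "ssmvep_domain_error")
  }
  i <- seq_len(n_rings)
  (2 * i - 1) * r_max / (2 * n_rings)
}

#' Inner radii from the band-area ratio
#'
#' The pattern disc (bounded by the outermost ring's outer radius) is
#' partitioned into annular cells `[r_{i-1}, r_i]` delimited by consecutive
#' outer radii, with `r_0 = 0`. Each ring band occupies the outer fraction
#' `C / (1 + C)` of its cell's area:
#' `inner^2 = outer^2 - C/(1+C) * (outer^2 - prev_outer^2)`,
#' which makes the global band/background area ratio within the pattern disc
#' exactly `C`.
#'
#' @param outer_radii Strictly increasing outer radii (from
#'   [compute_outer_radii()]).
#' @param area_ratio_C Target ratio of total band area to total background
#'   area, `C > 0`.
#' @return Numeric vector of inner radii, one per ring.
#' @export
compute_inner_radii <- function(outer_radii, area_ratio_C) {
  if (length(area_ratio_C) != 1L || !is.finite(area_ratio_C) ||
      area_ratio_C <= 0) {
    .err("area_ratio_C must be positive", "ssmvep_domain_error")
  }
  if (length(outer_radii) < 1L || any(!is.finite(outer_radii)) ||
      any(outer_radii <= 0) || is.unsorted(outer_radii, strictly = TRUE)) {
    .err("outer_radii must be strictly increasing and positive",
         "ssmvep_domain_error")
  }
  f <- area_ratio_C / (1 + area_ratio_C)
  prev <- c(0, outer_radii[-length(outer_radii)])
  sqrt(outer_radii^2 - f * (outer_radii^2 - prev^2))
}

#' Ring geometry for a Newton's-rings stimulus
#'
#' @inheritParams compute_outer_radii
#' @inheritParams compute_inner_radii
#' @return An object of class `ring_geometry` with the outer/inner radii,
#'   the pattern radius (outer radius of the outermost ring, which bounds
#'   the background region used for area accounting), and `area_ratio_C`.
#' @export
ring_geometry <- function(n_rings, r_max, area_ratio_C = 0.6) {
  outer <- compute_outer_radii(n_rings, r_max)
  inner <- compute_inner_radii(outer, area_ratio_C)
  structure(list(
    n_rings = as.integer(n_rings),
    r_max = r_max,
    outer_radii = outer,
    inner_radii = inner,
    area_ratio_C = area_ratio_C,
    pattern_radius = outer[length(outer)]
  ), class = "ring_geometry")
}

#' @export
print.ring_geometry <- function(x, ...) {
  cat(sprintf("Newton's rings: %d rings, r_max = %g px, C = %g\n",
              x$n_rings, x$r_max, x$area_ratio_C))
  cat("  outer radii:", paste(signif(x$outer_radii, 5), collapse = ", "), "\n")
  cat("  inner radii:", paste(signif(x$inner_radii, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Perceived luminance of an RGB colour
#'
#' Rec.709 luma weighted by a device constant:
#' `L = C1 * (0.2126 R + 0.7152 G + 0.0722 B)` with channels in `[0, 255]`.
#'
#' @param rgb Length-3 numeric vector, or an `n x 3` matrix of colours.
#' @param C1 Device constant scaling perceived luminance (default 0.7).
#' @return Perceived luminance value(s).
#' @export
perceived_luminance <- function(rgb, C1 = 0.7) {
  m <- if (is.matrix(rgb)) rgb else matrix(rgb, nrow = 1L)
  if (ncol(m) != 3L || any(!is.finite(m)) || any(m < 0) || any(m > 255)) {
    .err("rgb channels must lie in [0, 255]", "ssmvep_domain_error")
  }
  out <- C1 * (0.2126 * m[, 1L] + 0.7152 * m[, 2L] + 0.0722 * m[, 3L])
  if (is.matrix(rgb)) out else out[[1L]]
}

#' A colour with its stored perceived luminance
#' @inheritParams perceived_luminance
#' @return Object of class `color_state` with fields `rgb` and
#'   `perceived_luminance`.
#' @export
color_state <- function(rgb, C1 = 0.7) {
  structure(list(rgb = as.numeric(rgb),
                 perceived_luminance = perceived_luminance(rgb, C1),
                 C1 = C1),
            class = "color_state")
}

#' Luminance-match a pure hue to a reference colour
#'
#' Finds the value on a single colour channel whose perceived luminance
#' equals that of the reference, e.g. the green matching a given red is
#' `G = R * 0.2126 / 0.7152`. If the required luminance exceeds what the
#' target hue can reach at channel value 255, a gamut error is signalled
#' that reports the maximum achievable luminance.
#'
#' @param reference_rgb Reference colour (length-3, channels in `[0, 255]`).
#' @param target_hue One of `"red"`, `"green"`, `"blue"`.
#' @inheritParams perceived_luminance
#' @return A [color_state()] on the target hue.
#' @export
match_luminance <- function(reference_rgb, target_hue = c("green", "red", "blue"),
                            C1 = 0.7) {
  target_hue <- match.arg(target_hue)
  coefs <- c(red = 0.2126, green = 0.7152, blue = 0.0722)
  L_ref <- perceived_luminance(reference_rgb, C1)
  ch <- L_ref / (C1 * coefs[[target_hue]])
  if (ch > 255) {
    .err(sprintf(
      "luminance %.4f unreachable on %s: maximum achievable is %.4f",
      L_ref, target_hue, C1 * coefs[[target_hue]] * 255),
      "ssmvep_gamut_error")
  }
  rgb <- c(0, 0, 0)
  rgb[match(target_hue, names(coefs))] <- ch
  color_state(rgb, C1)
}

#' Sinusoidal colour-channel waveform
#'
#' Smooth red/green alternation driven by `R(t) = R_max (1 - cos(2 pi f t)) / 2`
#' (the raised-cosine scaled so the channel peaks at `R_max` and stays in
#' gamut): zero at `t = k/f`, maximal at `t = (k + 1/2)/f`.
#'
#' @param t Time(s) in seconds, `t >= 0`.
#' @param frequency_hz Stimulation frequency in Hz.
#' @param R_max Peak channel value, in `(0, 255]`.
#' @return Channel value(s) in `[0, R_max]`.
#' @export
color_waveform <- function(t, frequency_hz, R_max) {
  if (any(t < 0)) .err("t must be non-negative", "ssmvep_domain_error")
  if (length(R_max) != 1L || R_max <= 0 || R_max > 255) {
    .err("R_max must lie in (0, 255]", "ssmvep_domain_error")
  }
  if (frequency_hz <= 0) .err("frequency_hz must be positive",
                              "ssmvep_domain_error")
  R_max * (1 - cos(2 * pi * frequency_hz * t)) / 2
}

#' Peak channel value for a named brightness level
#'
#' Default mapping of the three brightness levels to peak channel values,
#' prior to luminance matching: low 85, medium 170, high 255.
#' @param brightness_level `"low"`, `"medium"` or `"high"`, or a numeric
#'   value in `(0, 255]` passed through unchanged.
#' @export
brightness_rmax <- function(brightness_level) {
  if (is.numeric(brightness_level)) {
    if (brightness_level <= 0 || brightness_level > 255) {
      .err("numeric brightness must lie in (0, 255]", "ssmvep_domain_error")
    }
    return(brightness_level)
  }
  switch(match.arg(brightness_level, c("low", "medium", "high")),
         low = 85, medium = 170, high = 255)
}

#' Stimulus configuration
#'
#' Bundles every parameter needed to render one stimulation target:
#' paradigm (`bimodal` motion+colour, `single_motion` black/white motion,
#' `single_color` static rings with colour modulation), stimulation
#' frequency, brightness level, band/background area ratio `C`, ring count,
#' canvas geometry, frame rate and the 4-target layout offsets
#' (defaults: 240 px vertical, 360 px horizontal).
#'
#' @param paradigm One of `"bimodal"`, `"single_motion"`, `"single_color"`.
#' @param frequency_hz Stimulation frequency in Hz (> 0).
#' @param brightness_level `"low"`, `"medium"`, `"high"` or a numeric peak
#'   channel value.
#' @param area_ratio_C Band/background area ratio (study values 0.5/0.6/0.7).
#' @param n_rings Number of rings.
#' @param canvas_px Canvas `c(width, height)` in pixels.
#' @param frame_rate_hz Frame rate; must be at least `2 * frequency_hz`.
#' @param target_offsets_px Named `c(vertical, horizontal)` centre offsets
#'   for the 4-target layout.
#' @param r_max Pattern scale radius in pixels; defaults to 95% of the
#'   largest radius the canvas can hold.
#' @param C1 Device luminance constant (default 0.7).
#' @return Object of class `stimulus_config`.
#' @export
stimulus_config <- function(paradigm = c("bimodal", "single_motion", "single_color"),
                            frequency_hz = 3,
                            brightness_level = "medium",
                            area_ratio_C = 0.6,
                            n_rings = 4,
                            canvas_px = c(width = 512, height = 512),
                            frame_rate_hz = 60,
                            target_offsets_px = c(vertical = 240, horizontal = 360),
                            r_max = NULL,
                            C1 = 0.7) {
  paradigm <- match.arg(paradigm)
  if (frequency_hz <= 0) .err("frequency_hz must be positive",
                              "ssmvep_domain_error")
  if (frame_rate_hz < 2 * frequency_hz) {
    .err("frame_rate_hz must be at least 2 * frequency_hz (Nyquist)",
         "ssmvep_config_error")
  }
  canvas_px <- as.numeric(canvas_px)
  if (length(canvas_px) != 2L || any(canvas_px < 8)) {
    .err("canvas_px must be c(width, height), each >= 8", "ssmvep_config_error")
  }
  if (is.null(r_max)) r_max <- 0.95 * min(canvas_px) / 2
  if (r_max > min(canvas_px) / 2) {
    .err("canvas too small to contain r_max", "ssmvep_config_error")
  }
  structure(list(
    paradigm = paradigm,
    frequency_hz = frequency_hz,
    brightness_level = brightness_level,
    R_max = brightness_rmax(brightness_level),
    area_ratio_C = area_ratio_C,
    n_rings = as.integer(n_rings),
    canvas_px = c(width = canvas_px[[1L]], height = canvas_px[[2L]]),
    frame_rate_hz = frame_rate_hz,
    target_offsets_px = c(vertical = target_offsets_px[[1L]],
                          horizontal = target_offsets_px[[2L]]),
    r_max = r_max,
    C1 = C1
  ), class = "stimulus_config")
}

#' @export
print.stimulus_config <- function(x, ...) {
  cat(sprintf(
    "stimulus_config: %s, %g Hz, brightness %s, C = %g, %d rings, %gx%g px @ %g fps\n",
    x$paradigm, x$frequency_hz, as.character(x$brightness_level),
    x$area_ratio_C, x$n_rings, x$canvas_px[["width"]],
    x$canvas_px[["height"]], x$frame_rate_hz))
  invisible(x)
}

# Read/write stimulus configs as JSON or YAML keyed by file extension.
#' @rdname stimulus_config
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @export
read_stimulus_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  do.call(stimulus_config, lst)
}

#' @rdname stimulus_config
#' @param config A `stimulus_config`.
#' @export
write_stimulus_config <- function(config, path) {
  lst <- unclass(config)
  lst$R_max <- NULL
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path, precision = 15L)
  }
  invisible(path)
}

# ---- internal rendering machinery -----------------------------------------

# Distance of each pixel centre from the canvas centre (y downward).
.pixel_radius <- function(canvas_px, center = c(0, 0)) {
  w <- canvas_px[[1L]]; h <- canvas_px[[2L]]
  x <- seq_len(w) - (w + 1) / 2 - center[[1L]]
  y <- seq_len(h) - (h + 1) / 2 - center[[2L]]
  sqrt(outer(y^2, x^2, `+`))  # h x w matrix
}

# Band boundary radii at motion phase s in [0, 1]. Bands slide within their
# annular cells in squared-radius coordinates, which preserves every band's
# area exactly at all phases; s = 1 places each band at the outer end of its
# cell (the static geometry of compute_inner_radii).
.band_intervals <- function(geometry, s = 1) {
  f <- geometry$area_ratio_C / (1 + geometry$area_ratio_C)
  outer2 <- geometry$outer_radii^2
  prev2 <- c(0, outer2[-length(outer2)])
  len <- f * (outer2 - prev2)
  slack <- (outer2 - prev2) - len
  lo2 <- prev2 + s * slack
  cbind(lower = sqrt(lo2), upper = sqrt(lo2 + len))
}

# Anti-aliased per-pixel band coverage in [0, 1] (1-px linear edge ramp).
.band_coverage <- function(rmat, intervals) {
  cov <- 0
  for (k in seq_len(nrow(intervals))) {
    a <- intervals[k, 1L]; b <- intervals[k, 2L]
    cov <- cov + pmax(0, pmin(rmat - a + 0.5, b + 0.5 - rmat, 1, b - a))
  }
  cov
}

#' Binary ring mask
#'
#' Renders the band membership of every pixel (no anti-aliasing), used for
#' pixel-count verification of the area ratio.
#'
#' @param geometry A [ring_geometry()].
#' @param canvas_px Canvas `c(width, height)`.
#' @param motion_phase Motion phase in `[0, 1]`; 1 is the static geometry.
#' @return Integer matrix (height x width), 1 inside a band.
#' @export
render_mask <- function(geometry, canvas_px = c(512, 512), motion_phase = 1) {
  rmat <- .pixel_radius(as.numeric(canvas_px))
  iv <- .band_intervals(geometry, motion_phase)
  mask <- matrix(0L, nrow(rmat), ncol(rmat))
  for (k in seq_len(nrow(iv))) {
    mask[rmat >= iv[k, 1L] & rmat < iv[k, 2L]] <- 1L
  }
  mask
}

#' Pixel-counted band/background area ratio
#'
#' Counts band pixels versus background pixels inside the pattern disc
#' (the disc bounded by the outermost ring's outer radius) on a binary
#' rendered mask. For a valid geometry the result matches `area_ratio_C`
#' within pixelisation error.
#'
#' @inheritParams render_mask
#' @return The realised ratio (band pixels / background pixels).
#' @export
measure_area_ratio <- function(geometry, canvas_px = c(512, 512),
                               motion_phase = 1) {
  if (2 * geometry$pattern_radius > min(as.numeric(canvas_px))) {
    .err("canvas too small to contain the pattern", "ssmvep_config_error")
  }
  rmat <- .pixel_radius(as.numeric(canvas_px))
  mask <- render_mask(geometry, canvas_px, motion_phase)
  disc <- rmat < geometry$pattern_radius
  band <- sum(mask[disc])
  band / (sum(disc) - band)
}

# Colour on the white -> green -> dark-green path with a given perceived
# luminance; used to build the luminance-compensated background endpoint.
.white_green_path_color <- function(L_target, C1 = 0.7) {
  L_white <- C1 * 255
  L_green <- C1 * 0.7152 * 255
  if (L_target > L_white || L_target < 0) {
    .err("background luminance target out of range", "ssmvep_gamut_error")
  }
  if (L_target >= L_green) {
    u <- (L_white - L_target) / (L_white - L_green)
    c(255 * (1 - u), 255, 255 * (1 - u))
  } else {
    c(0, 255 * L_target / L_green, 0)
  }
}

# Modulation endpoint colours for the colour paradigms: rings run
# black -> red(R_max); the background runs white -> a greenish colour whose
# luminance deficit, weighted by the band/rest pixel ratio rho, exactly
# offsets the rings' luminance gain, so mean frame luminance is constant.
.bimodal_endpoints <- function(R_max, rho, C1 = 0.7) {
  ring_end <- c(R_max, 0, 0)
  L_ring <- perceived_luminance(ring_end, C1)
  bg_end <- .white_green_path_color(C1 * 255 - rho * L_ring, C1)
  list(ring_end = ring_end, bg_end = bg_end)
}

#' Render one stimulation cycle
#'
#' Produces the RGB frame sequence for a single target over the smallest
#' whole number of stimulation periods representable at the frame rate.
#' Motion paradigms slide the ring bands outward over phase 0..pi and back
#' inward over pi..2*pi (area-preserving, see [render_mask()]); colour
#' paradigms drive ring colour black->red and background white->green along
#' the raised-cosine waveform of [color_waveform()], with the green endpoint
#' luminance-compensated so the mean frame luminance is constant.
#'
#' @param config A [stimulus_config()].
#' @param n_periods Number of stimulation periods to render; default is the
#'   smallest count giving an integer number of frames.
#' @return Object of class `frame_sequence`: list of `height x width x 3`
#'   frames with values in `[0, 255]`, `timestamps`,
#'   `mean_luminance_per_frame`, `area_ratio_per_frame`, and the rendering
#'   metadata.
#' @export
render_cycle <- function(config, n_periods = NULL) {
  geom <- ring_geometry(config$n_rings, config$r_max, config$area_ratio_C)
  if (2 * geom$pattern_radius > min(config$canvas_px)) {
    .err("canvas too small to contain r_max", "ssmvep_config_error")
  }
  fpp <- config$frame_rate_hz / config$frequency_hz
  if (is.null(n_periods)) n_periods <- .min_whole_periods(fpp)
  n_frames <- round(n_periods * fpp)
  if (abs(n_frames - n_periods * fpp) > 1e-6) {
    .err("n_periods does not give an integer number of frames",
         "ssmvep_config_error")
  }
  tt <- (seq_len(n_frames) - 1L) / config$frame_rate_hz

  rmat <- .pixel_radius(config$canvas_px)
  n_px <- length(rmat)
  cov0 <- .band_coverage(rmat, .band_intervals(geom, 1))
  s_band <- sum(cov0)
  rho <- s_band / (n_px - s_band)
  ep <- .bimodal_endpoints(config$R_max, rho, config$C1)
  white <- c(255, 255, 255)

  frames <- vector("list", n_frames)
  mean_lum <- numeric(n_frames)
  ratio <- numeric(n_frames)
  disc <- rmat < geom$pattern_radius
  n_disc <- sum(disc)

  for (j in seq_len(n_frames)) {
    ph <- (1 - cos(2 * pi * config$frequency_hz * tt[[j]])) / 2
    s <- if (config$paradigm == "single_color") 1 else ph
    w <- if (config$paradigm == "single_motion") NA else ph
    iv <- .band_intervals(geom, s)
    cov <- .band_coverage(rmat, iv)
    if (config$paradigm == "single_motion") {
      ring_rgb <- c(0, 0, 0); bg_rgb <- white
    } else {
      ring_rgb <- w * ep$ring_end
      bg_rgb <- white + w * (ep$bg_end - white)
    }
    fr <- array(0, dim = c(nrow(rmat), ncol(rmat), 3L))
    for (ch in 1:3) {
      fr[, , ch] <- cov * ring_rgb[[ch]] + (1 - cov) * bg_rgb[[ch]]
    }
    frames[[j]] <- fr
    mean_lum[[j]] <- config$C1 * (0.2126 * mean(fr[, , 1L]) +
                                  0.7152 * mean(fr[, , 2L]) +
                                  0.0722 * mean(fr[, , 3L]))
    band_bin <- 0
    for (k in seq_len(nrow(iv))) {
      band_bin <- band_bin + sum(disc & rmat >= iv[k, 1L] & rmat < iv[k, 2L])
    }
    ratio[[j]] <- band_bin / (n_disc - band_bin)
  }

  structure(list(
    frames = frames,
    timestamps = tt,
    mean_luminance_per_frame = mean_lum,
    area_ratio_per_frame = ratio,
    n_periods = n_periods,
    config = config,
    geometry = geom,
    ring_end = ep$ring_end,
    bg_end = ep$bg_end
  ), class = "frame_sequence")
}

# Smallest k such that k * frames-per-period is (numerically) an integer.
.min_whole_periods <- function(frames_per_period, max_k = 1000L) {
  for (k in seq_len(max_k)) {
    if (abs(k * frames_per_period - round(k * frames_per_period)) < 1e-6) {
      return(k)
    }
  }
  .err("frame rate and frequency have no small common period",
       "ssmvep_config_error")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf(
    "frame_sequence: %d frames of %dx%d px, %g s (%s periods), luminance ripple %.3g%%\n",
    length(x$frames), d[[2L]], d[[1L]],
    length(x$frames) / x$config$frame_rate_hz,
    paste(x$n_periods, collapse = "/"),
    100 * diff(range(x$mean_luminance_per_frame)) /
      mean(x$mean_luminance_per_frame)))
  invisible(x)
}

#' Compose the multi-target stimulation layout
#'
#' Arranges rendered targets on one canvas: with four configurations the
#' targets sit above/below the centre at the vertical offset and left/right
#' of the centre at the horizontal offset (defaults 240 px and 360 px), in
#' the order top, bottom, left, right; a single configuration is centred and
#' reproduces [render_cycle()] exactly. The sequence spans the smallest
#' duration containing a whole number of periods of every frequency.
#'
#' @param configs List of 1 or 4 [stimulus_config()]s (four targets must
#'   have distinct frequencies and share a frame rate).
#' @param canvas_px Overall canvas `c(width, height)` in pixels.
#' @return A `frame_sequence` with an additional `target_centers` matrix of
#'   `(x, y)` offsets from the canvas centre.
#' @export
compose_layout <- function(configs, canvas_px = c(1024, 768)) {
  if (inherits(configs, "stimulus_config")) configs <- list(configs)
  n <- length(configs)
  if (!n %in% c(1L, 4L)) {
    .err("compose_layout takes 1 or 4 configs", "ssmvep_layout_error")
  }
  canvas_px <- as.numeric(canvas_px)
  fr <- vapply(configs, `[[`, numeric(1), "frame_rate_hz")
  if (length(unique(fr)) != 1L) {
    .err("all configs must share a frame rate", "ssmvep_layout_error")
  }
  freqs <- vapply(configs, `[[`, numeric(1), "frequency_hz")
  if (n == 4L && anyDuplicated(freqs)) {
    .err("four targets must have distinct frequencies", "ssmvep_layout_error")
  }
  off <- configs[[1L]]$target_offsets_px
  centers <- if (n == 1L) {
    matrix(c(0, 0), 1L, dimnames = list(NULL, c("x", "y")))
  } else {
    matrix(c(0, -off[["vertical"]],
             0,  off[["vertical"]],
             -off[["horizontal"]], 0,
             off[["horizontal"]], 0),
           ncol = 2L, byrow = TRUE, dimnames = list(NULL, c("x", "y")))
  }

  full_canvas <- n == 1L
  half <- vapply(configs, function(cf) ceiling(cf$r_max) + 1, numeric(1))
  if (!full_canvas) {
    for (i in seq_len(n)) {
      if (abs(centers[i, "x"]) + half[[i]] > canvas_px[[1L]] / 2 ||
          abs(centers[i, "y"]) + half[[i]] > canvas_px[[2L]] / 2) {
        .err("target bounding box leaves the canvas", "ssmvep_layout_error")
      }
      for (k in seq_len(i - 1L)) {
        if (abs(centers[i, "x"] - centers[k, "x"]) < half[[i]] + half[[k]] &&
            abs(centers[i, "y"] - centers[k, "y"]) < half[[i]] + half[[k]]) {
          .err("target bounding boxes overlap", "ssmvep_layout_error")
        }
      }
    }
  }

  fpp <- fr[[1L]] / freqs
  per_target_frames <- vapply(fpp, function(p) {
    as.integer(round(.min_whole_periods(p) * p))
  }, integer(1))
  n_frames <- Reduce(.lcm, per_target_frames)
  tt <- (seq_len(n_frames) - 1L) / fr[[1L]]

  # Render each target over the common duration on its own patch.
  sub <- vector("list", n)
  for (i in seq_len(n)) {
    cf <- configs[[i]]
    patch_px <- if (full_canvas) canvas_px else rep(2 * half[[i]], 2L)
    cf$canvas_px <- c(width = patch_px[[1L]], height = patch_px[[2L]])
    sub[[i]] <- render_cycle(cf, n_periods = n_frames / fpp[[i]])
  }

  w <- canvas_px[[1L]]; h <- canvas_px[[2L]]
  frames <- vector("list", n_frames)
  mean_lum <- numeric(n_frames)
  for (j in seq_len(n_frames)) {
    fr_j <- array(128, dim = c(h, w, 3L))
    for (i in seq_len(n)) {
      p <- sub[[i]]$frames[[j]]
      ph <- dim(p)[[1L]]; pw <- dim(p)[[2L]]
      r0 <- round((h - ph) / 2 + centers[i, "y"])
      c0 <- round((w - pw) / 2 + centers[i, "x"])
      fr_j[r0 + seq_len(ph), c0 + seq_len(pw), ] <- p
    }
    frames[[j]] <- fr_j
    mean_lum[[j]] <- configs[[1L]]$C1 * (0.2126 * mean(fr_j[, , 1L]) +
                                         0.7152 * mean(fr_j[, , 2L]) +
                                         0.0722 * mean(fr_j[, , 3L]))
  }

  structure(list(
    frames = frames,
    timestamps = tt,
    mean_luminance_per_frame = mean_lum,
    area_ratio_per_frame = sub[[1L]]$area_ratio_per_frame,
    n_periods = n_frames / fpp,
    config = configs[[1L]],
    configs = configs,
    target_centers = centers,
    geometry = sub[[1L]]$geometry
  ), class = "frame_sequence")
}

.lcm <- function(a, b) {
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  a / g(a, b) * b
}

#' Export a frame sequence as numbered PNG files
#'
#' @param fseq A `frame_sequence`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the written paths.
#' @export
write_frames_png <- function(fseq, dir, prefix = "frame") {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG export")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(fseq$frames))
  for (j in seq_along(fseq$frames)) {
    paths[[j]] <- file.path(dir, sprintf("%s_%04d.png", prefix, j))
    png::writePNG(fseq$frames[[j]] / 255, paths[[j]])
  }
  invisible(paths)
}
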