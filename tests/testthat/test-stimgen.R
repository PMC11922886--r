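# Ring geometry, colorimetry and rendering.

test_that("outer radii follow the arithmetic midpoint sequence", {
  expect_equal(compute_outer_radii(1, 100), 50)
  expect_equal(compute_outer_radii(2, 100), c(25, 75))
  # independent term-by-term evaluation
  n <- 4; r_max <- 200
  expected <- vapply(1:n, function(i) (2 * i - 1) * r_max / (2 * n),
                     numeric(1))
  expect_equal(compute_outer_radii(n, r_max), expected)
  r <- compute_outer_radii(12, 300)
  expect_true(all(diff(r) > 0))
  expect_lt(max(r), 300)
  expect_error(compute_outer_radii(0, 100), class = "ssmvep_domain_error")
  expect_error(compute_outer_radii(3, -1), class = "ssmvep_domain_error")
})

test_that("inner radii hit the band-area fraction in every cell", {
  # zero-area limit: C -> 0 pushes the band width to zero
  expect_equal(compute_inner_radii(50, 1e-9), 50, tolerance = 1e-8)
  # C = 1: band and gap take equal area in each cell
  outer <- c(25, 75)
  inner <- compute_inner_radii(outer, 1)
  prev <- c(0, 25)
  expect_equal(inner^2 - prev^2, outer^2 - inner^2)
  expect_error(compute_inner_radii(c(25, 75), -0.5),
               class = "ssmvep_domain_error")
  expect_error(compute_inner_radii(c(75, 25), 0.5),
               class = "ssmvep_domain_error")
})

test_that("pixel-counted area ratio matches C across the parameter range", {
  # pixel-count oracle at the study's C = 0.6
  g <- ring_geometry(4, 200, 0.6)
  expect_lt(abs(measure_area_ratio(g, c(512, 512)) - 0.6) / 0.6, 0.02)
  # property sweep over ring counts and ratios
  for (n in c(1, 4, 8, 12)) {
    for (C in c(0.1, 0.5, 1.0, 1.5)) {
      g <- ring_geometry(n, 230, C)
      realized <- measure_area_ratio(g, c(512, 512))
      expect_lt(abs(realized - C) / C, 0.02,
                label = sprintf("n=%d C=%g realized=%.4f", n, C, realized))
    }
  }
})

test_that("perceived luminance is the scaled Rec.709 weighting", {
  expect_equal(perceived_luminance(c(0, 0, 0), 0.7), 0)
  expect_equal(perceived_luminance(c(255, 0, 0), 0.7), 0.7 * 0.2126 * 255)
  expect_equal(perceived_luminance(c(0, 255, 0), 0.7), 0.7 * 0.7152 * 255)
  expect_equal(perceived_luminance(c(0, 0, 255), 0.7), 0.7 * 0.0722 * 255)
  # linear in each channel
  expect_equal(perceived_luminance(c(100, 60, 20)),
               perceived_luminance(c(100, 0, 0)) +
                 perceived_luminance(c(0, 60, 0)) +
                 perceived_luminance(c(0, 0, 20)))
  expect_error(perceived_luminance(c(-1, 0, 0)),
               class = "ssmvep_domain_error")
  expect_error(perceived_luminance(c(0, 300, 0)),
               class = "ssmvep_domain_error")
})

test_that("luminance matching solves the channel equation and flags gamut", {
  black <- match_luminance(c(0, 0, 0), "green")
  expect_equal(black$perceived_luminance, 0)
  # red -> green closed form: G = R * 0.2126 / 0.7152
  m <- match_luminance(c(200, 0, 0), "green")
  expect_equal(m$rgb[[2L]], 200 * 0.2126 / 0.7152)
  expect_equal(m$perceived_luminance,
               perceived_luminance(c(200, 0, 0)))
  # color_state stores a luminance that recomputes exactly
  cs <- color_state(c(10, 20, 30))
  expect_identical(cs$perceived_luminance, perceived_luminance(cs$rgb))
  # white cannot be matched on the green axis: 0.7152 * 255 < 255
  expect_error(match_luminance(c(255, 255, 255), "green"),
               class = "ssmvep_gamut_error")
  err <- tryCatch(match_luminance(c(255, 255, 255), "green"),
                  error = function(e) conditionMessage(e))
  expect_match(err, "maximum achievable")
})

test_that("colour waveform is the scaled raised cosine", {
  f <- 3
  expect_equal(color_waveform(0, f, 200), 0)
  expect_equal(color_waveform(1 / (2 * f), f, 200), 200)
  expect_equal(color_waveform(1 / f, f, 200), 0, tolerance = 1e-12)
  # pointwise agreement with a direct evaluation over one period
  tt <- seq(0, 1 / f, length.out = 60)
  expect_equal(color_waveform(tt, f, 170),
               170 * (1 - cos(2 * pi * f * tt)) / 2)
  expect_error(color_waveform(-1, f, 200), class = "ssmvep_domain_error")
  expect_error(color_waveform(0.1, f, 300), class = "ssmvep_domain_error")
})

test_that("rendered cycles keep area ratio, luminance and periodicity", {
  cfg <- stimulus_config("bimodal", frequency_hz = 3,
                         brightness_level = "medium", area_ratio_C = 0.6,
                         canvas_px = c(256, 256), frame_rate_hz = 60)
  fs1 <- render_cycle(cfg)
  expect_length(fs1$frames, 20)  # 60 fps / 3 Hz
  # periodicity: frame 0 equals the frame one period later
  fs2 <- render_cycle(cfg, n_periods = 2)
  expect_equal(fs2$frames[[1L]], fs2$frames[[21L]])
  # per-frame pixel-counted C within 2%
  expect_true(all(abs(fs1$area_ratio_per_frame - 0.6) / 0.6 < 0.02))
  # mean-luminance ripple under 1%
  ripple <- diff(range(fs1$mean_luminance_per_frame)) /
    mean(fs1$mean_luminance_per_frame)
  expect_lt(ripple, 0.01)
  # colour trajectory: |L(t) - L(0)| / L(0) <= 1% at every frame
  expect_true(all(abs(fs1$mean_luminance_per_frame -
                        fs1$mean_luminance_per_frame[[1L]]) /
                    fs1$mean_luminance_per_frame[[1L]] <= 0.01))
})

test_that("single-colour paradigm has static masks; luminance still flat", {
  cfg <- stimulus_config("single_color", frequency_hz = 4,
                         canvas_px = c(192, 192), frame_rate_hz = 60)
  fs <- render_cycle(cfg)
  # geometry frozen: the pixel-counted ratio is bit-identical across frames
  expect_true(all(fs$area_ratio_per_frame == fs$area_ratio_per_frame[[1L]]))
  ripple <- diff(range(fs$mean_luminance_per_frame)) /
    mean(fs$mean_luminance_per_frame)
  expect_lt(ripple, 0.01)
})

test_that("single-motion paradigm is black and white with moving bands", {
  cfg <- stimulus_config("single_motion", frequency_hz = 3,
                         canvas_px = c(192, 192), frame_rate_hz = 30)
  fs <- render_cycle(cfg)
  # every pixel gray-scale (R = G = B)
  fr <- fs$frames[[4L]]
  expect_equal(fr[, , 1L], fr[, , 2L])
  expect_equal(fr[, , 2L], fr[, , 3L])
  # bands move between frames but area is conserved
  expect_false(isTRUE(all.equal(fs$frames[[1L]], fs$frames[[4L]])))
  expect_true(all(abs(fs$area_ratio_per_frame - 0.6) / 0.6 < 0.02))
})

test_that("configuration preconditions are enforced", {
  expect_error(stimulus_config("bimodal", frequency_hz = 40,
                               frame_rate_hz = 60),
               class = "ssmvep_config_error")
  expect_error(stimulus_config("bimodal", canvas_px = c(64, 64), r_max = 60),
               class = "ssmvep_config_error")
  cfg <- stimulus_config("bimodal", frequency_hz = 3)
  expect_equal(unname(cfg$target_offsets_px), c(240, 360))
})

test_that("stimulus configs round-trip through JSON and YAML", {
  cfg <- stimulus_config("single_color", frequency_hz = 3.5,
                         brightness_level = "high", area_ratio_C = 0.5,
                         n_rings = 5, canvas_px = c(300, 300),
                         frame_rate_hz = 50)
  for (ext in c("json", "yaml")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_stimulus_config(cfg, path)
    back <- read_stimulus_config(path)
    expect_equal(back[names(back) != "canvas_px"],
                 cfg[names(cfg) != "canvas_px"])
    expect_equal(unname(back$canvas_px), unname(cfg$canvas_px))
  }
})

test_that("layout composition places targets at the printed offsets", {
  mk <- function(f) stimulus_config("single_color", frequency_hz = f,
                                    canvas_px = c(64, 64), r_max = 30,
                                    frame_rate_hz = 12)
  cfgs <- list(mk(4), mk(6), mk(2), mk(3))  # top, bottom, left, right
  lay <- compose_layout(cfgs, canvas_px = c(790, 550))
  expect_equal(unname(lay$target_centers[, "y"]), c(-240, 240, 0, 0))
  expect_equal(unname(lay$target_centers[, "x"]), c(0, 0, -360, 360))
  # whole sequence spans an integer number of periods of every frequency
  expect_equal(lay$n_periods, round(lay$n_periods))
})

test_that("a centred single target reproduces render_cycle exactly", {
  cfg <- stimulus_config("bimodal", frequency_hz = 4,
                         canvas_px = c(128, 128), frame_rate_hz = 24)
  solo <- compose_layout(list(cfg), canvas_px = c(128, 128))
  direct <- render_cycle(cfg)
  expect_equal(solo$frames[[3L]], direct$frames[[3L]])
})

test_that("per-target pixel traces oscillate at their own frequencies", {
  mk <- function(f) {
    stimulus_config("single_color", frequency_hz = f,
                    canvas_px = c(44, 44), r_max = 20, frame_rate_hz = 36,
                    target_offsets_px = c(vertical = 40, horizontal = 60))
  }
  cfgs <- list(mk(3), mk(4.5), mk(6), mk(9))
  lay <- compose_layout(cfgs, canvas_px = c(168, 128))
  n_fr <- length(lay$frames)
  h <- dim(lay$frames[[1L]])[[1L]]; w <- dim(lay$frames[[1L]])[[2L]]
  for (i in 1:4) {
    # red-channel trace at a pixel near the target centre
    r0 <- round(h / 2 + lay$target_centers[i, "y"])
    c0 <- round(w / 2 + lay$target_centers[i, "x"]) + 3L
    trace <- vapply(lay$frames, function(fr) fr[r0, c0, 1L], numeric(1))
    amp <- Mod(stats::fft(trace - mean(trace)))[2:(n_fr %/% 2)]
    f_grid <- (1:(n_fr %/% 2 - 1)) * 36 / n_fr
    expect_equal(f_grid[which.max(amp)], cfgs[[i]]$frequency_hz,
                 label = sprintf("target %d", i))
  }
})

test_that("layout errors cover overlap and frequency clashes", {
  mk <- function(f, off) stimulus_config("single_color", frequency_hz = f,
                                         canvas_px = c(64, 64), r_max = 30,
                                         frame_rate_hz = 12,
                                         target_offsets_px = off)
  tight <- c(vertical = 30, horizontal = 40)
  expect_error(compose_layout(list(mk(2, tight), mk(3, tight),
                                   mk(4, tight), mk(6, tight)),
                              canvas_px = c(400, 400)),
               class = "ssmvep_layout_error")
  wide <- c(vertical = 100, horizontal = 150)
  expect_error(compose_layout(list(mk(2, wide), mk(2, wide),
                                   mk(4, wide), mk(6, wide)),
                              canvas_px = c(400, 400)),
               class = "ssmvep_layout_error")
})
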