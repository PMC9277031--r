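# Phantom generator: schedules, reproducibility, rendering fidelity,
# gravimetric model, camera frames, ground-truth bookkeeping.

test_that("the acquisition schedule has floor(duration/cadence) points", {
  expect_length(acquisition_schedule(phantom_config()), 240) # 10 min x 40 h
  expect_length(acquisition_schedule(phantom_config(duration_h = 1)), 6)
  expect_length(acquisition_schedule(phantom_config(duration_h = 0)), 0)
  expect_equal(acquisition_schedule(phantom_config(duration_h = 1)),
               c(0, 1, 2, 3, 4, 5) / 6)
})

test_that("zero-duration simulation returns empty series and empty events", {
  cfg <- small_phantom(duration_h = 0)
  out <- simulate_timecourse(cfg)
  expect_length(out$times, 0)
  expect_null(out$bscans)
  expect_identical(nrow(out$truth$events), 0L)
})

test_that("equal configuration and seed give bit-identical renders", {
  cfg <- test_phantom(seed_rng = 5)
  b1 <- render_bscan(cfg, 7)
  b2 <- render_bscan(cfg, 7)
  expect_identical(b1$image, b2$image)
  b3 <- render_bscan(cfg, 7, seed = 999L)
  expect_false(identical(b1$image, b3$image))
  c1 <- render_camera_image(cfg, 7)
  c2 <- render_camera_image(cfg, 7)
  expect_identical(c1$pixels, c2$pixels)
})

test_that("invalid configurations are rejected with informative messages", {
  expect_error(
    phantom_config(coat_thickness_curve = list(time_h = c(0, 10, 40),
                                               thickness_um = c(120, 110, 130))),
    "t = 10")
  expect_error(
    phantom_config(event_times_h = list(wrinkle = 10, cotyledon = 5,
                                        radicle = 14, crack = 31)),
    "wrinkle")
  expect_error(phantom_config(coat_ri = 0), "positive")
  expect_error(render_bscan(test_phantom(), t = 99), "outside")
})

test_that("noise-free flat phantom renders layers at the exact optical separation", {
  cfg <- flat_phantom(thickness_um = 112)
  b <- render_bscan(cfg, 3)
  dz <- b$depth_extent_mm * 1000 / nrow(b$image)
  expected_px <- round(112 * 1.42 / dz)
  x <- ((seq_len(ncol(b$image)) - 0.5) / ncol(b$image) - 0.5) * b$lateral_extent_mm
  inside <- which(abs(x) <= cfg$seed_halfspan_mm - 0.1)
  seps <- vapply(inside[seq(1, length(inside), by = 12)], function(j) {
    col <- b$image[, j]
    i1 <- which.max(col)
    rest <- col
    rest[max(1, i1 - 5):min(length(col), i1 + 5)] <- -Inf
    i2 <- which.max(rest)
    abs(i2 - i1)
  }, numeric(1))
  expect_true(all(abs(seps - expected_px) <= 1))
})

test_that("event rendering matches ground-truth gating frame by frame", {
  cfg <- test_phantom(seed_rng = 9)
  real <- germinoct:::phantom_realization(cfg, 1L)
  # radicle: central third peak appears exactly at the event time
  count_at <- function(t) {
    b <- render_bscan(cfg, t, realization = real)
    span <- germinoct:::detect_seed_span(b)
    germinoct:::count_subsurface_peaks(
      average_ascans(b, as.integer(round(mean(span))), 20))
  }
  ev_r <- real$radicle_h
  expect_gt(count_at(ev_r), count_at(ev_r - 0.2))
  # cotyledon flank peaks appear at their event
  flank_count <- function(t) {
    b <- render_bscan(cfg, t, realization = real)
    span <- germinoct:::detect_seed_span(b)
    q <- as.integer(round(span[1] + 0.25 * diff(span)))
    germinoct:::count_subsurface_peaks(average_ascans(b, q, 20))
  }
  ev_c <- cfg$event_times_h$cotyledon
  expect_gt(flank_count(ev_c), flank_count(ev_c - 0.2))
})

test_that("the default thickness trajectory reproduces the reference table", {
  cfg <- phantom_config()
  tab <- pea_coat_timecourse()
  got <- germinoct:::eval_curve(cfg$coat_thickness_curve, "thickness_um", tab$time_h)
  expect_true(all(abs(got - tab$thickness_um) <= 1))
  # trajectory is nondecreasing on a fine grid
  fine <- germinoct:::eval_curve(cfg$coat_thickness_curve, "thickness_um",
                                 seq(0, 40, by = 0.1))
  expect_true(all(diff(fine) >= -1e-9))
})

test_that("the weight model is triphasic, monotone and schedule-correct", {
  cfg <- phantom_config()
  w <- simulate_weight(cfg, 1, noise = FALSE)
  expect_identical(w$time_h, weighing_schedule(40))
  expect_true(all(diff(w$weight_g) >= 0))
  expect_length(weighing_schedule(40), 27) # 21 half-hourly + 6 five-hourly
  # zero plateau slope freezes phase-II samples
  cfg0 <- phantom_config(weight_model = utils::modifyList(
    cfg$weight_model, list(plateau_slope_g_h = 0)))
  w0 <- simulate_weight(cfg0, 1, noise = FALSE)
  real <- germinoct:::phantom_realization(cfg0, 1L)
  ph2 <- w0$weight_g[w0$time_h > real$radicle_h & w0$time_h <= real$crack_h]
  expect_true(length(ph2) >= 2)
  expect_equal(max(ph2) - min(ph2), 0)
})

test_that("true weight and thickness curves correlate above 0.95 by design", {
  cfg <- phantom_config()
  truth <- ground_truth(cfg)
  wbar <- dplyr::summarise(dplyr::group_by(truth$weights, time_h),
                           weight_g = mean(weight_g), .groups = "drop")
  p <- align_series(wbar, truth$thickness, "weight", "thickness")
  expect_gte(abs(pearson_r(p)$r), 0.95)
  pd <- align_series(wbar, truth$diameter, "weight", "diameter")
  expect_gte(abs(pearson_r(pd)$r), 0.95)
})

test_that("rendered camera discs recover the configured diameter", {
  cfg <- test_phantom(camera_size = c(241L, 322L), camera_pixel_scale_mm = 11 / 322)
  for (t in c(0, 20, 40)) {
    cm <- render_camera_image(cfg, t)
    mask <- segment_seed(cm)
    d_true <- germinoct:::true_diameter_mm(cfg, t)
    d_px_true <- d_true / cm$pixel_scale_mm
    d_px_est <- 2 * sqrt(sum(mask) / pi)
    expect_lt(abs(d_px_est - d_px_true), 2) # within 2 px
  }
})

test_that("camera wrinkles raise boundary roughness only after the event", {
  cfg <- test_phantom(camera_size = c(241L, 322L), camera_pixel_scale_mm = 11 / 322)
  r_before <- germinoct:::outline_roughness(
    seed_outline(segment_seed(render_camera_image(cfg, 1))))
  r_after <- germinoct:::outline_roughness(
    seed_outline(segment_seed(render_camera_image(cfg, 10))))
  expect_lt(r_before, 0.006)
  expect_gt(r_after, 2 * r_before)
})

test_that("simulate_timecourse writes frames, weights and ground truth to disk", {
  cfg <- small_phantom(duration_h = 1 / 3, cadence_min = 10,
                       camera_size = c(121L, 161L),
                       camera_pixel_scale_mm = 11 / 161)
  od <- tempfile("sim-")
  dir.create(od)
  out <- simulate_timecourse(cfg, outdir = od)
  expect_length(out$times, 2)
  expect_setequal(
    c("weights.csv", "ground_truth.json") %in% list.files(od), TRUE)
  tiffs <- list.files(od, pattern = "^bscan.*tiff$")
  expect_length(tiffs, 2)
  rt <- read_bscan_tiff(file.path(od, tiffs[1]))
  orig <- render_bscan(cfg, 0)
  expect_equal(rt$depth_extent_mm, orig$depth_extent_mm)
  expect_lt(max(abs(rt$image - orig$image)), 80 / 65535 + 1e-6) # 16-bit step
})
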