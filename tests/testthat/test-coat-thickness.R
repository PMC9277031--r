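# Coat-thickness estimation: PCHIP boundary fitting, picking accuracy,
# refractive-index conversion, boxplot summaries.

test_that("boundary fitting interpolates exactly and preserves shape", {
  # collinear points reproduce the straight line
  pts <- tibble::tibble(x_mm = 0:5, z_um = 100 + 20 * (0:5))
  bc <- fit_boundary(pts)
  xx <- seq(0, 5, by = 0.05)
  expect_equal(predict(bc, xx), 100 + 20 * xx, tolerance = 1e-9)
  # interpolation passes through every control point
  set.seed(1)
  pts2 <- tibble::tibble(x_mm = 0:7, z_um = cumsum(abs(stats::rnorm(8, 10, 5))))
  bc2 <- fit_boundary(pts2)
  expect_equal(predict(bc2, pts2$x_mm), pts2$z_um, tolerance = 1e-9)
  # shape preservation: no overshoot between monotone samples
  fine <- predict(bc2, seq(0, 7, by = 0.01))
  expect_true(all(diff(fine) >= -1e-9))
  expect_true(all(fine <= max(pts2$z_um) + 1e-9 & fine >= min(pts2$z_um) - 1e-9))
})

test_that("boundary fitting validates its inputs", {
  expect_error(fit_boundary(tibble::tibble(x_mm = c(1, 2, 2, 3),
                                           z_um = c(1, 2, 3, 4))), "Duplicate")
  expect_error(fit_boundary(tibble::tibble(x_mm = 1:3, z_um = 1:3)), "4")
  bc <- fit_boundary(tibble::tibble(x_mm = 1:5, z_um = 1:5))
  expect_error(predict(bc, 6), "span")
})

test_that("noise-free phantom boundaries are picked within one axial pixel", {
  cfg <- flat_phantom(thickness_um = 112)
  b <- render_bscan(cfg, 3)
  dz <- germinoct:::axial_pixel_um(b)
  pts <- pick_boundary_points(b)
  up <- pts[pts$role == "upper", ]
  lo <- pts[pts$role == "lower", ]
  expect_true(all(!is.na(up$z_um)))
  expect_true(all(abs(up$z_um - cfg$surface_apex_um) <= dz))
  expect_true(all(abs((lo$z_um - up$z_um) - 112 * 1.42) <= dz))
})

test_that("images without boundaries are rejected", {
  flat <- bscan(matrix(-80, 256, 100), depth_extent_mm = 0.55)
  expect_error(pick_boundary_points(flat), "No seed")
})

test_that("thickness profiles apply the refractive-index conversion", {
  up <- fit_boundary(tibble::tibble(x_mm = 0:5, z_um = rep(400, 6)))
  lo <- fit_boundary(tibble::tibble(x_mm = 0:5, z_um = rep(400 + 159.04, 6)))
  prof <- thickness_profile(up, lo, coat_ri = 1.42)
  expect_equal(prof$physical_um, rep(112, 200), tolerance = 1e-9)
  expect_equal(prof$optical_um, rep(159.04, 200), tolerance = 1e-9)
  # identical curves give zero thickness; ri = 1 keeps optical values
  prof0 <- thickness_profile(up, up)
  expect_true(all(prof0$physical_um == 0))
  prof1 <- thickness_profile(up, lo, coat_ri = 1)
  expect_equal(prof1$physical_um, prof1$optical_um)
  # 1/ri scaling for a fixed image
  prof2 <- thickness_profile(up, lo, coat_ri = 2.84)
  expect_equal(prof2$physical_um * 2, prof$physical_um)
})

test_that("crossing boundary curves are flagged, not clipped", {
  up <- fit_boundary(tibble::tibble(x_mm = 0:5, z_um = c(100, 100, 100, 100, 100, 100)))
  lo <- fit_boundary(tibble::tibble(x_mm = 0:5, z_um = c(150, 150, 80, 80, 150, 150)))
  expect_warning(prof <- thickness_profile(up, lo), "cross")
  expect_true(any(prof$flagged))
  expect_true(any(prof$optical_um < 0)) # preserved, not clipped
})

test_that("quick central thickness matches the boundary-fit value on a clean phantom", {
  cfg <- flat_phantom(thickness_um = 150)
  b <- render_bscan(cfg, 10)
  dz <- germinoct:::axial_pixel_um(b)
  quick <- central_quick_thickness(b)
  m <- measure_coat_thickness(b)
  center_val <- prof_at_center <- m$profile$physical_um[
    which.min(abs(m$profile$lateral_mm))]
  expect_lt(abs(quick - center_val), dz)
  # a coat below the axial resolution cannot be resolved
  cfg_thin <- flat_phantom(thickness_um = 3)
  expect_error(central_quick_thickness(render_bscan(cfg_thin, 10)), "peak")
})

test_that("speckled phantoms recover layer separation and quick thickness", {
  n_rep <- 100
  seps <- numeric(n_rep)
  quick_ok <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- phantom_config(
      seed_rng = 4000 + r, n_lateral = 160,
      surface_curvature_um_mm2 = 0,
      coat_thickness_curve = list(time_h = c(0, 40), thickness_um = c(150, 150)),
      roughness_curve = list(time_h = c(0, 40), amplitude_um = c(0, 0))
    )
    b <- render_bscan(cfg, 10)
    dz <- germinoct:::axial_pixel_um(b)
    pts <- pick_boundary_points(b, n_points = 20)
    sep <- (pts$z_um[pts$role == "lower"] - pts$z_um[pts$role == "upper"]) / 1.42
    seps[r] <- mean(sep, na.rm = TRUE)
    q <- tryCatch(central_quick_thickness(b), error = function(e) NA_real_)
    quick_ok[r] <- !is.na(q) && abs(q - 150) <= 2 * dz / 1.42
  }
  dz_phys <- 2200 / 1024 / 1.42
  expect_lt(abs(mean(seps) - 150), 2200 / 1024) # mean within one axial pixel
  expect_gte(mean(quick_ok), 0.95)
})

test_that("thickness summaries match a brute-force quantile oracle", {
  prof <- tibble::tibble(lateral_mm = seq(0, 1, length.out = 100),
                         optical_um = (1:100) * 1.42,
                         physical_um = as.numeric(1:100),
                         flagged = FALSE)
  class(prof) <- c("thickness_profile", class(prof))
  s <- summarize_thickness(prof)
  expect_equal(s$q1_um, oracle_quantile_linear(1:100, 0.25)) # 25.75
  expect_equal(s$q3_um, oracle_quantile_linear(1:100, 0.75)) # 75.25
  expect_equal(s$q1_um, 25.75)
  expect_equal(s$q3_um, 75.25)
  expect_equal(s$median_um, 50.5)
  expect_equal(s$mean_um, mean(1:100))
  expect_equal(s$sd_um, stats::sd(1:100))
  # whiskers: most extreme data within 2 IQR of the quartiles
  expect_equal(s$whisker_low_um, 1)
  expect_equal(s$whisker_high_um, 100)
  # constant profile degenerates cleanly
  profc <- prof
  profc$physical_um <- rep(7, 100)
  sc <- summarize_thickness(profc)
  expect_equal(sc$mean_um, 7)
  expect_equal(sc$sd_um, 0)
  expect_equal(sc$q1_um, sc$q3_um)
  expect_error(summarize_thickness(prof[1:3, ]), "5")
})

test_that("control points round-trip through their CSV representation", {
  pts <- tibble::tibble(role = rep(c("upper", "lower"), 5),
                        x_mm = rep(seq(0, 2, length.out = 5), each = 2),
                        z_um = stats::runif(10, 100, 400))
  p <- tempfile(fileext = ".csv")
  write_control_points(pts, p)
  back <- read_control_points(p)
  expect_equal(back$z_um, pts$z_um, tolerance = 1e-9)
  expect_identical(back$role, pts$role)
})
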