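# Camera morphometry: threshold segmentation, Canny chain, overlays,
# diameters, wrinkle roughness.

make_disc_image <- function(h = 200, w = 200, r = 60, value = c(200, 190, 170),
                            bg = c(0, 0, 0), cy = h / 2, cx = w / 2,
                            scale = 11 / 644) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  disc <- (xx - cx)^2 + (yy - cy)^2 <= r^2
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    plane <- matrix(bg[ch], h, w)
    plane[disc] <- value[ch]
    px[, , ch] <- plane
  }
  camera_image(px, pixel_scale_mm = scale)
}

test_that("threshold segmentation recovers a bright disc with inclusive bounds", {
  img <- make_disc_image(r = 50)
  mask <- segment_seed(img)
  truth <- (matrix(1:200, 200, 200, byrow = TRUE) - 100)^2 +
    (matrix(1:200, 200, 200) - 100)^2 <= 50^2
  expect_lt(sum(xor(mask, truth)), 0.02 * sum(truth))
  # pixel values exactly at (62, 45, 30) are included (inclusive low bounds)
  img_lo <- make_disc_image(r = 40, value = c(62, 45, 30))
  mask_lo <- segment_seed(img_lo)
  expect_gt(sum(mask_lo), 0.95 * pi * 40^2)
  # one unit below threshold on a single channel excludes the disc
  img_below <- make_disc_image(r = 40, value = c(61, 45, 30))
  expect_error(segment_seed(img_below), "No seed")
  expect_error(segment_seed(make_disc_image(r = 40, value = c(0, 0, 0))), "No seed")
})

test_that("segmentation is idempotent when its mask is rendered back to RGB", {
  img <- make_disc_image(r = 55)
  mask1 <- segment_seed(img)
  rgb2 <- array(0, dim = c(dim(mask1), 3))
  for (ch in 1:3) rgb2[, , ch] <- mask1 * 255
  mask2 <- segment_seed(camera_image(rgb2, pixel_scale_mm = img$pixel_scale_mm))
  expect_identical(unname(mask2), unname(mask1))
})

test_that("the water-surface shadow band is excluded from the seed mask", {
  cfg <- test_phantom(camera_size = c(241L, 322L), camera_pixel_scale_mm = 11 / 322)
  cm <- render_camera_image(cfg, 20)
  mask <- segment_seed(cm)
  # nothing below the water line remains
  expect_identical(sum(mask[round(0.8 * 241):241, ]), 0L)
  # and the kept outline is one closed contour
  edges <- germinoct:::mask_boundary(mask)
  expect_identical(max(germinoct:::label8(edges)), 1L)
})

test_that("the Canny chain matches the reference edge counts on discs", {
  h <- 300; w <- 300
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  mask <- (xx - 150)^2 + (yy - 150)^2 <= 100^2
  e <- canny_boundary(mask)
  # frozen expected count, cross-validated against an independent reference
  # implementation of the same chain (sigma 1.4, identical result)
  expect_identical(sum(e), 696L)
  expect_gt(sum(e) / (2 * pi * 100), 0.9)
  expect_lt(sum(e) / (2 * pi * 100), 1.15)
  # single closed contour, one pixel wide in the gradient direction
  expect_identical(max(germinoct:::label8(e)), 1L)
  # uniform input: no edges
  expect_identical(sum(canny_boundary(matrix(0.5, 64, 64))), 0L)
})

test_that("boundary overlays recolour exactly the edge pixels", {
  img <- make_disc_image(r = 40)
  edges <- canny_boundary(segment_seed(img))
  out <- overlay_boundary(img, edges, color = c(0, 80, 255))
  diffpx <- apply(out$pixels != img$pixels, c(1, 2), any)
  expect_identical(unname(which(diffpx)), unname(which(edges)))
  none <- overlay_boundary(img, matrix(FALSE, 200, 200))
  expect_identical(none$pixels, img$pixels)
  # PNG round trip preserves the annotation losslessly
  p <- tempfile(fileext = ".png")
  write_camera_png(out, p)
  back <- read_camera_png(p, pixel_scale_mm = img$pixel_scale_mm)
  expect_equal(back$pixels, out$pixels)
})

test_that("equivalent-circle diameters follow the closed form", {
  img <- make_disc_image(r = 100, h = 260, w = 260, cy = 130, cx = 130,
                         scale = 0.017)
  o <- seed_outline(segment_seed(img))
  expect_equal(measure_diameter(o), 2 * 100 * 0.017, tolerance = 0.01)
  # single pixel
  m1 <- matrix(FALSE, 9, 9); m1[5, 5] <- TRUE
  expect_equal(measure_diameter(m1, pixel_scale_mm = 0.017),
               2 * sqrt(1 / pi) * 0.017)
  # Feret never undershoots the equivalent diameter for convex shapes
  expect_gte(measure_diameter(o, method = "feret") + 0.05, measure_diameter(o))
})

test_that("diameter recovery stays within two pixel-scales across radii and positions", {
  for (r in c(50, 90, 140)) {
    img <- make_disc_image(h = 400, w = 400, r = r,
                           cy = 150 + r / 10, cx = 210, scale = 0.02)
    # add a water shadow band near the bottom
    for (ch in 1:3) img$pixels[370:395, , ch] <- c(70, 60, 50)[ch]
    o <- seed_outline(segment_seed(img))
    expect_lt(abs(measure_diameter(o) - 2 * r * 0.02), 2 * 0.02)
  }
})

test_that("wrinkle roughness onsets respect baseline and strict threshold", {
  mk_outline <- function(r0, a = 0, k = 12) {
    h <- 200; w <- 200
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    th <- atan2(yy - 100, xx - 100)
    rr <- sqrt((xx - 100)^2 + (yy - 100)^2)
    seed_outline(rr <= r0 * (1 + a * sin(k * th)), pixel_scale_mm = 0.02)
  }
  times <- (0:9) / 6
  # perfect circles: roughness stays near zero, onset never fires
  circles <- replicate(10, mk_outline(60), simplify = FALSE)
  wi <- wrinkle_index(circles, times)
  expect_true(is.na(wi$onset_h))
  expect_true(all(wi$roughness$roughness < 0.01))
  # sinusoidal perturbation from frame 7: onset at frame 7
  outlines <- c(replicate(6, mk_outline(60), simplify = FALSE),
                replicate(4, mk_outline(60, a = 0.04), simplify = FALSE))
  wi2 <- wrinkle_index(outlines, times)
  expect_identical(wi2$frame_index, 7L)
  expect_equal(wi2$onset_h, times[7])
  # constant roughness equals the threshold exactly (baseline sd = 0):
  # the strict inequality keeps the onset unset
  expect_true(is.na(wrinkle_index(circles, times)$onset_h))
})
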