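# Spectral-domain reconstruction: closed-form system quantities, Fourier
# round trips, resolution behaviour, A-scan averaging.

test_that("axial resolution follows the coherence-length formula", {
  src <- source_spec()
  # (2 ln2 / pi) * 840^2 / 50 nm = 6.227 um in air
  expect_equal(axial_resolution(src), 6.227, tolerance = 1e-3)
  src2 <- source_spec(bandwidth_fwhm = 100)
  expect_equal(axial_resolution(src2), axial_resolution(src) / 2)
  expect_equal(axial_resolution(src, refractive_index = 2),
               axial_resolution(src) / 2)
})

test_that("maximum imaging depth follows the spectral-sampling formula", {
  src <- source_spec()
  # 840^2 / (4 * 0.09) nm = 1.96 mm; the nominal 2.2 mm B-scan depth is
  # axis metadata, not a derived quantity
  expect_equal(max_imaging_depth(src), 1.96, tolerance = 1e-3)
  src2 <- source_spec(spectrometer_resolution = 0.045)
  expect_equal(max_imaging_depth(src2), 2 * max_imaging_depth(src))
  # degenerate: depth scales with lambda0^2
  src3 <- source_spec(center_wavelength = 84, bandwidth_fwhm = 5,
                      spectrometer_resolution = 0.009)
  expect_equal(max_imaging_depth(src3) / max_imaging_depth(source_spec(spectrometer_resolution = 0.009)),
               0.01, tolerance = 1e-12)
})

test_that("single synthetic reflectors are localized within one depth pixel", {
  src <- source_spec()
  a0 <- reconstruct_ascan(synthesize_spectral_frame(
    data.frame(depth_um = 500, reflectivity = 0.05), src), src)
  dz <- diff(a0$optical_depth_um[1:2])
  depths <- seq(100, 1800, length.out = 10)
  est <- vapply(depths, function(z) {
    fr <- synthesize_spectral_frame(data.frame(depth_um = z, reflectivity = 0.05), src)
    a <- reconstruct_ascan(fr, src)
    a$optical_depth_um[which.max(a$magnitude_db)]
  }, numeric(1))
  expect_true(all(abs(est - depths) <= dz))
  # depth-axis calibration: slope 1, intercept below one pixel
  fit <- stats::lm(est ~ depths)
  expect_equal(unname(stats::coef(fit)[2]), 1, tolerance = 1e-3)
  expect_lt(abs(unname(stats::coef(fit)[1])), dz)
})

test_that("reconstruction peak bin agrees with a brute-force DFT oracle", {
  src <- source_spec()
  fr <- synthesize_spectral_frame(data.frame(depth_um = 1000, reflectivity = 0.05), src)
  a <- reconstruct_ascan(fr, src)
  dz <- diff(a$optical_depth_um[1:2])
  z_hat <- a$optical_depth_um[which.max(a$magnitude_db)]
  z_oracle <- oracle_dft_peak_depth(fr, seq(900, 1100, by = 0.25))
  expect_lt(abs(z_hat - z_oracle), dz)
})

test_that("a DC-only frame reconstructs to near-zero signal", {
  src <- source_spec()
  fr_dc <- synthesize_spectral_frame(NULL, src) # envelope only
  fr_rf <- synthesize_spectral_frame(data.frame(depth_um = 800, reflectivity = 0.05), src)
  a_dc <- reconstruct_ascan(fr_dc, src)
  a_rf <- reconstruct_ascan(fr_rf, src)
  # ignore the first bins where windowed background residue concentrates
  deep <- a_dc$optical_depth_um > 50
  expect_lt(max(a_dc$magnitude[deep]) / max(a_rf$magnitude[deep]), 1e-3)
})

test_that("total A-scan energy grows with planted reflectivity", {
  src <- source_spec()
  energies <- vapply(c(0.01, 0.05, 0.2, 0.8), function(R) {
    a <- reconstruct_ascan(synthesize_spectral_frame(
      data.frame(depth_um = 700, reflectivity = R), src), src)
    sum(a$magnitude^2)
  }, numeric(1))
  expect_true(all(diff(energies) > 0))
})

test_that("reflector pairs resolve at 20 um but merge at 3 um separation", {
  src <- source_spec()
  count_peaks <- function(sep_um) {
    fr <- synthesize_spectral_frame(
      data.frame(depth_um = c(600, 600 + sep_um), reflectivity = c(0.05, 0.05)), src)
    a <- reconstruct_ascan(fr, src)
    pk <- detect_peaks(a, min_prominence_db = 3, min_separation_um = 2)
    nrow(pk[pk$magnitude_db > -25, ])
  }
  expect_identical(count_peaks(3), 1L) # below the ~6 um coherence length
  expect_identical(count_peaks(20), 2L) # well resolved
})

test_that("reflectors beyond the maximum depth are rejected with the aliasing depth", {
  src <- source_spec()
  expect_error(
    synthesize_spectral_frame(data.frame(depth_um = 2100, reflectivity = 0.1), src),
    "alias"
  )
})

test_that("reconstruction validates its input grid", {
  src <- source_spec()
  fr <- synthesize_spectral_frame(NULL, src)
  bad <- fr
  bad$wavelengths[5] <- bad$wavelengths[5] + 0.01
  expect_error(reconstruct_ascan(bad, src), "uniform")
  bad2 <- fr
  bad2$intensities[1] <- NaN
  expect_error(reconstruct_ascan(bad2, src), "NaN")
  short <- spectral_frame(fr$wavelengths[1:512], fr$intensities[1:512])
  expect_error(reconstruct_ascan(short, src), "pixel count")
})

test_that("assemble_bscan stacks reconstructed columns in scan order", {
  src <- source_spec(n_spectral_pixels = 256)
  frames <- lapply(c(300, 600, 900), function(z) {
    synthesize_spectral_frame(data.frame(depth_um = z, reflectivity = 0.05), src)
  })
  b <- assemble_bscan(frames, src, lateral_extent_mm = 1)
  expect_identical(ncol(b$image), 3L)
  expect_equal(b$image[, 2], reconstruct_ascan(frames[[2]], src)$magnitude_db)
  b1 <- assemble_bscan(frames[1], src)
  expect_identical(ncol(b1$image), 1L)
  short <- synthesize_spectral_frame(NULL, source_spec(n_spectral_pixels = 128))
  expect_error(assemble_bscan(c(frames, list(short)), src), "mixed")
})

test_that("average_ascans averages in linear intensity and clips at edges", {
  img <- matrix(rep(c(-10, -10, -40), times = 4), nrow = 3)
  b <- bscan(img, lateral_extent_mm = 1, depth_extent_mm = 0.1)
  # identical columns: the average equals any single column
  expect_equal(average_ascans(b, 2, window = 3)$magnitude_db, img[, 1])
  expect_equal(average_ascans(b, 2, window = 1)$magnitude_db, img[, 2])
  # clipped window at the image edge still works
  expect_equal(average_ascans(b, 1, window = 20)$magnitude_db, img[, 1])
  expect_error(average_ascans(b, 99), "outside")
})

test_that("20-column averaging reduces speckle variance of the peak height", {
  set.seed(42)
  n_rep <- 120
  single <- numeric(n_rep); avg20 <- numeric(n_rep)
  profile <- c(rep(1e-6, 40), 1e-2 * exp(-(-8:8)^2 / 8), rep(1e-6, 43))
  for (r in seq_len(n_rep)) {
    speck <- matrix(stats::rexp(length(profile) * 20), length(profile), 20)
    lin <- profile * speck
    img <- 10 * log10(pmax(lin / max(lin), 1e-8))
    b <- bscan(img, lateral_extent_mm = 1, depth_extent_mm = 0.1)
    single[r] <- max(average_ascans(b, 10, window = 1)$magnitude_db -
                       min(b$image))
    avg20[r] <- max(average_ascans(b, 10, window = 20)$magnitude_db -
                      min(b$image))
  }
  expect_lt(stats::var(avg20), stats::var(single))
})
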