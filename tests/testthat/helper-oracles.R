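# Independent oracles and shared reduced-size fixtures.

# Direct discrete-Fourier oracle for spectral frames: evaluates the
# interference power |sum_j s_j exp(2 i k_j z)|^2 on a depth grid without
# any resampling/FFT machinery, after crude DC removal.
oracle_dft_peak_depth <- function(frame, z_grid_um) {
  k <- 2 * pi / frame$wavelengths # rad / nm
  s <- frame$intensities - mean(frame$intensities)
  p <- vapply(z_grid_um, function(z) {
    ph <- 2 * k * (z * 1000)
    Mod(sum(s * exp(1i * ph)))^2
  }, numeric(1))
  z_grid_um[which.max(p)]
}

# Two-pass brute-force product-moment correlation (the textbook formula,
# written independently of pearson_r)
oracle_pearson <- function(x, y) {
  xb <- sum(x) / length(x)
  yb <- sum(y) / length(y)
  num <- 0; dx2 <- 0; dy2 <- 0
  for (i in seq_along(x)) {
    num <- num + (x[i] - xb) * (y[i] - yb)
    dx2 <- dx2 + (x[i] - xb)^2
    dy2 <- dy2 + (y[i] - yb)^2
  }
  num / sqrt(dx2 * dy2)
}

# Brute-force linear-interpolation quantile (type-7 convention written out)
oracle_quantile_linear <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# Reduced-size phantom geometry used across tests: same physics and axial
# pixel size as the full configuration, fewer lateral columns.
test_phantom <- function(seed_rng = 1L, ...) {
  phantom_config(seed_rng = seed_rng, n_lateral = 240, ...)
}

# Geometry for long time-series tests: half depth window at the same
# axial pixel size (all depth thresholds unchanged), 240 lateral columns
small_phantom <- function(seed_rng = 1L, ...) {
  phantom_config(seed_rng = seed_rng, n_lateral = 240, n_depth = 512,
                 depth_extent_mm = 1.1, surface_apex_um = 300, ...)
}

# noise-free flat-geometry phantom: flat surface, constant coat thickness,
# no roughness, no speckle
flat_phantom <- function(thickness_um = 112, seed_rng = 1L, ...) {
  phantom_config(
    seed_rng = seed_rng, n_lateral = 240,
    surface_curvature_um_mm2 = 0,
    coat_thickness_curve = list(time_h = c(0, 40),
                                thickness_um = rep(thickness_um, 2)),
    roughness_curve = list(time_h = c(0, 40), amplitude_um = c(0, 0)),
    speckle_contrast = 0,
    ...
  )
}

# build a synthetic averaged A-scan with Gaussian peaks (dB domain built
# from linear amplitudes), for indicator unit tests
synthetic_ascan <- function(peak_depths_um, peak_amps, sigma_um = 6,
                            n = 512, dz_um = 2.2 * 1000 / 1024,
                            floor_amp = 1e-4) {
  z <- (seq_len(n) - 1) * dz_um
  amp <- rep(floor_amp, n)
  for (i in seq_along(peak_depths_um)) {
    amp <- amp + peak_amps[i] * exp(-(z - peak_depths_um[i])^2 / (2 * sigma_um^2))
  }
  ascan(z, 20 * log10(amp / max(amp)))
}

# cached reduced-geometry default cohort pipeline run (shared between the
# correlation acceptance check and the thickness-invariant tests)
cohort_cache <- new.env(parent = emptyenv())
cached_cohort_run <- function() {
  if (is.null(cohort_cache$res)) {
    cfg <- run_config(
      phantom = phantom_config(seed_rng = 101L, n_lateral = 240,
                               camera_size = c(241L, 322L),
                               camera_pixel_scale_mm = 11 / 322),
      outdir = tempfile("cohort-")
    )
    cohort_cache$res <- suppressMessages(run_pipeline(cfg, write_outputs = FALSE))
  }
  cohort_cache$res
}
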