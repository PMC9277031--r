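# Spectral-domain OCT forward model and reconstruction.
#
# A reflector at optical depth z modulates the detected spectrum as
# cos(2 k z) on top of the source envelope; reconstruction resamples the
# interferogram to uniform wavenumber, windows, zero-pads and inverse
# Fourier transforms it into a depth profile (A-scan).

#' Construct a spectral interferogram frame
#'
#' @param wavelengths Strictly increasing, uniform wavelength grid (nm).
#' @param intensities Detector intensities (arbitrary units), same length.
#' @return Object of class `spectral_frame`.
#' @export
spectral_frame <- function(wavelengths, intensities) {
  stopifnot(length(wavelengths) == length(intensities))
  structure(list(wavelengths = wavelengths, intensities = intensities),
            class = "spectral_frame")
}

#' Synthesize a spectral interferogram for a set of reflectors
#'
#' Forward model of SD-OCT detection: the spectrum is the Gaussian source
#' envelope times `1 + sum_i 2 sqrt(R_ref R_i) cos(2 k z_i)` sampled on the
#' spectrometer wavelength grid, with optional additive Gaussian detector
#' noise. Reflectors must lie within the spectrometer's maximum imaging
#' depth, otherwise they would alias.
#'
#' @param reflectors Data frame with columns `depth_um` (optical depth, um)
#'   and `reflectivity` (intensity reflectance, >= 0). May have zero rows.
#' @param source A [source_spec()].
#' @param reference_reflectivity Reference-arm reflectance `R_ref`.
#' @param noise_sd Additive detector noise standard deviation, as a fraction
#'   of the envelope peak.
#' @param seed Optional integer seed for the noise draw (local RNG stream).
#' @return A [spectral_frame()].
#' @export
synthesize_spectral_frame <- function(reflectors, source = source_spec(),
                                      reference_reflectivity = 1,
                                      noise_sd = 0, seed = NULL) {
  stopifnot(inherits(source, "source_spec"))
  if (is.null(reflectors) || nrow(as.data.frame(reflectors)) == 0) {
    reflectors <- data.frame(depth_um = numeric(), reflectivity = numeric())
  }
  reflectors <- as.data.frame(reflectors)
  stopifnot(all(c("depth_um", "reflectivity") %in% names(reflectors)))
  if (any(reflectors$reflectivity < 0)) abort("Reflectivities must be >= 0.")
  zmax_um <- max_imaging_depth(source) * 1000
  bad <- reflectors$depth_um >= zmax_um
  if (any(bad)) {
    abort(sprintf(
      "Reflector at %.1f um exceeds the maximum imaging depth (%.1f um) and would alias to %.1f um.",
      reflectors$depth_um[which(bad)[1]], zmax_um,
      2 * zmax_um - reflectors$depth_um[which(bad)[1]]
    ))
  }
  lam <- wavelength_grid(source)
  envelope <- exp(-4 * log(2) * (lam - source$center_wavelength)^2 /
                    source$bandwidth_fwhm^2)
  k <- 2 * pi / lam # rad / nm
  fringe <- rep(0, length(lam))
  if (nrow(reflectors) > 0) {
    for (i in seq_len(nrow(reflectors))) {
      z_nm <- reflectors$depth_um[i] * 1000
      fringe <- fringe +
        2 * sqrt(reference_reflectivity * reflectors$reflectivity[i]) *
        cos(2 * k * z_nm)
    }
  }
  intens <- envelope * (1 + fringe)
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) {
      stats::rnorm(length(lam), sd = noise_sd)
    } else {
      withr::with_seed(as.integer(seed), stats::rnorm(length(lam), sd = noise_sd))
    }
    intens <- intens + noise
  }
  spectral_frame(lam, intens)
}

#' Construct an A-scan (depth profile)
#'
#' @param optical_depth_um Depth grid (um), starting at 0, uniform.
#' @param magnitude_db Log-compressed magnitude (dB).
#' @param lateral_index Optional lateral position index.
#' @return Object of class `ascan`.
#' @export
ascan <- function(optical_depth_um, magnitude_db, lateral_index = NA_integer_) {
  stopifnot(length(optical_depth_um) == length(magnitude_db))
  structure(
    list(optical_depth_um = optical_depth_um, magnitude_db = magnitude_db,
         lateral_index = lateral_index),
    class = "ascan"
  )
}

#' @export
print.ascan <- function(x, ...) {
  cat(sprintf("<ascan> %d depth bins, 0-%.0f um, peak %.1f dB\n",
              length(x$optical_depth_um), max(x$optical_depth_um),
              max(x$magnitude_db)))
  invisible(x)
}

#' Reconstruct an A-scan from a spectral interferogram
#'
#' Standard SD-OCT processing chain: subtract the slowly varying source/DC
#' background, resample from the uniform-wavelength grid to a uniform
#' wavenumber grid (cubic spline), apply a Hann window, zero-pad to twice
#' the length, inverse Fourier transform, keep the one-sided magnitude
#' (`n_spectral_pixels` bins) and log-compress (20 log10, floored at -80 dB
#' relative to the frame maximum).
#'
#' @param frame A [spectral_frame()].
#' @param source The [source_spec()] that produced the frame.
#' @param window Apodization window: `"hann"` (default) or `"none"`.
#' @return An [ascan()].
#' @export
reconstruct_ascan <- function(frame, source = source_spec(), window = "hann") {
  stopifnot(inherits(frame, "spectral_frame"))
  lam <- frame$wavelengths
  y <- frame$intensities
  n <- length(lam)
  if (n != source$n_spectral_pixels) {
    abort("Frame length does not match the source pixel count.")
  }
  if (any(!is.finite(y))) abort("Frame intensities contain NaN/Inf.")
  dl <- diff(lam)
  if (any(dl <= 0) || diff(range(dl)) > 1e-9 * mean(dl)) {
    abort("Wavelength grid must be strictly increasing and uniform.")
  }
  # background / DC removal: reflect-padded moving average
  w <- min(129L, if (n %% 2 == 0) n - 1 else n)
  bg <- moving_average_reflect(y, w)
  sig <- y - bg
  # uniform-k resampling (k descending in lambda; flip to ascending)
  k <- 2 * pi / lam
  ord <- order(k)
  kk <- seq(min(k), max(k), length.out = n)
  sig_k <- stats::spline(k[ord], sig[ord], xout = kk, method = "fmm")$y
  win <- switch(window,
    hann = 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1))),
    none = rep(1, n),
    abort("Unknown window; use 'hann' or 'none'.")
  )
  padded <- c(sig_k * win, rep(0, n))
  spec <- fft(padded)
  mag <- Mod(spec[seq_len(n)])
  dk <- (max(k) - min(k)) / (n - 1)
  z_nm <- pi * (seq_len(n) - 1) / (2 * n * dk)
  mx <- max(mag)
  db <- if (mx > 0) {
    20 * log10(pmax(mag / mx, 10^(DB_FLOOR / 20)))
  } else {
    rep(DB_FLOOR, n)
  }
  out <- ascan(z_nm / 1000, db)
  out$magnitude <- mag # unnormalized linear magnitude
  out
}

moving_average_reflect <- function(y, w) {
  h <- (w - 1) %/% 2
  n <- length(y)
  ypad <- c(rev(y[seq_len(h)]), y, rev(y[seq(n - h + 1, n)]))
  as.numeric(stats::filter(ypad, rep(1 / w, w), sides = 2))[seq(h + 1, h + n)]
}

#' Assemble a B-scan from an ordered set of spectral frames
#'
#' Reconstructs every frame with [reconstruct_ascan()] and stacks the
#' resulting depth profiles as image columns, in scan order.
#'
#' @param frames List of [spectral_frame()] objects, in lateral scan order.
#' @param source The [source_spec()].
#' @param lateral_extent_mm Physical scan length (mm).
#' @param timestamp_h Acquisition time (hours), stored as metadata.
#' @return A [bscan()].
#' @export
assemble_bscan <- function(frames, source = source_spec(),
                           lateral_extent_mm = 6, timestamp_h = NA_real_) {
  stopifnot(length(frames) >= 1)
  lens <- vapply(frames, function(f) length(f$wavelengths), integer(1))
  if (length(unique(lens)) != 1) abort("Frames have mixed grid lengths.")
  cols <- lapply(frames, reconstruct_ascan, source = source)
  img <- vapply(cols, function(a) a$magnitude_db,
                numeric(length(cols[[1]]$magnitude_db)))
  img <- matrix(img, nrow = length(cols[[1]]$magnitude_db))
  depth_mm <- max(cols[[1]]$optical_depth_um) / 1000
  bscan(img, lateral_extent_mm = lateral_extent_mm,
        depth_extent_mm = depth_mm, timestamp_h = timestamp_h)
}

#' B-scan container
#'
#' A reconstructed cross-sectional image: depth (rows, optical depth
#' increasing downward) by lateral position (columns), in dB, with physical
#' axis extents as metadata.
#'
#' @param image Numeric matrix `n_depth x n_lateral` of log-magnitude (dB).
#' @param lateral_extent_mm Lateral field of view (mm).
#' @param depth_extent_mm Optical depth range (mm).
#' @param timestamp_h Acquisition time (hours).
#' @return Object of class `bscan`.
#' @export
bscan <- function(image, lateral_extent_mm = 6, depth_extent_mm = 2.2,
                  timestamp_h = NA_real_) {
  stopifnot(is.matrix(image), lateral_extent_mm > 0, depth_extent_mm > 0)
  structure(
    list(image = image, lateral_extent_mm = lateral_extent_mm,
         depth_extent_mm = depth_extent_mm, timestamp_h = timestamp_h),
    class = "bscan"
  )
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan> %d x %d px, %.1f mm x %.2f mm (depth x lateral), t = %s h\n",
              nrow(x$image), ncol(x$image), x$depth_extent_mm,
              x$lateral_extent_mm,
              ifelse(is.na(x$timestamp_h), "?", format(x$timestamp_h))))
  invisible(x)
}

# axial (depth) pixel size in optical micrometres
axial_pixel_um <- function(bscan) bscan$depth_extent_mm * 1000 / nrow(bscan$image)

# lateral pixel size in millimetres
lateral_pixel_mm <- function(bscan) bscan$lateral_extent_mm / ncol(bscan$image)

# depth grid (optical um) of row centres
depth_grid_um <- function(bscan) (seq_len(nrow(bscan$image)) - 1) * axial_pixel_um(bscan)

# extract column j as an ascan
bscan_column <- function(bscan, j) {
  ascan(depth_grid_um(bscan), bscan$image[, j], lateral_index = j)
}

#' Average adjacent A-scans of a B-scan
#'
#' Averages a window of adjacent columns in linear intensity (windows are
#' clipped at the image edges), then log-compresses the mean profile. Used
#' to produce the low-noise averaged depth profiles at fixed lateral
#' positions.
#'
#' @param bscan A [bscan()].
#' @param center_index Central column; defaults to the middle of the image.
#' @param window Number of columns to average (default 20).
#' @return An [ascan()] of the averaged profile.
#' @export
average_ascans <- function(bscan, center_index = NULL, window = 20) {
  stopifnot(inherits(bscan, "bscan"), window >= 1)
  nc <- ncol(bscan$image)
  if (is.null(center_index)) center_index <- (nc + 1) %/% 2
  if (center_index < 1 || center_index > nc) {
    abort("`center_index` lies outside the image.")
  }
  half <- (window - 1) / 2
  j0 <- max(1L, as.integer(ceiling(center_index - half)))
  j1 <- min(nc, as.integer(floor(center_index + half)))
  lin <- db_to_intensity(bscan$image[, j0:j1, drop = FALSE])
  avg <- rowMeans(lin)
  db <- 10 * log10(pmax(avg, 10^(DB_FLOOR / 10)))
  ascan(depth_grid_um(bscan), db, lateral_index = center_index)
}
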