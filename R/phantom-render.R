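# Forward rendering of the layered-seed phantom: B-scan images (log
# intensity with multiplicative speckle) and camera photographs.

#' Render a synthetic B-scan of the phantom at time t
#'
#' Draws the layered seed on the configured depth x lateral grid: a bright
#' surface (testa) line along a convex arc, the coat/cotyledon interface at
#' an optical distance of physical thickness x refractive index below it,
#' weak volume scatter inside the coat and tissue, cotyledon layers on both
#' flanks once the cotyledon event has occurred, a central subsurface
#' radicle blob (capped below the surface-peak amplitude) once the radicle
#' event has occurred, and a surface gap with a displaced coat flap once the
#' crack event has occurred. Depth attenuation is applied below the surface;
#' fully developed exponential-intensity speckle is applied multiplicatively
#' on linear intensity before log compression.
#'
#' @param config A [phantom_config()].
#' @param t Acquisition time in hours.
#' @param seed Integer seed for the speckle draw; defaults to a stream
#'   derived from `config$seed_rng` and `t`, so equal seeds give identical
#'   images.
#' @param realization Frozen per-seed randomness from the internal
#'   realization step; defaults to the first monitored seed.
#' @return A [bscan()] with `depth_extent_mm`/`lateral_extent_mm` metadata.
#' @export
render_bscan <- function(config, t, seed = NULL, realization = NULL) {
  validate_phantom_config(config)
  if (t < 0 || t > config$duration_h) {
    abort(sprintf("t = %g h lies outside the simulated window [0, %g].", t, config$duration_h))
  }
  if (is.null(realization)) realization <- phantom_realization(config, 1L)
  if (is.null(seed)) seed <- derive_seed(config$seed_rng, round(t * 3600) + realization$seed_index)

  nz <- config$n_depth; nx <- config$n_lateral
  dz <- config$depth_extent_mm * 1000 / nz
  z <- (seq_len(nz) - 1) * dz # optical um
  x <- ((seq_len(nx) - 0.5) / nx - 0.5) * config$lateral_extent_mm # mm
  inside <- abs(x) <= config$seed_halfspan_mm

  ev <- config$event_times_h
  radicle_h <- realization$radicle_h
  crack_h <- realization$crack_h

  zs <- surface_depth_um(config, x)
  d_phys <- true_thickness_map(config, realization, x, t)
  zi <- zs + d_phys * config$coat_ri

  gap <- rep(FALSE, nx)
  if (!is.na(crack_h) && t >= crack_h) {
    w_mm <- config$crack_width_um / 1000
    off <- abs(x) # crack centred on the radicle position (scan centre)
    gap <- inside & off < w_mm / 2
    flap <- inside & off >= w_mm / 2 & off < 1.5 * w_mm
    zs[flap] <- zs[flap] + config$crack_step_um
    zi[flap] <- zi[flap] + config$crack_step_um
  }

  R <- config$layer_reflectivities
  sig_line <- 3 # axial 1-sigma of specular lines, um
  gauss_line <- function(centers, sig) {
    out <- exp(-outer(z, centers, `-`)^2 / (2 * sig^2))
    out[, !inside] <- 0
    out
  }
  att <- exp(-config$attenuation_mm / 1000 * pmax(outer(z, zs, `-`), 0))
  below_surf <- outer(z, zs, `>`)
  below_int <- outer(z, zi, `>`)
  in_coat <- below_surf & !below_int
  amp <- R$surface * gauss_line(zs, sig_line)
  amp[, gap] <- 0
  amp_int <- R$interface * gauss_line(zi, sig_line)
  amp_int[, gap] <- 0
  amp <- amp + amp_int * att
  amp <- amp + R$coat_scatter * in_coat * att
  amp <- amp + R$tissue_scatter * below_int * att
  amp[, !inside] <- 0

  if (!is.na(ev$cotyledon) && t >= ev$cotyledon) {
    xf <- config$seed_halfspan_mm / 2
    for (sgn in c(-1, 1)) {
      wl <- exp(-(x - sgn * xf)^2 / (2 * 0.45^2))
      wl[!inside] <- 0
      blob <- gauss_line(zi + 150, 20)
      amp <- amp + R$cotyledon * sweep(blob * att, 2, wl, `*`)
    }
  }
  if (!is.na(radicle_h) && t >= radicle_h) {
    wl <- exp(-x^2 / (2 * 0.7^2))
    wl[!inside] <- 0
    blob <- sweep(gauss_line(zi + 250, 35) * att, 2, wl, `*`)
    amp <- amp + pmin(R$radicle * blob, 0.9 * R$surface)
  }

  intens <- amp^2
  cs <- config$speckle_contrast
  if (cs > 0) {
    intens <- withr::with_seed(as.integer(seed), {
      intens * ((1 - cs) + cs * matrix(stats::rexp(nz * nx), nz, nx))
    })
  }
  intens <- intens + config$noise_floor
  mx <- max(intens)
  img <- 10 * log10(pmax(intens / mx, 10^(DB_FLOOR / 10)))
  bscan(img, lateral_extent_mm = config$lateral_extent_mm,
        depth_extent_mm = config$depth_extent_mm, timestamp_h = t)
}

#' Render a synthetic camera photograph at time t
#'
#' Draws a bright seed disc of the true diameter at time `t` on a dark
#' background, with a horizontal water-surface shadow band below the
#' configured water line and a sinusoidal boundary perturbation (surface
#' wrinkles) once the wrinkle event has occurred.
#'
#' @inheritParams render_bscan
#' @param noise_sd Additive pixel noise standard deviation (8-bit counts).
#' @return A [camera_image()].
#' @export
render_camera_image <- function(config, t, seed = NULL, realization = NULL,
                                noise_sd = 2) {
  validate_phantom_config(config)
  if (t < 0 || t > config$duration_h) {
    abort(sprintf("t = %g h lies outside the simulated window [0, %g].", t, config$duration_h))
  }
  if (is.null(realization)) realization <- phantom_realization(config, 1L)
  if (is.null(seed)) {
    seed <- derive_seed(config$seed_rng, round(t * 3600) + 500000 + realization$seed_index)
  }
  h <- config$camera_size[1]; w <- config$camera_size[2]
  scale <- config$camera_pixel_scale_mm
  r0 <- true_diameter_mm(config, t) / 2 / scale # px
  cy <- 0.42 * h; cx <- 0.50 * w
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  dy <- yy - cy; dx <- xx - cx
  rr <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  ev_w <- config$event_times_h$wrinkle
  a <- if (!is.na(ev_w) && t >= ev_w) config$wrinkle_amplitude else 0
  rim <- r0 * (1 + a * sin(12 * theta + realization$rough_phase[1]))
  disc <- rr <= rim

  img <- array(0, dim = c(h, w, 3))
  bg <- c(20, 15, 10)
  fg <- c(200, 190, 170)
  shadow <- c(70, 60, 50)
  band <- yy >= 0.88 * h & yy <= 0.95 * h
  for (ch in 1:3) {
    plane <- matrix(bg[ch], h, w)
    plane[band] <- shadow[ch]
    plane[disc] <- fg[ch] * (1 - 0.15 * (rr[disc] / pmax(rim[disc], 1))^2)
    img[, , ch] <- plane
  }
  img <- withr::with_seed(as.integer(seed), {
    img + array(stats::rnorm(h * w * 3, sd = noise_sd), dim = c(h, w, 3))
  })
  img <- pmin(pmax(round(img), 0), 255)
  camera_image(img, pixel_scale_mm = scale, timestamp_h = t)
}

#' Camera image container
#'
#' @param pixels `height x width x 3` numeric array of 8-bit values (0-255).
#' @param pixel_scale_mm Pixel scale in mm per pixel (isotropic).
#' @param timestamp_h Acquisition time (hours).
#' @return Object of class `camera_image`.
#' @export
camera_image <- function(pixels, pixel_scale_mm = 11 / 644, timestamp_h = NA_real_) {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  structure(
    list(pixels = pixels, pixel_scale_mm = pixel_scale_mm,
         timestamp_h = timestamp_h),
    class = "camera_image"
  )
}

#' @export
print.camera_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<camera_image> %d x %d px RGB, %.4f mm/px, t = %s h\n",
              d[1], d[2], x$pixel_scale_mm,
              ifelse(is.na(x$timestamp_h), "?", format(x$timestamp_h))))
  invisible(x)
}
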