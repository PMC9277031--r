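# Phantom configuration: geometry, optics, time courses and event times of
# the synthetic germinating-seed scene, plus the frozen per-seed randomness
# that makes every render bit-reproducible.

#' Reference seed-coat thickness time course
#'
#' Mean seed-coat physical thickness (and its lateral spread) of an imbibing
#' pea seed at 3-hour intervals, used as the default ground-truth thickness
#' trajectory of the phantom: the coat swells from ~112 um at 3 h towards
#' ~197 um at 36 h, with the lateral spread peaking around 9-15 h when the
#' coat surface is most uneven.
#'
#' @return A tibble with columns `time_h`, `thickness_um`, `sd_um`.
#' @export
pea_coat_timecourse <- function() {
  tibble::tibble(
    time_h = seq(3, 36, by = 3),
    thickness_um = c(112, 133, 155, 170, 175, 178, 185, 186, 190, 190, 196, 197),
    sd_um = c(4.6, 5.4, 13.1, 15.3, 12.6, 4.2, 5.8, 4.1, 2.9, 4.3, 4.0, 4.8)
  )
}

# default monotone thickness trajectory: shape-preserving cubic through the
# reference table, extended to the full 0-40 h window
default_thickness_curve <- function() {
  tab <- pea_coat_timecourse()
  t <- c(0, tab$time_h, 40)
  d <- c(105, tab$thickness_um, 198)
  list(time_h = t, thickness_um = d)
}

# default lateral-roughness amplitude trajectory (um, 1-sd): follows the
# reference spread column so recovered spread peaks at 9-15 h
default_roughness_curve <- function() {
  tab <- pea_coat_timecourse()
  list(time_h = c(0, tab$time_h, 40), amplitude_um = c(4.0, tab$sd_um, 4.8))
}

# evaluate a piecewise-cubic (PCHIP) curve stored as list(time_h, value);
# curves with fewer than three knots fall back to linear interpolation
eval_curve <- function(curve, value_field, t) {
  x <- curve$time_h
  y <- curve[[value_field]]
  t_cl <- pmin(pmax(t, min(x)), max(x))
  if (length(x) < 3) {
    return(approx(x, y, xout = t_cl)$y)
  }
  pracma::pchip(x, y, t_cl)
}

#' Configure the synthetic germinating-seed phantom
#'
#' Defines everything the generator needs: B-scan geometry, seed surface
#' shape, coat-thickness and roughness time courses, layer reflectivities,
#' speckle and attenuation, the four morphological event times, camera
#' geometry and the weight model. All randomness used in rendering derives
#' deterministically from `seed_rng`.
#'
#' @param seed_rng Integer master seed for all phantom randomness.
#' @param lateral_extent_mm,depth_extent_mm B-scan field of view (mm).
#' @param n_lateral,n_depth B-scan pixel counts (columns, rows).
#' @param cadence_min Acquisition cadence in minutes.
#' @param duration_h Total monitored duration in hours.
#' @param surface_apex_um Optical depth of the seed surface apex (um).
#' @param surface_curvature_um_mm2 Convexity of the surface arc (um per mm^2).
#' @param seed_halfspan_mm Half-width of the seed along the scan (mm).
#' @param coat_thickness_curve List with `time_h`, `thickness_um`: physical
#'   coat thickness trajectory, interpolated shape-preservingly; must be
#'   nondecreasing in time.
#' @param roughness_curve List with `time_h`, `amplitude_um`: 1-sd amplitude
#'   of the frozen zero-mean lateral thickness unevenness.
#' @param coat_ri Seed-coat group refractive index (default 1.42).
#' @param layer_reflectivities Named list of relative amplitude
#'   reflectivities: `surface`, `interface`, `cotyledon`, `radicle`,
#'   `coat_scatter`, `tissue_scatter`.
#' @param attenuation_mm Amplitude attenuation coefficient below the surface
#'   (1/mm).
#' @param speckle_contrast Contrast of the multiplicative exponential
#'   intensity speckle in `[0, 1]`; 0 disables speckle.
#' @param noise_floor Additive intensity noise floor relative to the surface
#'   peak intensity.
#' @param event_times_h Named list of event onsets in hours: `wrinkle`,
#'   `cotyledon`, `radicle`, `crack`; `NA` disables an event. Defaults must
#'   satisfy wrinkle <= cotyledon <= radicle <= crack.
#' @param crack_width_um Width of the rendered surface gap at the crack.
#' @param crack_step_um Depth displacement of the coat flap beside the crack.
#' @param n_seeds Cohort size for the gravimetric model.
#' @param n_monitored Number of seeds monitored by OCT + camera.
#' @param camera_size Camera frame size in pixels, `c(height, width)`.
#' @param camera_pixel_scale_mm Camera pixel scale (mm per pixel, isotropic).
#' @param diameter_curve List with `time_h`, `diameter_mm`: true seed
#'   diameter trajectory.
#' @param wrinkle_amplitude Camera-boundary wrinkle amplitude as a fraction
#'   of the seed radius once the wrinkle event has occurred.
#' @param weight_model Named list of gravimetric parameters: `w0_g` (dry
#'   weight), `uptake_g` and `tau1_h` (imbibition gain and time constant),
#'   `plateau_slope_g_h` (lag-phase drift), `phase3_g` and `tau3_h`
#'   (post-crack uptake), `noise_cv` (multiplicative noise CV).
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(seed_rng = 1L,
                           lateral_extent_mm = 6, depth_extent_mm = 2.2,
                           n_lateral = 1000, n_depth = 1024,
                           cadence_min = 10, duration_h = 40,
                           surface_apex_um = 400,
                           surface_curvature_um_mm2 = 12,
                           seed_halfspan_mm = 2.8,
                           coat_thickness_curve = default_thickness_curve(),
                           roughness_curve = default_roughness_curve(),
                           coat_ri = 1.42,
                           layer_reflectivities = list(
                             surface = 1.0, interface = 0.55,
                             cotyledon = 0.45, radicle = 0.6,
                             coat_scatter = 0.08, tissue_scatter = 0.05
                           ),
                           attenuation_mm = 0.9,
                           speckle_contrast = 0.5,
                           noise_floor = 1e-7,
                           event_times_h = list(
                             wrinkle = 5, cotyledon = 9,
                             radicle = 41 / 3, crack = 31
                           ),
                           crack_width_um = 200,
                           crack_step_um = 15,
                           n_seeds = 10,
                           n_monitored = 1,
                           camera_size = c(482, 644),
                           camera_pixel_scale_mm = 11 / 644,
                           diameter_curve = list(
                             time_h = c(0, 5, 10, 15, 20, 25, 30, 35, 40),
                             diameter_mm = c(5.0, 5.5, 5.85, 6.05, 6.2, 6.3, 6.4, 6.5, 6.6)
                           ),
                           wrinkle_amplitude = 0.015,
                           weight_model = list(
                             w0_g = 0.30, uptake_g = 0.15, tau1_h = 7,
                             plateau_slope_g_h = 0.004,
                             phase3_g = 0.03, tau3_h = 6,
                             noise_cv = 0.005
                           )) {
  cfg <- structure(
    list(
      seed_rng = as.integer(seed_rng),
      lateral_extent_mm = lateral_extent_mm,
      depth_extent_mm = depth_extent_mm,
      n_lateral = as.integer(n_lateral), n_depth = as.integer(n_depth),
      cadence_min = cadence_min, duration_h = duration_h,
      surface_apex_um = surface_apex_um,
      surface_curvature_um_mm2 = surface_curvature_um_mm2,
      seed_halfspan_mm = seed_halfspan_mm,
      coat_thickness_curve = coat_thickness_curve,
      roughness_curve = roughness_curve,
      coat_ri = coat_ri,
      layer_reflectivities = layer_reflectivities,
      attenuation_mm = attenuation_mm,
      speckle_contrast = speckle_contrast,
      noise_floor = noise_floor,
      event_times_h = event_times_h,
      crack_width_um = crack_width_um,
      crack_step_um = crack_step_um,
      n_seeds = as.integer(n_seeds),
      n_monitored = as.integer(n_monitored),
      camera_size = as.integer(camera_size),
      camera_pixel_scale_mm = camera_pixel_scale_mm,
      diameter_curve = diameter_curve,
      wrinkle_amplitude = wrinkle_amplitude,
      weight_model = weight_model
    ),
    class = "phantom_config"
  )
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (cfg$coat_ri <= 0) abort("Refractive index must be positive.")
  if (any(unlist(cfg$layer_reflectivities) < 0)) {
    abort("Layer reflectivities must be >= 0.")
  }
  tc <- cfg$coat_thickness_curve
  dd <- diff(tc$thickness_um)
  if (any(dd < 0)) {
    i <- which(dd < 0)[1]
    abort(sprintf(
      "Coat thickness curve decreases at t = %g h (%.1f -> %.1f um); it must be nondecreasing.",
      tc$time_h[i + 1], tc$thickness_um[i], tc$thickness_um[i + 1]
    ))
  }
  ev <- cfg$event_times_h
  evv <- c(ev$wrinkle, ev$cotyledon, ev$radicle, ev$crack)
  pres <- evv[!is.na(evv)]
  if (is.unsorted(pres)) {
    abort("Event times must satisfy wrinkle <= cotyledon <= radicle <= crack.")
  }
  if (cfg$speckle_contrast < 0 || cfg$speckle_contrast > 1) {
    abort("Speckle contrast must lie in [0, 1].")
  }
  invisible(cfg)
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf("<phantom_config> %d x %d px B-scan over %g x %g mm; cadence %g min, %g h\n",
              x$n_depth, x$n_lateral, x$lateral_extent_mm, x$depth_extent_mm,
              x$cadence_min, x$duration_h))
  ev <- x$event_times_h
  cat(sprintf("  events (h): wrinkle %s, cotyledon %s, radicle %s, crack %s; RI %.2f; speckle %.2f\n",
              format(ev$wrinkle), format(ev$cotyledon),
              format(round(ev$radicle, 3)), format(ev$crack),
              x$coat_ri, x$speckle_contrast))
  invisible(x)
}

#' Acquisition schedule of a phantom configuration
#'
#' @param config A [phantom_config()].
#' @return Numeric vector of acquisition times in hours:
#'   `0, cadence, 2 cadence, ...` with `floor(duration / cadence)` points.
#' @export
acquisition_schedule <- function(config) {
  n <- floor(config$duration_h * 60 / config$cadence_min)
  if (n <= 0) return(numeric(0))
  (seq_len(n) - 1) * config$cadence_min / 60
}

# Frozen per-seed randomness: lateral roughness profile coefficients,
# per-seed weight/diameter jitters and event-time jitters, all derived from
# seed_rng so that GroundTruth and renders agree bit-for-bit.
phantom_realization <- function(config, seed_index = 1L) {
  s <- derive_seed(config$seed_rng, 1000 + seed_index)
  withr::with_seed(s, {
    n_modes <- 6
    a <- stats::rnorm(n_modes)
    a <- a / sqrt(sum(a^2)) # unit total power -> unit profile sd
    phi <- stats::runif(n_modes, 0, 2 * pi)
    wm <- config$weight_model
    w0 <- wm$w0_g * exp(stats::rnorm(1, 0, 0.03))
    uptake <- wm$uptake_g * exp(stats::rnorm(1, 0, 0.05))
    ev <- config$event_times_h
    jitter <- if (seed_index == 1L) c(0, 0) else stats::rnorm(2, 0, 0.5)
    list(
      seed_index = seed_index,
      rough_amp = a, rough_phase = phi,
      w0_g = w0, uptake_g = uptake,
      radicle_h = if (is.na(ev$radicle)) NA_real_ else max(ev$radicle + jitter[1], 1),
      crack_h = if (is.na(ev$crack)) NA_real_ else {
        r <- if (is.na(ev$radicle)) 0 else max(ev$radicle + jitter[1], 1)
        max(ev$crack + jitter[2], r + 1)
      }
    )
  })
}

# frozen zero-mean unit-sd lateral roughness profile evaluated at lateral
# positions x (mm); u in [0,1] across the seed span
roughness_profile <- function(realization, x_mm, halfspan_mm) {
  u <- (x_mm + halfspan_mm) / (2 * halfspan_mm)
  out <- rep(0, length(u))
  for (m in seq_along(realization$rough_amp)) {
    out <- out + realization$rough_amp[m] * sqrt(2) *
      cos(2 * pi * m * u + realization$rough_phase[m])
  }
  out
}

# true physical thickness map (um) at lateral positions x and time t
true_thickness_map <- function(config, realization, x_mm, t) {
  base <- eval_curve(config$coat_thickness_curve, "thickness_um", t)
  amp <- eval_curve(config$roughness_curve, "amplitude_um", t)
  pmax(base + amp * roughness_profile(realization, x_mm, config$seed_halfspan_mm), 5)
}

# true seed surface optical depth (um) at lateral positions x (mm)
surface_depth_um <- function(config, x_mm) {
  config$surface_apex_um + config$surface_curvature_um_mm2 * x_mm^2
}

# true diameter (mm) at time t
true_diameter_mm <- function(config, t) {
  eval_curve(config$diameter_curve, "diameter_mm", t)
}
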