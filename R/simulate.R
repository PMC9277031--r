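# Time-course simulation: schedules, gravimetric model, ground truth.

#' Gravimetric weighing schedule
#'
#' Seeds are weighed every 30 minutes during the first 10 hours and every
#' 5 hours for the remainder of the record.
#'
#' @param duration_h Total duration in hours.
#' @return Numeric vector of weighing times (hours).
#' @export
weighing_schedule <- function(duration_h = 40) {
  if (duration_h < 0) abort("Duration must be non-negative.")
  t <- seq(0, min(10, duration_h), by = 0.5)
  if (duration_h >= 15) t <- c(t, seq(15, duration_h, by = 5))
  unique(t[t <= duration_h])
}

#' Simulate the triphasic weight-gain curve of one seed
#'
#' Saturating water uptake during imbibition until the radicle event, a
#' near-plateau (small linear drift) during the lag phase until the crack
#' event, and renewed saturating uptake afterwards, sampled on the
#' gravimetric weighing schedule with small multiplicative noise.
#'
#' @param config A [phantom_config()].
#' @param seed_id Seed index within the cohort (1-based).
#' @param seed Integer seed for the noise draw; defaults to a stream derived
#'   from `config$seed_rng` and `seed_id`.
#' @param noise Logical; set `FALSE` for the noise-free true curve.
#' @return Tibble with columns `seed_id`, `time_h`, `weight_g`.
#' @export
simulate_weight <- function(config, seed_id = 1L, seed = NULL, noise = TRUE) {
  validate_phantom_config(config)
  r <- phantom_realization(config, seed_id)
  times <- weighing_schedule(config$duration_h)
  w <- true_weight_curve(config, r, times)
  if (noise && config$weight_model$noise_cv > 0) {
    if (is.null(seed)) seed <- derive_seed(config$seed_rng, 900000 + seed_id)
    w <- withr::with_seed(as.integer(seed), {
      w * exp(stats::rnorm(length(w), 0, config$weight_model$noise_cv))
    })
  }
  tibble::tibble(seed_id = paste0("seed", seed_id), time_h = times, weight_g = w)
}

# noise-free triphasic weight model evaluated at arbitrary times
true_weight_curve <- function(config, realization, times) {
  wm <- config$weight_model
  t_r <- realization$radicle_h %||% NA_real_
  t_c <- realization$crack_h %||% NA_real_
  if (is.na(t_r)) t_r <- Inf
  if (is.na(t_c)) t_c <- Inf
  f1 <- function(t) realization$w0_g + realization$uptake_g * (1 - exp(-t / wm$tau1_h))
  vapply(times, function(t) {
    if (t <= t_r) {
      f1(t)
    } else if (t <= t_c) {
      f1(t_r) + wm$plateau_slope_g_h * (t - t_r)
    } else {
      f1(t_r) + wm$plateau_slope_g_h * (t_c - t_r) +
        wm$phase3_g * (1 - exp(-(t - t_c) / wm$tau3_h))
    }
  }, numeric(1))
}

#' Simulate the full monitored time course with known ground truth
#'
#' Generates, for each acquisition time point, a rendered B-scan and camera
#' frame of each monitored seed, plus the gravimetric series of the whole
#' cohort, together with the exact ground truth used during rendering
#' (thickness trajectory, event times, weight and diameter curves).
#'
#' For default full-size geometry the materialised OCT series is large, so
#' frames can be written to `outdir` (multi-page-free: one TIFF/PNG per
#' frame) instead of being returned in memory; pipeline code renders frames
#' on the fly instead of calling this with full-size in-memory output.
#'
#' @param config A [phantom_config()].
#' @param components Character subset of `c("oct", "camera", "weight")`.
#' @param outdir Optional directory; when given, frames are written there
#'   and file paths are returned instead of objects.
#' @return A list with `times`, `bscans`, `cameras`, `weights` (tibble) and
#'   `truth` (a `ground_truth` list: `events`, `thickness`, `weights`,
#'   `diameter`).
#' @export
simulate_timecourse <- function(config,
                                components = c("oct", "camera", "weight"),
                                outdir = NULL) {
  validate_phantom_config(config)
  times <- acquisition_schedule(config)
  truth <- ground_truth(config)
  bscans <- NULL; cameras <- NULL
  if (length(times) > 0 && "oct" %in% components) {
    est_mem <- as.double(config$n_depth) * config$n_lateral * length(times) *
      config$n_monitored * 8
    if (is.null(outdir) && est_mem > 2e9) {
      abort("In-memory OCT series would exceed ~2 GB; pass `outdir` or reduce the geometry.")
    }
  }
  reals <- lapply(seq_len(config$n_monitored), function(i) phantom_realization(config, i))
  if ("oct" %in% components && length(times) > 0) {
    bscans <- lapply(seq_len(config$n_monitored), function(i) {
      lapply(times, function(t) {
        b <- render_bscan(config, t, realization = reals[[i]])
        if (!is.null(outdir)) {
          p <- file.path(outdir, sprintf("bscan_seed%d_t%07.2f.tiff", i, t))
          write_bscan_tiff(b, p)
          p
        } else b
      })
    })
    if (config$n_monitored == 1L) bscans <- bscans[[1]]
  }
  if ("camera" %in% components && length(times) > 0) {
    cameras <- lapply(seq_len(config$n_monitored), function(i) {
      lapply(times, function(t) {
        cm <- render_camera_image(config, t, realization = reals[[i]])
        if (!is.null(outdir)) {
          p <- file.path(outdir, sprintf("camera_seed%d_t%07.2f.png", i, t))
          write_camera_png(cm, p)
          p
        } else cm
      })
    })
    if (config$n_monitored == 1L) cameras <- cameras[[1]]
  }
  weights <- NULL
  if ("weight" %in% components && length(times) > 0) {
    weights <- purrr::map_dfr(seq_len(config$n_seeds),
                              function(i) simulate_weight(config, i))
    if (!is.null(outdir)) {
      write.csv(weights, file.path(outdir, "weights.csv"), row.names = FALSE)
    }
  }
  if (!is.null(outdir)) {
    jsonlite::write_json(truth_to_list(truth),
                         file.path(outdir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(times = times, bscans = bscans, cameras = cameras,
       weights = weights, truth = truth)
}

#' Ground truth of a phantom configuration
#'
#' The hidden parameters actually used during rendering, for recovery tests:
#' per-seed event times, the mean-thickness trajectory on the acquisition
#' grid, noise-free weight curves on the weighing schedule, and the true
#' diameter curve.
#'
#' @param config A [phantom_config()].
#' @return Object of class `ground_truth` (a list of tibbles plus the
#'   thickness-map function).
#' @export
ground_truth <- function(config) {
  times <- acquisition_schedule(config)
  reals <- lapply(seq_len(max(config$n_seeds, config$n_monitored)),
                  function(i) phantom_realization(config, i))
  ev <- config$event_times_h
  events <- if (length(times) == 0) {
    tibble::tibble(seed_id = character(), wrinkle_h = numeric(),
                   cotyledon_h = numeric(), radicle_h = numeric(),
                   crack_h = numeric())
  } else {
    purrr::map_dfr(seq_along(reals), function(i) {
      tibble::tibble(
        seed_id = paste0("seed", i),
        wrinkle_h = ev$wrinkle %||% NA_real_,
        cotyledon_h = ev$cotyledon %||% NA_real_,
        radicle_h = reals[[i]]$radicle_h,
        crack_h = reals[[i]]$crack_h
      )
    })
  }
  thickness <- tibble::tibble(
    time_h = times,
    thickness_um = if (length(times)) {
      eval_curve(config$coat_thickness_curve, "thickness_um", times)
    } else numeric(0)
  )
  wt_times <- weighing_schedule(config$duration_h)
  weights <- purrr::map_dfr(seq_len(config$n_seeds), function(i) {
    tibble::tibble(seed_id = paste0("seed", i), time_h = wt_times,
                   weight_g = true_weight_curve(config, reals[[i]], wt_times))
  })
  diameter <- tibble::tibble(time_h = times,
                             diameter_mm = if (length(times)) {
                               true_diameter_mm(config, times)
                             } else numeric(0))
  structure(
    list(events = events, thickness = thickness, weights = weights,
         diameter = diameter,
         thickness_map = function(x_mm, t, seed_index = 1L) {
           true_thickness_map(config, phantom_realization(config, seed_index),
                              x_mm, t)
         }),
    class = "ground_truth"
  )
}

truth_to_list <- function(truth) {
  list(events = truth$events, thickness = truth$thickness,
       weights = truth$weights, diameter = truth$diameter)
}
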