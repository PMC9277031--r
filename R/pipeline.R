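# End-to-end orchestration: simulate -> reconstruct/quantify -> detect ->
# correlate, with CSV/PNG outputs and a machine-readable manifest.

#' Run configuration
#'
#' Bundles everything a reproducible run needs: the phantom configuration
#' (or an input directory of previously written frames), detector
#' thresholds, the output directory and the master random seed. The
#' configuration round-trips losslessly through its on-disk JSON
#' representation.
#'
#' @param phantom A [phantom_config()]; ignored in file mode.
#' @param input Either `"simulate"` or a directory containing B-scan TIFFs
#'   written by [write_bscan_tiff()].
#' @param outdir Output directory.
#' @param seed Master random seed (overrides `phantom$seed_rng`).
#' @param min_prominence_db Peak-prominence threshold used by all detectors.
#' @param n_points Boundary pick positions per frame.
#' @param coat_ri Coat refractive index used for thickness conversion.
#' @return Object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_config(), input = "simulate",
                       outdir = tempfile("germinoct-run-"), seed = NULL,
                       min_prominence_db = 6, n_points = 60, coat_ri = 1.42) {
  if (!is.null(seed)) {
    phantom$seed_rng <- as.integer(seed)
  }
  structure(
    list(phantom = phantom, input = input, outdir = outdir,
         seed = phantom$seed_rng, min_prominence_db = min_prominence_db,
         n_points = n_points, coat_ri = coat_ri),
    class = "run_config"
  )
}

#' Write / read a run configuration as JSON
#'
#' @param config A [run_config()].
#' @param path JSON file path.
#' @return `path` (write) or the restored `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$phantom <- unclass(x$phantom)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ph <- x$phantom
  ph$camera_size <- as.integer(ph$camera_size)
  ph <- do.call(phantom_config, ph[names(ph) %in% names(formals(phantom_config))])
  run_config(phantom = ph, input = x$input, outdir = x$outdir,
             seed = x$seed, min_prominence_db = x$min_prominence_db,
             n_points = x$n_points, coat_ri = x$coat_ri)
}

#' Run the full monitoring pipeline
#'
#' Simulates (or loads) the OCT + camera time series, quantifies the coat
#' thickness of every frame via boundary fitting, detects the four
#' germination indicators, segments the record into phases, measures seed
#' diameter and boundary roughness from the camera frames, simulates the
#' gravimetric cohort and correlates the image-derived series against it.
#' Writes `thickness.csv`, `indicators.csv`, `phases.csv`, `diameter.csv`,
#' `correlation.csv`, `weights.csv`, three summary plots (PNG) and
#' `manifest.json` to the output directory.
#'
#' @param config A [run_config()].
#' @param write_outputs Set `FALSE` to skip writing files (results are
#'   still returned).
#' @return (Invisibly) a list with `thickness`, `timeline`, `phases`,
#'   `morphometry`, `weights`, `correlations`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), write_outputs = TRUE) {
  stopifnot(inherits(config, "run_config"))
  t_start <- Sys.time()
  ph <- config$phantom
  warnings <- character(0)
  timing <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    timing[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }

  if (!identical(config$input, "simulate")) {
    files <- list.files(config$input, pattern = "\\.tiff?$", full.names = TRUE)
    if (length(files) == 0) {
      abort(sprintf("Input directory '%s' contains no TIFF frames.", config$input))
    }
    bscans <- lapply(sort(files), read_bscan_tiff)
    times <- vapply(bscans, function(b) b$timestamp_h, numeric(1))
    frame_source <- function(i) bscans[[i]]
    cameras_available <- FALSE
    realization <- NULL
  } else {
    times <- acquisition_schedule(ph)
    if (length(times) == 0) abort("Empty acquisition schedule; nothing to run.")
    realization <- phantom_realization(ph, 1L)
    frame_source <- function(i) render_bscan(ph, times[i], realization = realization)
    cameras_available <- TRUE
  }
  n_frames <- length(times)
  message(sprintf("[germinoct] %d frames to process", n_frames))

  dz_ref <- NULL
  thick_rows <- list()
  surface_picks <- vector("list", n_frames)
  central_scans <- vector("list", n_frames)
  flank1_scans <- vector("list", n_frames)
  flank2_scans <- vector("list", n_frames)
  morpho_rows <- list()
  outlines <- vector("list", n_frames)

  stage("frames", {
    for (i in seq_len(n_frames)) {
      b <- frame_source(i)
      if (is.null(dz_ref)) dz_ref <- axial_pixel_um(b)
      span <- detect_seed_span(b)
      pts <- NULL
      if (!is.null(span)) {
        pts <- tryCatch(
          pick_boundary_points(b, n_points = config$n_points,
                               min_prominence_db = config$min_prominence_db,
                               span = span),
          error = function(e) NULL
        )
      }
      if (!is.null(pts)) {
        up_pts <- pts[pts$role == "upper", ]
        surface_picks[[i]] <- up_pts
        summ <- tryCatch({
          upper <- fit_boundary(up_pts, role = "upper")
          lower <- fit_boundary(pts[pts$role == "lower", ], role = "lower")
          prof <- suppressWarnings(
            thickness_profile(upper, lower, coat_ri = config$coat_ri,
                              timestamp_h = b$timestamp_h)
          )
          summarize_thickness(prof)
        }, error = function(e) NULL)
        if (!is.null(summ)) {
          thick_rows[[i]] <- dplyr::bind_cols(tibble::tibble(time_h = times[i]), summ)
        }
        center <- as.integer(round(mean(span)))
        quarter <- as.integer(round(span[1] + 0.25 * diff(span)))
        threeq <- as.integer(round(span[1] + 0.75 * diff(span)))
        central_scans[[i]] <- average_ascans(b, center, 20)
        flank1_scans[[i]] <- average_ascans(b, quarter, 20)
        flank2_scans[[i]] <- average_ascans(b, threeq, 20)
      } else {
        surface_picks[[i]] <- tibble::tibble(x_mm = numeric(), z_um = numeric())
      }
      if (cameras_available) {
        cm <- render_camera_image(ph, times[i], realization = realization)
        mask <- tryCatch(segment_seed(cm), error = function(e) NULL)
        if (!is.null(mask)) {
          o <- seed_outline(mask)
          outlines[[i]] <- o
          morpho_rows[[i]] <- tibble::tibble(
            seed_id = "seed1", time_h = times[i],
            diameter_mm = measure_diameter(o),
            roughness = outline_roughness(o)
          )
        }
      }
    }
    NULL
  })

  thickness <- dplyr::bind_rows(thick_rows)
  morphometry <- dplyr::bind_rows(morpho_rows)

  timeline <- stage("indicators", {
    ok <- !vapply(central_scans, is.null, logical(1))
    rad <- detect_radicle_emergence(central_scans[ok], times[ok],
                                    min_prominence_db = config$min_prominence_db)
    cot <- detect_cotyledon_layer(flank1_scans[ok], flank2_scans[ok], times[ok],
                                  min_prominence_db = config$min_prominence_db)
    crk <- detect_coat_crack(surface_picks, times, axial_pixel_um = dz_ref)
    wr <- if (nrow(morphometry) >= 2) {
      keep <- !vapply(outlines, is.null, logical(1))
      wrinkle_index(outlines[keep], times[keep])
    } else list(onset_h = NA_real_)
    warnings <- c(warnings, cot$warnings)
    indicator_timeline(
      wrinkle_h = wr$onset_h, cotyledon_h = cot$onset_h,
      radicle_h = rad$onset_h, crack_h = crk$onset_h,
      seed_id = "seed1",
      evidence = list(radicle = rad$evidence, cotyledon = cot$evidence,
                      crack = crk$evidence)
    )
  })
  phases <- classify_phases(timeline, c(min(times), max(times)))
  phases <- dplyr::bind_cols(tibble::tibble(seed_id = "seed1"), phases)

  weights <- stage("gravimetry", {
    purrr::map_dfr(seq_len(ph$n_seeds), function(i) simulate_weight(ph, i))
  })

  correlations <- stage("correlate", {
    wbar <- weights |>
      dplyr::group_by(.data$time_h) |>
      dplyr::summarise(weight_g = mean(.data$weight_g), .groups = "drop")
    th <- if (nrow(thickness) >= 3) thickness[, c("time_h", "mean_um")] else NULL
    di <- if (nrow(morphometry) >= 3) {
      morphometry |>
        dplyr::group_by(.data$time_h) |>
        dplyr::summarise(diameter_mm = mean(.data$diameter_mm), .groups = "drop")
    } else NULL
    if (is.null(th) && is.null(di)) NULL else validate_against_weight(th, di, wbar)
  })

  manifest <- list(
    package = "germinoct",
    version = as.character(utils::packageVersion("germinoct")),
    seed = config$seed,
    n_frames = n_frames,
    cadence_min = ph$cadence_min,
    duration_h = ph$duration_h,
    warnings = warnings,
    timing_s = timing,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )

  result <- list(thickness = thickness, timeline = timeline, phases = phases,
                 morphometry = morphometry, weights = weights,
                 correlations = correlations, manifest = manifest)

  if (write_outputs) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    od <- config$outdir
    thick_out <- thickness
    if (nrow(thick_out)) {
      names(thick_out)[names(thick_out) == "n"] <- "n_points"
      write.csv(thick_out[, c("time_h", "mean_um", "sd_um", "median_um",
                              "q1_um", "q3_um", "n_points")],
                file.path(od, "thickness.csv"), row.names = FALSE)
    }
    ind <- tidy(timeline)
    ind$frame_index <- vapply(ind$onset_h, function(o) {
      if (is.na(o)) NA_integer_ else which.min(abs(times - o))
    }, integer(1))
    write.csv(ind, file.path(od, "indicators.csv"), row.names = FALSE)
    write.csv(phases, file.path(od, "phases.csv"), row.names = FALSE)
    if (nrow(morphometry)) {
      write.csv(morphometry, file.path(od, "diameter.csv"), row.names = FALSE)
    }
    write.csv(weights, file.path(od, "weights.csv"), row.names = FALSE)
    if (!is.null(correlations)) {
      write.csv(correlations, file.path(od, "correlation.csv"), row.names = FALSE)
    }
    write_run_config(config, file.path(od, "run_config.json"))
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    save_plot <- function(p, name, width = 7, height = 4) {
      tryCatch(ggplot2::ggsave(file.path(od, name), p, width = width,
                               height = height, dpi = 120),
               error = function(e) NULL)
    }
    if (nrow(thickness) >= 2) {
      save_plot(plot_thickness_boxes(thickness, phases), "thickness_boxes.png")
      wbar <- weights |>
        dplyr::group_by(.data$time_h) |>
        dplyr::summarise(weight_g = mean(.data$weight_g), .groups = "drop")
      save_plot(plot_timecourse(weight = wbar,
                                thickness = thickness[, c("time_h", "mean_um")],
                                diameter = if (nrow(morphometry) >= 2) {
                                  morphometry[, c("time_h", "diameter_mm")]
                                } else NULL),
                "timecourse.png")
    }
    save_plot(plot_indicator_bars(tidy(timeline), span_h = max(times)),
              "indicator_bars.png")
  }
  message(sprintf("[germinoct] done in %.1f s",
                  as.numeric(difftime(Sys.time(), t_start, units = "secs"))))
  invisible(result)
}
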