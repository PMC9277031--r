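# ggplot2 visualisations of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a B-scan image
#'
#' @param object A [bscan()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bscan <- function(object, ...) {
  img <- object$image
  d2 <- tibble::tibble(
    lateral_mm = rep((seq_len(ncol(img)) - 0.5) * object$lateral_extent_mm / ncol(img),
                     each = nrow(img)),
    depth_mm = rep((seq_len(nrow(img)) - 1) * object$depth_extent_mm / nrow(img),
                   times = ncol(img)),
    db = as.vector(img)
  )
  ggplot2::ggplot(d2, ggplot2::aes(.data$lateral_mm, .data$depth_mm, fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", name = "dB") +
    ggplot2::labs(x = "lateral position (mm)", y = "optical depth (mm)",
                  title = if (is.na(object$timestamp_h)) NULL else
                    sprintf("t = %.2f h", object$timestamp_h)) +
    ggplot2::coord_fixed(ratio = 1) +
    ggplot2::theme_minimal()
}

#' Boxplot-style summary of coat thickness over time
#'
#' Draws the per-time-point thickness distribution as a box (quartiles and
#' median) with whiskers at the most extreme values within two interquartile
#' ranges, optionally split by germination phase.
#'
#' @param summaries Tibble of per-time-point summaries (rows from
#'   [summarize_thickness()]) with an added `time_h` column.
#' @param phases Optional phase tibble from [classify_phases()]; phase
#'   boundaries are drawn as dashed lines.
#' @return A ggplot.
#' @export
plot_thickness_boxes <- function(summaries, phases = NULL) {
  stopifnot(all(c("time_h", "median_um", "q1_um", "q3_um") %in% names(summaries)))
  p <- ggplot2::ggplot(summaries, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$whisker_low_um,
                                        ymax = .data$whisker_high_um), width = 0.6) +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$median_um, ymin = .data$q1_um,
                                        ymax = .data$q3_um),
                           width = 1.4, fill = "grey85") +
    ggplot2::labs(x = "time (h)", y = "seed-coat thickness (µm)") +
    ggplot2::theme_minimal()
  if (!is.null(phases)) {
    cuts <- phases$start_h[-1]
    cuts <- cuts[cuts > min(summaries$time_h) & cuts < max(summaries$time_h)]
    if (length(cuts)) {
      p <- p + ggplot2::geom_vline(xintercept = cuts, linetype = "dashed",
                                   colour = "red")
    }
  }
  p
}

#' Time-course plot of weight, thickness and diameter
#'
#' Normalizes the three series to `[0, 1]` and overlays them, mirroring the
#' joint time-course view used to compare the image-derived measures with
#' the gravimetric gold standard.
#'
#' @param weight,thickness,diameter Data frames with `time_h` and a value
#'   column (any of them may be `NULL`).
#' @return A ggplot.
#' @export
plot_timecourse <- function(weight = NULL, thickness = NULL, diameter = NULL) {
  norm01 <- function(d, label) {
    s <- extract_series(d)
    rng <- range(s$value)
    v <- if (diff(rng) == 0) rep(0.5, nrow(s)) else (s$value - rng[1]) / diff(rng)
    tibble::tibble(time_h = s$time, value = v, series = label)
  }
  parts <- list()
  if (!is.null(weight)) parts <- c(parts, list(norm01(weight, "weight")))
  if (!is.null(thickness)) parts <- c(parts, list(norm01(thickness, "coat thickness")))
  if (!is.null(diameter)) parts <- c(parts, list(norm01(diameter, "diameter")))
  d <- dplyr::bind_rows(parts)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_h, .data$value,
                                  colour = .data$series, shape = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1.6) +
    ggplot2::labs(x = "time (h)", y = "normalized value") +
    ggplot2::theme_minimal()
}

#' Horizontal-bar timeline of the four indicators across a cohort
#'
#' One row per seed; each bar starts at the indicator's onset and runs to
#' the end of the record, stacked in the canonical order wrinkle, cotyledon,
#' radicle, crack.
#'
#' @param timelines Tibble with columns `seed_id`, `indicator`, `onset_h`
#'   (e.g. bound [tidy.indicator_timeline()] rows).
#' @param span_h Record end time (hours).
#' @return A ggplot.
#' @export
plot_indicator_bars <- function(timelines, span_h = 40) {
  lev <- c("wrinkle", "cotyledon", "radicle", "crack")
  d <- dplyr::filter(timelines, !is.na(.data$onset_h))
  d$indicator <- factor(d$indicator, levels = lev)
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$onset_h, xend = span_h, y = .data$seed_id,
                   yend = .data$seed_id, colour = .data$indicator),
      linewidth = 2.5, alpha = 0.75,
      position = ggplot2::position_nudge(
        y = (as.integer(d$indicator) - 2.5) * 0.18
      )
    ) +
    ggplot2::geom_point(ggplot2::aes(x = .data$onset_h, y = .data$seed_id,
                                     colour = .data$indicator),
                        position = ggplot2::position_nudge(
                          y = (as.integer(d$indicator) - 2.5) * 0.18
                        ), size = 2) +
    ggplot2::labs(x = "time (h)", y = NULL, colour = "indicator") +
    ggplot2::xlim(0, span_h) +
    ggplot2::theme_minimal()
}
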