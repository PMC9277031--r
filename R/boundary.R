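# Seed-coat thickness from B-scans: automated boundary-point picking at
# equally spaced lateral positions, shape-preserving (PCHIP) boundary
# curves, vertical-distance thickness with refractive-index correction,
# and boxplot-style summaries.

# Detect the seed's lateral span: the widest contiguous run of columns whose
# maximum intensity exceeds the air-noise level by 10 dB. The air level is
# estimated from the top image rows.
detect_seed_span <- function(bscan, margin_rows = NULL) {
  img <- bscan$image
  nr <- nrow(img)
  top <- img[seq_len(max(4, round(0.05 * nr))), , drop = FALSE]
  air_db <- stats::median(top)
  colmax <- apply(img, 2, max)
  run <- longest_run(colmax > air_db + 10)
  if (run$length == 0) return(NULL)
  c(run$start, run$start + run$length - 1L)
}

#' Pick surface and interface boundary points on a B-scan
#'
#' At `n_points` equally spaced lateral positions inside the detected seed
#' span, the picker averages a small window of adjacent columns in linear
#' intensity, smooths the profile axially, and locates depth peaks by
#' prominence: the upper point is the first peak rising at least 10 dB above
#' the air level (the seed surface) and the lower point is the next
#' prominent peak below it (the coat/cotyledon interface). Peak positions
#' are refined to sub-pixel precision by a three-point parabola on the log
#' profile. Positions without a valid surface/interface pair are flagged
#' (`NA`) and excluded from fitting.
#'
#' @param bscan A [bscan()].
#' @param n_points Number of equally spaced lateral pick positions.
#' @param min_prominence_db Minimum peak prominence (dB).
#' @param pick_window Columns averaged around each position.
#' @param span Optional integer `c(first, last)` column span of the seed;
#'   auto-detected when `NULL`.
#' @param min_interface_gap_um Minimum optical distance between the surface
#'   and interface picks (um): closer peaks (e.g. a step-displaced second
#'   surface image beside a coat crack) are not mistaken for the interface.
#' @return Tibble with columns `position`, `x_mm`, `role` (`"upper"` /
#'   `"lower"`), `z_um` (optical depth; `NA` where no valid peak pair).
#' @export
pick_boundary_points <- function(bscan, n_points = 60,
                                 min_prominence_db = 6,
                                 pick_window = 5, span = NULL,
                                 min_interface_gap_um = 30) {
  stopifnot(inherits(bscan, "bscan"), n_points >= 4)
  if (is.null(span)) span <- detect_seed_span(bscan)
  if (is.null(span)) abort("No seed found: no column rises 10 dB above the air level.")
  dz <- axial_pixel_um(bscan)
  dx <- lateral_pixel_mm(bscan)
  nr <- nrow(bscan$image)
  air_db <- stats::median(bscan$image[seq_len(max(4, round(0.05 * nr))), , drop = FALSE])
  min_sep_px <- max(2L, ceiling(6.3 / dz))
  # pick columns: equally spaced, 2% margin inside the span
  m <- max(1, round(0.02 * (span[2] - span[1])))
  cols <- round(seq(span[1] + m, span[2] - m, length.out = n_points))
  half <- (pick_window - 1) %/% 2
  nz <- nrow(bscan$image)
  nc <- ncol(bscan$image)
  jneed <- sort(unique(unlist(lapply(cols, function(cc) {
    max(1L, cc - half):min(nc, cc + half)
  }))))
  lin_cols <- db_to_intensity(bscan$image[, jneed, drop = FALSE])
  floor_lin <- 10^(DB_FLOOR / 10)
  # all window means at once (one matrix product), then a single axial
  # 3-sample smoothing pass over the whole profile matrix
  W <- matrix(0, length(jneed), n_points)
  for (i in seq_along(cols)) {
    jj <- match(max(1L, cols[i] - half):min(nc, cols[i] + half), jneed)
    W[jj, i] <- 1 / length(jj)
  }
  profs_lin <- lin_cols %*% W
  profs_lin <- rbind(profs_lin[1, ], profs_lin, profs_lin[nz, ])
  profs_lin <- stats::filter(profs_lin, rep(1 / 3, 3), sides = 2)[2:(nz + 1), , drop = FALSE]
  profs <- 10 * log10(pmax(profs_lin, floor_lin))
  up_v <- rep(NA_real_, n_points)
  lo_v <- rep(NA_real_, n_points)
  for (i in seq_along(cols)) {
    prof <- profs[, i]
    first_sig <- which(prof > air_db + 10)[1]
    if (is.na(first_sig)) next
    # restrict the search to the surface/coat window: the interface lies
    # at most ~300 um (optical) below the surface for a swollen coat
    w0 <- max(1L, first_sig - 12L)
    w1 <- min(nz, first_sig + as.integer(ceiling(450 / dz)))
    pw <- prof[w0:w1]
    pk <- find_prominent_peaks(pw, min_prominence = min_prominence_db,
                               min_separation = min_sep_px,
                               min_height = air_db + 10)
    pk <- pk[pk$height > air_db + 10, , drop = FALSE]
    if (nrow(pk) >= 1) {
      up_v[i] <- (w0 - 1 + pk$index[1] - 1 + refine_peak_subpixel(pw, pk$index[1])) * dz
      deeper <- which((pk$index - pk$index[1]) * dz >= min_interface_gap_um)
      if (length(deeper) >= 1) {
        k <- deeper[1]
        lo_v[i] <- (w0 - 1 + pk$index[k] - 1 + refine_peak_subpixel(pw, pk$index[k])) * dz
      }
    }
  }
  x_v <- (cols - 0.5) * dx - bscan$lateral_extent_mm / 2
  res <- tibble::tibble(
    position = rep(seq_len(n_points), each = 2),
    x_mm = rep(x_v, each = 2),
    role = rep(c("upper", "lower"), n_points),
    z_um = as.vector(rbind(up_v, lo_v))
  )
  n_valid <- sum(!is.na(res$z_um[res$role == "lower"]))
  if (n_valid < 4) {
    abort(sprintf("Only %d valid boundary-point pairs; at least 4 are needed to fit curves.",
                  n_valid))
  }
  res
}

#' Fit a shape-preserving boundary curve through picked points
#'
#' Interpolates depth-vs-lateral control points with a Piecewise Cubic
#' Hermite Interpolating Polynomial (PCHIP): the curve passes through every
#' control point exactly and preserves the local shape of the data (no
#' overshoot between points).
#'
#' @param points Tibble/data frame with columns `x_mm` and `z_um` (rows with
#'   `NA` depth are dropped); at least 4 valid points, strictly increasing
#'   in `x_mm`.
#' @param role Optional label, `"upper"` or `"lower"`.
#' @return Object of class `boundary_curve`; evaluate with [predict()].
#' @export
fit_boundary <- function(points, role = NA_character_) {
  pts <- as.data.frame(points)
  stopifnot(all(c("x_mm", "z_um") %in% names(pts)))
  if ("role" %in% names(pts) && is.na(role) && length(unique(pts$role)) == 1) {
    role <- pts$role[1]
  }
  pts <- pts[!is.na(pts$z_um), c("x_mm", "z_um")]
  if (nrow(pts) < 4) abort("At least 4 valid points are needed to fit a boundary curve.")
  if (any(duplicated(pts$x_mm))) abort("Duplicate lateral coordinates in control points.")
  if (is.unsorted(pts$x_mm)) pts <- pts[order(pts$x_mm), ]
  structure(
    list(control_points = tibble::as_tibble(pts), role = role),
    class = "boundary_curve"
  )
}

#' @export
predict.boundary_curve <- function(object, x_mm, ...) {
  cp <- object$control_points
  if (any(x_mm < min(cp$x_mm) - 1e-9) || any(x_mm > max(cp$x_mm) + 1e-9)) {
    abort("Evaluation grid extends beyond the control-point span.")
  }
  x_cl <- pmin(pmax(x_mm, min(cp$x_mm)), max(cp$x_mm))
  pracma::pchip(cp$x_mm, cp$z_um, x_cl)
}

#' @export
print.boundary_curve <- function(x, ...) {
  cat(sprintf("<boundary_curve> %s, %d control points over [%.2f, %.2f] mm\n",
              ifelse(is.na(x$role), "unlabelled", x$role),
              nrow(x$control_points),
              min(x$control_points$x_mm), max(x$control_points$x_mm)))
  invisible(x)
}

#' Tidy a boundary curve into its control points
#'
#' @param x A `boundary_curve`.
#' @param ... Unused.
#' @return Tibble with columns `role`, `x_mm`, `z_um`.
#' @export
tidy.boundary_curve <- function(x, ...) {
  tibble::tibble(role = x$role, x_mm = x$control_points$x_mm,
                 z_um = x$control_points$z_um)
}

#' Seed-coat thickness profile between two boundary curves
#'
#' Thickness is measured along the depth axis (vertical distance between
#' the fitted interface and surface curves), as optical path length, then
#' converted to physical thickness by dividing by the coat refractive
#' index. Grid positions where the curves cross (negative thickness) are
#' flagged, not clipped.
#'
#' @param upper,lower `boundary_curve` objects for the surface and the
#'   coat/cotyledon interface.
#' @param coat_ri Coat group refractive index (default 1.42).
#' @param grid Lateral evaluation grid (mm); defaults to 200 equally spaced
#'   positions over the common span of the two curves.
#' @param timestamp_h Optional acquisition time carried as metadata.
#' @return Tibble of class `thickness_profile` with columns `lateral_mm`,
#'   `optical_um`, `physical_um`, `flagged`; attributes `coat_ri`,
#'   `timestamp_h`.
#' @export
thickness_profile <- function(upper, lower, coat_ri = 1.42, grid = NULL,
                              timestamp_h = NA_real_) {
  stopifnot(inherits(upper, "boundary_curve"), inherits(lower, "boundary_curve"),
            coat_ri > 0)
  lo_span <- range(lower$control_points$x_mm)
  up_span <- range(upper$control_points$x_mm)
  span <- c(max(lo_span[1], up_span[1]), min(lo_span[2], up_span[2]))
  if (span[1] >= span[2]) abort("Boundary curves share no overlapping lateral span.")
  if (is.null(grid)) grid <- seq(span[1], span[2], length.out = 200)
  if (any(grid < span[1] - 1e-9 | grid > span[2] + 1e-9)) {
    abort("Grid extends beyond the curves' common lateral span.")
  }
  zu <- predict(upper, grid)
  zl <- predict(lower, grid)
  optical <- zl - zu
  out <- tibble::tibble(
    lateral_mm = grid,
    optical_um = optical,
    physical_um = optical / coat_ri,
    flagged = optical < 0
  )
  if (any(out$flagged)) {
    warn(sprintf("Boundary curves cross at %d of %d grid positions (negative thickness).",
                 sum(out$flagged), length(grid)))
  }
  attr(out, "coat_ri") <- coat_ri
  attr(out, "timestamp_h") <- timestamp_h
  class(out) <- c("thickness_profile", class(out))
  out
}

#' Quick central coat thickness from an averaged A-scan
#'
#' Averages `window` A-scans around the central lateral position, takes the
#' optical distance between the first two prominent depth peaks (surface and
#' coat interface) and converts it to physical thickness via the coat
#' refractive index.
#'
#' @param bscan A [bscan()].
#' @param window Number of adjacent A-scans averaged (default 20).
#' @param coat_ri Coat refractive index.
#' @param min_prominence_db Minimum peak prominence (dB).
#' @return Physical thickness in micrometres (length-1 numeric).
#' @export
central_quick_thickness <- function(bscan, window = 20, coat_ri = 1.42,
                                    min_prominence_db = 6) {
  span <- detect_seed_span(bscan)
  if (is.null(span)) abort("No seed found in the B-scan.")
  center <- as.integer(round(mean(span)))
  avg <- average_ascans(bscan, center_index = center, window = window)
  dz <- axial_pixel_um(bscan)
  prof <- avg$magnitude_db
  nr <- nrow(bscan$image)
  air_db <- stats::median(bscan$image[seq_len(max(4, round(0.05 * nr))), , drop = FALSE])
  pk <- find_prominent_peaks(prof, min_prominence = min_prominence_db,
                             min_separation = max(2L, ceiling(6.3 / dz)),
                             min_height = air_db + 10)
  pk <- pk[pk$height > air_db + 10, , drop = FALSE]
  if (nrow(pk) < 2) {
    abort("Fewer than two resolvable peaks in the central averaged A-scan; the coat is unresolvable.")
  }
  z1 <- (pk$index[1] - 1 + refine_peak_subpixel(prof, pk$index[1])) * dz
  k2 <- which((pk$index - pk$index[1]) * dz >= 1.5 * axial_resolution(source_spec()))
  if (length(k2) == 0) {
    abort("No interface peak resolvable below the surface; the coat is unresolvable.")
  }
  z2 <- (pk$index[k2[1]] - 1 + refine_peak_subpixel(prof, pk$index[k2[1]])) * dz
  (z2 - z1) / coat_ri
}

#' Summarize a thickness profile (boxplot statistics)
#'
#' Mean, sample standard deviation, median, linear-interpolation quartiles
#' and whiskers at the most extreme data within two interquartile ranges of
#' the quartile box.
#'
#' @param profile A [thickness_profile()] (flagged positions are excluded).
#' @param value Column summarized: `"physical_um"` (default) or
#'   `"optical_um"`.
#' @return One-row tibble: `mean_um`, `sd_um`, `median_um`, `q1_um`,
#'   `q3_um`, `whisker_low_um`, `whisker_high_um`, `n`.
#' @export
summarize_thickness <- function(profile, value = "physical_um") {
  x <- profile[[value]][!profile$flagged]
  x <- x[!is.na(x)]
  if (length(x) < 5) abort("At least 5 valid positions are needed to summarize thickness.")
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  wl <- min(x[x >= q[1] - 2 * iqr])
  wh <- max(x[x <= q[3] + 2 * iqr])
  tibble::tibble(
    mean_um = mean(x), sd_um = sd(x), median_um = q[2],
    q1_um = q[1], q3_um = q[3],
    whisker_low_um = wl, whisker_high_um = wh, n = length(x)
  )
}

#' Measure coat thickness of a B-scan end to end
#'
#' Convenience wrapper: pick boundary points, fit both PCHIP curves,
#' evaluate the thickness profile and summarize it.
#'
#' @inheritParams pick_boundary_points
#' @inheritParams thickness_profile
#' @return A list with `points`, `upper`, `lower`, `profile`, `summary`.
#' @export
measure_coat_thickness <- function(bscan, n_points = 60, coat_ri = 1.42,
                                   min_prominence_db = 6, pick_window = 5) {
  pts <- pick_boundary_points(bscan, n_points = n_points,
                              min_prominence_db = min_prominence_db,
                              pick_window = pick_window)
  upper <- fit_boundary(dplyr::filter(pts, .data$role == "upper"), role = "upper")
  lower <- fit_boundary(dplyr::filter(pts, .data$role == "lower"), role = "lower")
  prof <- thickness_profile(upper, lower, coat_ri = coat_ri,
                            timestamp_h = bscan$timestamp_h)
  list(points = pts, upper = upper, lower = lower, profile = prof,
       summary = summarize_thickness(prof))
}
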