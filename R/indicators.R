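# Morphological germination indicators from the OCT time series: new
# subsurface peaks (radicle, cotyledons), surface discontinuities (coat
# crack), and segmentation of the record into phases I/II/III.

#' Detect prominent peaks in an A-scan
#'
#' Local maxima of the depth profile passing a topographic-prominence filter
#' and a minimum-separation filter; the surface (shallowest) peak comes
#' first.
#'
#' @param ascan An [ascan()].
#' @param min_prominence_db Minimum prominence in dB (default 6).
#' @param min_separation_um Minimum peak separation in optical micrometres;
#'   defaults to the system axial resolution (6.3 um).
#' @return Tibble with columns `depth_um`, `magnitude_db`, `prominence_db`,
#'   sorted by depth; zero rows for flat input.
#' @export
detect_peaks <- function(ascan, min_prominence_db = 6, min_separation_um = 6.3) {
  stopifnot(inherits(ascan, "ascan"))
  y <- ascan$magnitude_db
  if (any(!is.finite(y))) abort("A-scan contains non-finite values.")
  dz <- if (length(ascan$optical_depth_um) > 1) {
    diff(ascan$optical_depth_um[1:2])
  } else 1
  sep_px <- max(2L, ceiling(min_separation_um / dz))
  pk <- find_prominent_peaks(y, min_prominence = min_prominence_db,
                             min_separation = sep_px)
  tibble::tibble(
    depth_um = ascan$optical_depth_um[pk$index],
    magnitude_db = pk$height,
    prominence_db = pk$prominence
  )
}

# count subsurface peaks: peaks deeper than the surface peak whose amplitude
# stays below it. The surface peak is the shallowest detected peak.
count_subsurface_peaks <- function(ascan, min_prominence_db = 6) {
  pk <- detect_peaks(ascan, min_prominence_db = min_prominence_db)
  if (nrow(pk) == 0) return(0L)
  surf <- pk$magnitude_db[1]
  sum(pk$depth_um > pk$depth_um[1] & pk$magnitude_db <= surf)
}

check_cadence <- function(times) {
  if (length(times) < 2) abort("At least 2 frames are required.")
  dt <- diff(times)
  if (diff(range(dt)) > 1e-6 * mean(dt)) {
    abort("Frame cadence is irregular; onset detection requires a fixed cadence.")
  }
}

# first index where `flag` holds for `persistence` consecutive frames
# (truncated at the end of the record: a feature appearing in the final
# frame(s) must persist through the remaining frames)
first_persistent <- function(flag, persistence) {
  n <- length(flag)
  for (i in seq_len(n)) {
    j <- min(n, i + persistence - 1)
    if (j - i + 1 >= persistence && all(flag[i:j])) return(i)
  }
  NA_integer_
}

#' Detect radicle emergence in a sequence of central averaged A-scans
#'
#' The radicle announces itself as a newly emerged subsurface peak in the
#' central averaged depth profile: deeper than the surface peak, with an
#' amplitude that does not exceed it. The onset is the earliest frame where
#' the subsurface peak count rises above the first frame's baseline and the
#' new peak persists for at least `persistence` consecutive frames.
#'
#' @param ascans List of central averaged [ascan()] objects, one per frame,
#'   at a fixed cadence.
#' @param times_h Frame acquisition times (hours), equally spaced.
#' @param persistence Number of consecutive frames the new peak must persist.
#' @param min_prominence_db Peak prominence threshold (dB).
#' @return A list `list(onset_h, frame_index, evidence)`; `onset_h` is `NA`
#'   when no persistent new peak appears.
#' @export
detect_radicle_emergence <- function(ascans, times_h, persistence = 2,
                                     min_prominence_db = 6) {
  stopifnot(length(ascans) == length(times_h))
  check_cadence(times_h)
  counts <- vapply(ascans, count_subsurface_peaks, integer(1),
                   min_prominence_db = min_prominence_db)
  baseline <- counts[1]
  flag <- counts > baseline
  idx <- first_persistent(flag, persistence)
  list(
    onset_h = if (is.na(idx)) NA_real_ else times_h[idx],
    frame_index = idx,
    evidence = tibble::tibble(frame = seq_along(times_h), time_h = times_h,
                              subsurface_peaks = counts)
  )
}

#' Detect the cotyledon-layer indicator on the flank A-scans
#'
#' The cotyledon layers appear as new subsurface peaks on *both* flank
#' positions (lateral fractions 0.25 and 0.75 of the seed span). The onset
#' is the earliest frame where both flanks show a persistent new subsurface
#' peak relative to their first-frame baselines. With only one flank
#' available the detector degrades to a single-flank rule and records a
#' warning in the evidence.
#'
#' @param flank1,flank2 Lists of averaged [ascan()] objects for the two
#'   flank positions (`flank2` may be `NULL`).
#' @param times_h Frame times (hours), fixed cadence.
#' @inheritParams detect_radicle_emergence
#' @return `list(onset_h, frame_index, evidence, warnings)`.
#' @export
detect_cotyledon_layer <- function(flank1, flank2, times_h, persistence = 2,
                                   min_prominence_db = 6) {
  check_cadence(times_h)
  warnings <- character(0)
  c1 <- vapply(flank1, count_subsurface_peaks, integer(1),
               min_prominence_db = min_prominence_db)
  f1 <- c1 > c1[1]
  if (is.null(flank2)) {
    warnings <- "Only one flank position available; using single-flank cotyledon rule."
    warn(warnings)
    flag <- f1
    counts <- tibble::tibble(frame = seq_along(times_h), time_h = times_h,
                             flank1 = c1, flank2 = NA_integer_)
  } else {
    stopifnot(length(flank2) == length(times_h))
    c2 <- vapply(flank2, count_subsurface_peaks, integer(1),
                 min_prominence_db = min_prominence_db)
    flag <- f1 & (c2 > c2[1])
    counts <- tibble::tibble(frame = seq_along(times_h), time_h = times_h,
                             flank1 = c1, flank2 = c2)
  }
  idx <- first_persistent(flag, persistence)
  list(
    onset_h = if (is.na(idx)) NA_real_ else times_h[idx],
    frame_index = idx, evidence = counts, warnings = warnings
  )
}

#' Detect seed-coat cracking from per-frame surface picks
#'
#' The crack manifests as a discontinuity of the picked surface boundary:
#' either a run of at least 3 consecutive pick positions with no detectable
#' surface, or a depth jump between adjacent positions strictly exceeding
#' 5 axial pixels. The onset is the earliest frame where either criterion
#' holds persistently.
#'
#' @param surface_picks List (one element per frame) of tibbles with columns
#'   `x_mm`, `z_um` for the picked surface points (`NA` depth = no surface).
#' @param times_h Frame times (hours).
#' @param axial_pixel_um Axial pixel size (optical um).
#' @param persistence Consecutive frames required.
#' @param jump_px Depth-jump threshold in axial pixels (strict inequality).
#' @param gap_positions Missing-surface run length that counts as a crack.
#' @return `list(onset_h, frame_index, evidence)`.
#' @export
detect_coat_crack <- function(surface_picks, times_h, axial_pixel_um,
                              persistence = 2, jump_px = 5,
                              gap_positions = 3) {
  stopifnot(length(surface_picks) == length(times_h))
  cracked <- vapply(surface_picks, function(p) {
    z <- p$z_um[order(p$x_mm)]
    miss <- longest_run(is.na(z))
    if (miss$length >= gap_positions) return(TRUE)
    zz <- z[!is.na(z)]
    if (length(zz) >= 2 && max(abs(diff(zz))) > jump_px * axial_pixel_um) {
      return(TRUE)
    }
    FALSE
  }, logical(1))
  idx <- first_persistent(cracked, persistence)
  list(
    onset_h = if (is.na(idx)) NA_real_ else times_h[idx],
    frame_index = idx,
    evidence = tibble::tibble(frame = seq_along(times_h), time_h = times_h,
                              cracked = cracked)
  )
}

#' Assemble an indicator timeline
#'
#' @param wrinkle_h,cotyledon_h,radicle_h,crack_h Onset times in hours
#'   (`NA` = indicator never fired).
#' @param seed_id Seed label.
#' @param evidence Optional named list of supporting per-frame evidence.
#' @return Object of class `indicator_timeline`.
#' @export
indicator_timeline <- function(wrinkle_h = NA_real_, cotyledon_h = NA_real_,
                               radicle_h = NA_real_, crack_h = NA_real_,
                               seed_id = "seed1", evidence = list()) {
  if (!is.na(radicle_h) && !is.na(crack_h) && crack_h < radicle_h) {
    abort("Inconsistent timeline: crack onset precedes radicle onset.")
  }
  structure(
    list(seed_id = seed_id, wrinkle_h = wrinkle_h, cotyledon_h = cotyledon_h,
         radicle_h = radicle_h, crack_h = crack_h, evidence = evidence),
    class = "indicator_timeline"
  )
}

#' @export
print.indicator_timeline <- function(x, ...) {
  cat(sprintf("<indicator_timeline> %s: wrinkle %s | cotyledon %s | radicle %s | crack %s (h)\n",
              x$seed_id, format(x$wrinkle_h), format(x$cotyledon_h),
              format(round(x$radicle_h, 3)), format(x$crack_h)))
  invisible(x)
}

#' Tidy an indicator timeline
#'
#' @param x An `indicator_timeline`.
#' @param ... Unused.
#' @return Tibble with columns `seed_id`, `indicator`, `onset_h`.
#' @export
tidy.indicator_timeline <- function(x, ...) {
  tibble::tibble(
    seed_id = x$seed_id,
    indicator = c("wrinkle", "cotyledon", "radicle", "crack"),
    onset_h = c(x$wrinkle_h, x$cotyledon_h, x$radicle_h, x$crack_h)
  )
}

#' Segment the record into germination phases
#'
#' Phase I (imbibition) runs from the start of the record to the radicle
#' onset, phase II (lag) from the radicle onset to the crack onset, and
#' phase III (completion) from the crack onset to the end. Missing onsets
#' collapse the later phases to empty intervals.
#'
#' @param timeline An [indicator_timeline()].
#' @param span_h Record span `c(start, end)` in hours (or a single end time).
#' @return Tibble with columns `phase`, `start_h`, `end_h` (empty phases
#'   have `start_h == end_h`).
#' @export
classify_phases <- function(timeline, span_h) {
  stopifnot(inherits(timeline, "indicator_timeline"))
  if (length(span_h) == 1) span_h <- c(0, span_h)
  if (diff(span_h) <= 0) abort("Record span must be positive.")
  r <- timeline$radicle_h; k <- timeline$crack_h
  if (!is.na(r) && !is.na(k) && k < r) {
    abort("Inconsistent timeline: crack onset precedes radicle onset.")
  }
  b1 <- if (is.na(r)) span_h[2] else min(max(r, span_h[1]), span_h[2])
  b2 <- if (is.na(k)) span_h[2] else min(max(k, b1), span_h[2])
  if (is.na(r)) b2 <- span_h[2] # no radicle: everything stays phase I
  tibble::tibble(
    phase = c("I", "II", "III"),
    start_h = c(span_h[1], b1, b2),
    end_h = c(b1, b2, span_h[2])
  )
}
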