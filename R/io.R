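# File IO: 16-bit TIFF for B-scans (with a text sidecar for the axis
# metadata), PNG for camera frames, CSV for tabular outputs.

#' Write / read a B-scan as 16-bit TIFF
#'
#' The dB image is mapped linearly from `[-80, 0]` dB to the 16-bit range;
#' axis metadata (extents, timestamp) goes to a `.json` sidecar next to the
#' TIFF so the image round-trips.
#'
#' @param bscan A [bscan()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_bscan_tiff <- function(bscan, path) {
  stopifnot(inherits(bscan, "bscan"))
  img01 <- pmin(pmax((bscan$image - DB_FLOOR) / (-DB_FLOOR), 0), 1)
  tiff::writeTIFF(img01, path, bits.per.sample = 16)
  jsonlite::write_json(
    list(lateral_extent_mm = bscan$lateral_extent_mm,
         depth_extent_mm = bscan$depth_extent_mm,
         timestamp_h = bscan$timestamp_h,
         db_floor = DB_FLOOR),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_bscan_tiff
#' @export
read_bscan_tiff <- function(path) {
  img01 <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  bscan(img01 * (-meta$db_floor) + meta$db_floor,
        lateral_extent_mm = meta$lateral_extent_mm,
        depth_extent_mm = meta$depth_extent_mm,
        timestamp_h = meta$timestamp_h)
}

#' Write / read a camera frame as PNG
#'
#' @param image A [camera_image()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_camera_png <- function(image, path) {
  stopifnot(inherits(image, "camera_image"))
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' @rdname write_camera_png
#' @param pixel_scale_mm Pixel scale to attach on read (mm/px).
#' @param timestamp_h Timestamp to attach on read (hours).
#' @export
read_camera_png <- function(path, pixel_scale_mm = 11 / 644,
                            timestamp_h = NA_real_) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), dim = c(dim(px), 3))
  camera_image(round(px[, , 1:3] * 255), pixel_scale_mm = pixel_scale_mm,
               timestamp_h = timestamp_h)
}

#' Write / read boundary control points as CSV
#'
#' Uses the column layout `role,x_mm,z_um`, where role is `"upper"`
#' (surface) or `"lower"` (coat interface), so manually marked point files
#' can be exchanged with the automated picker.
#'
#' @param points Tibble with columns `role`, `x_mm`, `z_um`.
#' @param path CSV path.
#' @return `path` (write) or the points tibble (read).
#' @export
write_control_points <- function(points, path) {
  stopifnot(all(c("role", "x_mm", "z_um") %in% names(points)))
  write.csv(points[, c("role", "x_mm", "z_um")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_control_points
#' @export
read_control_points <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
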