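# Camera morphometry: RGB-threshold segmentation of the seed disc, a full
# Canny edge chain, boundary overlay, equivalent-circle diameter and the
# surface-wrinkle roughness index.

#' Segment the seed in a camera photograph
#'
#' Per-channel in-range binarization (inclusive bounds, default 62-255 /
#' 45-255 / 30-255 for R/G/B) combined with a logical AND, followed by
#' connected-component labelling; the largest component whose centroid lies
#' above the configured water line is kept, which excludes the
#' water-surface shadow band.
#'
#' @param image A [camera_image()].
#' @param thresholds List/matrix of three `(low, high)` pairs for R, G, B.
#' @param water_line Water line as a fraction of image height; components
#'   with centroid below it are discarded.
#' @return Logical mask matrix (`TRUE` = seed), with the image's pixel
#'   scale attached as attribute `pixel_scale_mm`.
#' @export
segment_seed <- function(image,
                         thresholds = list(c(62, 255), c(45, 255), c(30, 255)),
                         water_line = 0.7) {
  stopifnot(inherits(image, "camera_image"))
  px <- image$pixels
  m <- px[, , 1] >= thresholds[[1]][1] & px[, , 1] <= thresholds[[1]][2] &
    px[, , 2] >= thresholds[[2]][1] & px[, , 2] <= thresholds[[2]][2] &
    px[, , 3] >= thresholds[[3]][1] & px[, , 3] <= thresholds[[3]][2]
  if (!any(m)) abort("No seed found: the threshold mask is empty.")
  lab <- EBImage::imageData(EBImage::bwlabel(m * 1))
  n <- max(lab)
  if (n == 0) abort("No seed found: the threshold mask is empty.")
  h <- nrow(m)
  best <- 0L; best_area <- -1
  for (i in seq_len(n)) {
    idx <- which(lab == i, arr.ind = TRUE)
    if (mean(idx[, 1]) <= water_line * h && nrow(idx) > best_area) {
      best <- i; best_area <- nrow(idx)
    }
  }
  if (best == 0L) abort("No seed found above the water line.")
  out <- lab == best
  attr(out, "pixel_scale_mm") <- image$pixel_scale_mm
  out
}

# separable Gaussian smoothing with reflected borders
gaussian_smooth <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(m) {
    n <- nrow(m)
    pad <- rbind(m[rev(seq_len(r)), , drop = FALSE], m,
                 m[rev(n - seq_len(r) + 1), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * pad[(i - 1) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(img))))
}

#' Canny edge detection
#'
#' Full classical chain: Gaussian smoothing, two orthogonal (Sobel)
#' gradient operators, gradient magnitude and direction, non-maximum
#' suppression along the quantized gradient direction, and double-threshold
#' hysteresis (weak edges are kept only when connected to a strong edge).
#' Returns one-pixel-wide edges.
#'
#' @param image Numeric matrix (grayscale) or logical mask.
#' @param sigma Gaussian smoothing standard deviation in pixels.
#' @param low,high Hysteresis thresholds as fractions of the maximum
#'   gradient magnitude.
#' @return Logical edge-map matrix.
#' @export
canny_boundary <- function(image, sigma = 1.4, low = 0.1, high = 0.2) {
  img <- if (is.logical(image)) image * 1 else image
  stopifnot(is.matrix(img))
  sm <- gaussian_smooth(img, sigma)
  h <- nrow(sm); w <- ncol(sm)
  pad <- function(m) {
    m2 <- matrix(0, h + 2, w + 2)
    m2[2:(h + 1), 2:(w + 1)] <- m
    m2[1, ] <- m2[2, ]; m2[h + 2, ] <- m2[h + 1, ]
    m2[, 1] <- m2[, 2]; m2[, w + 2] <- m2[, w + 1]
    m2
  }
  p <- pad(sm)
  sh <- function(di, dj) p[(2 + di):(h + 1 + di), (2 + dj):(w + 1 + dj)]
  # Sobel operators (rows = y, cols = x)
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
    (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
    (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) == 0) return(matrix(FALSE, h, w))
  # non-maximum suppression along the true gradient direction, with
  # bilinear interpolation of the two neighbour magnitudes
  pm <- pad(mag)
  shm <- function(di, dj) pm[(2 + di):(h + 1 + di), (2 + dj):(w + 1 + dj)]
  ax <- abs(gx); ay <- abs(gy)
  cond <- ax >= ay # nearer the horizontal-gradient octants
  t <- ifelse(cond, ifelse(ax > 0, ay / pmax(ax, 1e-12), 0),
              ax / pmax(ay, 1e-12))
  neighbour_along <- function(sgn) {
    sx <- sgn * sign(gx); sy <- sgn * sign(gy)
    near <- matrix(0, h, w); diag_ <- matrix(0, h, w)
    for (s in c(-1, 0, 1)) {
      sel <- cond & sx == s
      if (any(sel)) near[sel] <- shm(0, s)[sel]
      sel <- !cond & sy == s
      if (any(sel)) near[sel] <- shm(s, 0)[sel]
    }
    for (sr in c(-1, 0, 1)) for (sc in c(-1, 0, 1)) {
      sel <- sy == sr & sx == sc
      if (any(sel)) diag_[sel] <- shm(sr, sc)[sel]
    }
    (1 - t) * near + t * diag_
  }
  n1 <- neighbour_along(1)
  n2 <- neighbour_along(-1)
  keep <- mag >= n1 & mag > n2 & mag > 0
  strong <- keep & mag >= high * max(mag)
  weak <- keep & mag >= low * max(mag)
  # hysteresis: keep weak components (8-connected) touching a strong pixel
  lab <- label8(weak)
  ids <- unique(lab[strong & lab > 0])
  edges <- matrix(lab %in% ids, h, w) & weak
  prune_corners(edges)
}

# remove redundant staircase corners: edge pixels with exactly two edge
# neighbours that are 8-adjacent to each other (removal keeps the chain
# connected and one pixel wide)
prune_corners <- function(edges) {
  idx <- which(edges, arr.ind = TRUE)
  h <- nrow(edges); w <- ncol(edges)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]; j <- idx[k, 2]
      if (!edges[i, j]) next
      i0 <- max(1, i - 1); i1 <- min(h, i + 1)
      j0 <- max(1, j - 1); j1 <- min(w, j + 1)
      nb <- which(edges[i0:i1, j0:j1], arr.ind = TRUE)
      nb <- nb[!(nb[, 1] == i - i0 + 1 & nb[, 2] == j - j0 + 1), , drop = FALSE]
      if (nrow(nb) == 2 &&
          max(abs(nb[1, ] - nb[2, ])) <= 1) {
        edges[i, j] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
    idx <- which(edges, arr.ind = TRUE)
  }
  edges
}

# 8-connected component labelling built on EBImage's 4-connected bwlabel:
# diagonal-touching 4-components are merged by union-find
label8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask * 1))
  n <- max(lab)
  if (n <= 1) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  link <- function(a_mat, b_mat) {
    sel <- a_mat > 0 & b_mat > 0 & a_mat != b_mat
    if (any(sel)) {
      pairs <- unique(cbind(a_mat[sel], b_mat[sel]))
      for (k in seq_len(nrow(pairs))) union_(pairs[k, 1], pairs[k, 2])
    }
  }
  link(lab[-h, -w], lab[-1, -1]) # down-right diagonal
  link(lab[-h, -1], lab[-1, -w]) # down-left diagonal
  roots <- vapply(seq_len(n), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

#' Overlay an edge map on a camera image
#'
#' Recolours the edge pixels on a copy of the image; the input is untouched.
#'
#' @param image A [camera_image()].
#' @param edges Logical edge map with matching height/width.
#' @param color Length-3 RGB (0-255) overlay colour.
#' @return A new [camera_image()] with the boundary marked.
#' @export
overlay_boundary <- function(image, edges, color = c(0, 80, 255)) {
  stopifnot(inherits(image, "camera_image"),
            all(dim(edges) == dim(image$pixels)[1:2]))
  px <- image$pixels
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[edges] <- color[ch]
    px[, , ch] <- plane
  }
  camera_image(px, pixel_scale_mm = image$pixel_scale_mm,
               timestamp_h = image$timestamp_h)
}

# boundary pixels of a mask: mask pixels with at least one 4-neighbour
# outside the mask (or on the image border)
mask_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  inner <- pad[2:(h + 1), 2:(w + 1)] &
    pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  mask & !inner
}

#' Seed outline from a segmentation mask
#'
#' @param mask Logical mask from [segment_seed()].
#' @param pixel_scale_mm Pixel scale (mm/px); defaults to the attribute
#'   attached by [segment_seed()].
#' @return Object of class `seed_outline`: boundary pixel coordinates, the
#'   mask, area and equivalent-circle diameter.
#' @export
seed_outline <- function(mask, pixel_scale_mm = attr(mask, "pixel_scale_mm")) {
  stopifnot(is.matrix(mask))
  if (is.null(pixel_scale_mm)) pixel_scale_mm <- 11 / 644
  b <- which(mask_boundary(mask), arr.ind = TRUE)
  if (nrow(b) == 0) abort("Empty mask: no outline.")
  area_px <- sum(mask)
  structure(
    list(boundary = tibble::tibble(row = b[, 1], col = b[, 2]),
         mask = mask, area_px = area_px,
         pixel_scale_mm = pixel_scale_mm,
         equivalent_diameter_mm = 2 * sqrt(area_px / pi) * pixel_scale_mm),
    class = "seed_outline"
  )
}

#' Equivalent-circle diameter of a seed outline
#'
#' `2 sqrt(area / pi)` in pixels, scaled to millimetres. A maximum-Feret
#' diameter is available as an alternative definition.
#'
#' @param outline A [seed_outline()] (or a logical mask).
#' @param pixel_scale_mm Pixel scale; defaults to the outline's.
#' @param method `"equivalent"` (default) or `"feret"`.
#' @return Diameter in millimetres.
#' @export
measure_diameter <- function(outline, pixel_scale_mm = NULL,
                             method = c("equivalent", "feret")) {
  method <- match.arg(method)
  if (is.matrix(outline)) outline <- seed_outline(outline, pixel_scale_mm %||% attr(outline, "pixel_scale_mm"))
  scale <- pixel_scale_mm %||% outline$pixel_scale_mm
  if (method == "equivalent") {
    return(2 * sqrt(outline$area_px / pi) * scale)
  }
  b <- outline$boundary
  hull <- grDevices::chull(b$col, b$row)
  pts <- b[hull, ]
  d2 <- 0
  for (i in seq_len(nrow(pts))) {
    d2 <- max(d2, (pts$col[i] - pts$col)^2 + (pts$row[i] - pts$row)^2)
  }
  sqrt(d2) * scale
}

# least-squares (Kasa) circle fit through boundary pixels
fit_circle <- function(rows, cols) {
  x <- cols; y <- rows
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.solve(A, b)
  r <- sqrt(sol[3] + sol[1]^2 + sol[2]^2)
  list(cx = sol[1], cy = sol[2], r = r)
}

# boundary roughness: sd of radial residuals from the best-fit circle,
# normalized by the fitted radius
outline_roughness <- function(outline) {
  b <- outline$boundary
  if (nrow(b) < 8) return(NA_real_)
  f <- fit_circle(b$row, b$col)
  rad <- sqrt((b$col - f$cx)^2 + (b$row - f$cy)^2)
  sd(rad - f$r) / f$r
}

#' Boundary-roughness series and surface-wrinkle onset
#'
#' For each frame's outline the roughness is the standard deviation of the
#' radial residuals from the best-fit circle, normalized by the radius.
#' The wrinkle onset is the first frame, persisting for `persistence`
#' frames, whose roughness strictly exceeds the baseline mean plus
#' 3 baseline standard deviations (baseline = first `baseline_frames`
#' frames). Degenerate outlines are skipped with a warning.
#'
#' @param outlines List of [seed_outline()] objects, one per frame.
#' @param times_h Frame times in hours.
#' @param baseline_frames Frames defining the quiescent baseline.
#' @param persistence Consecutive frames required above threshold.
#' @return `list(roughness, onset_h, frame_index, threshold)` where
#'   `roughness` is a tibble `time_h`, `roughness`.
#' @export
wrinkle_index <- function(outlines, times_h, baseline_frames = 5,
                          persistence = 2) {
  stopifnot(length(outlines) == length(times_h), length(outlines) >= 2)
  rough <- vapply(outlines, function(o) {
    r <- outline_roughness(o)
    r
  }, numeric(1))
  if (any(is.na(rough))) warn("Degenerate outlines skipped in roughness series.")
  nb <- min(baseline_frames, length(rough))
  base <- rough[seq_len(nb)]
  thr <- mean(base, na.rm = TRUE) + 3 * sd(base, na.rm = TRUE)
  if (!is.finite(thr)) thr <- Inf
  flag <- !is.na(rough) & rough > thr
  flag[seq_len(nb)] <- FALSE # baseline frames define quiescence
  idx <- first_persistent(flag, persistence)
  list(
    roughness = tibble::tibble(time_h = times_h, roughness = rough),
    onset_h = if (is.na(idx)) NA_real_ else times_h[idx],
    frame_index = idx,
    threshold = thr
  )
}
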