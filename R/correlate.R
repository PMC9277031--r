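# Correlation of image-derived measures against the gravimetric gold
# standard: series alignment onto a common (coarser) time grid and the
# plain product-moment correlation coefficient,
#   r = sum((x - xbar)(y - ybar)) / sqrt(sum((x - xbar)^2) sum((y - ybar)^2)).

#' Align two time series onto a common grid
#'
#' Both series are restricted to their overlapping time span and linearly
#' interpolated onto the time stamps of the *coarser* series (the one with
#' the larger median sampling interval) inside the overlap, so that the
#' paired record is never denser than the slower measurement.
#'
#' @param x,y Data frames with a time column and a value column (the first
#'   two numeric columns are used, in that order).
#' @param x_label,y_label Labels carried into the result.
#' @return Tibble of class `paired_series` with columns `time_h`, `x`, `y`
#'   and attributes `x_label`, `y_label`, `alignment`.
#' @export
align_series <- function(x, y, x_label = "x", y_label = "y") {
  gx <- extract_series(x)
  gy <- extract_series(y)
  lo <- max(min(gx$time), min(gy$time))
  hi <- min(max(gx$time), max(gy$time))
  if (lo >= hi) abort("The two series have no overlapping time span.")
  coarser <- if (stats::median(diff(gx$time)) >= stats::median(diff(gy$time))) gx else gy
  grid <- coarser$time[coarser$time >= lo & coarser$time <= hi]
  if (length(grid) < 3) abort("Fewer than 3 common time points after alignment.")
  xi <- approx(gx$time, gx$value, xout = grid)$y
  yi <- approx(gy$time, gy$value, xout = grid)$y
  out <- tibble::tibble(time_h = grid, x = xi, y = yi)
  attr(out, "x_label") <- x_label
  attr(out, "y_label") <- y_label
  attr(out, "alignment") <- "linear interpolation onto the coarser grid"
  class(out) <- c("paired_series", class(out))
  out
}

extract_series <- function(d) {
  d <- as.data.frame(d)
  num <- d[vapply(d, is.numeric, logical(1))]
  if (ncol(num) < 2) abort("Series needs a numeric time column and a value column.")
  if (nrow(num) < 3) abort("Series needs at least 3 samples.")
  s <- data.frame(time = num[[1]], value = num[[2]])
  s <- s[order(s$time), ]
  if (any(duplicated(s$time))) abort("Series has duplicated time stamps.")
  s
}

#' Product-moment correlation of a paired series
#'
#' Computes `r = sum((x_i - xbar)(y_i - ybar)) / sqrt(sum((x_i - xbar)^2)
#' sum((y_i - ybar)^2))` directly from its definition.
#'
#' @param paired A [align_series()] result, or any data frame with numeric
#'   columns `x` and `y`.
#' @return One-row tibble of class `correlation_result`: `pair`, `x_label`,
#'   `y_label`, `n`, `r`.
#' @export
pearson_r <- function(paired) {
  x <- paired$x; y <- paired$y
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort("At least 3 paired samples are required.")
  dx <- x - mean(x); dy <- y - mean(y)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) abort("Correlation undefined: at least one series is constant.")
  xl <- attr(paired, "x_label") %||% "x"
  yl <- attr(paired, "y_label") %||% "y"
  out <- tibble::tibble(
    pair = paste(xl, "vs", yl), x_label = xl, y_label = yl,
    n = n, r = sum(dx * dy) / den
  )
  class(out) <- c("correlation_result", class(out))
  out
}

#' Validate OCT- and camera-derived series against seed weight
#'
#' Aligns the coat-thickness and diameter series to the gravimetric series
#' (the gold standard), computes the product-moment correlation for each
#' pair, and flags whether `|r| > 0.95`.
#'
#' @param thickness Data frame `time_h`, thickness value (um).
#' @param diameter Data frame `time_h`, diameter value (mm).
#' @param weight Data frame `time_h`, weight value (g); the reference series.
#' @param threshold Absolute-correlation pass threshold (default 0.95).
#' @return Tibble with one row per pair: `pair`, `x_label`, `y_label`, `n`,
#'   `r`, `passes_0.95`.
#' @export
validate_against_weight <- function(thickness, diameter, weight,
                                    threshold = 0.95) {
  rows <- list()
  if (!is.null(thickness)) {
    p <- align_series(weight, thickness, "weight", "thickness")
    rows <- c(rows, list(pearson_r(p)))
  }
  if (!is.null(diameter)) {
    p <- align_series(weight, diameter, "weight", "diameter")
    rows <- c(rows, list(pearson_r(p)))
  }
  if (length(rows) == 0) abort("No series to validate.")
  out <- dplyr::bind_rows(rows)
  # a pair passes when it tracks the gold standard: strong *positive*
  # correlation (an anti-correlated series does not validate the method)
  out$passes_0.95 <- out$r > threshold
  out
}

#' Glance at a correlation result
#'
#' @param x A `correlation_result`.
#' @param ... Unused.
#' @return One-row tibble with `r`, `n` and `abs_r`.
#' @export
glance.correlation_result <- function(x, ...) {
  tibble::tibble(r = x$r, n = x$n, abs_r = abs(x$r))
}
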