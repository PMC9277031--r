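# Shared numeric helpers: dB conversions, deterministic sub-seeds, peak finding.

DB_FLOOR <- -80 # log floor relative to frame maximum, in dB

#' Convert linear intensity to a floored decibel scale
#'
#' Intensities are log-compressed as `10 * log10(I / ref)` and floored at
#' -80 dB relative to the reference (the maximum by default), so that empty
#' regions do not produce `-Inf`.
#'
#' @param intensity Numeric vector or matrix of non-negative linear intensities.
#' @param ref Reference intensity mapped to 0 dB; defaults to `max(intensity)`.
#' @return Same shape as `intensity`, in dB.
#' @export
intensity_to_db <- function(intensity, ref = max(intensity)) {
  if (!is.numeric(intensity)) abort("`intensity` must be numeric.")
  if (!is.finite(ref) || ref <= 0) {
    return(intensity * 0 + DB_FLOOR)
  }
  db <- 10 * log10(pmax(intensity / ref, 10^(DB_FLOOR / 10)))
  db
}

#' @rdname intensity_to_db
#' @param db Values in dB (0 dB corresponds to `ref`).
#' @export
db_to_intensity <- function(db, ref = 1) {
  ref * 10^(db / 10)
}

# Deterministic 31-bit sub-seed derived from a base seed and a stream index,
# so that every frame / seed / target gets an independent reproducible stream.
derive_seed <- function(seed, index) {
  a <- (as.double(seed) %% 2147483647)
  x <- (a * 48271 + as.double(index) * 69621 + 11) %% 2147483647
  as.integer(x)
}

# Local maxima of `y` with topographic prominence and minimum separation
# (in samples). Returns a data frame of index, height, prominence, sorted by
# index. `min_height` pre-filters candidates before the prominence walk
# (cheap rejection for profiles dominated by a noise floor).
find_prominent_peaks <- function(y, min_prominence = 0, min_separation = 1,
                                 min_height = -Inf) {
  n <- length(y)
  if (n < 3 || !all(is.finite(y))) {
    return(data.frame(index = integer(), height = numeric(), prominence = numeric()))
  }
  cand <- which_local_maxima(y)
  cand <- cand[y[cand] >= min_height]
  if (length(cand) == 0) {
    return(data.frame(index = integer(), height = numeric(), prominence = numeric()))
  }
  prom <- vapply(cand, function(i) peak_prominence(y, i), numeric(1))
  keep <- prom >= min_prominence
  cand <- cand[keep]
  prom <- prom[keep]
  if (length(cand) > 1 && min_separation > 1) {
    ord <- order(y[cand], decreasing = TRUE)
    sel <- logical(length(cand))
    taken <- integer(0)
    for (j in ord) {
      if (all(abs(cand[j] - taken) >= min_separation)) {
        sel[j] <- TRUE
        taken <- c(taken, cand[j])
      }
    }
    cand <- cand[sel]
    prom <- prom[sel]
  }
  o <- order(cand)
  data.frame(index = cand[o], height = y[cand][o], prominence = prom[o])
}

# indices of local maxima (vectorized; the left edge of an exact-tie
# plateau is taken, which sub-sample refinement then corrects)
which_local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer())
  mid <- 2:(n - 1)
  mid[y[mid] > y[mid - 1] & y[mid] >= y[mid + 1]]
}

# topographic prominence of the peak at index i: height above the higher of
# the two key saddles (lowest point between the peak and the nearest
# at-least-as-high sample on each side, or the record minimum on open
# sides). Walks outward sample by sample; walks are short for minor peaks.
peak_prominence <- function(y, i) {
  h <- y[i]
  n <- length(y)
  kl <- h
  j <- i - 1
  while (j >= 1) {
    if (y[j] > h) break
    if (y[j] < kl) kl <- y[j]
    j <- j - 1
  }
  kr <- h
  j <- i + 1
  while (j <= n) {
    if (y[j] > h) break
    if (y[j] < kr) kr <- y[j]
    j <- j + 1
  }
  h - max(kl, kr)
}

# quadratic (three-point) sub-sample refinement of a peak position
refine_peak_subpixel <- function(y, i) {
  n <- length(y)
  if (i <= 1 || i >= n) return(0)
  a <- y[i - 1]; b <- y[i]; c <- y[i + 1]
  den <- a - 2 * b + c
  if (den >= 0) return(0) # not locally concave
  delta <- 0.5 * (a - c) / den
  max(min(delta, 0.5), -0.5)
}

# longest TRUE run; returns list(start, length) or length 0
longest_run <- function(flag) {
  r <- rle(flag)
  if (!any(r$values)) return(list(start = NA_integer_, length = 0L))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  j <- ok[which.max(r$lengths[ok])]
  list(start = starts[j], length = r$lengths[j])
}
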