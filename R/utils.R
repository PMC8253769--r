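# Internal numerical helpers shared across modules.

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot z-score a constant signal", call. = FALSE)
  }
  (x - mean(x)) / s
}

# Prominence of each peak: height above the higher of the two base minima,
# where each base spans from the peak to the nearest strictly higher sample
# (or the signal edge).
peak_prominence <- function(x, peaks) {
  n <- length(x)
  vapply(peaks, function(p) {
    h <- x[p]
    i <- p - 1L
    lmin <- h
    while (i >= 1L && x[i] <= h) {
      if (x[i] < lmin) lmin <- x[i]
      i <- i - 1L
    }
    j <- p + 1L
    rmin <- h
    while (j <= n && x[j] <= h) {
      if (x[j] < rmin) rmin <- x[j]
      j <- j + 1L
    }
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Find local maxima in a 1-D signal
#'
#' Simple peak picker with height, minimum-distance and prominence filters,
#' in the spirit of `scipy.signal.find_peaks`. Used for reference-pulse
#' detection, glottal-cycle detection and audio cycle marking.
#'
#' @param x numeric vector.
#' @param min_height minimum peak value.
#' @param min_distance minimum index spacing between kept peaks; when two
#'   candidates are closer, the higher one wins.
#' @param min_prominence minimum topographic prominence.
#' @return integer vector of peak indices, increasing.
#' @export
find_peaks <- function(x, min_height = -Inf, min_distance = 1,
                       min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (length(cand) && min_prominence > 0) {
    # prominence can never exceed height above the global minimum; filter
    # cheaply before the O(n) per-peak base scan
    cand <- cand[x[cand] - min(x) >= min_prominence]
    if (length(cand)) {
      cand <- cand[peak_prominence(x, cand) >= min_prominence]
    }
  }
  if (length(cand) > 1L && min_distance > 1) {
    if (any(diff(cand) < min_distance)) {
      ord <- cand[order(x[cand], decreasing = TRUE)]
      kept <- integer(0)
      for (p in ord) {
        if (!length(kept) || all(abs(kept - p) >= min_distance)) {
          kept <- c(kept, p)
        }
      }
      cand <- sort(kept)
    }
  }
  cand
}

gaussian_kernel1d <- function(sigma, radius = ceiling(3 * sigma)) {
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable 2-D filtering with replicate (edge-clamp) padding.
filter2_sep <- function(img, k) {
  r <- (length(k) - 1L) %/% 2L
  nr <- nrow(img)
  nc <- ncol(img)
  pad <- img[c(rep(1L, r), seq_len(nr), rep(nr, r)), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_along(k)) {
    out <- out + k[i] * pad[i:(i + nr - 1L), , drop = FALSE]
  }
  pad <- out[, c(rep(1L, r), seq_len(nc), rep(nc, r)), drop = FALSE]
  out2 <- matrix(0, nr, nc)
  for (i in seq_along(k)) {
    out2 <- out2 + k[i] * pad[, i:(i + nc - 1L), drop = FALSE]
  }
  out2
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  filter2_sep(img, gaussian_kernel1d(sigma))
}

# 0-based x (column) / y (row) coordinates of foreground pixels.
mask_coords <- function(mask) {
  idx <- which(mask != 0)
  nr <- nrow(mask)
  list(x = ((idx - 1L) %/% nr), y = ((idx - 1L) %% nr))
}
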