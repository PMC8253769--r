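# Glottal area waveform (GAW), cycle detection and phase decomposition.
#
# The GAW is the per-frame count of segmented glottis pixels — the primary
# one-dimensional vibration signal. Oscillation cycles are detected by peak
# finding on the GAW; each cycle spans minimum-to-minimum around one maximum
# and is decomposed into opening, closing and closed phases relative to a
# closure threshold, the substrate of all phase-based clinical quotients.

#' Glottal area waveform
#'
#' @param area numeric vector of per-frame glottal areas (pixels or
#'   normalized units), non-negative.
#' @param frame_rate frames per second.
#' @return object of class `gaw`.
#' @export
gaw <- function(area, frame_rate) {
  area <- as.numeric(area)
  if (any(area < 0)) stop("glottal area must be non-negative", call. = FALSE)
  if (!is.numeric(frame_rate) || frame_rate <= 0) {
    stop("frame_rate must be positive", call. = FALSE)
  }
  structure(list(area = area, frame_rate = frame_rate), class = "gaw")
}

#' @export
print.gaw <- function(x, ...) {
  cat(sprintf("GAW: %d frames @ %g fps (%.1f ms), area range [%g, %g]\n",
              length(x$area), x$frame_rate,
              1000 * length(x$area) / x$frame_rate,
              min(x$area), max(x$area)))
  invisible(x)
}

#' @export
plot.gaw <- function(x, ...) {
  t_ms <- (seq_along(x$area) - 1) / x$frame_rate * 1000
  graphics::plot(t_ms, x$area, type = "l", xlab = "time [ms]",
                 ylab = "glottal area [px]", ...)
  invisible(x)
}

#' @export
as.data.frame.gaw <- function(x, ...) {
  data.frame(frame = seq_along(x$area) - 1L,
             time_s = (seq_along(x$area) - 1) / x$frame_rate,
             gaw_px = x$area)
}

#' Glottal area waveform from a mask stack
#'
#' @param seg a [segmentation_sequence()].
#' @return a [gaw()] whose element t is the number of glottis pixels in
#'   frame t.
#' @export
gaw_from_masks <- function(seg) {
  d <- dim(seg$masks)
  if (d[3] == 0L) stop("empty mask stack", call. = FALSE)
  area <- colSums(matrix(seg$masks, ncol = d[3]))
  gaw(area, seg$frame_rate)
}

#' Detect oscillation cycles in a GAW
#'
#' Maxima are found with a prominence of at least `min_prominence_frac`
#' times the signal range; cycle boundaries are the minima between
#' consecutive maxima. Partial cycles at the signal edges are discarded,
#' except that a signal endpoint sitting at the interior-minimum level is
#' accepted as a cycle boundary.
#'
#' @param x a [gaw()].
#' @param min_prominence_frac prominence threshold as a fraction of the GAW
#'   range (default 0.1).
#' @return object of class `cycle_set`: a data frame with one row per
#'   complete cycle (`start`, `max_frame`, `end` as 1-based frame indices,
#'   `period_s`, `a_min`, `a_max`, `amplitude`), frame rate in
#'   `attr(, "frame_rate")`.
#' @export
detect_cycles <- function(x, min_prominence_frac = 0.1) {
  a <- x$area
  n <- length(a)
  if (n < 3L) stop("too few cycles: GAW shorter than 3 frames", call. = FALSE)
  rng <- max(a) - min(a)
  if (rng == 0) stop("too few cycles: constant GAW", call. = FALSE)
  pk <- find_peaks(a, min_prominence = min_prominence_frac * rng,
                   min_distance = 3)
  if (length(pk) < 2L) {
    stop("too few cycles: fewer than 2 maxima detected", call. = FALSE)
  }
  k <- length(pk)
  mins <- integer(k - 1L)
  for (j in seq_len(k - 1L)) {
    seg <- a[pk[j]:pk[j + 1L]]
    mins[j] <- pk[j] + which.min(seg) - 1L
  }
  bounds <- mins
  tol <- 0.01 * rng
  # a signal endpoint at the minimum level is accepted as a boundary only
  # when the edge cycle it closes has near-full length; otherwise it is a
  # partial cycle and is discarded
  md <- if (length(mins) > 1L) stats::median(diff(mins))
        else stats::median(diff(pk))
  edge_ok <- function(len) len >= 0.75 * md && len <= 1.25 * md
  if (a[1L] <= min(a[mins]) + tol && pk[1L] > 1L &&
      edge_ok(mins[1L] - 1L)) {
    bounds <- c(1L, bounds)
  }
  if (a[n] <= min(a[mins]) + tol && pk[k] < n &&
      edge_ok(n - mins[length(mins)])) {
    bounds <- c(bounds, n)
  }
  maxima <- pk[pk > bounds[1L] & pk < bounds[length(bounds)]]
  nb <- length(bounds)
  if (nb < 2L || length(maxima) < 1L) {
    stop("too few cycles: no complete cycle between minima", call. = FALSE)
  }
  starts <- bounds[-nb]
  ends <- bounds[-1L]
  keep <- vapply(seq_along(starts), function(i) {
    any(maxima > starts[i] & maxima < ends[i])
  }, logical(1))
  starts <- starts[keep]; ends <- ends[keep]
  max_frame <- vapply(seq_along(starts), function(i) {
    m <- maxima[maxima > starts[i] & maxima < ends[i]]
    m[which.max(a[m])]
  }, integer(1))
  fps <- x$frame_rate
  cyc <- data.frame(
    start = starts, max_frame = max_frame, end = ends,
    period_s = (ends - starts) / fps,
    a_min = vapply(seq_along(starts),
                   function(i) min(a[starts[i]:ends[i]]), numeric(1)),
    a_max = a[max_frame]
  )
  cyc$amplitude <- cyc$a_max - cyc$a_min
  attr(cyc, "frame_rate") <- fps
  attr(cyc, "peak_periods_s") <- diff(pk) / fps
  class(cyc) <- c("cycle_set", "data.frame")
  cyc
}

#' Decompose cycles into opening / closing / closed phases
#'
#' A frame is open when its area exceeds the closure threshold
#' `closure_eps * a_max` of its cycle (a small fraction of the cycle peak
#' area, robust to single-pixel segmentation noise). The opening phase runs
#' from the first open frame to the cycle maximum, the closing phase from
#' the maximum to the last open frame; the closed time is the remainder of
#' the period.
#'
#' @param x a [gaw()].
#' @param cycles a `cycle_set` from [detect_cycles()].
#' @param closure_eps relative closure threshold in \[0, 1) (default 0.02).
#' @return the `cycle_set` with columns `t_opening_s`, `t_closing_s`,
#'   `t_open_s`, `t_closed_s` added.
#' @export
decompose_phases <- function(x, cycles, closure_eps = 0.02) {
  if (!is.numeric(closure_eps) || closure_eps < 0 || closure_eps >= 1) {
    stop("closure_eps must be in [0, 1)", call. = FALSE)
  }
  a <- x$area
  fps <- attr(cycles, "frame_rate")
  n <- nrow(cycles)
  t_opening <- t_closing <- numeric(n)
  for (i in seq_len(n)) {
    s <- cycles$start[i]; e <- cycles$end[i]; m <- cycles$max_frame[i]
    theta <- closure_eps * cycles$a_max[i]
    open_idx <- which(a[s:e] > theta) + s - 1L
    first_open <- min(open_idx)
    last_open <- max(open_idx)
    # opening starts at the closure instant (last closed frame before the
    # open run, or the cycle start if the cycle never closes); closing ends
    # at the first closed frame after it, symmetrically.
    open_from <- if (first_open > s) first_open - 1L else s
    open_to <- if (last_open < e) last_open + 1L else e
    t_opening[i] <- (m - open_from) / fps
    t_closing[i] <- (open_to - m) / fps
  }
  cycles$t_opening_s <- t_opening
  cycles$t_closing_s <- t_closing
  cycles$t_open_s <- t_opening + t_closing
  cycles$t_closed_s <- cycles$period_s - cycles$t_open_s
  attr(cycles, "closure_eps") <- closure_eps
  cycles
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("Cycle set: %d complete cycles, mean period %.3f ms (F0 %.1f Hz)\n",
              nrow(x), 1000 * mean(x$period_s), 1 / mean(x$period_s)))
  if (!is.null(x$t_open_s)) {
    cat(sprintf("  mean open/closed: %.3f / %.3f ms\n",
                1000 * mean(x$t_open_s), 1000 * mean(x$t_closed_s)))
  }
  invisible(x)
}
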