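# Phonovibrogram (PVG): lateral vocal-fold displacement from the glottal
# midline, sampled at M stations between the posterior and anterior points
# and unrolled over time into a 2M x T image. Layout follows the PVG
# literature: left fold in the top half with the posterior-most station at
# row 1, right fold mirrored below so the anterior ends of both folds meet
# at the horizontal centre. Values are raw pixel distances (no per-recording
# normalization); the layout and station spacing are carried as attributes.

#' Compute the phonovibrogram
#'
#' For every frame and each of `M` equidistant stations along the midline,
#' the distance from the midline to the farthest mask pixel on each side is
#' measured along the perpendicular at that station (pixels within half a
#' station spacing of the perpendicular are scanned). Frames with empty
#' masks give all-zero columns.
#'
#' @param seg a [segmentation_sequence()].
#' @param midlines list of `midline_estimate`s from [estimate_midline()];
#'   each frame uses the temporally nearest estimate.
#' @param M number of stations (default 64, >= 2).
#' @return object of class `pvg`: list with `matrix` (2M x T, px),
#'   `M`, `frame_rate`, `station_spacing_px`, `layout`.
#' @export
compute_pvg <- function(seg, midlines, M = 64L) {
  if (M < 2L) stop("M must be >= 2", call. = FALSE)
  d <- dim(seg$masks)
  nfr <- d[3]
  mat <- matrix(0, nrow = 2L * M, ncol = nfr)
  spacings <- numeric(0)
  for (t in seq_len(nfr)) {
    mk <- seg$masks[, , t]
    if (sum(mk) == 0) next
    ml <- nearest_midline(midlines, t)
    P <- ml$posterior_point
    dir <- ml$direction
    L <- sqrt(sum((ml$anterior_point - P)^2))
    if (L == 0) next
    h <- L / (M - 1L)
    spacings <- c(spacings, h)
    co <- mask_coords(mk)
    s <- (co$x - P[1]) * dir[1] + (co$y - P[2]) * dir[2]
    dd <- (co$x - P[1]) * dir[2] - (co$y - P[2]) * dir[1]
    stn <- round(s / h) + 1L
    ok <- stn >= 1L & stn <= M
    stn <- stn[ok]; dd <- dd[ok]
    if (!length(stn)) next
    is_left <- dd < 0
    if (any(is_left)) {
      lv <- tapply(-dd[is_left], stn[is_left], max)
      mat[as.integer(names(lv)), t] <- lv
    }
    if (any(!is_left)) {
      rv <- tapply(dd[!is_left], stn[!is_left], max)
      mat[2L * M + 1L - as.integer(names(rv)), t] <- rv
    }
  }
  structure(
    list(matrix = mat, M = as.integer(M), frame_rate = seg$frame_rate,
         station_spacing_px = if (length(spacings)) mean(spacings) else NA_real_,
         layout = "posterior_at_outer_rows"),
    class = "pvg"
  )
}

#' @export
print.pvg <- function(x, ...) {
  cat(sprintf(
    "PVG: %d stations x 2 folds x %d frames, max displacement %.1f px\n",
    x$M, ncol(x$matrix), max(x$matrix)))
  invisible(x)
}

#' @export
plot.pvg <- function(x, ...) {
  t_ms <- (seq_len(ncol(x$matrix)) - 1) / x$frame_rate * 1000
  graphics::image(t_ms, seq_len(nrow(x$matrix)), t(x$matrix),
                  xlab = "time [ms]", ylab = "fold position",
                  col = grDevices::hcl.colors(64, "inferno"), ...)
  invisible(x)
}
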