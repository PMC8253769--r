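# Glottal midline estimation, anterior/posterior points and hemi-GAWs.
#
# The midline is the anterior-posterior symmetry axis of the glottis. It is
# estimated at each cycle maximum from the segmentation mask (summing a few
# adjacent frames for temporal context) either via image moments or via PCA
# of the pixel coordinates — both reduce to the principal axis of the
# second-moment matrix. The midline direction is normalized to point
# posterior -> anterior; by default the image-top extreme is posterior
# (typical rigid-endoscope orientation), configurable. Left/right are image
# coordinates (image-left = smaller x); the anatomical mapping depends on
# endoscope handling and is deliberately not assumed.

#' Estimate the glottal midline at each cycle maximum
#'
#' @param seg a [segmentation_sequence()].
#' @param cycles a `cycle_set` from [detect_cycles()].
#' @param method "moments" (orientation from central image moments) or
#'   "pca" (dominant eigenvector of the pixel-coordinate covariance); the
#'   two are algebraically equivalent for binary masks and both provided.
#' @param context_frames frames summed on each side of the cycle maximum
#'   (default 2, i.e. 5 masks).
#' @param posterior_top logical; if TRUE (default) the image-top end of the
#'   midline is labelled posterior.
#' @return list of `midline_estimate` objects (fields `anchor_frame`,
#'   `centroid`, `direction` (unit, posterior -> anterior),
#'   `posterior_point`, `anterior_point`, `degenerate`), one per cycle;
#'   cycles whose summed mask is empty yield `NULL` with a warning.
#' @export
estimate_midline <- function(seg, cycles, method = c("moments", "pca"),
                             context_frames = 2L, posterior_top = TRUE) {
  method <- match.arg(method)
  d <- dim(seg$masks)
  out <- vector("list", nrow(cycles))
  for (i in seq_len(nrow(cycles))) {
    m <- cycles$max_frame[i]
    idx <- max(1L, m - context_frames):min(d[3], m + context_frames)
    summed <- matrix(0, d[1], d[2])
    for (j in idx) summed <- summed + seg$masks[, , j]
    if (sum(summed) == 0) {
      warning(sprintf("midline undefined for cycle %d: empty summed mask", i))
      next
    }
    out[[i]] <- midline_from_weights(summed, anchor_frame = m,
                                     method = method,
                                     posterior_top = posterior_top)
  }
  if (all(vapply(out, is.null, logical(1)))) {
    stop("midline undefined: all cycle masks empty", call. = FALSE)
  }
  out
}

midline_from_weights <- function(w, anchor_frame, method = "moments",
                                 posterior_top = TRUE) {
  co <- mask_coords(w > 0)
  wt <- w[w > 0]
  tot <- sum(wt)
  cx <- sum(wt * co$x) / tot
  cy <- sum(wt * co$y) / tot
  mu20 <- sum(wt * (co$x - cx)^2)
  mu02 <- sum(wt * (co$y - cy)^2)
  mu11 <- sum(wt * (co$x - cx) * (co$y - cy))
  degenerate <- FALSE
  if (method == "moments") {
    if (abs(mu20 - mu02) < 1e-9 * tot && abs(mu11) < 1e-9 * tot) {
      degenerate <- TRUE
      dir <- c(0, 1)
    } else {
      ang <- 0.5 * atan2(2 * mu11, mu20 - mu02)
      dir <- c(cos(ang), sin(ang))
    }
  } else {
    covm <- matrix(c(mu20, mu11, mu11, mu02), 2, 2) / tot
    e <- eigen(covm, symmetric = TRUE)
    if ((e$values[1] - e$values[2]) < 1e-9 * max(e$values[1], 1e-12)) {
      degenerate <- TRUE
      dir <- c(0, 1)
    } else {
      dir <- e$vectors[, 1]
    }
  }
  if (degenerate) {
    warning("midline orientation is degenerate (isotropic mask); ",
            "falling back to the vertical axis")
  }
  # posterior -> anterior: with posterior at image top, point towards +y
  flip <- if (posterior_top) dir[2] < 0 || (dir[2] == 0 && dir[1] < 0)
          else dir[2] > 0 || (dir[2] == 0 && dir[1] < 0)
  if (flip) dir <- -dir
  dir <- dir / sqrt(sum(dir^2))
  proj <- (co$x - cx) * dir[1] + (co$y - cy) * dir[2]
  post <- c(cx, cy) + min(proj) * dir
  ant <- c(cx, cy) + max(proj) * dir
  structure(
    list(anchor_frame = anchor_frame, centroid = c(cx, cy), direction = dir,
         posterior_point = post, anterior_point = ant,
         degenerate = degenerate),
    class = "midline_estimate"
  )
}

#' @export
print.midline_estimate <- function(x, ...) {
  cat(sprintf(
    "Midline @ frame %d: centroid (%.1f, %.1f), direction (%.3f, %.3f)%s\n",
    x$anchor_frame, x$centroid[1], x$centroid[2], x$direction[1],
    x$direction[2], if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Anterior and posterior glottis points of a mask along a midline
#'
#' Mask pixels are projected onto the midline direction; the extreme
#' projections define the two commissure points (on the midline). Which
#' extreme is anterior follows the orientation convention baked into the
#' midline direction (posterior -> anterior).
#'
#' @param midline a `midline_estimate`.
#' @param mask binary matrix.
#' @return list with `posterior_point` and `anterior_point`, each `c(x, y)`.
#' @export
anterior_posterior_points <- function(midline, mask) {
  if (sum(mask != 0) == 0) stop("empty mask", call. = FALSE)
  co <- mask_coords(mask)
  cx <- midline$centroid[1]; cy <- midline$centroid[2]
  dir <- midline$direction
  proj <- (co$x - cx) * dir[1] + (co$y - cy) * dir[2]
  list(posterior_point = c(cx, cy) + min(proj) * dir,
       anterior_point = c(cx, cy) + max(proj) * dir)
}

nearest_midline <- function(midlines, frame) {
  ok <- !vapply(midlines, is.null, logical(1))
  if (!any(ok)) stop("no midline estimates available", call. = FALSE)
  ml <- midlines[ok]
  anchors <- vapply(ml, function(m) m$anchor_frame, numeric(1))
  ml[[which.min(abs(anchors - frame))]]
}

#' Split the GAW into left and right hemi-GAWs
#'
#' Each mask pixel is assigned to the left or right vocal fold by the sign
#' of its signed perpendicular distance to the glottal midline (nearest
#' cycle-maximum estimate in time); pixels within half a pixel of the line
#' are split half/half, so left + right equals the total GAW exactly.
#'
#' @param seg a [segmentation_sequence()].
#' @param midlines list of `midline_estimate`s from [estimate_midline()].
#' @return object of class `hemi_gaw`: list with `left_area`, `right_area`
#'   (per frame, px; "left" = image-left, i.e. smaller x) and `frame_rate`.
#' @export
split_hemi_gaw <- function(seg, midlines) {
  d <- dim(seg$masks)
  nfr <- d[3]
  left <- right <- numeric(nfr)
  for (t in seq_len(nfr)) {
    mk <- seg$masks[, , t]
    tot <- sum(mk)
    if (tot == 0) next
    ml <- nearest_midline(midlines, t)
    co <- mask_coords(mk)
    dir <- ml$direction
    # signed distance: positive on the image-right side of the midline
    dist <- (co$x - ml$centroid[1]) * dir[2] -
            (co$y - ml$centroid[2]) * dir[1]
    l <- sum(dist <= -0.5) + 0.5 * sum(abs(dist) < 0.5)
    left[t] <- l
    right[t] <- tot - l
  }
  structure(list(left_area = left, right_area = right,
                 frame_rate = seg$frame_rate, convention = "image_left"),
            class = "hemi_gaw")
}

#' @export
print.hemi_gaw <- function(x, ...) {
  cat(sprintf(
    "Hemi-GAW: %d frames @ %g fps; mean left/right area %.1f / %.1f px\n",
    length(x$left_area), x$frame_rate, mean(x$left_area),
    mean(x$right_area)))
  invisible(x)
}
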