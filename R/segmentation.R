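# Glottis segmentation: per-frame binary masks from ROI-cropped video.
#
# Two segmenters share one contract (frame in, mask out): a classical
# baseline (intensity inversion + Otsu threshold + largest centred connected
# component), adequate for synthetic and well-contrasted recordings, and a
# pluggable model interface for encoder-decoder networks (inference only;
# the model is any R callable mapping a frame to a per-pixel probability
# map).
#
# Image convention throughout the package: a frame is a numeric matrix
# indexed [row, col] = [y + 1, x + 1]; pixel coordinates are 0-based with x
# right, y down.

#' Video frame stack
#'
#' @param frames numeric array: H x W x N (grayscale) or H x W x 3 x N (RGB),
#'   8-bit scale (0-255).
#' @param frame_rate frames per second.
#' @param roi optional region of interest `c(x, y, w, h)` (0-based pixel
#'   coordinates) already applied to the frames; recorded as metadata.
#' @return object of class `video_frames`.
#' @export
video_frames <- function(frames, frame_rate, roi = NULL) {
  nd <- length(dim(frames))
  if (!nd %in% c(3L, 4L)) {
    stop("frames must be an H x W x N or H x W x 3 x N array", call. = FALSE)
  }
  if (!is.numeric(frame_rate) || frame_rate <= 0) {
    stop("frame_rate must be positive", call. = FALSE)
  }
  structure(list(frames = frames, frame_rate = frame_rate, roi = roi),
            class = "video_frames")
}

#' @export
print.video_frames <- function(x, ...) {
  d <- dim(x$frames)
  n <- d[length(d)]
  cat(sprintf("Video: %d frames of %d x %d px @ %g fps%s\n",
              n, d[1], d[2], x$frame_rate,
              if (length(d) == 4L) " (RGB)" else ""))
  invisible(x)
}

n_frames <- function(video) {
  d <- dim(video$frames)
  d[length(d)]
}

get_frame <- function(video, i) {
  if (length(dim(video$frames)) == 4L) {
    rgb_to_gray(video$frames[, , , i])
  } else {
    video$frames[, , i]
  }
}

# ITU-R BT.601 luma; glottis contrast is luminance-dominated.
rgb_to_gray <- function(rgb) {
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

#' Crop a video to a region of interest
#'
#' @param video a [video_frames()] object.
#' @param roi `c(x, y, w, h)` in 0-based pixel coordinates.
#' @return cropped [video_frames()] with `roi` recorded; applying the same
#'   roi twice is a no-op.
#' @export
apply_roi <- function(video, roi) {
  if (length(roi) != 4L) stop("roi must be c(x, y, w, h)", call. = FALSE)
  roi <- as.integer(roi)
  if (!is.null(video$roi) && identical(as.integer(video$roi), roi)) {
    return(video)
  }
  x <- roi[1]; y <- roi[2]; w <- roi[3]; h <- roi[4]
  d <- dim(video$frames)
  if (w <= 0L || h <= 0L || x < 0L || y < 0L ||
      x + w > d[2] || y + h > d[1]) {
    stop("invalid roi: outside frame bounds or zero area", call. = FALSE)
  }
  rows <- (y + 1L):(y + h)
  cols <- (x + 1L):(x + w)
  cropped <- if (length(d) == 4L) {
    video$frames[rows, cols, , , drop = FALSE]
  } else {
    video$frames[rows, cols, , drop = FALSE]
  }
  video_frames(cropped, video$frame_rate, roi = roi)
}

#' Per-frame binary glottis masks
#'
#' @param masks integer/logical array H x W x N with values in {0, 1}.
#' @param frame_rate frames per second.
#' @param roi optional ROI metadata carried over from the video.
#' @return object of class `segmentation_sequence`.
#' @export
segmentation_sequence <- function(masks, frame_rate, roi = NULL) {
  if (length(dim(masks)) != 3L) {
    stop("masks must be an H x W x N array", call. = FALSE)
  }
  storage.mode(masks) <- "integer"
  if (length(masks) && !all(masks %in% c(0L, 1L))) {
    stop("mask values must be 0 or 1", call. = FALSE)
  }
  structure(list(masks = masks, frame_rate = frame_rate, roi = roi),
            class = "segmentation_sequence")
}

#' @export
print.segmentation_sequence <- function(x, ...) {
  d <- dim(x$masks)
  cat(sprintf("Segmentation: %d masks of %d x %d px @ %g fps\n",
              d[3], d[1], d[2], x$frame_rate))
  invisible(x)
}

# Otsu's threshold on an 8-bit-scale image; returns the threshold value
# (pixels strictly above it are foreground).
otsu_threshold <- function(x) {
  v <- pmax(0, pmin(255, as.vector(x)))
  counts <- tabulate(as.integer(v) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  omega <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  denom <- omega * (1 - omega)
  sigma_b <- (mu_t * omega - mu)^2 / ifelse(denom > 0, denom, Inf)
  levels[which.max(sigma_b)]
}

#' Label connected components of a binary mask
#'
#' 4-connectivity, two-pass union-find (compiled).
#'
#' @param mask logical or 0/1 matrix.
#' @return integer matrix of component labels, 0 = background.
#' @export
label_components <- function(mask) {
  label_components_cpp(mask != 0)
}

# Keep the largest component that touches the central region of the frame
# (a rectangle of `center_frac` the frame dimensions); glottis lies near the
# ROI centre by construction of the ROI.
keep_central_component <- function(bw, center_frac = 0.5) {
  lab <- label_components(bw)
  k <- max(lab)
  if (k == 0L) return(matrix(0L, nrow(bw), ncol(bw)))
  nr <- nrow(bw); nc <- ncol(bw)
  r0 <- max(1L, floor(nr * (1 - center_frac) / 2))
  c0 <- max(1L, floor(nc * (1 - center_frac) / 2))
  central <- lab[r0:(nr - r0 + 1L), c0:(nc - c0 + 1L)]
  cand <- setdiff(unique(as.vector(central)), 0L)
  if (!length(cand)) return(matrix(0L, nr, nc))
  sizes <- tabulate(lab, nbins = k)
  best <- cand[which.max(sizes[cand])]
  matrix(as.integer(lab == best), nr, nc)
}

#' Classical baseline glottis segmentation
#'
#' Per frame: luminance inversion (the glottis is the dark gap between the
#' bright folds), global Otsu threshold, connected-component labelling, and
#' retention of the largest component overlapping the frame-centre region.
#' Degenerate frames (e.g. fully closed glottis on uniform tissue) yield
#' empty masks.
#'
#' @param video a [video_frames()] object.
#' @param center_frac fraction of the frame treated as the central region.
#' @param min_contrast minimum intensity range below which a frame is
#'   declared featureless and gets an empty mask.
#' @return a [segmentation_sequence()].
#' @export
segment_threshold <- function(video, center_frac = 0.5, min_contrast = 30) {
  n <- n_frames(video)
  if (n == 0L) stop("video is empty", call. = FALSE)
  f1 <- get_frame(video, 1L)
  masks <- array(0L, dim = c(nrow(f1), ncol(f1), n))
  for (i in seq_len(n)) {
    g <- get_frame(video, i)
    inv <- max(g) - g
    if (diff(range(g)) < min_contrast) next
    th <- otsu_threshold(inv)
    bw <- inv > th
    masks[, , i] <- keep_central_component(bw, center_frac)
  }
  segmentation_sequence(masks, video$frame_rate, roi = video$roi)
}

#' Segment with a pluggable probability-map model
#'
#' The model is any R callable taking one grayscale frame (matrix, 0-255)
#' and returning a per-pixel glottis probability map of identical shape,
#' e.g. a wrapper around an encoder-decoder network runtime. Probabilities
#' are thresholded at 0.5; optionally only the largest centred component is
#' kept, matching common glottis-segmentation practice.
#'
#' @param video a [video_frames()] object.
#' @param model function(frame matrix) -> probability matrix.
#' @param batch_size accepted for interface compatibility; inference here is
#'   frame-by-frame.
#' @param threshold probability cut (default 0.5, exclusive).
#' @param keep_largest apply the largest-central-component post-filter.
#' @return a [segmentation_sequence()].
#' @export
segment_model <- function(video, model, batch_size = 16L, threshold = 0.5,
                          keep_largest = TRUE) {
  n <- n_frames(video)
  if (n == 0L) stop("video is empty", call. = FALSE)
  f1 <- get_frame(video, 1L)
  masks <- array(0L, dim = c(nrow(f1), ncol(f1), n))
  for (i in seq_len(n)) {
    g <- get_frame(video, i)
    p <- model(g)
    if (!identical(dim(p), dim(g))) {
      stop(sprintf(
        "model output shape (%s) does not match frame shape (%s)",
        paste(dim(p), collapse = "x"), paste(dim(g), collapse = "x")),
        call. = FALSE)
    }
    bw <- p > threshold
    masks[, , i] <- if (keep_largest) {
      keep_central_component(bw, center_frac = 1)
    } else {
      matrix(as.integer(bw), nrow(g), ncol(g))
    }
  }
  segmentation_sequence(masks, video$frame_rate, roi = video$roi)
}
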