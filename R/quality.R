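# Blind image quality with NIQE (Natural Image Quality Evaluator).
#
# Quality-aware features are GGD/AGGD parameters of MSCN coefficients and
# their pairwise products, extracted per patch at two scales (18 features
# per scale, 36 total). A reference multivariate Gaussian (mean +
# covariance) is fitted to patches from pristine images; the score of a test
# image is the Mahalanobis-type distance between its own Gaussian fit and
# the reference. Lower is better. Absolute values depend on the reference
# model, whose provenance is therefore recorded alongside the score; the
# packaged default model is fitted at run time from *synthetic* clean
# endoscopy-like frames and is labelled as such.

#' MSCN coefficients of a grayscale image
#'
#' Mean-subtracted contrast-normalized coefficients:
#' (I - mu) / (sigma + 1) with mu and sigma from a Gaussian-weighted 7x7
#' local window.
#'
#' @param image numeric matrix (8-bit scale).
#' @return matrix of MSCN coefficients, same size.
#' @export
mscn_coefficients <- function(image) {
  if (nrow(image) < 7L || ncol(image) < 7L) {
    stop("image too small for MSCN estimation (< 7 px)", call. = FALSE)
  }
  k <- gaussian_kernel1d(7 / 6, radius = 3L)
  mu <- filter2_sep(image, k)
  sigma <- sqrt(pmax(filter2_sep(image^2, k) - mu^2, 0))
  (image - mu) / (sigma + 1)
}

# Generalized Gaussian fit by moment matching on a shape-parameter grid.
ggd_grid <- local({
  gam <- seq(0.2, 10, by = 0.001)
  r <- (gamma(2 / gam))^2 / (gamma(1 / gam) * gamma(3 / gam))
  list(gam = gam, r = r)
})

fit_ggd <- function(x) {
  sigma_sq <- mean(x^2)
  if (sigma_sq == 0) return(c(shape = 10, sigma_sq = 0))
  rho <- mean(abs(x))^2 / sigma_sq
  idx <- which.min((ggd_grid$r - rho)^2)
  c(shape = ggd_grid$gam[idx], sigma_sq = sigma_sq)
}

# Asymmetric generalized Gaussian fit (Mittal et al. procedure).
fit_aggd <- function(x) {
  left <- x[x < 0]
  right <- x[x > 0]
  sigma_l <- if (length(left)) sqrt(mean(left^2)) else 0
  sigma_r <- if (length(right)) sqrt(mean(right^2)) else 0
  if (sigma_l == 0 || sigma_r == 0) {
    return(c(shape = 10, eta = 0, sigma_l_sq = sigma_l^2,
             sigma_r_sq = sigma_r^2))
  }
  gammahat <- sigma_l / sigma_r
  rhat <- mean(abs(x))^2 / mean(x^2)
  rhatnorm <- rhat * (gammahat^3 + 1) * (gammahat + 1) / (gammahat^2 + 1)^2
  idx <- which.min((ggd_grid$r - rhatnorm)^2)
  alpha <- ggd_grid$gam[idx]
  eta <- (sigma_r - sigma_l) * gamma(2 / alpha) /
    sqrt(gamma(1 / alpha) * gamma(3 / alpha))
  c(shape = alpha, eta = eta, sigma_l_sq = sigma_l^2, sigma_r_sq = sigma_r^2)
}

# 18 quality-aware features of one patch of MSCN coefficients.
patch_features <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  h <- m[, -nc] * m[, -1]
  v <- m[-nr, ] * m[-1, ]
  d1 <- m[-nr, -nc] * m[-1, -1]
  d2 <- m[-1, -nc] * m[-nr, -1]
  c(fit_ggd(as.vector(m)),
    fit_aggd(as.vector(h)), fit_aggd(as.vector(v)),
    fit_aggd(as.vector(d1)), fit_aggd(as.vector(d2)))
}

downsample2 <- function(img) {
  nr <- 2L * (nrow(img) %/% 2L)
  nc <- 2L * (ncol(img) %/% 2L)
  img <- img[seq_len(nr), seq_len(nc)]
  0.25 * (img[seq(1, nr, 2), seq(1, nc, 2)] +
          img[seq(2, nr, 2), seq(1, nc, 2)] +
          img[seq(1, nr, 2), seq(2, nc, 2)] +
          img[seq(2, nr, 2), seq(2, nc, 2)])
}

# 36-dim feature vectors (rows = patches) at two scales; optionally also
# returns per-patch mean local sharpness at scale 1.
niqe_patch_features <- function(image, patch_size = 96L) {
  if (nrow(image) < patch_size || ncol(image) < patch_size) {
    stop("image smaller than NIQE patch size", call. = FALSE)
  }
  pr <- nrow(image) %/% patch_size
  pc <- ncol(image) %/% patch_size
  k <- gaussian_kernel1d(7 / 6, radius = 3L)
  feats <- NULL
  sharp <- NULL
  img <- image
  ps <- patch_size
  for (scale in 1:2) {
    mu <- filter2_sep(img, k)
    sigma <- sqrt(pmax(filter2_sep(img^2, k) - mu^2, 0))
    m <- (img - mu) / (sigma + 1)
    sc_feats <- matrix(0, pr * pc, 18L)
    sc_sharp <- numeric(pr * pc)
    p <- 0L
    for (i in seq_len(pr)) {
      for (j in seq_len(pc)) {
        p <- p + 1L
        rows <- ((i - 1L) * ps + 1L):(i * ps)
        cols <- ((j - 1L) * ps + 1L):(j * ps)
        sc_feats[p, ] <- patch_features(m[rows, cols])
        sc_sharp[p] <- mean(sigma[rows, cols])
      }
    }
    feats <- if (is.null(feats)) sc_feats else cbind(feats, sc_feats)
    if (scale == 1L) sharp <- sc_sharp
    img <- downsample2(img)
    ps <- ps %/% 2L
  }
  list(features = feats, sharpness = sharp)
}

#' Fit a NIQE reference model from pristine images
#'
#' Extracts quality-aware features from sharp patches of the supplied
#' images (patch sharpness above `sharpness_frac` of the per-image maximum)
#' and fits the reference multivariate Gaussian.
#'
#' @param images list of grayscale matrices (8-bit scale).
#' @param patch_size patch size in pixels at scale 1 (default 96).
#' @param sharpness_frac sharpness selection fraction (default 0.75).
#' @param provenance free-text description of the image source, stored in
#'   the model.
#' @return object of class `niqe_model` with `mu`, `cov`, `patch_size`,
#'   `scales`, `provenance`.
#' @export
niqe_fit_model <- function(images, patch_size = 96L, sharpness_frac = 0.75,
                           provenance = "user-supplied images") {
  feats <- NULL
  for (img in images) {
    pf <- niqe_patch_features(img, patch_size)
    keep <- pf$sharpness >= sharpness_frac * max(pf$sharpness)
    if (!any(keep)) keep <- rep(TRUE, length(pf$sharpness))
    feats <- rbind(feats, pf$features[keep, , drop = FALSE])
  }
  if (nrow(feats) < 2L) {
    stop("need at least 2 patches to fit a NIQE model", call. = FALSE)
  }
  structure(
    list(mu = colMeans(feats), cov = stats::cov(feats),
         patch_size = as.integer(patch_size), scales = 2L,
         provenance = provenance),
    class = "niqe_model"
  )
}

#' @export
print.niqe_model <- function(x, ...) {
  cat(sprintf("NIQE reference model: %d features, patch %d px, %d scales\n",
              length(x$mu), x$patch_size, x$scales))
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

# Mahalanobis-type distance between the reference Gaussian and a test fit.
niqe_distance <- function(mu, sigma, nu, sigma_test) {
  diffv <- mu - nu
  S <- (sigma + sigma_test) / 2
  inv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(inv)) {
    warning("singular combined covariance; using regularized inverse")
    inv <- solve(S + diag(1e-6 * (1 + mean(diag(S))), nrow(S)))
  }
  sqrt(max(0, as.numeric(t(diffv) %*% inv %*% diffv)))
}

#' NIQE score of one image
#'
#' Lower is better; 0 means the test features coincide with the reference
#' model mean.
#'
#' @param image grayscale matrix (8-bit scale); RGB arrays are converted to
#'   luma.
#' @param model a `niqe_model`.
#' @return non-negative score.
#' @export
niqe_score <- function(image, model) {
  if (length(dim(image)) == 3L) image <- rgb_to_gray(image)
  pf <- niqe_patch_features(image, model$patch_size)
  nu <- colMeans(pf$features)
  sigma_test <- if (nrow(pf$features) >= 2L) {
    stats::cov(pf$features)
  } else {
    matrix(0, length(nu), length(nu))
  }
  niqe_distance(model$mu, model$cov, nu, sigma_test)
}

#' NIQE scores over a frame stack
#'
#' @param video a [video_frames()] object.
#' @param model a `niqe_model`.
#' @param stride score every stride-th frame (default 1).
#' @return list with `scores` (per sampled frame), `frames` (their indices)
#'   and `mean_score`.
#' @export
niqe_batch <- function(video, model, stride = 1L) {
  n <- n_frames(video)
  if (n < 1L) stop("video is empty", call. = FALSE)
  idx <- seq(1L, n, by = max(1L, as.integer(stride)))
  scores <- vapply(idx, function(i) niqe_score(get_frame(video, i), model),
                   numeric(1))
  list(scores = scores, frames = idx, mean_score = mean(scores))
}

#' Synthetic pristine reference images for the default NIQE model
#'
#' Generates clean, sharp, endoscopy-like scenes (bright textured tissue
#' with dark lens-shaped openings and smooth illumination gradients). These
#' are SYNTHETIC stand-ins for a pristine natural-image corpus: scores from
#' the resulting model are internally consistent (relative comparisons,
#' distortion monotonicity) but not on the scale of models fitted to
#' natural photographs.
#'
#' @param n number of images.
#' @param size image side length in pixels.
#' @param seed RNG seed.
#' @return list of matrices.
#' @export
niqe_synthetic_reference_images <- function(n = 8L, size = 192L, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    base <- matrix(stats::rnorm(size^2), size, size)
    tex <- filter2_sep(base, gaussian_kernel1d(1.2))
    tex <- tex / stats::sd(tex) * 18
    gx <- matrix(rep(seq(0, 1, length.out = size), each = size), size)
    grad <- 30 * (stats::runif(1) - 0.5) * gx +
      30 * (stats::runif(1) - 0.5) * t(gx)
    img <- 165 + tex + grad
    # a few dark elliptic openings with sharp edges
    xs <- matrix(rep(seq_len(size), each = size), size)
    ys <- t(xs)
    for (k in seq_len(3L)) {
      cx <- stats::runif(1, 0.2, 0.8) * size
      cy <- stats::runif(1, 0.2, 0.8) * size
      a <- stats::runif(1, 0.03, 0.10) * size
      b <- stats::runif(1, 0.10, 0.25) * size
      ell <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 < 1
      img[ell] <- 25 + tex[ell] * 0.3
    }
    pmin(pmax(img, 0), 255)  # pmax/pmin keep dims only for a matrix first arg
  })
}

niqe_model_cache <- new.env(parent = emptyenv())

#' Default (synthetic-reference) NIQE model
#'
#' Fitted on demand from [niqe_synthetic_reference_images()] and cached for
#' the session. Deterministic for a given seed/size.
#'
#' @param patch_size patch size in pixels (default 48, suited to the
#'   synthetic reference size).
#' @param seed RNG seed for the reference images.
#' @return a `niqe_model`.
#' @export
niqe_default_model <- function(patch_size = 48L, seed = 1L) {
  key <- paste0("m", patch_size, "_", seed)
  if (!is.null(niqe_model_cache[[key]])) return(niqe_model_cache[[key]])
  imgs <- niqe_synthetic_reference_images(seed = seed)
  m <- niqe_fit_model(imgs, patch_size = patch_size,
                      provenance = sprintf(
                        "synthetic clean endoscopy-like frames (seed %d)",
                        seed))
  niqe_model_cache[[key]] <- m
  m
}
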