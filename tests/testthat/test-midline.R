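# Glottal midline, anterior/posterior points, hemi-GAW split.

angle_to_vertical <- function(dir) {
  acos(min(1, abs(dir[2]))) * 180 / pi
}

stack_of <- function(mask, n = 5) {
  segmentation_sequence(array(rep(mask, n), dim = c(dim(mask), n)), 4000)
}

test_that("midline orientation and centroid recover an ellipse axis", {
  mask <- ellipse_mask(100, 60, cx = 29.5, cy = 49.5, ax = 10, ay = 40)
  seg <- stack_of(mask)
  for (method in c("moments", "pca")) {
    ml <- estimate_midline(seg, fake_cycles(3, 5), method = method)[[1]]
    expect_lt(angle_to_vertical(ml$direction), 1)
    expect_lt(abs(ml$centroid[1] - 29.5), 0.5)
    expect_lt(abs(ml$centroid[2] - 49.5), 0.5)
    # posterior (image top) -> anterior: direction points down
    expect_gt(ml$direction[2], 0)
  }
})

test_that("midline orientation follows a rotated ellipse", {
  mask <- ellipse_mask(100, 100, 49.5, 49.5, ax = 10, ay = 38,
                       angle_deg = 30)
  for (method in c("moments", "pca")) {
    ml <- estimate_midline(stack_of(mask), fake_cycles(3, 5),
                           method = method)[[1]]
    got <- atan2(abs(ml$direction[1]), abs(ml$direction[2])) * 180 / pi
    expect_lt(abs(got - 30), 1)
  }
})

test_that("isotropic masks are flagged as degenerate", {
  mask <- ellipse_mask(40, 40, 19.5, 19.5, 10, 10)
  expect_warning(
    ml <- estimate_midline(stack_of(mask), fake_cycles(3, 5)),
    "degenerate")
  expect_true(ml[[1]]$degenerate)
})

test_that("empty masks give a midline-undefined error", {
  seg <- stack_of(matrix(0L, 10, 10))
  expect_warning(
    expect_error(estimate_midline(seg, fake_cycles(3, 5)), "midline undefined"),
    "empty summed mask")
})

test_that("anterior/posterior points sit at the mask extremes", {
  mask <- ellipse_mask(100, 60, 29.5, 49.5, 10, 40)
  ml <- estimate_midline(stack_of(mask), fake_cycles(3, 5))[[1]]
  pts <- anterior_posterior_points(ml, mask)
  expect_lt(abs(pts$posterior_point[2] - (49.5 - 40)), 1.5)
  expect_lt(abs(pts$anterior_point[2] - (49.5 + 40)), 1.5)
  expect_lt(abs(pts$posterior_point[1] - 29.5), 1)

  # single-pixel mask: both points equal that pixel
  single <- matrix(0L, 10, 10); single[4, 7] <- 1L
  mid <- structure(list(centroid = c(6, 3), direction = c(0, 1)),
                   class = "midline_estimate")
  p <- anterior_posterior_points(mid, single)
  expect_equal(p$posterior_point, c(6, 3))
  expect_equal(p$anterior_point, c(6, 3))

  # mask split in two blobs: extremes from the union
  blobs <- matrix(0L, 40, 11)
  blobs[2:6, 5:7] <- 1L
  blobs[31:36, 5:7] <- 1L
  midv <- structure(list(centroid = c(5, 18), direction = c(0, 1)),
                    class = "midline_estimate")
  pb <- anterior_posterior_points(midv, blobs)
  expect_equal(pb$posterior_point[2], 1)
  expect_equal(pb$anterior_point[2], 35)

  expect_error(anterior_posterior_points(mid, matrix(0L, 5, 5)), "empty")
})

test_that("hemi-GAW split conserves area and respects symmetry", {
  # mirror-symmetric mask about the pixel column x = 10
  mask <- ellipse_mask(40, 21, 10, 19.5, 6, 15)
  seg <- stack_of(mask, 3)
  ml <- estimate_midline(seg, fake_cycles(2, 3))
  hemi <- split_hemi_gaw(seg, ml)
  expect_equal(hemi$left_area, hemi$right_area)
  expect_equal(hemi$left_area + hemi$right_area,
               gaw_from_masks(seg)$area)

  expect_error(split_hemi_gaw(seg, list(NULL)), "no midline")
})

test_that("pixels strictly on one side give a zero opposite hemi-GAW", {
  mask <- matrix(0L, 30, 30)
  mask[10:20, 2:6] <- 1L  # far image-left
  seg <- stack_of(mask, 2)
  mid <- structure(list(anchor_frame = 1, centroid = c(15, 15),
                        direction = c(0, 1), degenerate = FALSE),
                   class = "midline_estimate")
  hemi <- split_hemi_gaw(seg, list(mid))
  expect_equal(hemi$right_area, c(0, 0))
  expect_equal(hemi$left_area, rep(sum(mask), 2))
})

test_that("hemi amplitude ratio tracks the injected left/right asymmetry", {
  # finer raster: at 96 px the discretized narrow fold inflates the ratio
  spec <- phonation_spec(seed = 4, left_right_amp_ratio = 0.8,
                         left_right_phase_lag = 0, duration = 0.1,
                         image_size = 160)
  rec <- synth_recording(spec, render_frames = FALSE)
  g <- gaw_from_masks(rec$masks)
  cyc <- detect_cycles(g)
  ml <- estimate_midline(rec$masks, cyc)
  hemi <- split_hemi_gaw(rec$masks, ml)
  sy <- symmetry_indices(hemi, cyc)
  expect_lt(abs(sy$ASI - 0.8), 0.05)
})

test_that("hemi-GAWs are equivariant under a 90-degree rotation", {
  spec <- phonation_spec(seed = 6, duration = 0.02, noise = 0)
  rec <- synth_recording(spec, render_frames = FALSE)
  seg <- rec$masks
  n <- dim(seg$masks)[3]
  rot <- array(0L, dim = c(dim(seg$masks)[2], dim(seg$masks)[1], n))
  for (i in seq_len(n)) {  # 90 deg clockwise
    rot[, , i] <- t(seg$masks[dim(seg$masks)[1]:1, , i])
  }
  segr <- segmentation_sequence(rot, seg$frame_rate)
  g <- gaw_from_masks(seg)
  cyc <- detect_cycles(g)
  h1 <- split_hemi_gaw(seg, estimate_midline(seg, cyc))
  h2 <- split_hemi_gaw(segr, estimate_midline(segr, cyc))
  expect_equal(pmin(h1$left_area, h1$right_area),
               pmin(h2$left_area, h2$right_area), tolerance = 1e-9)
  expect_equal(pmax(h1$left_area, h1$right_area),
               pmax(h2$left_area, h2$right_area), tolerance = 1e-9)
})

test_that("midline orientation is stable under 1% salt noise", {
  spec <- phonation_spec(seed = 9, duration = 0.02)
  rec <- synth_recording(spec, render_frames = FALSE)
  seg <- rec$masks
  cyc <- detect_cycles(gaw_from_masks(seg))
  ml0 <- estimate_midline(seg, cyc)
  set.seed(1)
  noisy <- seg$masks
  idx <- sample(length(noisy), round(0.01 * length(noisy)))
  noisy[idx] <- 1L
  mln <- estimate_midline(segmentation_sequence(noisy, seg$frame_rate), cyc)
  angs <- vapply(seq_along(ml0), function(i) {
    acos(min(1, abs(sum(ml0[[i]]$direction * mln[[i]]$direction)))) * 180 / pi
  }, numeric(1))
  expect_lt(mean(angs), 2)
})
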