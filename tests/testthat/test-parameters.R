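# Clinical parameter formulas: frozen arithmetic examples, Monte-Carlo
# oracles, invariances.

cycles_from_periods <- function(periods_s, amplitudes = NULL, fps = 4000) {
  n <- length(periods_s)
  cyc <- data.frame(start = seq_len(n), end = seq_len(n) + 1L,
                    period_s = periods_s,
                    amplitude = if (is.null(amplitudes)) rep(1, n)
                                else amplitudes)
  cyc$a_min <- 0
  cyc$a_max <- cyc$amplitude
  attr(cyc, "frame_rate") <- fps
  class(cyc) <- c("cycle_set", "data.frame")
  cyc
}

test_that("fundamental frequency is the reciprocal mean period", {
  expect_equal(fundamental_frequency(cycles_from_periods(rep(0.010, 30))),
               100)
  expect_equal(
    fundamental_frequency(cycles_from_periods(rep(c(0.009, 0.011), 10))),
    100)
  expect_error(fundamental_frequency(cycles_from_periods(0.01)),
               "too few cycles")
})

test_that("jitter matches direct arithmetic and a Monte-Carlo oracle", {
  expect_equal(jitter(cycles_from_periods(rep(0.01, 10))),
               list(mean_jitter_ms = 0, jitter_pct = 0))
  j <- jitter(cycles_from_periods(c(10, 11, 10, 11) / 1000))
  expect_equal(j$mean_jitter_ms, 1.0)
  expect_equal(j$jitter_pct, 100 / 10.5, tolerance = 1e-9)

  # E|T_{i+1} - T_i| for iid Gaussian perturbations is 2 sigma / sqrt(pi)
  sigma <- 1.5e-4
  est <- vapply(1:50, function(s) {
    set.seed(s)
    jitter(cycles_from_periods(1 / 300 + rnorm(200, 0, sigma)))$mean_jitter_ms
  }, numeric(1))
  expect_lt(abs(mean(est) / 1000 - 2 * sigma / sqrt(pi)) /
            (2 * sigma / sqrt(pi)), 0.15)
})

test_that("shimmer matches direct arithmetic", {
  expect_equal(shimmer(cycles_from_periods(rep(0.01, 5))),
               list(mean_shimmer_db = 0, shimmer_pct = 0))
  s <- shimmer(cycles_from_periods(rep(0.01, 6),
                                   amplitudes = rep(c(1, 2), 3)))
  expect_equal(s$mean_shimmer_db, 20 * log10(2), tolerance = 1e-9)
  s2 <- shimmer(cycles_from_periods(rep(0.01, 2), amplitudes = c(1, 1.1)))
  expect_equal(s2$shimmer_pct, 100 * 0.1 / 1.05, tolerance = 1e-9)
  expect_error(
    shimmer(cycles_from_periods(rep(0.01, 3), amplitudes = c(1, 0, 1))),
    "nonpositive")
})

test_that("phase quotients match the symmetric and 3:1 cycle anchors", {
  # symmetric cycle, no closed phase
  g <- symmetric_gaw(20)
  cyc <- decompose_phases(g, detect_cycles(g), closure_eps = 0)
  pq <- phase_quotients(cyc)
  expect_equal(pq$OQ, 1.0)
  expect_equal(pq$CQ, 0.5)
  expect_equal(pq$SQ, 1.0)
  expect_equal(pq$AQ, 0.5)
  expect_equal(pq$RQ, 1.0)
  expect_equal(pq$SI, 0.0)

  # rise 3, fall 1, no closed phase
  g3 <- triangle_gaw(n_cycles = 8, up = 3, down = 1)
  pq3 <- phase_quotients(decompose_phases(g3, detect_cycles(g3),
                                          closure_eps = 0))
  expect_equal(pq3$SQ, 3.0)
  expect_equal(pq3$SI, 0.5)
  expect_equal(pq3$AQ, 0.75)
  expect_equal(pq3$CQ, 0.25)
  expect_equal(pq3$RQ, 3.0)
})

test_that("glottal gap index averages the per-cycle min/max ratio", {
  g <- symmetric_gaw(10)
  cyc <- detect_cycles(g)
  expect_equal(glottal_gap_index(cyc), 0)

  cyc2 <- cycles_from_periods(rep(0.01, 5))
  cyc2$a_min <- 0.15
  cyc2$a_max <- 1
  expect_equal(glottal_gap_index(cyc2), 0.15)

  # synthetic never-closing GAW with a 0.3 floor
  gf <- gaw(0.3 + 0.7 * symmetric_gaw(10)$area / 100, 4000)
  cyc3 <- detect_cycles(gf)
  expect_lt(abs(glottal_gap_index(cyc3) - 0.3), 0.02)
})

test_that("amplitude quotient matches triangle and sinusoid oracles", {
  g <- triangle_gaw(n_cycles = 6, up = 3, down = 3)  # fall 3 px/frame
  cyc <- detect_cycles(g)
  expect_equal(amplitude_quotient(g, cyc), 3.0)
  gs <- gaw(g$area * 5, 4000)
  expect_equal(amplitude_quotient(gs, detect_cycles(gs)), 3.0)

  # sinusoid: A / |min dA/dt| = N / pi
  N <- 40
  g2 <- symmetric_gaw(12, period_frames = N)
  aq <- amplitude_quotient(g2, detect_cycles(g2))
  expect_lt(abs(aq - N / pi) / (N / pi), 0.05)
})

test_that("stiffness is the mean normalized area velocity", {
  g <- triangle_gaw(n_cycles = 6, up = 2, down = 2, step = 2)  # amp 4
  cyc <- detect_cycles(g)
  expect_equal(stiffness(g, cyc), 0.5)
  gs <- gaw(g$area * 3, 4000)
  expect_equal(stiffness(gs, detect_cycles(gs)), 0.5)
})

test_that("symmetry indices read hemi amplitude ratio and phase lag", {
  fps <- 4000
  n_cyc <- 8; P <- 20
  t <- 0:(n_cyc * P)
  base <- (1 - cos(2 * pi * t / P)) / 2
  g <- gaw(2 * base, fps)
  cyc <- detect_cycles(g)

  hemi_eq <- structure(list(left_area = base, right_area = base,
                            frame_rate = fps), class = "hemi_gaw")
  sy <- symmetry_indices(hemi_eq, cyc)
  expect_equal(sy$ASI, 1.0)
  expect_equal(sy$PAI, 0.0)

  hemi_amp <- structure(list(left_area = 0.9 * base, right_area = base,
                             frame_rate = fps), class = "hemi_gaw")
  expect_equal(symmetry_indices(hemi_amp, cyc)$ASI, 0.9)
  expect_equal(symmetry_indices(hemi_amp, cyc)$PAI, 0.0)

  lag <- P / 4
  right_lag <- (1 - cos(2 * pi * (t - lag) / P)) / 2
  hemi_lag <- structure(list(left_area = base, right_area = right_lag,
                             frame_rate = fps), class = "hemi_gaw")
  expect_equal(symmetry_indices(hemi_lag, cyc)$PAI, 0.25, tolerance = 0.02)
})

test_that("amplitude perturbation quotients match brute-force windows", {
  const <- cycles_from_periods(rep(0.01, 15))
  ap <- amplitude_perturbation(const)
  expect_equal(ap$APF, 0)
  expect_equal(ap$APQ3, 0)
  expect_equal(ap$APQ11, 0)

  # independent brute-force oracle for the centered-window definition
  brute_apq <- function(A, k) {
    h <- (k - 1) %/% 2
    devs <- vapply((h + 1):(length(A) - h), function(i) {
      abs(A[i] - mean(A[(i - h):(i + h)]))
    }, numeric(1))
    100 * mean(devs) / mean(A)
  }
  A_alt <- rep(c(1, 2), 6)
  alt <- cycles_from_periods(rep(0.01, 12), amplitudes = A_alt)
  expect_equal(amplitude_perturbation(alt)$APQ3, brute_apq(A_alt, 3),
               tolerance = 1e-9)
  expect_equal(amplitude_perturbation(alt)$APQ3, 100 * (2 / 3) / 1.5,
               tolerance = 1e-9)

  # single outlier: a wider window leaves a larger residual deviation, the
  # behaviour the clinical APQ3 < APQ5 < APQ11 ordering reflects
  A_out <- c(rep(1, 10), 2, rep(1, 10))
  out <- cycles_from_periods(rep(0.01, 21), amplitudes = A_out)
  ap2 <- amplitude_perturbation(out)
  for (k in c(3, 5, 11)) {
    expect_equal(ap2[[paste0("APQ", k)]], brute_apq(A_out, k),
                 tolerance = 1e-9)
  }
  expect_lt(ap2$APQ3, ap2$APQ5)
  expect_lt(ap2$APQ5, ap2$APQ11)

  few <- cycles_from_periods(rep(0.01, 5))
  expect_true(is.na(amplitude_perturbation(few)$APQ11))
})

test_that("HNR recovers a known signal-to-noise ratio", {
  sr <- 80000
  # perfectly periodic: residual zero, capped
  x <- harmonic_voice(16000, period = 320, snr_db = Inf)
  ac <- detect_audio_cycles(x, sr)
  expect_equal(hnr(x, ac, sr), 120)

  est <- vapply(1:20, function(s) {
    set.seed(s)
    xn <- harmonic_voice(16000, period = 320, snr_db = 15)
    hnr(xn, detect_audio_cycles(xn, sr), sr)
  }, numeric(1))
  expect_lt(abs(mean(est) - 15), 1.5)

  set.seed(3)
  x0 <- harmonic_voice(16000, period = 320, snr_db = 0)
  expect_lt(abs(hnr(x0, detect_audio_cycles(x0, sr), sr)), 2.5)

  expect_error(hnr(numeric(1000), ac, sr), "silent")
})

test_that("CPP separates periodic voice from noise and is gain-invariant", {
  spec <- phonation_spec(seed = 1)
  sch <- synth_gaw_schedule(spec)
  voice <- render_audio(spec, sch)$recording$audio[1:20000]
  cp <- cpp(voice, 80000)
  expect_gt(cp$cpp_db, 10)
  expect_lt(abs(cp$peak_quefrency_s - 1 / 300) / (1 / 300), 0.05)

  noise_cpp <- vapply(1:20, function(s) {
    set.seed(s)
    cpp(rnorm(20000), 80000)$cpp_db
  }, numeric(1))
  expect_lt(max(noise_cpp), 5)

  cp2 <- cpp(2 * voice, 80000)
  expect_equal(cp2$cpp_db, cp$cpp_db, tolerance = 1e-6)
  expect_error(cpp(rnorm(1000), 80000), "too short")
})

test_that("perturbation measures vanish on perfectly periodic input", {
  # GAW side: integer frames per cycle
  g <- symmetric_gaw(25)
  cyc <- decompose_phases(g, detect_cycles(g))
  expect_equal(jitter(cyc)$mean_jitter_ms, 0)
  expect_equal(shimmer(cyc)$mean_shimmer_db, 0)
  ap <- amplitude_perturbation(cyc)
  expect_equal(ap$APF, 0)
  expect_equal(ap$APQ11, 0)

  # audio side: integer samples per cycle
  x <- harmonic_voice(16000, period = 320)
  ac <- detect_audio_cycles(x, 80000)
  expect_equal(jitter(ac)$mean_jitter_ms, 0, tolerance = 1e-6)
  expect_equal(shimmer(ac)$shimmer_pct, 0, tolerance = 1e-6)
})

test_that("relative measures are invariant to GAW scaling", {
  spec <- phonation_spec(seed = 12, duration = 0.05,
                         jitter_sigma = 2e-4, shimmer_sigma = 0.02)
  sch <- synth_gaw_schedule(spec)
  g1 <- gaw(sch$level_total * 500, spec$fps)
  g2 <- gaw(sch$level_total * 500 * 3.7, spec$fps)
  r1 <- compute_report(g1, decompose_phases(g1, detect_cycles(g1)))
  r2 <- compute_report(g2, decompose_phases(g2, detect_cycles(g2)))
  rel <- c("jitter_pct", "shimmer_pct", "open_quotient", "closing_quotient",
           "speed_quotient", "asymmetry_quotient", "rate_quotient",
           "speed_index", "glottal_gap_index", "stiffness",
           "amplitude_quotient", "apf", "apq3", "apq5", "apq11")
  for (nm in rel) {
    expect_equal(r2$gaw[[nm]], r1$gaw[[nm]], tolerance = 1e-9, label = nm)
  }
})

test_that("compute_report assembles fields and reports absences", {
  spec <- phonation_spec(seed = 13, duration = 0.12)
  rec <- synth_recording(spec, render_frames = FALSE)
  g <- gaw_from_masks(rec$masks)
  cyc <- decompose_phases(g, detect_cycles(g))
  ml <- estimate_midline(rec$masks, cyc)
  hemi <- split_hemi_gaw(rec$masks, ml)
  audio <- rec$audio$audio[seq_len(round(spec$duration * 80000))]

  full <- compute_report(g, cyc, hemi, audio, 80000)
  expect_length(full$gaw, 20)
  expect_length(full$audio, 11)
  df <- as.data.frame(full)
  expect_equal(nrow(df), 31)
  expect_true(all(c("name", "value", "unit", "source_signal") %in% names(df)))

  video_only <- compute_report(g, cyc, hemi)
  expect_null(video_only$audio)
  audio_only <- compute_report(audio = audio, sample_rate = 80000)
  expect_null(audio_only$gaw)
  expect_length(audio_only$audio, 11)
  expect_error(compute_report(audio = audio), "sample_rate")
})
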