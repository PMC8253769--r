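# Synthetic phonation generator: ground-truthed high-speed video, paired
# audio and camera reference signal, emulating a clinical HSV acquisition so
# that every pipeline stage is testable without hardware.
#
# The stated world: a glottal cycle is a piecewise-sinusoidal opening
# template whose open fraction, rise/fall asymmetry and residual opening are
# set by the open-quotient, speed-index and glottal-floor targets; per-cycle
# periods and amplitudes are perturbed by seeded Gaussian jitter/shimmer.
# Defaults emulate the healthy phonations of the validation cohort: F0 300
# Hz (cohort range 235-412 Hz), 4000 fps video, 80 kHz audio, no closed
# phase (cohort OQ 0.989-1.000) with a relative glottal floor of 0.12
# (cohort GGI 0.000-0.367), symmetric cycles (SI ~ 0, CQ ~ 0.5), left/right
# amplitude ratio 0.97 (cohort ASI 0.932-0.993), left/right phase lag 0.03
# of a period (cohort PAI 0.006-0.258), jitter sigma 150 us and relative
# shimmer sigma 0.002 matching the cohort's mean GAW jitter/shimmer scale.
# The audio voice signal is a Rosenberg-type glottal pulse train sharing the
# video's per-cycle periods and amplitudes (no vocal-tract filter), plus
# white noise at a configurable SNR; the reference channel carries one unit
# pulse per frame, ceasing at the end trigger, followed by 1 s of quiet
# tail as in the acquisition protocol.

#' Specification of a synthetic phonation
#'
#' @param f0 fundamental frequency in Hz.
#' @param duration phonation duration in seconds (video length).
#' @param fps video frame rate (default 4000).
#' @param audio_rate audio sampling rate in Hz (default 80000).
#' @param open_quotient_target open fraction of each cycle, in (0, 1].
#' @param speed_index_target rise/fall asymmetry of the open phase,
#'   in (-1, 1).
#' @param left_right_amp_ratio left/right fold amplitude ratio, in (0, 1].
#' @param left_right_phase_lag left fold lag as a fraction of a period.
#' @param jitter_sigma per-cycle period perturbation SD in seconds.
#' @param shimmer_sigma per-cycle relative amplitude perturbation SD.
#' @param glottal_floor residual minimal opening relative to the cycle
#'   maximum (glottal-gap-index target), in \[0, 1).
#' @param image_size frame side length in pixels.
#' @param midline_angle glottal midline angle in degrees from the vertical.
#' @param noise additive pixel-noise SD (8-bit scale).
#' @param audio_snr_db voice-to-noise ratio of the audio channel in dB
#'   (Inf for noise-free).
#' @param seed RNG seed; all stochastic elements derive from it.
#' @return object of class `phonation_spec`.
#' @export
phonation_spec <- function(f0 = 300, duration = 0.25, fps = 4000,
                           audio_rate = 80000, open_quotient_target = 1,
                           speed_index_target = 0,
                           left_right_amp_ratio = 0.97,
                           left_right_phase_lag = 0.03,
                           jitter_sigma = 1.5e-4, shimmer_sigma = 0.002,
                           glottal_floor = 0.12, image_size = 96,
                           midline_angle = 0, noise = 5,
                           audio_snr_db = 30, seed = 1L) {
  if (f0 <= 0 || fps <= 0 || audio_rate <= 0 || duration <= 0) {
    stop("invalid spec: rates and duration must be positive", call. = FALSE)
  }
  if (open_quotient_target <= 0 || open_quotient_target > 1) {
    stop("invalid spec: open_quotient_target must be in (0, 1]",
         call. = FALSE)
  }
  if (abs(speed_index_target) >= 1) {
    stop("invalid spec: speed_index_target must be in (-1, 1)",
         call. = FALSE)
  }
  if (left_right_amp_ratio <= 0 || left_right_amp_ratio > 1) {
    stop("invalid spec: left_right_amp_ratio must be in (0, 1]",
         call. = FALSE)
  }
  if (glottal_floor < 0 || glottal_floor >= 1) {
    stop("invalid spec: glottal_floor must be in [0, 1)", call. = FALSE)
  }
  if (duration * f0 < 3) {
    stop("invalid spec: need at least 3 cycles (duration * f0 >= 3)",
         call. = FALSE)
  }
  structure(
    list(f0 = f0, duration = duration, fps = fps, audio_rate = audio_rate,
         open_quotient_target = open_quotient_target,
         speed_index_target = speed_index_target,
         left_right_amp_ratio = left_right_amp_ratio,
         left_right_phase_lag = left_right_phase_lag,
         jitter_sigma = jitter_sigma, shimmer_sigma = shimmer_sigma,
         glottal_floor = glottal_floor, image_size = image_size,
         midline_angle = midline_angle, noise = noise,
         audio_snr_db = audio_snr_db, seed = as.integer(seed)),
    class = "phonation_spec"
  )
}

#' @export
print.phonation_spec <- function(x, ...) {
  cat(sprintf(
    "Phonation spec: F0 %g Hz, %.3f s @ %g fps / %g Hz audio (seed %d)\n",
    x$f0, x$duration, x$fps, x$audio_rate, x$seed))
  cat(sprintf(
    "  OQ %.2f, SI %.2f, floor %.2f, L/R amp %.2f, lag %.3f, jitter %.2g s, shimmer %.2g\n",
    x$open_quotient_target, x$speed_index_target, x$glottal_floor,
    x$left_right_amp_ratio, x$left_right_phase_lag, x$jitter_sigma,
    x$shimmer_sigma))
  invisible(x)
}

# Opening template g(tau) in [0, 1] over one cycle of period T: closed
# margins of (1-OQ)T/2 at both ends, rise over t_opening, fall over
# t_closing. With a closed phase (OQ < 1) the edges take off linearly --
# vocal-fold collision ends the cycle abruptly -- so the rasterized closure
# instant stays sharp; without one (OQ = 1) the folds never collide and the
# waveform touches its minimum smoothly (zero derivative), so the sampled
# minimum reflects the glottal floor rather than sampling phase.
cycle_level <- function(tau, T_, oq, si) {
  D <- oq * T_
  t_op <- D * (1 + si) / 2
  t_cl <- D - t_op
  lead <- (1 - oq) * T_ / 2
  u <- tau - lead
  if (oq >= 0.999) {
    ifelse(u < 0 | u > D, 0,
           ifelse(u <= t_op, 0.5 * (1 - cos(pi * u / t_op)),
                  0.5 * (1 + cos(pi * (u - t_op) / t_cl))))
  } else {
    ifelse(u < 0 | u > D, 0,
           ifelse(u <= t_op, sin(pi / 2 * u / t_op),
                  cos(pi / 2 * (u - t_op) / t_cl)))
  }
}

#' Generate the ground-truth glottal area schedule
#'
#' Builds the per-cycle sequence (periods, amplitude factors, phase times)
#' and evaluates per-frame dimensionless opening levels for the left and
#' right fold, including the amplitude ratio and phase lag between folds.
#'
#' @param spec a [phonation_spec()].
#' @return list with `frame_times` (s), `level_left`, `level_right`,
#'   `level_total` (per frame), `cycles` (data frame: `start_s`, `period_s`,
#'   `amp_factor`, `t_opening_s`, `t_closing_s`) and the generating
#'   [phonation_spec()].
#' @export
synth_gaw_schedule <- function(spec) {
  set.seed(spec$seed)
  T0 <- 1 / spec$f0
  starts <- numeric(0)
  periods <- numeric(0)
  amps <- numeric(0)
  t <- 0
  # cover the video duration plus one lagged period
  while (t < spec$duration + 2 * T0) {
    Ti <- T0 + stats::rnorm(1, 0, spec$jitter_sigma)
    Ti <- min(max(Ti, 0.6 * T0), 1.4 * T0)
    mi <- max(0.1, 1 + stats::rnorm(1, 0, spec$shimmer_sigma))
    starts <- c(starts, t)
    periods <- c(periods, Ti)
    amps <- c(amps, mi)
    t <- t + Ti
  }
  oq <- spec$open_quotient_target
  si <- spec$speed_index_target
  floorv <- spec$glottal_floor
  level_at <- function(times) {
    idx <- findInterval(times, starts)
    idx[idx < 1L] <- 1L
    tau <- times - starts[idx]
    g <- cycle_level(tau, periods[idx], oq, si)
    amps[idx] * (floorv + (1 - floorv) * g)
  }
  nfr <- floor(spec$duration * spec$fps)
  frame_times <- (seq_len(nfr) - 1L) / spec$fps
  lag_s <- spec$left_right_phase_lag * T0
  right <- level_at(frame_times)
  left <- spec$left_right_amp_ratio * level_at(frame_times - lag_s)
  D <- oq * periods
  cyc <- data.frame(start_s = starts, period_s = periods, amp_factor = amps,
                    t_opening_s = D * (1 + si) / 2,
                    t_closing_s = D * (1 - si) / 2)
  list(frame_times = frame_times, level_left = left, level_right = right,
       level_total = left + right, cycles = cyc, spec = spec)
}

#' Render the synthetic high-speed video with ground-truth masks
#'
#' The glottis is a dark lens (two opposed parabolic edges about the
#' midline, zero displacement at the anterior/posterior endpoints) whose
#' per-side lateral width follows the schedule's hemi levels, on bright
#' textured tissue with additive Gaussian pixel noise. Exact rasterized
#' ground-truth masks are returned alongside.
#'
#' @param spec a [phonation_spec()].
#' @param schedule result of [synth_gaw_schedule()].
#' @return list with `video` ([video_frames()]), `masks` (ground-truth
#'   [segmentation_sequence()]), `area_left_px`, `area_right_px` (analytic
#'   continuous areas per frame) and midline geometry (`posterior_point`,
#'   `anterior_point`).
#' @export
render_video <- function(spec, schedule) {
  s <- spec$image_size
  L <- 0.72 * s
  wpeak <- 0.16 * s
  if (s < 16) stop("image too small for the glottis shape", call. = FALSE)
  ctr <- c((s - 1) / 2, (s - 1) / 2)
  th <- spec$midline_angle * pi / 180
  dirv <- c(sin(th), cos(th))  # posterior (top) -> anterior (bottom)
  P <- ctr - L / 2 * dirv
  A <- ctr + L / 2 * dirv
  xs <- matrix(rep(0:(s - 1), each = s), s)   # x = column index, 0-based
  ys <- matrix(rep(0:(s - 1), times = s), s)  # y = row index
  sg <- (xs - P[1]) * dirv[1] + (ys - P[2]) * dirv[2]
  dg <- (xs - P[1]) * dirv[2] - (ys - P[2]) * dirv[1]  # >0 image-right
  shape <- ifelse(sg >= 0 & sg <= L, 4 * sg * (L - sg) / L^2, -1)
  nfr <- length(schedule$frame_times)
  set.seed(spec$seed + 1L)
  tex <- filter2_sep(matrix(stats::rnorm(s^2), s, s), gaussian_kernel1d(1.5))
  tex <- tex / stats::sd(tex) * 12
  frames <- array(0, dim = c(s, s, nfr))
  masks <- array(0L, dim = c(s, s, nfr))
  for (i in seq_len(nfr)) {
    wl <- wpeak * schedule$level_left[i]
    wr <- wpeak * schedule$level_right[i]
    mask <- (dg <= 0 & -dg < wl * shape & shape > 0) |
            (dg > 0 & dg < wr * shape & shape > 0)
    img <- 180 + tex
    img[mask] <- 20 + 0.3 * tex[mask]
    if (spec$noise > 0) {
      img <- img + matrix(stats::rnorm(s^2, 0, spec$noise), s, s)
    }
    frames[, , i] <- pmax(0, pmin(255, img))
    masks[, , i] <- mask
  }
  list(video = video_frames(frames, spec$fps),
       masks = segmentation_sequence(masks, spec$fps),
       area_left_px = (2 / 3) * L * wpeak * schedule$level_left,
       area_right_px = (2 / 3) * L * wpeak * schedule$level_right,
       posterior_point = P, anterior_point = A)
}

# Rosenberg-type glottal flow pulse sampled at tau within a cycle. The
# pulse durations are fixed fractions of the NOMINAL period T0 (not the
# perturbed per-cycle period): period jitter is realized as onset-timing
# perturbation with a stable intra-cycle flow shape, so a cycle-locked
# landmark carries the full injected period perturbation.
rosenberg_pulse <- function(tau, T0) {
  tp <- 0.40 * T0
  tn <- 0.16 * T0
  ifelse(tau < 0, 0,
         ifelse(tau <= tp, 0.5 * (1 - cos(pi * tau / tp)),
                ifelse(tau <= tp + tn, cos(pi / 2 * (tau - tp) / tn), 0)))
}

#' Render the paired audio and camera reference channels
#'
#' Channel 1 (microphone): the time derivative of a Rosenberg glottal flow
#' pulse train sharing the schedule's per-cycle onsets and amplitudes (the
#' radiated acoustic pressure is proportional to the flow derivative), plus
#' white noise at `audio_snr_db`. Channel 2 (reference): one unit pulse per
#' video frame at `audio_rate / fps` spacing, ceasing at the end trigger,
#' followed by 1 s of quiet tail.
#'
#' @param spec a [phonation_spec()].
#' @param schedule result of [synth_gaw_schedule()].
#' @return list with `recording` ([two_channel_recording()]) and `truth`
#'   (list: `frame_pulse_samples`, `end_trigger_sample`, `n_frames`).
#' @export
render_audio <- function(spec, schedule) {
  sr <- spec$audio_rate
  nfr <- length(schedule$frame_times)
  n_total <- round(nfr / spec$fps * sr) + round(sr)  # + 1 s tail
  tt <- (seq_len(n_total) - 1L) / sr
  cyc <- schedule$cycles
  T0 <- 1 / spec$f0
  idx <- findInterval(tt, cyc$start_s)
  idx[idx < 1L] <- 1L
  tau <- tt - cyc$start_s[idx]
  flow <- cyc$amp_factor[idx] * rosenberg_pulse(tau, T0)
  voice <- c(0, diff(flow)) * sr  # radiated pressure ~ flow derivative
  voice[tt > spec$duration] <- 0
  voice <- voice / max(abs(voice)) * 0.8
  set.seed(spec$seed + 2L)
  if (is.finite(spec$audio_snr_db)) {
    rms <- sqrt(mean(voice[tt <= spec$duration]^2))
    noise_sd <- rms / 10^(spec$audio_snr_db / 20)
    voice <- voice + stats::rnorm(n_total, 0, noise_sd)
  }
  pulses <- as.integer(round((seq_len(nfr) - 1L) * (sr / spec$fps))) + 1L
  reference <- numeric(n_total)
  reference[pulses] <- 1
  truth <- list(frame_pulse_samples = pulses,
                end_trigger_sample = pulses[nfr],
                n_frames = nfr)
  list(recording = two_channel_recording(voice, reference, sample_rate = sr,
                                         bit_depth = 24L),
       truth = truth)
}

#' Generate a complete synthetic recording
#'
#' Convenience wrapper: schedule + rendered video/masks + paired audio.
#'
#' @param spec a [phonation_spec()].
#' @param render_frames if FALSE, skip rendering the textured video frames
#'   (ground-truth masks are still produced), which is faster when only the
#'   GAW-side pipeline is exercised.
#' @return list with `spec`, `schedule`, `video`, `masks`, `audio`
#'   (recording), `truth` (alignment ground truth) and analytic per-frame
#'   areas.
#' @export
synth_recording <- function(spec, render_frames = TRUE) {
  schedule <- synth_gaw_schedule(spec)
  vid <- render_video(spec, schedule)
  au <- render_audio(spec, schedule)
  list(spec = spec, schedule = schedule,
       video = if (render_frames) vid$video else NULL,
       masks = vid$masks,
       area_left_px = vid$area_left_px, area_right_px = vid$area_right_px,
       true_midline = structure(
         list(anchor_frame = 1L,
              centroid = (vid$posterior_point + vid$anterior_point) / 2,
              direction = (vid$anterior_point - vid$posterior_point) /
                sqrt(sum((vid$anterior_point - vid$posterior_point)^2)),
              posterior_point = vid$posterior_point,
              anterior_point = vid$anterior_point,
              degenerate = FALSE),
         class = "midline_estimate"),
       audio = au$recording, truth = au$truth)
}
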