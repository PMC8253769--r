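# Audio-video alignment from the camera reference channel.

make_pulse_train <- function(n_total, spacing, stop_sample,
                             amplitude = 1, polarity = 1) {
  ref <- numeric(n_total)
  idx <- seq(1, stop_sample, by = spacing)
  ref[idx] <- amplitude * polarity
  list(ref = ref, pulses = idx)
}

test_that("rolling_std matches closed-form values and checks its window", {
  expect_equal(rolling_std(rep(3.7, 1000), 2.5, 80000), rep(0, 1000))

  x <- rep(c(1, -1), 500)
  rs <- rolling_std(x, 2.5, 80000)  # 200-sample window
  expect_equal(length(rs), 1000)
  expect_true(all(abs(rs[200:800] - 1) < 1e-9))

  # 2.5 ms at 80 kHz is a 200-sample window: a 199-sample constant block
  # inside a +/-1 train is not enough to zero any centered window
  expect_true(min(rolling_std(c(rep(c(1, -1), 200), rep(0, 199),
                                rep(c(1, -1), 200)), 2.5, 80000)) > 0)

  expect_error(rolling_std(numeric(0), 2.5, 80000), "empty")
  expect_error(rolling_std(rnorm(100), 0.005, 80000), "at least 2")
})

test_that("detect_end_trigger finds the pulsed-to-quiescent transition", {
  sr <- 80000
  pt <- make_pulse_train(240000, 20, 160000)
  rec <- two_channel_recording(numeric(240000), pt$ref, sr)
  trig <- detect_end_trigger(rec)
  expect_lt(abs(trig - 160000), 200)

  # negative-polarity pulses work the same (std is polarity-blind)
  ptn <- make_pulse_train(240000, 20, 160000, polarity = -1)
  recn <- two_channel_recording(numeric(240000), ptn$ref, sr)
  expect_lt(abs(detect_end_trigger(recn) - 160000), 200)

  expect_error(
    detect_end_trigger(two_channel_recording(numeric(1e5), numeric(1e5), sr)),
    "trigger not found")
  full <- make_pulse_train(240000, 20, 240000)
  expect_error(
    detect_end_trigger(two_channel_recording(numeric(240000), full$ref, sr)),
    "trigger not found")
})

test_that("detect_frame_pulses counts frames and measures spacing", {
  sr <- 80000
  pt <- make_pulse_train(160000, 20, 80000)  # 1 s at 4000 fps + tail
  rec <- two_channel_recording(numeric(160000), pt$ref, sr)
  al <- detect_frame_pulses(rec, end_trigger = 80000, fps = 4000)
  expect_s3_class(al, "alignment_result")
  expect_equal(al$n_frames_detected, 4000)
  expect_equal(stats::median(diff(al$frame_pulse_samples)), 20)
  expect_equal(al$samples_per_frame, 20)
  expect_true(all(diff(al$frame_pulse_samples) > 0))
  expect_true(all(al$frame_pulse_samples <= 80000))

  # +/-1 sample timing noise does not change the pulse count
  set.seed(42)
  idx <- pt$pulses + sample(-1:1, length(pt$pulses), replace = TRUE)
  idx <- sort(unique(pmax(1, idx)))
  refj <- numeric(160000); refj[idx] <- 1
  alj <- detect_frame_pulses(two_channel_recording(numeric(160000), refj, sr),
                             80000, fps = 4000)
  expect_equal(alj$n_frames_detected, length(idx))
  expect_equal(alj$n_frames_detected, 4000)

  two <- make_pulse_train(4000, 20, 40)
  al2 <- detect_frame_pulses(two_channel_recording(numeric(4000), two$ref, sr),
                             2000, fps = 4000)
  expect_equal(al2$n_frames_detected, 2)

  one <- make_pulse_train(4000, 20, 20)
  expect_error(
    detect_frame_pulses(two_channel_recording(numeric(4000), one$ref, sr),
                        2000, fps = 4000),
    "insufficient pulses")

  # off-nominal spacing (wrong fps metadata) warns
  expect_warning(
    detect_frame_pulses(rec, 80000, fps = 3500),
    "deviates")
})

test_that("extract_audio_segment maps frame ranges to sample ranges", {
  sr <- 80000
  pt <- make_pulse_train(160000, 20, 80000)
  audio <- sin(2 * pi * 200 * (0:159999) / sr)
  rec <- two_channel_recording(audio, pt$ref, sr)
  al <- detect_frame_pulses(rec, 80000, fps = 4000)

  seg <- extract_audio_segment(rec, al, 0, 3999)
  expect_lte(abs(length(seg$samples) - 80000), 20)
  expect_equal(seg$samples[1], audio[al$frame_pulse_samples[1]])

  one <- extract_audio_segment(rec, al, 100, 100)
  expect_lte(abs(length(one$samples) - al$samples_per_frame), 1)

  expect_error(extract_audio_segment(rec, al, 0, 4000), "out of range")
  expect_error(extract_audio_segment(rec, al, -1, 10), "out of range")
  expect_error(extract_audio_segment(rec, al, 30, 10), "out of range")
})

test_that("recording constructor enforces its invariants", {
  expect_error(two_channel_recording(1:5, 1:4), "equal length")
  expect_error(two_channel_recording(1:5, 1:5, sample_rate = 0), "positive")
})

test_that("alignment round-trips on generated recordings across seeds", {
  # synthetic recordings with known trigger sample and frame count
  for (s in 1:20) {
    set.seed(s)
    f0 <- runif(1, 150, 350)
    spec <- phonation_spec(f0 = f0, duration = 0.08, seed = s)
    sch <- synth_gaw_schedule(spec)
    au <- render_audio(spec, sch)
    w <- round(2.5e-3 * spec$audio_rate)
    trig <- detect_end_trigger(au$recording)
    expect_lte(abs(trig - au$truth$end_trigger_sample), w)
    al <- detect_frame_pulses(au$recording, trig, fps = spec$fps)
    expect_identical(al$n_frames_detected, au$truth$n_frames)
    expect_identical(al$frame_pulse_samples, au$truth$frame_pulse_samples)
    expect_true(all(diff(al$frame_pulse_samples) > 0))
    # noise-free spacing deviates at most 1 sample from sample_rate/fps
    expect_lte(max(abs(diff(al$frame_pulse_samples) -
                       al$samples_per_frame)), 1)
  }
})
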