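# Shared in-code fixtures; everything is generated at test time.

# Raised-sinusoid GAW of identical, exactly time-symmetric cycles:
# a(t) = amp/2 * (1 - cos(2 pi t / period)), an integer number of frames per
# half-cycle, minima exactly 0 at the cycle boundaries.
symmetric_gaw <- function(n_cycles = 25, period_frames = 16, fps = 4000,
                          amp = 100) {
  t <- 0:(n_cycles * period_frames)
  gaw(amp / 2 * (1 - cos(2 * pi * t / period_frames)), fps)
}

# Identical asymmetric triangle cycles: rise `up` frames, fall `down`
# frames, peak amp = step * up.
triangle_gaw <- function(n_cycles = 10, up = 3, down = 1, fps = 4000,
                         step = 3) {
  cyc <- c(seq(0, step * up, by = step)[-(up + 1)],
           seq(step * up, 0, length.out = down + 1)[-(down + 1)])
  gaw(c(rep(cyc, n_cycles), 0), fps)
}

# Filled ellipse mask (0-based center coordinates, axes in px).
ellipse_mask <- function(h, w, cx, cy, ax, ay, angle_deg = 0) {
  xs <- matrix(rep(0:(w - 1), each = h), h)
  ys <- matrix(rep(0:(h - 1), times = w), h)
  th <- angle_deg * pi / 180
  u <- cos(th) * (xs - cx) + sin(th) * (ys - cy)
  v <- -sin(th) * (xs - cx) + cos(th) * (ys - cy)
  ((u / ax)^2 + (v / ay)^2 <= 1) * 1L
}

# Minimal cycle_set pointing at given anchor frames (for midline/PVG tests
# that operate on hand-built masks).
fake_cycles <- function(max_frames, n_stack) {
  cyc <- data.frame(start = pmax(1L, max_frames - 1L),
                    max_frame = as.integer(max_frames),
                    end = pmin(n_stack, max_frames + 1L))
  cyc$period_s <- (cyc$end - cyc$start) / 4000
  cyc$a_min <- 0
  cyc$a_max <- 1
  cyc$amplitude <- 1
  attr(cyc, "frame_rate") <- 4000
  class(cyc) <- c("cycle_set", "data.frame")
  cyc
}

# Periodic multi-harmonic voice with integer sample period (exactly
# periodic), optionally with white noise at a given SNR.
harmonic_voice <- function(n = 20000, period = 320, snr_db = Inf,
                           sr = 80000) {
  t <- seq_len(n) - 1
  x <- sin(2 * pi * t / period) + 0.5 * sin(4 * pi * t / period + 0.8) +
    0.25 * sin(6 * pi * t / period + 1.7)
  if (is.finite(snr_db)) {
    x <- x + stats::rnorm(n, 0, stats::sd(x) / 10^(snr_db / 20))
  }
  x
}
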