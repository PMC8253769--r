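# Clinical voice parameters: 18 GAW-based and 9 audio-based measures
# computed from detected cycles, hemi-GAWs and the aligned audio signal.
# Cycle-based measures (jitter, shimmer, F0, phase quotients, perturbation
# quotients) use per-cycle period and amplitude sequences; HNR and CPP use
# the complete audio signal. Every formula is identified by a formula_id in
# the report so exported CSVs are self-describing.

#' Fundamental frequency from detected cycles
#'
#' F0 = 1 / mean(T_i) over complete cycles. For reliable clinical reporting
#' at least 20 cycles are recommended.
#'
#' @param cycles a `cycle_set` (from the GAW or from audio cycle detection).
#' @return F0 in Hz.
#' @export
fundamental_frequency <- function(cycles) {
  if (nrow(cycles) < 2L) {
    stop("too few cycles: need at least 2 for F0", call. = FALSE)
  }
  1 / mean(cycles$period_s)
}

#' Cycle-to-cycle period perturbation (jitter)
#'
#' @param cycles a `cycle_set`.
#' @return list with `mean_jitter_ms` = mean |T_{i+1} - T_i| in ms and
#'   `jitter_pct` = 100 * mean |T_{i+1} - T_i| / mean(T_i).
#' @export
jitter <- function(cycles) {
  T_ <- cycles$period_s
  if (length(T_) < 2L) stop("too few cycles for jitter", call. = FALSE)
  dT <- abs(diff(T_))
  list(mean_jitter_ms = mean(dT) * 1000,
       jitter_pct = 100 * mean(dT) / mean(T_))
}

#' Cycle-to-cycle amplitude perturbation (shimmer)
#'
#' @param cycles a `cycle_set`; amplitudes are per-cycle peak-to-trough
#'   (`a_max - a_min`), so the measure is offset-independent.
#' @return list with `mean_shimmer_db` = mean |20 log10(A_{i+1}/A_i)| and
#'   `shimmer_pct` = 100 * mean |A_{i+1} - A_i| / mean(A_i).
#' @export
shimmer <- function(cycles) {
  A <- cycles$amplitude
  if (length(A) < 2L) stop("too few cycles for shimmer", call. = FALSE)
  if (any(A <= 0)) stop("nonpositive cycle amplitude", call. = FALSE)
  list(mean_shimmer_db = mean(abs(20 * log10(A[-1] / A[-length(A)]))),
       shimmer_pct = 100 * mean(abs(diff(A))) / mean(A))
}

#' Phase-duration quotients of the glottal cycle
#'
#' Per-cycle values averaged over cycles: OQ = t_open / T,
#' CQ = t_closing / t_open, SQ = t_opening / t_closing,
#' AQ = t_opening / (t_opening + t_closing),
#' RQ = (t_closed + t_opening) / t_closing,
#' SI = (t_opening - t_closing) / (t_opening + t_closing).
#' Cycles with a zero closing phase are excluded from SQ/RQ (and from
#' CQ/AQ/SI if the whole open phase is degenerate) with a warning.
#'
#' @param cycles a `cycle_set` with phases from [decompose_phases()].
#' @return list with elements `OQ`, `CQ`, `SQ`, `AQ`, `RQ`, `SI`.
#' @export
phase_quotients <- function(cycles) {
  if (is.null(cycles$t_opening_s)) {
    stop("phases not decomposed; run decompose_phases() first", call. = FALSE)
  }
  to <- cycles$t_opening_s
  tc <- cycles$t_closing_s
  topen <- cycles$t_open_s
  tclosed <- cycles$t_closed_s
  T_ <- cycles$period_s
  ok_open <- topen > 0
  if (!all(ok_open)) warning("cycles with zero open phase excluded")
  ok_closing <- tc > 0
  if (!all(ok_closing)) {
    warning("cycles with zero closing phase excluded from SQ/RQ")
  }
  list(
    OQ = mean(topen[ok_open] / T_[ok_open]),
    CQ = mean(tc[ok_open] / topen[ok_open]),
    SQ = mean(to[ok_closing] / tc[ok_closing]),
    AQ = mean(to[ok_open] / topen[ok_open]),
    RQ = mean((tclosed[ok_closing] + to[ok_closing]) / tc[ok_closing]),
    SI = mean((to[ok_open] - tc[ok_open]) / topen[ok_open])
  )
}

#' Glottal gap index
#'
#' Residual relative opening at maximal closure: mean over cycles of
#' a_min / a_max. 0 for full closure every cycle.
#'
#' @param cycles a `cycle_set`.
#' @return GGI in \[0, 1\].
#' @export
glottal_gap_index <- function(cycles) {
  ok <- cycles$a_max > 0
  if (!all(ok)) warning("cycles with zero maximum area excluded from GGI")
  if (!any(ok)) stop("no cycle with positive maximum area", call. = FALSE)
  mean(cycles$a_min[ok] / cycles$a_max[ok])
}

#' Amplitude quotient of the GAW
#'
#' Per cycle: amplitude divided by the magnitude of the steepest area
#' decline, AQamp_i = A_i / |min dA/dt| with dt in frames; mean over cycles.
#' Dimensionless (frames); scale-invariant in the area.
#'
#' @param x a [gaw()].
#' @param cycles a `cycle_set`.
#' @return mean amplitude quotient.
#' @export
amplitude_quotient <- function(x, cycles) {
  a <- x$area
  vals <- vapply(seq_len(nrow(cycles)), function(i) {
    seg <- a[cycles$start[i]:cycles$end[i]]
    dmin <- min(diff(seg))
    if (dmin >= 0) return(NA_real_)
    cycles$amplitude[i] / abs(dmin)
  }, numeric(1))
  if (anyNA(vals)) warning("cycles without negative area derivative excluded")
  mean(vals, na.rm = TRUE)
}

#' Stiffness measure of the GAW
#'
#' Per cycle: mean absolute frame-to-frame area change divided by the cycle
#' amplitude; mean over cycles. Scale-invariant.
#'
#' @param x a [gaw()].
#' @param cycles a `cycle_set`.
#' @return mean stiffness (dimensionless).
#' @export
stiffness <- function(x, cycles) {
  a <- x$area
  ok <- cycles$amplitude > 0
  if (!all(ok)) warning("cycles with zero amplitude excluded from stiffness")
  vals <- vapply(which(ok), function(i) {
    seg <- a[cycles$start[i]:cycles$end[i]]
    mean(abs(diff(seg))) / cycles$amplitude[i]
  }, numeric(1))
  mean(vals)
}

#' Left/right symmetry indices from hemi-GAWs
#'
#' Per cycle (boundaries from the total GAW): hemi amplitudes A_L, A_R
#' (max - min within the cycle) and hemi-maximum times t_L, t_R.
#' ASI_i = min(A_L, A_R) / max(A_L, A_R);
#' PAI_i = |t_L - t_R| / T_i, wrapped to <= 0.5. Means over cycles.
#'
#' @param hemi a `hemi_gaw` from [split_hemi_gaw()].
#' @param cycles a `cycle_set` from the total GAW.
#' @return list with `ASI` and `PAI`.
#' @export
symmetry_indices <- function(hemi, cycles) {
  n <- nrow(cycles)
  asi <- pai <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s <- cycles$start[i]; e <- cycles$end[i]
    l <- hemi$left_area[s:e]
    r <- hemi$right_area[s:e]
    al <- max(l) - min(l)
    ar <- max(r) - min(r)
    if (al <= 0 || ar <= 0) next
    asi[i] <- min(al, ar) / max(al, ar)
    lag <- abs(which.max(l) - which.max(r)) / (e - s)
    pai[i] <- min(lag, 1 - lag)
  }
  if (anyNA(asi)) warning("cycles with zero hemi amplitude excluded")
  list(ASI = mean(asi, na.rm = TRUE), PAI = mean(pai, na.rm = TRUE))
}

#' Amplitude perturbation factor and quotients
#'
#' APF = 100 * mean over i of |A_i - A_{i+1}| / A_i;
#' APQk = 100 * mean over valid i of |A_i - mean(k-window around i)| /
#' mean(A). Windows with too few cycles give NA.
#'
#' @param cycles a `cycle_set`.
#' @param windows odd window sizes for APQ (default c(3, 5, 11)).
#' @return list with `APF` and one `APQk` per window.
#' @export
amplitude_perturbation <- function(cycles, windows = c(3L, 5L, 11L)) {
  A <- cycles$amplitude
  n <- length(A)
  out <- list(APF = if (n >= 2L) {
    100 * mean(abs(A[-n] - A[-1]) / A[-n])
  } else NA_real_)
  for (k in windows) {
    h <- (k - 1L) %/% 2L
    nm <- paste0("APQ", k)
    if (n < k) {
      out[[nm]] <- NA_real_
      next
    }
    idx <- (h + 1L):(n - h)
    devs <- vapply(idx, function(i) {
      abs(A[i] - mean(A[(i - h):(i + h)]))
    }, numeric(1))
    out[[nm]] <- 100 * mean(devs) / mean(A)
  }
  out
}

# --- audio-side cycle detection -------------------------------------------

# Autocorrelation F0 prior with parabolic interpolation of the peak lag.
acf_f0 <- function(audio, sample_rate, f0_range = c(60, 500)) {
  x <- audio - mean(audio)
  n <- length(x)
  nfft <- 2^ceiling(log2(2 * n))
  X <- stats::fft(c(x, rep(0, nfft - n)))
  ac <- Re(stats::fft(Mod(X)^2, inverse = TRUE))[1:n] / nfft
  lag_min <- max(2L, floor(sample_rate / f0_range[2]))
  lag_max <- min(n - 2L, ceiling(sample_rate / f0_range[1]))
  if (lag_max <= lag_min) stop("signal too short for F0 search", call. = FALSE)
  seg <- ac[(lag_min + 1L):(lag_max + 1L)]
  k <- which.max(seg) + lag_min  # lag in samples
  # parabolic interpolation around the peak
  y0 <- ac[k]; ym <- ac[k - 1L]; yp <- ac[k + 1L]
  denom <- ym - 2 * y0 + yp
  delta <- if (denom != 0) 0.5 * (ym - yp) / denom else 0
  sample_rate / (k - 1 + delta)
}

# Zero-phase band-pass via FFT masking.
fft_bandpass <- function(x, sample_rate, lo, hi) {
  n <- length(x)
  X <- stats::fft(x)
  freqs <- (seq_len(n) - 1) * sample_rate / n
  freqs <- pmin(freqs, sample_rate - freqs)  # two-sided
  X[freqs < lo | freqs > hi] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Detect phonation cycles in an audio waveform
#'
#' An autocorrelation F0 prior (with parabolic peak interpolation) guides a
#' band-pass (0.5-1.5 x F0) of the waveform whose peaks give coarse cycle
#' marks; the period of each cycle is then measured by waveform matching:
#' the lag maximizing the cross-correlation of the raw waveform between
#' consecutive marks, with parabolic sub-sample interpolation. Pairs whose
#' matched lag deviates more than 30% from the F0 prior (octave errors,
#' missed marks) are rejected. Per-cycle amplitudes are peak-to-trough of
#' the raw waveform within the cycle.
#'
#' @param audio numeric waveform.
#' @param sample_rate Hz.
#' @param f0_range F0 search range in Hz (default 60-500).
#' @return a `cycle_set`-compatible data frame with `period_s` and
#'   `amplitude` (plus `start`/`end` sample indices); `attr(,"f0_prior")`
#'   holds the autocorrelation prior.
#' @export
detect_audio_cycles <- function(audio, sample_rate, f0_range = c(60, 500)) {
  x <- audio - mean(audio)
  f0p <- acf_f0(x, sample_rate, f0_range)
  bp <- fft_bandpass(x, sample_rate, 0.5 * f0p, 1.5 * f0p)
  dist <- floor(0.5 * sample_rate / f0p)
  pk <- find_peaks(bp, min_height = 0.3 * max(bp), min_distance = dist)
  if (length(pk) < 3L) {
    stop("too few cycles detected in audio signal", call. = FALSE)
  }
  n <- length(x)
  h <- round(0.6 * sample_rate / f0p)   # matching segment half-length
  W <- round(0.2 * sample_rate / f0p)   # lag search half-width
  nominal <- sample_rate / f0p
  starts <- ends <- integer(0)
  periods <- numeric(0)
  for (i in seq_len(length(pk) - 1L)) {
    m <- pk[i]
    l0 <- pk[i + 1L] - m
    if (abs(l0 - nominal) > 0.3 * nominal) next
    if (m - h < 1L || m + h + l0 + W > n) next
    a <- x[(m - h):(m + h)]
    ea <- sum(a^2)
    lags <- (l0 - W):(l0 + W)
    cors <- vapply(lags, function(l) {
      b <- x[(m - h + l):(m + h + l)]
      sum(a * b) / sqrt(ea * sum(b^2))
    }, numeric(1))
    j <- which.max(cors)
    d <- 0
    if (j > 1L && j < length(cors)) {
      den <- cors[j - 1L] - 2 * cors[j] + cors[j + 1L]
      if (den < 0) d <- 0.5 * (cors[j - 1L] - cors[j + 1L]) / den
    }
    Ti <- (lags[j] + d) / sample_rate
    if (abs(Ti * f0p - 1) > 0.3) next
    starts <- c(starts, m)
    ends <- c(ends, pk[i + 1L])
    periods <- c(periods, Ti)
  }
  if (length(periods) < 2L) {
    stop("too few cycles detected in audio signal", call. = FALSE)
  }
  amp <- vapply(seq_along(starts), function(i) {
    seg <- x[starts[i]:(ends[i] - 1L)]
    max(seg) - min(seg)
  }, numeric(1))
  cyc <- data.frame(start = starts, end = ends, period_s = periods,
                    amplitude = amp)
  attr(cyc, "f0_prior") <- f0p
  attr(cyc, "sample_rate") <- sample_rate
  class(cyc) <- c("cycle_set", "data.frame")
  cyc
}

#' Harmonics-to-noise ratio (Yumoto method)
#'
#' Each detected cycle is resampled to the mean cycle length; HNR is the
#' energy of the mean waveform over the mean cycle-to-cycle residual:
#' HNR = 10 log10( N * sum(f_bar^2) / sum_i sum_t (f_i - f_bar)^2 ).
#'
#' @param audio numeric waveform.
#' @param cycles audio `cycle_set` from [detect_audio_cycles()].
#' @param sample_rate Hz.
#' @param cap_db cap for (near-)zero residual (default 120 dB).
#' @return HNR in dB.
#' @export
hnr <- function(audio, cycles, sample_rate, cap_db = 120) {
  if (nrow(cycles) < 5L) stop("need at least 5 audio cycles for HNR",
                              call. = FALSE)
  x <- audio - mean(audio)
  if (all(x == 0)) stop("HNR undefined for silent signal", call. = FALSE)
  L <- round(mean(cycles$end - cycles$start))
  N <- nrow(cycles)
  mat <- matrix(0, nrow = L, ncol = N)
  for (i in seq_len(N)) {
    seg <- x[cycles$start[i]:(cycles$end[i] - 1L)]
    mat[, i] <- stats::approx(seq_along(seg), seg, n = L)$y
  }
  # integer-shift alignment of each resampled cycle to the first one
  # (pitch periods are aligned before averaging; guards against sub-cycle
  # mark placement drift)
  ref_cycle <- mat[, 1]
  maxshift <- min(3L, L %/% 4L)
  for (i in seq_len(N)[-1]) {
    best <- 0L
    bestcor <- -Inf
    for (sh in -maxshift:maxshift) {
      a <- mat[max(1L, 1L + sh):min(L, L + sh), i]
      b <- ref_cycle[max(1L, 1L - sh):min(L, L - sh)]
      cc <- sum(a * b)
      if (cc > bestcor) {
        bestcor <- cc
        best <- sh
      }
    }
    if (best != 0L) {
      shifted <- rep(mat[1L, i], L)
      src <- max(1L, 1L + best):min(L, L + best)
      dst <- max(1L, 1L - best):min(L, L - best)
      shifted[dst] <- mat[src, i]
      mat[, i] <- shifted
    }
  }
  fbar <- rowMeans(mat)
  resid <- sum((mat - fbar)^2)
  if (resid <= .Machine$double.eps * sum(fbar^2)) return(cap_db)
  min(cap_db, 10 * log10(N * sum(fbar^2) / resid))
}

#' Cepstral peak prominence
#'
#' Smoothed-CPP variant: the complete signal is covered by half-overlapping
#' Hann frames whose dB power cepstra (log power spectrum of the log power
#' spectrum, in the Hillenbrand sense) are averaged, followed by a light
#' quefrency smoothing (0.1 ms moving average). The cepstral peak is then
#' located in the quefrency band of the F0 search range and its prominence
#' measured against a linear regression of cepstrum magnitude on quefrency
#' over that band. The averaging keeps the aperiodic (noise) score near
#' zero, which a single whole-signal cepstrum cannot do: its noise floor is
#' an extreme-value statistic of ~10 dB.
#'
#' @param audio numeric waveform (>= 4096 samples; all samples are used).
#' @param sample_rate Hz.
#' @param f0_search F0 search range in Hz (default 60-500); the quefrency
#'   band is its reciprocal.
#' @param smooth_s quefrency smoothing window in seconds (default 1e-4).
#' @return list with `cpp_db` and `peak_quefrency_s`.
#' @export
cpp <- function(audio, sample_rate, f0_search = c(60, 500),
                smooth_s = 1e-4) {
  x <- audio - mean(audio)
  n <- length(x)
  if (n < 4096L) stop("signal too short for CPP (need >= 4096 samples)",
                      call. = FALSE)
  flen <- max(4096L, 2^floor(log2(n / 4)))
  hop <- flen %/% 2L
  starts <- seq(1L, max(1L, n - flen + 1L), by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(flen) - 1) / (flen - 1))
  acc <- numeric(flen)
  for (s0 in starts) {
    seg <- x[s0:(s0 + flen - 1L)] * w
    S <- 10 * log10(Mod(stats::fft(seg))^2 + .Machine$double.eps)
    acc <- acc + Mod(stats::fft(S))^2 / flen
  }
  ceps <- 10 * log10(acc / length(starts) + .Machine$double.eps)
  sm <- max(1L, round(smooth_s * sample_rate))
  if (sm > 1L) {
    cs <- c(0, cumsum(ceps))
    idx <- seq_along(ceps)
    lo <- pmax(1L, idx - sm %/% 2L)
    hi <- pmin(length(ceps), idx + sm %/% 2L)
    ceps <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  quef <- (seq_len(flen) - 1) / sample_rate
  band <- which(quef >= 1 / f0_search[2] & quef <= 1 / f0_search[1])
  cb <- ceps[band]
  qb <- quef[band]
  ipk <- which.max(cb)
  fit <- stats::lm.fit(cbind(1, qb), cb)
  pred <- fit$coefficients[1] + fit$coefficients[2] * qb[ipk]
  list(cpp_db = cb[ipk] - pred, peak_quefrency_s = qb[ipk])
}

# --- report assembly -------------------------------------------------------

#' Assemble the full clinical parameter report
#'
#' Computes the 18 GAW-based parameters (given GAW + decomposed cycles, and
#' hemi-GAWs for the symmetry indices) and the 9 audio-based parameters
#' (given the aligned audio waveform). Missing inputs leave the
#' corresponding fields absent - never silently zero.
#'
#' @param gaw_signal a [gaw()], or NULL.
#' @param cycles `cycle_set` of the GAW with phases decomposed, or NULL.
#' @param hemi a `hemi_gaw`, or NULL.
#' @param audio numeric audio waveform, or NULL.
#' @param sample_rate audio sampling rate (required with `audio`).
#' @param f0_range audio F0 search range in Hz.
#' @return object of class `parameter_report`: list with elements `gaw` and
#'   `audio`, each a named list of values (units via
#'   [as.data.frame.parameter_report()]).
#' @export
compute_report <- function(gaw_signal = NULL, cycles = NULL, hemi = NULL,
                           audio = NULL, sample_rate = NULL,
                           f0_range = c(60, 500)) {
  rep_gaw <- NULL
  if (!is.null(gaw_signal) && !is.null(cycles)) {
    j <- jitter(cycles)
    s <- shimmer(cycles)
    pq <- phase_quotients(cycles)
    ap <- amplitude_perturbation(cycles)
    rep_gaw <- c(
      list(mean_jitter_ms = j$mean_jitter_ms, jitter_pct = j$jitter_pct,
           mean_shimmer_db = s$mean_shimmer_db, shimmer_pct = s$shimmer_pct,
           f0_hz = fundamental_frequency(cycles)),
      list(open_quotient = pq$OQ, closing_quotient = pq$CQ,
           speed_quotient = pq$SQ, asymmetry_quotient = pq$AQ,
           rate_quotient = pq$RQ, speed_index = pq$SI,
           glottal_gap_index = glottal_gap_index(cycles),
           amplitude_quotient = amplitude_quotient(gaw_signal, cycles),
           stiffness = stiffness(gaw_signal, cycles)),
      list(apf = ap$APF, apq3 = ap$APQ3, apq5 = ap$APQ5, apq11 = ap$APQ11)
    )
    if (!is.null(hemi)) {
      sy <- symmetry_indices(hemi, cycles)
      rep_gaw$amplitude_symmetry_index <- sy$ASI
      rep_gaw$phase_asymmetry_index <- sy$PAI
    }
  }
  rep_audio <- NULL
  if (!is.null(audio)) {
    if (is.null(sample_rate)) {
      stop("sample_rate required with audio input", call. = FALSE)
    }
    ac <- detect_audio_cycles(audio, sample_rate, f0_range)
    j <- jitter(ac)
    s <- shimmer(ac)
    ap <- amplitude_perturbation(ac)
    # whole-signal measures degrade to absent fields (never silently zero)
    # when the segment is too short or degenerate
    absent <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        warning(what, " not computed: ", conditionMessage(e))
        NA_real_
      })
    }
    rep_audio <- list(
      mean_jitter_ms = j$mean_jitter_ms, jitter_pct = j$jitter_pct,
      mean_shimmer_db = s$mean_shimmer_db, shimmer_pct = s$shimmer_pct,
      f0_hz = fundamental_frequency(ac),
      hnr_db = absent("HNR", hnr(audio, ac, sample_rate)),
      cpp_db = absent("CPP", cpp(audio, sample_rate,
                                 f0_search = f0_range)$cpp_db),
      apf = ap$APF, apq3 = ap$APQ3, apq5 = ap$APQ5, apq11 = ap$APQ11)
  }
  structure(list(gaw = rep_gaw, audio = rep_audio),
            class = "parameter_report")
}

report_units <- c(
  mean_jitter_ms = "ms", jitter_pct = "%", mean_shimmer_db = "dB",
  shimmer_pct = "%", f0_hz = "Hz", open_quotient = "au",
  closing_quotient = "au", speed_quotient = "au", asymmetry_quotient = "au",
  rate_quotient = "au", speed_index = "au", glottal_gap_index = "au",
  amplitude_quotient = "au", stiffness = "au",
  amplitude_symmetry_index = "au", phase_asymmetry_index = "au",
  apf = "au", apq3 = "au", apq5 = "au", apq11 = "au",
  hnr_db = "dB", cpp_db = "dB")

#' @export
as.data.frame.parameter_report <- function(x, ...) {
  rows <- list()
  for (src in c("gaw", "audio")) {
    part <- x[[src]]
    if (is.null(part)) next
    rows[[src]] <- data.frame(
      name = names(part),
      value = vapply(part, function(v) {
        if (is.null(v)) NA_real_ else as.numeric(v)
      }, numeric(1)),
      unit = unname(report_units[names(part)]),
      source_signal = if (src == "gaw") "GAW" else "Audio",
      formula_id = paste0(src, ".", names(part)),
      row.names = NULL)
  }
  do.call(rbind, rows)
}

#' @export
print.parameter_report <- function(x, ...) {
  df <- as.data.frame(x)
  if (is.null(df)) {
    cat("Parameter report: empty\n")
    return(invisible(x))
  }
  cat("Clinical parameter report\n")
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-26s %10.4f %-3s [%s]\n", df$name[i], df$value[i],
                df$unit[i], df$source_signal[i]))
  }
  invisible(x)
}
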