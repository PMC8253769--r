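# On-disk recording bundles and the pipeline driver.
#
# A recording bundle is a directory with: frames/ (lossless PGM frame
# stack), masks/ (PGM, 0/255), audio.wav (2-channel PCM: microphone +
# reference), metadata.json (acquisition + conventions + alignment),
# parameters.csv (the clinical report) and pvg.csv. Video from the clinic
# arrives as mp4/h264; this R implementation reads lossless frame
# directories (the round-trip-validated path) and leaves codec decoding to
# external tooling (e.g. ffmpeg -> PGM). Coordinates are 0-based, x right,
# y down; the convention is stamped into the metadata.

#' Write a grayscale matrix as binary PGM (P5)
#'
#' @param mat numeric matrix, values 0-255.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(mat, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(mat), nrow(mat)), con,
            eos = NULL)
  writeBin(as.raw(pmax(0, pmin(255, round(t(mat))))), con)
  invisible(path)
}

#' Read a PGM image (P2 or P5)
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # header: magic, width, height, maxval (comments skipped)
  buf <- character(0)
  while (length(tokens) < 4L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (!length(ch) || ch == "") stop("truncated PGM header: ", path,
                                      call. = FALSE)
    if (ch == "#") {
      repeat {
        c2 <- rawToChar(readBin(con, "raw", 1L))
        if (c2 == "\n" || c2 == "") break
      }
      next
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) {
        tokens <- c(tokens, paste(buf, collapse = ""))
        buf <- character(0)
      }
    } else {
      buf <- c(buf, ch)
    }
  }
  magic <- tokens[1]
  w <- as.integer(tokens[2])
  h <- as.integer(tokens[3])
  if (identical(magic, "P5")) {
    vals <- as.integer(readBin(con, "raw", w * h))
  } else if (identical(magic, "P2")) {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  } else {
    stop("unsupported PGM magic: ", magic, call. = FALSE)
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a recording bundle to a directory
#'
#' @param bundle list with any of: `video` ([video_frames()]), `masks`
#'   ([segmentation_sequence()]), `audio` ([two_channel_recording()]),
#'   `report` (`parameter_report`), `pvg` (`pvg`), `metadata` (named list
#'   merged into the JSON sidecar).
#' @param out_dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  meta <- c(bundle$metadata,
            list(coordinate_convention = "0-based, x right, y down",
                 left_right_convention = "image_left"))
  if (!is.null(bundle$video)) {
    fd <- file.path(out_dir, "frames")
    dir.create(fd, showWarnings = FALSE)
    n <- n_frames(bundle$video)
    for (i in seq_len(n)) {
      write_pgm(get_frame(bundle$video, i),
                file.path(fd, sprintf("frame_%05d.pgm", i - 1L)))
    }
    meta$frame_rate <- bundle$video$frame_rate
    meta$n_frames <- n
    if (!is.null(bundle$video$roi)) meta$roi <- bundle$video$roi
    paths$frames <- fd
  }
  if (!is.null(bundle$masks)) {
    md <- file.path(out_dir, "masks")
    dir.create(md, showWarnings = FALSE)
    nm <- dim(bundle$masks$masks)[3]
    for (i in seq_len(nm)) {
      write_pgm(bundle$masks$masks[, , i] * 255,
                file.path(md, sprintf("mask_%05d.pgm", i - 1L)))
    }
    meta$frame_rate <- bundle$masks$frame_rate
    paths$masks <- md
  }
  if (!is.null(bundle$audio)) {
    ap <- file.path(out_dir, "audio.wav")
    write_wav(cbind(bundle$audio$audio, bundle$audio$reference), ap,
              sample_rate = bundle$audio$sample_rate,
              bit_depth = bundle$audio$bit_depth)
    meta$sample_rate <- bundle$audio$sample_rate
    meta$bit_depth <- bundle$audio$bit_depth
    paths$audio <- ap
  }
  if (!is.null(bundle$report)) {
    rp <- file.path(out_dir, "parameters.csv")
    utils::write.csv(as.data.frame(bundle$report), rp, row.names = FALSE)
    paths$parameters <- rp
  }
  if (!is.null(bundle$pvg)) {
    pp <- file.path(out_dir, "pvg.csv")
    utils::write.table(bundle$pvg$matrix, pp, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    meta$pvg <- list(M = bundle$pvg$M, layout = bundle$pvg$layout,
                     station_spacing_px = bundle$pvg$station_spacing_px)
    paths$pvg <- pp
  }
  if (!is.null(bundle$alignment)) {
    meta$alignment <- list(
      end_trigger_sample = bundle$alignment$end_trigger_sample,
      samples_per_frame = bundle$alignment$samples_per_frame,
      n_frames_detected = bundle$alignment$n_frames_detected,
      frame_pulse_samples = bundle$alignment$frame_pulse_samples)
  }
  mp <- file.path(out_dir, "metadata.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths$metadata <- mp
  invisible(paths)
}

read_stack_dir <- function(dirpath, member) {
  files <- sort(list.files(dirpath, pattern = "\\.pgm$", full.names = TRUE))
  if (!length(files)) {
    stop("corrupt bundle: no PGM files in ", member, " directory",
         call. = FALSE)
  }
  first <- read_pgm(files[1])
  arr <- array(0, dim = c(nrow(first), ncol(first), length(files)))
  arr[, , 1] <- first
  for (i in seq_along(files)[-1]) arr[, , i] <- read_pgm(files[i])
  arr
}

#' Read a recording bundle from a directory
#'
#' Errors name the missing or inconsistent member.
#'
#' @param dir bundle directory written by [write_bundle()] (or assembled by
#'   external tooling with the same layout).
#' @return list with `video`, `masks`, `audio`, `metadata` (members NULL
#'   when absent on disk).
#' @export
read_bundle <- function(dir) {
  mp <- file.path(dir, "metadata.json")
  if (!file.exists(mp)) {
    stop("missing bundle member: metadata.json", call. = FALSE)
  }
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  out <- list(metadata = meta, video = NULL, masks = NULL, audio = NULL)
  fd <- file.path(dir, "frames")
  if (dir.exists(fd)) {
    if (is.null(meta$frame_rate)) {
      stop("invalid metadata: missing \"frame_rate\"", call. = FALSE)
    }
    arr <- read_stack_dir(fd, "frames")
    out$video <- video_frames(arr, meta$frame_rate,
                              roi = if (!is.null(meta$roi))
                                as.integer(meta$roi) else NULL)
  }
  md <- file.path(dir, "masks")
  if (dir.exists(md)) {
    if (is.null(meta$frame_rate)) {
      stop("invalid metadata: missing \"frame_rate\"", call. = FALSE)
    }
    arr <- read_stack_dir(md, "masks")
    out$masks <- segmentation_sequence((arr > 127) * 1L, meta$frame_rate)
  }
  ap <- file.path(dir, "audio.wav")
  if (file.exists(ap)) {
    if (is.null(meta$sample_rate)) {
      stop("invalid metadata: missing \"sample_rate\"", call. = FALSE)
    }
    out$audio <- read_recording_wav(ap)
  }
  out
}

#' Run the full analysis pipeline on a recording bundle
#'
#' Stages: audio-video alignment (when audio is present), ROI crop,
#' segmentation (threshold baseline or supplied model), GAW + cycle
#' detection + phase decomposition, midline + hemi-GAWs, phonovibrogram,
#' and the clinical parameter report. Refuses to report parameters from
#' fewer than `min_cycles` detected cycles (the recommended minimum is 20)
#' unless `force = TRUE`.
#'
#' @param bundle list as returned by [read_bundle()] or [synth_recording()]
#'   (needs `video` or `masks`; `audio` optional).
#' @param roi optional `c(x, y, w, h)` crop.
#' @param frames optional 0-based frame range `c(first, last)` selecting the
#'   analysis segment (default: all frames).
#' @param model optional segmentation model callable (see
#'   [segment_model()]); default uses [segment_threshold()].
#' @param closure_eps closure threshold for phase decomposition.
#' @param min_prominence_frac cycle-detection prominence fraction.
#' @param context_frames temporal context for the midline estimate.
#' @param M phonovibrogram stations.
#' @param min_cycles minimum cycles required to report parameters.
#' @param force report parameters even below `min_cycles`.
#' @param verbose log stage progress via message().
#' @return the bundle with `seg`, `gaw`, `cycles`, `midlines`, `hemi`,
#'   `pvg`, `alignment`, `audio_segment` and `report` filled in.
#' @export
run_pipeline <- function(bundle, roi = NULL, frames = NULL, model = NULL,
                         closure_eps = 0.02, min_prominence_frac = 0.1,
                         context_frames = 2L, M = 64L, min_cycles = 20L,
                         force = FALSE, verbose = TRUE) {
  log_stage <- function(...) if (verbose) message("[pipeline] ", sprintf(...))
  if (is.null(bundle$video) && is.null(bundle$masks)) {
    stop("pipeline stage 'input': bundle has neither video nor masks",
         call. = FALSE)
  }
  fps <- if (!is.null(bundle$video)) bundle$video$frame_rate
         else bundle$masks$frame_rate

  audio_seg <- NULL
  if (!is.null(bundle$audio)) {
    log_stage("sync: locating end trigger and frame pulses")
    trig <- detect_end_trigger(bundle$audio)
    al <- detect_frame_pulses(bundle$audio, trig, fps = fps)
    bundle$alignment <- al
    n_avail <- if (!is.null(bundle$video)) n_frames(bundle$video)
               else dim(bundle$masks$masks)[3]
    fr <- if (is.null(frames)) c(0L, min(n_avail, al$n_frames_detected) - 1L)
          else as.integer(frames)
    audio_seg <- extract_audio_segment(bundle$audio, al, fr[1], fr[2])
    bundle$audio_segment <- audio_seg
    log_stage("sync: %d pulses, trigger at sample %d",
              al$n_frames_detected, al$end_trigger_sample)
  } else {
    log_stage("sync: no audio channel; GAW-only analysis")
    warning("no audio in bundle; audio parameters will be absent")
  }

  if (!is.null(frames)) {
    sel <- (frames[1] + 1L):(frames[2] + 1L)
  } else {
    sel <- NULL
  }

  if (is.null(bundle$masks)) {
    vid <- bundle$video
    if (!is.null(sel)) {
      vid <- video_frames(vid$frames[, , sel, drop = FALSE], fps, vid$roi)
    }
    if (!is.null(roi)) {
      log_stage("roi: cropping to (%s)", paste(roi, collapse = ", "))
      vid <- apply_roi(vid, roi)
    }
    log_stage("segmentation: %s", if (is.null(model)) "threshold baseline"
              else "user model")
    bundle$seg <- if (is.null(model)) segment_threshold(vid)
                  else segment_model(vid, model)
  } else {
    m <- bundle$masks
    if (!is.null(sel)) {
      m <- segmentation_sequence(m$masks[, , sel, drop = FALSE], fps)
    }
    log_stage("segmentation: using masks provided in bundle")
    bundle$seg <- m
  }

  log_stage("waveform: GAW, cycles, phases")
  g <- gaw_from_masks(bundle$seg)
  cyc <- detect_cycles(g, min_prominence_frac = min_prominence_frac)
  if (nrow(cyc) < min_cycles && !force) {
    stop(sprintf(
      "pipeline stage 'parameters' refused: only %d cycles detected (< %d recommended); use force = TRUE to override",
      nrow(cyc), min_cycles), call. = FALSE)
  }
  cyc <- decompose_phases(g, cyc, closure_eps = closure_eps)
  bundle$gaw <- g
  bundle$cycles <- cyc

  log_stage("midline: %d cycle anchors", nrow(cyc))
  ml <- estimate_midline(bundle$seg, cyc, context_frames = context_frames)
  bundle$midlines <- ml
  bundle$hemi <- split_hemi_gaw(bundle$seg, ml)

  log_stage("pvg: %d stations", M)
  bundle$pvg <- compute_pvg(bundle$seg, ml, M = M)

  log_stage("parameters: assembling report")
  bundle$report <- compute_report(
    gaw_signal = g, cycles = cyc, hemi = bundle$hemi,
    audio = if (!is.null(audio_seg)) audio_seg$samples else NULL,
    sample_rate = if (!is.null(bundle$audio)) bundle$audio$sample_rate
                  else NULL)
  bundle
}
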