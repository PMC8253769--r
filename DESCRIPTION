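Package: hsvoice
Title: Analysis of Laryngeal High-Speed Videoendoscopy and Acoustic Voice Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A headless analysis pipeline for laryngeal high-speed
    videoendoscopy (HSV) paired with acoustic recordings. Synchronizes
    video frames with the audio track via the camera reference pulse
    channel, segments the glottis, derives the glottal area waveform
    (GAW), estimates the glottal midline and hemi-GAWs, computes the
    phonovibrogram, and reports 18 GAW-based and 9 audio-based clinical
    voice parameters (jitter, shimmer, HNR, CPP, phase quotients,
    symmetry indices, perturbation quotients). Includes blind image
    quality scoring (NIQE) and a fully ground-truthed synthetic
    phonation generator for end-to-end validation without hardware.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
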