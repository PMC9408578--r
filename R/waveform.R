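# Signal-level grounding of the ST-measurement convention: synthesise
# 12-lead ECG-like beats with programmable ST offset and QRS width, then
# measure the ST deviation back from the samples.
#
# Morphology is a sum of Gaussian bumps (P, Q, R, S, T) plus a plateau of the
# programmed ST amplitude between the J point and T onset. Amplitudes are in
# mm (1 mm = 0.1 mV). Fiducial sample indices are carried as ground truth
# from the generator; this module demonstrates the measurement convention,
# it is not a delineation algorithm.

#' Beat synthesis parameters
#'
#' @param heart_rate_bpm Heart rate in beats per minute.
#' @param qrs_ms QRS duration in ms, in `[40, 300]`.
#' @param st_offset_mm Programmed ST deviation in mm (plateau amplitude
#'   between the J point and T onset).
#' @param fs_hz Sampling rate in Hz, at least 250.
#' @param noise_sd_mm Additive white-noise standard deviation in mm (>= 0).
#' @param n_beats Number of beats to synthesise.
#' @return A `beat_params` list.
#' @export
beat_params <- function(heart_rate_bpm = 60, qrs_ms = 90, st_offset_mm = 0,
                        fs_hz = 500, noise_sd_mm = 0, n_beats = 1) {
  if (fs_hz < 250) abort("`fs_hz` must be at least 250 Hz.")
  if (qrs_ms < 40 || qrs_ms > 300) abort("`qrs_ms` must lie in [40, 300].")
  if (noise_sd_mm < 0) abort("`noise_sd_mm` must be >= 0.")
  if (heart_rate_bpm <= 0 || n_beats < 1) abort("Invalid rate or beat count.")
  structure(list(heart_rate_bpm = heart_rate_bpm, qrs_ms = qrs_ms,
                 st_offset_mm = st_offset_mm, fs_hz = fs_hz,
                 noise_sd_mm = noise_sd_mm, n_beats = n_beats),
            class = "beat_params")
}

gauss_bump <- function(t, centre, width, amp) {
  amp * exp(-((t - centre)^2) / (2 * width^2))
}

#' Synthesise an ECG-like beat train
#'
#' @param params A [beat_params()] object.
#' @return A list with `signal` (numeric, mm), `fs_hz`, and `fiducials`: a
#'   tibble of per-beat sample indices (1-based) of P onset, QRS onset, the J
#'   point and T end, strictly increasing within each beat.
#' @export
#' @examples
#' b <- synthesize_beat(beat_params(st_offset_mm = 2))
#' measure_st(b) # ~2 mm
synthesize_beat <- function(params) {
  stopifnot(inherits(params, "beat_params"))
  fs <- params$fs_hz
  beat_s <- 60 / params$heart_rate_bpm
  n_samp <- round(beat_s * fs)
  qrs_s <- params$qrs_ms / 1000

  # within-beat timing (seconds from beat onset); wave widths are kept
  # several sigma away from both the terminal PR reference window and the
  # J + 60 ms measurement window so the noiseless round trip is exact to
  # numerical precision
  p_on <- 0.05
  p_centre <- p_on + 0.025
  qrs_on <- p_on + 0.12
  j_point <- qrs_on + qrs_s
  t_on <- j_point + 0.10
  t_centre <- j_point + 0.20
  t_end <- j_point + 0.26
  if (t_end >= beat_s) abort("Beat does not fit at this rate/QRS width.")

  t_rel <- (seq_len(n_samp) - 1) / fs
  qrs_mid <- (qrs_on + j_point) / 2
  qrs_w <- qrs_s / 8
  one <- gauss_bump(t_rel, p_centre, 0.008, 1.0) +
    gauss_bump(t_rel, qrs_mid - 1.5 * qrs_w, qrs_w / 2, -1.5) +
    gauss_bump(t_rel, qrs_mid, qrs_w, 10) +
    gauss_bump(t_rel, qrs_mid + 1.5 * qrs_w, qrs_w / 2, -2.5) +
    gauss_bump(t_rel, t_centre, 0.02, 2.0)
  # ST plateau between J and T onset, smoothly gated
  gate <- (t_rel >= j_point & t_rel < t_on)
  one <- one + params$st_offset_mm * gate

  signal <- rep(one, params$n_beats)
  if (params$noise_sd_mm > 0) {
    signal <- signal + rnorm(length(signal), 0, params$noise_sd_mm)
  }
  offsets <- (seq_len(params$n_beats) - 1) * n_samp
  fiducials <- tibble::tibble(
    beat = seq_len(params$n_beats),
    p_on = offsets + round(p_on * fs) + 1L,
    qrs_on = offsets + round(qrs_on * fs) + 1L,
    j_point = offsets + round(j_point * fs) + 1L,
    t_end = offsets + round(t_end * fs) + 1L
  )
  list(signal = signal, fs_hz = fs, fiducials = fiducials)
}

#' Measure ST deviation from a synthesised beat train
#'
#' Deviation is the mean amplitude over a +/-10 ms window centred at
#' J + `j_offset_ms`, referenced to the median of the terminal 50 ms of the
#' PR segment (the iso-electric stretch just before QRS onset), averaged
#' across beats.
#'
#' @param beat A list as returned by [synthesize_beat()] (fields `signal`,
#'   `fs_hz`, `fiducials`).
#' @param j_offset_ms Measurement point after the J point, default 60 ms
#'   (configurable 40-80 in common practice).
#' @return ST deviation in mm.
#' @export
measure_st <- function(beat, j_offset_ms = 60) {
  sig <- beat$signal
  fs <- beat$fs_hz
  fid <- beat$fiducials
  win <- round(0.010 * fs)
  per_beat <- vapply(seq_len(nrow(fid)), function(i) {
    centre <- fid$j_point[i] + round(j_offset_ms / 1000 * fs)
    idx <- (centre - win):(centre + win)
    if (min(idx) < 1 || max(idx) > length(sig)) {
      abort("Measurement window falls outside the signal.")
    }
    pr_end <- fid$qrs_on[i] - round(0.010 * fs)
    pr_start <- max(fid$p_on[i], fid$qrs_on[i] - round(0.060 * fs))
    pr <- sig[pr_start:pr_end]
    mean(sig[idx]) - stats::median(pr)
  }, 0)
  mean(per_beat)
}

#' Assemble an ECG feature record from 12 synthesised lead signals
#'
#' Measures the ST deviation of each lead signal and the QRS duration from
#' the shared fiducials, and assembles a one-row cohort tibble.
#'
#' @param beats Named list of 12 beat objects (names = [ecg_leads()]), each
#'   as returned by [synthesize_beat()] with identical timing.
#' @param sex `"male"` or `"female"`.
#' @param lafb,rbbb,lbbb,hdavb Conduction flags.
#' @param j_offset_ms Measurement point, as in [measure_st()].
#' @param id Record identifier.
#' @return A one-row cohort tibble.
#' @export
#' @examples
#' leads <- lapply(setNames(nm = ecg_leads()), function(ld) {
#'   synthesize_beat(beat_params(st_offset_mm = if (ld == "aVR") 1.5 else -1))
#' })
#' classify_main(record_from_waveforms(leads, sex = "male"))
record_from_waveforms <- function(beats, sex, lafb = FALSE, rbbb = FALSE,
                                  lbbb = FALSE, hdavb = FALSE,
                                  j_offset_ms = 60, id = "wf1") {
  missing <- setdiff(ecg_leads(), names(beats))
  if (length(missing)) {
    abort(paste0("Missing lead signal(s): ", paste(missing, collapse = ", ")))
  }
  st <- vapply(ecg_leads(), function(ld) measure_st(beats[[ld]], j_offset_ms), 0)
  fid <- beats[[1]]$fiducials
  qrs_ms <- (fid$j_point[1] - fid$qrs_on[1]) / beats[[1]]$fs_hz * 1000
  ecg_record(st = st, sex = sex, qrs_ms = qrs_ms, lafb = lafb, rbbb = rbbb,
             lbbb = lbbb, hdavb = hdavb, id = id)
}
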