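#' Filter chain specification
#'
#' Offline filter settings applied to every channel: a zero-phase Butterworth
#' band-pass plus an optional notch. Defaults reproduce a common clinical
#' acquisition chain: 0.4823 Hz high-pass (the cutoff implied by a 0.33 s
#' amplifier time constant, 1 / (2 * pi * 0.33)), 12 dB/octave; 70 Hz
#' low-pass, 24 dB/octave; 60 Hz mains notch.
#'
#' Slopes are realized as Butterworth orders (6 dB/octave per pole):
#' order 2 for 12 dB/octave, order 4 for 24 dB/octave, applied
#' forward-backward for zero phase.
#'
#' @param highpass_hz high-pass cutoff in Hz.
#' @param highpass_db_oct high-pass asymptotic slope in dB/octave (6, 12, 18
#'   or 24).
#' @param lowpass_hz low-pass cutoff in Hz.
#' @param lowpass_db_oct low-pass slope in dB/octave.
#' @param notch_hz notch center frequency in Hz, or `NULL` to disable.
#' @param notch_halfwidth_hz half-width of the stop band in Hz.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(highpass_hz = 0.4823, highpass_db_oct = 12,
                        lowpass_hz = 70, lowpass_db_oct = 24,
                        notch_hz = 60, notch_halfwidth_hz = 2) {
  stopifnot(highpass_hz > 0, lowpass_hz > highpass_hz)
  ord <- function(db) {
    o <- db / 6
    if (o != round(o) || o < 1) stop("slope must be a multiple of 6 dB/octave")
    as.integer(o)
  }
  structure(list(highpass_hz = highpass_hz, hp_order = ord(highpass_db_oct),
                 lowpass_hz = lowpass_hz, lp_order = ord(lowpass_db_oct),
                 notch_hz = notch_hz, notch_halfwidth_hz = notch_halfwidth_hz),
            class = "filter_spec")
}

#' Re-reference a recording to the averaged mastoids
#'
#' Subtracts the mean of the two mastoid channels (A1, A2) from every scalp
#' and EOG channel; the mastoid channels are dropped from the output.
#'
#' @param rec an [eeg_recording()] containing channels `A1` and `A2` with
#'   role `"mastoid"`.
#' @return An [eeg_recording()] without mastoid channels.
#' @export
rereference <- function(rec) {
  mast <- names(rec$roles)[rec$roles == "mastoid"]
  for (m in c("A1", "A2"))
    if (!m %in% rec$channels) stop("missing mastoid channel: ", m)
  ref <- (rec$data[, "A1"] + rec$data[, "A2"]) / 2
  keep <- setdiff(rec$channels, mast)
  out <- rec$data[, keep, drop = FALSE] - ref
  eeg_recording(out, keep, unname(rec$roles[keep]), rec$fs, rec$start_s)
}

zero_phase <- function(x, filt) filtfilt_fast(filt, x)

#' Apply the offline filter chain
#'
#' Zero-phase (forward-backward) Butterworth high-pass, low-pass, and
#' optional notch, per channel. Channel means are removed first so the
#' high-pass transient does not ring on the DC offset.
#'
#' @param rec an [eeg_recording()].
#' @param spec a [filter_spec()].
#' @return Filtered [eeg_recording()].
#' @export
filter_chain <- function(rec, spec = filter_spec()) {
  nyq <- rec$fs / 2
  if (spec$lowpass_hz >= nyq)
    stop("low-pass cutoff (", spec$lowpass_hz, " Hz) must be below Nyquist (",
         nyq, " Hz)")
  if (!is.null(spec$notch_hz) && spec$notch_hz + spec$notch_halfwidth_hz >= nyq)
    stop("notch band must lie below Nyquist (", nyq, " Hz)")
  hp <- signal::butter(spec$hp_order, spec$highpass_hz / nyq, type = "high")
  lp <- signal::butter(spec$lp_order, spec$lowpass_hz / nyq, type = "low")
  nf <- if (!is.null(spec$notch_hz))
    signal::butter(2, c(spec$notch_hz - spec$notch_halfwidth_hz,
                        spec$notch_hz + spec$notch_halfwidth_hz) / nyq,
                   type = "stop")
  out <- rec$data
  for (j in seq_len(ncol(out))) {
    x <- out[, j] - mean(out[, j])
    x <- zero_phase(x, hp)
    x <- zero_phase(x, lp)
    if (!is.null(nf)) x <- zero_phase(x, nf)
    out[, j] <- x
  }
  eeg_recording(out, rec$channels, unname(rec$roles), rec$fs, rec$start_s)
}

#' Detect ocular artifacts from the EOG product signal
#'
#' Marks eye movements and blinks by thresholding the magnitude of the
#' product of the two EOG traces: every sample where
#' `|EOG-L * EOG-R| > mean + k_sd * SD` (moments of the absolute product)
#' contributes a `window_s`-long exclusion interval centered on it; the
#' intervals are clipped to the recording and merged.
#'
#' @param eog_left,eog_right numeric EOG traces (equal length, microvolts),
#'   already re-referenced and filtered.
#' @param fs sampling rate in Hz.
#' @param k_sd threshold in SD units above the mean absolute product.
#' @param window_s length of the exclusion window centered on each
#'   suprathreshold sample, seconds.
#' @return An `artifact_mask`: list with `intervals` (two-column matrix of
#'   merged `[start, end)` seconds), `excluded_fraction`, `threshold`,
#'   `duration_s`.
#' @export
detect_ocular_artifacts <- function(eog_left, eog_right, fs,
                                    k_sd = 3, window_s = 2) {
  if (length(eog_left) != length(eog_right))
    stop("EOG traces must have equal length")
  n <- length(eog_left)
  dur <- n / fs
  p <- abs(eog_left * eog_right)
  if (stats::sd(p) == 0) {
    warning("EOG product has zero variance; returning empty mask")
    return(artifact_mask(NULL, dur, threshold = Inf))
  }
  thr <- mean(p) + k_sd * stats::sd(p)
  hit <- which(p > thr)
  if (!length(hit)) return(artifact_mask(NULL, dur, threshold = thr))
  tc <- (hit - 1) / fs
  iv <- cbind(tc - window_s / 2, tc + window_s / 2)
  iv <- merge_intervals(clip_intervals(iv, 0, dur))
  artifact_mask(iv, dur, threshold = thr)
}

artifact_mask <- function(iv, duration_s, threshold = NA_real_) {
  if (is.null(iv)) iv <- matrix(numeric(0), ncol = 2)
  iv <- merge_intervals(clip_intervals(iv, 0, duration_s))
  structure(list(intervals = iv, duration_s = duration_s,
                 excluded_fraction = interval_total(iv) / duration_s,
                 threshold = threshold),
            class = "artifact_mask")
}

#' Build an artifact mask from explicit intervals
#'
#' @param intervals two-column matrix (or NULL) of `[start, end)` seconds.
#' @param duration_s recording duration in seconds.
#' @return An `artifact_mask`.
#' @export
mask_from_intervals <- function(intervals, duration_s)
  artifact_mask(intervals, duration_s)

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("<artifact_mask> %d interval(s), %.1f%% of %.1f s excluded\n",
              nrow(x$intervals), 100 * x$excluded_fraction, x$duration_s))
  invisible(x)
}

#' Excise masked intervals, returning clean contiguous segments
#'
#' Splits the recording at the mask boundaries (rounded to sample
#' resolution) and keeps every clean stretch at least `min_segment_s` long.
#' Stretches shorter than `min_segment_s` are discarded and counted as
#' excluded, so retained + excluded time equals the recording duration
#' exactly (to one sample).
#'
#' @param rec an [eeg_recording()].
#' @param mask an `artifact_mask` (from [detect_ocular_artifacts()] or
#'   [mask_from_intervals()]).
#' @param min_segment_s shortest clean stretch worth keeping, seconds.
#'   The default 2 s is the shortest stretch that still supports estimation
#'   down to a 1 Hz band edge.
#' @return An `eeg_segments` object: list of segments (each with `start_s`,
#'   `end_s`, `data`), plus `fs`, `channels`, `roles`, `retained_s`,
#'   `excluded_s`.
#' @export
apply_mask <- function(rec, mask, min_segment_s = 2) {
  dur <- duration_s(rec)
  clean <- complement_intervals(mask$intervals, 0, dur)
  segs <- list()
  for (i in seq_len(nrow(clean))) {
    i0 <- floor(as.numeric(clean[i, 1L]) * rec$fs) + 1L
    i1 <- floor(as.numeric(clean[i, 2L]) * rec$fs)
    if (i1 < i0) next
    if ((i1 - i0 + 1L) / rec$fs < min_segment_s) next
    segs[[length(segs) + 1L]] <- list(
      start_s = (i0 - 1L) / rec$fs, end_s = i1 / rec$fs,
      data = rec$data[i0:i1, , drop = FALSE])
  }
  if (!length(segs))
    warning("mask leaves no clean segment of at least ", min_segment_s, " s")
  retained <- sum(vapply(segs, function(s) nrow(s$data), numeric(1))) / rec$fs
  structure(list(segments = segs, fs = rec$fs, channels = rec$channels,
                 roles = rec$roles, retained_s = retained,
                 excluded_s = dur - retained, duration_s = dur),
            class = "eeg_segments")
}

#' @export
print.eeg_segments <- function(x, ...) {
  cat(sprintf("<eeg_segments> %d segment(s), %.1f s retained / %.1f s total\n",
              length(x$segments), x$retained_s, x$duration_s))
  invisible(x)
}
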