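#' SREM detector parameters
#'
#' A slow rolling eye movement (SREM) is an out-of-phase, rolling deflection
#' lasting at least 0.5 s in both EOG channels. The detector uses a
#' dual-threshold (hysteresis) rule on the slow-filtered pair: an event
#' must contain a high-amplitude anti-phase core, and its extent — hence
#' its duration — is measured where both envelopes hold the lower
#' amplitude threshold. Amplitude thresholds are multiples of the robust
#' background SD (bias-corrected lower decile of the per-second RMS
#' profile), so the detector is scale-free.
#'
#' @param slow_band_hz two-element band for the slow filter (Hz).
#' @param amplitude_factor extension (lower) threshold, in background-SD
#'   units; sets the measured event boundaries.
#' @param core_factor core (upper) threshold, in background-SD units; a
#'   candidate without a core this large is discarded, which rejects
#'   filter-ringing satellites of genuine events.
#' @param antiphase_max maximum sliding-window Pearson correlation for a
#'   sample to count toward an anti-phase core (default -0.5).
#' @param min_duration_s minimum event duration (s).
#' @param core_min_s minimum core duration (s).
#' @param corr_window_s sliding correlation window (s).
#' @param merge_gap_s events separated by less than this are merged: one
#'   rolling movement, not two (band-pass ringing can split a single
#'   deflection).
#' @param slow_fraction_min minimum fraction of the event's 0.1-10 Hz
#'   power that must lie in the slow band; rejects brief high-amplitude
#'   jerks whose smeared slow residue would otherwise pass the duration
#'   rule.
#' @return An `srem_params` list.
#' @export
srem_params <- function(slow_band_hz = c(0.1, 1.5), amplitude_factor = 2,
                        core_factor = 4, antiphase_max = -0.5,
                        min_duration_s = 0.5, core_min_s = 0.25,
                        corr_window_s = 0.5, merge_gap_s = 0.5,
                        slow_fraction_min = 0.5) {
  stopifnot(length(slow_band_hz) == 2, slow_band_hz[1] > 0,
            slow_band_hz[2] > slow_band_hz[1], amplitude_factor > 0,
            core_factor >= amplitude_factor, antiphase_max < 0,
            min_duration_s > 0, core_min_s > 0, corr_window_s > 0,
            slow_fraction_min >= 0, slow_fraction_min <= 1)
  structure(list(slow_band_hz = slow_band_hz,
                 amplitude_factor = amplitude_factor,
                 core_factor = core_factor,
                 antiphase_max = antiphase_max,
                 min_duration_s = min_duration_s,
                 core_min_s = core_min_s,
                 corr_window_s = corr_window_s,
                 merge_gap_s = merge_gap_s,
                 slow_fraction_min = slow_fraction_min),
            class = "srem_params")
}

slow_filter <- function(x, fs, band) {
  bf <- signal::butter(2, pmin(band / (fs / 2), 0.98), type = "pass")
  filtfilt_fast(bf, x)
}

# robust background SD: lower decile of the per-second RMS profile,
# bias-corrected. One-second blocks keep the estimator valid at high
# event densities (the quietest tenth stays clean even when eye
# movements cover half the recording, where the MAD breaks down);
# because a block of a B-Hz-wide Gaussian process has only ~2B degrees
# of freedom, the raw decile underestimates sigma and is divided by the
# chi-square decile factor sqrt(q_{0.10}(chi2_nu)/nu).
robust_background_sd <- function(x, fs, bw_hz = 1.4, block_s = 1) {
  bl <- round(block_s * fs)
  nb <- floor(length(x) / bl)
  if (nb < 10) return(stats::mad(x))
  rms <- sqrt(colMeans(matrix(x[seq_len(nb * bl)]^2, nrow = bl)))
  nu <- max(2, round(2 * bw_hz * block_s) + 1)
  corr <- sqrt(stats::qchisq(0.10, nu) / nu)
  unname(stats::quantile(rms, 0.10)) / corr
}

# centered sliding-window Pearson correlation via running sums
sliding_corr <- function(x, y, w) {
  n <- length(x)
  w <- min(w, n)
  cs <- function(v) {
    c0 <- cumsum(v)
    c(c0[w], c0[(w + 1):n] - c0[1:(n - w)])
  }
  sx <- cs(x); sy <- cs(y)
  sxx <- cs(x * x); syy <- cs(y * y); sxy <- cs(x * y)
  cov <- sxy - sx * sy / w
  vx <- pmax(sxx - sx^2 / w, 0)
  vy <- pmax(syy - sy^2 / w, 0)
  r <- cov / sqrt(vx * vy)
  r[!is.finite(r)] <- 0
  # windows end at samples w..n; assign to window centers, pad edges
  ctr <- numeric(n)
  off <- floor(w / 2)
  idx <- seq_len(n - w + 1L)
  ctr[idx + off] <- r
  ctr[seq_len(off)] <- r[1L]
  if (off + length(idx) < n) ctr[(off + length(idx) + 1L):n] <- r[length(r)]
  ctr
}

runs_from_logical <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect slow rolling eye movements in a bilateral EOG pair
#'
#' Rule-based automation of the SREM scoring definition. The two traces
#' are filtered to the slow band and their Hilbert envelopes computed (the
#' envelope, not the rectified trace, carries the amplitude criterion so
#' one rolling deflection is not fragmented at band-pass zero crossings).
#' Candidate cores are runs of at least `core_min_s` where both envelopes
#' exceed the core threshold and the sliding correlation is at or below
#' `antiphase_max`; each core is extended outward while both envelopes
#' hold the lower threshold, fixing the event boundaries. Extended events
#' closer than `merge_gap_s` merge; events shorter than `min_duration_s`,
#' events without slow-band power dominance, and events whose envelope
#' peak falls inside a masked artifact interval are dropped.
#'
#' @param eog_left,eog_right preprocessed EOG traces (equal length,
#'   microvolts).
#' @param fs sampling rate, Hz.
#' @param params an [srem_params()].
#' @param mask optional `artifact_mask`; events whose envelope peak lies
#'   inside a masked interval are excluded.
#' @return Tibble of events: `onset_s`, `duration_s`, `antiphase_score`
#'   (mean sliding correlation over the event, in \[-1, 0)).
#' @export
detect_srems <- function(eog_left, eog_right, fs, params = srem_params(),
                         mask = NULL) {
  if (length(eog_left) != length(eog_right))
    stop("EOG traces must have equal length")
  n <- length(eog_left)
  ls <- slow_filter(eog_left, fs, params$slow_band_hz)
  rs <- slow_filter(eog_right, fs, params$slow_band_hz)
  bw <- diff(params$slow_band_hz)
  bg_l <- robust_background_sd(ls, fs, bw)
  bg_r <- robust_background_sd(rs, fs, bw)
  ext_l <- params$amplitude_factor * bg_l
  ext_r <- params$amplitude_factor * bg_r
  core_l <- params$core_factor * bg_l
  core_r <- params$core_factor * bg_r
  el <- Mod(hilbert_analytic(ls))
  er <- Mod(hilbert_analytic(rs))
  w <- max(3L, round(params$corr_window_s * fs))
  rho <- sliding_corr(ls, rs, w)

  core <- el > core_l & er > core_r & rho <= params$antiphase_max
  if (!any(core)) return(empty_srem_table())
  runs <- runs_from_logical(core)
  runs <- runs[(runs[, 2L] - runs[, 1L] + 1L) / fs >= params$core_min_s, ,
               drop = FALSE]
  if (!nrow(runs)) return(empty_srem_table())

  # hysteresis: extend each core outward while both envelopes hold the
  # background floor (capped at a 10 s horizon)
  horizon <- 10L * as.integer(fs)
  iv <- t(vapply(seq_len(nrow(runs)), function(i) {
    r0 <- runs[i, 1L]; r1 <- runs[i, 2L]
    w0 <- max(1L, r0 - horizon)
    pre <- which(!(el[w0:r0] > ext_l & er[w0:r0] > ext_r))
    left <- if (length(pre)) w0 + pre[length(pre)] else w0
    w1 <- min(n, r1 + horizon)
    post <- which(!(el[r1:w1] > ext_l & er[r1:w1] > ext_r))
    right <- if (length(post)) r1 + post[1L] - 2L else w1
    c((left - 1L) / fs, right / fs)
  }, numeric(2)))
  iv <- merge_intervals(iv)
  # merge events separated by < merge_gap_s (ringing splits one movement)
  if (nrow(iv) > 1L) {
    iv2 <- cbind(iv[, 1L], iv[, 2L] + params$merge_gap_s)
    iv <- merge_intervals(iv2)
    iv[, 2L] <- pmin(iv[, 2L] - params$merge_gap_s, n / fs)
  }
  # trim each event to the span where the traces hold the larger of the
  # floor and 30% of the event's own peak: boundaries track the
  # deflection itself, and ringing tails merged into the event are cut
  trimmed <- lapply(seq_len(nrow(iv)), function(i) {
    i0 <- max(1L, floor(iv[i, 1L] * fs) + 1L)
    i1 <- min(n, ceiling(iv[i, 2L] * fs))
    ok <- which(abs(ls[i0:i1]) > max(ext_l, 0.3 * max(abs(ls[i0:i1]))) &
                  abs(rs[i0:i1]) > max(ext_r, 0.3 * max(abs(rs[i0:i1]))))
    if (!length(ok)) return(NULL)
    c((i0 + ok[1L] - 2L) / fs, (i0 + ok[length(ok)] - 1L) / fs)
  })
  iv <- do.call(rbind, trimmed)
  if (is.null(iv)) return(empty_srem_table())
  keep <- (iv[, 2L] - iv[, 1L]) >= params$min_duration_s
  iv <- iv[keep, , drop = FALSE]
  if (!nrow(iv)) return(empty_srem_table())
  # a trimmed event must still contain its anti-phase core: amplitude
  # trimming can otherwise slide an event onto an adjacent in-phase
  # deflection
  has_core <- vapply(seq_len(nrow(iv)), function(i) {
    i0 <- max(1L, floor(iv[i, 1L] * fs) + 1L)
    i1 <- min(n, ceiling(iv[i, 2L] * fs))
    any(core[i0:i1])
  }, logical(1))
  iv <- iv[has_core, , drop = FALSE]
  if (!nrow(iv)) return(empty_srem_table())
  # slow-dominance: a rolling movement concentrates its 0.1-10 Hz power
  # in the slow band; brief jerks do not, however large their amplitude
  if (params$slow_fraction_min > 0) {
    hi <- min(10, 0.45 * fs)
    pad <- round(2 * fs)  # event-local filtering with a 2 s margin
    frac <- vapply(seq_len(nrow(iv)), function(i) {
      i0 <- max(1L, floor(iv[i, 1L] * fs) + 1L)
      i1 <- min(n, ceiling(iv[i, 2L] * fs))
      w0 <- max(1L, i0 - pad); w1 <- min(n, i1 + pad)
      fl <- slow_filter(eog_left[w0:w1], fs, c(params$slow_band_hz[1], hi))
      fr <- slow_filter(eog_right[w0:w1], fs, c(params$slow_band_hz[1], hi))
      sel <- (i0 - w0 + 1L):(i1 - w0 + 1L)
      tot <- mean(fl[sel]^2 + fr[sel]^2)
      if (tot <= 0) return(1)
      mean(ls[i0:i1]^2 + rs[i0:i1]^2) / tot
    }, numeric(1))
    iv <- iv[frac >= params$slow_fraction_min, , drop = FALSE]
    if (!nrow(iv)) return(empty_srem_table())
  }
  # exclusion by artifact mask: judged at the event's envelope peak, so
  # a genuine deflection is not discarded because its smeared flanks
  # touch a neighbouring blink's window
  if (!is.null(mask) && nrow(mask$intervals)) {
    peak_t <- vapply(seq_len(nrow(iv)), function(i) {
      i0 <- max(1L, floor(iv[i, 1L] * fs) + 1L)
      i1 <- min(n, ceiling(iv[i, 2L] * fs))
      idx <- i0:i1
      idx_core <- idx[core[idx]]     # anti-phase samples only: a nearby
      if (!length(idx_core)) idx_core <- idx  # blink cannot be the peak
      (idx_core[which.max(pmin(el[idx_core], er[idx_core]))] - 1L) / fs
    }, numeric(1))
    iv <- iv[!point_in_set(peak_t, mask$intervals), , drop = FALSE]
  }
  if (!nrow(iv)) return(empty_srem_table())
  # anti-phase score: mean sliding correlation over the event's core
  # samples (the envelope-smeared flanks would dilute it toward 0)
  score <- vapply(seq_len(nrow(iv)), function(i) {
    i0 <- max(1L, floor(iv[i, 1L] * fs) + 1L)
    i1 <- min(n, ceiling(iv[i, 2L] * fs))
    idx <- i0:i1
    idx_core <- idx[core[idx]]
    if (!length(idx_core)) idx_core <- idx
    min(mean(rho[idx_core]), -1e-9)
  }, numeric(1))
  tibble::tibble(onset_s = iv[, 1L], duration_s = iv[, 2L] - iv[, 1L],
                 antiphase_score = pmax(score, -1))
}

empty_srem_table <- function()
  tibble::tibble(onset_s = numeric(0), duration_s = numeric(0),
                 antiphase_score = numeric(0))

#' Count SREM events in one session
#'
#' @param events event table from [detect_srems()].
#' @return Integer count.
#' @export
count_srems <- function(events) nrow(events)

#' Time-to-first-SREM survival record
#'
#' @param events event table from [detect_srems()] (one session).
#' @param drive_duration_s scheduled drive duration, seconds.
#' @param terminated_early_at_s optional premature termination time; an
#'   event-free drive is censored at `min(duration, termination)`.
#' @return List: `time_s`, `event` (1 = first SREM observed, 0 = censored).
#' @export
time_to_first_srem <- function(events, drive_duration_s,
                               terminated_early_at_s = NULL) {
  if (drive_duration_s <= 0) stop("drive duration must be positive")
  end <- if (is.null(terminated_early_at_s)) drive_duration_s
         else min(drive_duration_s, terminated_early_at_s)
  if (nrow(events) && min(events$onset_s) <= end)
    list(time_s = min(events$onset_s), event = 1L)
  else
    list(time_s = end, event = 0L)
}

#' Match detected SREMs against ground truth
#'
#' A detected event is a true positive when it overlaps a ground-truth
#' interval; recall and precision follow.
#'
#' @param detected tibble from [detect_srems()].
#' @param truth ground-truth tibble with `onset_s`, `duration_s`.
#' @return List: `recall`, `precision`, `n_detected`, `n_truth`.
#' @export
srem_detection_scores <- function(detected, truth) {
  if (!nrow(truth))
    return(list(recall = NA_real_,
                precision = if (nrow(detected)) 0 else NA_real_,
                n_detected = nrow(detected), n_truth = 0L))
  t_iv <- cbind(truth$onset_s, truth$onset_s + truth$duration_s)
  d_iv <- if (nrow(detected))
    cbind(detected$onset_s, detected$onset_s + detected$duration_s)
  else matrix(numeric(0), ncol = 2)
  hit_truth <- vapply(seq_len(nrow(t_iv)), function(i)
    overlap_with_set(t_iv[i, 1], t_iv[i, 2], d_iv) > 0, logical(1))
  hit_det <- if (nrow(d_iv)) vapply(seq_len(nrow(d_iv)), function(i)
    overlap_with_set(d_iv[i, 1], d_iv[i, 2], t_iv) > 0, logical(1))
  else logical(0)
  list(recall = mean(hit_truth),
       precision = if (length(hit_det)) mean(hit_det) else NA_real_,
       n_detected = nrow(detected), n_truth = nrow(truth))
}
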