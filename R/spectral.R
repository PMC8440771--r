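#' Canonical EEG frequency bands
#'
#' delta 1-3, theta 4-7, alpha 8-12, beta 13-25, gamma 26-40 Hz.
#'
#' @return Tibble with `band`, `low_hz`, `high_hz`.
#' @export
eeg_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    low_hz = c(1, 4, 8, 13, 26),
    high_hz = c(3, 7, 12, 25, 40))
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' @param x real numeric vector.
#' @return Complex vector of the same length.
#' @export
hilbert_analytic <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

bandpass <- function(x, fs, low, high, order = 2) {
  nyq <- fs / 2
  if (!(low > 0 && high > low && high < nyq))
    stop("band must satisfy 0 < low < high < Nyquist")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  filtfilt_fast(bf, x)
}

#' Welch power spectral density over clean segments
#'
#' Standard averaged modified periodogram: each segment is cut into
#' Hamming-windowed, 50%-overlapping stretches of `window_s`, per-window
#' one-sided periodograms (density scaling, microvolts squared per Hz) are
#' averaged with equal weight per window (hence duration weighting across
#' segments), and the channel-average spectrum is reported alongside the
#' per-channel ones.
#'
#' @param segments an `eeg_segments` object from [apply_mask()], or a single
#'   numeric matrix/vector (treated as one segment).
#' @param fs sampling rate, Hz (taken from `segments` when available).
#' @param window_s window length in seconds.
#' @param overlap_frac fractional window overlap in \[0, 1).
#' @param channels optional subset of channel labels.
#' @return A `psd_result`: `freq_hz`, `power` (freq x channel matrix),
#'   `channel_avg`, `n_windows`.
#' @export
welch_psd <- function(segments, fs = NULL, window_s = 4,
                      overlap_frac = 0.5, channels = NULL) {
  segs <- as_segment_list(segments, fs, channels)
  fs <- segs$fs
  nw <- round(window_s * fs)
  step <- max(1L, round(nw * (1 - overlap_frac)))
  usable <- Filter(function(s) nrow(s) >= nw, segs$data)
  if (!length(usable))
    stop("no clean segment of at least ", window_s, " s available")
  win <- 0.54 - 0.46 * cos(2 * pi * seq_len(nw) / (nw + 1))  # Hamming
  u <- sum(win^2)
  nfreq <- floor(nw / 2) + 1L
  acc <- matrix(0, nfreq, ncol(usable[[1]]))
  nwin <- 0L
  for (seg in usable) {
    starts <- seq(1L, nrow(seg) - nw + 1L, by = step)
    for (s0 in starts) {
      blk <- seg[s0:(s0 + nw - 1L), , drop = FALSE]
      blk <- sweep(blk, 2, colMeans(blk))
      spec <- Mod(stats::mvfft(blk * win))^2 / (fs * u)
      one <- spec[seq_len(nfreq), , drop = FALSE]
      if (nw %% 2 == 0) {
        if (nfreq > 2) one[2:(nfreq - 1L), ] <- 2 * one[2:(nfreq - 1L), ]
      } else if (nfreq > 1) one[2:nfreq, ] <- 2 * one[2:nfreq, ]
      acc <- acc + one
      nwin <- nwin + 1L
    }
  }
  power <- acc / nwin
  colnames(power) <- segs$channels
  structure(list(freq_hz = (seq_len(nfreq) - 1L) * fs / nw,
                 power = power, channel_avg = rowMeans(power),
                 n_windows = nwin),
            class = "psd_result")
}

# normalize the various segment inputs to list(data=list of matrices, fs,
# channels)
as_segment_list <- function(segments, fs = NULL, channels = NULL) {
  if (inherits(segments, "eeg_segments")) {
    keep <- channels %||% segments$channels
    data <- lapply(segments$segments, function(s)
      s$data[, keep, drop = FALSE])
    list(data = data, fs = segments$fs, channels = keep)
  } else {
    if (is.null(fs)) stop("`fs` is required for raw-matrix input")
    m <- as.matrix(segments)
    if (is.null(colnames(m)))
      colnames(m) <- paste0("ch", seq_len(ncol(m)))
    keep <- channels %||% colnames(m)
    list(data = list(m[, keep, drop = FALSE]), fs = fs, channels = keep)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-channel agreement of binarized derivative signs
#'
#' The core BDM statistic: for an n x C matrix of +/-1 signs, the per-sample
#' agreement is |row sum| / C and the synchrony is its time average. Equals
#' 1 iff all channels agree at every sample; for C = 4 independent
#' equiprobable signs the expectation is E|S|/4 = 0.375.
#'
#' @param signs numeric matrix of +/-1 (samples x channels).
#' @return Scalar in \[0, 1\].
#' @export
sign_agreement <- function(signs) {
  if (ncol(signs) < 2) stop("synchrony is undefined for a single channel")
  mean(abs(rowSums(signs)) / ncol(signs))
}

#' Band-specific BDM synchrony across channels
#'
#' Per segment: band-pass each channel, take the power envelope (squared
#' magnitude of the analytic signal), first-difference it, binarize the
#' derivative with a signum (ties mapped to +1), and average the per-sample
#' cross-channel agreement |sum of signs| / C. Segments are processed
#' independently (filtering never crosses excised gaps), a 1 s filter-edge
#' guard is dropped at each segment boundary, and the segment values are
#' duration-weighted.
#'
#' @param segments `eeg_segments` or a numeric matrix (see [welch_psd()]).
#' @param band two-element numeric `c(low, high)` Hz, or a row of
#'   [eeg_bands()].
#' @param fs sampling rate when `segments` is a matrix.
#' @param channels channel subset (defaults to scalp channels when
#'   `segments` carries roles).
#' @param edge_guard_s samples dropped at each segment edge, seconds.
#' @return List: `synchrony` in \[0, 1\], `retained_s` seconds actually
#'   used.
#' @export
bdm_synchrony <- function(segments, band, fs = NULL, channels = NULL,
                          edge_guard_s = 1) {
  if (is.data.frame(band)) band <- c(band$low_hz, band$high_hz)
  if (inherits(segments, "eeg_segments") && is.null(channels))
    channels <- names(segments$roles)[segments$roles == "scalp"]
  segs <- as_segment_list(segments, fs, channels)
  if (length(segs$channels) < 2)
    stop("synchrony is undefined for fewer than 2 channels")
  fs <- segs$fs
  guard <- round(edge_guard_s * fs)
  total <- 0
  acc <- 0
  for (seg in segs$data) {
    n <- nrow(seg)
    if (n - 2 * guard < fs) next  # need >= 1 s of usable envelope
    env <- vapply(seq_len(ncol(seg)), function(j) {
      xb <- bandpass(seg[, j], fs, band[1], band[2])
      Mod(hilbert_analytic(xb))^2
    }, numeric(n))
    use <- (guard + 1L):(n - guard)
    d <- diff(env[use, , drop = FALSE])
    s <- sign(d)
    s[s == 0] <- 1
    wgt <- nrow(d)
    acc <- acc + sign_agreement(s) * wgt
    total <- total + wgt
  }
  if (total == 0)
    stop("no segment long enough for band [", band[1], ", ", band[2],
         "] Hz after edge guards")
  list(synchrony = acc / total, retained_s = total / fs)
}

#' BDM synchrony on a continuous recording with masked samples excised
#'
#' Alternative to the per-segment route for short recordings: each channel
#' is band-limited and made analytic in one step (frequency-domain
#' brick-wall band-pass of the analytic spectrum) over the whole
#' recording, the power envelope is first-differenced and binarized, and
#' samples falling inside the artifact mask (or within `margin_s` of it)
#' are dropped from the sign stream before averaging the cross-channel
#' agreement. Avoids the per-segment filter transients that dominate the
#' slow bands when artifacts chop the recording finely.
#'
#' @param rec an [eeg_recording()] (already re-referenced/filtered).
#' @param mask an `artifact_mask`, or `NULL` for no exclusion.
#' @param band `c(low, high)` Hz.
#' @param channels channel subset (default: scalp channels).
#' @param margin_s extra guard excised around each masked interval.
#' @return List: `synchrony`, `retained_s`.
#' @export
bdm_synchrony_masked <- function(rec, mask, band, channels = NULL,
                                 margin_s = 0.5) {
  if (is.data.frame(band)) band <- c(band$low_hz, band$high_hz)
  if (is.null(channels))
    channels <- names(rec$roles)[rec$roles == "scalp"]
  if (length(channels) < 2)
    stop("synchrony is undefined for fewer than 2 channels")
  fs <- rec$fs
  if (!(band[1] > 0 && band[2] > band[1] && band[2] < fs / 2))
    stop("band must satisfy 0 < low < high < Nyquist")
  n <- n_samples(rec)
  freq <- (seq_len(n) - 1L) * fs / n
  sel <- freq >= band[1] & freq <= band[2]  # analytic: positive side only
  gain <- ifelse(sel, 2, 0)
  gain[1] <- 0
  env <- vapply(channels, function(ch) {
    a <- stats::fft(stats::fft(rec$data[, ch]) * gain, inverse = TRUE) / n
    Mod(a)^2
  }, numeric(n))
  d <- diff(env)
  s <- sign(d)
  s[s == 0] <- 1
  keep <- rep(TRUE, nrow(s))
  iv <- if (is.null(mask)) NULL else mask$intervals
  if (!is.null(iv) && nrow(iv)) {
    grow <- cbind(iv[, 1] - margin_s, iv[, 2] + margin_s)
    tt <- (seq_len(nrow(s)) - 0.5) / fs
    keep <- !point_in_set(tt, merge_intervals(grow))
  }
  if (!any(keep)) stop("mask leaves no samples for synchrony")
  list(synchrony = sign_agreement(s[keep, , drop = FALSE]),
       retained_s = sum(keep) / fs)
}

#' Per-band synchrony profile for one session
#'
#' @param segments `eeg_segments` (scalp channels used by default).
#' @param bands tibble as from [eeg_bands()].
#' @param ... passed to [bdm_synchrony()].
#' @return Tibble: `band`, `synchrony`, `retained_s`.
#' @export
synchrony_profile <- function(segments, bands = eeg_bands(), ...) {
  if (inherits(segments, "eeg_segments") && !length(segments$segments))
    stop("empty segment set: no clean data to synchronize")
  res <- lapply(seq_len(nrow(bands)), function(i) {
    r <- bdm_synchrony(segments, c(bands$low_hz[i], bands$high_hz[i]), ...)
    tibble::tibble(band = bands$band[i], synchrony = r$synchrony,
                   retained_s = r$retained_s)
  })
  dplyr::bind_rows(res)
}
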