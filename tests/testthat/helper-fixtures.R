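# Shared fixtures: small, fast, fully synthetic.

# filter settings usable at the compressed sampling rates (Nyquist 62.5 Hz)
compressed_filter <- function() filter_spec(lowpass_hz = 45, notch_hz = NULL)

# a minimal recording with known content on every channel role
toy_recording <- function(n = 1000, fs = 100, fill = 0) {
  data <- matrix(fill, n, 8)
  eeg_recording(data,
                channels = c("Fz", "Cz", "Pz", "Oz", "EOG-L", "EOG-R",
                             "A1", "A2"),
                roles = c(rep("scalp", 4), "eog", "eog",
                          "mastoid", "mastoid"),
                fs = fs)
}

# bilateral EOG background: slow correlated noise at a given SD
toy_eog_background <- function(n, fs, sd_uv = 5, seed = 1) {
  set.seed(seed)
  lp <- signal::butter(2, 5 / (fs / 2), type = "low")
  mk <- function() {
    x <- as.numeric(signal::filtfilt(lp, rnorm(n)))
    sd_uv * x / sd(x)
  }
  list(l = mk(), r = mk())
}

# inject a half-sine deflection; phase_sign -1 gives the anti-phase pair
inject_halfsine <- function(l, r, fs, onset_s, dur_s, amp_uv,
                            phase_sign = -1) {
  tt <- seq(0, dur_s, by = 1 / fs)
  hs <- amp_uv * sin(pi * tt / dur_s)
  idx <- round(onset_s * fs) + seq_along(hs)
  l[idx] <- l[idx] + hs
  r[idx] <- r[idx] + phase_sign * 0.9 * hs
  list(l = l, r = r)
}

# independent-oracle Wilcoxon signed-rank: exact two-sided p by full
# enumeration of the 2^n sign patterns (no ties, zeros removed upstream)
enum_wilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  ev <- n * (n + 1) / 4
  vs <- vapply(0:(2^n - 1), function(m) {
    signs <- as.logical(bitwAnd(m, 2^(0:(n - 1))))
    sum(rk[signs])
  }, numeric(1))
  mean(abs(vs - ev) >= abs(v_obs - ev) - 1e-12)
}
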