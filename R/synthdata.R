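#' Cohort configuration for the synthetic paired-drive study
#'
#' Defines the study conditions the generator emulates: each subject
#' completes one manually controlled and one self-driving drive (order
#' counterbalanced in blocks of four), with slow rolling eye movement (SREM)
#' counts following an over-dispersed negative-binomial law whose rate
#' depends on condition and habitual sleep duration, band-limited EEG with
#' controllable cross-channel envelope coupling, ocular artifacts, and
#' condition-dependent PVT/KSS outcomes.
#'
#' Condition-varying parameters (`band_coupling`, `pvt_mu_ms`,
#' `pvt_sigma_ms`, `lapse_prob`) take a named value per condition
#' (`manual`, `self_driving`); scalars are recycled to both conditions.
#'
#' @param n_subjects number of subjects (two sessions each).
#' @param drive_duration_s drive length in seconds (default 2880, i.e.
#'   48 min).
#' @param sampling_rate_hz EEG/EOG sampling rate in Hz.
#' @param srem_mean_manual expected SREM count per manual drive at the
#'   cohort-mean habitual sleep duration.
#' @param condition_effect_srem_log_rr log rate ratio of SREM counts,
#'   self-driving vs manual.
#' @param sleep_slope_log_b per-hour log slope of the SREM rate on habitual
#'   sleep duration (negative: shorter sleepers roll more).
#' @param nb_dispersion negative-binomial dispersion (gamma shape k, > 0);
#'   count variance is `m + m^2 / k`. Must be > 0 (finite over-dispersion).
#' @param band_coupling per-condition named list of per-band shared-envelope
#'   weights in \[0, 1\] (names `delta`, `theta`, `alpha`, `beta`, `gamma`).
#' @param artifact_rate_per_min blink/eye-movement artifact rate (events
#'   per minute).
#' @param kss_shift ordinal KSS shift, self-driving minus manual, on the
#'   latent scale.
#' @param pvt_mu_ms latency-adjusted mean RT of the PVT body per condition
#'   (ms).
#' @param pvt_sigma_ms within-subject trial SD of the PVT body (ms).
#' @param lapse_prob per-trial probability of an attentional lapse
#'   (adjusted RT > 500 ms) per condition.
#' @param pvt_n_trials trials per 5-min PVT administration.
#' @param sleep_mean_h,sleep_sd_h cohort distribution of habitual sleep (h).
#' @param eeg_noise_uv,eog_noise_uv broadband noise SD, microvolts.
#' @param seed integer RNG seed; every stochastic element derives from it.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 20,
                          drive_duration_s = 2880,
                          sampling_rate_hz = 500,
                          srem_mean_manual = 5,
                          condition_effect_srem_log_rr = 1.06,
                          sleep_slope_log_b = -0.48,
                          nb_dispersion = 0.85,
                          band_coupling = list(
                            manual = c(delta = 0.55, theta = 0.45,
                                       alpha = 0.50, beta = 0.40,
                                       gamma = 0.35),
                            self_driving = c(delta = 0.40, theta = 0.40,
                                             alpha = 0.42, beta = 0.40,
                                             gamma = 0.35)),
                          artifact_rate_per_min = 5,
                          kss_shift = 1.5,
                          pvt_mu_ms = c(manual = 273, self_driving = 294),
                          pvt_sigma_ms = c(manual = 65, self_driving = 65),
                          lapse_prob = c(manual = 0.014,
                                         self_driving = 0.037),
                          pvt_n_trials = 45,
                          sleep_mean_h = 5.9, sleep_sd_h = 0.9,
                          eeg_noise_uv = 3, eog_noise_uv = 6,
                          seed = 1L) {
  chk_pos <- function(x, nm, strict = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
        (if (strict) x <= 0 else x < 0))
      stop("invalid `", nm, "`: must be a ",
           if (strict) "positive" else "nonnegative", " scalar")
  }
  chk_pos(n_subjects, "n_subjects")
  if (n_subjects != round(n_subjects)) stop("invalid `n_subjects`: not integer")
  chk_pos(drive_duration_s, "drive_duration_s")
  chk_pos(sampling_rate_hz, "sampling_rate_hz")
  chk_pos(srem_mean_manual, "srem_mean_manual", strict = FALSE)
  chk_pos(nb_dispersion, "nb_dispersion")
  chk_pos(artifact_rate_per_min, "artifact_rate_per_min", strict = FALSE)
  if (!is.numeric(condition_effect_srem_log_rr) ||
      length(condition_effect_srem_log_rr) != 1L)
    stop("invalid `condition_effect_srem_log_rr`")
  if (!is.numeric(sleep_slope_log_b) || length(sleep_slope_log_b) != 1L)
    stop("invalid `sleep_slope_log_b`")
  per_cond <- function(x, nm) {
    if (length(x) == 1L) x <- c(manual = unname(x), self_driving = unname(x))
    if (!all(c("manual", "self_driving") %in% names(x)))
      stop("invalid `", nm, "`: needs values for manual and self_driving")
    x[c("manual", "self_driving")]
  }
  pvt_mu_ms <- per_cond(pvt_mu_ms, "pvt_mu_ms")
  pvt_sigma_ms <- per_cond(pvt_sigma_ms, "pvt_sigma_ms")
  lapse_prob <- per_cond(lapse_prob, "lapse_prob")
  if (any(lapse_prob < 0 | lapse_prob > 1))
    stop("invalid `lapse_prob`: must lie in [0, 1]")
  if (any(pvt_mu_ms <= 150))
    stop("invalid `pvt_mu_ms`: body mean must exceed the 150 ms shift")
  band_names <- c("delta", "theta", "alpha", "beta", "gamma")
  if (!is.list(band_coupling))
    band_coupling <- list(manual = band_coupling,
                          self_driving = band_coupling)
  for (cond in c("manual", "self_driving")) {
    w <- band_coupling[[cond]]
    if (is.null(w) || !all(band_names %in% names(w)))
      stop("invalid `band_coupling`: need named per-band weights for ", cond)
    if (any(w < 0 | w > 1))
      stop("invalid `band_coupling`: weights must lie in [0, 1]")
    band_coupling[[cond]] <- w[band_names]
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("invalid `seed`")
  structure(list(
    n_subjects = as.integer(n_subjects),
    drive_duration_s = drive_duration_s,
    sampling_rate_hz = sampling_rate_hz,
    srem_mean_manual = srem_mean_manual,
    condition_effect_srem_log_rr = condition_effect_srem_log_rr,
    sleep_slope_log_b = sleep_slope_log_b,
    nb_dispersion = nb_dispersion,
    band_coupling = band_coupling,
    artifact_rate_per_min = artifact_rate_per_min,
    kss_shift = kss_shift,
    pvt_mu_ms = pvt_mu_ms, pvt_sigma_ms = pvt_sigma_ms,
    lapse_prob = lapse_prob, pvt_n_trials = as.integer(pvt_n_trials),
    sleep_mean_h = sleep_mean_h, sleep_sd_h = sleep_sd_h,
    eeg_noise_uv = eeg_noise_uv, eog_noise_uv = eog_noise_uv,
    seed = as.integer(seed)), class = "cohort_config")
}

#' Reduced-scale configuration for continuous-integration-sized runs
#'
#' Same statistical structure as [cohort_config()] but 8 subjects and 8-min
#' drives at 250 Hz, so a full [run_study()] completes in minutes. The
#' expected per-session SREM counts are preserved at the default levels
#' (rate compressed in time), so the count models see the same data scale.
#'
#' @param ... overrides passed on to [cohort_config()].
#' @return A `cohort_config`.
#' @export
ci_config <- function(...) {
  defaults <- list(n_subjects = 8, drive_duration_s = 480,
                   sampling_rate_hz = 250)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}

band_center <- function() c(delta = 2, theta = 5.5, alpha = 10,
                            beta = 19, gamma = 33)

band_amp_uv <- function() c(delta = 12, theta = 8, alpha = 10,
                            beta = 5, gamma = 3)

# smooth nonnegative amplitude envelope, mean 1, bandwidth < 1 Hz.
# Synthesized at a low internal rate (the envelope has < bw_hz of
# bandwidth) and linearly interpolated up to fs. The default bandwidth is
# fast enough that the envelope's own derivative dominates filter-leakage
# ripple when the BDM differences it sample by sample.
smooth_envelope <- function(n, fs, bw_hz = 0.8) {
  fs_e <- min(fs, max(10, 8 * bw_hz))
  n_e <- ceiling(n * fs_e / fs) + 4L
  w <- abs(rnorm(n_e))
  bf <- signal::butter(2, min(bw_hz / (fs_e / 2), 0.95), type = "low")
  e <- filtfilt_fast(bf, w)
  e <- stats::approx(seq(0, by = 1 / fs_e, length.out = n_e), e,
                     xout = (seq_len(n) - 1) / fs)$y
  e <- pmax(e, 0.02)
  e / mean(e)
}

# biexponential blink pulse, peak-normalized, length ~dur_s
blink_pulse <- function(fs, dur_s = 0.35, tau_rise = 0.03, tau_fall = 0.1) {
  t <- seq(0, dur_s, by = 1 / fs)
  p <- exp(-t / tau_fall) - exp(-t / tau_rise)
  p / max(p)
}

draw_event_times <- function(n_events, lo, hi, min_gap) {
  if (n_events <= 0L || hi <= lo) return(numeric(0))
  times <- numeric(0)
  for (tries in seq_len(50L * max(n_events, 1L))) {
    if (length(times) >= n_events) break
    cand <- runif(1, lo, hi)
    if (!length(times) || all(abs(cand - times) >= min_gap))
      times <- c(times, cand)
  }
  sort(times)
}

#' Generate a paired-drive cohort with full ground truth
#'
#' Draws, for each subject, habitual sleep duration, a latent sleepiness
#' trait, and a shared gamma frailty; assigns condition order counterbalanced
#' in blocks of four (so a 20-subject cohort has exactly 10 subjects starting
#' with the manual drive); and, per session, draws the SREM count from the
#' frailty-mixed Poisson (marginally negative binomial) law
#' `lambda = m_manual * exp(log_rr * self + slope * (sleep_h - mean))`,
#' places SREM onsets/durations and blink artifacts, and records everything
#' in the ground truth.
#'
#' Blink onsets are kept at least 1 s away from SREM intervals: blinking is
#' physiologically suppressed while the eyes roll at the wake-sleep
#' transition.
#'
#' @param config a [cohort_config()].
#' @return A `cohort` list: `sessions` (list of session descriptors, each
#'   with `id`, `subject`, `condition`, `order`, `seed`, `sleep_h`),
#'   `truth` (per-session SREM/artifact tables, per-band coupling,
#'   per-subject traits), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  dur <- config$drive_duration_s

  sleep_h <- rnorm(n, config$sleep_mean_h, config$sleep_sd_h)
  sleep_h <- pmin(pmax(sleep_h, 3), 10)
  latent <- rnorm(n)
  frailty <- rgamma(n, shape = config$nb_dispersion,
                    rate = config$nb_dispersion)
  pvt_offset <- rnorm(n, 0, 30)

  # counterbalanced order in blocks of four: two manual-first per block
  first_cond <- character(n)
  b0 <- 0L
  while (b0 < n) {
    blk <- seq(b0 + 1L, min(b0 + 4L, n))
    k <- length(blk)
    n_manual <- ceiling(k / 2)
    pick <- sample(blk, n_manual)
    first_cond[blk] <- "self_driving"
    first_cond[pick] <- "manual"
    b0 <- b0 + 4L
  }

  subj_seed <- sample.int(.Machine$integer.max - 10L, n)
  sessions <- list()
  truth_sessions <- list()
  subjects <- tibble::tibble(subject = seq_len(n), sleep_h = sleep_h,
                             latent = latent, frailty = frailty,
                             pvt_offset = pvt_offset,
                             first_condition = first_cond,
                             seed = subj_seed)

  for (i in seq_len(n)) {
    conds <- if (first_cond[i] == "manual")
      c("manual", "self_driving") else c("self_driving", "manual")
    for (j in 1:2) {
      cond <- conds[j]
      lambda <- config$srem_mean_manual *
        exp(config$condition_effect_srem_log_rr *
              (cond == "self_driving") +
            config$sleep_slope_log_b * (sleep_h[i] - config$sleep_mean_h)) *
        frailty[i]
      n_srem <- rpois(1, lambda)
      srem_dur <- runif(n_srem, 1.0, 3.0)
      onsets <- draw_event_times(n_srem, 5, max(dur - 8, 5.01), 4)
      n_placed <- length(onsets)
      srem <- tibble::tibble(onset_s = onsets,
                             duration_s = srem_dur[seq_len(n_placed)],
                             amplitude_uv = runif(n_placed, 35, 60))
      srem <- srem[order(srem$onset_s), ]

      n_blink <- rpois(1, config$artifact_rate_per_min * dur / 60)
      bl <- runif(n_blink, 1, max(dur - 1.5, 1.01))
      if (nrow(srem)) {
        ok <- !vapply(bl, function(b)
          any(b > srem$onset_s - 1.4 &
              b < srem$onset_s + srem$duration_s + 1.0), logical(1))
        bl <- bl[ok]
      }
      bl <- sort(bl)
      art <- tibble::tibble(onset_s = bl, duration_s = 0.35,
                            amplitude_uv = runif(length(bl), 180, 300))

      id <- sprintf("S%03d_%s", i, cond)
      sessions[[id]] <- list(
        id = id, subject = i, condition = cond, order = j,
        duration_s = dur, fs = config$sampling_rate_hz,
        sleep_h = sleep_h[i],
        seed = (subj_seed[i] + 7L * j) %% .Machine$integer.max)
      truth_sessions[[id]] <- list(
        srem = srem, artifacts = art,
        coupling = config$band_coupling[[cond]],
        srem_count = n_placed, srem_count_drawn = n_srem)
    }
  }
  structure(list(sessions = sessions,
                 truth = list(sessions = truth_sessions,
                              subjects = subjects),
                 config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects, %d sessions of %.0f s @ %g Hz\n",
              x$config$n_subjects, length(x$sessions),
              x$config$drive_duration_s, x$config$sampling_rate_hz))
  invisible(x)
}

#' Synthesize the EEG/EOG recording for one session
#'
#' Builds the eight-channel recording (Fz, Cz, Pz, Oz, EOG-L, EOG-R, A1,
#' A2). Each scalp channel is the sum over the five canonical bands of a
#' sinusoidal carrier at the band center, amplitude-modulated by a mixture
#' of a band-shared envelope (weight = the session's coupling for that band)
#' and a channel-private envelope, plus broadband noise. EOG channels carry
#' slow background activity, in-phase biexponential blinks, and anti-phase
#' half-sine SREM deflections (EOG-R = -0.9 x EOG-L) at the ground-truth
#' onsets. Mastoids are low-amplitude noise.
#'
#' @param session a session descriptor from [generate_cohort()].
#' @param truth the matching per-session ground truth
#'   (`cohort$truth$sessions[[session$id]]`).
#' @param config the [cohort_config()] used to build the cohort.
#' @param seed optional seed override (defaults to the session seed).
#' @return An [eeg_recording()] in microvolts.
#' @export
generate_eeg_eog <- function(session, truth, config, seed = session$seed) {
  w <- truth$coupling
  if (any(w < 0 | w > 1)) stop("band coupling must lie in [0, 1]")
  set.seed(seed)
  fs <- session$fs
  nsmp <- round(session$duration_s * fs)
  t <- (seq_len(nsmp) - 1) / fs
  scalp <- c("Fz", "Cz", "Pz", "Oz")
  fc <- band_center()
  amp <- band_amp_uv()

  eeg <- matrix(0, nsmp, 4, dimnames = list(NULL, scalp))
  for (b in names(fc)) {
    shared <- smooth_envelope(nsmp, fs)
    for (k in seq_along(scalp)) {
      env <- w[[b]] * shared +
        (1 - w[[b]]) * smooth_envelope(nsmp, fs)
      phi <- runif(1, 0, 2 * pi)
      eeg[, k] <- eeg[, k] + amp[[b]] * env * sin(2 * pi * fc[[b]] * t + phi)
    }
  }
  if (config$eeg_noise_uv > 0)
    eeg <- eeg + matrix(rnorm(nsmp * 4, 0, config$eeg_noise_uv), nsmp, 4)

  # EOG background: partly conjugate (shared gaze), partly private.
  # Built at 25 Hz (content is < 5 Hz) and interpolated up.
  slow_noise <- function() {
    fs_e <- min(fs, 25)
    n_e <- ceiling(nsmp * fs_e / fs) + 4L
    bf <- signal::butter(2, min(5 / (fs_e / 2), 0.9), type = "low")
    e <- filtfilt_fast(bf, rnorm(n_e))
    stats::approx(seq(0, by = 1 / fs_e, length.out = n_e), e,
                  xout = (seq_len(nsmp) - 1) / fs)$y
  }
  sig_eog <- config$eog_noise_uv
  if (sig_eog > 0) {
    shared_g <- slow_noise()
    mk <- function() {
      x <- 0.6 * shared_g + 0.8 * slow_noise()
      sig_eog * x / max(stats::sd(x), 1e-12)
    }
    eog_l <- mk(); eog_r <- mk()
  } else {
    eog_l <- numeric(nsmp); eog_r <- numeric(nsmp)
  }

  add_at <- function(x, i0, pulse) {
    idx <- i0 + seq_along(pulse) - 1L
    keep <- idx >= 1L & idx <= nsmp
    x[idx[keep]] <- x[idx[keep]] + pulse[keep]
    x
  }
  if (nrow(truth$artifacts)) {
    bp <- blink_pulse(fs)
    for (r in seq_len(nrow(truth$artifacts))) {
      i0 <- round(truth$artifacts$onset_s[r] * fs) + 1L
      a <- truth$artifacts$amplitude_uv[r]
      eog_l <- add_at(eog_l, i0, a * bp)
      eog_r <- add_at(eog_r, i0, 0.9 * a * bp)
    }
  }
  if (nrow(truth$srem)) {
    for (r in seq_len(nrow(truth$srem))) {
      d <- truth$srem$duration_s[r]
      a <- truth$srem$amplitude_uv[r]
      tt <- seq(0, d, by = 1 / fs)
      hs <- a * sin(pi * tt / d)
      i0 <- round(truth$srem$onset_s[r] * fs) + 1L
      eog_l <- add_at(eog_l, i0, hs)
      eog_r <- add_at(eog_r, i0, -0.9 * hs)
    }
  }

  mast <- matrix(rnorm(nsmp * 2, 0, 2), nsmp, 2)
  if (config$eeg_noise_uv == 0 && config$eog_noise_uv == 0)
    mast[] <- 0
  data <- cbind(eeg, `EOG-L` = eog_l, `EOG-R` = eog_r,
                A1 = mast[, 1], A2 = mast[, 2])
  eeg_recording(data,
                channels = c(scalp, "EOG-L", "EOG-R", "A1", "A2"),
                roles = c(rep("scalp", 4), "eog", "eog",
                          "mastoid", "mastoid"),
                fs = fs, start_s = 0)
}

#' Sample raw PVT reaction times
#'
#' Trial RTs are a mixture of a shifted-lognormal body (150 ms shift;
#' `mean_ms`/`sd_ms` parameterize the body mean and SD on the
#' latency-adjusted scale) and, with probability `lapse_prob`, a lapse tail
#' of `500 + Exp(mean 120)` ms. The device system latency is added so the
#' returned values are raw button-press times; [summarize_pvt()] subtracts
#' it again.
#'
#' @param n number of trials.
#' @param mean_ms,sd_ms body mean and SD on the adjusted scale (ms).
#' @param lapse_prob per-trial lapse probability.
#' @param shift_ms lognormal shift (ms).
#' @param latency_ms system latency added to every trial (ms).
#' @return Numeric vector of raw RTs (ms).
#' @export
r_pvt_trials <- function(n, mean_ms, sd_ms, lapse_prob = 0,
                         shift_ms = 150, latency_ms = 82) {
  stopifnot(mean_ms > shift_ms, sd_ms > 0,
            lapse_prob >= 0, lapse_prob <= 1)
  m <- mean_ms - shift_ms
  sl2 <- log(1 + sd_ms^2 / m^2)
  body <- shift_ms + rlnorm(n, log(m) - sl2 / 2, sqrt(sl2))
  is_lapse <- runif(n) < lapse_prob
  body[is_lapse] <- 500 + rexp(sum(is_lapse), rate = 1 / 120)
  body + latency_ms
}

#' Generate behavioral outcomes for one session
#'
#' PVT trials via [r_pvt_trials()] with the condition's parameters plus the
#' subject's stable speed offset; a KSS rating from a latent-normal model
#' (base 5.2 + 0.8 x latent trait + shift for self-driving + noise,
#' thresholded to 1..9); and the subject's 14-day sleep history (daily
#' minutes around the habitual mean). The sleep history derives from the
#' subject-level seed, so both sessions of a subject return the same
#' history.
#'
#' @param session a session descriptor from [generate_cohort()].
#' @param cohort_truth the cohort ground truth (`cohort$truth`).
#' @param config the [cohort_config()].
#' @param seed optional seed override.
#' @return List with `pvt` (tibble: trial, rt_raw_ms), `kss` (integer 1-9),
#'   `sleep` (tibble: day, sleep_min).
#' @export
generate_behavioral <- function(session, cohort_truth, config,
                                seed = session$seed) {
  subj <- cohort_truth$subjects[cohort_truth$subjects$subject ==
                                  session$subject, ]
  cond <- session$condition
  set.seed(subj$seed)  # subject-level: identical across sessions
  sleep_min <- rnorm(14, subj$sleep_h * 60, 45)
  sleep_min <- pmin(pmax(sleep_min, 0), 1440)
  sleep <- tibble::tibble(day = 1:14, sleep_min = sleep_min)

  set.seed(seed + 1L)
  rts <- r_pvt_trials(config$pvt_n_trials,
                      config$pvt_mu_ms[[cond]] + subj$pvt_offset,
                      config$pvt_sigma_ms[[cond]],
                      config$lapse_prob[[cond]])
  pvt <- tibble::tibble(trial = seq_along(rts), rt_raw_ms = rts)

  latent_kss <- 5.2 + 0.8 * subj$latent +
    config$kss_shift * (cond == "self_driving") + rnorm(1, 0, 1.8)
  kss <- as.integer(pmin(pmax(round(latent_kss), 1), 9))
  list(pvt = pvt, kss = kss, sleep = sleep)
}

#' Simulate a 14-day actigraphy record with known sleep totals
#'
#' Construction oracle for the actigraphy summarizer: builds one-minute
#' epochs (activity count + sleep/wake classification) and the matching
#' rest-interval diary such that the per-day sleep totals equal
#' `sleep_min_by_day` exactly. Each night's rest interval starts at 23:00
#' and contains the planned sleep minutes as `sleep` epochs (activity
#' < 150) padded with `wake` epochs; daytime epochs are active.
#'
#' @param sleep_min_by_day integer vector of nightly sleep minutes (one per
#'   day, each <= 480 to fit the 8-h rest window).
#' @param nap_min_by_day optional vector of nap minutes (following day),
#'   same length.
#' @param seed RNG seed for the activity counts.
#' @return List with `epochs` (tibble: minute, activity, status) and
#'   `rest_intervals` (tibble: day, type, start_min, end_min).
#' @export
simulate_actigraphy <- function(sleep_min_by_day, nap_min_by_day = NULL,
                                seed = 1L) {
  n_days <- length(sleep_min_by_day)
  if (is.null(nap_min_by_day)) nap_min_by_day <- rep(0L, n_days)
  stopifnot(length(nap_min_by_day) == n_days,
            all(sleep_min_by_day >= 0), all(sleep_min_by_day <= 480))
  set.seed(seed)
  total_min <- n_days * 1440L + 600L  # room for the last night
  activity <- round(runif(total_min, 200, 600))
  status <- rep("wake", total_min)
  rest <- list()
  for (d in seq_len(n_days)) {
    r0 <- (d - 1L) * 1440L + 23L * 60L
    r1 <- r0 + 500L
    idx_rest <- (r0 + 1L):r1
    activity[idx_rest] <- round(runif(length(idx_rest), 160, 400))
    ns <- sleep_min_by_day[d]
    if (ns > 0) {
      sl <- (r0 + 11L):(r0 + 10L + ns)  # 10 min settling, then sleep
      status[sl] <- "sleep"
      activity[sl] <- round(runif(ns, 0, 120))
    }
    rest[[length(rest) + 1L]] <-
      tibble::tibble(day = d, type = "main", start_min = r0, end_min = r1)
    if (nap_min_by_day[d] > 0) {
      n0 <- (d - 1L) * 1440L + 14L * 60L
      nn <- nap_min_by_day[d]
      nidx <- (n0 + 1L):(n0 + nn)
      status[nidx] <- "sleep"
      activity[nidx] <- round(runif(nn, 0, 120))
      rest[[length(rest) + 1L]] <-
        tibble::tibble(day = d, type = "nap", start_min = n0,
                       end_min = n0 + nn)
    }
  }
  list(epochs = tibble::tibble(minute = seq_len(total_min) - 1L,
                               activity = activity, status = status),
       rest_intervals = dplyr::bind_rows(rest))
}
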