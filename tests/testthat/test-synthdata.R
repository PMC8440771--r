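test_that("config validation names the offending field", {
  expect_error(cohort_config(n_subjects = -1), "n_subjects")
  expect_error(cohort_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(cohort_config(lapse_prob = 1.5), "lapse_prob")
  expect_error(cohort_config(band_coupling = list(
    manual = c(delta = 1.2, theta = 0.4, alpha = 0.4, beta = 0.4,
               gamma = 0.4),
    self_driving = c(delta = 0.4, theta = 0.4, alpha = 0.4, beta = 0.4,
                     gamma = 0.4))), "band_coupling")
  expect_error(cohort_config(drive_duration_s = 0), "drive_duration_s")
})

test_that("block-of-four counterbalancing puts half the cohort manual-first", {
  co <- generate_cohort(cohort_config(n_subjects = 20, drive_duration_s = 60,
                                      sampling_rate_hz = 100, seed = 3))
  first <- co$truth$subjects$first_condition
  expect_equal(sum(first == "manual"), 10L)
  # and within every block of four, exactly two
  blocks <- split(first, rep(1:5, each = 4))
  for (b in blocks) expect_equal(sum(b == "manual"), 2L)
  # every subject has exactly two sessions, one per condition
  cond <- vapply(co$sessions, function(s) s$condition, character(1))
  subj <- vapply(co$sessions, function(s) s$subject, numeric(1))
  tab <- table(subj, cond)
  expect_true(all(tab == 1L))
})

test_that("cohort generation is deterministic in (config, seed)", {
  cfg <- cohort_config(n_subjects = 4, drive_duration_s = 120,
                       sampling_rate_hz = 100, seed = 77)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- cohort_config(n_subjects = 4, drive_duration_s = 120,
                        sampling_rate_hz = 100, seed = 78)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg2)
  expect_false(identical(co1$truth$subjects$sleep_h,
                         co2$truth$subjects$sleep_h))
})

test_that("SREM counts are over-dispersed and recover the NB moments", {
  k <- 2
  m <- 5
  cfg <- cohort_config(n_subjects = 10000, drive_duration_s = 600,
                       sampling_rate_hz = 100, srem_mean_manual = m,
                       condition_effect_srem_log_rr = 0,
                       sleep_slope_log_b = 0, nb_dispersion = k,
                       artifact_rate_per_min = 0, seed = 9)
  co <- generate_cohort(cfg)
  counts <- vapply(co$truth$sessions, function(s) s$srem_count, numeric(1))
  expect_gt(var(counts), mean(counts))  # over-dispersion
  expect_lt(abs(mean(counts) - m) / m, 0.05)
  v_expect <- m + m^2 / k
  expect_lt(abs(var(counts) - v_expect) / v_expect, 0.05)
})

test_that("null-effect configuration gives exchangeable conditions", {
  cfg <- cohort_config(n_subjects = 400, drive_duration_s = 600,
                       sampling_rate_hz = 100,
                       condition_effect_srem_log_rr = 0,
                       sleep_slope_log_b = 0, artifact_rate_per_min = 0,
                       kss_shift = 0,
                       pvt_mu_ms = 280, pvt_sigma_ms = 60,
                       lapse_prob = 0.02, seed = 21)
  co <- generate_cohort(cfg)
  counts <- vapply(co$sessions, function(s)
    co$truth$sessions[[s$id]]$srem_count, numeric(1))
  cond <- vapply(co$sessions, function(s) s$condition, character(1))
  tt <- t.test(counts[cond == "self_driving"], counts[cond == "manual"])
  expect_gt(tt$p.value, 0.01)
  # paired KSS differences symmetric about zero under the null
  kss <- vapply(co$sessions, function(s)
    generate_behavioral(s, co$truth, cfg)$kss, integer(1))
  d <- kss[cond == "self_driving"][order(vapply(
        co$sessions[cond == "self_driving"], `[[`, 0, "subject"))] -
       kss[cond == "manual"][order(vapply(
        co$sessions[cond == "manual"], `[[`, 0, "subject"))]
  expect_lt(abs(mean(d)), 0.3)
})

test_that("recordings are bit-identical under the same seed and differ across seeds", {
  cfg <- cohort_config(n_subjects = 1, drive_duration_s = 20,
                       sampling_rate_hz = 125, seed = 5)
  co <- generate_cohort(cfg)
  ses <- co$sessions[[1]]
  tr <- co$truth$sessions[[ses$id]]
  r1 <- generate_eeg_eog(ses, tr, cfg)
  r2 <- generate_eeg_eog(ses, tr, cfg)
  expect_identical(r1$data, r2$data)
  r3 <- generate_eeg_eog(ses, tr, cfg, seed = ses$seed + 1)
  expect_false(identical(r1$data, r3$data))
})

test_that("full coupling with zero noise yields identical band envelopes", {
  one <- c(delta = 1, theta = 1, alpha = 1, beta = 1, gamma = 1)
  cfg <- cohort_config(n_subjects = 1, drive_duration_s = 40,
                       sampling_rate_hz = 125,
                       band_coupling = list(manual = one, self_driving = one),
                       srem_mean_manual = 0, artifact_rate_per_min = 0,
                       eeg_noise_uv = 0, eog_noise_uv = 0, seed = 8)
  co <- generate_cohort(cfg)
  ses <- co$sessions[[1]]
  rec <- generate_eeg_eog(ses, co$truth$sessions[[ses$id]], cfg)
  # delta band: envelopes of all four scalp channels agree (interior)
  fs <- rec$fs
  env <- sapply(c("Fz", "Cz", "Pz", "Oz"), function(ch) {
    bf <- signal::butter(2, c(1, 3) / (fs / 2), type = "pass")
    x <- as.numeric(signal::filtfilt(bf, channel(rec, ch)))
    Mod(hilbert_analytic(x))
  })
  interior <- (2 * fs):(nrow(env) - 2 * fs)
  spread <- apply(env[interior, ], 1, function(r) diff(range(r)))
  expect_lt(median(spread / mean(env[interior, ])), 0.05)
})

test_that("ground-truth SREMs appear as anti-phase deflections in the EOG", {
  cfg <- cohort_config(n_subjects = 1, drive_duration_s = 60,
                       sampling_rate_hz = 125, srem_mean_manual = 3,
                       artifact_rate_per_min = 0, eog_noise_uv = 0.2,
                       seed = 14)
  co <- generate_cohort(cfg)
  ses <- co$sessions[[1]]
  tr <- co$truth$sessions[[ses$id]]
  expect_true(nrow(tr$srem) >= 1)
  expect_true(all(tr$srem$duration_s >= 0.5))
  rec <- generate_eeg_eog(ses, tr, cfg)
  l <- channel(rec, "EOG-L")
  r <- channel(rec, "EOG-R")
  for (i in seq_len(nrow(tr$srem))) {
    mid <- round((tr$srem$onset_s[i] + tr$srem$duration_s[i] / 2) *
                   rec$fs) + 1L
    expect_equal(l[mid], tr$srem$amplitude_uv[i], tolerance = 0.05)
    expect_equal(r[mid], -0.9 * tr$srem$amplitude_uv[i], tolerance = 0.05)
  }
})

test_that("synthetic band carriers concentrate power inside their band", {
  fs <- 250
  n <- 120 * fs
  bands <- eeg_bands()
  set.seed(42)
  for (i in seq_len(nrow(bands))) {
    f0 <- (bands$low_hz[i] + bands$high_hz[i]) / 2
    env <- drowsydrive:::smooth_envelope(n, fs)
    x <- env * sin(2 * pi * f0 * (0:(n - 1)) / fs)
    psd <- welch_psd(matrix(x, ncol = 1), fs = fs, window_s = 4)
    inband <- psd$freq_hz >= bands$low_hz[i] & psd$freq_hz <= bands$high_hz[i]
    frac <- sum(psd$channel_avg[inband]) / sum(psd$channel_avg)
    expect_gt(frac, 0.90)
  }
})

test_that("PVT trial generator recovers its configured moments", {
  set.seed(31)
  rt <- r_pvt_trials(10000, mean_ms = 300, sd_ms = 65, lapse_prob = 0)
  adj <- rt - 82
  expect_lt(abs(mean(adj) - 300), 2)
  expect_lt(abs(sd(adj) - 65), 3)
  # tight body, no lapse channel: no adjusted RT can cross 500 ms
  set.seed(32)
  rt0 <- r_pvt_trials(10000, mean_ms = 300, sd_ms = 20, lapse_prob = 0)
  expect_equal(sum(rt0 - 82 > 500), 0L)
})

test_that("behavioral outcomes are deterministic and share sleep history", {
  cfg <- cohort_config(n_subjects = 2, drive_duration_s = 30,
                       sampling_rate_hz = 100, seed = 19)
  co <- generate_cohort(cfg)
  s1 <- co$sessions[[1]]
  s2 <- co$sessions[[2]]  # same subject, other condition
  expect_equal(s1$subject, s2$subject)
  b1 <- generate_behavioral(s1, co$truth, cfg)
  b2 <- generate_behavioral(s2, co$truth, cfg)
  expect_identical(b1$sleep, b2$sleep)          # subject-level history
  expect_false(identical(b1$pvt, b2$pvt))       # session-level trials
  expect_identical(b1, generate_behavioral(s1, co$truth, cfg))
  expect_true(b1$kss >= 1 && b1$kss <= 9)
  expect_true(all(b1$sleep$sleep_min >= 0 & b1$sleep$sleep_min <= 1440))
})
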