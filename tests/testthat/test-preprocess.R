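test_that("mastoid re-referencing is exact channel arithmetic", {
  rec <- toy_recording(n = 500, fs = 100)
  set.seed(2)
  rec$data[] <- rnorm(length(rec$data))

  # zero mastoids leave everything unchanged
  r0 <- rec
  r0$data[, c("A1", "A2")] <- 0
  out0 <- rereference(r0)
  expect_equal(out0$data, r0$data[, 1:6])

  # constant mastoids shift every channel by -c
  rc <- rec
  rc$data[, c("A1", "A2")] <- 3.5
  outc <- rereference(rc)
  expect_equal(outc$data, rc$data[, 1:6] - 3.5)

  # random recording: sample-wise oracle
  out <- rereference(rec)
  ref <- (rec$data[, "A1"] + rec$data[, "A2"]) / 2
  expect_equal(out$data, rec$data[, 1:6] - ref)
  expect_false("A1" %in% out$channels)

  rec$channels[7] <- "M1"
  colnames(rec$data)[7] <- "M1"
  names(rec$roles)[7] <- "M1"
  expect_error(rereference(rec), "A1")
})

test_that("filter chain removes DC, notches mains, passes mid-band", {
  fs <- 500
  t <- (0:(20 * fs - 1)) / fs
  spec <- filter_spec()
  mk <- function(x) {
    rec <- toy_recording(n = length(x), fs = fs)
    rec$data[, "Cz"] <- x
    rec
  }
  rms <- function(x) sqrt(mean(x^2))
  interior <- (2 * fs):(18 * fs)

  dc <- filter_chain(mk(rep(5, length(t))), spec)
  expect_lt(max(abs(channel(dc, "Cz"))), 0.05)

  s60 <- filter_chain(mk(sin(2 * pi * 60 * t)), spec)
  atten_db <- 20 * log10(rms(sin(2 * pi * 60 * t)[interior]) /
                           rms(channel(s60, "Cz")[interior]))
  expect_gt(atten_db, 20)

  s10 <- filter_chain(mk(sin(2 * pi * 10 * t)), spec)
  gain_db <- 20 * log10(rms(channel(s10, "Cz")[interior]) /
                          rms(sin(2 * pi * 10 * t)[interior]))
  expect_lt(abs(gain_db), 0.5)

  expect_error(filter_chain(mk(t), filter_spec(lowpass_hz = 300)),
               "Nyquist")
})

test_that("filtering is linear in the input amplitude", {
  fs <- 250
  set.seed(4)
  rec <- toy_recording(n = 10 * fs, fs = fs)
  rec$data[] <- rnorm(length(rec$data))
  sc <- rec
  sc$data <- 3.7 * sc$data
  f1 <- filter_chain(rec, filter_spec())
  f2 <- filter_chain(sc, filter_spec())
  expect_equal(f2$data, 3.7 * f1$data, tolerance = 1e-8)
})

test_that("ocular artifact mask matches a brute-force threshold oracle", {
  fs <- 250
  n <- 30 * fs
  t <- (0:(n - 1)) / fs
  l <- 5 * sin(2 * pi * 0.8 * t)
  r <- 5 * sin(2 * pi * 0.8 * t + 0.4)
  # one large blink at t = 10 s on both channels
  pulse <- drowsydrive:::blink_pulse(fs)
  idx <- round(10 * fs) + seq_along(pulse)
  l[idx] <- l[idx] + 200 * pulse
  r[idx] <- r[idx] + 180 * pulse
  mask <- detect_ocular_artifacts(l, r, fs)
  # brute-force oracle for the threshold and flagged region
  p <- abs(l * r)
  thr <- mean(p) + 3 * sd(p)
  hit <- which(p > thr)
  expect_equal(mask$threshold, thr)
  expect_equal(nrow(mask$intervals), 1L)
  expect_equal(unname(mask$intervals[1, 1]), (hit[1] - 1) / fs - 1)
  expect_equal(unname(mask$intervals[1, 2]),
               (hit[length(hit)] - 1) / fs + 1)
  # the two seconds around the blink are gone
  expect_lte(mask$intervals[1, 1], 9.1)
  expect_gte(mask$intervals[1, 2], 11.0)

  # nothing above threshold: empty mask
  m0 <- detect_ocular_artifacts(5 * sin(2 * pi * t) + rnorm(n, 0, 0.1),
                                5 * sin(2 * pi * t + 1) + rnorm(n, 0, 0.1),
                                fs)
  expect_equal(nrow(m0$intervals), 0L)
  expect_equal(m0$excluded_fraction, 0)

  expect_warning(mc <- detect_ocular_artifacts(rep(1, n), rep(2, n), fs),
                 "zero variance")
  expect_equal(nrow(mc$intervals), 0L)
})

test_that("mask application partitions the recording exactly", {
  fs <- 100
  rec <- toy_recording(n = 30 * fs, fs = fs, fill = 1)

  segs0 <- apply_mask(rec, mask_from_intervals(NULL, 30))
  expect_equal(length(segs0$segments), 1L)
  expect_equal(segs0$segments[[1]]$start_s, 0)
  expect_equal(segs0$segments[[1]]$end_s, 30)

  m <- mask_from_intervals(cbind(10, 12), 30)
  segs <- apply_mask(rec, m, min_segment_s = 1)
  expect_equal(length(segs$segments), 2L)
  expect_equal(segs$segments[[1]]$start_s, 0)
  expect_equal(segs$segments[[1]]$end_s, 10)
  expect_equal(segs$segments[[2]]$start_s, 12)
  expect_equal(segs$segments[[2]]$end_s, 30)
  expect_equal(segs$retained_s + segs$excluded_s, 30)

  # property: over random masks, retained + excluded always rebuilds the
  # duration to one-sample accuracy and segments avoid the mask
  set.seed(11)
  for (i in 1:100) {
    k <- sample(0:6, 1)
    iv <- if (k > 0) {
      a <- sort(runif(k, 0, 29))
      cbind(a, pmin(a + runif(k, 0.1, 4), 30))
    } else NULL
    mk <- mask_from_intervals(iv, 30)
    sg <- suppressWarnings(apply_mask(rec, mk, min_segment_s = 0))
    expect_equal(sg$retained_s + sg$excluded_s, 30, tolerance = 1e-9)
    for (s in sg$segments)
      expect_lte(drowsydrive:::overlap_with_set(s$start_s + 1e-9,
                                                s$end_s - 1e-9,
                                                mk$intervals),
                 2 / fs)
  }

  expect_warning(apply_mask(rec, mask_from_intervals(cbind(0, 30), 30)),
                 "no clean segment")
})

test_that("excluded fraction on compressed cohort sessions is plausible", {
  cfg <- cohort_config(n_subjects = 2, drive_duration_s = 300,
                       sampling_rate_hz = 125, srem_mean_manual = 3,
                       seed = 6)
  co <- generate_cohort(cfg)
  fr <- vapply(co$sessions, function(ses) {
    rec <- generate_eeg_eog(ses, co$truth$sessions[[ses$id]], cfg)
    f <- filter_chain(rereference(rec), compressed_filter())
    detect_ocular_artifacts(channel(f, "EOG-L"), channel(f, "EOG-R"),
                            f$fs)$excluded_fraction
  }, numeric(1))
  expect_gt(mean(fr), 0.065)
  expect_lt(mean(fr), 0.265)
})
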