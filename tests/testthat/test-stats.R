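test_that("adjusted Hedge's g reproduces a published value and its
          symmetries", {
  g <- hedges_g_adj(14.47, 13.32, 5.00, 7.02, 17)
  expect_equal(drowsydrive:::round_half_up(g, 2), 0.79)

  expect_equal(hedges_g_adj(3, 1, 3, 2, 10), 0)
  # antisymmetric under swapping conditions
  expect_equal(hedges_g_adj(5, 2, 3, 1, 12),
               -hedges_g_adj(3, 1, 5, 2, 12))
  # invariant under common rescaling of all moments
  expect_equal(hedges_g_adj(5, 2, 3, 1, 12),
               hedges_g_adj(50, 20, 30, 10, 12))
  expect_error(hedges_g_adj(1, 1, 0, 1, 3), "n >= 4")
  expect_error(hedges_g_adj(1, 0, 0, 0, 10), "undefined")
})

test_that("Wilcoxon signed-rank matches full enumeration", {
  r <- wilcoxon_signed_rank(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))
  expect_equal(r$V, 15)
  expect_equal(r$p, 0.0625)   # 2/32, all-positive extreme
  expect_equal(r$p, enum_wilcoxon(c(1, 2, 3, 4, 5)))

  # exhaustive agreement with the 2^n oracle for n = 5..12
  set.seed(123)
  for (n in 5:12) {
    d <- round(rnorm(n, 0.3, 1), 6)
    while (anyDuplicated(abs(d)) || any(d == 0))
      d <- round(rnorm(n, 0.3, 1), 6)
    r <- wilcoxon_signed_rank(d, rep(0, n))
    expect_true(r$exact)
    expect_equal(r$p, enum_wilcoxon(d), tolerance = 1e-10)
  }

  # antisymmetric differences: V at half the rank sum, p at 1
  ra <- wilcoxon_signed_rank(c(1, -1, 2, -2), rep(0, 4))
  expect_equal(ra$V, 5)
  expect_equal(ra$p, 1, tolerance = 1e-9)

  expect_error(wilcoxon_signed_rank(c(1, 1), c(1, 1)), "zero")
})

test_that("paired t-test matches the closed-form t distribution", {
  x <- c(11, 22, 33)
  y <- c(10, 20, 30)
  r <- paired_ttest(x, y)
  expect_equal(r$t, 2 / (sd(c(1, 2, 3)) / sqrt(3)), tolerance = 1e-9)
  expect_equal(r$t, 3.4641, tolerance = 1e-4)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * pt(-abs(r$t), 2))
  expect_equal(r$p, 0.0742, tolerance = 1e-3)
  expect_error(paired_ttest(c(1, 2, 3), c(0, 1, 2)), "zero variance")
})

test_that("mixed model equals the paired t-test on balanced data and
          falls back when singular", {
  set.seed(42)
  n <- 12
  subj_eff <- rnorm(n, 0, 3)
  manual <- 10 + subj_eff + rnorm(n, 0, 1)
  self <- 11.5 + subj_eff + rnorm(n, 0, 1)
  d <- tibble::tibble(
    subject = rep(1:n, 2),
    condition = rep(c("manual", "self_driving"), each = n),
    value = c(manual, self))
  mm <- mixed_random_intercept(d)
  tt <- paired_ttest(self, manual)
  expect_false(mm$singular)
  expect_equal(mm$p, tt$p, tolerance = 1e-6)
  expect_equal(mm$b, tt$estimate, tolerance = 1e-8)
  expect_equal(mm$df, n - 1, tolerance = 1e-3)

  # strongly negative within-pair correlation: singular fit, t fallback
  set.seed(43)
  a <- rnorm(n)
  d2 <- tibble::tibble(
    subject = rep(1:n, 2),
    condition = rep(c("manual", "self_driving"), each = n),
    value = c(a, 1 - a + rnorm(n, 0, 0.1)))
  expect_warning(m2 <- mixed_random_intercept(d2), "singular")
  expect_true(m2$singular)
})

test_that("repeated-measures NB model recovers a known rate ratio", {
  # identical counts in both conditions: exactly null
  d0 <- tibble::tibble(subject = rep(1:10, 2),
                       condition = rep(c("manual", "self_driving"),
                                       each = 10),
                       count = rep(c(3, 5, 2, 8, 1, 4, 6, 2, 3, 7), 2))
  r0 <- nb_repeated_condition(d0)
  expect_lt(abs(r0$log_rr), 1e-6)
  expect_lt(r0$chisq, 1e-6)

  # simulation recovery: true RR = 2, gamma frailty dispersion 1
  set.seed(7)
  n <- 200
  u <- rgamma(n, 1, 1)
  d <- tibble::tibble(
    subject = rep(1:n, 2),
    condition = rep(c("manual", "self_driving"), each = n),
    count = c(rpois(n, 5 * u), rpois(n, 10 * u)))
  r <- nb_repeated_condition(d)
  expect_gt(exp(r$log_rr), 1.8)
  expect_lt(exp(r$log_rr), 2.2)
  expect_lt(r$p, 0.001)
  expect_true(r$ci[1] < r$log_rr && r$log_rr < r$ci[2])

  d_zero <- d0
  d_zero$count[d_zero$condition == "manual"] <- 0
  expect_warning(nb_repeated_condition(d_zero), "all-zero")
})

test_that("NB sleep-slope regression recovers the generating slope", {
  set.seed(11)
  n <- 200
  sleep <- rnorm(n, 5.9, 0.9)
  mu <- 6 * exp(-0.5 * (sleep - 5.9))
  counts <- MASS::rnegbin(n, mu = mu, theta = 2)
  r <- nb_sleep_slope(tibble::tibble(count = counts, sleep_h = sleep))
  expect_true(r$ci[1] < -0.5 && -0.5 < r$ci[2])
  expect_lt(abs(r$log_b + 0.5), 0.2)

  expect_error(nb_sleep_slope(tibble::tibble(count = c(1, 2, 3),
                                             sleep_h = rep(6, 3))),
               "constant")
  expect_error(nb_sleep_slope(tibble::tibble(count = rep(2, 3),
                                             sleep_h = c(5, 6, 7))),
               "zero variance")

  # null coverage: when counts ignore sleep, the slope CI covers zero
  set.seed(12)
  cover0 <- replicate(1000, {
    sleep <- rnorm(50, 5.9, 0.9)
    counts <- MASS::rnegbin(50, mu = 5, theta = 1)
    r <- suppressWarnings(
      nb_sleep_slope(tibble::tibble(count = counts, sleep_h = sleep)))
    r$ci[1] <= 0 && 0 <= r$ci[2]
  })
  expect_gte(mean(cover0), 0.93)
})

test_that("paired log-rank separates early from late first events", {
  # tied within pairs: no information, falls back, statistic ~ 0
  d0 <- tibble::tibble(subject = rep(1:8, 2),
                       condition = rep(c("manual", "self_driving"),
                                       each = 8),
                       time_s = rep(seq(100, 800, by = 100), 2),
                       event = 1L)
  r0 <- suppressWarnings(paired_logrank(d0))
  expect_lt(r0$chisq, 1e-8)

  # self-driving events uniformly earlier: strong rejection
  set.seed(9)
  n <- 20
  tm <- runif(n, 500, 2000)
  d <- tibble::tibble(
    subject = rep(1:n, 2),
    condition = rep(c("manual", "self_driving"), each = n),
    time_s = c(tm, tm * 0.25),
    event = 1L)
  r <- paired_logrank(d)
  expect_true(r$stratified)
  expect_lt(r$p, 0.01)

  d_cens <- d
  d_cens$event <- 0L
  expect_error(paired_logrank(d_cens), "no events")
})

test_that("sample-size formula reproduces the normal-approximation values", {
  expect_equal(sample_size_mean_change(50, 65, 0.80, 0.05), 14L)
  expect_equal(sample_size_mean_change(1, 1, 0.80, 0.05), 8L)
  # doubling the SD quadruples the pre-ceiling requirement
  expect_equal(sample_size_mean_change(1, 2, 0.80, 0.05), 32L)
  expect_error(sample_size_mean_change(-1, 1), "positive")
  expect_error(sample_size_mean_change(1, 1, power = 0.02, alpha = 0.2),
               "power")
})
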