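#' Adjusted Hedge's g for a paired two-condition comparison
#'
#' Standardized mean difference with a multiplicative small-sample bias
#' correction:
#' \deqn{g = \frac{M_1 - M_2}{SD^{*}_{pooled}}
#'   \times \frac{N - 3}{N - 2.25} \times \sqrt{\frac{N - 2}{N}}}
#' where \eqn{SD^{*}_{pooled} = \sqrt{(SD_1^2 + SD_2^2)/2}} (equal-weight
#' root mean square of the two condition SDs) and N is the number of paired
#' participants contributing to the comparison.
#'
#' @param m1,sd1 mean and SD of condition 1.
#' @param m2,sd2 mean and SD of condition 2.
#' @param n number of paired participants (>= 4).
#' @return Scalar g (sign follows `m1 - m2`).
#' @export
hedges_g_adj <- function(m1, sd1, m2, sd2, n) {
  if (n < 4) stop("the small-sample correction requires n >= 4")
  if (sd1 < 0 || sd2 < 0) stop("SDs must be nonnegative")
  sd_pooled <- sqrt((sd1^2 + sd2^2) / 2)
  if (sd_pooled == 0) stop("both SDs are zero; g is undefined")
  (m1 - m2) / sd_pooled * (n - 3) / (n - 2.25) * sqrt((n - 2) / n)
}

# half-up rounding to `digits`, magnitude-based (printed-value convention)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

cond_factor <- function(condition)
  factor(condition, levels = c("manual", "self_driving"))

#' Repeated-measures negative binomial condition comparison
#'
#' Marginal negative-binomial regression of per-session counts on
#' condition, with within-subject correlation handled by cluster-robust
#' (sandwich) standard errors — the independence-working-correlation GEE
#' estimator. Reports the log rate ratio (self-driving vs manual), the
#' robust Wald chi-square on 1 df, and the fitted dispersion; the p value
#' uses the t reference with G - 1 degrees of freedom (G = number of
#' subjects), the standard small-sample correction for cluster-robust
#' tests. When the NB likelihood degenerates (no overdispersion, or a
#' condition with all-zero counts), the fit falls back to Poisson with
#' the same robust inference.
#'
#' @param data tibble with `subject`, `condition` (`"manual"`/
#'   `"self_driving"`), `count`.
#' @return List: `log_rr`, `se`, `ci` (robust 95%), `chisq`, `df`, `p`,
#'   `dispersion_theta`, `family`.
#' @export
nb_repeated_condition <- function(data) {
  stopifnot(all(c("subject", "condition", "count") %in% names(data)))
  if (any(data$count < 0)) stop("counts must be nonnegative")
  data$condition <- cond_factor(data$condition)
  zero_arm <- any(tapply(data$count, data$condition, function(x) all(x == 0)))
  if (zero_arm)
    warning("a condition has all-zero counts; the fit may be degenerate")
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(count ~ condition, data = data)),
    error = function(e) NULL)
  family <- "negative binomial"
  theta <- if (!is.null(fit)) fit$theta else NA_real_
  if (is.null(fit)) {
    fit <- stats::glm(count ~ condition, data = data, family = stats::poisson())
    family <- "poisson"
  }
  V <- suppressWarnings(sandwich::vcovCL(fit, cluster = data$subject))
  b <- stats::coef(fit)[["conditionself_driving"]]
  # clamp tiny negative variances from numerically singular robust meat
  se <- sqrt(max(V["conditionself_driving", "conditionself_driving"], 0))
  chisq <- if (is.finite(se) && se > 0) (b / se)^2
           else if (abs(b) < 1e-10) 0 else Inf
  g_cl <- length(unique(data$subject))
  p <- if (is.finite(chisq)) 2 * pt(-sqrt(chisq), df = max(g_cl - 1, 1))
       else 0
  list(log_rr = b, se = se, ci = b + c(-1, 1) * qnorm(0.975) * se,
       chisq = chisq, df = 1L, p = p,
       dispersion_theta = theta, family = family)
}

#' Negative binomial regression of SREM counts on habitual sleep
#'
#' Fit separately per condition: `count ~ sleep_h`, reporting the per-hour
#' log slope with its model-based 95% CI.
#'
#' @param data tibble with `count`, `sleep_h` (one row per subject within
#'   one condition).
#' @return List: `log_b`, `se`, `ci`, `p`, `dispersion_theta`.
#' @export
nb_sleep_slope <- function(data) {
  stopifnot(all(c("count", "sleep_h") %in% names(data)))
  if (stats::var(data$sleep_h) == 0)
    stop("sleep durations are constant; slope is unidentified")
  if (stats::var(data$count) == 0)
    stop("counts have zero variance; slope is unidentified")
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(count ~ sleep_h, data = data)),
    error = function(e)
      stats::glm(count ~ sleep_h, data = data, family = stats::poisson()))
  b <- stats::coef(fit)[["sleep_h"]]
  se <- sqrt(stats::vcov(fit)["sleep_h", "sleep_h"])
  z <- b / se
  list(log_b = b, se = se, ci = b + c(-1, 1) * qnorm(0.975) * se,
       p = 2 * pnorm(-abs(z)),
       dispersion_theta = if (!is.null(fit$theta)) fit$theta else NA_real_)
}

#' Wilcoxon signed-rank test for paired ordinal outcomes
#'
#' Zero differences are dropped; V is the sum of positive-difference
#' ranks; the p value is exact for up to 25 informative pairs without
#' ties and uses the tie-corrected normal approximation otherwise.
#'
#' @param x,y paired samples (e.g. KSS after each drive).
#' @return List: `V`, `p`, `n_used`, `exact`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n < 1) stop("all paired differences are zero")
  has_ties <- anyDuplicated(abs(d)) > 0
  exact <- n <= 25 && !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = FALSE))
  list(V = unname(wt$statistic), p = wt$p.value, n_used = n, exact = exact)
}

#' Subject-stratified (paired) log-rank test for time-to-first-SREM
#'
#' Log-rank statistic stratified by subject, which conditions out the
#' between-subject correlation of the paired drives. When every stratum is
#' uninformative (the stratified variance is zero) the test falls back to
#' the unstratified log-rank with a warning.
#'
#' @param records tibble with `subject`, `condition`, `time_s`, `event`
#'   (1 = SREM observed, 0 = censored).
#' @return List: `chisq`, `df`, `p`, `stratified`.
#' @export
paired_logrank <- function(records) {
  stopifnot(all(c("subject", "condition", "time_s", "event") %in%
                  names(records)))
  if (!any(records$event == 1)) stop("no events observed; log-rank undefined")
  records$condition <- cond_factor(records$condition)
  sv <- survival::Surv(records$time_s, records$event)
  fit <- tryCatch(
    survival::survdiff(sv ~ condition + survival::strata(subject),
                       data = records),
    error = function(e) NULL)
  stratified <- TRUE
  if (is.null(fit) || !is.finite(fit$chisq)) {
    warning("strata uninformative; falling back to unstratified log-rank")
    fit <- survival::survdiff(sv ~ condition, data = records)
    stratified <- FALSE
  }
  list(chisq = fit$chisq, df = 1L,
       p = pchisq(fit$chisq, 1, lower.tail = FALSE),
       stratified = stratified)
}

#' Random-intercept linear mixed model for a paired condition effect
#'
#' REML fit of `value ~ condition + (1 | subject)` with Satterthwaite
#' degrees of freedom for the condition coefficient (self-driving minus
#' manual). On balanced complete data this reproduces the paired t-test.
#' A singular fit (zero between-subject variance) falls back to the paired
#' t-test with a warning.
#'
#' @param data tibble with `subject`, `condition`, `value`.
#' @return List: `b`, `se`, `ci`, `t`, `df`, `p`, `singular`.
#' @export
mixed_random_intercept <- function(data) {
  stopifnot(all(c("subject", "condition", "value") %in% names(data)))
  if (length(unique(data$subject)) < 2) stop("need at least 2 subjects")
  data$condition <- cond_factor(data$condition)
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(value ~ condition + (1 | subject), data = data,
                   REML = TRUE)))
  if (lme4::isSingular(fit, tol = 1e-5)) {
    warning("singular random-intercept fit; falling back to paired t-test")
    wide <- split(data$value[order(data$subject)],
                  data$condition[order(data$subject)])
    tt <- paired_ttest(wide$self_driving, wide$manual)
    return(list(b = tt$estimate, se = tt$se,
                ci = tt$estimate + c(-1, 1) * qnorm(0.975) * tt$se,
                t = tt$t, df = tt$df, p = tt$p, singular = TRUE))
  }
  cf <- stats::coef(summary(fit))["conditionself_driving", ]
  b <- cf[["Estimate"]]; se <- cf[["Std. Error"]]
  list(b = b, se = se, ci = b + c(-1, 1) * qnorm(0.975) * se,
       t = cf[["t value"]], df = cf[["df"]], p = cf[["Pr(>|t|)"]],
       singular = FALSE)
}

#' Paired-samples t-test
#'
#' @param x,y paired samples (x - y differences are tested against 0).
#' @return List: `t`, `df`, `p`, `estimate` (mean difference), `se`.
#' @export
paired_ttest <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::var(d) == 0)
    stop("paired differences have zero variance; t is undefined")
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, estimate = unname(tt$estimate),
       se = unname(tt$stderr))
}

#' Sample size to detect a mean change (normal approximation)
#'
#' \eqn{n = \lceil (z_{1-\alpha/2} + z_{power})^2 \sigma^2 / \delta^2 \rceil}
#'
#' @param delta_ms detectable mean change.
#' @param sd_ms standard deviation of the change.
#' @param power target power in (0, 1).
#' @param alpha two-sided type-I error rate in (0, 1).
#' @return Integer sample size.
#' @export
sample_size_mean_change <- function(delta_ms, sd_ms, power = 0.80,
                                    alpha = 0.05) {
  if (delta_ms <= 0 || sd_ms <= 0) stop("delta and sd must be positive")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie in (0, 1)")
  if (power <= alpha / 2)
    stop("power must exceed alpha/2 for the approximation to make sense")
  z <- qnorm(1 - alpha / 2) + qnorm(power)
  as.integer(ceiling(z^2 * sd_ms^2 / delta_ms^2))
}
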