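#' Summarize a psychomotor vigilance task administration
#'
#' Adjusts every raw reaction time by the device system latency, then
#' reports the mean adjusted RT and the number of attentional lapses
#' (adjusted RT strictly greater than the lapse threshold).
#'
#' @param raw_rts_ms positive raw reaction times, ms.
#' @param latency_ms system latency subtracted from each trial (default
#'   82 ms).
#' @param lapse_threshold_ms lapse cutoff on the adjusted scale (default
#'   500 ms; strict inequality).
#' @return List: `mean_rt_ms`, `lapses`, `n_trials`, `latency_ms`,
#'   `lapse_threshold_ms`.
#' @export
summarize_pvt <- function(raw_rts_ms, latency_ms = 82,
                          lapse_threshold_ms = 500) {
  if (!length(raw_rts_ms)) stop("no PVT trials supplied")
  if (any(raw_rts_ms <= 0)) stop("reaction times must be positive")
  adj <- raw_rts_ms - latency_ms
  list(mean_rt_ms = mean(adj),
       lapses = sum(adj > lapse_threshold_ms),
       n_trials = length(adj),
       latency_ms = latency_ms,
       lapse_threshold_ms = lapse_threshold_ms)
}

#' Summarize actigraphy-classified sleep over a 14-day diary
#'
#' Daily sleep duration = minutes classified as sleep inside that day's
#' main rest interval plus minutes of sleep in any nap intervals assigned
#' to the following day (nap rows carry the day they are credited to).
#' The mean is taken over the available days, with a warning when fewer
#' than the expected 14 are present.
#'
#' @param epochs tibble of one-minute epochs: `minute` (0-based),
#'   `activity`, `status` (`"sleep"`/`"wake"`).
#' @param rest_intervals tibble: `day`, `type` (`"main"`/`"nap"`),
#'   `start_min`, `end_min` (half-open, minutes).
#' @param n_days_expected diary length (default 14).
#' @return List: `daily` (tibble `day`, `sleep_min`), `mean_h`.
#' @export
summarize_sleep <- function(epochs, rest_intervals, n_days_expected = 14) {
  if (is.null(rest_intervals) || !nrow(rest_intervals))
    stop("no rest intervals supplied; cannot assign sleep episodes")
  days <- sort(unique(rest_intervals$day))
  if (length(days) < n_days_expected)
    warning("sleep history covers ", length(days), " day(s); expected ",
            n_days_expected)
  daily <- vapply(days, function(d) {
    iv <- rest_intervals[rest_intervals$day == d, , drop = FALSE]
    tot <- 0
    for (i in seq_len(nrow(iv))) {
      inside <- epochs$minute >= iv$start_min[i] &
        epochs$minute < iv$end_min[i]
      tot <- tot + sum(epochs$status[inside] == "sleep")
    }
    min(tot, 1440)
  }, numeric(1))
  list(daily = tibble::tibble(day = days, sleep_min = daily),
       mean_h = mean(daily) / 60)
}

#' Fallback rest-interval estimation from activity counts
#'
#' For diaries with missing bedtime/waketime: bedtime is the first epoch
#' whose activity count falls below 150 while classified as sleep;
#' waketime is the first later epoch whose count rises above 150 while the
#' status is active (wake).
#'
#' @param activity_counts per-minute activity counts.
#' @param statuses per-minute classification, `"sleep"`/`"wake"` (wake is
#'   treated as the active interval status).
#' @return List: `bedtime_min`, `waketime_min` (0-based epoch indices;
#'   `NA` when no qualifying epoch exists).
#' @export
estimate_rest_interval_fallback <- function(activity_counts, statuses) {
  stopifnot(length(activity_counts) == length(statuses))
  bed <- which(activity_counts < 150 & statuses == "sleep")
  if (!length(bed))
    return(list(bedtime_min = NA_integer_, waketime_min = NA_integer_))
  b <- bed[1L]
  wake <- which(seq_along(statuses) > b & activity_counts > 150 &
                  statuses == "wake")
  list(bedtime_min = b - 1L,
       waketime_min = if (length(wake)) wake[1L] - 1L else NA_integer_)
}
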