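#' Multichannel EEG/EOG recording
#'
#' Light container for a uniformly sampled multichannel recording in
#' microvolts. Channels carry a role (`"scalp"`, `"eog"`, `"mastoid"`) so the
#' preprocessing stages can address them without hard-coded label lists.
#'
#' @param data numeric matrix, samples x channels, in microvolts.
#' @param channels character vector of unique channel labels.
#' @param roles character vector, one of `"scalp"`, `"eog"`, `"mastoid"` per
#'   channel.
#' @param fs sampling rate in Hz (> 0).
#' @param start_s time of the first sample in seconds from drive start.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, channels, roles, fs, start_s = 0) {
  data <- as.matrix(data)
  if (ncol(data) != length(channels))
    stop("`data` must have one column per entry of `channels`")
  if (length(roles) != length(channels))
    stop("`roles` must have one entry per channel")
  if (anyDuplicated(channels))
    stop("channel labels must be unique")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar sampling rate in Hz")
  bad <- setdiff(roles, c("scalp", "eog", "mastoid"))
  if (length(bad))
    stop("unknown channel role(s): ", paste(bad, collapse = ", "))
  colnames(data) <- channels
  structure(
    list(data = data, channels = channels,
         roles = stats::setNames(roles, channels),
         fs = fs, start_s = start_s),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$data), nrow(x$data), x$fs, nrow(x$data) / x$fs))
  cat("  channels:", paste(sprintf("%s[%s]", x$channels,
                                   substr(x$roles, 1, 1)), collapse = " "),
      "\n")
  invisible(x)
}

n_samples <- function(rec) nrow(rec$data)

#' Recording duration in seconds
#'
#' @param rec an [eeg_recording()].
#' @return Scalar duration (s).
#' @export
duration_s <- function(rec) nrow(rec$data) / rec$fs

#' Extract one channel as a numeric vector
#'
#' @param rec an [eeg_recording()].
#' @param label channel label.
#' @return Numeric vector of samples (microvolts).
#' @export
channel <- function(rec, label) {
  if (!label %in% rec$channels) stop("no channel labelled '", label, "'")
  rec$data[, label]
}
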