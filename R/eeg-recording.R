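#' Continuous multi-channel EEG recording
#'
#' Light container for a continuous EEG signal: a channels-by-samples
#' numeric matrix, its sampling rate, channel labels and the current
#' reference scheme. Amplitudes are in microvolts.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector of channel names; defaults to
#'   `"Ch01"`, `"Ch02"`, ...
#' @param reference Reference description, e.g. a channel label or `"CAR"`
#'   once [rereference_car()] has been applied.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL, reference = "raw") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is_scalar(fs, min = 0)) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stop("EEG data must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("Ch%02d", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop("`channel_labels` length must equal the number of channels",
         call. = FALSE)
  }
  structure(
    list(data = data, fs = as.numeric(fs),
         channel_labels = as.character(channel_labels),
         reference = reference),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), reference: %s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              x$reference))
  invisible(x)
}

#' Per-trial event table
#'
#' Validates a per-trial event table: phase onsets as 0-based sample
#' indices, a timeout flag, and start/target positions in meters. Onsets
#' must increase within each trial (baseline < planning < go <= reached)
#' and trials must not overlap.
#'
#' @param df A data frame with columns `trial`, `baseline_onset`,
#'   `planning_onset`, `go_onset`, `reached_sample`, `timeout`,
#'   `start_x`, `start_y`, `start_z`, `target_x`, `target_y`, `target_z`.
#' @return The validated data frame with class `trial_events`.
#' @export
trial_events <- function(df) {
  required <- c("trial", "baseline_onset", "planning_onset", "go_onset",
                "reached_sample", "timeout",
                "start_x", "start_y", "start_z",
                "target_x", "target_y", "target_z")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("event table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[required]
  if (anyDuplicated(df$trial)) {
    stop("trial indices must be unique", call. = FALSE)
  }
  df <- df[order(df$trial), , drop = FALSE]
  ok <- df$baseline_onset < df$planning_onset &
    df$planning_onset < df$go_onset &
    df$go_onset <= df$reached_sample
  if (!all(ok)) {
    stop("phase onsets must increase within trial(s): ",
         paste(df$trial[!ok], collapse = ", "), call. = FALSE)
  }
  if (nrow(df) > 1 &&
      any(df$baseline_onset[-1] <= df$reached_sample[-nrow(df)])) {
    stop("trials overlap in time", call. = FALSE)
  }
  class(df) <- c("trial_events", "data.frame")
  df
}
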