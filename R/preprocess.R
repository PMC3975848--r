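# Referencing, filtering, epoching and pooled dimensionality reduction.

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the channel mean is zero at every sample.
#'
#' @param rec An [eeg_recording()].
#' @return The re-referenced recording with `reference = "CAR"`.
#' @export
rereference_car <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2) {
    stop("common average reference needs at least 2 channels", call. = FALSE)
  }
  rec$data <- sweep(rec$data, 2, colMeans(rec$data), "-")
  rec$reference <- "CAR"
  rec
}

#' Butterworth high-pass filter
#'
#' Applies an `order`-th order Butterworth high-pass to every channel.
#' Filtering is zero-phase (forward-backward), which doubles the effective
#' order but leaves epoch timing undistorted.
#'
#' @param rec An [eeg_recording()].
#' @param cutoff_hz Cut-off frequency in Hz (must be below Nyquist).
#' @param order Filter order (default 3).
#' @return The filtered recording.
#' @export
highpass <- function(rec, cutoff_hz, order = 3) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (cutoff_hz <= 0 || cutoff_hz >= rec$fs / 2) {
    stop("`cutoff_hz` must lie in (0, fs/2)", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / (rec$fs / 2), type = "high")
  # pad by ~3 time constants of the cut-off so start-of-recording epochs
  # are free of filter transients
  padlen <- round(3 * rec$fs / cutoff_hz)
  for (ch in seq_len(nrow(rec$data))) {
    rec$data[ch, ] <- filtfilt_padded(bf, rec$data[ch, ], padlen)
  }
  rec
}

#' Extract fixed-length trial epochs
#'
#' Baseline epochs cover 5 s from each baseline onset; planning epochs
#' cover the first 2.5 s from each planning onset (the guaranteed minimum
#' planning duration, so all epochs have equal length).
#'
#' @param rec An [eeg_recording()].
#' @param events A [trial_events()] table (onsets are 0-based samples).
#' @param phase `"baseline"` or `"planning"`.
#' @param baseline_s,planning_s Epoch lengths in seconds.
#' @return An `epoch_set`: list with `epochs` (trials x channels x
#'   samples array), `phase`, `fs` and `trials`.
#' @export
extract_epochs <- function(rec, events, phase = c("baseline", "planning"),
                           baseline_s = 5, planning_s = 2.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  phase <- match.arg(phase)
  onset <- switch(phase,
                  baseline = events$baseline_onset,
                  planning = events$planning_onset)
  len <- round(switch(phase, baseline = baseline_s,
                      planning = planning_s) * rec$fs)
  n_samp <- ncol(rec$data)
  bad <- which(onset + len > n_samp | onset < 0)
  if (length(bad) > 0) {
    stop("epoch window outside recording for trial(s): ",
         paste(events$trial[bad], collapse = ", "), call. = FALSE)
  }
  n_tr <- nrow(events)
  ep <- array(0, dim = c(n_tr, nrow(rec$data), len))
  for (i in seq_len(n_tr)) {
    ep[i, , ] <- rec$data[, (onset[i] + 1):(onset[i] + len)]
  }
  structure(list(epochs = ep, phase = phase, fs = rec$fs,
                 trials = events$trial),
            class = "epoch_set")
}

#' Pool subjects and reduce to principal components
#'
#' Concatenates the subjects' recordings in time, computes PCA on the
#' pooled (mean-centered) data and returns the top `n_components` scores
#' in decreasing order of explained variance. The projection matrix has
#' orthonormal rows; with `whiten = TRUE` (default) the returned scores
#' are additionally scaled to unit variance per component, the form the
#' SOBI joint diagonalization expects at lag 0.
#'
#' @param recordings List of [eeg_recording()]s with identical channel
#'   sets and sampling rates.
#' @param n_components Number of components to keep.
#' @param whiten Scale scores to unit variance (default `TRUE`).
#' @return A `pca_reduction`: list with `scores` (components x pooled
#'   samples), `rotation` (components x channels, orthonormal rows),
#'   `center`, `sdev` (score standard deviations before whitening),
#'   `explained` (variance fractions), `whiten` flag, `fs` and
#'   `boundaries` (per-subject first/last pooled-column indices).
#' @export
pool_and_reduce <- function(recordings, n_components, whiten = TRUE) {
  stopifnot(length(recordings) >= 1)
  labs <- recordings[[1]]$channel_labels
  fs <- recordings[[1]]$fs
  for (r in recordings) {
    if (!identical(r$channel_labels, labs) || !identical(r$fs, fs)) {
      stop("all recordings must share channel labels and sampling rate",
           call. = FALSE)
    }
  }
  n_ch <- length(labs)
  if (n_components > n_ch) {
    stop("`n_components` cannot exceed the channel count", call. = FALSE)
  }
  # pooled mean and covariance accumulated per subject (memory-aware)
  n_tot <- sum(vapply(recordings, function(r) ncol(r$data), 0))
  mu <- Reduce(`+`, lapply(recordings, function(r) rowSums(r$data))) / n_tot
  cc <- matrix(0, n_ch, n_ch)
  for (r in recordings) {
    xc <- r$data - mu
    cc <- cc + tcrossprod(xc)
  }
  cov_pooled <- cc / (n_tot - 1)
  eig <- eigen(cov_pooled, symmetric = TRUE)
  keep <- seq_len(n_components)
  rot <- t(eig$vectors[, keep, drop = FALSE])      # components x channels
  sdev <- sqrt(pmax(eig$values[keep], 0))
  explained <- eig$values / sum(eig$values)

  boundaries <- vector("list", length(recordings))
  scores <- matrix(0, n_components, n_tot)
  at <- 0L
  for (s in seq_along(recordings)) {
    x <- rot %*% (recordings[[s]]$data - mu)
    scores[, (at + 1):(at + ncol(x))] <- x
    boundaries[[s]] <- c(at + 1L, at + ncol(x))
    at <- at + ncol(x)
  }
  if (whiten) {
    scl <- ifelse(sdev > 0, 1 / sdev, 0)
    scores <- scores * scl
  }
  structure(list(scores = scores, rotation = rot, center = mu, sdev = sdev,
                 explained = explained[keep], whiten = whiten, fs = fs,
                 boundaries = boundaries),
            class = "pca_reduction")
}

#' Apply a pooled-PCA reduction to one recording
#'
#' Projects a single subject's recording with the pooled projection
#' (and whitening scale, if the reduction was whitened).
#'
#' @param rec An [eeg_recording()].
#' @param reduction A `pca_reduction` from [pool_and_reduce()].
#' @return Components-by-samples score matrix.
#' @export
project_reduced <- function(rec, reduction) {
  x <- reduction$rotation %*% (rec$data - reduction$center)
  if (reduction$whiten) {
    x <- x * ifelse(reduction$sdev > 0, 1 / reduction$sdev, 0)
  }
  x
}
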