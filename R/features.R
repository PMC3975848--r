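# Per-trial log-bandpower features, trial-domain filtering, normalized
# time-to-target and its power spectral density.

#' The five analysis frequency bands
#'
#' delta 0.1-4 Hz, theta 4-7 Hz, alpha/mu 8-14 Hz, beta 20-30 Hz and
#' gamma 55-85 Hz.
#'
#' @return Data frame with columns `name`, `lower`, `upper` (Hz).
#' @export
band_definitions <- function() {
  data.frame(name = c("delta", "theta", "alpha_mu", "beta", "gamma"),
             lower = c(0.1, 4, 8, 20, 55),
             upper = c(4, 7, 14, 30, 85),
             stringsAsFactors = FALSE)
}

#' Log-bandpower of an epoch
#'
#' A Hann window is applied to the full epoch, a single FFT taken per row
#' and one-sided power summed over bins whose center frequency lies in
#' `[lower, upper)`; the natural log of the summed power is returned. A
#' small power floor (`1e-12`) guards degenerate (all-zero) epochs, which
#' additionally trigger a warning.
#'
#' @param epoch Rows-by-samples matrix (channels or components) or a
#'   vector.
#' @param fs Sampling rate (Hz).
#' @param band A single row of [band_definitions()] (or any list with
#'   `lower`/`upper`).
#' @param floor Power floor added before the log.
#' @return One log-power value (log microvolt^2) per row.
#' @export
log_bandpower <- function(epoch, fs, band, floor = 1e-12) {
  if (is.null(dim(epoch))) epoch <- matrix(epoch, nrow = 1)
  n <- ncol(epoch)
  if (band$upper > fs / 2) {
    stop("band extends above the Nyquist frequency", call. = FALSE)
  }
  f <- (seq_len(n) - 1) * fs / n
  bins <- which(f >= band$lower & f < band$upper & f <= fs / 2)
  if (length(bins) == 0) {
    stop("epoch too short: no FFT bin falls inside the band", call. = FALSE)
  }
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  X <- stats::mvfft(t(epoch * rep(w, each = nrow(epoch))))
  pw <- (2 / (fs * sum(w^2))) *
    colSums(Mod(X[bins, , drop = FALSE])^2) * (fs / n)
  if (any(pw == 0)) {
    warning("zero-power epoch; returning log of the power floor")
  }
  log(pw + floor)
}

#' Per-trial feature table of log-bandpowers
#'
#' One row per trial, one column per (component, band) pair in fixed
#' IC-major, band-minor order (`IC01_delta`, `IC01_theta`, ...); the
#' stable column order is what allows cross-subject model transfer.
#'
#' @param epoch_set An `epoch_set` whose channel dimension holds component
#'   activations (see [extract_epochs()] and [sobi()]).
#' @param kept Indices of the components (rows of the epoch array) to
#'   featurize; defaults to all.
#' @param bands Band table (default [band_definitions()]).
#' @param subject Optional subject identifier stored with the table.
#' @param ids Component identifiers used in the column labels; defaults
#'   to `kept` (pass the original component numbers when the epoch array
#'   has already been subset).
#' @return A `feature_table`: numeric matrix (trials x features) with
#'   attributes `subject`, `trials`, `bands`.
#' @export
build_feature_table <- function(epoch_set, kept = NULL,
                                bands = band_definitions(),
                                subject = NA_integer_, ids = kept) {
  ep <- epoch_set$epochs
  if (is.null(kept)) kept <- seq_len(dim(ep)[2])
  if (is.null(ids)) ids <- kept
  n_tr <- dim(ep)[1]
  vals <- matrix(NA_real_, n_tr, length(kept) * nrow(bands))
  cols <- character(ncol(vals))
  for (ci in seq_along(ids)) {
    for (bi in seq_len(nrow(bands))) {
      cols[(ci - 1) * nrow(bands) + bi] <-
        sprintf("IC%02d_%s", ids[ci], bands$name[bi])
    }
  }
  for (t in seq_len(n_tr)) {
    m <- ep[t, kept, , drop = FALSE]
    dim(m) <- c(length(kept), dim(ep)[3])
    for (bi in seq_len(nrow(bands))) {
      vals[t, seq.int(bi, by = nrow(bands),
                      length.out = length(kept))] <-
        log_bandpower(m, epoch_set$fs, bands[bi, ])
    }
  }
  colnames(vals) <- cols
  structure(vals, class = c("feature_table", "matrix", "array"),
            subject = subject, trials = epoch_set$trials, bands = bands)
}

#' Zero-phase low-pass filter in the trial domain
#'
#' Third-order Butterworth low-pass at normalized angular cut-off `c`
#' radians per trial (one sample = one trial; `c = 0.1` keeps roughly the
#' slowest 1.6% of the trial-frequency axis), applied forward-backward
#' with odd-reflection edge padding. Constant series pass unchanged.
#'
#' @param x Numeric per-trial series (length > 20).
#' @param c Cut-off in radians per trial, in `(0, pi)`.
#' @param order Butterworth order (default 3).
#' @return Filtered series, same length as `x`.
#' @export
trial_domain_lowpass <- function(x, c = 0.1, order = 3) {
  if (c <= 0 || c >= pi) {
    stop("cut-off `c` must lie in (0, pi) radians/trial", call. = FALSE)
  }
  if (length(x) <= 20) {
    stop("series too short for trial-domain filtering (need > 20 trials)",
         call. = FALSE)
  }
  bf <- signal::butter(order, c / pi, type = "low")
  lowpass_zerophase(x, bf)
}

# shared zero-phase core so hot loops can reuse precomputed coefficients
#' @noRd
lowpass_zerophase <- function(x, bf) {
  # mirror padding: every trial, including the first and last, is
  # genuinely smoothed (odd reflection would pin the series ends to
  # their raw values, leaving the most extreme trials unfiltered)
  filtfilt_padded(bf, x, padlen = 3 * (length(bf$b) + length(bf$a)),
                  type = "even")
}

#' Normalized time-to-target from the event table
#'
#' TTT = (reach sample - go sample) / fs divided by the start-target
#' distance (s/m). Timed-out trials carry the full `go_limit` duration
#' and are flagged.
#'
#' @param events A [trial_events()] table.
#' @param fs Sampling rate (Hz).
#' @param go_limit Movement time limit in seconds (default 10).
#' @return A `ttt_series`: list with `ttt` (s/m), `timeout` (logical),
#'   `trial` and `distance` (m).
#' @export
normalized_ttt <- function(events, fs, go_limit = 10) {
  d <- sqrt((events$target_x - events$start_x)^2 +
              (events$target_y - events$start_y)^2 +
              (events$target_z - events$start_z)^2)
  if (any(d <= 0)) {
    stop("zero start-target distance in trial(s): ",
         paste(events$trial[d <= 0], collapse = ", "), call. = FALSE)
  }
  secs <- (events$reached_sample - events$go_onset) / fs
  secs[events$timeout] <- go_limit
  if (any(secs == 0)) {
    warning("trial(s) with zero movement time: ",
            paste(events$trial[secs == 0], collapse = ", "))
  }
  structure(list(ttt = secs / d, timeout = events$timeout,
                 trial = events$trial, distance = d),
            class = "ttt_series")
}

#' Periodogram of a per-trial series
#'
#' Mean-removed periodogram on the normalized angular-frequency grid
#' `[0, pi]` radians per trial; used to choose the trial-domain low-pass
#' cut-off by inspecting where the series' spectral mass lives.
#'
#' @param x Per-trial series (length >= 32).
#' @return List with `omega` (radians/trial) and `psd` (non-negative).
#' @export
ttt_psd <- function(x) {
  n <- length(x)
  if (n < 32) {
    stop("series too short for a meaningful periodogram (need >= 32)",
         call. = FALSE)
  }
  d <- x - mean(x)
  P <- Mod(stats::fft(d))^2 / n
  half <- seq_len(floor(n / 2) + 1)
  list(omega = 2 * pi * (half - 1) / n, psd = P[half])
}
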