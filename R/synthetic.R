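# Synthetic multi-subject EEG with a latent learning curve.
#
# Generative model: per subject, observed TTT follows an exponential
# learning curve plus i.i.d. Gaussian noise; latent learning state is the
# noiseless decay normalized to 1 at trial 1. Each cortical source is
# band-limited noise on a 1/f background; for informative sources the
# band-limited amplitude is modulated per trial by the latent state.
# Channels are an instantaneous linear mixture plus sensor noise.

#' Per-subject learning curve and latent state
#'
#' Expected TTT decays exponentially from `initial` toward `asymptote`
#' with time constant `decay` (trials); observed TTT adds i.i.d. Gaussian
#' noise and is clipped to be strictly positive. The latent state is the
#' normalized noiseless decay: 1 at trial 1, approaching 0.
#'
#' @param cfg A [sim_config()].
#' @param subject_index Subject number (1-based); determines the noise
#'   realization via a seed derived from `cfg$seed`.
#' @return List with `ttt` (observed, s/m), `expected` (noiseless, s/m)
#'   and `latent` (dimensionless, in (0, 1]).
#' @export
generate_learning_curve <- function(cfg, subject_index) {
  lc <- cfg$learning_curve
  if (!(lc$decay > 0)) {
    stop("`decay` must be positive", call. = FALSE)
  }
  trial <- seq_len(cfg$n_trials)
  latent <- exp(-(trial - 1) / lc$decay)
  expected <- lc$asymptote + (lc$initial - lc$asymptote) * latent
  # floor at 0.5 s/m: faster reaches are not physiologically plausible,
  # and the floor keeps movement durations strictly positive
  ttt <- with_seed(derive_seed(cfg$seed, subject_index, 1L), {
    pmax(expected + stats::rnorm(cfg$n_trials, 0, lc$noise_sd), 0.5)
  })
  list(ttt = ttt, expected = expected, latent = latent)
}

#' Band-limited Gaussian noise via spectral masking
#' @noRd
bandlimited_noise <- function(n, fs, lower, upper, seed) {
  nfft <- stats::nextn(n)
  x <- with_seed(seed, stats::rnorm(nfft))
  f <- seq(0, nfft - 1) * fs / nfft
  f <- pmin(f, fs - f)          # two-sided frequency axis
  mask <- f >= lower & f <= upper
  X <- stats::fft(x) * mask
  y <- Re(stats::fft(X, inverse = TRUE)) / nfft
  y <- y[seq_len(n)]
  s <- stats::sd(y)
  if (s > 0) y <- y / s
  y
}

#' 1/f^a ("pink-ish") background noise
#' @noRd
one_over_f_noise <- function(n, fs, exponent, sd, seed) {
  nfft <- stats::nextn(n)
  x <- with_seed(seed, stats::rnorm(nfft))
  f <- seq(0, nfft - 1) * fs / nfft
  f <- pmin(f, fs - f)
  shape <- c(0, f[-1]^(-exponent / 2))   # kill DC
  y <- Re(stats::fft(stats::fft(x) * shape, inverse = TRUE)) / nfft
  y <- y[seq_len(n)]
  s <- stats::sd(y)
  if (s > 0) y <- y * sd / s
  y
}

#' Source signal matrix for one synthetic session
#'
#' Each source is unit-variance band-limited noise superposed on a 1/f
#' background. Sources sharing a labeled band split it into adjacent
#' sub-bands (distinct peak frequencies, as cortical rhythms across
#' regions have): identical spectra would make the sources statistically
#' indistinguishable to any second-order separation method. For
#' informative sources the within-trial amplitude of the band-limited
#' component is `exp(sign * strength * (latent - 1/2))`, i.e. a monotone
#' function of the latent learning state with the configured coupling
#' sign relative to TTT (latent and expected TTT rise and fall together).
#' Non-informative sources are trial-stationary. Sources are mutually
#' independent by construction.
#'
#' @param cfg A [sim_config()].
#' @param latent Per-trial latent state (length `cfg$n_trials`).
#' @param events A [trial_events()] table giving each trial's span.
#' @param n_samples Total session length in samples.
#' @param subject_index Subject number, used for seed derivation.
#' @return Matrix, sources (plus one artifact source if configured) by
#'   samples.
#' @export
generate_sources <- function(cfg, latent, events, n_samples, subject_index) {
  if (length(latent) != cfg$n_trials) {
    stop("`latent` must have one value per trial", call. = FALSE)
  }
  bands <- band_definitions()
  nyq <- cfg$fs / 2
  n_src <- cfg$n_sources + as.integer(cfg$artifact_source)
  S <- matrix(0, n_src, n_samples)

  # map samples to trials (0 = outside any trial); a trial's modulation
  # span runs from its baseline onset up to the next trial's onset
  trial_of <- integer(n_samples)
  starts <- events$baseline_onset + 1          # to 1-based
  ends <- c(events$baseline_onset[-1], n_samples)
  for (i in seq_len(nrow(events))) {
    trial_of[starts[i]:ends[i]] <- events$trial[i]
  }

  # partition each labeled band among the sources that share it, so every
  # source has a distinct spectral peak (second-order identifiability)
  sub_lower <- sub_upper <- numeric(cfg$n_sources)
  for (bn in unique(cfg$source_bands)) {
    idx <- which(cfg$source_bands == bn)
    b <- bands[bands$name == bn, ]
    w <- (b$upper - b$lower) / length(idx)
    sub_lower[idx] <- b$lower + (seq_along(idx) - 1) * w
    sub_upper[idx] <- b$lower + seq_along(idx) * w
  }

  inf <- cfg$informative_sources
  for (j in seq_len(cfg$n_sources)) {
    b <- bands[bands$name == cfg$source_bands[j], ]
    if (b$upper > nyq) {
      stop(sprintf("band %s exceeds the Nyquist frequency", b$name),
           call. = FALSE)
    }
    osc <- bandlimited_noise(n_samples, cfg$fs, sub_lower[j], sub_upper[j],
                             derive_seed(cfg$seed, subject_index, 10L, j))
    bg <- one_over_f_noise(n_samples, cfg$fs, cfg$background$exponent,
                           cfg$background$sd,
                           derive_seed(cfg$seed, subject_index, 20L, j))
    amp <- rep(1, n_samples)
    k <- match(j, inf$source)
    if (!is.na(k) && inf$strength[k] != 0) {
      per_trial <- exp(inf$sign[k] * inf$strength[k] * (latent - 0.5))
      in_trial <- trial_of > 0
      amp[in_trial] <- per_trial[trial_of[in_trial]]
    }
    S[j, ] <- amp * osc + bg
  }
  if (cfg$artifact_source) {
    # broadband (white) transient-rich artifact: most power above 40 Hz
    S[n_src, ] <- with_seed(derive_seed(cfg$seed, subject_index, 30L),
                            stats::rnorm(n_samples, 0, 3))
  }
  S
}

#' Mix sources into a sensor-space recording
#'
#' `data = mixing \%*\% sources + noise` with i.i.d. Gaussian sensor
#' noise; deterministic given `seed`.
#'
#' @param sources Sources-by-samples matrix.
#' @param true_mixing Channels-by-sources matrix of full column rank.
#' @param sensor_noise_sd Noise standard deviation (microvolts).
#' @param fs Sampling rate (Hz).
#' @param seed Integer seed for the sensor noise.
#' @param channel_labels Optional channel names.
#' @return An [eeg_recording()].
#' @export
mix_and_record <- function(sources, true_mixing, sensor_noise_sd, fs, seed,
                           channel_labels = NULL) {
  true_mixing <- as.matrix(true_mixing)
  if (ncol(true_mixing) != nrow(sources)) {
    stop("mixing columns must match the number of sources", call. = FALSE)
  }
  if (qr(true_mixing)$rank < ncol(true_mixing)) {
    stop("`true_mixing` must have full column rank", call. = FALSE)
  }
  x <- true_mixing %*% sources
  if (sensor_noise_sd > 0) {
    x <- x + with_seed(seed, {
      matrix(stats::rnorm(length(x), 0, sensor_noise_sd), nrow(x), ncol(x))
    })
  }
  eeg_recording(x, fs, channel_labels = channel_labels, reference = "raw")
}

#' Assemble the event timeline and behavioral outcomes for one subject
#' @noRd
build_session_events <- function(cfg, ttt, subject_index, targets) {
  fs <- cfg$fs
  ph <- cfg$phase_durations
  n <- cfg$n_trials
  with_seed(derive_seed(cfg$seed, subject_index, 2L), {
    target_idx <- sample.int(nrow(targets), n, replace = TRUE)
    planning_dur <- stats::runif(n, ph$planning_min, ph$planning_max)
    return_dur <- stats::runif(n, ph$return_min, ph$return_max)
    start <- c(0, 0, 0)
    dist <- sqrt(rowSums(targets^2))[target_idx]
    move_time <- ttt * dist
    timeout <- move_time > ph$go_limit
    move_time[timeout] <- ph$go_limit

    cur <- 0L
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      b0 <- cur
      p0 <- b0 + round(ph$baseline * fs)
      g0 <- p0 + round(planning_dur[i] * fs)
      r0 <- g0 + round(move_time[i] * fs)
      cur <- r0 + round(return_dur[i] * fs)
      if (i %% cfg$block_size == 0 && i < n) {
        cur <- cur + round(ph$intermission * fs)
      }
      rows[[i]] <- data.frame(trial = i, baseline_onset = b0,
                              planning_onset = p0, go_onset = g0,
                              reached_sample = r0, timeout = timeout[i],
                              start_x = start[1], start_y = start[2],
                              start_z = start[3],
                              target_x = targets[target_idx[i], 1],
                              target_y = targets[target_idx[i], 2],
                              target_z = targets[target_idx[i], 3])
    }
    list(events = trial_events(do.call(rbind, rows)),
         n_samples = cur + round(fs))   # 1 s tail padding
  })
}

#' Generate one synthetic session
#'
#' @param cfg A [sim_config()].
#' @param subject_index Subject number (1-based).
#' @param base_mixing Cohort-level channels-by-sources mixing matrix; if
#'   `NULL` it is drawn from `cfg$seed` as in [generate_cohort()].
#' @param targets Optional matrix of target positions (rows = targets,
#'   columns = x/y/z in meters); drawn from `cfg$seed` if `NULL`.
#' @return A `vmil_session`: list with `eeg` ([eeg_recording()]), `events`
#'   ([trial_events()]), `ttt_true` (pre-timeout noisy TTT, s/m),
#'   `latent_curve`, `true_mixing` and `subject`.
#' @export
generate_session <- function(cfg, subject_index, base_mixing = NULL,
                             targets = NULL) {
  if (is.null(base_mixing)) base_mixing <- draw_base_mixing(cfg)
  if (is.null(targets)) targets <- draw_targets(cfg)
  curve <- generate_learning_curve(cfg, subject_index)
  layout <- build_session_events(cfg, curve$ttt, subject_index, targets)
  S <- generate_sources(cfg, curve$latent, layout$events, layout$n_samples,
                        subject_index)
  A <- base_mixing
  if (cfg$mixing_jitter > 0) {
    A <- A + with_seed(derive_seed(cfg$seed, subject_index, 3L), {
      matrix(stats::rnorm(length(A), 0, cfg$mixing_jitter * stats::sd(A)),
             nrow(A), ncol(A))
    })
  }
  A <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  rec <- mix_and_record(S, A, cfg$sensor_noise_sd, cfg$fs,
                        derive_seed(cfg$seed, subject_index, 4L))
  structure(
    list(eeg = rec, events = layout$events, ttt_true = curve$ttt,
         latent_curve = curve$latent, true_mixing = A,
         subject = subject_index),
    class = "vmil_session"
  )
}

#' @noRd
draw_base_mixing <- function(cfg) {
  n_src <- cfg$n_sources + as.integer(cfg$artifact_source)
  with_seed(derive_seed(cfg$seed, 0L, 5L), {
    A <- matrix(stats::rnorm(cfg$n_channels * n_src), cfg$n_channels, n_src)
    if (cfg$artifact_source) {
      # artifact dominated by a single channel
      a <- numeric(cfg$n_channels)
      a[1] <- 1
      a[-1] <- stats::rnorm(cfg$n_channels - 1, 0, 0.05)
      A[, n_src] <- a
    }
    sweep(A, 2, sqrt(colSums(A^2)), "/")
  })
}

#' @noRd
draw_targets <- function(cfg, n_targets = 8) {
  with_seed(derive_seed(cfg$seed, 0L, 6L), {
    dir <- matrix(stats::rnorm(n_targets * 3), n_targets, 3)
    dir <- sweep(dir, 1, sqrt(rowSums(dir^2)), "/")
    dist <- stats::runif(n_targets, 0.15, 0.30)
    dir * dist
  })
}

#' Generate a multi-subject synthetic cohort
#'
#' Subjects share the cohort-level mixing topographies up to a small
#' Gaussian per-subject perturbation (`cfg$mixing_jitter`); noise
#' realizations are independent across subjects, with all seeds derived
#' deterministically from `cfg$seed` and the subject index.
#'
#' @param cfg A [sim_config()].
#' @return A `vmil_cohort`: list of `vmil_session` objects with the
#'   config attached as attribute `config`.
#' @export
generate_cohort <- function(cfg) {
  base_mixing <- draw_base_mixing(cfg)
  targets <- draw_targets(cfg)
  sessions <- lapply(seq_len(cfg$n_subjects), function(s) {
    generate_session(cfg, s, base_mixing = base_mixing, targets = targets)
  })
  structure(sessions, class = "vmil_cohort", config = cfg,
            base_mixing = base_mixing)
}

#' @export
print.vmil_session <- function(x, ...) {
  cat(sprintf("<vmil_session> subject %d: %d trials, %.1f s of EEG\n",
              x$subject, nrow(x$events), ncol(x$eeg$data) / x$eeg$fs))
  invisible(x)
}

#' @export
print.vmil_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<vmil_cohort> %d subjects x %d trials @ %g Hz\n",
              length(x), cfg$n_trials, cfg$fs))
  invisible(x)
}
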