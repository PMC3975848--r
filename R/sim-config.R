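#' Configuration of the synthetic visuomotor-learning cohort
#'
#' Defines every generative parameter of the simulated experiment: cohort
#' size, session layout (trials, blocks, trial phases), sensor geometry,
#' source content, the latent learning curve that drives time-to-target
#' (TTT), and the coupling between that curve and the oscillatory power of
#' designated cortical sources.
#'
#' The defaults emulate a reaching study in which each subject performs
#' 200 trials in four blocks of 50 with one-minute intermissions; every
#' trial consists of a 5 s baseline, a 2.5-4 s planning phase, a go phase
#' capped at 10 s and a return phase. Observed TTT (s/m) follows a
#' three-parameter exponential learning curve plus Gaussian trial noise.
#' A subset of sources ("informative sources") have their band-limited
#' oscillatory amplitude modulated per trial by the latent learning state;
#' a negative `sign` means more bandpower goes with faster movements
#' (lower TTT), the direction reported for alpha/mu rhythms over motor
#' areas.
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param n_trials Trials per subject; must be divisible by `block_size`.
#' @param block_size Trials per block (blocks are separated by an
#'   intermission).
#' @param fs Sampling rate in Hz; must be at least twice the upper edge of
#'   the highest analysis band (85 Hz), i.e. >= 170 Hz.
#' @param n_channels Number of EEG channels.
#' @param n_sources Number of latent cortical sources.
#' @param informative_sources Data frame with columns `source` (index),
#'   `band` (one of the five analysis bands, see [band_definitions()]),
#'   `sign` (+1/-1, sign of the bandpower-TTT coupling) and `strength`
#'   (dimensionless log-amplitude swing of the modulation).
#' @param learning_curve List with `initial` and `asymptote` TTT (s/m),
#'   `decay` constant (trials, > 0) and `noise_sd` (s/m).
#' @param phase_durations List of phase durations in seconds: `baseline`,
#'   `planning_min`/`planning_max`, `go_limit`, `return_min`/`return_max`,
#'   `intermission`.
#' @param background List with the `exponent` of the 1/f background
#'   spectrum and its `sd` (microvolts).
#' @param source_bands Optional character vector (length `n_sources`)
#'   naming the oscillatory band of each source; defaults to cycling
#'   alpha/mu, beta and theta, overridden by `informative_sources$band`
#'   for informative sources.
#' @param sensor_noise_sd Standard deviation of i.i.d. sensor noise
#'   (microvolts).
#' @param mixing_jitter Relative per-subject Gaussian jitter on the shared
#'   mixing topographies (anatomical variability; 0 = identical
#'   topographies across subjects).
#' @param artifact_source If `TRUE`, append one broadband artifact source
#'   dominated by a single channel (for testing component rejection).
#' @param seed Integer master seed; all per-subject seeds derive from it.
#' @return A validated list of class `sim_config`.
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(n_subjects = 6,
                       n_trials = 200,
                       block_size = 50,
                       fs = 250,
                       n_channels = 32,
                       n_sources = 16,
                       informative_sources = data.frame(
                         source = 1:3, band = "alpha_mu",
                         sign = -1, strength = 0.25),
                       learning_curve = list(initial = 25, asymptote = 8,
                                             decay = 50, noise_sd = 3),
                       phase_durations = list(baseline = 5,
                                              planning_min = 2.5,
                                              planning_max = 4,
                                              go_limit = 10,
                                              return_min = 1.5,
                                              return_max = 3,
                                              intermission = 60),
                       background = list(exponent = 1, sd = 1),
                       source_bands = NULL,
                       sensor_noise_sd = 0.5,
                       mixing_jitter = 0.05,
                       artifact_source = FALSE,
                       seed = 1L) {
  if (!is_count(n_subjects) || !is_count(n_trials) || !is_count(block_size) ||
      !is_count(n_channels, 2) || !is_count(n_sources)) {
    stop("cohort dimensions must be positive integers", call. = FALSE)
  }
  if (n_trials %% block_size != 0) {
    stop("`n_trials` must be divisible by `block_size`", call. = FALSE)
  }
  bands <- band_definitions()
  if (!is_scalar(fs, 0) || fs < 2 * max(bands$upper)) {
    stop(sprintf("`fs` must be at least %g Hz (2x the upper gamma edge)",
                 2 * max(bands$upper)), call. = FALSE)
  }
  inf <- as.data.frame(informative_sources)
  if (nrow(inf) > 0) {
    if (!all(c("source", "band", "sign", "strength") %in% names(inf))) {
      stop("`informative_sources` needs columns source, band, sign, strength",
           call. = FALSE)
    }
    if (!all(inf$source %in% seq_len(n_sources))) {
      stop("`informative_sources$source` must index existing sources",
           call. = FALSE)
    }
    if (!all(inf$band %in% bands$name)) {
      stop("unknown band label(s) in `informative_sources`", call. = FALSE)
    }
    if (!all(inf$sign %in% c(-1, 1))) {
      stop("`informative_sources$sign` must be +1 or -1", call. = FALSE)
    }
  }
  lc <- learning_curve
  if (!is_scalar(lc$decay, 0)) {
    # Inf is allowed as the no-learning limit (constant expected TTT)
    if (!(is.numeric(lc$decay) && length(lc$decay) == 1 && lc$decay > 0)) {
      stop("`learning_curve$decay` must be positive", call. = FALSE)
    }
  }
  if (!is_scalar(lc$initial, 0) || !is_scalar(lc$asymptote, 0) ||
      !is_scalar(lc$noise_sd, -1e-12)) {
    stop("learning-curve parameters must be positive (noise_sd >= 0)",
         call. = FALSE)
  }
  if (is.null(source_bands)) {
    source_bands <- rep(c("alpha_mu", "beta", "theta"),
                        length.out = n_sources)
  }
  if (length(source_bands) != n_sources ||
      !all(source_bands %in% bands$name)) {
    stop("`source_bands` must name one analysis band per source",
         call. = FALSE)
  }
  if (nrow(inf) > 0) {
    source_bands[inf$source] <- inf$band
  }
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_trials = as.integer(n_trials),
              block_size = as.integer(block_size),
              fs = fs, n_channels = as.integer(n_channels),
              n_sources = as.integer(n_sources),
              informative_sources = inf,
              learning_curve = lc,
              phase_durations = phase_durations,
              background = background,
              source_bands = source_bands,
              sensor_noise_sd = sensor_noise_sd,
              mixing_jitter = mixing_jitter,
              artifact_source = isTRUE(artifact_source),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d subjects x %d trials (%d-trial blocks), %d ch / %d sources @ %g Hz\n",
              x$n_subjects, x$n_trials, x$block_size, x$n_channels,
              x$n_sources, x$fs))
  cat(sprintf("  learning curve: %g -> %g s/m, decay %g trials, noise sd %g\n",
              x$learning_curve$initial, x$learning_curve$asymptote,
              x$learning_curve$decay, x$learning_curve$noise_sd))
  if (nrow(x$informative_sources) > 0) {
    cat(sprintf("  informative sources: %s (%s, sign %s, strength %g)\n",
                paste(x$informative_sources$source, collapse = ","),
                paste(unique(x$informative_sources$band), collapse = ","),
                paste(unique(x$informative_sources$sign), collapse = ","),
                x$informative_sources$strength[1]))
  }
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
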