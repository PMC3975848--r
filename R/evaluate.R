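# Prediction-quality statistic for low-pass-filtered targets and the
# group-level trial-permutation test.

#' Coefficient of determination
#'
#' `1 - sum((x - y)^2) / sum((x - mean(x))^2)` for observed `x` and
#' modeled `y`; may be negative, and equals 1 only when `y = x`.
#'
#' @param x Observed series (non-constant).
#' @param y Modeled series of the same length.
#' @return Scalar R-squared.
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop("`x` and `y` must have equal length >= 2", call. = FALSE)
  }
  ss_tot <- sum((x - mean(x))^2)
  if (ss_tot == 0) {
    stop("`x` is constant: R-squared is undefined", call. = FALSE)
  }
  1 - sum((x - y)^2) / ss_tot
}

#' Modified R-squared for band-limited predictions
#'
#' Ordinary R-squared of the prediction divided by the R-squared that the
#' low-pass-filtered observed series itself achieves:
#' `r2_mod = R2(x, y) / R2(x, LP(x, c))`. The denominator is the best any
#' model restricted to frequencies below `c` can do, so the statistic
#' ranges over `(-Inf, 1]`: 1 means all explainable slow variance is
#' explained, values below 0 mean variance was added.
#'
#' @param x Observed per-trial series.
#' @param y Predicted series.
#' @param c Trial-domain cut-off (radians/trial) defining the low-pass
#'   reference.
#' @return Scalar statistic.
#' @export
r2_mod <- function(x, y, c = 0.1) {
  den <- r_squared(x, trial_domain_lowpass(x, c))
  if (den <= 0) {
    stop(sprintf(
      "r2_mod undefined: R2(x, LP(x, c)) = %.4f is not positive", den),
      call. = FALSE)
  }
  r_squared(x, y) / den
}

#' Group-level trial-permutation test
#'
#' The observed statistic is the subject aggregate (mean by default; the
#' median is also reported) of per-subject `r2_mod(observed, predicted)`.
#' For each permutation draw the trial order of every subject's observed
#' series is permuted independently, `r2_mod` is recomputed against the
#' fixed predictions, and the aggregate retained; the p-value is the
#' add-one estimator `(1 + #draws >= observed) / (1 + n_perm)`, so it is
#' never exactly zero. Permuting usually destroys the slow structure of
#' the observed series; when a permuted denominator is not positive that
#' subject's draw value is set to 0 (no explainable slow variance means
#' no credit). Setting `recompute_denominator = FALSE` reuses each
#' subject's unpermuted denominator instead.
#'
#' @param pairs A `loso_result` or a list of lists with elements
#'   `observed` and `predicted`.
#' @param c Trial-domain cut-off (radians/trial).
#' @param n_perm Number of permutation draws (>= 100).
#' @param seed Integer seed; the test is deterministic given it.
#' @param aggregate `"mean"` (default) or `"median"`.
#' @param recompute_denominator Recompute `R2(x, LP(x, c))` on each
#'   permuted series (default `TRUE`).
#' @return A `vmil_permtest`: list with `observed`, `observed_median`,
#'   `draws`, `p`, `n_perm`, `seed`, `aggregate`, `c` and a `per_subject`
#'   table.
#' @export
group_permutation_test <- function(pairs, c = 0.1, n_perm = 10000,
                                   seed = 1L,
                                   aggregate = c("mean", "median"),
                                   recompute_denominator = TRUE) {
  aggregate <- match.arg(aggregate)
  if (inherits(pairs, "loso_result")) {
    c <- pairs$c
    pairs <- pairs$folds
  }
  if (length(pairs) < 2) {
    stop("group test needs at least 2 subjects", call. = FALSE)
  }
  if (n_perm < 100) {
    stop("`n_perm` must be at least 100", call. = FALSE)
  }
  agg_fun <- if (aggregate == "mean") mean else stats::median
  bf <- signal::butter(3, c / pi, type = "low")
  lp <- function(v) lowpass_zerophase(v, bf)
  per_subject <- lapply(pairs, function(p) {
    x <- p$observed
    y <- p$predicted
    den <- r_squared(x, lp(x))
    if (den <= 0) {
      stop(sprintf(
        "r2_mod undefined for a subject: denominator %.4f", den),
        call. = FALSE)
    }
    list(x = x, y = y, den = den, num = r_squared(x, y))
  })
  obs_vals <- vapply(per_subject, function(p) p$num / p$den, 0)
  observed <- agg_fun(obs_vals)
  draws <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      vals <- vapply(per_subject, function(p) {
        xp <- p$x[sample.int(length(p$x))]
        num <- r_squared(xp, p$y)
        den <- if (recompute_denominator) r_squared(xp, lp(xp)) else p$den
        if (den <= 0) 0 else num / den
      }, 0)
      agg_fun(vals)
    }, 0)
  })
  p_value <- (1 + sum(draws >= observed)) / (1 + n_perm)
  structure(
    list(observed = observed,
         observed_median = stats::median(obs_vals),
         draws = draws, p = p_value, n_perm = as.integer(n_perm),
         seed = as.integer(seed), aggregate = aggregate, c = c,
         per_subject = data.frame(subject = seq_along(obs_vals),
                                  r2 = vapply(per_subject, `[[`, 0, "num"),
                                  r2_denominator =
                                    vapply(per_subject, `[[`, 0, "den"),
                                  r2_mod = obs_vals)),
    class = "vmil_permtest"
  )
}

#' @export
print.vmil_permtest <- function(x, ...) {
  cat(sprintf("<vmil_permtest> observed %s R2_mod = %.3f (median %.3f), p = %.4g (%d permutations)\n",
              x$aggregate, x$observed, x$observed_median, x$p, x$n_perm))
  invisible(x)
}

#' Null calibration of the group permutation test
#'
#' Repeatedly simulates cohorts in which the features carry no
#' information about performance and measures how often the permutation
#' test rejects at level `alpha`. Each replicate draws per-subject TTT
#' learning curves, builds feature tables of trial-domain-smoothed noise
#' (the same smoothing the real pipeline applies to bandpowers, with zero
#' behavioral coupling), runs leave-one-subject-out prediction and the
#' group permutation test. A well-calibrated test rejects at close to the
#' nominal rate.
#'
#' @param n_reps Number of replicate cohorts.
#' @param cfg A [sim_config()] providing cohort size and learning-curve
#'   parameters (EEG-level parameters are not used here).
#' @param n_features Number of noise feature columns per subject.
#' @param spec A [forest_spec()] for the per-fold forests.
#' @param c Trial-domain cut-off (radians/trial).
#' @param n_perm Permutations per replicate.
#' @param alpha Nominal level (default 0.05).
#' @param seed Master seed.
#' @return List with `rejection_rate`, `p_values`, `alpha`, `n_reps`.
#' @export
null_calibration <- function(n_reps = 100, cfg = sim_config(),
                             n_features = 20,
                             spec = forest_spec(n_trees = 100),
                             c = 0.1, n_perm = 500, alpha = 0.05,
                             seed = 1L, ...) {
  p_values <- vapply(seq_len(n_reps), function(rep_i) {
    rep_seed <- derive_seed(seed, rep_i)
    cfg_r <- cfg
    cfg_r$seed <- rep_seed
    tables <- lapply(seq_len(cfg$n_subjects), function(s) {
      ttt <- generate_learning_curve(cfg_r, s)$ttt
      feats <- with_seed(derive_seed(rep_seed, s, 7L), {
        matrix(stats::rnorm(cfg$n_trials * n_features),
               cfg$n_trials, n_features)
      })
      feats <- apply(feats, 2, trial_domain_lowpass, c = c)
      colnames(feats) <- sprintf("F%02d", seq_len(n_features))
      list(features = feats, ttt = ttt)
    })
    spec_r <- spec
    spec_r$seed <- derive_seed(rep_seed, 8L)
    cv <- loso_cv(tables, spec_r, c = c)
    group_permutation_test(cv, n_perm = n_perm,
                           seed = derive_seed(rep_seed, 9L), ...)$p
  }, 0)
  list(rejection_rate = mean(p_values < alpha), p_values = p_values,
       alpha = alpha, n_reps = n_reps)
}
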