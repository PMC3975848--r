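# End-to-end orchestration: simulate -> preprocess -> SOBI -> features ->
# LOSO prediction -> evaluation -> interpretation.

#' Pipeline configuration
#'
#' Bundles every stage's parameters. One global `seed` deterministically
#' derives all stage seeds, so a config fully reproduces a run.
#'
#' @param sim A [sim_config()] describing the synthetic cohort (or the
#'   cohort to be loaded; see [run_pipeline()]).
#' @param phase `"planning"`, `"baseline"` or `"both"`: which pre-trial
#'   phase's epochs feed the feature extraction.
#' @param c Trial-domain low-pass cut-off in radians per trial.
#' @param n_components Number of pooled principal components; defaults to
#'   the generator's source count.
#' @param lags SOBI lag set (samples).
#' @param sobi_tol,sobi_max_sweeps Joint-diagonalization controls.
#' @param feature_highpass_hz High-pass cut-off (Hz) for the data the
#'   bandpower features are computed on (the SOBI decomposition itself is
#'   always trained on 3 Hz high-passed data).
#' @param forest A [forest_spec()].
#' @param n_perm Permutation draws for the group test.
#' @param importance_repeats Permutations per variable for importance.
#' @param influence_top_k Number of top-importance variables to trace
#'   influence curves for.
#' @param grid_size Influence-curve grid size.
#' @param seed Global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            phase = c("planning", "baseline", "both"),
                            c = 0.1,
                            n_components = sim$n_sources,
                            lags = 1:50,
                            sobi_tol = 1e-8,
                            sobi_max_sweeps = 200,
                            feature_highpass_hz = 0.1,
                            forest = forest_spec(),
                            n_perm = 10000,
                            importance_repeats = 3,
                            influence_top_k = 4,
                            grid_size = 50,
                            seed = 1L) {
  phase <- match.arg(phase)
  cfg <- list(sim = sim, phase = phase, c = c,
              n_components = n_components, lags = lags,
              sobi_tol = sobi_tol, sobi_max_sweeps = sobi_max_sweeps,
              feature_highpass_hz = feature_highpass_hz,
              forest = forest, n_perm = as.integer(n_perm),
              importance_repeats = as.integer(importance_repeats),
              influence_top_k = as.integer(influence_top_k),
              grid_size = as.integer(grid_size), seed = as.integer(seed))
  cfg$sim$seed <- derive_seed(cfg$seed, 100L)
  cfg$forest$seed <- derive_seed(cfg$seed, 200L)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) a cohort, re-references to common average,
#' trains one pooled PCA + SOBI decomposition on 3 Hz high-passed data,
#' rejects artifact components, computes per-trial log-bandpower features
#' on minimally (0.1 Hz) high-passed data for the requested pre-trial
#' phase(s), low-pass filters features and targets in the trial domain,
#' runs leave-one-subject-out forest prediction, the group permutation
#' test, and the interpretation procedures. Deterministic given the
#' config.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-built `vmil_cohort`; by default the cohort
#'   is generated from `config$sim`.
#' @param output_dir Optional directory; when given, the report and CSV
#'   tables are written there via [write_report()].
#' @param verbose Print stage progress.
#' @return A `vmil_report`: list with `phases` (per phase: `r2_table`,
#'   `permutation`, `importance`, `influence`), `sobi` summary,
#'   `source_matching`, `config` echo and `version`.
#' @export
run_pipeline <- function(config, cohort = NULL, output_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  sim <- config$sim
  if (is.null(cohort)) {
    say("generating cohort (%d subjects x %d trials)...",
        sim$n_subjects, sim$n_trials)
    cohort <- generate_cohort(sim)
  }
  phases <- if (config$phase == "both") c("baseline", "planning") else
    config$phase
  fs <- cohort[[1]]$eeg$fs

  say("preprocessing...")
  hp_train <- vector("list", length(cohort))
  raw_epochs <- vector("list", length(cohort))   # per subject, per phase
  ttt_obs <- vector("list", length(cohort))
  for (s in seq_along(cohort)) {
    car <- rereference_car(cohort[[s]]$eeg)
    cohort[[s]]$eeg$data <- matrix(0, 0, 0)      # free the raw copy
    hp_feat <- highpass(car, config$feature_highpass_hz)
    raw_epochs[[s]] <- lapply(stats::setNames(phases, phases), function(ph) {
      extract_epochs(hp_feat, cohort[[s]]$events, ph)
    })
    rm(hp_feat)
    hp_train[[s]] <- highpass(car, 3)
    rm(car)
    ttt_obs[[s]] <- normalized_ttt(
      cohort[[s]]$events, fs,
      go_limit = sim$phase_durations$go_limit)
  }

  say("pooled PCA (%d components) + SOBI...", config$n_components)
  reduction <- pool_and_reduce(hp_train, config$n_components)
  sb <- sobi(reduction$scores, lags = config$lags, tol = config$sobi_tol,
             max_sweeps = config$sobi_max_sweeps, reduction = reduction,
             boundaries = reduction$boundaries)
  model <- reject_artifact_ics(sb$model, sb$activations, fs)
  kept <- model$kept
  say("kept %d of %d components", length(kept), nrow(model$unmixing))
  rm(sb)
  hp_train <- NULL

  # transform from CAR channel space to component activations
  scl <- ifelse(reduction$sdev > 0, 1 / reduction$sdev, 0)
  act_transform <- model$unmixing %*% (reduction$rotation * scl)

  matching <- match_sources(model$topographies[, kept, drop = FALSE],
                            cohort[[1]]$true_mixing[, seq_len(sim$n_sources),
                                                    drop = FALSE])
  matching$component <- kept[matching$component]

  say("features + LOSO prediction...")
  report_phases <- list()
  for (ph in phases) {
    tables <- lapply(seq_along(cohort), function(s) {
      ep <- raw_epochs[[s]][[ph]]
      act <- array(0, dim = c(dim(ep$epochs)[1], length(kept),
                              dim(ep$epochs)[3]))
      for (t in seq_len(dim(ep$epochs)[1])) {
        x <- ep$epochs[t, , ]
        dim(x) <- dim(ep$epochs)[2:3]
        act[t, , ] <- act_transform[kept, , drop = FALSE] %*% x
      }
      ep_act <- structure(list(epochs = act, phase = ep$phase, fs = ep$fs,
                               trials = ep$trials), class = "epoch_set")
      ft <- build_feature_table(ep_act, kept = seq_along(kept),
                                subject = s, ids = kept)
      smoothed <- apply(unclass(ft), 2, trial_domain_lowpass, c = config$c)
      colnames(smoothed) <- colnames(ft)
      list(features = smoothed, ttt = ttt_obs[[s]])
    })
    cv <- loso_cv(tables, config$forest, c = config$c)
    perm <- group_permutation_test(
      cv, n_perm = config$n_perm,
      seed = derive_seed(config$seed, 300L, match(ph, phases)))

    say("  %s: mean R2_mod %.3f, p = %.4g", ph, perm$observed, perm$p)
    imp_tables <- lapply(seq_along(cv$folds), function(s) {
      train <- do.call(rbind, lapply(tables[-s], `[[`, "features"))
      ytr <- unlist(lapply(seq_along(tables)[-s], function(o) {
        prediction_target(tables[[o]]$ttt, c = config$c)$target
      }))
      variable_importance(cv$folds[[s]]$model, train, ytr,
                          n_repeats = config$importance_repeats,
                          seed = derive_seed(config$seed, 400L, s))
    })
    imp <- aggregate_importance(imp_tables)
    top_vars <- imp$variable[seq_len(min(config$influence_top_k,
                                         nrow(imp)))]
    influence <- lapply(top_vars, function(v) {
      # trace on the first fold whose training data spans the variable
      train <- do.call(rbind, lapply(tables[-1], `[[`, "features"))
      feature_influence(cv$folds[[1]]$model, train, v,
                        grid_size = config$grid_size)
    })
    names(influence) <- top_vars
    r2_table <- data.frame(
      subject = seq_along(cv$folds),
      r2 = vapply(cv$folds, `[[`, 0, "r2"),
      r2_denominator = vapply(cv$folds, `[[`, 0, "r2_denominator"),
      r2_mod = vapply(cv$folds, `[[`, 0, "r2_mod"))
    report_phases[[ph]] <- list(
      r2_table = r2_table,
      feature_tables = lapply(tables, `[[`, "features"),
      group_mean = mean(r2_table$r2_mod),
      group_median = stats::median(r2_table$r2_mod),
      permutation = perm,
      importance = imp,
      importance_by_fold = imp_tables,
      influence = influence,
      cv = cv)
  }

  report <- structure(
    list(phases = report_phases,
         sobi = list(kept = kept, rejection = model$rejection,
                     converged = model$converged),
         source_matching = matching,
         config = config,
         version = as.character(utils::packageVersion("vmil"))),
    class = "vmil_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' @export
print.vmil_report <- function(x, ...) {
  cat("<vmil_report>\n")
  for (nm in names(x$phases)) {
    ph <- x$phases[[nm]]
    cat(sprintf("  %s: group mean R2_mod %.3f, median %.3f, p = %.4g (%d perms)\n",
                nm, ph$group_mean, ph$group_median, ph$permutation$p,
                ph$permutation$n_perm))
    cat(sprintf("    top variables: %s\n",
                paste(utils::head(ph$importance$variable, 3),
                      collapse = ", ")))
  }
  cat(sprintf("  SOBI kept %d components\n", length(x$sobi$kept)))
  invisible(x)
}
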