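# Cross-subject prediction of filtered TTT with a bagged regression-tree
# ensemble under leave-one-subject-out cross-validation. The ensemble
# itself is fitted with 'ranger'; this module owns target construction,
# fold isolation and the prediction-result bookkeeping.

#' Random-forest hyperparameters
#'
#' @param n_trees Number of trees (default 500).
#' @param mtry Candidate features per split; `NULL` means the regression
#'   convention `ceiling(p / 3)`.
#' @param min_node Minimum node size (default 5).
#' @param bootstrap Sample with replacement per tree (default `TRUE`).
#' @param seed Integer seed; forests are deterministic given it.
#' @return A `forest_spec` list.
#' @export
forest_spec <- function(n_trees = 500, mtry = NULL, min_node = 5,
                        bootstrap = TRUE, seed = 1L) {
  if (!is_count(n_trees)) stop("`n_trees` must be >= 1", call. = FALSE)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 min_node = as.integer(min_node),
                 bootstrap = isTRUE(bootstrap), seed = as.integer(seed)),
            class = "forest_spec")
}

#' Train a regression forest
#'
#' Each tree is fit on a bootstrap resample with random per-split feature
#' subsets; per-tree in-bag counts are retained so out-of-bag rows can be
#' recovered for permutation importance.
#'
#' @param features Numeric matrix or data frame of predictors (named
#'   columns).
#' @param targets Numeric response, one value per row.
#' @param spec A [forest_spec()].
#' @return A `vmil_forest` wrapping the fitted ensemble and the training
#'   column names.
#' @export
train_forest <- function(features, targets, spec = forest_spec()) {
  features <- as.data.frame(features)
  if (nrow(features) == 0) stop("empty training set", call. = FALSE)
  if (nrow(features) != length(targets)) {
    stop("`targets` must have one value per feature row", call. = FALSE)
  }
  if (anyNA(features) || anyNA(targets)) {
    stop("NA values are not allowed in training data", call. = FALSE)
  }
  mtry <- spec$mtry
  if (is.null(mtry)) mtry <- ceiling(ncol(features) / 3)
  if (mtry > ncol(features)) {
    stop("`mtry` cannot exceed the feature count", call. = FALSE)
  }
  df <- cbind(.target = targets, features)
  fit <- ranger::ranger(
    dependent.variable.name = ".target", data = df,
    num.trees = spec$n_trees, mtry = mtry,
    min.node.size = spec$min_node, replace = spec$bootstrap,
    sample.fraction = if (spec$bootstrap) 1 else 0.632,
    keep.inbag = TRUE, seed = spec$seed, num.threads = 1)
  structure(list(fit = fit, columns = colnames(features), spec = spec,
                 train_range = range(targets)),
            class = "vmil_forest")
}

#' Predict from a trained forest
#'
#' Columns are matched by label (and reordered if necessary); unknown or
#' missing columns are an error naming the offenders. Predictions are the
#' mean over tree outputs.
#'
#' @param object A `vmil_forest`.
#' @param newdata Feature matrix or data frame.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.vmil_forest <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$columns, colnames(newdata))
  extra <- setdiff(colnames(newdata), object$columns)
  if (length(missing) > 0 || length(extra) > 0) {
    stop("feature columns do not match training columns; missing: [",
         paste(missing, collapse = ", "), "], unexpected: [",
         paste(extra, collapse = ", "), "]", call. = FALSE)
  }
  newdata <- newdata[, object$columns, drop = FALSE]
  stats::predict(object$fit, data = newdata, num.threads = 1)$predictions
}

#' Build the regression target for one subject
#'
#' The target is the observed TTT z-scored within subject and low-pass
#' filtered in the trial domain at cut-off `c`; the z-scored unfiltered
#' series is kept as the observed series the prediction is later scored
#' against.
#'
#' @param ttt Numeric raw TTT series (s/m) or a `ttt_series`.
#' @param c Trial-domain cut-off (radians/trial).
#' @param filter_target If `FALSE`, the raw z-scored TTT is used as the
#'   training target instead of its low-pass-filtered version.
#' @return List with `observed` (z-scored) and `target`.
#' @export
prediction_target <- function(ttt, c = 0.1, filter_target = TRUE) {
  if (inherits(ttt, "ttt_series")) ttt <- ttt$ttt
  observed <- zscore(ttt)
  target <- if (filter_target) trial_domain_lowpass(observed, c) else observed
  list(observed = observed, target = target)
}

#' Leave-one-subject-out cross-validation
#'
#' For each held-out subject a forest is trained on the concatenated
#' feature tables of all other subjects and used to predict the held-out
#' subject's trials in order; no held-out row ever enters its own
#' training set, and each fold's seed derives only from `spec$seed` and
#' the fold index.
#'
#' @param tables List with one element per subject, each a list with
#'   `features` (matrix/data frame, common columns across subjects) and
#'   `ttt` (raw TTT series or `ttt_series`).
#' @param spec A [forest_spec()].
#' @param c Trial-domain cut-off used for targets and scoring
#'   (radians/trial).
#' @param filter_target Passed to [prediction_target()].
#' @return A `loso_result`: list of per-subject folds (each with
#'   `subject`, `observed`, `target`, `predicted`, `r2`, `r2_denominator`,
#'   `r2_mod`) plus `c` and `spec`.
#' @export
loso_cv <- function(tables, spec = forest_spec(), c = 0.1,
                    filter_target = TRUE) {
  n_sub <- length(tables)
  if (n_sub < 2) {
    stop("leave-one-subject-out needs at least 2 subjects", call. = FALSE)
  }
  prep <- lapply(tables, function(tb) {
    tt <- prediction_target(tb$ttt, c = c, filter_target = filter_target)
    list(features = as.data.frame(as.matrix(tb$features)),
         observed = tt$observed, target = tt$target)
  })
  folds <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    train <- prep[-s]
    xtr <- do.call(rbind, lapply(train, `[[`, "features"))
    ytr <- unlist(lapply(train, `[[`, "target"))
    fold_spec <- spec
    fold_spec$seed <- derive_seed(spec$seed, s)
    fit <- train_forest(xtr, ytr, fold_spec)
    pred <- predict(fit, prep[[s]]$features)
    obs <- prep[[s]]$observed
    den <- r_squared(obs, trial_domain_lowpass(obs, c))
    folds[[s]] <- list(subject = s, observed = obs,
                       target = prep[[s]]$target, predicted = pred,
                       r2 = r_squared(obs, pred),
                       r2_denominator = den,
                       r2_mod = r2_mod(obs, pred, c = c),
                       model = fit)
  }
  structure(list(folds = folds, c = c, spec = spec),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  r <- vapply(x$folds, `[[`, 0, "r2_mod")
  cat(sprintf("<loso_result> %d subjects, R2_mod: %s (median %.3f, mean %.3f)\n",
              length(x$folds),
              paste(sprintf("%.2f", r), collapse = " "),
              stats::median(r), mean(r)))
  invisible(x)
}
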