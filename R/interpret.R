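# Mapping model behavior back to (component, band) variables: out-of-bag
# permutation variable importance and value-substitution influence curves.

#' Out-of-bag permutation variable importance
#'
#' For every variable, the increase in per-tree out-of-bag mean squared
#' error when that variable's values are permuted, averaged over trees
#' and over `n_repeats` independent permutations. Variables the model
#' relies on show a large error increase; irrelevant variables hover
#' around zero.
#'
#' @param model A `vmil_forest` trained with retained in-bag counts
#'   (always true for [train_forest()]).
#' @param features The training feature matrix/data frame.
#' @param targets The training targets.
#' @param n_repeats Permutations per variable (default 10).
#' @param seed Integer seed.
#' @return An `importance_table` data frame with `variable`,
#'   `importance` (error increase, target units squared) and `rank`.
#' @export
variable_importance <- function(model, features, targets, n_repeats = 10,
                                seed = 1L) {
  stopifnot(inherits(model, "vmil_forest"))
  if (n_repeats < 1) stop("`n_repeats` must be >= 1", call. = FALSE)
  features <- as.data.frame(features)[, model$columns, drop = FALSE]
  n <- nrow(features)
  inbag <- simplify2array(model$fit$inbag.counts)   # n x ntree
  oob <- inbag == 0
  tree_pred <- function(df) {
    stats::predict(model$fit, data = df, predict.all = TRUE,
                   num.threads = 1)$predictions     # n x ntree
  }
  base_pred <- tree_pred(features)
  err <- (base_pred - targets)^2
  ntree <- ncol(base_pred)
  base_mse <- vapply(seq_len(ntree),
                     function(t) mean(err[oob[, t], t]), 0)
  p <- length(model$columns)
  imp <- numeric(p)
  with_seed(seed, {
    for (v in seq_len(p)) {
      acc <- 0
      for (r in seq_len(n_repeats)) {
        perm <- features
        perm[[v]] <- perm[[v]][sample.int(n)]
        pp <- tree_pred(perm)
        pe <- (pp - targets)^2
        mse <- vapply(seq_len(ntree),
                      function(t) mean(pe[oob[, t], t]), 0)
        acc <- acc + mean(mse - base_mse)
      }
      imp[v] <- acc / n_repeats
    }
  })
  out <- data.frame(variable = model$columns, importance = imp,
                    rank = rank(-imp, ties.method = "first"))
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Value-substitution feature influence curve
#'
#' Traces a variable's marginal effect on the prediction: over an evenly
#' spaced grid spanning the variable's training minimum and maximum, the
#' variable is fixed to each grid value in every training row, the model
#' predicts the modified data, and the predictions are averaged (a
#' partial-dependence construction).
#'
#' @param model A `vmil_forest`.
#' @param features The training feature matrix/data frame.
#' @param variable Column name to trace.
#' @param grid_size Number of grid points (default 50, >= 2).
#' @return An `influence_curve`: list with `variable`, `grid` and
#'   `effect` (mean prediction at each grid value).
#' @export
feature_influence <- function(model, features, variable, grid_size = 50) {
  stopifnot(inherits(model, "vmil_forest"))
  if (grid_size < 2) stop("`grid_size` must be >= 2", call. = FALSE)
  features <- as.data.frame(features)
  if (!variable %in% model$columns || !variable %in% colnames(features)) {
    stop(sprintf("unknown variable '%s'", variable), call. = FALSE)
  }
  rng <- range(features[[variable]])
  grid <- seq(rng[1], rng[2], length.out = grid_size)
  effect <- vapply(grid, function(v_hat) {
    mod <- features
    mod[[variable]] <- v_hat
    mean(predict(model, mod))
  }, 0)
  structure(list(variable = variable, grid = grid, effect = effect),
            class = "influence_curve")
}

#' Aggregate importance tables across cross-validation folds
#'
#' @param fold_tables List of `importance_table`s with identical variable
#'   sets (one per fold).
#' @param top_k Rank threshold for the consistency score (default 3).
#' @return Data frame with per-variable `mean_importance`,
#'   `sd_importance`, per-fold ranks and `consistency` (fraction of folds
#'   where the variable ranks in the top `top_k`).
#' @export
aggregate_importance <- function(fold_tables, top_k = 3) {
  if (length(fold_tables) < 1) stop("need at least one fold", call. = FALSE)
  vars <- fold_tables[[1]]$variable
  imp <- vapply(fold_tables, function(tb) {
    tb$importance[match(vars, tb$variable)]
  }, numeric(length(vars)))
  imp <- matrix(imp, nrow = length(vars))
  rk <- apply(-imp, 2, rank, ties.method = "first")
  rk <- matrix(rk, nrow = length(vars))
  out <- data.frame(
    variable = vars,
    mean_importance = rowMeans(imp),
    sd_importance = if (ncol(imp) == 1) rep(0, length(vars)) else
      apply(imp, 1, stats::sd),
    consistency = rowMeans(rk <= top_k))
  out$rank_by_fold <- I(split(rk, row(rk)))
  out[order(-out$mean_importance), , drop = FALSE]
}
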