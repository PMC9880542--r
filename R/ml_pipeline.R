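# Nested cross-validation benchmark: 10 outer folds estimate generalisation
# while an inner CV per outer fold selects hyperparameters without ever
# touching that fold's hold-out.

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`; may be negative when predictions underperform the
#' mean (negative values are meaningful model-ranking evidence, not errors).
#'
#' @param truth,predictions Numeric vectors of equal length >= 2.
#' @return Scalar R^2.
#' @export
r2_score <- function(truth, predictions) {
  stopifnot(length(truth) == length(predictions), length(truth) >= 2)
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) stop("r2_score: constant truth, score undefined",
                        call. = FALSE)
  1 - sum((truth - predictions)^2) / ss_tot
}

#' Root-mean-square prediction error
#' @param truth,predictions Numeric vectors of equal length >= 1.
#' @return Non-negative scalar in the units of the target (GPR %).
#' @export
rmse_score <- function(truth, predictions) {
  stopifnot(length(truth) == length(predictions), length(truth) >= 1)
  sqrt(mean((truth - predictions)^2))
}

#' Cross-validation configuration
#'
#' @param n_outer_folds Outer folds (default 10).
#' @param n_inner_folds Inner folds for hyperparameter selection (default 3).
#' @param grids Named list of hyperparameter grids per model
#'   (default [default_grids()]).
#' @param master_seed Integer seed from which fold shuffles and per-fit
#'   model seeds are derived.
#' @return A `cv_config` list.
#' @export
cv_config <- function(n_outer_folds = 10, n_inner_folds = 3,
                      grids = default_grids(), master_seed = 1L) {
  stopifnot(n_outer_folds >= 2, n_inner_folds >= 2)
  for (m in MODEL_NAMES) {
    if (is.null(grids[[m]]) || nrow(grids[[m]]) == 0) {
      stop("cv_config: empty hyperparameter grid for ", m, call. = FALSE)
    }
  }
  structure(list(n_outer_folds = as.integer(n_outer_folds),
                 n_inner_folds = as.integer(n_inner_folds),
                 grids = grids, master_seed = as.integer(master_seed)),
            class = "cv_config")
}

#' Deterministic k-fold assignment
#' @param n Number of rows.
#' @param k Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return Integer vector of fold ids in `1..k`, each row in exactly one
#'   fold, sizes differing by at most one.
#' @export
make_folds <- function(n, k, seed) {
  stopifnot(k >= 2, n >= k)
  with_seed(seed, {
    ord <- sample.int(n)
    folds <- integer(n)
    folds[ord] <- rep_len(seq_len(k), n)
    folds
  })
}

# Inner grid search: mean inner-fold RMSE per candidate row; ties break to
# the first (deterministic) row.
inner_select <- function(X, y, model_name, grid, n_inner, seed) {
  folds <- make_folds(nrow(X), n_inner, seed)
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    params <- grid[g, , drop = FALSE]
    rmses <- vapply(seq_len(n_inner), function(f) {
      tr <- folds != f
      m <- fit_model(X[tr, , drop = FALSE], y[tr], model_name, params,
                     seed = derive_seed(seed, "inner", g, f))
      rmse_score(y[!tr], predict(m, X[!tr, , drop = FALSE]))
    }, numeric(1))
    mean(rmses)
  }, numeric(1))
  list(params = grid[which.min(scores), , drop = FALSE],
       inner_rmse = min(scores))
}

#' Nested cross-validation of one model
#'
#' Outer folds partition the rows exactly once each into a hold-out set; an
#' inner k-fold grid search on the remaining training rows selects
#' hyperparameters by mean inner RMSE; the winning setting is refit on the
#' full training part and scored on the hold-out. Fully deterministic for a
#' fixed `master_seed`.
#'
#' @param features Numeric matrix/data frame (n x p, named columns).
#' @param gpr Numeric target vector (GPR %).
#' @param model_name One of `"lasso"`, `"svm"`, `"random_forest"`,
#'   `"xgboost"`.
#' @param config A [cv_config()].
#' @return A `model_result`: `per_fold_r2`, `per_fold_rmse`, `r2_mean`,
#'   `r2_sd`, `rmse_mean`, `rmse_sd`, `chosen_params` (one row per fold),
#'   `fold_assignment`, and pooled out-of-fold `predictions`/`truth`.
#' @export
nested_cv <- function(features, gpr, model_name, config = cv_config()) {
  model_name <- match.arg(model_name, MODEL_NAMES)
  X <- as_feature_matrix(features)
  y <- as.numeric(gpr)
  n <- nrow(X)
  k <- config$n_outer_folds
  if (n < 2 * k) {
    stop(sprintf(
      "nested_cv: %d rows cannot support %d outer folds; use fewer folds",
      n, k), call. = FALSE)
  }
  grid <- config$grids[[model_name]]
  folds <- make_folds(n, k, derive_seed(config$master_seed, "outer"))
  per_r2 <- per_rmse <- numeric(k)
  chosen <- vector("list", k)
  oof_pred <- numeric(n)
  for (f in seq_len(k)) {
    tr <- folds != f
    sel <- inner_select(X[tr, , drop = FALSE], y[tr], model_name, grid,
                        config$n_inner_folds,
                        derive_seed(config$master_seed, model_name, f))
    m <- fit_model(X[tr, , drop = FALSE], y[tr], model_name, sel$params,
                   seed = derive_seed(config$master_seed, model_name, f,
                                      "refit"))
    pred <- predict(m, X[!tr, , drop = FALSE])
    oof_pred[!tr] <- pred
    per_r2[f] <- r2_score(y[!tr], pred)
    per_rmse[f] <- rmse_score(y[!tr], pred)
    chosen[[f]] <- sel$params
  }
  structure(list(model_name = model_name,
                 per_fold_r2 = per_r2, per_fold_rmse = per_rmse,
                 r2_mean = mean(per_r2), r2_sd = sd(per_r2),
                 rmse_mean = mean(per_rmse), rmse_sd = sd(per_rmse),
                 chosen_params = do.call(rbind, chosen),
                 fold_assignment = folds,
                 predictions = oof_pred, truth = y),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> %s: R2 %.3f +- %.3f, RMSE %.3f +- %.3f (%d folds)\n",
              x$model_name, x$r2_mean, x$r2_sd, x$rmse_mean, x$rmse_sd,
              length(x$per_fold_r2)))
  invisible(x)
}

#' Run the four-model benchmark over site stratifications
#'
#' Evaluates each model with [nested_cv()] on the pooled cohort (`"all"`)
#' and within each treatment site. Strata too small for the fold structure
#' are flagged in the result rather than aborting the benchmark.
#'
#' @param features Numeric feature matrix/data frame.
#' @param gpr Numeric target vector.
#' @param sites Character vector of site labels (one per row), or `NULL`
#'   for pooled-only.
#' @param config A [cv_config()].
#' @param models Models to run (default all four).
#' @return A `benchmark_result`: `results[[stratum]][[model]]`
#'   (`model_result` or a `condition` for failed strata), `summary` data
#'   frame (one row per model x stratum with mean +- sd metrics) and
#'   `ranking` (models ordered by `r2_mean` within each stratum).
#' @export
run_benchmark <- function(features, gpr, sites = NULL,
                          config = cv_config(), models = MODEL_NAMES) {
  X <- as_feature_matrix(features)
  strata <- list(all = rep(TRUE, nrow(X)))
  if (!is.null(sites)) {
    for (s in unique(sites)) strata[[s]] <- sites == s
  }
  results <- list()
  rows <- list()
  for (st in names(strata)) {
    rowsel <- strata[[st]]
    results[[st]] <- list()
    for (m in models) {
      res <- tryCatch(
        nested_cv(X[rowsel, , drop = FALSE], gpr[rowsel], m, config),
        error = function(e) e)
      results[[st]][[m]] <- res
      ok <- inherits(res, "model_result")
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = st, model = m, n = sum(rowsel),
        r2_mean = if (ok) res$r2_mean else NA_real_,
        r2_sd = if (ok) res$r2_sd else NA_real_,
        rmse_mean = if (ok) res$rmse_mean else NA_real_,
        rmse_sd = if (ok) res$rmse_sd else NA_real_,
        failed = !ok,
        message = if (ok) "" else conditionMessage(res),
        stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, rows)
  ranking <- lapply(split(summary, summary$stratum), function(d) {
    d$model[order(-d$r2_mean)]
  })
  structure(list(results = results, summary = summary, ranking = ranking,
                 config = config),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  print(x$summary[, c("stratum", "model", "n", "r2_mean", "r2_sd",
                      "rmse_mean", "rmse_sd")])
  invisible(x)
}

#' Train the deployable final model on the entire dataset
#'
#' Hyperparameters are selected by the same inner CV as in [nested_cv()],
#' then the model is refit on all rows. The attached metrics are in-sample
#' (a soundness check for the final artifact, not an evaluation — use
#' [nested_cv()] for generalisation estimates).
#'
#' @inheritParams nested_cv
#' @return A `logqa_model` with attribute `in_sample` holding `r2`, `rmse`
#'   and the selected hyperparameters.
#' @export
train_final_model <- function(features, gpr, model_name,
                              config = cv_config()) {
  model_name <- match.arg(model_name, MODEL_NAMES)
  X <- as_feature_matrix(features)
  y <- as.numeric(gpr)
  sel <- inner_select(X, y, model_name, config$grids[[model_name]],
                      config$n_inner_folds,
                      derive_seed(config$master_seed, model_name, "final"))
  model <- fit_model(X, y, model_name, sel$params,
                     seed = derive_seed(config$master_seed, model_name,
                                        "final", "refit"))
  pred <- predict(model, X)
  attr(model, "in_sample") <- list(r2 = r2_score(y, pred),
                                   rmse = rmse_score(y, pred),
                                   params = sel$params)
  model
}
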