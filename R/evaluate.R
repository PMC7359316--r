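#' Prediction-accuracy metrics
#'
#' Root-mean-square error, mean absolute error, and the coefficient of
#' determination R-squared (1 - SSE/SST with SST about the mean of the
#' observed values). With a zero-variance response R-squared is undefined and
#' reported as `NA`.
#'
#' @param y Observed values.
#' @param yhat Predicted values, same length.
#' @return A one-row tibble with columns `rmse`, `mae`, `r2`.
#' @export
#' @examples
#' yield_metrics(c(0, 2), c(1, 1))
yield_metrics <- function(y, yhat) {
  if (length(y) == 0 || length(y) != length(yhat)) {
    abort("y and yhat must be equal-length, non-empty vectors")
  }
  err <- y - yhat
  sst <- sum((y - mean(y))^2)
  tibble(
    rmse = sqrt(mean(err^2)),
    mae = mean(abs(err)),
    r2 = if (sst == 0) NA_real_ else 1 - sum(err^2) / sst
  )
}

# Disjoint k-fold assignment over n rows under a fixed seed.
make_folds <- function(n, k, seed) {
  if (k < 2 || n < k) abort(sprintf("cannot split n = %d rows into k = %d folds", n, k))
  with_local_seed(seed, sample(rep(seq_len(k), length.out = n)))
}

assert_no_leakage <- function(train_idx, val_idx) {
  if (length(intersect(train_idx, val_idx)) > 0) {
    abort("internal leakage guard tripped: train and validation rows overlap")
  }
  invisible(TRUE)
}

#' Cross-validate a model on trial records
#'
#' Outer k-fold cross-validation over the unique (post-aggregation)
#' combinations. Within each outer fold the model may first be tuned by an
#' inner grid search restricted to the outer training rows, then is refitted
#' on all outer training rows and scored on the held-out fold. Train and
#' validation index sets are asserted disjoint at every level.
#'
#' @param records A trial-record tibble.
#' @param model `"stacked"` or `"rf1"` (first-stage forest alone).
#' @param k Number of outer folds.
#' @param inner_k Number of inner tuning folds.
#' @param tune_grid Optional data frame of candidate forest hyperparameters
#'   with columns `n_trees`, `n_features`, `node_size`; `NULL` skips tuning
#'   and uses `...` parameters as given.
#' @param seed Integer seed for fold assignment (and, offset per fold, for
#'   the fitted models).
#' @param ... Passed to [fit_stacked()] (or, for `model = "rf1"`,
#'   [forest_params()] fields `rf1 = ...`).
#' @return A `cv_report`: tibble of per-fold metrics with attributes `folds`
#'   and `settings`; see [tidy.cv_report()] / [glance.cv_report()].
#' @export
cross_validate <- function(records, model = c("stacked", "rf1"), k = 10,
                           inner_k = 5, tune_grid = NULL, seed = 2020, ...) {
  model <- match.arg(model)
  agg <- aggregate_replicates(records)
  n <- nrow(agg)
  folds <- make_folds(n, k, seed)
  dots <- list(...)

  per_fold <- purrr::map_dfr(seq_len(k), function(f) {
    tr <- which(folds != f); va <- which(folds == f)
    assert_no_leakage(tr, va)
    params <- if (is.null(tune_grid)) NULL else {
      tune_forest(agg[tr, ], model, tune_grid, inner_k, seed + f)
    }
    fit <- fit_cv_model(agg[tr, ], model, params, dots, seed + f, inner_k)
    pred_va <- predict_cv_model(fit, agg[va, ])
    pred_tr <- predict_cv_model(fit, agg[tr, ])
    dplyr::bind_cols(
      tibble(fold = f, split = c("train", "validation")),
      dplyr::bind_rows(yield_metrics(agg$yield[tr], pred_tr),
                       yield_metrics(agg$yield[va], pred_va))
    )
  })
  structure(per_fold,
            class = c("cv_report", class(per_fold)),
            folds = folds,
            settings = list(model = model, k = k, inner_k = inner_k,
                            seed = seed, tuned = !is.null(tune_grid)))
}

# Fit one outer-fold model. For "rf1" the records are encoded and only the
# first-stage forest is fitted; for "stacked" the full pipeline runs.
fit_cv_model <- function(train_records, model, params, dots, seed, inner_k) {
  if (model == "rf1") {
    fs <- build_feature_space(train_records)
    enc <- encode_records(train_records, fs)
    fp <- params %||% dots$rf1 %||% forest_params()
    list(kind = "rf1", fit = fit_rf(enc$X, enc$y, fp, seed = seed), fs = fs)
  } else {
    args <- c(list(records = train_records, seed = seed, inner_k = inner_k),
              dots)
    if (!is.null(params)) args$rf1 <- params
    list(kind = "stacked", fit = do.call(fit_stacked, args))
  }
}

predict_cv_model <- function(fit, records) {
  if (fit$kind == "rf1") {
    enc <- encode_records(records, fit$fs)
    predict(fit$fit, enc$X)
  } else {
    predict(fit$fit, records)
  }
}

# Inner grid search: inner_k-fold CV of the first-stage forest over the
# candidate grid, on outer-training rows only; returns the forest_params row
# with the lowest mean validation RMSE.
tune_forest <- function(train_records, model, grid, inner_k, seed) {
  fs <- build_feature_space(train_records)
  enc <- encode_records(train_records, fs)
  folds <- make_folds(nrow(enc$X), inner_k, seed)
  score <- vapply(seq_len(nrow(grid)), function(g) {
    fp <- forest_params(grid$n_trees[g],
                        min(grid$n_features[g], ncol(enc$X)),
                        grid$node_size[g])
    mean(vapply(seq_len(inner_k), function(f) {
      tr <- which(folds != f); va <- which(folds == f)
      assert_no_leakage(tr, va)
      fit <- fit_rf(enc$X[tr, , drop = FALSE], enc$y[tr], fp, seed = seed + f)
      yield_metrics(enc$y[va], predict(fit, enc$X[va, , drop = FALSE]))$rmse
    }, numeric(1)))
  }, numeric(1))
  g <- which.min(score)
  forest_params(grid$n_trees[g], grid$n_features[g], grid$node_size[g])
}

#' Default forest tuning grid
#'
#' Brackets the production hyperparameters (1000 trees, 100 or 20 features,
#' node size 10) at desk scale.
#'
#' @param p Number of available features (bounds the feature counts).
#' @return A tibble grid of `n_trees`, `n_features`, `node_size`.
#' @export
default_tune_grid <- function(p) {
  tidyr::expand_grid(
    n_trees = c(500, 1000),
    n_features = unique(pmax(1, pmin(p, c(floor(sqrt(p)), 100, floor(p / 4))))),
    node_size = c(5, 10)
  )
}

#' @export
glance.cv_report <- function(x, ...) {
  x |>
    dplyr::group_by(.data$split) |>
    dplyr::summarise(dplyr::across(c("rmse", "mae", "r2"), mean),
                     .groups = "drop") |>
    dplyr::mutate(model = attr(x, "settings")$model, .before = 1)
}

#' @export
tidy.cv_report <- function(x, ...) as_tibble(x)

#' Compare the stacked model against the first-stage forest under shared folds
#'
#' Runs one outer cross-validation in which each fold fits the first-stage
#' forest once and reuses it both as the standalone baseline and as stage one
#' of the stacked model, so the comparison isolates the contribution of the
#' interaction stages.
#'
#' @param records A trial-record tibble.
#' @param k Number of outer folds.
#' @param seed Integer seed.
#' @param rf1,rf2 Forest parameters for the two stages.
#' @param ... Passed to [search_interactions()] (`max_K`, `max_order`,
#'   `n_restarts`, `inner_k`, `tol`).
#' @return A tibble with one row per fold and model, with validation metrics.
#' @export
cv_compare_stacked <- function(records, k = 10, seed = 2020,
                               rf1 = forest_params(), rf2 = rf2_params(),
                               ...) {
  agg <- aggregate_replicates(records)
  fs <- build_feature_space(agg)
  enc <- encode_records(agg, fs)
  folds <- make_folds(nrow(agg), k, seed)
  purrr::map_dfr(seq_len(k), function(f) {
    tr <- which(folds != f); va <- which(folds == f)
    assert_no_leakage(tr, va)
    Xtr <- enc$X[tr, , drop = FALSE]; ytr <- enc$y[tr]
    Xva <- enc$X[va, , drop = FALSE]; yva <- enc$y[va]
    rf1_fit <- fit_rf(Xtr, ytr, rf1, seed = seed + f)
    y1_va <- predict(rf1_fit, Xva)
    gxe <- search_interactions(Xtr, ytr, seed = seed + f, ...)
    resid <- ytr - rf1_fit$oob
    Ztr <- build_Z(gxe$alpha, Xtr)
    if (ncol(Ztr) == 0) {
      y2_va <- rep(mean(resid), length(va))
    } else {
      p2 <- rf2; p2$n_features <- min(p2$n_features, ncol(Ztr))
      rf2_fit <- fit_rf(Ztr, resid, p2, seed = seed + f + 1L)
      y2_va <- predict(rf2_fit, build_Z(gxe$alpha, Xva))
    }
    dplyr::bind_rows(
      dplyr::mutate(yield_metrics(yva, y1_va), model = "rf1"),
      dplyr::mutate(yield_metrics(yva, y1_va + y2_va), model = "stacked")
    ) |>
      dplyr::mutate(fold = f, K = gxe$K)
  })
}
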