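# Bagged regression forests. The ensemble learner is delegated to ranger,
# which provides the required contract — bootstrap bagging, per-split feature
# sampling, terminal node-size control, and out-of-bag predictions — behind a
# thin wrapper that pins determinism (single thread, explicit seed) and
# clamps mtry to the available feature count.

#' Default forest hyperparameters
#'
#' The first-stage forest uses 1000 trees, 100 candidate features per split,
#' and minimum terminal node size 10; the residual-stage forest uses the same
#' trees and node size but 20 features per split (clamped to the number of
#' interaction columns available).
#'
#' @param n_trees Number of trees.
#' @param n_features Features sampled at each split (mtry).
#' @param node_size Minimum terminal node size.
#' @return A `forest_params` list.
#' @export
forest_params <- function(n_trees = 1000, n_features = 100, node_size = 10) {
  stopifnot(n_trees >= 1, n_features >= 1, node_size >= 1)
  structure(list(n_trees = n_trees, n_features = n_features,
                 node_size = node_size), class = "forest_params")
}

#' @rdname forest_params
#' @export
rf2_params <- function(n_trees = 1000, n_features = 20, node_size = 10) {
  forest_params(n_trees, n_features, node_size)
}

#' Fit a bagged regression forest
#'
#' @param X Numeric feature matrix (n-by-q).
#' @param y Response vector.
#' @param params A [forest_params()] object.
#' @param seed Integer seed; fits are bit-reproducible given the seed.
#' @return An `rf_fit` object wrapping the fitted ensemble, with `$oob`
#'   holding out-of-bag predictions for the training rows.
#' @export
fit_rf <- function(X, y, params = forest_params(), seed = 2020) {
  X <- as.matrix(X)
  if (nrow(X) < 2) abort("need at least 2 observations to fit a forest")
  if (length(y) != nrow(X)) abort("length(y) must equal nrow(X)")
  q <- ncol(X)
  mtry <- params$n_features
  if (mtry > q) {
    warn(sprintf("n_features = %d exceeds %d available feature(s); clamping",
                 mtry, q))
    mtry <- q
  }
  dat <- as.data.frame(X)
  names(dat) <- paste0("f", seq_len(q))
  dat$..y <- y
  fit <- ranger::ranger(
    dependent.variable.name = "..y", data = dat,
    num.trees = params$n_trees, mtry = mtry,
    min.node.size = params$node_size,
    num.threads = 1, seed = seed, oob.error = TRUE
  )
  oob <- fit$predictions
  # rows never out of bag (tiny n or few trees) fall back to the mean
  oob[!is.finite(oob)] <- mean(y)
  structure(list(fit = fit, oob = oob, q = q, params = params, seed = seed,
                 y_mean = mean(y)),
            class = "rf_fit")
}

#' @export
predict.rf_fit <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != object$q) {
    abort(sprintf("newdata has %d columns; forest expects %d",
                  ncol(X), object$q))
  }
  dat <- as.data.frame(X)
  names(dat) <- paste0("f", seq_len(object$q))
  predict(object$fit, data = dat, num.threads = 1)$predictions
}

#' @export
print.rf_fit <- function(x, ...) {
  cat("<rf_fit>", x$params$n_trees, "trees,", x$q, "features, node size",
      x$params$node_size, "\n")
  invisible(x)
}

#' Fit the stacked yield-prediction model
#'
#' The full pipeline on a trial-record table: replicate plots are averaged,
#' records are one-hot encoded, a first random forest is fitted on the
#' encoded design, the combinatorial G-by-E interaction model is searched on
#' the same design and response, and a second random forest is fitted on the
#' interaction membership matrix Z against the first forest's out-of-bag
#' residuals. Predictions are the sum of the two forest outputs.
#'
#' Out-of-bag (rather than in-sample) first-stage residuals are used as the
#' second-stage response: in-sample forest residuals are shrunk nearly to
#' zero and carry no usable signal, while out-of-bag residuals are unbiased
#' estimates of what the first stage misses.
#'
#' @param records A trial-record tibble (replicates allowed).
#' @param rf1 [forest_params()] for the first-stage forest.
#' @param rf2 [forest_params()] for the residual-stage forest; its
#'   `n_features` is clamped to the number of detected interactions.
#' @param max_K,max_order,n_restarts,inner_k,tol Passed to
#'   [search_interactions()].
#' @param rf2_include_X If `TRUE`, the residual forest sees `[Z | X]` rather
#'   than Z alone. Off by default: the second stage is meant to model the
#'   interaction structure the first stage cannot represent.
#' @param seed Integer seed driving every stochastic stage.
#' @return A `stacked_model` with components `rf1`, `gxe`, `rf2`, `fs`, and
#'   the aggregated training table.
#' @export
#' @examples
#' sim <- simulate_trials(sim_config(seed = 3))
#' mod <- fit_stacked(sim$records, rf1 = forest_params(n_trees = 50),
#'                    rf2 = rf2_params(n_trees = 50), max_K = 2, seed = 3)
#' head(predict(mod, sim$records))
fit_stacked <- function(records,
                        rf1 = forest_params(),
                        rf2 = rf2_params(),
                        max_K = 5, max_order = 4, n_restarts = 5,
                        inner_k = 5, tol = 1e-6,
                        rf2_include_X = FALSE, seed = 2020) {
  agg <- tryCatch(aggregate_replicates(records),
                  error = function(e) abort(paste0("aggregation stage: ",
                                                   conditionMessage(e))))
  if (nrow(agg) < 2) abort("need at least 2 unique combinations to fit")
  fs <- build_feature_space(agg)
  enc <- encode_records(agg, fs)

  rf1_fit <- tryCatch(
    fit_rf(enc$X, enc$y, rf1, seed = seed),
    error = function(e) abort(paste0("random-forest-1 stage: ",
                                     conditionMessage(e))))
  gxe <- tryCatch(
    search_interactions(enc$X, enc$y, max_K = max_K, max_order = max_order,
                        n_restarts = n_restarts, inner_k = min(inner_k, nrow(agg)),
                        tol = tol, seed = seed),
    error = function(e) abort(paste0("interaction-search stage: ",
                                     conditionMessage(e))))

  resid <- enc$y - rf1_fit$oob
  Z <- build_Z(gxe$alpha, enc$X)
  Z2 <- if (rf2_include_X) cbind(Z, enc$X) else Z
  if (ncol(Z2) == 0) {
    # no interactions found: the residual stage degenerates to the mean
    rf2_fit <- NULL
    rf2_const <- mean(resid)
  } else {
    p2 <- rf2
    p2$n_features <- min(p2$n_features, ncol(Z2))
    rf2_fit <- tryCatch(
      fit_rf(Z2, resid, p2, seed = seed + 1L),
      error = function(e) abort(paste0("random-forest-2 stage: ",
                                       conditionMessage(e))))
    rf2_const <- NULL
  }
  structure(
    list(rf1 = rf1_fit, gxe = gxe, rf2 = rf2_fit, rf2_const = rf2_const,
         rf2_include_X = rf2_include_X, fs = fs, training = agg, seed = seed),
    class = "stacked_model"
  )
}

#' Predict yields from a stacked model
#'
#' @param object A `stacked_model`.
#' @param newdata Either a trial-record tibble (roster mode; labels must all
#'   be known to the model's feature space) or an encoded design matrix.
#' @param ... Unused.
#' @return The predicted yield vector, first-stage plus residual-stage.
#' @export
predict.stacked_model <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else {
    nd <- as_tibble(newdata)
    if (!"yield" %in% names(nd)) nd$yield <- 1
    encode_records(nd, object$fs)$X
  }
  y1 <- predict(object$rf1, X)
  if (is.null(object$rf2)) {
    return(y1 + object$rf2_const)
  }
  Z <- build_Z(object$gxe$alpha, X)
  Z2 <- if (object$rf2_include_X) cbind(Z, X) else Z
  y1 + predict(object$rf2, Z2)
}

#' @export
print.stacked_model <- function(x, ...) {
  cat("<stacked_model>\n")
  cat("  RF1:", x$rf1$params$n_trees, "trees on", x$rf1$q, "one-hot columns\n")
  cat("  GxE:", x$gxe$K, "interaction(s), training SSE",
      format(x$gxe$training_sse, digits = 4), "\n")
  if (is.null(x$rf2)) {
    cat("  RF2: degenerate (no interactions; mean residual",
        format(x$rf2_const, digits = 3), ")\n")
  } else {
    cat("  RF2:", x$rf2$params$n_trees, "trees on", x$rf2$q, "column(s)\n")
  }
  invisible(x)
}

#' @export
glance.stacked_model <- function(x, ...) {
  tibble(
    n = nrow(x$training), p = x$fs$p, K = x$gxe$K,
    rf1_trees = x$rf1$params$n_trees,
    rf2_trees = if (is.null(x$rf2)) NA_integer_ else x$rf2$params$n_trees,
    gxe_training_sse = x$gxe$training_sse
  )
}

#' @export
tidy.stacked_model <- function(x, ...) {
  summarize_interactions(x$gxe, x$fs)
}

#' Save a stacked model bundle to a directory
#'
#' Writes `feature_space.json`, `gxe_model.json`, a manifest with seeds and
#' forest parameters, and the two forests as RDS files. The JSON parts are
#' portable; the forest files are opaque serialized objects.
#'
#' @param model A `stacked_model`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_stacked_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_space(model$fs, file.path(dir, "feature_space.json"))
  write_gxe_model(model$gxe, file.path(dir, "gxe_model.json"))
  jsonlite::write_json(
    list(seed = model$seed,
         rf1 = model$rf1$params[c("n_trees", "n_features", "node_size")],
         rf2 = if (!is.null(model$rf2))
           model$rf2$params[c("n_trees", "n_features", "node_size")],
         rf2_const = model$rf2_const,
         rf2_include_X = model$rf2_include_X),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, null = "null")
  saveRDS(model$rf1, file.path(dir, "rf1.rds"))
  if (!is.null(model$rf2)) saveRDS(model$rf2, file.path(dir, "rf2.rds"))
  saveRDS(model, file.path(dir, "stacked_model.rds"))
  invisible(dir)
}

#' @rdname write_stacked_model
#' @export
read_stacked_model <- function(dir) {
  readRDS(file.path(dir, "stacked_model.rds"))
}
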