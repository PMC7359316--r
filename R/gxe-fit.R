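#' Membership of observations in an interaction pattern
#'
#' An interaction pattern is a length-p vector over \{0, 0.5, 1\}. Entry 0.5
#' means the variable is not involved; 0 or 1 requires the one-hot variable to
#' take that value. Observation i is a member of the pattern (receives the
#' interaction) iff `X[i, j] + alpha[j] != 1` for every j — equivalently, for
#' every non-neutral position the observation matches the required value.
#'
#' @param alpha Numeric vector of length `ncol(X)` over \{0, 0.5, 1\}.
#' @param X Binary design matrix.
#' @return A 0/1 vector of length `nrow(X)`.
#' @export
#' @examples
#' fx <- figure2_fixture()
#' membership(c(0.5, 0, 0), fx$X)  # the infertile-soil, dry-weather pattern
membership <- function(alpha, X) {
  check_pattern(alpha, ncol(X))
  act <- which(alpha != 0.5)
  if (length(act) == 0) return(rep(1, nrow(X)))
  tgt <- matrix(alpha[act], nrow(X), length(act), byrow = TRUE)
  as.numeric(rowSums(X[, act, drop = FALSE] != tgt) == 0)
}

check_pattern <- function(alpha, p) {
  if (length(alpha) != p) {
    abort(sprintf("pattern length %d does not match p = %d", length(alpha), p))
  }
  if (!all(alpha %in% c(0, 0.5, 1))) {
    abort("pattern entries must be 0, 0.5, or 1")
  }
  invisible(alpha)
}

# Number of non-neutral entries.
pattern_order <- function(alpha) sum(alpha != 0.5)

#' Build the membership matrix Z for a set of interaction patterns
#'
#' @param alpha_mat K-by-p matrix of interaction patterns (rows over
#'   \{0, 0.5, 1\}); a K = 0 matrix gives an n-by-0 result.
#' @param X Binary design matrix.
#' @return The n-by-K binary membership matrix Z, one column per pattern.
#' @export
build_Z <- function(alpha_mat, X) {
  alpha_mat <- as_alpha_matrix(alpha_mat, ncol(X))
  K <- nrow(alpha_mat)
  Z <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) Z[, k] <- membership(alpha_mat[k, ], X)
  Z
}

as_alpha_matrix <- function(alpha_mat, p) {
  if (is.null(alpha_mat) || length(alpha_mat) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = p))
  }
  if (is.vector(alpha_mat)) alpha_mat <- matrix(alpha_mat, nrow = 1)
  if (ncol(alpha_mat) != p) {
    abort(sprintf("pattern width %d does not match p = %d", ncol(alpha_mat), p))
  }
  alpha_mat
}

# Minimum-norm least-squares solution of A x = y via the SVD pseudoinverse.
# One-hot blocks are exactly collinear with the intercept, so [1 | X | Z] is
# rank deficient on roster designs; the minimum-norm solution keeps toy
# full-rank examples exact while staying defined everywhere.
lstsq_minnorm <- function(A, y) {
  sv <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  if (!any(pos)) return(rep(0, ncol(A)))
  drop(sv$v[, pos, drop = FALSE] %*%
         ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos]))
}

#' Fit additive and interaction effects by least squares
#'
#' Fits the linear G-by-E model
#' `y_i = beta0 + sum_j X_ij beta_j + sum_k b_k Z_ik + eps_i`
#' with the membership matrix Z fixed, by minimum-norm least squares on
#' `[1 | X | Z]`. With the pattern matrix known this is an ordinary multiple
#' linear regression; the search over patterns lives in
#' [search_interactions()].
#'
#' @param X Binary design matrix (n-by-p).
#' @param y Yield response vector of length n.
#' @param alpha_mat K-by-p pattern matrix (or `NULL` for a purely additive
#'   model).
#' @param b Optional fixed effect vector; by default effects are estimated.
#' @return A `gxe_model` object with elements `beta0`, `beta`, `alpha`
#'   (K-by-p), `b` (length K), `training_sse`, `fitted`, and `p`.
#' @export
#' @examples
#' fx <- figure2_fixture()
#' fit <- fit_gxe(fx$X, fx$y, fx$truth$alpha)
#' fit$beta0          # baseline yield, 2
#' fit$b              # interaction effects (-1, 1, 2)
fit_gxe <- function(X, y, alpha_mat = NULL, b = NULL) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) abort("length(y) must equal nrow(X)")
  if (any(!is.finite(y))) abort("y must be finite")
  alpha_mat <- as_alpha_matrix(alpha_mat, ncol(X))
  Z <- build_Z(alpha_mat, X)
  K <- ncol(Z)
  p <- ncol(X)
  A <- cbind(1, X, Z)
  coefs <- lstsq_minnorm(A, y)
  fitted <- drop(A %*% coefs)
  new_gxe_model(
    beta0 = coefs[1],
    beta = setNames(coefs[2:(p + 1)], colnames(X)),
    alpha = alpha_mat,
    b = if (K > 0) coefs[(p + 2):(p + 1 + K)] else numeric(0),
    training_sse = sum((y - fitted)^2),
    fitted = fitted,
    p = p,
    z_counts = as.integer(colSums(Z))
  )
}

new_gxe_model <- function(beta0, beta, alpha, b, training_sse, fitted, p,
                          z_counts = NULL, search = NULL) {
  structure(
    list(beta0 = beta0, beta = beta, alpha = alpha, b = b,
         training_sse = training_sse, fitted = fitted, p = p,
         K = length(b), z_counts = z_counts, search = search),
    class = "gxe_model"
  )
}

#' @export
print.gxe_model <- function(x, ...) {
  cat("<gxe_model> p =", x$p, "variables, K =", x$K, "interaction(s)\n")
  cat("  intercept:", format(x$beta0, digits = 4),
      " training SSE:", format(x$training_sse, digits = 4), "\n")
  if (x$K > 0) {
    ord <- apply(x$alpha, 1, pattern_order)
    cat("  interaction orders:", paste(ord, collapse = ", "),
        " effects:", paste(format(x$b, digits = 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict yields from a fitted G-by-E linear model
#'
#' @param object A `gxe_model`.
#' @param X Binary design matrix with the same p as the training design.
#' @param ... Unused.
#' @return Predicted yield vector `beta0 + X beta + Z b`.
#' @export
predict.gxe_model <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != object$p) {
    abort(sprintf("newdata has %d columns; model expects %d", ncol(X), object$p))
  }
  Z <- build_Z(object$alpha, X)
  drop(object$beta0 + X %*% object$beta +
         (if (object$K > 0) Z %*% object$b else 0))
}

#' @export
tidy.gxe_model <- function(x, ...) {
  add <- tibble(
    term = c("(Intercept)", names(x$beta) %||% paste0("x", seq_along(x$beta))),
    type = c("intercept", rep("additive", length(x$beta))),
    order = c(0L, rep(1L, length(x$beta))),
    estimate = c(x$beta0, unname(x$beta))
  )
  if (x$K > 0) {
    int <- tibble(
      term = apply(x$alpha, 1, format_pattern, feature_names = names(x$beta)),
      type = "interaction",
      order = as.integer(apply(x$alpha, 1, pattern_order)),
      estimate = x$b
    )
    add <- dplyr::bind_rows(add, int)
  }
  add
}

format_pattern <- function(alpha, feature_names = NULL) {
  act <- which(alpha != 0.5)
  nm <- if (is.null(feature_names)) paste0("x", act) else feature_names[act]
  paste(paste0(nm, "==", alpha[act]), collapse = " & ")
}

#' @export
glance.gxe_model <- function(x, ...) {
  tibble(K = x$K, p = x$p, training_sse = x$training_sse,
         max_order = if (x$K > 0) max(apply(x$alpha, 1, pattern_order)) else NA_integer_)
}

#' Serialize a fitted G-by-E model to JSON
#'
#' Writes `{beta0, beta, interactions: [{alpha, b}]}` so a fitted model can be
#' reloaded without the training data.
#'
#' @param model A `gxe_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_gxe_model <- function(model, path) {
  stopifnot(inherits(model, "gxe_model"))
  obj <- list(
    beta0 = model$beta0,
    beta = unname(model$beta),
    feature_names = names(model$beta),
    interactions = lapply(seq_len(model$K), function(k) {
      list(alpha = model$alpha[k, ], b = model$b[k])
    }),
    training_sse = model$training_sse
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gxe_model
#' @export
read_gxe_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(obj$beta)
  K <- if (is.data.frame(obj$interactions)) nrow(obj$interactions)
       else length(obj$interactions)
  if (K > 0 && is.data.frame(obj$interactions)) {
    alpha <- do.call(rbind, obj$interactions$alpha)
    b <- obj$interactions$b
  } else if (K > 0) {
    alpha <- do.call(rbind, lapply(obj$interactions, `[[`, "alpha"))
    b <- vapply(obj$interactions, `[[`, numeric(1), "b")
  } else {
    alpha <- matrix(numeric(0), 0, p)
    b <- numeric(0)
  }
  new_gxe_model(
    beta0 = obj$beta0,
    beta = setNames(obj$beta, obj$feature_names),
    alpha = alpha, b = b,
    training_sse = obj$training_sse %||% NA_real_,
    fitted = NULL, p = p
  )
}
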