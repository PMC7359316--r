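# Heuristic detection of combinatorial G-by-E interaction patterns.
#
# The search is greedy forward construction: starting from the additive
# model, candidate patterns are proposed from the residual signal, refined by
# coordinate local search over {0, 0.5, 1}, and accepted only if they improve
# the acceptance score. The score has two keys: the mean validation SSE over
# `inner_k` internal folds (the guard against overfitting — any high-order
# pattern can zero out single residuals), and, to break validation ties, the
# training SSE. A pattern is never accepted if it worsens the validation SSE.
# With `inner_k = 1` no internal split is made and the score reduces to the
# training SSE — the right setting for tiny noiseless problems, where
# leave-few-out validation of an interpolating model is meaningless.
#
# All candidate evaluations share per-fold SVD factorizations of the additive
# design [1 | X[fold, ]], so scoring a candidate costs one projection of its
# membership column rather than a full refit.

#' Search for interaction patterns by greedy forward local search
#'
#' Learns the interaction pattern matrix of the linear G-by-E model: each
#' pattern is a length-p vector over \{0, 0.5, 1\} whose induced membership
#' column (see [membership()]) enters the regression alongside the additive
#' one-hot terms. Patterns are proposed from the variable pairs whose product
#' best covaries with the current residual, improved one coordinate at a
#' time, and accepted only when the acceptance score improves by at least a
#' relative `tol`: the mean validation SSE over `inner_k` internal folds must
#' drop, or hold exactly while the training SSE drops.
#'
#' @param X Binary design matrix (n-by-p).
#' @param y Yield response vector.
#' @param max_K Maximum number of interaction patterns to accept.
#' @param max_order Maximum number of non-neutral entries per pattern;
#'   two-way and three-way interactions are the scientifically reportable
#'   range, and very high orders produce membership columns supported on a
#'   handful of observations.
#' @param n_restarts Number of residual-seeded candidate starts per accepted
#'   slot.
#' @param inner_k Number of internal validation folds scoring candidate
#'   patterns; `1` disables the split so candidates are scored on training
#'   SSE alone (appropriate for small noiseless designs).
#' @param tol Minimum relative score decrease for a pattern to be accepted.
#' @param seed Integer seed for the internal fold assignment.
#' @return A `gxe_model` fitted on all of `(X, y)` with the accepted
#'   patterns; `$search` holds the acceptance history (one row per accepted
#'   pattern with its score).
#' @export
#' @examples
#' fx <- figure2_fixture()
#' fit <- search_interactions(fx$X, fx$y, max_K = 3, max_order = 2,
#'                            n_restarts = 3, inner_k = 1, seed = 1)
#' fit$training_sse   # ~0: the toy example is exactly explained
search_interactions <- function(X, y, max_K = 5, max_order = 4,
                                n_restarts = 5, inner_k = 5, tol = 1e-6,
                                seed = 2020) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) abort("length(y) must equal nrow(X)")
  if (inner_k > 1 && n < inner_k) {
    abort(sprintf("n = %d is smaller than inner_k = %d", n, inner_k))
  }
  if (max_order < 2) abort("max_order must be at least 2")
  if (var(y) == 0) {
    warn("response has zero variance; returning additive-only model")
    return(fit_gxe(X, y))
  }

  cache <- make_search_cache(X, y, inner_k, seed)
  acc <- init_accepted(cache)
  cur <- score_accepted(cache, acc)
  history <- list()

  while (acc$K < max_K) {
    resid <- full_data_residual(X, y, acc$alpha)
    seeds <- seed_pairs(X, resid, n_restarts)
    best <- NULL
    for (s in seq_len(nrow(seeds))) {
      cand <- init_candidate(X, resid, seeds[s, 1], seeds[s, 2])
      cand <- refine_candidate(cand, X, cache, acc, max_order)
      if (is.null(cand) || pattern_order(cand$alpha) < 2) next
      if (is_duplicate_pattern(cand$alpha, acc$alpha)) next
      if (is.null(best) || score_better(cand$score, best$score, 0)) best <- cand
    }
    if (is.null(best) || !score_better(best$score, cur, tol)) break
    acc <- accept_pattern(cache, acc, best$alpha, X)
    cur <- best$score
    history[[length(history) + 1]] <-
      tibble(K = acc$K, order = pattern_order(best$alpha),
             score = cur$primary, training_sse = cur$train)
  }

  model <- fit_gxe(X, y, acc$alpha)
  model$search <- if (length(history)) dplyr::bind_rows(history) else
    tibble(K = integer(), order = integer(), score = double(),
           training_sse = double())
  model
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---- scores ----------------------------------------------------------------

# A score is a pair: `primary` (mean inner-validation SSE, or training SSE
# when no split is used) and `train` (training SSE, the tie-breaker).
# `new` beats `cur` if primary drops by relative `tol`, or primary holds
# within rounding while train drops by relative `tol`. Primary may never get
# worse.
score_better <- function(new, cur, tol) {
  drop_p <- cur$primary - new$primary
  if (drop_p >= tol * max(cur$primary, 1e-12)) return(TRUE)
  tie <- new$primary <= cur$primary + 1e-9 * max(cur$primary, 1e-12)
  tie && (cur$train - new$train >= tol * max(cur$train, 1e-12))
}

# ---- fold-cached least-squares machinery -----------------------------------

# One entry per fold: truncated SVD of the additive training design, the
# additive fit and residual, and the validation rows. The `full` entry is a
# pseudo-fold with tr = val = all rows, whose "validation" SSE is exactly the
# joint training SSE of the refitted model.
make_search_cache <- function(X, y, inner_k, seed) {
  n <- nrow(X)
  folds <- if (inner_k > 1) {
    assign_f <- with_local_seed(seed, sample(rep(seq_len(inner_k),
                                                 length.out = n)))
    lapply(seq_len(inner_k), function(f) {
      make_fold_entry(X, y, which(assign_f != f), which(assign_f == f))
    })
  } else list()
  list(folds = folds,
       full = make_fold_entry(X, y, seq_len(n), seq_len(n)),
       use_cv = inner_k > 1)
}

make_fold_entry <- function(X, y, tr, val) {
  A_tr <- cbind(1, X[tr, , drop = FALSE])
  sv <- svd(A_tr)
  keep <- sv$d > max(dim(A_tr)) * .Machine$double.eps * max(sv$d)
  U <- sv$u[, keep, drop = FALSE]
  d <- sv$d[keep]
  V <- sv$v[, keep, drop = FALSE]
  beta_add <- drop(V %*% (crossprod(U, y[tr]) / d))
  list(tr = tr, val = val, A_tr = A_tr, U = U, d = d, V = V,
       beta_add = beta_add,
       r_tr = y[tr] - drop(A_tr %*% beta_add),
       A_val = cbind(1, X[val, , drop = FALSE]),
       y_val = y[val])
}

empty_fold_state <- function(f) {
  list(W = matrix(0, length(f$tr), 0), G = matrix(0, nrow(f$V), 0),
       Z_val = matrix(0, length(f$val), 0))
}

init_accepted <- function(cache) {
  list(K = 0, alpha = NULL,
       fold = lapply(cache$folds, empty_fold_state),
       full = empty_fold_state(cache$full))
}

# Project a block of membership columns out of a fold's additive column
# space: residual block W, additive-coefficient adjustment G, and the
# validation-row values.
project_columns <- function(f, Zc) {
  Zc_tr <- Zc[f$tr, , drop = FALSE]
  G <- f$V %*% (crossprod(f$U, Zc_tr) / f$d)
  list(W = Zc_tr - f$A_tr %*% G, G = G,
       Z_val = Zc[f$val, , drop = FALSE])
}

# Solve the small normal system M b = q for interaction effects;
# pseudoinverse handles collinear or all-zero membership columns.
solve_normal <- function(M, q) {
  K <- ncol(M)
  if (K == 0) return(numeric(0))
  sv <- svd(M)
  keep <- sv$d > K * .Machine$double.eps * max(sv$d, 0)
  if (!any(keep)) return(rep(0, K))
  drop(sv$v[, keep, drop = FALSE] %*%
         (crossprod(sv$u[, keep, drop = FALSE], q) / sv$d[keep]))
}

solve_effects <- function(W, r) solve_normal(crossprod(W), crossprod(W, r))

fold_val_sse <- function(f, W, G, Z_val) {
  b <- solve_effects(W, f$r_tr)
  beta <- f$beta_add - drop(G %*% b)
  pred <- drop(f$A_val %*% beta) + drop(Z_val %*% b)
  sum((f$y_val - pred)^2)
}

state_sse <- function(f, st) fold_val_sse(f, st$W, st$G, st$Z_val)

score_accepted <- function(cache, acc) {
  train <- state_sse(cache$full, acc$full)
  primary <- if (cache$use_cv) {
    mean(vapply(seq_along(cache$folds), function(i) {
      state_sse(cache$folds[[i]], acc$fold[[i]])
    }, numeric(1)))
  } else train
  list(primary = primary, train = train)
}

# Score the accepted set plus each of m candidate membership columns
# (n-by-m matrix Zc). All heavy linear algebra — projections, effect
# adjustments, validation predictions — is batched over candidates into
# single BLAS calls per fold; only the (K+1)-dimensional normal solves loop.
score_candidates <- function(cache, acc, Zc) {
  m <- ncol(Zc)
  if (m == 0) return(list(primary = numeric(0), train = numeric(0)))
  one_fold <- function(f, st) {
    pr <- project_columns(f, Zc)
    K <- ncol(st$W)
    M_acc <- crossprod(st$W)                    # K x K
    q_acc <- drop(crossprod(st$W, f$r_tr))      # K
    C_acc <- crossprod(pr$W, st$W)              # m x K
    w2 <- colSums(pr$W^2)                       # m
    q_c <- drop(crossprod(pr$W, f$r_tr))        # m
    B <- matrix(0, K + 1, m)                    # joint effects per candidate
    for (c in seq_len(m)) {
      Mc <- rbind(cbind(M_acc, C_acc[c, ]), c(C_acc[c, ], w2[c]))
      B[, c] <- solve_normal(Mc, c(q_acc, q_c[c]))
    }
    b_acc <- B[seq_len(K), , drop = FALSE]
    b_new <- B[K + 1, ]
    Beta <- matrix(f$beta_add, nrow(f$V), m) -
      (if (K > 0) st$G %*% b_acc else 0) -
      sweep(pr$G, 2, b_new, "*")
    pred <- f$A_val %*% Beta +
      (if (K > 0) st$Z_val %*% b_acc else 0) +
      sweep(pr$Z_val, 2, b_new, "*")
    colSums((f$y_val - pred)^2)
  }
  train <- one_fold(cache$full, acc$full)
  primary <- if (cache$use_cv) {
    sse <- vapply(seq_along(cache$folds), function(i) {
      one_fold(cache$folds[[i]], acc$fold[[i]])
    }, numeric(m))
    if (m == 1) mean(sse) else rowMeans(matrix(sse, nrow = m))
  } else train
  list(primary = primary, train = train)
}

accept_pattern <- function(cache, acc, alpha, X) {
  z <- matrix(membership(alpha, X), ncol = 1)
  grow <- function(f, st) {
    pr <- project_columns(f, z)
    list(W = cbind(st$W, pr$W), G = cbind(st$G, pr$G),
         Z_val = cbind(st$Z_val, pr$Z_val))
  }
  acc$alpha <- rbind(acc$alpha, alpha)
  acc$K <- acc$K + 1
  acc$fold <- lapply(seq_along(cache$folds), function(i) {
    grow(cache$folds[[i]], acc$fold[[i]])
  })
  acc$full <- grow(cache$full, acc$full)
  acc
}

# ---- candidate construction and refinement ---------------------------------

# Score all variable pairs by |cov(x_j1 * x_j2, resid)| and return the top
# `n_restarts` as a two-column index matrix. For binary columns the product
# sums are a single crossproduct.
seed_pairs <- function(X, resid, n_restarts) {
  score <- abs(crossprod(X, X * resid) - crossprod(X) * mean(resid))
  score[lower.tri(score, diag = TRUE)] <- -Inf
  ord <- order(score, decreasing = TRUE)
  k <- min(n_restarts, sum(score > -Inf))
  if (k == 0) return(matrix(integer(0), 0, 2))
  arrayInd(ord[seq_len(k)], dim(score))
}

# Initialize a candidate pattern on a seed pair: pick the required-value
# combo whose membership indicator best covaries with the residual.
init_candidate <- function(X, resid, j1, j2) {
  best <- NULL
  for (v1 in c(0, 1)) for (v2 in c(0, 1)) {
    z <- as.numeric(X[, j1] == v1 & X[, j2] == v2)
    s <- abs(sum(z * resid) - sum(z) * mean(resid))
    if (is.null(best) || s > best$s) best <- list(v1 = v1, v2 = v2, s = s)
  }
  alpha <- rep(0.5, ncol(X))
  alpha[j1] <- best$v1
  alpha[j2] <- best$v2
  list(alpha = alpha, score = NULL)
}

# Coordinate local search by steepest descent: at every step, score all
# single-coordinate moves (any position to any other allowed value in
# {0, 0.5, 1}) in one batch and apply the best one; stop when no move
# improves the score. Taking the best move rather than the first improving
# one matters on sparse rosters, where many small chance improvements compete
# with the one large move that completes a real pattern. Ties prefer the
# neutral 0.5 (a simpler pattern), then the lower value, then the lower
# position, via the candidate scan order.
refine_candidate <- function(cand, X, cache, acc, max_order,
                             max_moves = 25) {
  p <- ncol(X)
  alpha <- cand$alpha
  sc <- score_candidates(cache, acc, matrix(membership(alpha, X), ncol = 1))
  cur <- list(primary = sc$primary, train = sc$train)
  for (move in seq_len(max_moves)) {
    at_cap <- pattern_order(alpha) >= max_order
    trials <- list()
    for (v in c(0.5, 0, 1)) {             # preference order for ties
      for (j in seq_len(p)) {
        if (alpha[j] == v) next
        if (v != 0.5 && alpha[j] == 0.5 && at_cap) next
        trials[[length(trials) + 1]] <- c(j, v)
      }
    }
    if (length(trials) == 0) break
    tr_mat <- do.call(rbind, trials)
    Zc <- vapply(seq_len(nrow(tr_mat)), function(t) {
      a2 <- alpha; a2[tr_mat[t, 1]] <- tr_mat[t, 2]
      membership(a2, X)
    }, numeric(nrow(X)))
    sc <- score_candidates(cache, acc, Zc)
    best <- cur
    best_t <- 0
    for (t in seq_len(nrow(tr_mat))) {
      trial <- list(primary = sc$primary[t], train = sc$train[t])
      if (score_better(trial, best, 1e-9)) {
        best <- trial
        best_t <- t
      }
    }
    if (best_t == 0) break
    alpha[tr_mat[best_t, 1]] <- tr_mat[best_t, 2]
    cur <- best
  }
  list(alpha = alpha, score = cur)
}

is_duplicate_pattern <- function(alpha, alpha_mat) {
  if (is.null(alpha_mat) || nrow(alpha_mat) == 0) return(FALSE)
  any(apply(alpha_mat, 1, function(a) all(a == alpha)))
}

full_data_residual <- function(X, y, alpha_mat) {
  fit <- fit_gxe(X, y, alpha_mat)
  y - fit$fitted
}

# ---- brute-force oracle -----------------------------------------------------

#' Exhaustive search over small interaction-pattern spaces
#'
#' Enumerates every pattern with 2 to `max_order` non-neutral entries over
#' all value assignments, and every set of `K` of them, returning the set
#' with globally minimal training SSE (ties broken by the lexicographically
#' smallest pattern matrix). Feasible only for toy problems; it exists as an
#' independent optimality oracle for [search_interactions()].
#'
#' @param X Binary design matrix with at most 12 columns.
#' @param y Yield response vector.
#' @param K Number of patterns to select (0, 1, or 2).
#' @param max_order Maximum pattern order to enumerate.
#' @param budget Maximum number of patterns to enumerate before refusing.
#' @return A `gxe_model` fitted with the optimal pattern set.
#' @export
brute_force_search <- function(X, y, K = 1, max_order = 2, budget = 20000) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p > 12) abort("brute force limited to p <= 12")
  if (!K %in% 0:2) abort("brute force limited to K in {0, 1, 2}")
  if (K == 0) return(fit_gxe(X, y))
  count <- sum(vapply(2:max_order, function(o) choose(p, o) * 2^o, numeric(1)))
  if (count > budget) {
    abort(sprintf("enumeration of %d patterns exceeds budget %d", count, budget))
  }
  pats <- enumerate_patterns(p, max_order)
  if (K == 1) {
    sets <- lapply(seq_len(nrow(pats)), function(i) pats[i, , drop = FALSE])
  } else {
    idx <- combn(nrow(pats), 2)
    sets <- lapply(seq_len(ncol(idx)), function(i) pats[idx[, i], , drop = FALSE])
  }
  best <- NULL
  best_key <- NULL
  for (am in sets) {
    fit <- fit_gxe(X, y, am)
    key <- paste(t(am), collapse = ",")
    if (is.null(best) || fit$training_sse < best$training_sse - 1e-12 ||
        (abs(fit$training_sse - best$training_sse) <= 1e-12 && key < best_key)) {
      best <- fit
      best_key <- key
    }
  }
  best
}

# All patterns of order 2..max_order over p positions, one row each, in
# lexicographic order.
enumerate_patterns <- function(p, max_order) {
  out <- list()
  for (o in 2:max_order) {
    pos_sets <- combn(p, o)
    vals <- as.matrix(expand.grid(rep(list(c(0, 1)), o)))
    for (s in seq_len(ncol(pos_sets))) {
      for (v in seq_len(nrow(vals))) {
        a <- rep(0.5, p)
        a[pos_sets[, s]] <- vals[v, ]
        out[[length(out) + 1]] <- a
      }
    }
  }
  mat <- do.call(rbind, out)
  mat[do.call(order, as.data.frame(mat)), , drop = FALSE]
}

#' Tabulate the interactions of a fitted G-by-E model
#'
#' One row per accepted interaction pattern: the involved variables (and
#' their one-hot blocks when a feature space is supplied), the required
#' values, the interaction order, the estimated effect, and the number of
#' training observations that received the interaction.
#'
#' @param model A fitted `gxe_model`.
#' @param fs Optional `feature_space` used to name variables and blocks.
#' @return A tibble sorted by interaction order then by effect magnitude.
#' @export
summarize_interactions <- function(model, fs = NULL) {
  stopifnot(inherits(model, "gxe_model"))
  if (model$K == 0) {
    return(tibble(interaction = character(), order = integer(),
                  variables = character(), blocks = character(),
                  required = character(), effect = double(),
                  n_members = integer()))
  }
  nm <- if (!is.null(fs)) feature_names(fs) else
    names(model$beta) %||% paste0("x", seq_len(model$p))
  blk <- if (!is.null(fs)) BLOCK_NAMES[feature_block_index(fs)] else
    rep(NA_character_, model$p)
  rows <- lapply(seq_len(model$K), function(k) {
    a <- model$alpha[k, ]
    act <- which(a != 0.5)
    tibble(
      interaction = format_pattern(a, nm),
      order = length(act),
      variables = paste(nm[act], collapse = " & "),
      blocks = paste(blk[act], collapse = " & "),
      required = paste(a[act], collapse = ","),
      effect = model$b[k],
      n_members = model$z_counts[k] %||% NA_integer_
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$order, dplyr::desc(abs(.data$effect)))
}
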