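# Parent ranking and cross-grid nomination: once a yield model is fitted,
# every inbred x tester cross can be scored by its predicted yield averaged
# over all location x year environments, and parents ranked by their average
# performance — the quantities a breeder uses to nominate promising crosses.

# Size of a "top q" parent list: floor of the fraction, at least one parent
# (29 inbreds of 593 and 24 testers of 496 at q = 0.05).
top_list_size <- function(q, count) max(1L, floor(q * count))

#' Enumerate all inbred-by-tester pairs of a roster
#'
#' @param fs A `feature_space`.
#' @return A tibble with one row per inbred x tester combination.
#' @export
cross_pairs <- function(fs) {
  stopifnot(inherits(fs, "feature_space"))
  tidyr::expand_grid(inbred = fs$blocks$inbred, tester = fs$blocks$tester)
}

# All roster combinations for the chosen blocks, joined with each parent's
# cluster (taken from the model's training table, where it is unique).
grid_records <- function(model, inbreds = NULL, testers = NULL) {
  stopifnot(inherits(model, "stacked_model"))
  fs <- model$fs
  ic <- dplyr::distinct(model$training, .data$inbred, .data$inbred_cluster)
  tc <- dplyr::distinct(model$training, .data$tester, .data$tester_cluster)
  tidyr::expand_grid(
    inbred = inbreds %||% fs$blocks$inbred,
    tester = testers %||% fs$blocks$tester,
    location = fs$blocks$location,
    year = fs$blocks$year
  ) |>
    dplyr::inner_join(ic, by = "inbred") |>
    dplyr::inner_join(tc, by = "tester") |>
    dplyr::mutate(yield = 1)
}

#' Predict the full inbred-by-tester cross grid
#'
#' Predicts every inbred x tester combination averaged over all location x
#' year cells of the model's roster, the table from which promising crosses
#' are nominated.
#'
#' @param model A fitted `stacked_model`.
#' @param max_cells Refuse grids larger than this many
#'   hybrid-location-year cells unless raised; guards against accidentally
#'   enumerating hundreds of millions of predictions.
#' @return A tibble with one row per inbred x tester pair and its mean
#'   predicted yield (`pred`), sorted decreasing.
#' @export
cross_grid <- function(model, max_cells = 1e7) {
  fs <- model$fs
  n_cells <- length(fs$blocks$inbred) * length(fs$blocks$tester) *
    length(fs$blocks$location) * length(fs$blocks$year)
  if (n_cells > max_cells) {
    abort(sprintf("cross grid has %g cells; raise max_cells to override",
                  n_cells))
  }
  g <- grid_records(model)
  g$pred <- predict(model, g)
  g |>
    dplyr::group_by(.data$inbred, .data$tester) |>
    dplyr::summarise(pred = mean(.data$pred), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$pred))
}

#' Summarise the cross grid by high- and low-yield parent groups
#'
#' The 2-by-2 table of mean predicted yield over the four combinations of
#' {top q, bottom q} inbreds with {top q, bottom q} testers, where parents
#' are ranked by their average predicted yield.
#'
#' @param grid A [cross_grid()] result.
#' @param q Quantile fraction defining the top/bottom groups.
#' @return A tibble with columns `inbred_group`, `tester_group`,
#'   `mean_pred`, `n_pairs`.
#' @export
cross_grid_summary <- function(grid, q = 0.05) {
  rank_group <- function(df, id_col) {
    avg <- df |>
      dplyr::group_by(.data[[id_col]]) |>
      dplyr::summarise(m = mean(.data$pred), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$m))
    sz <- top_list_size(q, nrow(avg))
    list(high = avg[[id_col]][seq_len(sz)],
         low = avg[[id_col]][(nrow(avg) - sz + 1):nrow(avg)])
  }
  gi <- rank_group(grid, "inbred")
  gt <- rank_group(grid, "tester")
  purrr::map_dfr(c("high", "low"), function(a) {
    purrr::map_dfr(c("high", "low"), function(b) {
      sub <- grid[grid$inbred %in% gi[[a]] & grid$tester %in% gt[[b]], ]
      tibble(inbred_group = a, tester_group = b,
             mean_pred = mean(sub$pred), n_pairs = nrow(sub))
    })
  })
}

#' Rank parents by average predicted yield and check observed consistency
#'
#' Averages model predictions over all grid cells for every parent, forms
#' the top and bottom `floor(q * count)` lists, and counts how many of the
#' predicted top/bottom parents also appear in the top/bottom lists ranked by
#' observed average yield (parents with no observations are excluded from
#' the consistency count and noted).
#'
#' @param model A fitted `stacked_model`.
#' @param records Observed trial records for the consistency comparison;
#'   defaults to the model's training table.
#' @param q Quantile fraction (0.05 gives the conventional top-5% lists).
#' @return A `ranking_report` list with tibbles `inbreds` and `testers`
#'   (per-parent predicted and observed averages and ranks) and a
#'   `consistency` tibble (one row per parent pool and end, with list size
#'   and overlap count).
#' @export
rank_parents <- function(model, records = NULL, q = 0.05) {
  records <- if (is.null(records)) model$training else
    aggregate_replicates(records)
  grid <- cross_grid(model)

  one_pool <- function(id_col) {
    pred_avg <- grid |>
      dplyr::group_by(.data[[id_col]]) |>
      dplyr::summarise(pred = mean(.data$pred), .groups = "drop")
    obs_avg <- records |>
      dplyr::group_by(.data[[id_col]]) |>
      dplyr::summarise(observed = mean(.data$yield), n_obs = dplyr::n(),
                       .groups = "drop")
    dplyr::left_join(pred_avg, obs_avg, by = id_col) |>
      dplyr::arrange(dplyr::desc(.data$pred)) |>
      dplyr::mutate(pred_rank = dplyr::row_number(),
                    obs_rank = dplyr::min_rank(dplyr::desc(.data$observed)))
  }
  pools <- list(inbreds = one_pool("inbred"), testers = one_pool("tester"))

  consistency <- purrr::map_dfr(names(pools), function(nm) {
    tab <- pools[[nm]]
    id_col <- if (nm == "inbreds") "inbred" else "tester"
    observed <- tab[!is.na(tab$observed), ]
    n_unobserved <- sum(is.na(tab$observed))
    sz <- top_list_size(q, nrow(tab))
    top_pred <- tab[[id_col]][order(-tab$pred)][seq_len(sz)]
    bot_pred <- tab[[id_col]][order(tab$pred)][seq_len(sz)]
    top_obs <- observed[[id_col]][order(-observed$observed)][seq_len(min(sz, nrow(observed)))]
    bot_obs <- observed[[id_col]][order(observed$observed)][seq_len(min(sz, nrow(observed)))]
    tibble(pool = nm, end = c("top", "bottom"), q = q, list_size = sz,
           consistent = c(length(intersect(top_pred, top_obs)),
                          length(intersect(bot_pred, bot_obs))),
           n_unobserved = n_unobserved)
  })
  if (any(consistency$n_unobserved > 0)) {
    warn(sprintf("%d parent(s) without observations excluded from consistency",
                 max(consistency$n_unobserved)))
  }
  structure(list(inbreds = pools$inbreds, testers = pools$testers,
                 consistency = consistency, q = q),
            class = "ranking_report")
}

#' @export
print.ranking_report <- function(x, ...) {
  cat("<ranking_report> q =", x$q, "\n")
  print(x$consistency)
  invisible(x)
}

#' @export
tidy.ranking_report <- function(x, ...) x$consistency

#' Mean predicted and observed yield per genetic cluster
#'
#' @param model A fitted `stacked_model`.
#' @param records Observed records; defaults to the model's training table.
#' @return A tibble with one row per cluster (both pools) carrying mean
#'   predicted and mean observed yield over that cluster's observed
#'   combinations.
#' @export
cluster_summary <- function(model, records = NULL) {
  records <- if (is.null(records)) model$training else
    aggregate_replicates(records)
  records$pred <- predict(model, records)
  one <- function(col, pool) {
    records |>
      dplyr::group_by(cluster = .data[[col]]) |>
      dplyr::summarise(predicted = mean(.data$pred),
                       observed = mean(.data$yield),
                       n = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(pool = pool, .before = 1)
  }
  dplyr::bind_rows(one("inbred_cluster", "inbred"),
                   one("tester_cluster", "tester"))
}
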