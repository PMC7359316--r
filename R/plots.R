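# ggplot2 views of the main result types.

#' Predicted-versus-observed density plot
#'
#' @param y Observed yields.
#' @param yhat Predicted yields.
#' @param bins Number of hexagon bins.
#' @return A ggplot object.
#' @export
plot_pred_obs <- function(y, yhat, bins = 40) {
  df <- tibble(observed = y, predicted = yhat)
  ggplot2::ggplot(df, ggplot2::aes(.data$observed, .data$predicted)) +
    ggplot2::geom_bin2d(bins = bins) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Observed yield", y = "Predicted yield")
}

#' Interaction-effect plot for a fitted G-by-E model
#'
#' One horizontal bar per detected interaction, labelled by the involved
#' variables, grouped by interaction order.
#'
#' @param object A `gxe_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gxe_model <- function(object, ...) {
  tab <- summarize_interactions(object)
  if (nrow(tab) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", 0, 0, label = "no interactions") +
             ggplot2::theme_void())
  }
  tab$interaction <- factor(tab$interaction, levels = rev(tab$interaction))
  ggplot2::ggplot(tab, ggplot2::aes(.data$effect, .data$interaction,
                                    fill = factor(.data$order))) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Interaction effect (yield units)", y = NULL,
                  fill = "Order")
}

#' Cross-grid heatmap of top and bottom parents
#'
#' Predicted yields for all combinations of the top and bottom `q` fraction
#' of inbreds and testers (ranked by their grid-average prediction), the
#' visual used to nominate and avoid crosses.
#'
#' @param grid A [cross_grid()] result.
#' @param q Fraction of parents on each end.
#' @return A ggplot object.
#' @export
plot_cross_grid <- function(grid, q = 0.05) {
  sel <- function(col) {
    avg <- grid |>
      dplyr::group_by(.data[[col]]) |>
      dplyr::summarise(m = mean(.data$pred), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$m))
    sz <- top_list_size(q, nrow(avg))
    avg[[col]][c(seq_len(sz), (nrow(avg) - sz + 1):nrow(avg))]
  }
  ins <- sel("inbred"); tes <- sel("tester")
  sub <- grid[grid$inbred %in% ins & grid$tester %in% tes, ]
  sub$inbred <- factor(sub$inbred, levels = ins)
  sub$tester <- factor(sub$tester, levels = tes)
  ggplot2::ggplot(sub, ggplot2::aes(.data$tester, .data$inbred,
                                    fill = .data$pred)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Tester (top then bottom)",
                  y = "Inbred (top then bottom)", fill = "Predicted\nyield") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Per-fold cross-validation metric plot
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot object showing per-fold RMSE by split.
#' @export
autoplot.cv_report <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$fold), .data$rmse,
                                   colour = .data$split)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Fold", y = "RMSE", colour = NULL)
}
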