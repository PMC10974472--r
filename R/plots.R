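#' Plot methods for gipca result objects
#'
#' `autoplot.gi_pca()` draws the explained-variance (scree) profile;
#' `autoplot.gi_trial()` the six plate channels; `autoplot.gi_confusion()`
#' a percentage tile plot; `plot_score_clouds()` overlays the per-group
#' bootstrapped-mean clouds with their confidence ellipses in one 2-D
#' subspace, the figure practitioners use to judge cluster separation.
#'
#' @param object Result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name gipca-plots
NULL

#' @rdname gipca-plots
#' @method autoplot gi_pca
#' @export
autoplot.gi_pca <- function(object, ...) {
  d <- tibble(component = factor(paste0("PC", seq_along(object$explained_fraction)),
                                 levels = paste0("PC", seq_along(object$explained_fraction))),
              fraction = object$explained_fraction)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_line(ggplot2::aes(
      y = cumsum(.data$fraction), group = 1), colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = cumsum(.data$fraction)),
                        colour = "firebrick") +
    ggplot2::labs(y = "explained variance fraction", x = NULL,
                  title = "PCA explained variance") +
    ggplot2::theme_minimal()
}

#' @rdname gipca-plots
#' @method autoplot gi_trial
#' @export
autoplot.gi_trial <- function(object, ...) {
  d <- tidyr::pivot_longer(object$data, -"t",
                           names_to = "channel", values_to = "value")
  d$channel <- factor(d$channel, levels = c("Fx", "Fy", "Fz", "Mx", "My", "Mz"))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 2) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(object$truth$events)) {
    p <- p + ggplot2::geom_vline(xintercept = unname(object$truth$events),
                                 linetype = "dashed", colour = "grey55",
                                 linewidth = 0.3)
  }
  p
}

#' @rdname gipca-plots
#' @method autoplot gi_confusion
#' @export
autoplot.gi_confusion <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted, y = .data$true,
                                  fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$percent))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = "predicted group", y = "true group") +
    ggplot2::theme_minimal()
}

#' @rdname gipca-plots
#' @param clouds Named list of `gi_boot` objects (one per group).
#' @param pcs Character pair of score columns, e.g. `c("PC1", "PC2")`.
#' @param level Ellipse confidence level.
#' @export
plot_score_clouds <- function(clouds, pcs = c("PC1", "PC2"), level = 0.95) {
  pts <- purrr::map_dfr(clouds, function(cl) {
    tibble(group = cl$group %||% "cloud",
           x = cl$means[[pcs[1]]], y = cl$means[[pcs[2]]])
  })
  paths <- purrr::map_dfr(clouds, function(cl) {
    e <- confidence_ellipse(cl$means[pcs], level)
    dplyr::mutate(ellipse_path(e), group = cl$group %||% "cloud")
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$group)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.4) +
    ggplot2::geom_path(data = paths, linewidth = 0.7) +
    ggplot2::labs(x = pcs[1], y = pcs[2],
                  title = sprintf("Bootstrapped group means (%.0f%% ellipses)",
                                  100 * level)) +
    ggplot2::theme_minimal()
}
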