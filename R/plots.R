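#' Violin plots of a metric across age groups
#'
#' @param table a cohort tibble (see [run_cohort_analysis()]).
#' @param metric column name to plot.
#' @return A ggplot object.
#' @export
plot_violin <- function(table, metric = "bvtv") {
  ggplot2::ggplot(table, ggplot2::aes(x = .data$age_group,
                                      y = .data[[metric]],
                                      fill = .data$element)) +
    ggplot2::geom_violin(alpha = 0.6, position = ggplot2::position_dodge(0.8)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.8), size = 0.6) +
    ggplot2::labs(x = "age group", y = metric) +
    ggplot2::theme_minimal()
}

#' Allometric regression plot for one metric
#'
#' Raw metric against log10 body mass with the CV-chosen polynomial curve
#' and the isometric reference slope through the data centroid (log-log).
#'
#' @param table a cohort tibble.
#' @param fit the matching [scaling_regression()] on log10 metric.
#' @param metric column name.
#' @param element element to plot.
#' @return A ggplot object.
#' @export
plot_scaling <- function(table, fit, metric = "bvtv", element = "humerus") {
  sub <- table[table$element == element, ]
  iso_int <- mean(log10(sub[[metric]])) - fit$isometric_reference *
    mean(sub$logbm)
  grid <- tibble::tibble(logbm = seq(min(sub$logbm), max(sub$logbm),
                                     length.out = 100))
  xp <- outer(grid$logbm, seq_len(fit$chosen_degree), `^`)
  grid$fit <- 10^(cbind(1, xp) %*%
                    stats::coef(stats::lm(
                      log10(sub[[metric]]) ~ stats::poly(sub$logbm,
                                                         degree = fit$chosen_degree,
                                                         raw = TRUE))))[, 1]
  grid$iso <- 10^(iso_int + fit$isometric_reference * grid$logbm)
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$logbm, y = .data[[metric]])) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$age_group)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$iso),
                       linetype = "dotted") +
    ggplot2::labs(x = "log10 body mass (kg)", y = metric,
                  title = sprintf("%s %s: slope %.3f [%.3f, %.3f]", element,
                                  metric, fit$slope, fit$slope_ci[1],
                                  fit$slope_ci[2])) +
    ggplot2::theme_minimal()
}

#' Stereonet of primary trabecular orientations
#'
#' Lower-hemisphere equal-area disk; point size encodes the degree of
#' anisotropy, colour the age group.
#'
#' @param projection the `projection` tibble of a [run_cohort_analysis()]
#'   report (columns `px`, `py`, `age_group`, `element`, `da`).
#' @return A ggplot object.
#' @export
plot_stereonet <- function(projection) {
  circle <- tibble::tibble(theta = seq(0, 2 * pi, length.out = 181))
  ggplot2::ggplot(projection, ggplot2::aes(x = .data$px, y = .data$py)) +
    ggplot2::geom_path(data = tibble::tibble(px = cos(circle$theta),
                                             py = sin(circle$theta)),
                       linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$age_group,
                                     size = .data$da), alpha = 0.8) +
    ggplot2::scale_size_continuous(range = c(0.5, 3)) +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~element) +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "right")
}

#' Biplot of a metric-table PCA
#'
#' @param object a [pca_metrics()] result.
#' @param data optional tibble aligned with the scores (for `colour_by`).
#' @param colour_by optional column of `data` used for point colour.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.trab_pca <- function(object, data = NULL, colour_by = "age_group",
                              ...) {
  sc <- object$scores
  pct <- round(100 * object$explained_variance[1:2], 1)
  arrow_scale <- 0.8 * min(
    max(abs(sc$PC1)) / max(abs(object$loadings[, 1])),
    max(abs(sc$PC2)) / max(abs(object$loadings[, 2]))
  )
  arrows <- tibble::tibble(
    variable = rownames(object$loadings),
    x = object$loadings[, 1] * arrow_scale,
    y = object$loadings[, 2] * arrow_scale
  )
  if (!is.null(data) && colour_by %in% names(data)) {
    sc[[colour_by]] <- data[[colour_by]][seq_len(nrow(sc))]
  }
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  p <- if (!is.null(data) && colour_by %in% names(sc)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour_by]]))
  } else {
    p + ggplot2::geom_point()
  }
  p +
    ggplot2::geom_segment(data = arrows,
                          ggplot2::aes(x = 0, y = 0, xend = .data$x,
                                       yend = .data$y),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          colour = "grey40") +
    ggplot2::geom_text(data = arrows,
                       ggplot2::aes(x = .data$x * 1.08, y = .data$y * 1.08,
                                    label = .data$variable), size = 3) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", pct[1]),
                  y = sprintf("PC2 (%.1f%%)", pct[2])) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
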