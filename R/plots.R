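#' Plot per-cell metrics by group
#'
#' Column-and-jitter comparison of one morphometric metric between groups,
#' in the style standard for per-cell group comparisons (bar = group mean,
#' error bar = SEM, points = individual cells).
#'
#' @param object An `mg_cells` tibble (with a `group` column).
#' @param metric Column to plot (default `volume_um3`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mg_cells <- function(object, metric = "volume_um3", ...) {
  stopifnot(metric %in% names(object), "group" %in% names(object))
  sg <- summarize_groups(object, metric, "group")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$group, y = .data[[metric]])) +
    ggplot2::geom_col(data = sg, ggplot2::aes(y = .data$mean),
                      fill = "grey80", width = 0.6) +
    ggplot2::geom_errorbar(
      data = sg,
      ggplot2::aes(y = .data$mean, ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem), width = 0.15) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_classic()
}

#' @rdname autoplot.mg_cells
#' @export
plot_group_comparison <- function(object, metric = "volume_um3", ...) {
  autoplot.mg_cells(object, metric, ...)
}

#' Plot a gated two-sample test
#'
#' @param object An `mg_test`.
#' @param ... Unused.
#' @return A ggplot: both samples with the p-value and stars in the title.
#' @export
autoplot.mg_test <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(sample = "a", value = object$samples$a),
    tibble(sample = "b", value = object$samples$b)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.5, size = 0.8) +
    ggplot2::labs(
      title = sprintf("%s: p = %.3g %s", object$method, object$p_value,
                      object$stars),
      x = NULL, y = NULL) +
    ggplot2::theme_classic()
}

#' Plot the group x CD68 interaction
#'
#' @param object An `mg_anova`.
#' @param ... Unused.
#' @return A ggplot of cell means with SEM bars by group and CD68 status.
#' @export
autoplot.mg_anova <- function(object, ...) {
  df <- object$data
  sg <- df |>
    dplyr::group_by(.data$.g, .data$.f) |>
    dplyr::summarise(mean = mean(.data$.y),
                     sem = sd(.data$.y) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(sg, ggplot2::aes(x = .data$.g, y = .data$mean,
                                   fill = .data$.f)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(0.8), width = 0.2) +
    ggplot2::labs(x = object$group, y = object$value, fill = object$factor2) +
    ggplot2::theme_classic()
}

#' Show one z-slice of a stack or label volume
#'
#' @param x An [mg_stack()], 3D array or `label_volume`.
#' @param z Slice index.
#' @param channel Channel (for stacks).
#' @return A ggplot raster of the slice.
#' @export
plot_stack_slice <- function(x, z = 1L, channel = 1L) {
  sl <- if (inherits(x, "mg_stack")) {
    x$data[, , z, channel]
  } else {
    x[, , z]
  }
  df <- expand.grid(y = seq_len(nrow(sl)), x = seq_len(ncol(sl)))
  df$value <- as.numeric(sl)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::theme_void()
}
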