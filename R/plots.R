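# ggplot2 graphics for the main result types.

#' Learning curves of a gain sweep
#'
#' One line per excitability level, colored from low (blue) to high
#' (yellow) gain.
#'
#' @param object a `gt_sweep`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gt_sweep <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$iteration, y = .data$accuracy,
                               color = .data$gain,
                               group = .data$gain)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_viridis_c(name = "gain G") +
    ggplot2::labs(x = "training iteration", y = "test accuracy",
                  title = "Learning trajectories across excitability levels") +
    ggplot2::theme_minimal()
}

#' Behavioral-distance profile of a cohort match
#'
#' Cohort-mean behavioral distance per evaluated iteration, with the
#' reference iteration marked.
#'
#' @param object a `gt_match`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gt_match <- function(object, ...) {
  prof <- object$table %>%
    group_by(.data$iteration, .data$group) %>%
    summarise(mean_distance = mean(.data$distance), .groups = "drop")
  ref <- select_reference_iteration(object)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$iteration,
                                     y = .data$mean_distance,
                                     color = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = ref, linetype = "dashed") +
    ggplot2::labs(x = "training iteration", y = "mean behavioral distance",
                  title = paste0("Model-subject matching (reference iteration ",
                                 ref, ")")) +
    ggplot2::theme_minimal()
}

#' Behavioral metrics against excitability
#'
#' @param behavior a [sweep_behavior()] tibble.
#' @return a ggplot, one facet per metric.
#' @export
plot_behavior_by_gain <- function(behavior) {
  long <- tidyr::pivot_longer(behavior,
                              c("accuracy", "systematic_error",
                                "imprecision", "effective_responses"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gain, y = .data$value)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "gain G", y = NULL,
                  title = "Behavioral metrics vs neural excitability") +
    ggplot2::theme_minimal()
}

#' NRS block averages against excitability
#'
#' @param nrs a tibble of [network_nrs()] rows over several gains.
#' @return a ggplot faceted by layer.
#' @export
plot_nrs_by_gain <- function(nrs) {
  long <- tidyr::pivot_longer(nrs, c("add_sub", "add_add", "sub_sub"),
                              names_to = "block", values_to = "nrs")
  long$layer <- factor(long$layer, levels = c("V1", "V2", "V3", "IPS"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gain, y = .data$nrs,
                                     color = .data$block)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::facet_wrap(~layer) +
    ggplot2::labs(x = "gain G", y = "mean similarity",
                  title = "Representational similarity vs excitability") +
    ggplot2::theme_minimal()
}

#' Manifold geometry against excitability
#'
#' @param geometry a tibble of [network_manifolds()] rows over gains.
#' @return a ggplot, one facet per geometric property.
#' @export
plot_manifold_geometry <- function(geometry) {
  long <- tidyr::pivot_longer(geometry,
                              c("capacity", "radius", "dimension",
                                "center_correlation"),
                              names_to = "property")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gain, y = .data$value)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::facet_wrap(~property, scales = "free_y") +
    ggplot2::labs(x = "gain G", y = NULL,
                  title = "Result-manifold geometry vs excitability") +
    ggplot2::theme_minimal()
}

#' Show a stimulus image
#'
#' @param pixels a 28x140x3 stimulus array (or the first image of a batch).
#' @return a ggplot raster.
#' @export
plot_stimulus <- function(pixels) {
  if (length(dim(pixels)) == 4) pixels <- pixels[, , , 1]
  df <- expand.grid(y = 1:28, x = 1:140)
  df$v <- as.vector(pixels[, , 1])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, -.data$y, fill = .data$v)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::coord_equal() + ggplot2::theme_void()
}
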