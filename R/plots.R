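#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_hline labs theme_minimal facet_wrap scale_x_continuous
NULL

#' Plot a fitted psychometric function
#'
#' Observed accuracy per numerical ratio with the fitted ratio-dependent
#' psychometric curve overlaid; the dashed line marks chance.
#'
#' @param object A `weber_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.weber_fit <- function(object, ...) {
  grid <- tibble::tibble(ratio = seq(min(object$table$ratio) * 0.9,
                                     max(object$table$ratio) * 1.02,
                                     length.out = 200))
  grid$p <- weber_model(grid$ratio, object$w, object$lapse)
  ggplot(object$table, aes(x = .data$ratio, y = .data$accuracy)) +
    geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey60") +
    geom_line(data = grid, aes(y = .data$p), colour = "steelblue") +
    geom_point(size = 2) +
    labs(x = "numerical ratio (smaller : larger)", y = "accuracy",
         title = sprintf("Weber fraction w = %.3f%s", object$w,
                         if (is.na(object$condition)) ""
                         else paste0("  (", object$condition, ")"))) +
    theme_minimal()
}

#' Plot a Weber-fraction learning trajectory
#'
#' @param trajectory Tibble from [learning_trajectory()] (`epoch`, `w`).
#' @return A ggplot.
#' @export
plot_trajectory <- function(trajectory) {
  ggplot(trajectory, aes(x = .data$epoch, y = .data$w)) +
    geom_line(colour = "steelblue") + geom_point(size = 2) +
    labs(x = "unsupervised learning epoch", y = "Weber fraction w") +
    theme_minimal()
}

#' Plot summation-coding regression coefficients
#'
#' Scatter of the standardized numerosity coefficient against the
#' cumulative-area coefficient, coloured by coding class.
#'
#' @param profiles A [classify_summation()] result (a `network` column, if
#'   present, facets the plot).
#' @return A ggplot.
#' @export
plot_summation <- function(profiles) {
  p <- ggplot(profiles, aes(x = .data$b_n, y = .data$b_a,
                            colour = .data$class)) +
    geom_point(alpha = 0.6) +
    labs(x = "numerosity coefficient (B)", y = "cumulative-area coefficient (B)",
         colour = "coding class") +
    theme_minimal()
  if ("network" %in% names(profiles)) p <- p + facet_wrap(~network)
  p
}

#' Plot pooled tuning curves of numerosity-selective units
#'
#' @param pool A [pool_tuning_curves()] result.
#' @param view `"preferred"` (curves grouped by preferred numerosity) or
#'   `"distance"` (aligned on numerical distance from preferred).
#' @return A ggplot.
#' @export
plot_tuning_pool <- function(pool, view = c("preferred", "distance")) {
  view <- match.arg(view)
  if (view == "preferred") {
    ggplot(pool$curves, aes(x = .data$n, y = .data$response,
                            colour = factor(.data$preferred_n))) +
      geom_line() + geom_point() +
      labs(x = "numerosity", y = "normalised response",
           colour = "preferred N") +
      theme_minimal()
  } else {
    ggplot(pool$distance_curves, aes(x = .data$distance, y = .data$response)) +
      geom_line(colour = "steelblue") + geom_point() +
      labs(x = "numerical distance from preferred", y = "normalised response") +
      theme_minimal()
  }
}

#' Plot distance and size effects from the comparison battery
#'
#' @param effects A [distance_size_effects()] result.
#' @return A ggplot of accuracy (and mean RT) against numerical distance.
#' @export
plot_distance_effects <- function(effects) {
  d <- effects$distance |>
    tidyr::pivot_longer(c("accuracy", "mean_rt"),
                        names_to = "measure", values_to = "value")
  ggplot(d, aes(x = .data$distance, y = .data$value)) +
    geom_line(colour = "steelblue") + geom_point() +
    facet_wrap(~measure, scales = "free_y") +
    scale_x_continuous(breaks = unique(d$distance)) +
    labs(x = "numerical distance") +
    theme_minimal()
}

#' Plot the mean-fitness trace of an evolving ecosystem
#'
#' @param eco An `ecosystem` (or a tibble with `iteration`,
#'   `mean_fitness`).
#' @return A ggplot.
#' @export
plot_fitness_trace <- function(eco) {
  trace <- if (inherits(eco, "ecosystem")) eco$trace else eco
  ggplot(trace, aes(x = .data$iteration, y = .data$mean_fitness)) +
    geom_line(colour = "steelblue") +
    labs(x = "ecosystem iteration", y = "mean food-collection rate") +
    theme_minimal()
}

#' Display a stimulus image
#'
#' @param x A `num_img`.
#' @param ... Unused.
#' @return A ggplot raster of the binary image.
#' @export
autoplot.num_img <- function(x, ...) {
  df <- expand.grid(row = seq_len(nrow(x$pixels)),
                    col = seq_len(ncol(x$pixels)))
  df$on <- as.vector(x$pixels) > 0
  ggplot(df, aes(x = .data$col, y = -.data$row, fill = .data$on)) +
    ggplot2::geom_tile(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c("TRUE" = "black", "FALSE" = "white")) +
    ggplot2::coord_equal() +
    labs(title = sprintf("N = %d, area = %d, contour = %d",
                         x$n, x$area, x$contour), x = NULL, y = NULL) +
    theme_minimal()
}
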