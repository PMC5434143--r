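# ggplot2 visualisations for the main result types.

#' Plot an allocation line
#'
#' Median allocation per probability setting with the fitted line, the
#' probability-matching diagonal (dotted) and the maximizing step (dashed).
#'
#' @param object An `allocation_line`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.allocation_line <- function(object, ...) {
  cf <- stats::coef(object$model)
  step_df <- tibble::tibble(
    prob = c(0, 0.5, 0.5, 1),
    allocation = c(0, 0, 1, 1)
  )
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$prob,
                                              y = .data$allocation)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_path(data = step_df, linetype = "dashed", colour = "grey70") +
    ggplot2::geom_abline(intercept = cf[[1]], slope = cf[[2]],
                         colour = "#2166AC") +
    ggplot2::geom_point(size = 3) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Programmed probability top row correct",
      y = "Median allocation of attention to top row",
      title = sprintf("Allocation line: intercept %.2f, slope %.2f",
                      cf[[1]], cf[[2]])
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-AOI conditional accuracy
#'
#' Probability of a correct response per AOI, split by which row was
#' correct; mirror-imaged panels indicate overt-gaze dependence, parallel
#' panels indicate covert shifts.
#'
#' @param object An `aoi_accuracy` table from [per_aoi_accuracy()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.aoi_accuracy <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  dat$aoi <- factor(dat$aoi, levels = unique(dat$aoi))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$aoi, y = .data$prob,
                                    fill = .data$correct_row)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~cued, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "AOI", y = "P(correct | fixation AOI)",
                  fill = "Correct row") +
    ggplot2::theme_minimal()
}

#' Plot a distance-accuracy fit
#'
#' Accuracy against AOI midpoint distance with the linear (dashed) and
#' quadratic (solid) least-squares curves.
#'
#' @param object A `distance_accuracy_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.distance_accuracy_fit <- function(object, ...) {
  grid <- tibble::tibble(
    distance_deg = seq(min(object$data$distance_deg),
                       max(object$data$distance_deg), length.out = 100)
  )
  grid$linear <- stats::predict(object$linear, grid)
  grid$quadratic <- stats::predict(object$quadratic, grid)
  long <- tidyr::pivot_longer(grid, c("linear", "quadratic"),
                              names_to = "model", values_to = "prob")
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$distance_deg, y = .data$prob)) +
    ggplot2::geom_line(data = long, ggplot2::aes(linetype = .data$model)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$correct_row), size = 2.5) +
    ggplot2::labs(x = "Midpoint distance from correct stimulus (deg)",
                  y = "P(correct)", colour = "Correct row",
                  linetype = "Fit") +
    ggplot2::theme_minimal()
}
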