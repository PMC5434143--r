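# broom-style tidiers for fitted objects.

#' Tidy an allocation line
#'
#' @param x An `allocation_line` from [fit_allocation_line()].
#' @param ... Unused.
#' @return Tibble of coefficient terms (as [broom::tidy()] for `lm`).
#' @export
tidy.allocation_line <- function(x, ...) {
  broom::tidy(x$model)
}

#' Glance at an allocation line
#'
#' @inheritParams tidy.allocation_line
#' @return One-row tibble: `intercept`, `slope`, `r.squared`, `n_points`.
#' @export
glance.allocation_line <- function(x, ...) {
  cf <- stats::coef(x$model)
  tibble::tibble(
    intercept = cf[[1]],
    slope = cf[[2]],
    r.squared = summary(x$model)$r.squared,
    n_points = x$n_points
  )
}

#' Tidy a distance-accuracy fit
#'
#' @param x A `distance_accuracy_fit` from [distance_accuracy_fit()].
#' @param ... Unused.
#' @return Coefficient tibble with a `model` column (`"linear"` /
#'   `"quadratic"`).
#' @export
tidy.distance_accuracy_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(broom::tidy(x$linear), model = "linear"),
    dplyr::mutate(broom::tidy(x$quadratic), model = "quadratic")
  )
}

#' Glance at a distance-accuracy fit
#'
#' @inheritParams tidy.distance_accuracy_fit
#' @return Two-row tibble: `model`, `r.squared`, `adj.r.squared`, `df`,
#'   `n`.
#' @export
glance.distance_accuracy_fit <- function(x, ...) {
  one <- function(m, name) {
    s <- summary(m)
    tibble::tibble(model = name, r.squared = s$r.squared,
                   adj.r.squared = s$adj.r.squared,
                   df = unname(s$df[1]), n = nrow(x$data))
  }
  dplyr::bind_rows(one(x$linear, "linear"), one(x$quadratic, "quadratic"))
}
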