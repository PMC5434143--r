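# Cohort-level attention-allocation analysis: per-subject estimates,
# probability-matching line fits, and the weighted expected-line arithmetic.

#' Per-subject allocation estimates
#'
#' Applies the closed-form inversion subject by subject: A from that
#' subject's cued trials, PCT/PCB as empirical fractions correct on uncued
#' top-correct / bottom-correct trials. Sessions are pooled within subject
#' by default (set `by_session = TRUE` for per-session estimates).
#'
#' Because the correct row is Bernoulli on every trial, a subject at an
#' extreme probability setting can end up with no cued trials for one row;
#' A is then taken from the remaining row alone (with a warning) rather
#' than aborting the cohort. A subject with no cued trials at all, or no
#' uncued trials for a row, is an error.
#'
#' @param trials Trial table (behavioural columns of the generator schema:
#'   `subject_id`, `session`, `cued`, `correct_row`, `response_correct`,
#'   plus `gap_condition`/`prob_top` which are carried through if present).
#' @param by_session Estimate per subject x session instead of pooling.
#'
#' @return Tibble with one row per subject (x session): identifiers,
#'   `PCT`, `PCB`, `A_used`, `p_hat`, `g_hat`, counts and clamping flags.
#' @export
subject_allocations <- function(trials, by_session = FALSE) {
  stopifnot(is.data.frame(trials),
            all(c("subject_id", "cued", "correct_row", "response_correct")
                %in% names(trials)))
  keys <- c("subject_id", if (by_session) "session")
  carry <- intersect(c("gap_condition", "prob_top"), names(trials))

  one <- function(df) {
    acc <- tryCatch(estimate_accuracy(df), error = function(e) {
      cued <- df[df$cued, , drop = FALSE]
      if (nrow(cued) == 0L) stop(e)
      warning("subject ", df$subject_id[1], ": cued trials cover only one ",
              "row; A estimated from that row alone", call. = FALSE)
      tibble::tibble(A = mean(cued$response_correct))
    })
    unc <- df[!df$cued, , drop = FALSE]
    top <- unc$response_correct[unc$correct_row == "top"]
    bot <- unc$response_correct[unc$correct_row == "bottom"]
    if (!length(top) || !length(bot)) {
      stop("insufficient data: subject ", df$subject_id[1],
           " has no uncued trials for one of the rows", call. = FALSE)
    }
    est <- estimate_allocation(mean(top), mean(bot), acc$A,
                               n_top = length(top), n_bottom = length(bot))
    dplyr::bind_cols(
      df[1, c(keys, carry), drop = FALSE],
      tibble::tibble(PCT = mean(top), PCB = mean(bot)),
      est
    )
  }
  trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_split() |>
    purrr::map(one) |>
    dplyr::bind_rows()
}

#' Fit the allocation-vs-probability line
#'
#' Takes per-subject allocation estimates, collapses them to the median
#' estimate per programmed top-row probability, and fits an ordinary
#' least-squares line of median allocation on probability. A slope of 1
#' with intercept 0 is exact probability matching; a step at 0.5 is
#' maximizing.
#'
#' @param data Data frame with the programmed probability and an
#'   allocation-estimate column (defaults `prob_top`, `p_hat`), e.g. the
#'   output of [subject_allocations()]. If several rows share a
#'   probability, their median is taken before fitting.
#' @param x,y Column names for probability and allocation.
#'
#' @return Object of class `allocation_line`: list with the `lm` fit
#'   (`model`), the `(prob, median allocation)` `points`, and `n_points`.
#'   `tidy()`, `glance()` and `autoplot()` methods are available.
#' @export
#' @examples
#' pts <- data.frame(prob_top = c(0.1, 0.25, 0.75, 0.9),
#'                   p_hat = c(0.1, 0.25, 0.75, 0.9))
#' glance(fit_allocation_line(pts))
fit_allocation_line <- function(data, x = "prob_top", y = "p_hat") {
  stopifnot(is.data.frame(data), all(c(x, y) %in% names(data)))
  pts <- data |>
    dplyr::group_by(prob = .data[[x]]) |>
    dplyr::summarise(allocation = stats::median(.data[[y]]), .groups = "drop") |>
    dplyr::arrange(.data$prob)
  if (nrow(pts) < 2L) {
    stop("fit undefined: need at least 2 distinct probability settings",
         call. = FALSE)
  }
  structure(
    list(
      model = stats::lm(allocation ~ prob, data = pts),
      points = pts,
      n_points = nrow(pts)
    ),
    class = "allocation_line"
  )
}

#' @export
print.allocation_line <- function(x, ...) {
  cf <- stats::coef(x$model)
  cat(sprintf(
    "Allocation line over %d probability settings: intercept %.3f, slope %.3f\n",
    x$n_points, cf[[1]], cf[[2]]
  ))
  invisible(x)
}

#' Weight-averaged expected line
#'
#' Combines expected (intercept, slope) pairs from several session groups
#' into a single expected line by weight-proportional averaging of the
#' intercepts and slopes independently — e.g. mixing five first-session
#' with eleven second-session expectations.
#'
#' @param components Data frame with columns `weight`, `intercept`,
#'   `slope` (weights positive).
#'
#' @return One-row tibble with `intercept` and `slope`.
#' @export
#' @examples
#' mix_expected_line(data.frame(weight = c(5, 11),
#'                              intercept = c(0.35, 0.17),
#'                              slope = c(0.48, 0.70)))
mix_expected_line <- function(components) {
  stopifnot(is.data.frame(components),
            all(c("weight", "intercept", "slope") %in% names(components)))
  w <- components$weight
  if (any(w <= 0) || sum(w) == 0) {
    stop("weights must be positive with a non-zero total", call. = FALSE)
  }
  tibble::tibble(
    intercept = sum(w * components$intercept) / sum(w),
    slope = sum(w * components$slope) / sum(w)
  )
}

#' Matching-vs-maximizing comparison
#'
#' Evaluates the fitted allocation line at the four programmed probability
#' settings and reports its sum of squared deviations from the
#' probability-matching prediction (allocation = probability) and from the
#' maximizing prediction (allocate fully to the more likely row).
#'
#' @param line An [fit_allocation_line()] result.
#' @param prob_settings Probabilities at which to evaluate.
#'
#' @return One-row tibble: `slope`, `intercept`, `matching_ss`,
#'   `maximizing_ss`, `closer_to`.
#' @export
matching_vs_maximizing <- function(line,
                                   prob_settings = c(0.10, 0.25, 0.75, 0.90)) {
  stopifnot(inherits(line, "allocation_line"))
  cf <- stats::coef(line$model)
  pred <- cf[[1]] + cf[[2]] * prob_settings
  match_ss <- sum((pred - prob_settings)^2)
  maxim_ss <- sum((pred - as.numeric(prob_settings > 0.5))^2)
  tibble::tibble(
    intercept = cf[[1]], slope = cf[[2]],
    matching_ss = match_ss, maximizing_ss = maxim_ss,
    closer_to = ifelse(match_ss <= maxim_ss, "matching", "maximizing")
  )
}
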