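# Forward generative model of the two-row attention task.
#
# On each trial one of two digit rows is the correct one (top with
# probability PT, bottom with PB = 1 - PT). The subject attends the top row
# with probability p. Attending the correct row yields a correct response
# with probability A (cued-trial accuracy: arithmetic slips and lapses);
# attending the wrong row leaves only a guess among the 7 probe
# alternatives, correct with probability g.

#' Expected correct-response probabilities given attention parameters
#'
#' Conditional on which row is correct:
#' \deqn{PCT = p A + (1 - p) g, \qquad PCB = (1 - p) A + p g.}
#' With `A = 1` these are the two branches of the basic linear model of
#' expected correct matches. The pair satisfies the conservation identity
#' `PCT + PCB = A + g` for all parameter values, which is what makes the
#' closed-form inversion ([estimate_allocation()]) exact.
#'
#' @param p Probability of attending the top row, in `[0, 1]`. Vectorised.
#' @param g Correct-guess probability (1/7 under uniform guessing over the
#'   seven probe alternatives).
#' @param A Probability of a correct response given the correct row was
#'   attended (estimated from cued trials; see [estimate_accuracy()]).
#'
#' @return Tibble with columns `p`, `g`, `A`, `PCT`, `PCB`.
#' @export
#' @examples
#' forward_response_probs(p = 0.7, g = 1 / 7, A = 0.9)
forward_response_probs <- function(p, g = 1 / 7, A = 1) {
  n <- max(length(p), length(g), length(A))
  p <- rep_len(p, n)
  g <- rep_len(g, n)
  A <- rep_len(A, n)
  if (any(p < 0 | p > 1 | g < 0 | g > 1 | A < 0 | A > 1)) {
    stop("p, g and A must all lie in [0, 1]", call. = FALSE)
  }
  if (any(A <= g)) {
    warning("A <= g: accuracy does not exceed the guess rate; ",
            "estimates from such data are uninformative", call. = FALSE)
  }
  tibble::tibble(
    p = p, g = g, A = A,
    PCT = p * A + (1 - p) * g,
    PCB = (1 - p) * A + p * g
  )
}

#' Expected overall proportion correct
#'
#' Marginalises the conditional correct-response probabilities over which
#' row is correct: `PT * PCT + PB * PCB`. With `A = 1` this reduces term by
#' term to the linear model
#' `PT p + PT (1 - p) g + PB (1 - p) + PB p g`.
#'
#' @param PT Probability that the top row is the correct one, in `(0, 1)`.
#'   `PB` is always `1 - PT`.
#' @inheritParams forward_response_probs
#'
#' @return Numeric vector of expected proportions correct.
#' @export
#' @examples
#' expected_overall_correct(PT = 0.9, p = 1, g = 1 / 7) # ~0.914
expected_overall_correct <- function(PT, p, g = 1 / 7, A = 1) {
  if (any(PT <= 0 | PT >= 1)) {
    stop("PT must lie strictly inside (0, 1)", call. = FALSE)
  }
  fw <- suppressWarnings(forward_response_probs(p, g, A))
  PT * fw$PCT + (1 - PT) * fw$PCB
}
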