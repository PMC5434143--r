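# Inversion of observed correct-response rates into attention parameters.
#
# The forward model PCT = pA + (1-p)g, PCB = (1-p)A + pg inverts in closed
# form:
#   p = (PCB - A) / (PCT + PCB - 2A)
#   g = (PCT + PCB) - A
# A is not fitted: it is measured on cued trials, where the subject was told
# which row is correct and guessing plays no role.

#' Cued-trial accuracy A
#'
#' Estimates the accuracy parameter from cued trials as the unweighted mean
#' of the top-cued and bottom-cued fractions correct (cued trial counts are
#' balanced by design, and the model uses a single scalar A).
#'
#' @param trials Data frame of trials with logical `cued`, character
#'   `correct_row` (`"top"`/`"bottom"`) and logical `response_correct`.
#'
#' @return One-row tibble with `A`, `acc_top`, `acc_bottom`, `n_top`,
#'   `n_bottom`.
#' @export
estimate_accuracy <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("cued", "correct_row", "response_correct") %in% names(trials)))
  cued <- trials[trials$cued, , drop = FALSE]
  for (row in c("top", "bottom")) {
    if (!any(cued$correct_row == row)) {
      stop("insufficient data: no cued trials with the ", row, " row correct",
           call. = FALSE)
    }
  }
  top <- cued$response_correct[cued$correct_row == "top"]
  bot <- cued$response_correct[cued$correct_row == "bottom"]
  tibble::tibble(
    A = (mean(top) + mean(bot)) / 2,
    acc_top = mean(top),
    acc_bottom = mean(bot),
    n_top = length(top),
    n_bottom = length(bot)
  )
}

#' Invert correct-response rates into attention allocation and guess rate
#'
#' Applies the closed-form inversion of the linear task model. Estimates
#' falling outside `[0, 1]` (legitimate under small-sample noise) are
#' clamped and flagged rather than rejected. A near-zero denominator
#' (`PCT + PCB` within `tol` of `2A`) carries no directional information:
#' `p_hat` is reported as 0.5 with the `degenerate_denominator` flag set.
#'
#' @param PCT Observed fraction correct on uncued trials where the top row
#'   was correct. Vectorised.
#' @param PCB Same for bottom-correct trials.
#' @param A Cued-trial accuracy (see [estimate_accuracy()]).
#' @param n_top,n_bottom Optional trial counts behind `PCT` / `PCB`,
#'   carried through for bookkeeping.
#' @param tol Degeneracy tolerance for the denominator.
#'
#' @return Tibble with `p_hat`, `g_hat`, `A_used`, `p_raw`, `g_raw`,
#'   `n_top`, `n_bottom` and logical flags `degenerate_denominator`,
#'   `clamped_p`, `clamped_g`.
#' @export
#' @examples
#' estimate_allocation(PCT = 0.6729, PCB = 0.37, A = 0.9)
estimate_allocation <- function(PCT, PCB, A,
                                n_top = NA_integer_, n_bottom = NA_integer_,
                                tol = 1e-9) {
  n <- max(length(PCT), length(PCB), length(A))
  PCT <- rep_len(PCT, n)
  PCB <- rep_len(PCB, n)
  A <- rep_len(A, n)
  n_top <- rep_len(n_top, n)
  n_bottom <- rep_len(n_bottom, n)
  if (any(c(PCT, PCB, A) < 0 | c(PCT, PCB, A) > 1)) {
    stop("PCT, PCB and A must lie in [0, 1]", call. = FALSE)
  }
  denom <- PCT + PCB - 2 * A
  degenerate <- abs(denom) < tol
  p_raw <- ifelse(degenerate, 0.5, (PCB - A) / denom)
  g_raw <- (PCT + PCB) - A
  p_hat <- pmin(1, pmax(0, p_raw))
  g_hat <- pmin(1, pmax(0, g_raw))
  tibble::tibble(
    p_hat = p_hat,
    g_hat = g_hat,
    A_used = A,
    p_raw = p_raw,
    g_raw = g_raw,
    n_top = n_top,
    n_bottom = n_bottom,
    degenerate_denominator = degenerate,
    clamped_p = p_hat != p_raw,
    clamped_g = g_hat != g_raw
  )
}

#' Wilcoxon signed-rank test of the guess rate against uniform guessing
#'
#' Tests per-subject guess-rate estimates against the 7-alternative uniform
#' prediction 1/7 (0.143). Because many estimates sit near zero, the test is
#' run on square-root-transformed values, i.e. on
#' `sqrt(g) - sqrt(null_g)`. The p-value comes from the exact signed-rank
#' distribution when `n <= 25` (and the data permit it), otherwise from the
#' normal approximation with continuity correction; the reported `statistic`
#' is the signed standardized Z with tie-corrected variance.
#'
#' @param g Numeric vector of per-subject guess-rate estimates (>= 2
#'   values).
#' @param null_g Null guess rate; defaults to 1/7.
#'
#' @return One-row tibble: `statistic` (Z), `V` (signed-rank sum),
#'   `p_value`, `median_g`, `null_g`, `n`, `n_used` (non-zero differences).
#' @export
test_guess_rate <- function(g, null_g = 1 / 7) {
  stopifnot(is.numeric(g), length(g) >= 2, all(g >= 0), null_g >= 0)
  d <- sqrt(g) - sqrt(null_g)
  nz <- d != 0
  out <- tibble::tibble(
    statistic = 0, V = NA_real_, p_value = 1,
    median_g = stats::median(g), null_g = null_g,
    n = length(g), n_used = sum(nz)
  )
  if (!any(nz)) {
    return(out) # all differences zero: statistic 0, p = 1 by convention
  }
  d <- d[nz]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  cc <- 0.5 * sign(V - mu)
  z <- if (sigma2 > 0) (V - mu - cc) / sqrt(sigma2) else 0
  exact <- n <= 25 && !any(duplicated(abs(d)))
  pv <- suppressWarnings(
    stats::wilcox.test(sqrt(g[nz]), mu = sqrt(null_g), exact = exact,
                       correct = TRUE)$p.value
  )
  out$statistic <- z
  out$V <- V
  out$p_value <- pv
  out
}
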