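# Independent oracles and small fixture builders used across test files.

# Brute-force Spearman: explicit average-rank table, explicit Pearson
# formula. Kept deliberately naive and separate from the package code path.
brute_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x)
  ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Exact distribution of the sum of three independent uniform{1..9} digits,
# by enumeration of the 9^3 combinations.
digit_sum_distribution <- function() {
  grid <- expand.grid(1:9, 1:9, 1:9)
  table(rowSums(grid)) / 9^3
}

# Minimal behavioural trial table with prescribed counts.
make_trials <- function(subject_id = "S1",
                        n_cued_top = 10, cued_top_correct = 10,
                        n_cued_bottom = 10, cued_bottom_correct = 10,
                        n_unc_top = 50, unc_top_correct = 30,
                        n_unc_bottom = 50, unc_bottom_correct = 20,
                        prob_top = 0.5, gap_condition = "standard") {
  block <- function(n, k, cued, row) {
    if (n == 0) return(NULL)
    tibble::tibble(
      subject_id = subject_id, gap_condition = gap_condition,
      prob_top = prob_top, session = 1L, trial = 0L, cued = cued,
      correct_row = row,
      response_correct = rep(c(TRUE, FALSE), c(k, n - k))
    )
  }
  out <- dplyr::bind_rows(
    block(n_cued_top, cued_top_correct, TRUE, "top"),
    block(n_cued_bottom, cued_bottom_correct, TRUE, "bottom"),
    block(n_unc_top, unc_top_correct, FALSE, "top"),
    block(n_unc_bottom, unc_bottom_correct, FALSE, "bottom")
  )
  out$trial <- seq_len(nrow(out))
  out
}

# One standard far-condition test profile with a fixed exposure.
far_profile <- function(id = "S1", ...) {
  subject_profile(id, "far", 0.75, exposure_ms = 158, ...)
}
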