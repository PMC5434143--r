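# Published fixation-distribution percentages, packaged as a fixture.
#
# The percentages of single-AOI fixations per region, by gap condition,
# correct row and cueing, as printed in the source experiment's summary
# table. They serve as a reference input: the headline rank-correlation
# analysis can be reproduced from them without any simulation.

#' Published fixation-distribution percentages
#'
#' Percentage of fixations per AOI as a function of gap condition (15 deg
#' vs 0.32 deg), which row was correct, and cueing. Columns were published
#' rounded to whole percent.
#'
#' @return Tibble: `gap_condition` (`"far"`/`"standard"`), `aoi` (top to
#'   bottom), `correct_row`, `cued`, `pct`.
#' @export
#' @examples
#' reference_fixation_distribution()
reference_fixation_distribution <- function() {
  far_aois <- c("T1", "T2", "T3", "B3", "B2", "B1")
  std_aois <- c("ST1", "ST2", "ST3", "SB3", "SB2", "SB1")
  cols <- list(
    list("far", "top", TRUE, c(37, 35, 23, 4, 0, 0)),
    list("far", "top", FALSE, c(16, 33, 16, 12, 11, 12)),
    list("far", "bottom", TRUE, c(0, 6, 2, 13, 30, 49)),
    list("far", "bottom", FALSE, c(5, 14, 22, 14, 16, 28)),
    list("standard", "top", TRUE, c(0, 20, 23, 28, 25, 2)),
    list("standard", "top", FALSE, c(3, 14, 8, 37, 22, 2)),
    list("standard", "bottom", TRUE, c(3, 13, 20, 37, 23, 4)),
    list("standard", "bottom", FALSE, c(3, 19, 27, 32, 18, 4))
  )
  dplyr::bind_rows(lapply(cols, function(cc) {
    tibble::tibble(
      gap_condition = cc[[1]],
      aoi = if (cc[[1]] == "far") far_aois else std_aois,
      correct_row = cc[[2]],
      cued = cc[[3]],
      pct = cc[[4]]
    )
  }))
}

#' Rank correlations of the published fixation distributions
#'
#' For each gap condition and cueing, computes the tie-corrected Spearman
#' correlation between the top-correct and bottom-correct fixation
#' percentage columns of [reference_fixation_distribution()]. Negative
#' correlations in the 15 deg condition and positive ones in the 0.32 deg
#' condition are the overt/covert dissociation signature.
#'
#' @return Tibble: `gap_condition`, `cued`, `rs`, `n_aoi`.
#' @export
#' @examples
#' reference_fixation_correlations()
reference_fixation_correlations <- function() {
  ref <- reference_fixation_distribution()
  ref |>
    dplyr::group_by(.data$gap_condition, .data$cued) |>
    dplyr::group_modify(function(df, key) {
      wide <- tidyr::pivot_wider(df[, c("aoi", "correct_row", "pct")],
                                 names_from = "correct_row",
                                 values_from = "pct")
      tibble::tibble(
        rs = spearman_tie_corrected(wide$top, wide$bottom),
        n_aoi = nrow(wide)
      )
    }) |>
    dplyr::ungroup()
}
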