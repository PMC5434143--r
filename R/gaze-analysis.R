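# From raw gaze streams to fixations, AOI visits, per-AOI conditional
# accuracy, fixation-distribution tables and distance-accuracy curves.

#' Velocity-threshold fixation detection
#'
#' Converts the gaze stream to degrees, computes velocity over a 3-sample
#' central difference, and turns maximal runs of below-threshold valid
#' samples spanning at least `min_duration_ms` into fixation events.
#' Invalid samples split runs. Defaults mirror the modelled tracker setup:
#' 40 deg/s saccade threshold, 100 ms minimum fixation duration.
#'
#' @param gaze Data frame with columns `t_ms`, `x_px`, `y_px`, `valid`,
#'   plus the grouping columns in `by`.
#' @param geometry A [display_geometry()] for the pixel-to-degree
#'   conversion.
#' @param velocity_threshold Saccade velocity threshold, deg/s.
#' @param min_duration_ms Minimum fixation duration, ms.
#' @param by Character vector of columns identifying one trial's stream.
#' @param map Optional [aoi_map()]; when given, an `aoi` label column is
#'   appended (classification by centroid).
#'
#' @return Tibble of fixation events: grouping columns, `start_ms`,
#'   `duration_ms`, `x_deg`, `y_deg` (centroid of valid samples) and
#'   optionally `aoi`. Groups with fewer than 3 valid samples contribute no
#'   events.
#' @export
detect_fixations <- function(gaze, geometry = display_geometry(),
                             velocity_threshold = 40,
                             min_duration_ms = 100,
                             by = c("subject_id", "session", "trial"),
                             map = NULL) {
  stopifnot(is.data.frame(gaze),
            all(c("t_ms", "x_px", "y_px", "valid") %in% names(gaze)))
  by <- intersect(by, names(gaze))
  gz <- pixel_to_degree(gaze, geometry)

  detect_one <- function(df) {
    df <- df[order(df$t_ms), ]
    n <- nrow(df)
    if (sum(df$valid) < 3L || n < 3L) return(NULL)
    x <- df$x_deg
    y <- df$y_deg
    t <- df$t_ms
    v <- rep(Inf, n)
    i <- 2:(n - 1)
    dt <- (t[i + 1] - t[i - 1]) / 1000
    v[i] <- sqrt((x[i + 1] - x[i - 1])^2 + (y[i + 1] - y[i - 1])^2) / dt
    v[1] <- v[2]
    v[n] <- v[n - 1]
    ok <- df$valid & is.finite(v) & v < velocity_threshold
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    res <- lapply(keep, function(k) {
      s <- starts[k]; e <- ends[k]
      span <- t[e] - t[s]
      if (span < min_duration_ms) return(NULL)
      idx <- s:e
      idx <- idx[df$valid[idx]]
      tibble::tibble(
        start_ms = t[s], duration_ms = span,
        x_deg = mean(x[idx]), y_deg = mean(y[idx])
      )
    })
    dplyr::bind_rows(res)
  }

  keys <- if (length(by)) interaction(gz[by], drop = TRUE, lex.order = TRUE) else
    factor(rep(1L, nrow(gz)))
  pieces <- lapply(split(seq_len(nrow(gz)), keys), function(ix) {
    ev <- detect_one(gz[ix, ])
    if (is.null(ev) || nrow(ev) == 0L) return(NULL)
    dplyr::bind_cols(gz[ix[seq_len(nrow(ev))], by, drop = FALSE], ev)
  })
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0L) {
    return(tibble::tibble(start_ms = numeric(), duration_ms = numeric(),
                          x_deg = numeric(), y_deg = numeric(),
                          aoi = character()))
  }
  if (!is.null(map)) {
    out$aoi <- assign_aoi(out, map)
  }
  dplyr::arrange(out, dplyr::across(dplyr::all_of(c(by, "start_ms"))))
}

#' Summarise detected fixations into per-trial AOI strings
#'
#' Collapses a fixation-event table into one row per trial with the
#' time-ordered AOI labels joined by `";"` (`NA` centroids become the
#' literal `"none"`), the schema the single-AOI filter consumes.
#'
#' @param fixations Fixation tibble from [detect_fixations()] (with `aoi`).
#' @param by Trial-identifying columns.
#' @return Tibble: `by` columns, `fixation_aois`, `n_fixations`.
#' @export
summarise_fixation_aois <- function(fixations,
                                    by = c("subject_id", "session", "trial")) {
  stopifnot("aoi" %in% names(fixations))
  fixations |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(by, "start_ms")))) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      fixation_aois = paste(ifelse(is.na(.data$aoi), "none", .data$aoi),
                            collapse = ";"),
      n_fixations = dplyr::n(),
      .groups = "drop"
    )
}

.split_aois <- function(s) strsplit(ifelse(is.na(s), "", s), ";", fixed = TRUE)

#' Restrict to trials whose fixations stayed in one AOI
#'
#' When a trial contains more than one point of regard it is impossible to
#' know which one supported the response, so such trials are dropped from
#' the AOI-conditional analyses. A fixation outside every AOI counts as a
#' distinct point of regard (conservative exclusion), as does a trial with
#' no detected fixation.
#'
#' @param trials Data frame with a `fixation_aois` column (";"-separated
#'   labels, `"none"` or `NA` for off-AOI fixations).
#'
#' @return Tibble of kept trials with a single `aoi` column added; the
#'   fraction excluded is attached as attribute `"excluded_fraction"` (also
#'   via [excluded_fraction()]).
#' @export
filter_single_aoi_trials <- function(trials) {
  stopifnot(is.data.frame(trials), "fixation_aois" %in% names(trials))
  labs <- .split_aois(trials$fixation_aois)
  single <- vapply(labs, function(l) {
    length(l) >= 1L && length(unique(l)) == 1L &&
      !any(l %in% c("none", "NA", "")) && !anyNA(l)
  }, logical(1L))
  out <- tibble::as_tibble(trials[single, , drop = FALSE])
  out$aoi <- vapply(labs[single], `[[`, character(1L), 1L)
  attr(out, "excluded_fraction") <- 1 - mean(single)
  out
}

#' @rdname filter_single_aoi_trials
#' @param x Result of [filter_single_aoi_trials()].
#' @export
excluded_fraction <- function(x) attr(x, "excluded_fraction")

#' Per-AOI conditional accuracy
#'
#' Pools trials (across subjects) and tabulates, for every combination of
#' AOI, correct row and cueing, the number of visits and the probability of
#' a correct response. Only AOIs visited at least `min_visits` times over
#' the whole data set are reported (sparser AOIs make the probabilities
#' meaningless); the unfiltered table is kept as attribute `"full"`. When a
#' `map` is supplied, each row also carries the angular distance from the
#' AOI midpoint to the trial's correct row (`distance_deg`, exactly 0 for
#' the region in which that stimulus is embedded).
#'
#' @param trials Single-AOI trials from [filter_single_aoi_trials()] (needs
#'   `aoi`, `correct_row`, `cued`, `response_correct`).
#' @param map Optional [aoi_map()] for midpoint distances.
#' @param layout Optional [stimulus_layout()] matching `map`.
#' @param min_visits Minimum total visits for an AOI to be reported.
#'
#' @return Tibble of class `aoi_accuracy`: `aoi`, `correct_row`, `cued`,
#'   `visits`, `correct`, `prob`, and `distance_deg` when `map` is given.
#' @export
per_aoi_accuracy <- function(trials, map = NULL, layout = NULL,
                             min_visits = 10L) {
  stopifnot(all(c("aoi", "correct_row", "cued", "response_correct") %in%
                  names(trials)))
  tab <- trials |>
    dplyr::group_by(.data$aoi, .data$correct_row, .data$cued) |>
    dplyr::summarise(
      visits = dplyr::n(),
      correct = sum(.data$response_correct),
      prob = mean(.data$response_correct),
      .groups = "drop"
    )
  if (!is.null(map)) {
    if (is.null(layout)) layout <- stimulus_layout(attr(map, "gap_condition"))
    dd <- dplyr::bind_rows(
      aoi_distances(map, "top", layout),
      aoi_distances(map, "bottom", layout)
    )
    tab <- dplyr::left_join(
      tab, dplyr::rename(dd, aoi = "label", correct_row = "target_row"),
      by = c("aoi", "correct_row")
    )
  }
  totals <- tab |>
    dplyr::group_by(.data$aoi) |>
    dplyr::summarise(total_visits = sum(.data$visits), .groups = "drop")
  tab <- dplyr::left_join(tab, totals, by = "aoi")
  out <- dplyr::filter(tab, .data$total_visits >= min_visits)
  out <- dplyr::select(out, -"total_visits")
  attr(out, "full") <- dplyr::select(tab, -"total_visits")
  class(out) <- c("aoi_accuracy", class(out))
  out
}

#' Fixation-distribution table
#'
#' Percentage of (single-AOI) fixations falling in each AOI, within each
#' cueing x correct-row condition. Percentages are column-normalised at
#' full precision; use `round_pct()` on the result for the integer display
#' convention (round half to even).
#'
#' @param trials Single-AOI trials (needs `aoi`, `correct_row`, `cued`).
#' @param map Optional [aoi_map()]; when given, unvisited AOIs appear with
#'   0% so every column covers all six regions.
#'
#' @return Tibble: `aoi`, `correct_row`, `cued`, `n`, `pct`.
#' @export
fixation_distribution <- function(trials, map = NULL) {
  stopifnot(all(c("aoi", "correct_row", "cued") %in% names(trials)))
  tab <- trials |>
    dplyr::count(.data$aoi, .data$correct_row, .data$cued, name = "n")
  if (!is.null(map)) {
    grid <- tidyr::expand_grid(
      aoi = map$label,
      correct_row = c("top", "bottom"),
      cued = unique(trials$cued)
    )
    tab <- dplyr::left_join(grid, tab, by = c("aoi", "correct_row", "cued")) |>
      dplyr::mutate(n = tidyr::replace_na(.data$n, 0L))
  }
  tab |>
    dplyr::group_by(.data$correct_row, .data$cued) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Round percentages for display (half to even)
#' @param pct Numeric vector of percentages.
#' @return Integer vector.
#' @export
round_pct <- function(pct) as.integer(round(pct))

#' Cumulative fixation time per AOI
#'
#' Time-weighted analogue of [per_aoi_accuracy()] that keeps multi-AOI
#' trials: visits are replaced by summed fixation durations and the
#' probability correct is duration-weighted. Also reports (as attribute
#' `"extra_time_fraction"`) the fraction of total fixation time spent in
#' AOIs absent from a reference single-fixation analysis.
#'
#' @param trials Trial table (any trials; needs `correct_row`, `cued`,
#'   `response_correct` and the `by` columns).
#' @param fixations AOI-labelled fixation events ([detect_fixations()] with
#'   `map`, or generator ground truth reshaped likewise).
#' @param by Trial-identifying columns shared by both tables.
#' @param reference_aois Optional character vector of AOIs present in the
#'   single-fixation analysis (e.g. `unique(acc_table$aoi)`).
#'
#' @return Tibble: `aoi`, `correct_row`, `cued`, `time_ms`, `prob`.
#' @export
cumulative_time_per_aoi <- function(trials, fixations,
                                    by = c("subject_id", "session", "trial"),
                                    reference_aois = NULL) {
  stopifnot("aoi" %in% names(fixations), "duration_ms" %in% names(fixations))
  joined <- dplyr::inner_join(
    fixations,
    dplyr::select(trials, dplyr::all_of(by), "correct_row", "cued",
                  "response_correct"),
    by = by
  )
  joined <- dplyr::filter(joined, !is.na(.data$aoi))
  out <- joined |>
    dplyr::group_by(.data$aoi, .data$correct_row, .data$cued) |>
    dplyr::summarise(
      time_ms = sum(.data$duration_ms),
      prob = stats::weighted.mean(.data$response_correct, .data$duration_ms),
      .groups = "drop"
    )
  if (!is.null(reference_aois)) {
    extra <- sum(out$time_ms[!out$aoi %in% reference_aois]) / sum(out$time_ms)
    attr(out, "extra_time_fraction") <- extra
  }
  out
}

#' Tie-corrected Spearman rank correlation
#'
#' Average ranks are assigned to ties and the Pearson correlation of the
#' rank vectors is returned. Pairs with a missing entry are dropped. With
#' only two pairs the coefficient is degenerate (always +1 or -1); this is
#' permitted because mutually exclusive two-AOI accuracy profiles are a
#' meaningful limiting case here, but interpret such values accordingly.
#'
#' @param x,y Numeric vectors of equal length (>= 2 complete pairs).
#'
#' @return Correlation in `[-1, 1]`, or `NA` (with a warning) when either
#'   rank vector has zero variance.
#' @export
#' @examples
#' spearman_tie_corrected(c(37, 35, 23, 4, 0, 0), c(0, 6, 2, 13, 30, 49))
spearman_tie_corrected <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 2L) {
    stop("need at least 2 complete pairs for a rank correlation", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("undefined correlation: a rank vector has zero variance",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(rx, ry)
}

#' Rank correlation between top- and bottom-correct accuracy profiles
#'
#' Reshapes a [per_aoi_accuracy()] table into paired per-AOI accuracy
#' profiles for top-correct and bottom-correct trials and correlates them.
#' A positive correlation means the same AOIs support correct responses to
#' both rows (covert attention shifts without eye movements); a negative
#' one means the supporting AOIs are disjoint (responses tied to overt
#' gaze).
#'
#' @param acc_table An `aoi_accuracy` tibble.
#' @param cued_only `NULL` for all rows, `TRUE`/`FALSE` to restrict to
#'   cued/uncued rows.
#' @param value Column to correlate (default `"prob"`; use `"pct"` with a
#'   [fixation_distribution()] table).
#'
#' @return One-row tibble: `rs`, `n_aoi`.
#' @export
accuracy_profile_correlation <- function(acc_table, cued_only = NULL,
                                         value = "prob") {
  tab <- acc_table
  if (!is.null(cued_only)) tab <- dplyr::filter(tab, .data$cued == cued_only)
  if (!is.null(cued_only) || !"cued" %in% names(tab)) {
    wide <- tidyr::pivot_wider(
      dplyr::select(tab, "aoi", "correct_row", dplyr::all_of(value)),
      names_from = "correct_row", values_from = dplyr::all_of(value)
    )
  } else {
    # pool over cueing by visit-weighted accuracy first
    tab <- tab |>
      dplyr::group_by(.data$aoi, .data$correct_row) |>
      dplyr::summarise(v = stats::weighted.mean(.data[[value]], .data$visits),
                       .groups = "drop")
    wide <- tidyr::pivot_wider(tab, names_from = "correct_row",
                               values_from = "v")
  }
  wide <- dplyr::filter(wide, !is.na(.data$top) & !is.na(.data$bottom))
  tibble::tibble(
    rs = if (nrow(wide) < 2L) NA_real_ else
      spearman_tie_corrected(wide$top, wide$bottom),
    n_aoi = nrow(wide)
  )
}

#' Accuracy as a function of fixation distance: linear and quadratic fits
#'
#' Ordinary least-squares fits (unweighted) of probability correct against
#' the AOI midpoint distance, for polynomial degrees 1 and 2, with
#' R-squared for each. The quadratic captures the floor imposed by the
#' 7-alternative probe (accuracy cannot fall to zero).
#'
#' @param acc_table An `aoi_accuracy` tibble carrying `distance_deg` (build
#'   with `per_aoi_accuracy(..., map = )`), or any data frame with
#'   `distance_deg` and `prob`.
#'
#' @return Object of class `distance_accuracy_fit`: list with `linear` and
#'   `quadratic` `lm` fits and the `data` used. `tidy()`, `glance()` and
#'   `autoplot()` methods are available.
#' @export
distance_accuracy_fit <- function(acc_table) {
  stopifnot(all(c("distance_deg", "prob") %in% names(acc_table)))
  dat <- tibble::as_tibble(acc_table)[, intersect(
    c("aoi", "correct_row", "cued", "visits", "distance_deg", "prob"),
    names(acc_table)
  )]
  dat <- dat[stats::complete.cases(dat$distance_deg, dat$prob), ]
  if (length(unique(dat$distance_deg)) < 3L) {
    stop("fit undefined: need at least 3 distinct distances", call. = FALSE)
  }
  structure(
    list(
      linear = stats::lm(prob ~ distance_deg, data = dat),
      quadratic = stats::lm(prob ~ distance_deg + I(distance_deg^2), data = dat),
      data = dat
    ),
    class = "distance_accuracy_fit"
  )
}

#' @export
print.distance_accuracy_fit <- function(x, ...) {
  r2 <- function(m) summary(m)$r.squared
  cat("Distance-accuracy fit (", nrow(x$data), " points)\n", sep = "")
  cat(sprintf("  linear   : R^2 = %.3f\n", r2(x$linear)))
  cat(sprintf("  quadratic: R^2 = %.3f\n", r2(x$quadratic)))
  invisible(x)
}
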