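# End-to-end orchestration: simulate a cohort to disk, analyse a cohort
# from disk (or in memory), with schema-checked CSV I/O.

.trial_obs_cols <- c(
  "subject_id", "gap_condition", "prob_top", "session", "trial", "cued",
  "cue_target", "correct_row", "digits_top", "digits_bottom", "probe_sums",
  "correct_sum", "response_correct", "exposure_ms", "n_fixations",
  "fixation_aois", "fix_x_deg", "fix_y_deg", "fix2_x_deg", "fix2_y_deg",
  "fix_distance_deg"
)
.trial_truth_cols <- c("subject_id", "session", "trial", "p_attend",
                       "attended_row")
.gaze_cols <- c("subject_id", "session", "trial", "t_ms", "x_px", "y_px",
                "valid")

.check_schema <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("schema mismatch in ", what, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Simulate a cohort and write it to disk
#'
#' Runs [simulate_cohort()] and writes `trials.csv` (observed fields),
#' `ground_truth.csv` (latent attention and attended rows), optionally
#' `gaze.csv` (500 Hz streams), and `config.json` (cohort layout, realised
#' subject parameters and the seed). Outputs are deterministic given the
#' seed.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer root seed.
#' @param cohort Cohort layout, see [default_cohort()].
#' @param gaze Also write gaze streams (large).
#' @param ... Passed to [simulate_cohort()].
#'
#' @return Invisibly, the [simulate_cohort()] result with a `paths`
#'   element added.
#' @export
simulate_experiment <- function(out_dir, seed = 1L, cohort = default_cohort(),
                                gaze = TRUE, ...) {
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    message("created output directory ", out_dir)
  }
  sim <- simulate_cohort(cohort, seed = seed, gaze = gaze, ...)
  paths <- list(
    trials = file.path(out_dir, "trials.csv"),
    ground_truth = file.path(out_dir, "ground_truth.csv"),
    gaze = if (gaze) file.path(out_dir, "gaze.csv"),
    config = file.path(out_dir, "config.json")
  )
  readr::write_csv(sim$trials[, .trial_obs_cols], paths$trials)
  readr::write_csv(sim$trials[, .trial_truth_cols], paths$ground_truth)
  if (gaze) readr::write_csv(sim$gaze[, .gaze_cols], paths$gaze)
  jsonlite::write_json(
    list(seed = seed, cohort = cohort, profiles = sim$profiles),
    paths$config, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  message(nrow(sim$trials), " trials written for ", nrow(cohort), " subjects")
  sim$paths <- paths
  invisible(sim)
}

#' Analyse an experiment (simulated or recorded)
#'
#' Full behavioural + gaze analysis: fixation detection (when a gaze table
#' is supplied; otherwise the trial table's `fixation_aois` plan is used),
#' single-AOI filtering, per-AOI conditional accuracy, fixation
#' distributions and their top/bottom rank correlations, distance-accuracy
#' fits, and the allocation analysis (per-subject estimates, median line,
#' matching-vs-maximizing, guess-rate test). Gap conditions are analysed
#' against their own AOI maps.
#'
#' @param trials Trial table or path to a `trials.csv`.
#' @param gaze Optional gaze table or path to a `gaze.csv`. When supplied,
#'   fixations are re-detected from the stream and override the trial
#'   table's AOI plan; an empty table degrades gracefully to the
#'   behavioural analysis.
#' @param out_dir Optional directory; when given, result tables are written
#'   as CSV and the reports as JSON.
#' @param geometry A [display_geometry()].
#' @param min_visits AOI inclusion threshold for the accuracy tables.
#' @param velocity_threshold,min_duration_ms Fixation-detector settings.
#'
#' @return Named list: `allocations`, `allocation_line`, `line_report`,
#'   `guess_rate_test`, and per gap condition `aoi_accuracy`,
#'   `fixation_distribution`, `profile_correlations`, `distance_fit`,
#'   `excluded_fraction`.
#' @export
analyze_experiment <- function(trials, gaze = NULL, out_dir = NULL,
                               geometry = display_geometry(),
                               min_visits = 10L,
                               velocity_threshold = 40,
                               min_duration_ms = 100) {
  if (is.character(trials)) {
    trials <- readr::read_csv(trials, show_col_types = FALSE)
  }
  .check_schema(trials, c("subject_id", "session", "trial", "cued",
                          "correct_row", "response_correct", "gap_condition"),
                "trials")
  trials <- tibble::as_tibble(trials)
  if (is.character(gaze)) {
    gaze <- readr::read_csv(gaze, show_col_types = FALSE)
  }
  if (!is.null(gaze) && nrow(gaze) == 0L) {
    warning("empty gaze table: proceeding on behavioural data only",
            call. = FALSE)
    gaze <- NULL
  }
  if (!is.null(gaze)) .check_schema(gaze, .gaze_cols, "gaze")

  out <- list()

  # --- behavioural / allocation block ---------------------------------
  out$allocations <- subject_allocations(trials)
  out$allocation_line <- fit_allocation_line(out$allocations)
  out$line_report <- matching_vs_maximizing(out$allocation_line)
  out$guess_rate_test <- test_guess_rate(out$allocations$g_hat)

  # --- gaze block, per gap condition ----------------------------------
  per_condition <- list()
  for (gc in unique(trials$gap_condition)) {
    tr <- dplyr::filter(trials, .data$gap_condition == gc)
    layout <- stimulus_layout(gc)
    map <- default_aoi_map(gc, geometry, layout)
    if (!is.null(gaze)) {
      gz <- dplyr::semi_join(gaze, tr, by = c("subject_id", "session", "trial"))
      fx <- detect_fixations(gz, geometry,
                             velocity_threshold = velocity_threshold,
                             min_duration_ms = min_duration_ms, map = map)
      plan <- summarise_fixation_aois(fx)
      tr <- tr |>
        dplyr::select(-dplyr::any_of(c("fixation_aois", "n_fixations"))) |>
        dplyr::left_join(plan, by = c("subject_id", "session", "trial"))
    } else {
      fx <- NULL
    }
    if (!"fixation_aois" %in% names(tr)) {
      warning("no fixation information for condition ", gc,
              "; AOI tables skipped", call. = FALSE)
      next
    }
    kept <- filter_single_aoi_trials(tr)
    acc <- per_aoi_accuracy(kept, map = map, layout = layout,
                            min_visits = min_visits)
    dist_tab <- fixation_distribution(kept, map = map)
    corrs <- dplyr::bind_rows(
      dplyr::mutate(accuracy_profile_correlation(acc, cued_only = TRUE),
                    cued = TRUE),
      dplyr::mutate(accuracy_profile_correlation(acc, cued_only = FALSE),
                    cued = FALSE)
    )
    dfit <- tryCatch(distance_accuracy_fit(acc), error = function(e) NULL)
    per_condition[[gc]] <- list(
      aoi_accuracy = acc,
      fixation_distribution = dist_tab,
      profile_correlations = corrs,
      distance_fit = dfit,
      excluded_fraction = excluded_fraction(kept),
      fixations = fx
    )
    message(sprintf(
      "condition %s: %d trials, %.1f%% excluded by the single-AOI filter",
      gc, nrow(tr), 100 * excluded_fraction(kept)
    ))
  }
  out$conditions <- per_condition

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(out$allocations, file.path(out_dir, "allocations.csv"))
    for (gc in names(per_condition)) {
      pc <- per_condition[[gc]]
      readr::write_csv(pc$aoi_accuracy,
                       file.path(out_dir, paste0("aoi_accuracy_", gc, ".csv")))
      readr::write_csv(pc$fixation_distribution,
                       file.path(out_dir, paste0("fixation_distribution_", gc, ".csv")))
    }
    report <- list(
      line = broom::tidy(out$allocation_line),
      line_report = out$line_report,
      guess_rate_test = out$guess_rate_test,
      correlations = lapply(per_condition, `[[`, "profile_correlations"),
      excluded_fraction = lapply(per_condition, `[[`, "excluded_fraction")
    )
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  out
}
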