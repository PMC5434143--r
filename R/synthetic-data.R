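# Synthetic experiment generator.
#
# Emulates the two-row attention experiment end to end: subjects assigned to
# a gap condition (0.32 or 15 deg) and one of four top-row probabilities
# {0.10, 0.25, 0.75, 0.90}, two sessions of 22 cued + 110 uncued trials,
# staircase-calibrated exposure times, and 500 Hz gaze streams with planted
# fixations, so the whole analysis pipeline can be exercised against known
# ground truth.

#' Effective-field-of-view accuracy decay
#'
#' Multiplicative decay applied to cued-trial accuracy as a function of the
#' angular distance between the fixation and the target row. Flat (1) out to
#' `d0`, then linearly decreasing, with a floor at the guess rate so that
#' performance never drops below chance on the 7-alternative probe. The knee
#' at 1.25 deg and the gentle fall-off keep accuracy near 0.8 over the
#' 1.25-5 deg range, matching the effective-field-of-view literature for
#' college-age observers.
#'
#' @param d Angular distance in degrees. Vectorised.
#' @param g Floor (guess rate), default 1/7.
#' @param d0 Flat-region radius in degrees.
#' @param d_max Distance at which the floor is reached.
#'
#' @return Numeric vector of multipliers in `[g, 1]`.
#' @export
#' @examples
#' fov_decay(c(0, 3, 12))
fov_decay <- function(d, g = 1 / 7, d0 = 1.25, d_max = 12) {
  stopifnot(d_max > d0, all(d >= 0))
  pmax(g, pmin(1, 1 - (1 - g) * (d - d0) / (d_max - d0)))
}

#' Subject profile
#'
#' Bundle of latent parameters controlling one synthetic subject.
#'
#' @param id Subject identifier.
#' @param gap_condition `"standard"` (0.32 deg) or `"far"` (15 deg).
#' @param prob_top Programmed probability that the top row is correct; one
#'   of 0.10, 0.25, 0.75, 0.90 in the modelled design (other values in
#'   (0, 1) are allowed for simulation studies).
#' @param p_asymptote Asymptotic attention allocation to the top row. When
#'   `NULL`, set by the allocation rule
#'   `allocation_intercept + allocation_slope * prob_top`, clamped to
#'   `[0.02, 0.98]`.
#' @param allocation_intercept,allocation_slope Allocation rule mapping the
#'   programmed probability to the attention asymptote. The defaults
#'   (0.15, 0.78) are probability matching with the undermatching observed
#'   in unrewarded human cohorts; `(0, 1)` is exact matching.
#' @param learning_rate Per-trial exponential approach rate towards
#'   `p_asymptote` from the 0.5 starting point; `Inf` means attention sits
#'   at the asymptote from trial one.
#' @param A_true True cued-trial accuracy (response accuracy when the
#'   attended row is the correct one and fixation is on target).
#' @param g_true True correct-guess rate; 1/7 for the 7-alternative probe.
#' @param exposure_ms Stimulus exposure. `NULL` means "determine by
#'   staircase calibration" (see [calibrate_exposure()]).
#' @param two_fixation_rate Probability that a trial contains two points of
#'   regard (a second >= 100 ms fixation in a neighbouring AOI).
#' @param fixation_jitter_deg Scale of the slow oculomotor drift within a
#'   fixation (degrees; 0 gives perfectly static samples).
#' @param wander_rate Far condition only: probability that the fixation
#'   lands on the *other* row's stimulus region instead of the attended
#'   row's (anticipation errors).
#' @param scatter_deg Standard condition only: s.d. of the central fixation
#'   placement around the screen centre.
#' @param countdown_ms Duration of the preparatory countdown epoch included
#'   in the gaze stream (the fixation clock runs during the countdown).
#' @param threshold_ms Psychometric midpoint of the subject's cued accuracy
#'   as a function of exposure (used by calibration); `NULL` draws one
#'   uniformly from 120-152 ms.
#'
#' @return A list of class `subject_profile`.
#' @export
subject_profile <- function(id,
                            gap_condition = c("standard", "far"),
                            prob_top = 0.75,
                            p_asymptote = NULL,
                            allocation_intercept = 0.15,
                            allocation_slope = 0.78,
                            learning_rate = 0.1,
                            A_true = 0.91,
                            g_true = 1 / 7,
                            exposure_ms = NULL,
                            two_fixation_rate = 0.22,
                            fixation_jitter_deg = 0.3,
                            wander_rate = 0.05,
                            scatter_deg = 2,
                            countdown_ms = 1000,
                            threshold_ms = NULL) {
  gap_condition <- match.arg(gap_condition)
  stopifnot(prob_top > 0, prob_top < 1,
            A_true >= 0, A_true <= 1, g_true >= 0, g_true <= 1,
            two_fixation_rate >= 0, two_fixation_rate <= 1,
            fixation_jitter_deg >= 0, wander_rate >= 0, wander_rate <= 1)
  if (is.null(p_asymptote)) {
    p_asymptote <- min(0.98, max(0.02,
                                 allocation_intercept + allocation_slope * prob_top))
  }
  stopifnot(p_asymptote >= 0, p_asymptote <= 1)
  if (!is.null(exposure_ms)) {
    stopifnot(exposure_ms >= 100, exposure_ms <= 300)
  }
  structure(
    list(
      id = as.character(id), gap_condition = gap_condition,
      prob_top = prob_top, p_asymptote = p_asymptote,
      learning_rate = learning_rate, A_true = A_true, g_true = g_true,
      exposure_ms = exposure_ms, two_fixation_rate = two_fixation_rate,
      fixation_jitter_deg = fixation_jitter_deg, wander_rate = wander_rate,
      scatter_deg = scatter_deg, countdown_ms = countdown_ms,
      threshold_ms = threshold_ms
    ),
    class = "subject_profile"
  )
}

#' Default 16-subject cohort layout
#'
#' Eight subjects per gap condition, two per top-row probability setting —
#' the design of the modelled experiment.
#'
#' @param prob_settings Top-row probability settings.
#' @return Tibble with `subject_id`, `gap_condition`, `prob_top`.
#' @export
default_cohort <- function(prob_settings = c(0.10, 0.25, 0.75, 0.90)) {
  grid <- tidyr::expand_grid(
    gap_condition = c("standard", "far"),
    prob_top = prob_settings,
    replicate = 1:2
  )
  tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(nrow(grid))),
    gap_condition = grid$gap_condition,
    prob_top = grid$prob_top
  )
}

#' Generate one stimulus/probe screen
#'
#' Each row holds three digits drawn uniformly from 1-9 (rows are redrawn
#' until their sums differ). The probe screen lists seven distinct integers
#' in `[3, 27]`: exactly one equals the correct row's sum and none equals
#' the incorrect row's sum — without the latter exclusion the uniform
#' correct-guess rate would not be 1/7. Label order is randomised.
#'
#' @param correct_row `"top"` or `"bottom"`.
#' @return List with `digits_top`, `digits_bottom` (integer triplets),
#'   `probe_sums` (7 integers) and `correct_sum`.
#' @export
generate_stimulus <- function(correct_row = c("top", "bottom")) {
  correct_row <- match.arg(correct_row)
  repeat {
    digits_top <- sample.int(9L, 3L, replace = TRUE)
    digits_bottom <- sample.int(9L, 3L, replace = TRUE)
    if (sum(digits_top) != sum(digits_bottom)) break
  }
  correct_sum <- if (correct_row == "top") sum(digits_top) else sum(digits_bottom)
  wrong_sum <- if (correct_row == "top") sum(digits_bottom) else sum(digits_top)
  pool <- setdiff(3:27, c(correct_sum, wrong_sum))
  probe <- sample(c(correct_sum, sample(pool, 6L)))
  list(digits_top = digits_top, digits_bottom = digits_bottom,
       probe_sums = probe, correct_sum = correct_sum)
}

#' Simulate a response
#'
#' If the attended row is the correct one, the response is correct with
#' probability `A_true * fov_decay(d)`; otherwise the subject holds no
#' usable sum and guesses by picking one of the seven probe entries
#' uniformly — correct exactly when the pick equals the correct sum, so the
#' 1/7 guess rate is emergent rather than assumed.
#'
#' @param attended_correct Logical: was the attended row the correct one?
#'   Vectorised.
#' @param fixation_distance_deg Distance from the (primary) fixation to the
#'   correct row's centre, degrees.
#' @param A_true,g_true Subject accuracy and guess-rate parameters.
#' @param probe_sums Optional 7-column integer matrix of probe screens (one
#'   row per trial) used for mechanistic guessing; when `NULL`, guesses are
#'   Bernoulli(`g_true`) draws.
#' @param correct_sum Integer vector of correct sums (needed with
#'   `probe_sums`).
#' @param ... Passed to [fov_decay()].
#'
#' @return Logical vector of response correctness.
#' @export
simulate_response <- function(attended_correct, fixation_distance_deg,
                              A_true = 0.91, g_true = 1 / 7,
                              probe_sums = NULL, correct_sum = NULL, ...) {
  n <- length(attended_correct)
  fixation_distance_deg <- rep_len(fixation_distance_deg, n)
  p_hit <- A_true * fov_decay(fixation_distance_deg, g = g_true, ...)
  out <- logical(n)
  att <- which(attended_correct)
  out[att] <- stats::runif(length(att)) < p_hit[att]
  miss <- which(!attended_correct)
  if (length(miss)) {
    if (!is.null(probe_sums)) {
      stopifnot(!is.null(correct_sum), ncol(probe_sums) == 7L)
      pick <- sample.int(7L, length(miss), replace = TRUE)
      out[miss] <- probe_sums[cbind(miss, pick)] == correct_sum[miss]
    } else {
      out[miss] <- stats::runif(length(miss)) < g_true
    }
  }
  out
}

# Clamp a point into a region's rectangle, keeping a small margin.
.clamp_into <- function(x, y, region, margin = 0.15) {
  mx <- pmin(margin, (region$x_max - region$x_min) / 4)
  my <- pmin(margin, (region$y_max - region$y_min) / 4)
  list(
    x = pmin(region$x_max - mx, pmax(region$x_min + mx, x)),
    y = pmin(region$y_max - my, pmax(region$y_min + my, y))
  )
}

#' Generate one session of trials
#'
#' A session is 132 trials: 22 cued (cue matches the correct row) and 110
#' uncued, interleaved uniformly at random. The correct row is Bernoulli in
#' the subject's `prob_top` on every trial. Latent attention on uncued
#' trials follows an exponential approach from 0.5 to the subject's
#' asymptote, `p_t = p_inf + (0.5 - p_inf) exp(-lambda (t - 1))`; on cued
#' trials the cued row is attended. Each trial also carries a fixation plan
#' (AOI labels and fixation points) realised later by [generate_gaze()]:
#' far-condition subjects fixate the attended row's stimulus region (the
#' other row's with probability `wander_rate`); standard-condition subjects
#' hold a central fixation scattered around the screen centre regardless of
#' covert attention. With probability `two_fixation_rate` a second point of
#' regard in a neighbouring AOI precedes the primary fixation.
#'
#' @param profile A [subject_profile()]. Its `exposure_ms` must be set (run
#'   [calibrate_exposure()] first, or rely on the 158 ms fallback).
#' @param session Session index (1 or 2).
#' @param n_cued,n_uncued Trial counts.
#' @param map,geometry,layout Geometry objects; defaults follow
#'   `profile$gap_condition`.
#'
#' @return Tibble with one row per trial: identifiers, condition, stimulus
#'   digits and probe sums (";"-separated), response correctness, the
#'   fixation plan (`fixation_aois`, fixation points, `fix_distance_deg`)
#'   and the latent ground truth (`p_attend`, `attended_row`).
#' @export
generate_session <- function(profile, session = 1L,
                             n_cued = 22L, n_uncued = 110L,
                             map = NULL, geometry = display_geometry(),
                             layout = NULL) {
  stopifnot(inherits(profile, "subject_profile"))
  if (is.null(layout)) layout <- stimulus_layout(profile$gap_condition)
  if (is.null(map)) map <- default_aoi_map(profile$gap_condition, geometry, layout)
  exposure <- profile$exposure_ms %||% 158
  n <- n_cued + n_uncued
  cued <- rep(FALSE, n)
  cued[sample.int(n, n_cued)] <- TRUE

  correct_row <- ifelse(stats::runif(n) < profile$prob_top, "top", "bottom")
  t_idx <- seq_len(n)
  decay <- if (is.infinite(profile$learning_rate)) 0 else
    exp(-profile$learning_rate * (t_idx - 1))
  p_t <- profile$p_asymptote + (0.5 - profile$p_asymptote) * decay
  attended_row <- ifelse(cued, correct_row,
                         ifelse(stats::runif(n) < p_t, "top", "bottom"))

  stim <- lapply(correct_row, generate_stimulus)
  probe_mat <- t(vapply(stim, `[[`, integer(7L), "probe_sums"))
  correct_sum <- vapply(stim, `[[`, integer(1L), "correct_sum")

  # --- fixation plan ---------------------------------------------------
  if (profile$gap_condition == "far") {
    fix_row <- ifelse(stats::runif(n) < profile$wander_rate,
                      ifelse(attended_row == "top", "bottom", "top"),
                      attended_row)
    ctr <- row_center(layout, fix_row)
    fx <- stats::rnorm(n, ctr[, "x"], 0.4)
    fy <- stats::rnorm(n, ctr[, "y"], 0.4)
    reg_idx <- match(fix_row, map$stimulus_row)
    cl <- .clamp_into(fx, fy, map[reg_idx, ])
    fx <- cl$x; fy <- cl$y
  } else {
    half <- screen_half_extent_deg(geometry)
    fx <- pmin(half[["x"]] * 0.98, pmax(-half[["x"]] * 0.98,
               stats::rnorm(n, 0, profile$scatter_deg / 2)))
    fy <- pmin(half[["y"]] * 0.98, pmax(-half[["y"]] * 0.98,
               stats::rnorm(n, 0, profile$scatter_deg)))
  }
  fix_aoi <- assign_aoi(x = fx, y = fy, map = map)

  two_fix <- stats::runif(n) < profile$two_fixation_rate
  idx <- match(fix_aoi, map$label)
  up <- pmax(1L, idx - 1L)
  down <- pmin(nrow(map), idx + 1L)
  nb <- ifelse(stats::runif(n) < 0.5, up, down)
  nb <- ifelse(nb == idx, ifelse(idx == 1L, 2L, idx - 1L), nb) # edge bands
  mx <- (map$x_min + map$x_max) / 2
  my <- (map$y_min + map$y_max) / 2
  f2x <- ifelse(two_fix, stats::rnorm(n, mx[nb], 0.3), NA_real_)
  f2y <- ifelse(two_fix, stats::rnorm(n, my[nb], 0.3), NA_real_)
  if (any(two_fix)) {
    cl2 <- .clamp_into(f2x[two_fix], f2y[two_fix], map[nb[two_fix], ])
    f2x[two_fix] <- cl2$x; f2y[two_fix] <- cl2$y
  }
  fix2_aoi <- ifelse(two_fix, map$label[nb], NA_character_)

  tgt <- row_center(layout, correct_row)
  d <- sqrt((fx - tgt[, "x"])^2 + (fy - tgt[, "y"])^2)
  correct <- simulate_response(attended_row == correct_row, d,
                               A_true = profile$A_true, g_true = profile$g_true,
                               probe_sums = probe_mat, correct_sum = correct_sum)

  tibble::tibble(
    subject_id = profile$id,
    gap_condition = profile$gap_condition,
    prob_top = profile$prob_top,
    session = as.integer(session),
    trial = t_idx,
    cued = cued,
    cue_target = ifelse(cued, correct_row, "none"),
    correct_row = correct_row,
    digits_top = vapply(stim, function(s) paste(s$digits_top, collapse = ";"), ""),
    digits_bottom = vapply(stim, function(s) paste(s$digits_bottom, collapse = ";"), ""),
    probe_sums = apply(probe_mat, 1L, paste, collapse = ";"),
    correct_sum = correct_sum,
    response_correct = correct,
    exposure_ms = exposure,
    n_fixations = 1L + as.integer(two_fix),
    fixation_aois = ifelse(two_fix, paste(fix2_aoi, fix_aoi, sep = ";"), fix_aoi),
    fix_x_deg = fx, fix_y_deg = fy,
    fix2_x_deg = f2x, fix2_y_deg = f2y,
    fix_distance_deg = d,
    p_attend = ifelse(cued, NA_real_, p_t),
    attended_row = attended_row
  )
}

#' Staircase calibration of the stimulus exposure
#'
#' Finds the shortest exposure supporting at least 85% correct on cued
#' trials while 50:50 uncued performance stays inside the binomial 95% band
#' of chance-level (one-stimulus) performance. Starting from 250 ms, blocks
#' of 40 trials (three quarters cued) are simulated and the duration is
#' reduced in 15 ms steps (snapped to the 2 ms frame grid) while both
#' criteria hold; the last passing duration is returned.
#'
#' The subject's cued accuracy as a function of exposure is a logistic,
#' `0.5 + (a_max - 0.5) * plogis((ms - t50) / 6)` with
#' `a_max = min(0.97, A_true + 0.06)`; a custom curve can be supplied via
#' `cued_acc_fn`.
#'
#' @param profile A [subject_profile()].
#' @param cued_acc_fn Optional function `ms -> probability` overriding the
#'   built-in psychometric.
#' @param start_ms,step_ms,block,cued_frac Staircase parameters.
#' @param min_ms,max_ms Admissible exposure range.
#'
#' @return Exposure duration in ms (even integer).
#' @export
calibrate_exposure <- function(profile, cued_acc_fn = NULL,
                               start_ms = 250, step_ms = 15,
                               block = 40L, cued_frac = 0.75,
                               min_ms = 100, max_ms = 300) {
  stopifnot(inherits(profile, "subject_profile"), start_ms <= max_ms)
  t50 <- profile$threshold_ms %||% stats::runif(1, 120, 152)
  a_max <- min(0.97, profile$A_true + 0.06)
  acc <- cued_acc_fn %||% function(ms) {
    0.5 + (a_max - 0.5) * stats::plogis((ms - t50) / 6)
  }
  snap <- function(ms) 2 * round(ms / 2)
  n_cued <- round(block * cued_frac)
  n_unc <- block - n_cued

  block_ok <- function(ms) {
    a <- acc(ms)
    cued_obs <- stats::rbinom(1L, n_cued, a) / n_cued
    p_unc <- 0.5 * a + 0.5 * profile$g_true
    p_ref <- 0.5 * acc(max_ms) + 0.5 * profile$g_true
    band <- stats::qbinom(c(0.025, 0.975), n_unc, p_ref)
    unc_obs <- stats::rbinom(1L, n_unc, p_unc)
    cued_obs >= 0.85 && unc_obs >= band[1] && unc_obs <= band[2]
  }

  ms <- snap(start_ms)
  if (acc(ms) < 0.85) {
    stop("calibration failure: no exposure in [", min_ms, ", ", max_ms,
         "] ms satisfies the accuracy criteria", call. = FALSE)
  }
  # a failing block is re-tested once before the staircase stops (single
  # noisy blocks should not end the descent)
  step_ok <- function(ms) block_ok(ms) || block_ok(ms)
  last_ok <- ms
  repeat {
    ms <- snap(ms - step_ms)
    if (ms < min_ms || !step_ok(ms)) break
    last_ok <- ms
  }
  last_ok
}

#' Realise the 500 Hz gaze stream for planned trials
#'
#' Expands each trial's fixation plan into a 2 ms-spaced gaze stream
#' spanning the countdown and stimulus epochs. Within a fixation, samples
#' follow a slow random-walk drift (step s.d. `fixation_jitter_deg / 33`
#' per sample), so velocities stay far below the 40 deg/s saccade
#' threshold; two-fixation trials place the secondary fixation first,
#' linked to the primary one by a 20 ms linear saccade whose velocity
#' exceeds the threshold by construction. Positions are written in pixels
#' (origin top-left, +y down), as an eye tracker would.
#'
#' @param trials Trial tibble from [generate_session()] (any subset).
#' @param profile The matching [subject_profile()].
#' @param geometry A [display_geometry()].
#'
#' @return Tibble: `subject_id`, `session`, `trial`, `t_ms`, `x_px`,
#'   `y_px`, `valid`.
#' @export
generate_gaze <- function(trials, profile, geometry = display_geometry()) {
  stopifnot(is.data.frame(trials), inherits(profile, "subject_profile"))
  step_sd <- profile$fixation_jitter_deg / 33
  countdown <- profile$countdown_ms
  one_trial <- function(i) {
    tr <- trials[i, ]
    total <- countdown + tr$exposure_ms
    t_ms <- seq(0, total - 2, by = 2)
    ns <- length(t_ms)
    drift <- function(k, x0, y0) {
      if (k <= 0) return(cbind(x = numeric(0), y = numeric(0)))
      cbind(x = x0 + cumsum(stats::rnorm(k, 0, step_sd)),
            y = y0 + cumsum(stats::rnorm(k, 0, step_sd)))
    }
    if (tr$n_fixations == 2L) {
      n2 <- 240L                       # 480 ms secondary dwell
      nsac <- 10L                      # 20 ms saccade
      n1 <- ns - n2 - nsac
      seg2 <- drift(n2, tr$fix2_x_deg, tr$fix2_y_deg)
      seg1 <- drift(n1, tr$fix_x_deg, tr$fix_y_deg)
      from <- seg2[n2, ]
      to <- seg1[1, ]
      w <- seq_len(nsac) / (nsac + 1)
      sac <- cbind(x = from[["x"]] + w * (to[["x"]] - from[["x"]]),
                   y = from[["y"]] + w * (to[["y"]] - from[["y"]]))
      pos <- rbind(seg2, sac, seg1)
    } else {
      pos <- drift(ns, tr$fix_x_deg, tr$fix_y_deg)
    }
    px <- degree_to_pixel(tibble::tibble(x_deg = pos[, "x"], y_deg = pos[, "y"]),
                          geometry)
    tibble::tibble(
      subject_id = tr$subject_id, session = tr$session, trial = tr$trial,
      t_ms = t_ms, x_px = px$x_px, y_px = px$y_px, valid = TRUE
    )
  }
  dplyr::bind_rows(lapply(seq_len(nrow(trials)), one_trial))
}

#' Simulate a full cohort
#'
#' Drives [calibrate_exposure()], [generate_session()] and (optionally)
#' [generate_gaze()] for every subject in a cohort layout. All randomness
#' flows from `seed`: per-subject child seeds are drawn deterministically
#' from the root stream, so any subject's data can be regenerated
#' bit-for-bit.
#'
#' @param cohort Tibble with `subject_id`, `gap_condition`, `prob_top`
#'   (see [default_cohort()]).
#' @param seed Integer root seed.
#' @param sessions Number of sessions per subject.
#' @param n_cued,n_uncued Trials per session.
#' @param gaze Also synthesise 500 Hz gaze streams? (Substantially larger
#'   output; behavioural analyses only need the trial table.)
#' @param calibrate Run the exposure staircase per subject? Otherwise a
#'   fixed 158 ms exposure is used.
#' @param ... Further arguments passed to [subject_profile()]
#'   (e.g. `learning_rate`, `A_true`, `two_fixation_rate`).
#'
#' @return List with elements `trials` (tibble), `gaze` (tibble or `NULL`),
#'   `profiles` (tibble of realised subject parameters) and `seed`.
#' @export
#' @examples
#' sim <- simulate_cohort(default_cohort()[1:2, ], seed = 7, sessions = 1)
#' dplyr::count(sim$trials, subject_id, cued)
simulate_cohort <- function(cohort = default_cohort(), seed = 1L,
                            sessions = 2L, n_cued = 22L, n_uncued = 110L,
                            gaze = FALSE, calibrate = TRUE, ...) {
  stopifnot(is.data.frame(cohort),
            all(c("subject_id", "gap_condition", "prob_top") %in% names(cohort)))
  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, nrow(cohort))
  geometry <- display_geometry()

  all_trials <- vector("list", nrow(cohort))
  all_gaze <- vector("list", nrow(cohort))
  prof_rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    set.seed(child_seeds[i])
    profile <- subject_profile(
      id = cohort$subject_id[i],
      gap_condition = cohort$gap_condition[i],
      prob_top = cohort$prob_top[i],
      ...
    )
    if (is.null(profile$exposure_ms)) {
      profile$exposure_ms <- if (calibrate) calibrate_exposure(profile) else 158
    }
    trs <- dplyr::bind_rows(lapply(seq_len(sessions), function(s) {
      generate_session(profile, session = s, n_cued = n_cued,
                       n_uncued = n_uncued, geometry = geometry)
    }))
    all_trials[[i]] <- trs
    if (gaze) all_gaze[[i]] <- generate_gaze(trs, profile, geometry)
    prof_rows[[i]] <- tibble::tibble(
      subject_id = profile$id, gap_condition = profile$gap_condition,
      prob_top = profile$prob_top, p_asymptote = profile$p_asymptote,
      learning_rate = profile$learning_rate, A_true = profile$A_true,
      g_true = profile$g_true, exposure_ms = profile$exposure_ms,
      two_fixation_rate = profile$two_fixation_rate,
      child_seed = child_seeds[i]
    )
  }
  list(
    trials = dplyr::bind_rows(all_trials),
    gaze = if (gaze) dplyr::bind_rows(all_gaze) else NULL,
    profiles = dplyr::bind_rows(prof_rows),
    seed = seed
  )
}

#' Monte-Carlo estimate of the correct-guess rate
#'
#' Simulates wrong-row attendance: stimuli and probe screens are generated
#' by [generate_stimulus()] and the subject picks one of the seven probe
#' entries uniformly. The long-run fraction correct converges to 1/7.
#'
#' @param n Number of simulated guesses.
#' @param n_stimuli Number of distinct stimulus screens to generate (trials
#'   resample from these).
#' @return Fraction of correct guesses.
#' @export
simulate_guess_rate <- function(n = 1e5, n_stimuli = min(n, 2000L)) {
  stim <- lapply(sample(c("top", "bottom"), n_stimuli, replace = TRUE),
                 generate_stimulus)
  probe <- t(vapply(stim, `[[`, integer(7L), "probe_sums"))
  cs <- vapply(stim, `[[`, integer(1L), "correct_sum")
  idx <- sample.int(n_stimuli, n, replace = TRUE)
  pick <- sample.int(7L, n, replace = TRUE)
  mean(probe[cbind(idx, pick)] == cs[idx])
}
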