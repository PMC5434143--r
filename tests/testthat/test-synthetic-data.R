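test_that("stimulus screens satisfy the probe constraints", {
  withr::local_seed(21)
  for (i in 1:300) {
    row <- sample(c("top", "bottom"), 1)
    st <- generate_stimulus(row)
    correct <- if (row == "top") sum(st$digits_top) else sum(st$digits_bottom)
    wrong <- if (row == "top") sum(st$digits_bottom) else sum(st$digits_top)
    expect_equal(sum(st$probe_sums == correct), 1L)
    expect_false(wrong %in% st$probe_sums)
    expect_equal(length(unique(st$probe_sums)), 7L)
    expect_true(all(st$probe_sums >= 3 & st$probe_sums <= 27))
    expect_true(all(st$digits_top %in% 1:9 & st$digits_bottom %in% 1:9))
  }
})

test_that("correct-row sums follow the enumerated three-digit distribution", {
  withr::local_seed(22)
  sums <- vapply(1:5000, function(i) generate_stimulus("top")$correct_sum, 0L)
  expected <- digit_sum_distribution()
  obs <- table(factor(sums, levels = names(expected)))
  # conditioning on unequal row sums barely perturbs the marginal
  chi <- suppressWarnings(chisq.test(obs, p = as.numeric(expected)))
  expect_gt(chi$p.value, 0.01)
})

test_that("sessions have the designed trial structure", {
  withr::local_seed(23)
  prof <- far_profile()
  tr <- generate_session(prof, 1)
  expect_equal(nrow(tr), 132L)
  expect_equal(sum(tr$cued), 22L)
  expect_equal(sum(!tr$cued), 110L)
  expect_true(all(tr$cue_target[tr$cued] == tr$correct_row[tr$cued]))
  expect_true(all(tr$cue_target[!tr$cued] == "none"))
  expect_true(all(tr$attended_row[tr$cued] == tr$correct_row[tr$cued]))
})

test_that("the programmed top-row probability is respected", {
  withr::local_seed(24)
  prof <- subject_profile("S1", "standard", 0.75, exposure_ms = 158)
  tr <- dplyr::bind_rows(lapply(1:40, function(s) generate_session(prof, s)))
  expect_lt(abs(mean(tr$correct_row == "top") - 0.75), 0.02)
})

test_that("infinite learning rate pins attention at the asymptote", {
  withr::local_seed(25)
  prof <- subject_profile("S1", "standard", 0.9, learning_rate = Inf,
                          exposure_ms = 158)
  tr <- generate_session(prof, 1)
  expect_true(all(tr$p_attend[!tr$cued] == prof$p_asymptote))
  # finite rate: approach from 0.5 towards the asymptote
  prof2 <- subject_profile("S1", "standard", 0.9, learning_rate = 0.05,
                           exposure_ms = 158)
  tr2 <- generate_session(prof2, 1)
  p <- tr2$p_attend[!tr2$cued]
  expect_equal(tr2$p_attend[which(!tr2$cued)[1]],
               prof2$p_asymptote + (0.5 - prof2$p_asymptote) *
                 exp(-0.05 * (which(!tr2$cued)[1] - 1)))
  expect_true(all(diff(p) >= 0))
})

test_that("wrong-row attendance yields the 1/7 guess rate mechanistically", {
  withr::local_seed(26)
  stim <- lapply(1:2000, function(i) generate_stimulus("top"))
  probe <- t(vapply(stim, `[[`, integer(7L), "probe_sums"))
  cs <- vapply(stim, `[[`, integer(1L), "correct_sum")
  idx <- sample.int(2000, 1e4, replace = TRUE)
  got <- simulate_response(rep(FALSE, 1e4), 0, probe_sums = probe[idx, ],
                           correct_sum = cs[idx])
  expect_lt(abs(mean(got) - 1 / 7), 0.01)
})

test_that("attending the correct row follows the field-of-view decay", {
  withr::local_seed(27)
  # at fixation, perfect accuracy is perfect
  expect_true(all(simulate_response(rep(TRUE, 200), 0, A_true = 1)))
  # in the 1.25-5 deg annulus accuracy sits near 0.8
  got <- simulate_response(rep(TRUE, 2e4), 3, A_true = 0.91)
  expect_lt(abs(mean(got) - 0.91 * fov_decay(3)), 0.01)
  expect_gt(mean(got), 0.75)
  expect_lt(mean(got), 0.85)
})

test_that("fov_decay is flat, then linear, then floored", {
  expect_equal(fov_decay(c(0, 0.5, 1.25)), c(1, 1, 1))
  expect_equal(fov_decay(12), 1 / 7)
  expect_equal(fov_decay(20), 1 / 7)
  d <- seq(0, 15, by = 0.1)
  expect_true(all(diff(fov_decay(d)) <= 0))
})

test_that("exposure staircase honours a deterministic step-function observer", {
  withr::local_seed(28)
  prof <- far_profile()
  step_fn <- function(ms) ifelse(ms > 150, 1.0, 0.5)
  got <- calibrate_exposure(prof, cued_acc_fn = step_fn)
  expect_gte(got, 150)
  expect_lte(got, 165)
  expect_equal(got %% 2, 0)
})

test_that("default calibrated exposures land in the observed percentile band", {
  sim <- simulate_cohort(seed = 29, gaze = FALSE, sessions = 1,
                         n_cued = 2, n_uncued = 2)
  q <- quantile(sim$profiles$exposure_ms, c(0.2, 0.5, 0.8))
  expect_true(all(q >= 135 & q <= 180))
})

test_that("an observer too inaccurate to calibrate raises an error", {
  withr::local_seed(30)
  prof <- subject_profile("S1", "far", 0.75, A_true = 0.3)
  expect_error(calibrate_exposure(prof), "calibration failure")
})

test_that("gaze streams are 500 Hz, reproducible, and static at zero jitter", {
  prof <- far_profile(fixation_jitter_deg = 0, two_fixation_rate = 0)
  set.seed(31)
  tr <- generate_session(prof, 1)[1:5, ]
  set.seed(32)
  gz <- generate_gaze(tr, prof)
  expect_true(all(unlist(tapply(gz$t_ms, gz$trial, diff)) == 2))
  one <- gz[gz$trial == tr$trial[1], ]
  expect_equal(length(unique(one$x_px)), 1L)
  expect_equal(length(unique(one$y_px)), 1L)
  # reproducibility from the seed
  set.seed(32)
  gz2 <- generate_gaze(tr, prof)
  expect_identical(gz, gz2)
})

test_that("two-fixation frequency matches the generator parameter", {
  withr::local_seed(33)
  prof <- subject_profile("S1", "far", 0.75, exposure_ms = 158,
                          two_fixation_rate = 0.22)
  tr <- dplyr::bind_rows(lapply(1:76, function(s) generate_session(prof, s)))
  expect_gte(nrow(tr), 1e4)
  expect_lt(abs(mean(tr$n_fixations == 2L) - 0.22), 0.01)
})

test_that("cohort simulation is reproducible bit for bit", {
  coh <- default_cohort()[c(1, 9), ]
  a <- simulate_cohort(coh, seed = 34, sessions = 1, gaze = TRUE)
  b <- simulate_cohort(coh, seed = 34, sessions = 1, gaze = TRUE)
  expect_identical(a$trials, b$trials)
  expect_identical(a$gaze, b$gaze)
  c <- simulate_cohort(coh, seed = 35, sessions = 1, gaze = FALSE)
  expect_false(identical(a$trials, c$trials))
})

test_that("far-condition fixation distributions are anti-ordered, standard ones are not", {
  sim <- simulate_cohort(seed = 36, gaze = FALSE, calibrate = FALSE)
  rs <- sapply(c("far", "standard"), function(gc) {
    tr <- dplyr::filter(sim$trials, gap_condition == gc)
    kept <- filter_single_aoi_trials(tr)
    dist <- fixation_distribution(kept)
    wide <- tidyr::pivot_wider(
      dplyr::filter(dist, !cued)[, c("aoi", "correct_row", "pct")],
      names_from = "correct_row", values_from = "pct"
    )
    wide <- dplyr::filter(wide, !is.na(top) & !is.na(bottom))
    spearman_tie_corrected(wide$top, wide$bottom)
  })
  expect_lt(rs[["far"]], 0)
  expect_gt(rs[["standard"]], 0)
})
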