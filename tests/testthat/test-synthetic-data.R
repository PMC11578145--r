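cfg <- task_config()

test_that("hand holds the midline on no-jump trials without noise", {
  set.seed(1)
  h <- simulate_hand(no_jump_spec(), noiseless_params(), cfg)
  expect_true(max(abs(h$trace$x_cm)) <= 1e-12)
  expect_identical(h$truth$preemptive_type, "none")
})

test_that("programmed hand reaction time is recorded exactly", {
  set.seed(1)
  sp <- make_spec(urgency = "high", jump_size = 6, jump_direction = 1)
  h <- simulate_hand(sp, noiseless_params(), cfg, rt_ms = 190,
                     preemptive_type = "none")
  expect_equal(h$truth$hand_rt_ms, 190)
  # physical onset leads the nominal (extrapolation-scale) onset by the
  # closed-form foot offset of the minimum-jerk chord
  foot_ms <- 0.06117627 * h$truth$hand_duration_ms
  expect_equal(h$truth$hand_onset_phys_ms, 630 + 190 - foot_ms,
               tolerance = 1e-6)
})

test_that("programmed hand peak velocity follows the hyperbolic law", {
  set.seed(1)
  p <- noiseless_params(undershoot_cm = 0,
                        hand_vigor = c(low = 1, medium = 1, high = 1))
  sp <- make_spec(urgency = "low", jump_size = 6, jump_direction = 1)
  h <- simulate_hand(sp, p, cfg, rt_ms = 150, preemptive_type = "none")
  v_expected <- p$hand_alpha * (1 - 1 / (1 + p$hand_beta * 6))
  expect_equal(h$truth$hand_peak_velocity_cms, v_expected,
               tolerance = 1e-3)
  # realized peak of the raw velocity trace matches too
  v <- diff(h$trace$x_cm) / diff(h$trace$t_ms / 1000)
  expect_equal(max(v), v_expected, tolerance = 1e-3)
})

test_that("eye is still before the jump when pursuit gain is zero", {
  set.seed(1)
  p <- noiseless_params(pursuit_gain = 0, catchup_prob = 0)
  e <- simulate_eye(make_spec(), p, cfg, eye_rt_ms = 135)
  pre <- e$trace$t_ms < 630
  expect_lt(max(abs(diff(e$trace$y_cm[pre]))), 1e-10)
})

test_that("programmed saccade latency and kinematics are recorded", {
  set.seed(1)
  p <- noiseless_params(catchup_prob = 0)
  sp <- make_spec(urgency = "medium", jump_size = 6, jump_direction = -1)
  e <- simulate_eye(sp, p, cfg, eye_rt_ms = 135)
  expect_equal(e$truth$eye_rt_ms, 135)
  expect_true(e$truth$saccade_present)
  # nominal onset = physical onset + detection offset
  expect_equal(e$truth$sacc_onset_phys_ms + e$truth$detection_offset_ms,
               530 + 135, tolerance = 1e-6)
  # peak velocity of the raw saccade equals the main-sequence value
  v_exp <- p$eye_alpha * (1 - 1 / (1 + p$eye_beta * e$truth$sacc_amplitude_cm))
  expect_equal(e$truth$sacc_peak_velocity_cms, v_exp, tolerance = 1e-6)
})

test_that("pre-jump eye speed reflects the pursuit gain", {
  set.seed(2)
  p <- noiseless_params(pursuit_gain = 0.3, catchup_prob = 0)
  e <- simulate_eye(make_spec(urgency = "low"), p, cfg, eye_rt_ms = 150)
  pre <- e$trace$t_ms > 20 & e$trace$t_ms < 420
  speed <- sqrt(diff(e$trace$x_cm[pre])^2 + diff(e$trace$y_cm[pre])^2) /
    diff(e$trace$t_ms[pre] / 1000)
  expect_equal(mean(speed), 0.3 * 25, tolerance = 0.1)
})

test_that("blink gaps are masked, not interpolated", {
  set.seed(3)
  p <- noiseless_params(blink_prob = 1)
  e <- simulate_eye(make_spec(), p, cfg, eye_rt_ms = 140)
  expect_true(any(!e$trace$valid))
  expect_true(all(is.na(e$trace$x_cm[!e$trace$valid])))
  gap_ms <- sum(!e$trace$valid) * 2
  expect_equal(gap_ms, p$blink_duration_ms, tolerance = 4)
})

test_that("simulation is deterministic for a fixed seed", {
  co1 <- simulate_cohort(1, cfg, toy_allocation(), seed = 11)
  co2 <- simulate_cohort(1, cfg, toy_allocation(), seed = 11)
  expect_identical(co1$measures, co2$measures)
  expect_identical(co1$truth, co2$truth)
  co3 <- simulate_cohort(1, cfg, toy_allocation(), seed = 12)
  expect_false(identical(co3$truth$eye_rt_ms, co1$truth$eye_rt_ms))
})

test_that("cohorts have one recording per scheduled trial", {
  al <- tibble::tibble(certainty = "high", jump_size_condition = "6cm",
                       jumps_per_urgency_per_size = 2, n_nojump = 0)
  co <- simulate_cohort(2, cfg, al, seed = 4, measure = FALSE,
                        keep_recordings = TRUE)
  expect_length(co$recordings, 12)
  expect_equal(nrow(co$truth), 12)
  expect_s3_class(co$recordings[[1]], "trial_recording")
})

test_that("trial samples survive a CSV round trip", {
  set.seed(5)
  rec <- simulate_trial(make_spec(), noiseless_params(), cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_samples(rec, path)
  back <- read_trial_samples(path, spec = rec$spec)
  expect_equal(back$hand$x_cm, rec$hand$x_cm)
  expect_equal(back$eye$y_cm, rec$eye$y_cm)
  expect_equal(back$target$t_ms, rec$target$t_ms)
})
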