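cfg <- task_config()

prep <- function(tr) differentiate(filter_eye(tr))

test_that("saccade detection needs five consecutive super-threshold samples", {
  t_s <- seq(0, 0.93, by = 0.002)
  still <- tibble::tibble(t_ms = t_s * 1000, x_cm = 0, y_cm = 2, valid = TRUE)
  expect_equal(nrow(detect_saccades(prep(still))), 0)

  # hand-built velocity staircase: exactly 4 samples above threshold
  n <- length(t_s)
  fake <- tibble::tibble(t_ms = t_s * 1000, x_cm = rep(0, n), y_cm = rep(0, n),
                         vx_cms = rep(0, n), vy_cms = rep(0, n),
                         speed_cms = rep(0, n), accel_cms2 = rep(0, n))
  fake$speed_cms[100:103] <- 50
  expect_equal(nrow(detect_saccades(fake)), 0)
  fake$speed_cms[100:104] <- 50
  expect_equal(nrow(detect_saccades(fake)), 1)
})

test_that("a synthetic saccade is detected within one sample of its onset", {
  # peak 200 cm/s: duration chosen so 1.875 * A / T = 200
  A <- 6; T <- 1.875 * A / 200
  tr <- minjerk_trace(0.5, T, dx = A, dy = 0, rate = 500, y0 = 2)
  ev <- detect_saccades(prep(tr))
  expect_equal(nrow(ev), 1)
  # the detected onset precedes the physical onset by the filter spread;
  # compare against the brute-force oracle instead of the physical time
  oracle <- brute_force_saccades(prep(tr))
  expect_equal(ev$onset_ms, oracle$onset_ms, tolerance = 1e-9)
  expect_lt(abs(ev$onset_ms - 500) , 25)
  expect_equal(ev$amplitude_cm, A, tolerance = 0.1)
})

test_that("detector agrees with the brute-force oracle on random traces", {
  set.seed(123)
  for (i in 1:60) {
    d <- prep(random_eye_trace())
    ev <- detect_saccades(d)
    or <- brute_force_saccades(d)
    expect_equal(nrow(ev), nrow(or))
    if (nrow(ev)) {
      expect_true(all(abs(ev$onset_ms - or$onset_ms) <= 2))
      expect_true(all(abs(ev$offset_ms - or$offset_ms) <= 2))
    }
  }
})

test_that("first reactive saccade respects the 50 ms rule", {
  ev <- tibble::tibble(onset_ms = c(660, 770), offset_ms = c(700, 820),
                       start_x_cm = 0, start_y_cm = 0, end_x_cm = 0,
                       end_y_cm = 0, amplitude_cm = 3, peak_velocity_cms = 100)
  rs <- first_response_saccade(ev, jump_ms = 630)
  expect_equal(rs$onset_ms, 770)  # +30 ms event skipped
  expect_equal(rs$eye_rt_ms, 140)
  expect_equal(nrow(first_response_saccade(ev[0, ], 630)), 0)
  expect_equal(nrow(first_response_saccade(ev, NA)), 0)
  # inclusive bound at exactly +50 ms
  ev50 <- ev[1, ]; ev50$onset_ms <- 680
  expect_equal(first_response_saccade(ev50, 630)$eye_rt_ms, 50)
})

test_that("extrapolated reaction time is exact for a triangular rise", {
  t_ms <- seq(0, 930, by = 1)
  v <- pmax(0, (t_ms - 700) * 0.5)   # rises linearly from t0 = 700
  hand <- tibble::tibble(t_ms = t_ms, x_cm = 0, y_cm = 0, vx_cms = v,
                         vy_cms = 0, speed_cms = abs(v), accel_cms2 = 0)
  rt <- hand_reaction_time(hand, jump_ms = 630, jump_direction = 1,
                           window_end_ms = 930)
  expect_equal(rt, 70, tolerance = 1e-9)
})

test_that("extrapolated reaction time recovers a programmed minimum-jerk onset", {
  set.seed(1)
  sp <- make_spec(urgency = "low", jump_size = 6, jump_direction = 1)
  h <- simulate_hand(sp, noiseless_params(), cfg, rt_ms = 190,
                     preemptive_type = "none")
  hd <- differentiate(filter_hand(h$trace))
  rt <- hand_reaction_time(hd, 430, 1, window_end_ms = 930)
  expect_equal(rt, 190, tolerance = 5)
  # no-jump trials have no reaction time
  expect_true(is.na(hand_reaction_time(hd, NA, 0, 930)))
  # a motionless hand is "no response"
  still <- tibble::tibble(t_ms = seq(0, 930), x_cm = 0, y_cm = 0,
                          vx_cms = 0, vy_cms = 0, speed_cms = 0, accel_cms2 = 0)
  expect_true(is.na(hand_reaction_time(still, 430, 1, 930)))
})

test_that("interception geometry is a circle-rectangle contact", {
  still_hand <- function(x) {
    t_ms <- seq(0, trial_end_time(cfg), by = 1)
    tibble::tibble(t_ms = t_ms, x_cm = rep(x, length(t_ms)),
                   y_cm = 0, valid = TRUE)
  }
  tgt <- target_trajectory(no_jump_spec(), cfg)
  # paddle centred under the falling target
  hit <- detect_interception(still_hand(0), tgt, cfg)
  expect_true(hit$success)
  expect_equal(hit$contact_x_cm, 0)
  # contact when the target bottom reaches the paddle top: y = 0.25 + 0.5
  expect_equal(hit$contact_t_ms, (22 - 0.75) / 25 * 1000, tolerance = 1)
  # parked far away (half-width 1 + radius 0.5 + margin) -> miss
  miss <- detect_interception(still_hand(3.6), tgt, cfg)
  expect_false(miss$success)
  expect_equal(miss$zone_exit_ms, trial_end_time(cfg))
  # grazing contact at exactly half-width + radius
  graze <- detect_interception(still_hand(1.5), tgt, cfg)
  expect_true(graze$success)
  # brute-force oracle on a dense lateral grid: contact iff |x| <= 1.5
  for (x in seq(0, 2.5, by = 0.25)) {
    expect_equal(detect_interception(still_hand(x), tgt, cfg)$success,
                 x <= 1.5)
  }
})

test_that("epoch positions are read at onset, jump and jump + 250 ms", {
  t_s <- seq(0, 0.93, by = 0.002)
  fix <- tibble::tibble(t_ms = t_s * 1000, x_cm = 0, y_cm = 2, valid = TRUE)
  ep <- epoch_positions(fix, jump_ms = 630)
  expect_equal(ep$x_cm, c(0, 0, 0))
  expect_equal(ep$y_cm, c(2, 2, 2))
  ep_nj <- epoch_positions(fix, jump_ms = NA)
  expect_true(all(is.na(ep_nj$x_cm[2:3])))
  expect_equal(ep_nj$y_cm[1], 2)
  # saccade completing before jump + 250 lands the eye near the jumped target
  set.seed(2)
  sp <- make_spec(urgency = "medium", jump_size = 6, jump_direction = 1)
  e <- simulate_eye(sp, noiseless_params(catchup_prob = 0), cfg, eye_rt_ms = 130)
  epj <- epoch_positions(differentiate(filter_eye(e$trace)), jump_ms = 530)
  expect_equal(epj$x_cm[3], 6 * (1 - 0.11), tolerance = 0.3)
})

test_that("movement amplitude is the farthest excursion from the start", {
  t_ms <- seq(0, 930)
  still <- tibble::tibble(t_ms = t_ms, x_cm = 0, y_cm = 0)
  expect_equal(movement_amplitude(still, 930), 0)
  step <- tibble::tibble(t_ms = t_ms, x_cm = c(rep(0, 400), rep(6, 531)),
                         y_cm = 0)
  expect_equal(movement_amplitude(step, 930), 6)
  # L-shaped path: 3 right then 4 down -> 5 by Pythagoras
  ell <- tibble::tibble(t_ms = t_ms,
                        x_cm = c(seq(0, 3, length.out = 400), rep(3, 531)),
                        y_cm = c(rep(0, 400), seq(0, -4, length.out = 531)))
  expect_equal(movement_amplitude(ell, 930), 5)
})
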