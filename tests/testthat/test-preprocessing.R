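cfg <- task_config()

constant_trace <- function(x = 1.3, y = -0.7, rate = 1000, t_end_s = 0.5) {
  t_s <- seq(0, t_end_s, by = 1 / rate)
  tibble::tibble(t_ms = t_s * 1000, x_cm = rep(x, length(t_s)),
                 y_cm = rep(y, length(t_s)), valid = TRUE)
}

test_that("filters pass constants unchanged (DC gain 1)", {
  tr <- constant_trace()
  expect_equal(filter_hand(tr)$x_cm, tr$x_cm, tolerance = 1e-6)
  tr500 <- constant_trace(rate = 500)
  expect_equal(filter_eye(tr500)$y_cm, tr500$y_cm, tolerance = 1e-6)
})

test_that("filter attenuation matches the analytic Butterworth response", {
  # hand: 3rd order, 20 Hz, applied twice (zero phase)
  a2 <- sinusoid_attenuation(filter_hand, 2, rate = 1000)
  expect_gt(a2, 0.99)
  expect_equal(a2, butterworth_filtfilt_gain(2, 20, 3), tolerance = 0.01)
  a100 <- sinusoid_attenuation(filter_hand, 100, rate = 1000)
  expect_lt(a100, 0.01)
  # eye: 2nd order, 15 Hz
  e1 <- sinusoid_attenuation(filter_eye, 1, rate = 500)
  expect_gt(e1, 0.99)
  expect_equal(e1, butterworth_filtfilt_gain(1, 15, 2), tolerance = 0.01)
  e60 <- sinusoid_attenuation(filter_eye, 60, rate = 500)
  expect_lt(e60, 0.01)
})

test_that("filtering is near-idempotent in the pass band and zero-phase", {
  t_s <- seq(0, 2, by = 1e-3)
  tr <- tibble::tibble(t_ms = t_s * 1000,
                       x_cm = sin(2 * pi * 3 * t_s) + 0.5 * sin(2 * pi * 5 * t_s),
                       y_cm = 0, valid = TRUE)
  once <- filter_hand(tr)
  twice <- filter_hand(once)
  core <- seq(200, 1800)
  expect_lt(max(abs(twice$x_cm[core] - once$x_cm[core])) /
              max(abs(once$x_cm[core])), 0.02)
  # zero phase: cross-correlation peak at lag 0
  cc <- stats::ccf(once$x_cm[core], tr$x_cm[core], lag.max = 30, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("masked gaps are preserved through filtering without leakage", {
  tr <- constant_trace(rate = 500)
  tr$valid[100:140] <- FALSE
  out <- filter_eye(tr)
  expect_true(all(is.na(out$x_cm[100:140])))
  expect_true(all(!is.na(out$x_cm[-(100:140)])))
  expect_identical(out$valid, tr$valid)
})

test_that("too-short traces are rejected with an informative error", {
  tr <- constant_trace(t_end_s = 0.01)
  expect_error(filter_hand(tr), "20 samples")
  expect_error(filter_eye(tr[1:5, ]), "20 samples")
})

test_that("differentiation recovers known velocity and acceleration", {
  t_s <- seq(0, 1, by = 1e-3)
  ramp <- tibble::tibble(t_ms = t_s * 1000, x_cm = 25 * t_s, y_cm = 0)
  d <- differentiate(ramp)
  expect_equal(d$speed_cms, rep(25, nrow(d)), tolerance = 1e-9)
  quad <- tibble::tibble(t_ms = t_s * 1000, x_cm = t_s^2, y_cm = 0)
  dq <- differentiate(quad)
  inner <- 3:(nrow(dq) - 2)
  acc <- diff(dq$vx_cms) / 1e-3
  expect_equal(acc[inner], rep(2, length(inner)), tolerance = 1e-6)
  # minimum-jerk peak speed 1.875 A / T
  mj <- minjerk_trace(0.3, 0.2, dx = 5, dy = 0, rate = 1000)
  dm <- differentiate(mj)
  expect_equal(max(dm$speed_cms), 1.875 * 5 / 0.2, tolerance = 0.005 * 1.875 * 5 / 0.2)
})

test_that("trials are flagged by the exclusion rules", {
  p <- noiseless_params()
  sp <- make_spec(urgency = "low", jump_size = 6, jump_direction = 1)

  # blink inside the analysis window -> signal loss
  set.seed(1)
  rec <- simulate_trial(sp, p, cfg)
  rec$eye$valid[120:160] <- FALSE
  rec$eye$x_cm[120:160] <- NA
  rec$eye$y_cm[120:160] <- NA
  f <- preprocess_trial(rec, cfg)
  expect_equal(f$flag, "signal_loss")

  # programmed onset 100 ms after the jump -> preemptive
  set.seed(2)
  h <- simulate_hand(sp, p, cfg, rt_ms = 100, preemptive_type = "early")
  rec2 <- simulate_trial(sp, p, cfg)
  rec2$hand <- h$trace
  f2 <- preprocess_trial(rec2, cfg)
  expect_equal(f2$flag, "preemptive")

  # movement toward the wrong side -> preemptive
  set.seed(3)
  hw <- simulate_hand(sp, p, cfg, rt_ms = 180, preemptive_type = "wrong")
  rec3 <- simulate_trial(sp, p, cfg)
  rec3$hand <- hw$trace
  f3 <- preprocess_trial(rec3, cfg)
  expect_equal(f3$flag, "preemptive")

  # ordinary response at 200 ms toward the jump -> unflagged
  set.seed(4)
  h4 <- simulate_hand(sp, p, cfg, rt_ms = 200, preemptive_type = "none")
  rec4 <- simulate_trial(sp, p, cfg)
  rec4$hand <- h4$trace
  f4 <- preprocess_trial(rec4, cfg)
  expect_equal(f4$flag, "none")
})
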