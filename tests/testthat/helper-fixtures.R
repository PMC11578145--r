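# Shared fixtures: small allocations, trace builders and independent oracles.

toy_allocation <- function() {
  tibble::tibble(
    certainty = c("high", "low"),
    jump_size_condition = c("mixed", "mixed"),
    jumps_per_urgency_per_size = c(2, 2),
    n_nojump = c(0, 8))
}

# one-row trial spec without going through build_schedule
make_spec <- function(urgency = "high", jump_size = 6, jump_direction = 1,
                      certainty = "high", trial_id = 1L,
                      config = task_config()) {
  tibble::tibble(
    trial_id = trial_id, block_id = 1L, certainty = certainty,
    jump_size_condition = "mixed", urgency = urgency,
    jump_size = jump_size, jump_direction = jump_direction,
    jump_onset_ms = if (urgency == "none") NA_real_ else
      jump_onset_time(config, urgency))
}

no_jump_spec <- function(...) {
  make_spec(urgency = "none", jump_size = 0, jump_direction = 0, ...)
}

# raw trace containing a single minimum-jerk displacement on a constant or
# drifting baseline
minjerk_trace <- function(onset_s, duration_s, dx, dy, rate = 500,
                          t_end_s = 0.93, x0 = 0, y0 = 0, drift_vy = 0,
                          noise_sd = 0) {
  t_s <- seq(0, t_end_s, by = 1 / rate)
  s <- minimum_jerk(t_s, onset_s, duration_s, 1)
  tibble::tibble(
    t_ms = t_s * 1000,
    x_cm = x0 + dx * s + rnorm(length(t_s), 0, noise_sd),
    y_cm = y0 + drift_vy * t_s + dy * s + rnorm(length(t_s), 0, noise_sd),
    valid = TRUE)
}

# analytic squared-magnitude response of an order-n Butterworth applied
# forward and backward (amplitude gain at frequency f_hz)
butterworth_filtfilt_gain <- function(f_hz, cutoff_hz, order) {
  1 / (1 + (f_hz / cutoff_hz)^(2 * order))
}

# measured amplitude attenuation of a sinusoid through a filter function
sinusoid_attenuation <- function(filter_fun, f_hz, rate, n_cycles = 20) {
  t_s <- seq(0, n_cycles / f_hz, by = 1 / rate)
  tr <- tibble::tibble(t_ms = t_s * 1000, x_cm = sin(2 * pi * f_hz * t_s),
                       y_cm = 0, valid = TRUE)
  out <- filter_fun(tr)
  core <- seq(round(length(t_s) * 0.25), round(length(t_s) * 0.75))
  max(abs(out$x_cm[core]))
}

# Brute-force saccade scanner: a literal sample-by-sample implementation of
# the published criterion (5 consecutive samples above 30 cm/s; onset = last
# acceleration sign reversal before the run, offset = first after the run,
# searches bounded at 100 ms, 1% dead band, 10 ms merging), written with
# plain loops and no shared code with detect_saccades.
brute_force_saccades <- function(eye, threshold = 30, min_run = 5,
                                 merge_ms = 10, search_ms = 100) {
  sp <- eye$speed_cms
  ac <- eye$accel_cms2
  n <- length(sp)
  dt_ms <- eye$t_ms[2] - eye$t_ms[1]
  nsearch <- round(search_ms / dt_ms)
  # collect maximal runs
  runs <- list()
  i <- 1
  while (i <= n) {
    if (!is.na(sp[i]) && sp[i] > threshold) {
      j <- i
      while (j < n && !is.na(sp[j + 1]) && sp[j + 1] > threshold) j <- j + 1
      if (j - i + 1 >= min_run) runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  if (length(runs) == 0) return(data.frame(onset_ms = numeric()))
  # merge
  merged <- list(runs[[1]])
  if (length(runs) > 1) {
    for (k in 2:length(runs)) {
      prev <- merged[[length(merged)]]
      if ((runs[[k]][1] - prev[2]) * dt_ms < merge_ms) {
        merged[[length(merged)]][2] <- runs[[k]][2]
      } else merged[[length(merged) + 1]] <- runs[[k]]
    }
  }
  onsets <- numeric(0); offsets <- numeric(0)
  for (r in merged) {
    span <- max(1, r[1] - nsearch):min(n, r[2] + 1 + nsearch)
    eps <- 0.01 * max(abs(ac[span]), na.rm = TRUE)
    onset <- max(1, r[1] - nsearch)
    for (k in r[1]:max(1, r[1] - nsearch)) {  # walk backwards
      if (!is.na(ac[k]) && ac[k] <= eps) { onset <- k; break }
    }
    off_start <- min(n, r[2] + 1)
    offset <- min(n, r[2] + 1 + nsearch)
    for (k in off_start:min(n, r[2] + 1 + nsearch)) {
      if (!is.na(ac[k]) && ac[k] >= -eps) { offset <- k; break }
    }
    onsets <- c(onsets, eye$t_ms[onset])
    offsets <- c(offsets, eye$t_ms[offset])
  }
  data.frame(onset_ms = onsets, offset_ms = offsets)
}

# random synthetic eye trace for the oracle-equivalence check: fixation plus
# 0-3 saccades of random amplitude/timing plus white noise
random_eye_trace <- function(rate = 500, t_end_s = 0.93) {
  t_s <- seq(0, t_end_s, by = 1 / rate)
  x <- rep(runif(1, -1, 1), length(t_s))
  y <- rep(runif(1, 0, 8), length(t_s)) - runif(1, 0, 8) * t_s
  nsacc <- sample(0:3, 1)
  if (nsacc > 0) {
    onsets <- sort(runif(nsacc, 0.05, t_end_s - 0.15))
    for (o in onsets) {
      A <- runif(1, 1, 8)
      ang <- runif(1, 0, 2 * pi)
      dur <- runif(1, 0.03, 0.08)
      s <- minimum_jerk(t_s, o, dur, 1)
      x <- x + A * cos(ang) * s
      y <- y + A * sin(ang) * s
    }
  }
  tibble::tibble(t_ms = t_s * 1000,
                 x_cm = x + rnorm(length(t_s), 0, 0.05),
                 y_cm = y + rnorm(length(t_s), 0, 0.05),
                 valid = TRUE)
}
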