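# --- internal helpers -------------------------------------------------------

cell_mean <- function(cells, certainty, urgency) {
  cells$mean_ms[cells$certainty == certainty & cells$urgency == urgency]
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

hand_grid_ms <- function(config) seq(0, trial_end_time(config), by = 1000 / config$hand_rate)
eye_grid_ms <- function(config) seq(0, trial_end_time(config), by = 1000 / config$eye_rate)

# Onset-detection offset of the saccade criterion for a given saccade.
#
# Programmed latencies are defined on the measurement scale: the latency the
# velocity-criterion detector reports after zero-phase filtering. Because the
# filter spreads the foot of the velocity bell backward in time, the
# physically programmed movement start must be shifted so that the detected
# onset lands on the nominal latency. The offset is measured on a template
# with the identical local geometry (saccade displacement `dx`, `dy` riding
# on a constant drift velocity), passed through the same filter +
# differentiation + criterion chain.
saccade_onset_offset <- function(duration_s, dx, dy, drift_vy_cms, config) {
  rate <- config$eye_rate
  dt <- 1 / rate
  t_s <- seq(0, 0.7, by = dt)
  t0 <- 0.35
  s <- minimum_jerk(t_s, t0, duration_s, 1)
  tr <- tibble::tibble(t_ms = t_s * 1000,
                       x_cm = dx * s,
                       y_cm = drift_vy_cms * t_s + dy * s)
  ev <- detect_saccades(differentiate(filter_eye(tr)))
  if (nrow(ev) == 0) return(0)
  ev$onset_ms[1] / 1000 - t0
}

# --- hand -------------------------------------------------------------------

#' Simulate the hand trace of one trial
#'
#' The paddle holds in the start area (with a static hold offset bounded by
#' twice `fixation_jitter_sd`); on jump trials a minimum-jerk lateral
#' correction is launched whose amplitude is `jump_size - undershoot_cm` and
#' whose peak velocity is the urgency-specific vigor multiplier times the
#' participant's hyperbolic main-sequence value at that amplitude. The drawn
#' reaction time is defined on the scale of the 25-75% extrapolation method:
#' the physical movement start is placed `0.0612 * duration` earlier, the
#' closed-form offset between the extrapolated foot and the physical start of
#' a minimum-jerk velocity profile. Preemptive trials start early (uniform
#' 40-110 ms) or move to the wrong side. White positional noise is added
#' throughout.
#'
#' @param spec One schedule row.
#' @param params A [participant_params()].
#' @param config A [task_config()].
#' @param rt_ms Optional fixed reaction time (ms after the jump); drawn from
#'   the (certainty, urgency) cell if `NULL`.
#' @param preemptive_type `"none"`, `"early"`, `"wrong"`, or `NULL` to draw.
#' @return A list with `trace` (tibble `t_ms`, `x_cm`, `y_cm`, `valid`),
#'   `clean` (the same trace before measurement noise) and `truth`
#'   (programmed reaction time, physical onset, amplitude, peak velocity,
#'   duration, preemptive type, truncation flag).
#' @export
simulate_hand <- function(spec, params, config, rt_ms = NULL,
                          preemptive_type = NULL) {
  t_ms <- hand_grid_ms(config)
  t_s <- t_ms / 1000
  n <- length(t_ms)
  jit <- params$fixation_jitter_sd
  x0 <- if (jit > 0) clamp(rnorm(1, 0, jit), -2 * jit, 2 * jit) else 0
  x <- rep(x0, n)
  y <- numeric(n)

  is_jump <- !is.na(spec$jump_onset_ms) && spec$jump_direction != 0
  truth <- list(hand_rt_ms = NA_real_, hand_onset_phys_ms = NA_real_,
                hand_amplitude_cm = NA_real_, hand_peak_velocity_cms = NA_real_,
                hand_duration_ms = NA_real_, preemptive_type = "none",
                hand_truncated = FALSE)

  if (is_jump) {
    if (is.null(preemptive_type)) {
      preemptive_type <- if (runif(1) < params$preemptive_prob) {
        sample(c("early", "wrong"), 1)
      } else "none"
    }
    if (is.null(rt_ms)) {
      rt_ms <- if (preemptive_type == "early") {
        runif(1, 40, 110)
      } else {
        max(rnorm(1, cell_mean(params$hand_rt_mean, spec$certainty, spec$urgency),
                  params$hand_rt_sd), params$rt_floor_ms)
      }
    }
    dir <- spec$jump_direction
    if (preemptive_type == "wrong") dir <- -dir
    A <- max(spec$jump_size - params$undershoot_cm, 0.5)
    vig <- params$hand_vigor[[spec$urgency]]
    vpk <- vig * params$hand_alpha * (1 - 1 / (1 + params$hand_beta * A))
    T_s <- 1.875 * A / vpk
    onset_phys_s <- (spec$jump_onset_ms + rt_ms) / 1000 -
      minjerk_extrapolation_foot() * T_s
    x <- x + dir * A * minimum_jerk(t_s, onset_phys_s, T_s, 1)
    truncated <- onset_phys_s + T_s > t_s[n]
    realized_vpk <- if (truncated) {
      tau_end <- clamp((t_s[n] - onset_phys_s) / T_s, 0, 1)
      tau_max <- min(tau_end, 0.5)
      (30 * tau_max^2 * (1 - tau_max)^2) * A / T_s
    } else vpk
    truth <- list(hand_rt_ms = rt_ms,
                  hand_onset_phys_ms = onset_phys_s * 1000,
                  hand_amplitude_cm = A,
                  hand_peak_velocity_cms = realized_vpk,
                  hand_duration_ms = T_s * 1000,
                  preemptive_type = preemptive_type,
                  hand_truncated = truncated)
  }

  clean <- tibble::tibble(t_ms = t_ms, x_cm = x, y_cm = y,
                          valid = rep(TRUE, n))
  if (params$hand_noise_sd > 0) {
    x <- x + rnorm(n, 0, params$hand_noise_sd)
    y <- y + rnorm(n, 0, params$hand_noise_sd)
  }
  list(trace = tibble::tibble(t_ms = t_ms, x_cm = x, y_cm = y,
                              valid = rep(TRUE, n)),
       clean = clean,
       truth = truth)
}

# --- eye --------------------------------------------------------------------

#' Simulate the eye trace of one trial
#'
#' Before the jump the eye drifts downward at `pursuit_gain` times the target
#' speed from a jittered fixation point, optionally interrupted by one
#' catch-up saccade that re-foveates half the eye-target gap. On jump trials
#' a reactive saccade is launched toward the jumped target at the drawn eye
#' latency (defined, like the hand, on the measurement scale: the physical
#' onset is shifted by the filter-induced detection offset computed on a
#' geometry-matched template). The saccade lands at the target's horizontal
#' position scaled by the undershoot fraction and at its vertical position at
#' saccade end plus the urgency-specific landing error; its peak velocity
#' follows the eye main sequence and its duration is `1.875 * A / v_peak`.
#' After the saccade the eye tracks the target velocity. Optional blink gaps
#' mask samples; white positional noise is added throughout.
#'
#' @inheritParams simulate_hand
#' @param eye_rt_ms Optional fixed eye latency (ms after the jump).
#' @param saccade_present Logical; `NULL` draws with `saccade_prob`.
#' @return A list with `trace` (tibble `t_ms`, `x_cm`, `y_cm`, `valid`) and
#'   `truth` (latency, physical onset/offset, amplitude, peak velocity,
#'   landing point, blink window, number of pre-jump saccades, detection
#'   offset used).
#' @export
simulate_eye <- function(spec, params, config, eye_rt_ms = NULL,
                         saccade_present = NULL) {
  t_ms <- eye_grid_ms(config)
  t_s <- t_ms / 1000
  n <- length(t_ms)
  jit <- params$fixation_jitter_sd
  fx <- if (jit > 0) clamp(rnorm(1, 0, jit), -2 * jit, 2 * jit) else 0
  fy <- 5 + (if (jit > 0) rnorm(1, 0, 10 * jit) else 0)
  g <- params$pursuit_gain
  drift_vy <- -g * config$target_speed
  jump_ms <- spec$jump_onset_ms
  is_jump <- !is.na(jump_ms) && spec$jump_direction != 0

  tgt_x <- if (is_jump) spec$jump_size * spec$jump_direction else 0
  tgt_y <- function(tt_s) config$target_start_height - config$target_speed * tt_s

  # optional catch-up saccade halving the eye-target gap
  cu_dx <- 0; cu_dy <- 0; cu <- NULL
  pre_end_ms <- if (is_jump) jump_ms else trial_end_time(config)
  if (runif(1) < params$catchup_prob && pre_end_ms > 320) {
    tc_s <- runif(1, 0.15, (pre_end_ms - 150) / 1000)
    eye_at <- c(fx, fy + drift_vy * tc_s)
    gap <- c(0 - eye_at[1], tgt_y(tc_s) - eye_at[2])
    cu_d <- 0.5 * gap
    cu_A <- sqrt(sum(cu_d^2))
    if (cu_A > 0.5) {
      cu_T <- main_sequence_duration(cu_A, params$eye_alpha, params$eye_beta)
      cu <- list(onset_s = tc_s, T_s = cu_T)
      cu_dx <- cu_d[1]; cu_dy <- cu_d[2]
    }
  }

  truth <- list(eye_rt_ms = NA_real_, sacc_onset_phys_ms = NA_real_,
                sacc_offset_phys_ms = NA_real_, sacc_amplitude_cm = NA_real_,
                sacc_peak_velocity_cms = NA_real_,
                sacc_land_x_cm = NA_real_, sacc_land_y_cm = NA_real_,
                detection_offset_ms = NA_real_,
                saccade_present = FALSE, n_presaccades = if (is.null(cu)) 0L else 1L,
                blink_start_ms = NA_real_, blink_end_ms = NA_real_,
                pursuit_gain = g)

  sac <- NULL
  if (is_jump) {
    if (is.null(saccade_present)) saccade_present <- runif(1) < params$saccade_prob
    if (saccade_present) {
      if (is.null(eye_rt_ms)) {
        eye_rt_ms <- max(rnorm(1, cell_mean(params$eye_rt_mean, spec$certainty,
                                            spec$urgency), params$eye_rt_sd),
                         params$eye_rt_floor_ms)
      }
      err <- rnorm(2, 0, params$landing_error_sd)
      err_y_mean <- params$landing_error_y_mean[[spec$urgency]]
      vig <- params$eye_vigor[[spec$urgency]]
      t_phys_s <- (jump_ms + eye_rt_ms) / 1000
      delta_s <- 0
      for (iter in 1:2) {
        eo <- c(fx + cu_dx, fy + drift_vy * t_phys_s + cu_dy)
        A1 <- sqrt(sum((c(tgt_x, tgt_y(t_phys_s)) - eo)^2))
        T1 <- main_sequence_duration(A1, params$eye_alpha, params$eye_beta, vig)
        land <- c(tgt_x * (1 - params$eye_undershoot_frac) + err[1],
                  tgt_y(t_phys_s + T1) + err_y_mean + err[2])
        d <- land - eo
        A <- sqrt(sum(d^2))
        T_s <- main_sequence_duration(A, params$eye_alpha, params$eye_beta, vig)
        delta_s <- saccade_onset_offset(T_s, d[1], d[2], drift_vy, config)
        t_phys_s <- (jump_ms + eye_rt_ms) / 1000 - delta_s
      }
      vpk <- vig * params$eye_alpha * (1 - 1 / (1 + params$eye_beta * A))
      sac <- list(onset_s = t_phys_s, T_s = T_s, dx = d[1], dy = d[2])
      truth$eye_rt_ms <- eye_rt_ms
      truth$sacc_onset_phys_ms <- t_phys_s * 1000
      truth$sacc_offset_phys_ms <- (t_phys_s + T_s) * 1000
      truth$sacc_amplitude_cm <- A
      truth$sacc_peak_velocity_cms <- vpk
      truth$sacc_land_x_cm <- land[1]
      truth$sacc_land_y_cm <- land[2]
      truth$detection_offset_ms <- delta_s * 1000
      truth$saccade_present <- TRUE
    }
  }

  # assemble: pursuit drift until saccade end, then target-velocity tracking
  if (!is.null(sac)) {
    t_off <- sac$onset_s + sac$T_s
    drift <- fy + drift_vy * pmin(t_s, t_off) -
      config$target_speed * pmax(t_s - t_off, 0)
  } else {
    drift <- fy + drift_vy * t_s
  }
  ex <- rep(fx, n)
  ey <- drift
  if (!is.null(cu)) {
    s <- minimum_jerk(t_s, cu$onset_s, cu$T_s, 1)
    ex <- ex + cu_dx * s
    ey <- ey + cu_dy * s
  }
  if (!is.null(sac)) {
    s <- minimum_jerk(t_s, sac$onset_s, sac$T_s, 1)
    ex <- ex + sac$dx * s
    ey <- ey + sac$dy * s
  }
  if (params$eye_noise_sd > 0) {
    ex <- ex + rnorm(n, 0, params$eye_noise_sd)
    ey <- ey + rnorm(n, 0, params$eye_noise_sd)
  }

  valid <- rep(TRUE, n)
  if (runif(1) < params$blink_prob) {
    b0 <- runif(1, 0, trial_end_time(config) - params$blink_duration_ms)
    bmask <- t_ms >= b0 & t_ms <= b0 + params$blink_duration_ms
    valid[bmask] <- FALSE
    ex[bmask] <- NA_real_
    ey[bmask] <- NA_real_
    truth$blink_start_ms <- b0
    truth$blink_end_ms <- b0 + params$blink_duration_ms
  }

  list(trace = tibble::tibble(t_ms = t_ms, x_cm = ex, y_cm = ey, valid = valid),
       truth = truth)
}

# --- trial ------------------------------------------------------------------

#' Simulate one full trial
#'
#' Draws correlated eye and hand latencies from the trial's (certainty,
#' urgency) cell (`eye_hand_rt_cor` via a shared Gaussian component), the
#' preemptive and saccade-present indicators, then generates hand, eye and
#' target traces and the ground-truth record. The recorded interception
#' outcome is computed on the noise-free hand trace passed through the
#' standard hand filter, i.e. on the same measurement convention the
#' analysis chain uses.
#'
#' @param spec One schedule row.
#' @param params A [participant_params()].
#' @param config A [task_config()].
#' @return A list of class `trial_recording`: `spec`, `hand`, `eye`, `target`
#'   (tibbles), `participant_id`, `ground_truth` (one-row tibble).
#' @export
simulate_trial <- function(spec, params, config) {
  spec <- as_tibble(spec)
  is_jump <- !is.na(spec$jump_onset_ms) && spec$jump_direction != 0

  hand_rt <- NULL; eye_rt <- NULL; pre_type <- NULL
  if (is_jump) {
    pre_type <- if (runif(1) < params$preemptive_prob) {
      sample(c("early", "wrong"), 1)
    } else "none"
    z1 <- rnorm(1); z2 <- rnorm(1)
    rho <- params$eye_hand_rt_cor
    me <- cell_mean(params$eye_rt_mean, spec$certainty, spec$urgency)
    mh <- cell_mean(params$hand_rt_mean, spec$certainty, spec$urgency)
    eye_rt <- max(me + params$eye_rt_sd * z1, params$eye_rt_floor_ms)
    hand_rt <- if (pre_type == "early") {
      runif(1, 40, 110)
    } else {
      max(mh + params$hand_rt_sd * (rho * z1 + sqrt(1 - rho^2) * z2),
          params$rt_floor_ms)
    }
  }

  hand <- simulate_hand(spec, params, config, rt_ms = hand_rt,
                        preemptive_type = pre_type)
  eye <- simulate_eye(spec, params, config, eye_rt_ms = eye_rt)
  target <- target_trajectory(spec, config, dt_ms = 1000 / config$hand_rate)

  # ground-truth outcome on the measurement convention: the noise-free hand
  # trace through the standard hand filter (so a noiseless analysis run
  # reproduces the recorded outcome exactly, including corner grazes)
  icpt <- detect_interception(filter_hand(hand$clean), target, config)
  truth <- tibble::as_tibble(c(
    list(participant_id = params$participant_id, trial_id = spec$trial_id),
    hand$truth, eye$truth,
    list(success = icpt$success, contact_t_ms = icpt$contact_t_ms,
         contact_x_cm = icpt$contact_x_cm, contact_y_cm = icpt$contact_y_cm)))

  structure(list(spec = spec, hand = hand$trace, eye = eye$trace,
                 target = target, participant_id = params$participant_id,
                 ground_truth = truth),
            class = "trial_recording")
}

# --- cohort -----------------------------------------------------------------

#' Simulate a cohort of participants
#'
#' Draws `n_participants` parameter sets, builds each participant a full
#' schedule, simulates every trial and (by default) measures it immediately
#' with [measure_trial()], discarding the traces to keep memory flat. The
#' whole run is reproducible for a fixed seed.
#'
#' @param n_participants Number of participants.
#' @param config A [task_config()].
#' @param allocation Block allocation, see [default_allocation()].
#' @param seed Integer seed.
#' @param base Base [participant_params()] (e.g. [noiseless_params()]).
#' @param ranges Between-participant ranges, see [default_param_ranges()].
#' @param measure Compute per-trial measures (`TRUE`) while simulating.
#' @param keep_recordings Keep the raw `trial_recording` objects (memory-heavy
#'   for large cohorts).
#' @return A list of class `cohort`: `config`, `params` (list), `schedule`
#'   (all participants, with `participant_id`), `truth` (ground-truth tibble),
#'   and, as requested, `measures` (tibble) and `recordings` (list).
#' @examples
#' co <- simulate_cohort(1, allocation = default_allocation()[1, ],
#'                       seed = 1, measure = FALSE)
#' nrow(co$truth)  # 96 trials in the first block alone
#' @export
simulate_cohort <- function(n_participants = 13, config = task_config(),
                            allocation = default_allocation(), seed = 1L,
                            base = participant_params(),
                            ranges = default_param_ranges(),
                            measure = TRUE, keep_recordings = FALSE) {
  set.seed(seed)
  participants <- draw_participants(n_participants, ranges, base)
  sched_seeds <- sample.int(.Machine$integer.max - 1, n_participants)
  all_sched <- vector("list", n_participants)
  truth <- list()
  rows <- list()
  recordings <- list()
  k <- 0
  for (p in seq_len(n_participants)) {
    pp <- participants[[p]]
    sched <- build_schedule(config, allocation, seed = sched_seeds[p])
    sched$participant_id <- pp$participant_id
    all_sched[[p]] <- sched
    set.seed(sched_seeds[p] + 1L)
    for (i in seq_len(nrow(sched))) {
      k <- k + 1
      rec <- simulate_trial(sched[i, ], pp, config)
      truth[[k]] <- rec$ground_truth
      if (measure) rows[[k]] <- measure_trial(rec, config)
      if (keep_recordings) recordings[[k]] <- rec
    }
  }
  structure(list(config = config, allocation = allocation,
                 params = participants,
                 schedule = dplyr::bind_rows(all_sched),
                 truth = dplyr::bind_rows(truth),
                 measures = if (measure) dplyr::bind_rows(rows) else NULL,
                 recordings = if (keep_recordings) recordings else NULL),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants, %d trials\n",
              length(x$params), nrow(x$schedule)))
  if (!is.null(x$measures)) {
    cat(sprintf("  measured: %d trials, %d flagged (%.1f%%)\n",
                nrow(x$measures), sum(x$measures$flag != "none"),
                100 * mean(x$measures$flag != "none")))
  }
  invisible(x)
}

#' Write / read trial samples as tidy CSV
#'
#' One row per sample: `trial_id`, `stream` (eye / hand / target), `t_ms`,
#' `x_cm`, `y_cm`, `valid`.
#'
#' @param recording A `trial_recording`.
#' @param path File path.
#' @return `write_trial_samples` returns `path` invisibly;
#'   `read_trial_samples` returns a `trial_recording`-shaped list (without
#'   ground truth, which travels separately as JSON).
#' @export
write_trial_samples <- function(recording, path) {
  pack <- function(tr, stream) {
    tibble::tibble(trial_id = recording$spec$trial_id, stream = stream,
                   t_ms = tr$t_ms, x_cm = tr$x_cm, y_cm = tr$y_cm,
                   valid = if ("valid" %in% names(tr)) tr$valid else TRUE)
  }
  out <- dplyr::bind_rows(pack(recording$eye, "eye"),
                          pack(recording$hand, "hand"),
                          pack(recording$target, "target"))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_samples
#' @param spec The schedule row for the trial (re-attached on read).
#' @export
read_trial_samples <- function(path, spec = NULL) {
  raw <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  pick <- function(stream) {
    tr <- raw[raw$stream == stream, c("t_ms", "x_cm", "y_cm", "valid")]
    tibble::as_tibble(tr)
  }
  structure(list(spec = spec, hand = pick("hand"), eye = pick("eye"),
                 target = pick("target")[, c("t_ms", "x_cm", "y_cm")],
                 participant_id = NA_integer_, ground_truth = NULL),
            class = "trial_recording")
}

#' Export a cohort's ground truth as JSON
#'
#' @param cohort A `cohort` object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(cohort, path) {
  jsonlite::write_json(cohort$truth, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
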