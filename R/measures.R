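target_position_at <- function(target, t_ms) {
  if (is.na(t_ms)) return(c(NA_real_, NA_real_))
  i <- which.min(abs(target$t_ms - t_ms))
  c(target$x_cm[i], target$y_cm[i])
}

#' Derive all per-trial measures
#'
#' Runs the full per-trial analysis chain: zero-phase filtering and
#' differentiation of both streams, trial flagging, saccade detection, the
#' first reactive saccade and its latency and landing error, the
#' extrapolation hand reaction time, the interception outcome, movement
#' amplitude and peak velocity, pre-jump eye speed (saccade samples
#' excluded) and the eye positions at the three analysis epochs.
#'
#' @param recording A `trial_recording` (from [simulate_trial()] or
#'   [read_trial_samples()]).
#' @param config A [task_config()].
#' @return A one-row tibble of trial measures, including the schedule columns
#'   and the flag.
#' @export
measure_trial <- function(recording, config) {
  spec <- recording$spec
  f <- preprocess_trial(recording, config)
  jump_ms <- spec$jump_onset_ms
  is_jump <- !is.na(jump_ms) && spec$jump_direction != 0

  icpt <- detect_interception(f$hand, f$target, config)
  window_end <- if (icpt$success) icpt$contact_t_ms else icpt$zone_exit_ms

  sacc <- detect_saccades(f$eye)
  rs <- first_response_saccade(sacc, jump_ms)
  saccade_present <- nrow(rs) == 1

  sacc_err <- c(NA_real_, NA_real_)
  if (saccade_present) {
    tp <- target_position_at(f$target, rs$offset_ms)
    sacc_err <- c(rs$end_x_cm - tp[1], rs$end_y_cm - tp[2])
  }

  pre_end <- if (is_jump) jump_ms else window_end
  pre_sel <- f$eye$t_ms < pre_end
  n_presacc <- sum(sacc$onset_ms < pre_end)
  in_sacc <- rep(FALSE, nrow(f$eye))
  if (nrow(sacc)) {
    for (i in seq_len(nrow(sacc))) {
      in_sacc <- in_sacc | (f$eye$t_ms >= sacc$onset_ms[i] &
                              f$eye$t_ms <= sacc$offset_ms[i])
    }
  }
  pre_speed <- mean(f$eye$speed_cms[pre_sel & !in_sacc], na.rm = TRUE)

  hand_rt <- if (is_jump) {
    hand_reaction_time(f$hand, jump_ms, spec$jump_direction,
                       window_end_ms = max(f$hand$t_ms))
  } else NA_real_
  amp <- movement_amplitude(f$hand, window_end)
  hand_vpk <- max(f$hand$speed_cms, na.rm = TRUE)

  ep <- epoch_positions(f$eye, jump_ms)

  dplyr::bind_cols(
    tibble::tibble(participant_id = recording$participant_id %||% NA_integer_),
    spec[setdiff(names(spec), "participant_id")],
    tibble::tibble(
      flag = f$flag, flag_reason = f$flag_reason,
      hand_rt_ms = hand_rt,
      eye_rt_ms = if (saccade_present) rs$eye_rt_ms else NA_real_,
      saccade_present = saccade_present,
      n_presaccades = n_presacc,
      pre_jump_eye_speed_cms = pre_speed,
      hand_amplitude_cm = amp,
      hand_peak_velocity_cms = hand_vpk,
      sacc_amplitude_cm = if (saccade_present) rs$amplitude_cm else NA_real_,
      sacc_peak_velocity_cms = if (saccade_present) rs$peak_velocity_cms else NA_real_,
      sacc_onset_ms = if (saccade_present) rs$onset_ms else NA_real_,
      sacc_offset_ms = if (saccade_present) rs$offset_ms else NA_real_,
      sacc_err_x_cm = sacc_err[1], sacc_err_y_cm = sacc_err[2],
      eye_x_onset_cm = ep$x_cm[1], eye_y_onset_cm = ep$y_cm[1],
      eye_x_jump_cm = ep$x_cm[2], eye_y_jump_cm = ep$y_cm[2],
      eye_x_jump_p250_cm = ep$x_cm[3], eye_y_jump_p250_cm = ep$y_cm[3],
      success = icpt$success,
      contact_t_ms = icpt$contact_t_ms,
      contact_x_cm = icpt$contact_x_cm, contact_y_cm = icpt$contact_y_cm))
}

#' Measure every recording in a list
#'
#' @param recordings List of `trial_recording` objects.
#' @param config A [task_config()].
#' @return A tibble with one row per trial.
#' @export
analyze_recordings <- function(recordings, config) {
  dplyr::bind_rows(lapply(recordings, measure_trial, config = config))
}

#' Write per-trial measures as CSV
#'
#' @param measures Measures tibble from [measure_trial()] rows.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_measures <- function(measures, path) {
  write.csv(measures, path, row.names = FALSE)
  invisible(path)
}
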