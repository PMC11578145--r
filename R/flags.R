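#' Flag a trial for exclusion
#'
#' Applies the paradigm's trial-flagging rules to a filtered trial:
#'
#' * `signal_loss` — a masked eye-signal gap of at least `gap_ms` (default
#'   40 ms; shorter gaps are bridged by interpolation during filtering)
#'   intersects the analysis window from target motion onset to the
#'   interception (or to the end of the interception zone on misses).
#' * `preemptive` — on jump trials, the provisional extrapolation reaction
#'   time of the hand is below `preempt_ms` (120 ms) after the jump, or the
#'   hand first moved to the opposite side of the jump direction (a
#'   displacement of at least `opposite_cm` opposite to the jump before any
#'   same-sized displacement toward it).
#'
#' @param filtered A `filtered_trial` (or a list with `spec`, `hand`, `eye`,
#'   `target` holding filtered, differentiated traces).
#' @param config A [task_config()].
#' @param preempt_ms Preemptive reaction-time threshold, ms.
#' @param opposite_cm Opposite-side displacement criterion, cm.
#' @param gap_ms Minimum gap duration that counts as signal loss, ms.
#' @return A list with `flag` (`"signal_loss"`, `"preemptive"` or `"none"`)
#'   and `reason` (text).
#' @export
flag_trial <- function(filtered, config, preempt_ms = 120, opposite_cm = 0.5,
                       gap_ms = 40) {
  spec <- filtered$spec
  icpt <- detect_interception(filtered$hand, filtered$target, config)
  window_end <- if (icpt$success) icpt$contact_t_ms else icpt$zone_exit_ms

  # signal loss: long masked gaps inside the analysis window
  eye <- filtered$eye
  valid <- if ("valid" %in% names(eye)) eye$valid else rep(TRUE, nrow(eye))
  if (any(!valid)) {
    rate <- sampling_rate(eye)
    r <- rle(!valid)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    gaps <- which(r$values & r$lengths >= gap_ms / 1000 * rate)
    for (g in gaps) {
      if (eye$t_ms[starts[g]] <= window_end && eye$t_ms[ends[g]] >= 0) {
        return(list(flag = "signal_loss",
                    reason = sprintf("eye gap %.0f-%.0f ms in analysis window",
                                     eye$t_ms[starts[g]], eye$t_ms[ends[g]])))
      }
    }
  }

  jump_ms <- spec$jump_onset_ms
  if (!is.na(jump_ms) && spec$jump_direction != 0) {
    hand <- filtered$hand
    rt <- hand_reaction_time(hand, jump_ms, spec$jump_direction,
                             window_end_ms = max(hand$t_ms))
    if (!is.na(rt) && rt < preempt_ms) {
      return(list(flag = "preemptive",
                  reason = sprintf("hand RT %.0f ms < %g ms", rt, preempt_ms)))
    }
    # opposite-side test: signed displacement from the position at jump time
    sel <- hand$t_ms >= jump_ms
    x_at_jump <- hand$x_cm[which(sel)[1]]
    d <- spec$jump_direction * (hand$x_cm[sel] - x_at_jump)
    first_big <- which(abs(d) >= opposite_cm)
    if (length(first_big) && d[first_big[1]] < 0) {
      return(list(flag = "preemptive",
                  reason = sprintf("moved >= %g cm opposite to the jump", opposite_cm)))
    }
  }
  list(flag = "none", reason = "")
}
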