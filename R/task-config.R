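#' Task configuration for the target-jump interception paradigm
#'
#' Bundles every geometric and timing constant of the task: a target descends
#' at constant speed down the vertical midline of a workspace and, on jump
#' trials, is displaced instantaneously sideways at one of three onset
#' heights. The hand controls a small paddle that must contact the target
#' before it leaves the workspace. The coordinate frame has its origin at the
#' centre of the start area, x rightward and y upward, all positions in cm;
#' the target appears at `target_start_height` on the midline.
#'
#' Defaults are the standard values of the paradigm: 25 cm/s target speed,
#' 22 cm start height, 0.5 cm target radius, a 2 x 0.5 cm paddle inside a
#' 28 x 3.5 cm workspace with a 3.5 x 2 cm start area, jump onset heights of
#' 11.25 / 8.75 / 6.25 cm (low / medium / high urgency), 3 and 6 cm jumps,
#' 37 cm viewing distance, 1000 Hz hand and 500 Hz eye sampling, 200 ms hold,
#' 500 ms intertrial delay and a ~50 ms display latency (modelled only as a
#' constant visuomotor delay in the generator).
#'
#' @param target_speed Target descent speed, cm/s.
#' @param target_start_height Height of target appearance above the start-area
#'   centre, cm.
#' @param target_radius Target radius, cm.
#' @param paddle_width,paddle_height Paddle dimensions, cm.
#' @param workspace_width,workspace_height Workspace dimensions, cm.
#' @param start_area_width,start_area_height Start-area dimensions, cm.
#' @param jump_onset_heights Named numeric vector (low, medium, high) of jump
#'   onset heights above the start-area centre, cm; must be strictly
#'   decreasing from low to high urgency.
#' @param jump_sizes Allowed horizontal jump magnitudes, cm.
#' @param viewing_distance Eye-to-screen distance, cm.
#' @param hand_rate,eye_rate Sampling rates, Hz; `hand_rate >= eye_rate`.
#' @param hold_duration Required hold in the start area before target onset, ms.
#' @param intertrial_delay Delay between trials, ms.
#' @param display_latency Constant visuomotor display delay, ms.
#'
#' @return An object of class `task_config` (a named list).
#' @examples
#' cfg <- task_config()
#' response_window(cfg, "high")
#' @export
task_config <- function(target_speed = 25,
                        target_start_height = 22,
                        target_radius = 0.5,
                        paddle_width = 2,
                        paddle_height = 0.5,
                        workspace_width = 28,
                        workspace_height = 3.5,
                        start_area_width = 3.5,
                        start_area_height = 2,
                        jump_onset_heights = c(low = 11.25, medium = 8.75, high = 6.25),
                        jump_sizes = c(3, 6),
                        viewing_distance = 37,
                        hand_rate = 1000,
                        eye_rate = 500,
                        hold_duration = 200,
                        intertrial_delay = 500,
                        display_latency = 50) {
  lengths <- c(target_speed, target_start_height, target_radius, paddle_width,
               paddle_height, workspace_width, workspace_height,
               start_area_width, start_area_height, jump_onset_heights,
               jump_sizes, viewing_distance)
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("all task lengths and speeds must be positive and finite", call. = FALSE)
  }
  if (!all(c("low", "medium", "high") %in% names(jump_onset_heights))) {
    stop("`jump_onset_heights` must be named low, medium, high", call. = FALSE)
  }
  jump_onset_heights <- jump_onset_heights[c("low", "medium", "high")]
  if (any(diff(jump_onset_heights) >= 0)) {
    stop("`jump_onset_heights` must be strictly decreasing from low to high urgency",
         call. = FALSE)
  }
  if (hand_rate < eye_rate) stop("`hand_rate` must be >= `eye_rate`", call. = FALSE)
  structure(
    list(target_speed = target_speed,
         target_start_height = target_start_height,
         target_radius = target_radius,
         paddle_width = paddle_width, paddle_height = paddle_height,
         workspace_width = workspace_width, workspace_height = workspace_height,
         start_area_width = start_area_width, start_area_height = start_area_height,
         jump_onset_heights = jump_onset_heights,
         jump_sizes = jump_sizes,
         viewing_distance = viewing_distance,
         hand_rate = hand_rate, eye_rate = eye_rate,
         hold_duration = hold_duration, intertrial_delay = intertrial_delay,
         display_latency = display_latency),
    class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config>\n")
  cat(sprintf("  target: %.3g cm/s down from %.3g cm, radius %.3g cm\n",
              x$target_speed, x$target_start_height, x$target_radius))
  cat(sprintf("  paddle %.3g x %.3g cm, workspace %.3g x %.3g cm\n",
              x$paddle_width, x$paddle_height, x$workspace_width, x$workspace_height))
  cat(sprintf("  jump onsets (cm): low %.4g, medium %.4g, high %.4g; sizes %s cm\n",
              x$jump_onset_heights[["low"]], x$jump_onset_heights[["medium"]],
              x$jump_onset_heights[["high"]],
              paste(x$jump_sizes, collapse = "/")))
  cat(sprintf("  sampling: hand %g Hz, eye %g Hz\n", x$hand_rate, x$eye_rate))
  invisible(x)
}

#' Read a task configuration from a YAML file
#'
#' Any field of [task_config()] may appear in the file; missing fields keep
#' their defaults. `jump_onset_heights` is read as a mapping with keys
#' `low`, `medium`, `high`.
#'
#' @param path Path to a YAML file.
#' @return A `task_config` object.
#' @export
read_task_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(task_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("unknown task_config fields in YAML: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$jump_onset_heights)) {
    raw$jump_onset_heights <- unlist(raw$jump_onset_heights)
  }
  do.call(task_config, raw)
}

#' Time available to respond after a target jump
#'
#' The response window is the time the target needs to travel from its jump
#' onset height to the start-area centre: `jump_onset_height / target_speed`.
#' With the default geometry this is 450, 350 and 250 ms for low, medium and
#' high urgency.
#'
#' @param config A [task_config()].
#' @param urgency One of `"low"`, `"medium"`, `"high"` (vectorised).
#' @return Response window(s) in ms.
#' @examples
#' response_window(task_config(), c("low", "medium", "high"))
#' @export
response_window <- function(config, urgency) {
  stopifnot(inherits(config, "task_config"))
  if (!all(urgency %in% c("low", "medium", "high"))) {
    stop("`urgency` must be one of 'low', 'medium', 'high'", call. = FALSE)
  }
  unname(config$jump_onset_heights[urgency] / config$target_speed * 1000)
}

#' Time of jump onset from target motion onset
#'
#' @param config A [task_config()].
#' @param urgency Urgency level(s).
#' @return Jump onset time(s) in ms: the time for the target to descend from
#'   its start height to the jump onset height.
#' @export
jump_onset_time <- function(config, urgency) {
  stopifnot(inherits(config, "task_config"))
  if (!all(urgency %in% c("low", "medium", "high"))) {
    stop("`urgency` must be one of 'low', 'medium', 'high'", call. = FALSE)
  }
  unname((config$target_start_height - config$jump_onset_heights[urgency]) /
           config$target_speed * 1000)
}

#' Convert an on-screen length to visual angle
#'
#' Uses the small-segment convention `atan(length / viewing_distance)`, i.e.
#' the angle subtended at the eye by a segment extending from the line of
#' sight. At 37 cm this reproduces the paradigm's 1.5 visual degrees per cm.
#'
#' @param length Length(s) on the screen, cm.
#' @param viewing_distance Eye-to-screen distance, cm (default 37).
#' @return Visual angle(s) in degrees.
#' @examples
#' cm_to_deg(1)  # ~1.5
#' cm_to_deg(3)  # ~4.6
#' @export
cm_to_deg <- function(length, viewing_distance = 37) {
  if (!is.numeric(viewing_distance) || any(viewing_distance <= 0)) {
    stop("`viewing_distance` must be positive", call. = FALSE)
  }
  atan(length / viewing_distance) * 180 / pi
}

#' End of the interception window
#'
#' Last moment at which the target can still be contacted: the time when the
#' bottom of the target passes the bottom edge of the workspace.
#'
#' @param config A [task_config()].
#' @return Time in ms from target motion onset.
#' @export
trial_end_time <- function(config) {
  stopifnot(inherits(config, "task_config"))
  (config$target_start_height + config$workspace_height / 2 + config$target_radius) /
    config$target_speed * 1000
}
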