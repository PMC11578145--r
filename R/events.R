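#' Detect saccades by the velocity criterion
#'
#' A saccade is any maximal run of at least `min_run` consecutive samples in
#' which the filtered eye speed exceeds `threshold_cms` (30 cm/s on screen by
#' default, applied to 2-D speed). The onset is the last reversal of the sign
#' of the acceleration signal (rate of change of speed) at or before the run
#' start, and the offset is the first reversal after the speed falls back
#' below the criterion; both searches are bounded at `search_ms` around the
#' threshold crossings, with ties resolved toward the earlier sample for
#' onsets and the later sample for offsets. Events whose gap is shorter than
#' `merge_ms` are merged. Masked (`NA`) samples never exceed the criterion.
#'
#' @param eye A filtered, differentiated eye trace ([filter_eye()] +
#'   [differentiate()]).
#' @param threshold_cms Speed criterion, cm/s.
#' @param min_run Minimum run length in samples.
#' @param merge_ms Events closer than this are merged, ms.
#' @param search_ms Bound on the acceleration-reversal search, ms.
#' @return A tibble with one row per saccade: `onset_ms`, `offset_ms`,
#'   `start_x_cm`, `start_y_cm`, `end_x_cm`, `end_y_cm`, `amplitude_cm`
#'   (Euclidean onset-to-offset distance) and `peak_velocity_cms`.
#' @export
detect_saccades <- function(eye, threshold_cms = 30, min_run = 5,
                            merge_ms = 10, search_ms = 100) {
  n <- nrow(eye)
  empty <- tibble::tibble(onset_ms = numeric(), offset_ms = numeric(),
                          start_x_cm = numeric(), start_y_cm = numeric(),
                          end_x_cm = numeric(), end_y_cm = numeric(),
                          amplitude_cm = numeric(), peak_velocity_cms = numeric())
  if (n < min_run) return(empty)
  rate <- sampling_rate(eye)
  nsearch <- round(search_ms / 1000 * rate)
  sp <- eye$speed_cms
  ac <- eye$accel_cms2
  above <- !is.na(sp) & sp > threshold_cms
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= min_run)
  if (length(keep) == 0) return(empty)
  runs <- data.frame(start = starts[keep], end = ends[keep])

  # merge runs whose gap is shorter than merge_ms
  gap_samp <- merge_ms / 1000 * rate
  if (nrow(runs) > 1) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] < gap_samp) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }

  out <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    i1 <- runs$start[i]; i2 <- runs$end[i]
    # sign test carries a small dead band (1% of the event's peak
    # acceleration) so that sub-cm/s^2 ripple left by zero-phase filtering
    # cannot masquerade as a sign reversal far from the event
    span <- max(1, i1 - nsearch):min(n, i2 + 1 + nsearch)
    eps <- 0.01 * max(abs(ac[span]), na.rm = TRUE)
    win_on <- max(1, i1 - nsearch):i1
    cand <- win_on[!is.na(ac[win_on]) & ac[win_on] <= eps]
    onset <- if (length(cand)) max(cand) else win_on[1]
    win_off <- min(n, i2 + 1):min(n, i2 + 1 + nsearch)
    cand <- win_off[!is.na(ac[win_off]) & ac[win_off] >= -eps]
    offset <- if (length(cand)) min(cand) else win_off[length(win_off)]
    seg <- onset:offset
    out[[i]] <- tibble::tibble(
      onset_ms = eye$t_ms[onset], offset_ms = eye$t_ms[offset],
      start_x_cm = eye$x_cm[onset], start_y_cm = eye$y_cm[onset],
      end_x_cm = eye$x_cm[offset], end_y_cm = eye$y_cm[offset],
      amplitude_cm = sqrt((eye$x_cm[offset] - eye$x_cm[onset])^2 +
                            (eye$y_cm[offset] - eye$y_cm[onset])^2),
      peak_velocity_cms = max(sp[seg], na.rm = TRUE))
  }
  dplyr::bind_rows(out)
}

#' First reactive saccade after a target jump
#'
#' Returns the earliest detected saccade whose onset is at least 50 ms after
#' the jump (inclusive bound), or no row when the trial has no jump or no
#' such saccade.
#'
#' @param events Saccade tibble from [detect_saccades()], sorted by onset.
#' @param jump_ms Jump time, ms (`NA` for no-jump trials).
#' @param min_latency_ms Minimum latency, ms (default 50).
#' @return A one-row tibble (the event plus `eye_rt_ms = onset - jump`), or a
#'   zero-row tibble if absent.
#' @export
first_response_saccade <- function(events, jump_ms, min_latency_ms = 50) {
  none <- events[0, ]
  none$eye_rt_ms <- numeric(0)
  if (is.na(jump_ms) || nrow(events) == 0) return(none)
  hit <- which(events$onset_ms >= jump_ms + min_latency_ms)
  if (length(hit) == 0) return(none)
  ev <- events[hit[1], ]
  ev$eye_rt_ms <- ev$onset_ms - jump_ms
  ev
}

#' Hand reaction time by the extrapolation method
#'
#' Takes the jump-direction-signed horizontal hand velocity on the window
#' from the jump to `window_end_ms`, finds its peak, locates (with linear
#' interpolation between samples) the last upward crossings of 25% and 75%
#' of the peak on the rising limb, and extrapolates the line through those
#' two points back to zero velocity. The reaction time is that intercept
#' minus the jump time; a negative value means the movement started before
#' the jump (the caller flags such trials preemptive).
#'
#' @param hand A filtered, differentiated hand trace.
#' @param jump_ms Jump time, ms.
#' @param jump_direction +1 or -1.
#' @param window_end_ms End of the response window, ms.
#' @param min_peak_cms Peak signed velocity below which the trial counts as
#'   "no response" (returns `NA`), cm/s.
#' @return Reaction time in ms, or `NA` if there was no response.
#' @export
hand_reaction_time <- function(hand, jump_ms, jump_direction, window_end_ms,
                               min_peak_cms = 2) {
  if (is.na(jump_ms) || jump_direction == 0) return(NA_real_)
  sel <- which(hand$t_ms >= jump_ms & hand$t_ms <= window_end_ms)
  if (length(sel) < 3) return(NA_real_)
  v <- jump_direction * hand$vx_cms[sel]
  t <- hand$t_ms[sel]
  ipk <- which.max(v)
  vpk <- v[ipk]
  if (!is.finite(vpk) || vpk < min_peak_cms) return(NA_real_)

  cross_time <- function(level) {
    # last upward crossing of `level` on the rising limb
    idx <- which(v[seq_len(ipk - 1)] < level & v[2:ipk] >= level)
    if (length(idx) == 0) return(NA_real_)
    i <- max(idx)
    t[i] + (level - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
  }
  t25 <- cross_time(0.25 * vpk)
  t75 <- cross_time(0.75 * vpk)
  if (is.na(t25) || is.na(t75) || t75 <= t25) return(NA_real_)
  slope <- 0.5 * vpk / (t75 - t25)
  t0 <- t25 - 0.25 * vpk / slope
  t0 - jump_ms
}

#' Detect paddle-target contact
#'
#' The paddle is an axis-aligned rectangle centred on the hand position;
#' contact occurs at the first common-timeline sample where the distance from
#' the target centre to the rectangle is at most the target radius. The
#' interception succeeds if contact happens before the bottom of the target
#' passes the bottom of the workspace; otherwise the time the target left the
#' interception zone is recorded.
#'
#' @param hand Hand trace (`t_ms`, `x_cm`, `y_cm`).
#' @param target Target trace on a timeline covering the hand timeline.
#' @param config A [task_config()].
#' @return A list: `success`, `contact_t_ms`, `contact_x_cm`, `contact_y_cm`
#'   (hand position at contact; `NA` on a miss) and `zone_exit_ms`.
#' @export
detect_interception <- function(hand, target, config) {
  stopifnot(inherits(config, "task_config"))
  zone_exit <- trial_end_time(config)
  common <- intersect(hand$t_ms, target$t_ms)
  common <- common[common <= zone_exit]
  hi <- match(common, hand$t_ms)
  ti <- match(common, target$t_ms)
  ddx <- pmax(abs(target$x_cm[ti] - hand$x_cm[hi]) - config$paddle_width / 2, 0)
  ddy <- pmax(abs(target$y_cm[ti] - hand$y_cm[hi]) - config$paddle_height / 2, 0)
  hit <- which(sqrt(ddx^2 + ddy^2) <= config$target_radius)
  if (length(hit) == 0) {
    return(list(success = FALSE, contact_t_ms = NA_real_,
                contact_x_cm = NA_real_, contact_y_cm = NA_real_,
                zone_exit_ms = zone_exit))
  }
  k <- hit[1]
  list(success = TRUE, contact_t_ms = common[k],
       contact_x_cm = hand$x_cm[hi[k]], contact_y_cm = hand$y_cm[hi[k]],
       zone_exit_ms = zone_exit)
}

#' Eye positions at the three analysis epochs
#'
#' Nearest-sample eye positions at target motion onset, at the target jump
#' and 250 ms after the jump. Masked samples give `NA`; on no-jump trials the
#' jump-referenced epochs are undefined (`NA`).
#'
#' @param eye Eye trace (`t_ms`, `x_cm`, `y_cm`, optionally `valid`).
#' @param jump_ms Jump time, ms (`NA` for no-jump trials).
#' @return A tibble with columns `epoch` (`onset`, `jump`, `jump_p250`),
#'   `t_ms`, `x_cm`, `y_cm`.
#' @export
epoch_positions <- function(eye, jump_ms) {
  times <- c(onset = 0, jump = jump_ms, jump_p250 = jump_ms + 250)
  at <- function(tt) {
    if (is.na(tt)) return(c(NA_real_, NA_real_))
    i <- which.min(abs(eye$t_ms - tt))
    c(eye$x_cm[i], eye$y_cm[i])
  }
  pos <- vapply(times, at, numeric(2))
  tibble::tibble(epoch = names(times), t_ms = unname(times),
                 x_cm = unname(pos[1, ]), y_cm = unname(pos[2, ]))
}

#' Hand movement amplitude
#'
#' The farthest Euclidean distance the hand travelled from its position at
#' target motion onset, over the window from motion onset to the interception
#' (or to the time the target left the interception zone on misses).
#'
#' @param hand Hand trace.
#' @param window_end_ms End of the window, ms.
#' @return Amplitude in cm.
#' @export
movement_amplitude <- function(hand, window_end_ms) {
  sel <- hand$t_ms <= window_end_ms
  dx <- hand$x_cm[sel] - hand$x_cm[1]
  dy <- hand$y_cm[sel] - hand$y_cm[1]
  max(sqrt(dx^2 + dy^2))
}
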