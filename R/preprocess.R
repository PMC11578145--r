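# Zero-phase Butterworth filtering of kinematic traces.
#
# signal::filtfilt applies no edge treatment, so a trace that starts away
# from zero would carry a large startup transient. We therefore pad both ends
# by odd reflection (2*x[1] - x, mirrored) before the forward-backward pass
# and drop the padding afterwards; pad length covers about three time
# constants of the filter.
zero_phase_filter <- function(x, order, cutoff_hz, rate_hz) {
  bf <- signal::butter(order, cutoff_hz / (rate_hz / 2), type = "low")
  n <- length(x)
  np <- min(n - 1, ceiling(5 * rate_hz / cutoff_hz))
  pre <- 2 * x[1] - x[(np + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- signal::filtfilt(bf, c(pre, x, post))
  y[(np + 1):(np + n)]
}

sampling_rate <- function(trace) {
  dt <- diff(trace$t_ms)
  if (length(dt) == 0 || any(abs(dt - dt[1]) > 1e-6)) {
    stop("trace must be uniformly sampled", call. = FALSE)
  }
  1000 / dt[1]
}

# Linear interpolation across masked samples (for filtering continuity only).
bridge_gaps <- function(x, valid) {
  if (all(valid)) return(x)
  idx <- seq_along(x)
  if (sum(valid) < 2) stop("too few valid samples to bridge gaps", call. = FALSE)
  out <- x
  out[!valid] <- stats::approx(idx[valid], x[valid], xout = idx[!valid],
                               rule = 2)$y
  out
}

#' Low-pass filter a hand trace
#'
#' Third-order zero-phase (forward-backward) Butterworth low-pass at 20 Hz,
#' applied to the x and y position signals independently.
#'
#' @param trace Tibble with `t_ms`, `x_cm`, `y_cm` (uniformly sampled) and
#'   optionally `valid`.
#' @param order,cutoff_hz Filter order and cutoff (defaults 3, 20 Hz).
#' @return The trace with `x_cm`, `y_cm` replaced by their filtered versions.
#' @export
filter_hand <- function(trace, order = 3, cutoff_hz = 20) {
  rate <- sampling_rate(trace)
  if (nrow(trace) < 20) {
    stop("hand trace too short to filter: need at least 20 samples", call. = FALSE)
  }
  trace$x_cm <- zero_phase_filter(trace$x_cm, order, cutoff_hz, rate)
  trace$y_cm <- zero_phase_filter(trace$y_cm, order, cutoff_hz, rate)
  trace
}

#' Low-pass filter an eye trace
#'
#' Second-order zero-phase Butterworth low-pass at 15 Hz. Samples masked as
#' invalid (blinks, signal loss) are bridged by linear interpolation so the
#' filter sees a continuous signal, but remain masked in the output: filtered
#' positions at masked samples are set to `NA`, so interpolated values never
#' leak into downstream analyses.
#'
#' @param trace Tibble with `t_ms`, `x_cm`, `y_cm` and optionally a logical
#'   `valid` column (missing means all valid).
#' @param order,cutoff_hz Filter order and cutoff (defaults 2, 15 Hz).
#' @return The trace with filtered positions, `NA` at masked samples, and a
#'   `valid` column.
#' @export
filter_eye <- function(trace, order = 2, cutoff_hz = 15) {
  rate <- sampling_rate(trace)
  if (nrow(trace) < 20) {
    stop("eye trace too short to filter: need at least 20 samples", call. = FALSE)
  }
  valid <- if ("valid" %in% names(trace)) trace$valid else rep(TRUE, nrow(trace))
  x <- bridge_gaps(trace$x_cm, valid)
  y <- bridge_gaps(trace$y_cm, valid)
  x <- zero_phase_filter(x, order, cutoff_hz, rate)
  y <- zero_phase_filter(y, order, cutoff_hz, rate)
  x[!valid] <- NA_real_
  y[!valid] <- NA_real_
  trace$x_cm <- x
  trace$y_cm <- y
  trace$valid <- valid
  trace
}

#' Differentiate a filtered trace
#'
#' Central differences on the uniform sample grid (one-sided at the
#' endpoints). Speed is the Euclidean norm of the velocity components and the
#' acceleration column is the signed rate of change of speed, which is what
#' the saccade onset/offset criterion operates on.
#'
#' @param trace Tibble with `t_ms`, `x_cm`, `y_cm` (filtered).
#' @return The trace with added columns `vx_cms`, `vy_cms`, `speed_cms`,
#'   `accel_cms2`.
#' @export
differentiate <- function(trace) {
  if (nrow(trace) < 3) stop("need at least 3 samples to differentiate", call. = FALSE)
  dt <- 1 / sampling_rate(trace)
  trace$vx_cms <- central_diff(trace$x_cm, dt)
  trace$vy_cms <- central_diff(trace$y_cm, dt)
  trace$speed_cms <- sqrt(trace$vx_cms^2 + trace$vy_cms^2)
  trace$accel_cms2 <- central_diff(trace$speed_cms, dt)
  trace
}

central_diff <- function(z, dt) {
  n <- length(z)
  v <- numeric(n)
  v[2:(n - 1)] <- (z[3:n] - z[1:(n - 2)]) / (2 * dt)
  v[1] <- (z[2] - z[1]) / dt
  v[n] <- (z[n] - z[n - 1]) / dt
  v
}

#' Filter and differentiate both streams of a trial recording
#'
#' Applies [filter_hand()] and [filter_eye()] with their default settings,
#' then [differentiate()], and attaches the trial flag from [flag_trial()].
#'
#' @param recording A `trial_recording` from [simulate_trial()] (or a list
#'   with `spec`, `hand`, `eye`, `target` in the same format).
#' @param config A [task_config()].
#' @return A list of class `filtered_trial` with elements `spec`, `hand`,
#'   `eye`, `target`, `flag`, `flag_reason`.
#' @export
preprocess_trial <- function(recording, config) {
  hand <- differentiate(filter_hand(recording$hand))
  eye <- differentiate(filter_eye(recording$eye))
  out <- structure(list(spec = recording$spec, hand = hand, eye = eye,
                        target = recording$target,
                        participant_id = recording$participant_id,
                        flag = "none", flag_reason = ""),
                   class = "filtered_trial")
  fl <- flag_trial(out, config)
  out$flag <- fl$flag
  out$flag_reason <- fl$reason
  out
}
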