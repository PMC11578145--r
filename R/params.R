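#' Participant parameters for the synthetic-cohort generator
#'
#' Ground-truth description of one simulated participant. Reaction-time means
#' are specified per (certainty, urgency) cell and are defined on the
#' measurement scale of the pipeline: the hand RT is the value the 25-75%
#' extrapolation method reports and the eye RT is the latency the
#' velocity-criterion saccade detector reports on noiseless data (see the
#' methods vignette). Main-sequence ground truth follows the hyperbolic law
#' `v = alpha * (1 - 1/(1 + beta * x))` per effector.
#'
#' Default values emulate the published cohort: hand RTs averaging 188.8 ms
#' and eye RTs 135.4 ms, a 14 ms advantage of high over low certainty for
#' both effectors, hand RTs decreasing monotonically with urgency while eye
#' RTs are fastest at medium urgency, hand vigor increasing with urgency and
#' eye vigor flat, pursuit gain 0.3 (7.5 cm/s against the 25 cm/s target), a
#' 93% reactive-saccade rate, 6.5% blink and 8.5% preemptive trial rates, and
#' eye landing errors that lead the target at low urgency and trail it at
#' high urgency.
#'
#' @param participant_id Integer id.
#' @param hand_rt_mean,eye_rt_mean Named-cell tibbles (`certainty`, `urgency`,
#'   `mean_ms`) or `NULL` for the defaults.
#' @param hand_rt_sd,eye_rt_sd Within-cell RT standard deviations, ms.
#' @param hand_alpha,hand_beta,eye_alpha,eye_beta Main-sequence ground truth
#'   (cm/s and 1/cm); all must be positive.
#' @param hand_vigor,eye_vigor Named vectors of vigor multipliers per urgency
#'   level (unitless).
#' @param eye_hand_rt_cor Within-cell trial-by-trial correlation between eye
#'   and hand RT draws, in \[-1, 1\].
#' @param pursuit_gain Pre-jump smooth-pursuit gain in \[0, 1\].
#' @param catchup_prob Probability of one pre-jump catch-up saccade.
#' @param saccade_prob Probability that a jump trial elicits a reactive
#'   saccade.
#' @param fixation_jitter_sd SD of the initial fixation offset, cm.
#' @param eye_noise_sd,hand_noise_sd Additive white measurement noise, cm.
#' @param blink_prob Per-trial probability of a blink gap.
#' @param blink_duration_ms Blink gap duration, ms.
#' @param preemptive_prob Per-trial probability of a preemptive hand movement
#'   (early or wrong-direction).
#' @param rt_floor_ms Truncation floor for non-preemptive hand RT draws, ms;
#'   kept above the 120 ms preemptive threshold so flag bookkeeping is exact.
#' @param eye_rt_floor_ms Truncation floor for eye RT draws, ms.
#' @param undershoot_cm Hand interception undershoot: the movement amplitude
#'   is `jump_size - undershoot_cm` (contact with the outer paddle edge).
#' @param eye_undershoot_frac Fractional horizontal saccade undershoot.
#' @param landing_error_y_mean Named vector per urgency of mean vertical
#'   saccade landing error, cm (negative = below / ahead of the target).
#' @param landing_error_sd SD of saccade landing error per axis, cm.
#'
#' @return An object of class `participant_params` (a named list).
#' @export
participant_params <- function(participant_id = 1L,
                               hand_rt_mean = NULL,
                               eye_rt_mean = NULL,
                               hand_rt_sd = 25,
                               eye_rt_sd = 18,
                               hand_alpha = 90, hand_beta = 0.25,
                               eye_alpha = 350, eye_beta = 0.2,
                               hand_vigor = c(low = 0.92, medium = 1, high = 1.08),
                               eye_vigor = c(low = 1, medium = 1, high = 1),
                               eye_hand_rt_cor = 0.3,
                               pursuit_gain = 0.3,
                               catchup_prob = 0.55,
                               saccade_prob = 0.93,
                               fixation_jitter_sd = 0.15,
                               eye_noise_sd = 0.08,
                               hand_noise_sd = 0.03,
                               blink_prob = 0.065,
                               blink_duration_ms = 120,
                               preemptive_prob = 0.085,
                               rt_floor_ms = 125,
                               eye_rt_floor_ms = 60,
                               undershoot_cm = 1,
                               eye_undershoot_frac = 0.11,
                               landing_error_y_mean = c(low = -0.94, medium = 0.05,
                                                        high = 1.19),
                               landing_error_sd = 0.25) {
  hand_rt_mean <- hand_rt_mean %||% default_rt_cells("hand")
  eye_rt_mean <- eye_rt_mean %||% default_rt_cells("eye")
  stopifnot(hand_rt_sd >= 0, eye_rt_sd >= 0,
            hand_alpha > 0, hand_beta > 0, eye_alpha > 0, eye_beta > 0,
            pursuit_gain >= 0, pursuit_gain <= 1,
            abs(eye_hand_rt_cor) <= 1,
            rt_floor_ms >= 0, eye_rt_floor_ms >= 0)
  probs <- c(catchup_prob, saccade_prob, blink_prob, preemptive_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  structure(
    list(participant_id = as.integer(participant_id),
         hand_rt_mean = hand_rt_mean, eye_rt_mean = eye_rt_mean,
         hand_rt_sd = hand_rt_sd, eye_rt_sd = eye_rt_sd,
         hand_alpha = hand_alpha, hand_beta = hand_beta,
         eye_alpha = eye_alpha, eye_beta = eye_beta,
         hand_vigor = hand_vigor, eye_vigor = eye_vigor,
         eye_hand_rt_cor = eye_hand_rt_cor,
         pursuit_gain = pursuit_gain, catchup_prob = catchup_prob,
         saccade_prob = saccade_prob,
         fixation_jitter_sd = fixation_jitter_sd,
         eye_noise_sd = eye_noise_sd, hand_noise_sd = hand_noise_sd,
         blink_prob = blink_prob, blink_duration_ms = blink_duration_ms,
         preemptive_prob = preemptive_prob,
         rt_floor_ms = rt_floor_ms, eye_rt_floor_ms = eye_rt_floor_ms,
         undershoot_cm = undershoot_cm,
         eye_undershoot_frac = eye_undershoot_frac,
         landing_error_y_mean = landing_error_y_mean,
         landing_error_sd = landing_error_sd),
    class = "participant_params")
}

# Default per-cell RT means (ms). Cell structure: overall means of 188.8 ms
# (hand) and 135.4 ms (eye); high-certainty cells 7 ms faster and
# low-certainty cells 7 ms slower (14 ms contrast); hand urgency offsets
# low/medium/high = 0/-19/-24 ms about a low-urgency anchor chosen to keep
# the overall mean; eye offsets +5/0/+11 ms about the medium-urgency anchor.
default_rt_cells <- function(effector = c("hand", "eye")) {
  effector <- match.arg(effector)
  cells <- tidyr::expand_grid(certainty = c("high", "low"),
                              urgency = c("low", "medium", "high"))
  if (effector == "hand") {
    anchor <- 188.8 + (19 + 24) / 3
    urg <- c(low = 0, medium = -19, high = -24)
  } else {
    anchor <- 135.4 - (5 + 11) / 3
    urg <- c(low = 5, medium = 0, high = 11)
  }
  cells$mean_ms <- anchor + urg[cells$urgency] +
    ifelse(cells$certainty == "high", -7, 7)
  cells
}

#' @export
print.participant_params <- function(x, ...) {
  cat(sprintf("<participant_params> id %d\n", x$participant_id))
  cat(sprintf("  hand main sequence: alpha %.3g cm/s, beta %.3g /cm\n",
              x$hand_alpha, x$hand_beta))
  cat(sprintf("  eye main sequence: alpha %.3g cm/s, beta %.3g /cm\n",
              x$eye_alpha, x$eye_beta))
  cat(sprintf("  pursuit gain %.2f, saccade rate %.2f, blink %.3f, preemptive %.3f\n",
              x$pursuit_gain, x$saccade_prob, x$blink_prob, x$preemptive_prob))
  invisible(x)
}

#' Noiseless parameter preset
#'
#' Convenience wrapper around [participant_params()] with all measurement
#' noise and artifact probabilities set to zero (no positional noise, no
#' fixation jitter, no blinks, no preemptive movements, saccade on every jump
#' trial, no landing-error scatter). Latency and kinematic variability are
#' retained. Used for ground-truth closure checks.
#'
#' @param ... Passed on to [participant_params()].
#' @return A `participant_params` object.
#' @export
noiseless_params <- function(...) {
  args <- list(fixation_jitter_sd = 0, eye_noise_sd = 0, hand_noise_sd = 0,
               blink_prob = 0, preemptive_prob = 0, saccade_prob = 1,
               landing_error_sd = 0)
  override <- list(...)
  args[names(override)] <- override
  do.call(participant_params, args)
}

#' Draw a cohort of participant parameter sets
#'
#' Participant-to-participant variability is introduced by perturbing the
#' defaults: RT cell means are shifted by participant-level offsets (SD 12 ms
#' hand, 8 ms eye), main-sequence parameters are drawn uniformly from
#' `ranges`, and pursuit gain from its range. All other fields keep the
#' supplied base values.
#'
#' @param n_participants Number of participants (>= 1).
#' @param ranges Named list of `c(min, max)` ranges for `hand_alpha`,
#'   `hand_beta`, `eye_alpha`, `eye_beta`, `pursuit_gain`.
#' @param base A `participant_params` object supplying all non-drawn fields.
#' @param rt_offset_sd Named vector `c(hand = , eye = )` of SDs (ms) for the
#'   participant-level RT shifts.
#' @return A list of `participant_params`, one per participant.
#' @export
draw_participants <- function(n_participants,
                              ranges = default_param_ranges(),
                              base = participant_params(),
                              rt_offset_sd = c(hand = 12, eye = 8)) {
  stopifnot(n_participants >= 1)
  lapply(seq_len(n_participants), function(i) {
    p <- base
    p$participant_id <- as.integer(i)
    p$hand_alpha <- runif(1, ranges$hand_alpha[1], ranges$hand_alpha[2])
    p$hand_beta <- runif(1, ranges$hand_beta[1], ranges$hand_beta[2])
    p$eye_alpha <- runif(1, ranges$eye_alpha[1], ranges$eye_alpha[2])
    p$eye_beta <- runif(1, ranges$eye_beta[1], ranges$eye_beta[2])
    p$pursuit_gain <- runif(1, ranges$pursuit_gain[1], ranges$pursuit_gain[2])
    p$hand_rt_mean$mean_ms <- p$hand_rt_mean$mean_ms + rnorm(1, 0, rt_offset_sd[["hand"]])
    p$eye_rt_mean$mean_ms <- p$eye_rt_mean$mean_ms + rnorm(1, 0, rt_offset_sd[["eye"]])
    p
  })
}

#' Default between-participant parameter ranges
#'
#' @return Named list of `c(min, max)` ranges used by [draw_participants()].
#' @export
default_param_ranges <- function() {
  list(hand_alpha = c(75, 105), hand_beta = c(0.18, 0.32),
       eye_alpha = c(300, 400), eye_beta = c(0.15, 0.25),
       pursuit_gain = c(0.2, 0.4))
}
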