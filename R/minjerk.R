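#' Minimum-jerk position profile
#'
#' Smooth point-to-point displacement used as the movement primitive for both
#' effectors: `s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5` on `tau in [0, 1]`,
#' clamped outside. The associated velocity is bell-shaped with peak
#' `1.875 * A / T` at the movement midpoint.
#'
#' @param t_s Sample times, s.
#' @param onset_s Movement start, s.
#' @param duration_s Movement duration, s.
#' @param amplitude Total displacement (any unit).
#' @return Displacement at `t_s`, same unit as `amplitude`.
#' @export
minimum_jerk <- function(t_s, onset_s, duration_s, amplitude = 1) {
  tau <- pmin(pmax((t_s - onset_s) / duration_s, 0), 1)
  amplitude * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

# Foot of the chord through the 25% and 75% points of the rising limb of a
# minimum-jerk velocity bell, as a fraction of movement duration after the
# true movement start. Closed form: tau at v = p*vpk solves
# tau(1-tau) = sqrt(p)/4 on the rising limb.
minjerk_extrapolation_foot <- function() {
  tau_at <- function(p) (1 - sqrt(1 - sqrt(p))) / 2
  v_at <- function(tau) 30 * tau^2 * (1 - tau)^2
  t25 <- tau_at(0.25); t75 <- tau_at(0.75)
  slope <- (v_at(t75) - v_at(t25)) / (t75 - t25)
  t25 - v_at(t25) / slope
}

# duration (s) of a movement of amplitude A whose peak velocity follows the
# hyperbolic main sequence v = alpha * (1 - 1/(1 + beta * A)), scaled by a
# vigor multiplier
main_sequence_duration <- function(amplitude, alpha, beta, vigor = 1) {
  vpk <- vigor * alpha * (1 - 1 / (1 + beta * amplitude))
  1.875 * amplitude / vpk
}
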