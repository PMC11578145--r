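#' Fit the hyperbolic main-sequence relation
#'
#' Least-squares fit of the saturating amplitude-peak-velocity law
#' `v = alpha * (1 - 1 / (1 + beta * x))` to one participant's movements
#' (one fit per effector, pooled across conditions). Fitting uses
#' Levenberg-Marquardt with multi-start initialisation (`alpha0 = 1.1 * max
#' observed velocity`; `beta0` in 0.1, 1, 10), keeping the converged start
#' with the lowest residual sum of squares.
#'
#' @param points A data frame with columns `amplitude_cm` and
#'   `peak_velocity_cms` (one row per movement), or two numeric vectors via
#'   `amplitude` / `velocity`.
#' @param effector Label stored in the fit (`"hand"` or `"eye"`).
#' @param participant_id Optional id stored in the fit.
#' @param min_points Minimum number of points required (default 20).
#' @return An object of class `main_sequence_fit` with fields `alpha`, `beta`,
#'   `n_points`, `rmse`, `converged`, `effector`, `participant_id` and the
#'   underlying `nls` fit.
#' @examples
#' x <- runif(50, 1, 8)
#' v <- 60 * (1 - 1 / (1 + 0.8 * x))
#' fit <- fit_main_sequence(data.frame(amplitude_cm = x, peak_velocity_cms = v))
#' coef(fit)
#' @export
fit_main_sequence <- function(points, effector = c("hand", "eye"),
                              participant_id = NA_integer_, min_points = 20) {
  effector <- match.arg(effector)
  dat <- data.frame(x = points$amplitude_cm, v = points$peak_velocity_cms)
  dat <- dat[stats::complete.cases(dat) & dat$x > 0, ]
  if (nrow(dat) < min_points) {
    stop(sprintf("main-sequence fit needs at least %d points, got %d",
                 min_points, nrow(dat)), call. = FALSE)
  }
  alpha0 <- 1.1 * max(dat$v)
  best <- NULL
  for (beta0 in c(0.1, 1, 10)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ alpha * (1 - 1 / (1 + beta * x)), data = dat,
                        start = list(alpha = alpha0, beta = beta0),
                        lower = c(alpha = 1e-9, beta = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    out <- structure(list(alpha = NA_real_, beta = NA_real_,
                          n_points = nrow(dat), rmse = NA_real_,
                          converged = FALSE, effector = effector,
                          participant_id = participant_id, fit = NULL,
                          data = dat),
                     class = "main_sequence_fit")
    return(out)
  }
  cf <- coef(best$fit)
  structure(list(alpha = unname(cf["alpha"]), beta = unname(cf["beta"]),
                 n_points = nrow(dat),
                 rmse = sqrt(best$rss / nrow(dat)),
                 converged = best$fit$convInfo$isConv,
                 effector = effector, participant_id = participant_id,
                 fit = best$fit, data = dat),
            class = "main_sequence_fit")
}

#' @export
print.main_sequence_fit <- function(x, ...) {
  cat(sprintf("<main_sequence_fit> %s: alpha %.4g cm/s, beta %.4g /cm (n = %d, rmse %.3g)%s\n",
              x$effector, x$alpha, x$beta, x$n_points, x$rmse,
              if (isTRUE(x$converged)) "" else " [not converged]"))
  invisible(x)
}

#' @export
coef.main_sequence_fit <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta)
}

#' @export
tidy.main_sequence_fit <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(term = c("alpha", "beta"),
                          estimate = c(x$alpha, x$beta),
                          std.error = NA_real_))
  }
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2])
}

#' @export
glance.main_sequence_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, beta = x$beta, n_points = x$n_points,
                 rmse = x$rmse, converged = x$converged,
                 effector = x$effector, participant_id = x$participant_id)
}

#' @export
autoplot.main_sequence_fit <- function(object, ...) {
  grid <- tibble::tibble(
    amplitude_cm = seq(0, max(object$data$x) * 1.05, length.out = 200))
  grid$peak_velocity_cms <- expected_velocity(object, grid$amplitude_cm)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$v)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$amplitude_cm,
                                    y = .data$peak_velocity_cms),
                       colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "movement amplitude (cm)",
                  y = "peak velocity (cm/s)",
                  title = sprintf("%s main sequence: alpha = %.3g, beta = %.3g",
                                  object$effector, object$alpha, object$beta)) +
    ggplot2::theme_minimal()
}

#' Expected peak velocity at a given amplitude
#'
#' Evaluates the fitted hyperbolic law `alpha * (1 - 1/(1 + beta * x))`;
#' zero at zero amplitude and bounded above by `alpha`.
#'
#' @param fit A converged `main_sequence_fit`.
#' @param amplitude_cm Amplitude(s), cm; must be non-negative.
#' @return Expected peak velocity, cm/s.
#' @export
expected_velocity <- function(fit, amplitude_cm) {
  stopifnot(inherits(fit, "main_sequence_fit"))
  if (!isTRUE(fit$converged)) {
    stop("expected_velocity requires a converged fit", call. = FALSE)
  }
  if (any(amplitude_cm < 0, na.rm = TRUE)) {
    stop("`amplitude_cm` must be non-negative", call. = FALSE)
  }
  fit$alpha * (1 - 1 / (1 + fit$beta * amplitude_cm))
}

#' Movement vigor
#'
#' Vigor is the ratio of a movement's observed peak velocity to the velocity
#' expected from the participant's main-sequence fit at the same amplitude
#' (`v / v_fit`); values above 1 mark movements faster than that
#' participant's average movement of that amplitude. Undefined (NA) at
#' (near-)zero amplitudes, where the expected velocity vanishes.
#'
#' @param observed_cms Observed peak velocity(ies), cm/s.
#' @param fit A converged `main_sequence_fit`.
#' @param amplitude_cm Movement amplitude(s), cm.
#' @param min_amplitude_cm Amplitudes below this give `NA` (default 0.1 cm).
#' @return Vigor value(s), unitless.
#' @export
vigor_score <- function(observed_cms, fit, amplitude_cm,
                        min_amplitude_cm = 0.1) {
  expected <- expected_velocity(fit, pmax(amplitude_cm, 0))
  out <- observed_cms / expected
  out[is.na(amplitude_cm) | amplitude_cm < min_amplitude_cm] <- NA_real_
  out
}

#' Add per-trial vigor scores to a measures table
#'
#' Fits one main sequence per participant and effector on unflagged trials
#' (saccade-present trials for the eye), then scores every trial against its
#' participant's fit. Trials of participants whose fit did not converge (or
#' had too few points) keep `NA` vigor.
#'
#' @param measures Measures tibble (rows from [measure_trial()]).
#' @param min_points Minimum points per fit, passed to [fit_main_sequence()].
#' @return A list: `measures` (input plus `hand_vigor`, `eye_vigor`) and
#'   `fits` (tibble of per-participant fit parameters via [glance()]).
#' @export
add_vigor <- function(measures, min_points = 20) {
  measures$hand_vigor <- NA_real_
  measures$eye_vigor <- NA_real_
  fits <- list()
  for (pid in unique(measures$participant_id)) {
    rows <- measures$participant_id == pid
    ok <- rows & measures$flag == "none"
    hand_pts <- data.frame(amplitude_cm = measures$hand_amplitude_cm[ok & !is.na(measures$hand_rt_ms)],
                           peak_velocity_cms = measures$hand_peak_velocity_cms[ok & !is.na(measures$hand_rt_ms)])
    eye_ok <- ok & measures$saccade_present
    eye_pts <- data.frame(amplitude_cm = measures$sacc_amplitude_cm[eye_ok],
                          peak_velocity_cms = measures$sacc_peak_velocity_cms[eye_ok])
    for (eff in c("hand", "eye")) {
      pts <- if (eff == "hand") hand_pts else eye_pts
      fit <- tryCatch(fit_main_sequence(pts, eff, pid, min_points),
                      error = function(e) NULL)
      if (!is.null(fit)) fits[[length(fits) + 1]] <- glance(fit)
      if (!is.null(fit) && isTRUE(fit$converged)) {
        if (eff == "hand") {
          sel <- rows & !is.na(measures$hand_rt_ms)
          measures$hand_vigor[sel] <- vigor_score(
            measures$hand_peak_velocity_cms[sel], fit,
            measures$hand_amplitude_cm[sel])
        } else {
          sel <- rows & measures$saccade_present
          measures$eye_vigor[sel] <- vigor_score(
            measures$sacc_peak_velocity_cms[sel], fit,
            measures$sacc_amplitude_cm[sel])
        }
      }
    }
  }
  list(measures = measures, fits = dplyr::bind_rows(fits))
}

#' Export main-sequence fits as JSON
#'
#' @param fits Tibble of fit parameters (from [add_vigor()]).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fits <- function(fits, path) {
  jsonlite::write_json(fits, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
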