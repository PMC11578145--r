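#' Per-participant condition medians
#'
#' Collapses a per-trial measures table to the median of each measure per
#' (participant, certainty, urgency) cell, using unflagged jump trials only
#' and, for measures that require a saccade (the eye measures), only trials
#' in which a reactive saccade was made. Jump size is collapsed by default.
#'
#' @param measures Measures tibble (optionally with vigor columns from
#'   [add_vigor()]).
#' @param measure_cols Character vector of measure columns to summarise;
#'   defaults to the standard set present in the table.
#' @param require_saccade Columns restricted to saccade-present trials.
#' @return A tibble `participant_id`, `certainty`, `urgency`, `measure`,
#'   `median`, `n`; empty cells give `NA` medians.
#' @export
condition_medians <- function(measures,
                              measure_cols = NULL,
                              require_saccade = c("eye_rt_ms", "eye_vigor",
                                                  "sacc_err_x_cm", "sacc_err_y_cm",
                                                  "sacc_amplitude_cm",
                                                  "sacc_peak_velocity_cms")) {
  default_cols <- c("hand_rt_ms", "eye_rt_ms", "hand_vigor", "eye_vigor",
                    "sacc_err_x_cm", "sacc_err_y_cm", "contact_x_cm",
                    "contact_y_cm", "success")
  measure_cols <- measure_cols %||% intersect(default_cols, names(measures))
  dat <- measures[measures$flag == "none" & measures$urgency != "none", ]
  long <- tidyr::pivot_longer(
    dat[, c("participant_id", "certainty", "urgency", "saccade_present",
            measure_cols)],
    dplyr::all_of(measure_cols), names_to = "measure", values_to = "value")
  long$value <- as.numeric(long$value)
  long <- long[!(long$measure %in% require_saccade) | long$saccade_present, ]
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$participant_id, .data$certainty,
                    .data$urgency, .data$measure),
    median = median(.data$value, na.rm = TRUE),
    n = sum(!is.na(.data$value)), .groups = "drop")
  out$median[out$n == 0] <- NA_real_
  out$urgency <- factor(out$urgency, levels = c("low", "medium", "high"))
  out$certainty <- factor(out$certainty, levels = c("high", "low"))
  out
}

#' Two-by-three repeated-measures ANOVA
#'
#' Within-subject ANOVA with factors certainty (2 levels) and urgency (3
#' levels) on per-participant cell values (typically condition medians). Uses
#' the classical univariate partitioning (`aov` with participant error
#' strata, uncorrected degrees of freedom: urgency terms carry
#' `(2, 2 (n - 1))`). Effect sizes are partial eta squared,
#' `SS_effect / (SS_effect + SS_error)` within each stratum. A term with zero
#' effect sum of squares is reported as `F = 0`, `p = 1`.
#'
#' @param summaries Tibble with `participant_id`, `certainty`, `urgency` and
#'   a value column.
#' @param measure Name of the value column (default `"median"`).
#' @return An object of class `rm_anova` whose `table` is a tibble with one
#'   row per term: `term`, `df1`, `df2`, `statistic`, `p.value`, `pes`.
#' @export
rm_anova_2x3 <- function(summaries, measure = "median") {
  dat <- data.frame(
    participant = factor(summaries$participant_id),
    certainty = factor(summaries$certainty),
    urgency = factor(summaries$urgency),
    value = summaries[[measure]])
  dat <- dat[stats::complete.cases(dat), ]
  # listwise deletion: keep participants with all 6 cells
  counts <- table(dat$participant)
  dat <- dat[dat$participant %in% names(counts)[counts == 6], ]
  dat$participant <- droplevels(dat$participant)
  n <- nlevels(dat$participant)
  if (n < 3) stop("need at least 3 complete participants", call. = FALSE)

  fit <- aov(value ~ certainty * urgency +
               Error(participant / (certainty * urgency)), data = dat)
  sm <- summary(fit)
  term_map <- c("certainty" = "Error: participant:certainty",
                "urgency" = "Error: participant:urgency",
                "certainty:urgency" = "Error: participant:certainty:urgency")
  rows <- lapply(names(term_map), function(tm) {
    stratum <- sm[[term_map[[tm]]]][[1]]
    rn <- trimws(rownames(stratum))
    i <- match(tm, rn)
    j <- match("Residuals", rn)
    ss_e <- stratum$`Sum Sq`[i]
    ss_r <- stratum$`Sum Sq`[j]
    f <- stratum$`F value`[i]
    p <- stratum$`Pr(>F)`[i]
    if (!is.finite(f) || ss_e <= .Machine$double.eps * (ss_e + ss_r + 1)) {
      f <- 0; p <- 1
    }
    tibble::tibble(term = tm, df1 = stratum$Df[i], df2 = stratum$Df[j],
                   statistic = f, p.value = p,
                   pes = if (ss_e + ss_r > 0) ss_e / (ss_e + ss_r) else 0)
  })
  structure(list(table = dplyr::bind_rows(rows), n_participants = n,
                 measure = measure),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova> 2x3 within-subject, %d participants, measure '%s'\n",
              x$n_participants, x$measure))
  tb <- x$table
  for (i in seq_len(nrow(tb))) {
    cat(sprintf("  %-18s F(%d, %d) = %.2f, p = %.4g, pes = %.2f\n",
                tb$term[i], tb$df1[i], tb$df2[i], tb$statistic[i],
                tb$p.value[i], tb$pes[i]))
  }
  invisible(x)
}

#' @export
tidy.rm_anova <- function(x, ...) x$table

#' Paired post hoc t-tests with Bonferroni correction
#'
#' Two-sided paired t-tests over a family of contrasts; raw p-values are
#' multiplied by the family size (capped at 1) and Cohen's d is the mean
#' difference over the SD of the differences. Zero-variance, zero-mean
#' difference vectors give `t = 0`, `p = 1`.
#'
#' @param summaries Tibble with `participant_id`, a `cell` column naming the
#'   condition, and a value column.
#' @param contrasts List of length-2 character vectors (cell names to
#'   compare).
#' @param cell Name of the condition column.
#' @param measure Name of the value column.
#' @return A tibble: `contrast`, `estimate` (mean difference), `statistic`,
#'   `df`, `p.value` (raw), `p.adjust` (Bonferroni), `cohens_d`, `n`.
#' @export
posthoc_paired <- function(summaries, contrasts, cell = "cell",
                           measure = "median") {
  k <- length(contrasts)
  rows <- lapply(contrasts, function(ct) {
    a <- summaries[summaries[[cell]] == ct[1], c("participant_id", measure)]
    b <- summaries[summaries[[cell]] == ct[2], c("participant_id", measure)]
    m <- merge(a, b, by = "participant_id")
    d <- m[[paste0(measure, ".x")]] - m[[paste0(measure, ".y")]]
    d <- d[!is.na(d)]
    if (length(d) < 2) stop("need at least 2 complete pairs", call. = FALSE)
    if (sd(d) == 0) {
      tstat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      p <- if (mean(d) == 0) 1 else 0
    } else {
      tt <- t.test(d)
      tstat <- unname(tt$statistic)
      p <- tt$p.value
    }
    tibble::tibble(contrast = paste(ct, collapse = " - "),
                   estimate = mean(d), statistic = tstat,
                   df = length(d) - 1, p.value = p,
                   p.adjust = min(p * k, 1),
                   cohens_d = if (sd(d) == 0) ifelse(mean(d) == 0, 0, Inf)
                   else mean(d) / sd(d),
                   n = length(d))
  })
  dplyr::bind_rows(rows)
}

#' Trial-by-trial linear mixed model linking eye and hand measures
#'
#' Fits `hand ~ eye * certainty * urgency + (1 + eye | participant)` on
#' unflagged jump trials with both measures present. Predictors are
#' standardized before fitting (the eye measure and urgency as centred,
#' unit-variance numeric covariates; certainty as a standardized 0/1
#' indicator of low certainty), so each term is summarised by a single
#' coefficient. If the random-slope fit is singular it is refitted with a
#' random intercept only, with a warning. Confidence intervals are Wald 95%
#' and p-values use Satterthwaite degrees of freedom.
#'
#' @param trials Measures tibble.
#' @param outcome,predictor Column names (e.g. `"hand_rt_ms"`, `"eye_rt_ms"`).
#' @return An object of class `lmm_result`: `table` (tibble of fixed effects:
#'   `term`, `estimate`, `conf.low`, `conf.high`, `p.value`), `ranef_var`
#'   (random-effect variances), `n_trials`, `singular`, and the `lmerMod`
#'   fit.
#' @export
fit_lmm <- function(trials, outcome = "hand_rt_ms", predictor = "eye_rt_ms") {
  dat <- trials[trials$flag == "none" & trials$urgency != "none" &
                  !is.na(trials[[outcome]]) & !is.na(trials[[predictor]]), ]
  zdat <- data.frame(
    y = dat[[outcome]],
    eye = as.numeric(scale(dat[[predictor]])),
    certainty = as.numeric(scale(as.numeric(dat$certainty == "low"))),
    urgency = as.numeric(scale(match(dat$urgency, c("low", "medium", "high")))),
    participant = factor(dat$participant_id))
  form <- y ~ eye * certainty * urgency + (1 + eye | participant)
  fit <- lmerTest::lmer(form, data = zdat, REML = TRUE)
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning("singular random-slope fit; refitting with random intercept only",
            call. = FALSE)
    fit <- lmerTest::lmer(y ~ eye * certainty * urgency + (1 | participant),
                          data = zdat, REML = TRUE)
  }
  sm <- summary(fit)$coefficients
  ci <- confint(fit, parm = "beta_", method = "Wald")
  table <- tibble::tibble(term = rownames(sm), estimate = sm[, "Estimate"],
                          conf.low = ci[rownames(sm), 1],
                          conf.high = ci[rownames(sm), 2],
                          p.value = sm[, "Pr(>|t|)"])
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(table = table,
                 ranef_var = setNames(vc$vcov, paste(vc$grp, vc$var1, vc$var2,
                                                     sep = ".")),
                 n_trials = nrow(zdat), singular = singular, fit = fit,
                 outcome = outcome, predictor = predictor),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("<lmm_result> %s ~ %s * certainty * urgency (%d trials)%s\n",
              x$outcome, x$predictor, x$n_trials,
              if (x$singular) " [random intercept only]" else ""))
  tb <- x$table
  for (i in seq_len(nrow(tb))) {
    cat(sprintf("  %-24s beta = %8.3f [%8.3f, %8.3f], p = %.3g\n",
                tb$term[i], tb$estimate[i], tb$conf.low[i], tb$conf.high[i],
                tb$p.value[i]))
  }
  invisible(x)
}

#' @export
tidy.lmm_result <- function(x, ...) x$table

#' @export
glance.lmm_result <- function(x, ...) {
  tibble::tibble(n_trials = x$n_trials, singular = x$singular,
                 outcome = x$outcome, predictor = x$predictor)
}

#' Per-participant trial-by-trial eye-hand correlations
#'
#' Pearson correlation between the eye and hand measure across unflagged
#' jump trials, per participant and urgency level.
#'
#' @param trials Measures tibble.
#' @param x,y Column names to correlate.
#' @param min_trials Cells with fewer complete trials give `NA`.
#' @return A tibble `participant_id`, `urgency`, `r`, `n`.
#' @export
trialwise_correlations <- function(trials, x = "eye_rt_ms", y = "hand_rt_ms",
                                   min_trials = 5) {
  dat <- trials[trials$flag == "none" & trials$urgency != "none", ]
  dplyr::summarise(
    dplyr::group_by(dat, .data$participant_id, .data$urgency),
    n = sum(stats::complete.cases(.data[[x]], .data[[y]])),
    r = if (n >= min_trials) {
      suppressWarnings(cor(.data[[x]], .data[[y]], use = "complete.obs"))
    } else NA_real_,
    .groups = "drop")
}

#' Condition-level reaction-time plot
#'
#' Median reaction times per participant across certainty and urgency, with
#' group means, in the style of the paradigm's condition summaries.
#'
#' @param summaries Output of [condition_medians()].
#' @param measure Which measure to plot (default `"hand_rt_ms"`).
#' @return A ggplot object.
#' @export
plot_condition_medians <- function(summaries, measure = "hand_rt_ms") {
  dat <- summaries[summaries$measure == measure & !is.na(summaries$median), ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$urgency, y = .data$median,
                                    colour = .data$urgency,
                                    shape = .data$certainty)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4),
                        alpha = 0.6) +
    ggplot2::stat_summary(ggplot2::aes(group = .data$certainty),
                          fun = mean, geom = "line", colour = "black",
                          position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(y = measure, x = "response urgency") +
    ggplot2::theme_minimal()
}
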