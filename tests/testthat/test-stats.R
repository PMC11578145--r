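make_summaries <- function(values) {
  # values: named list cell -> vector over participants
  cells <- tidyr::expand_grid(certainty = c("high", "low"),
                              urgency = c("low", "medium", "high"))
  out <- list()
  for (i in seq_len(nrow(cells))) {
    key <- paste(cells$certainty[i], cells$urgency[i], sep = ".")
    v <- values[[key]]
    out[[i]] <- tibble::tibble(participant_id = seq_along(v),
                               certainty = cells$certainty[i],
                               urgency = cells$urgency[i], median = v)
  }
  dplyr::bind_rows(out)
}

test_that("condition medians are robust cell medians over eligible trials", {
  meas <- tibble::tibble(
    participant_id = 1L, certainty = "high", urgency = "low",
    jump_size = 3, flag = c("none", "none", "none", "preemptive"),
    saccade_present = c(TRUE, TRUE, TRUE, TRUE),
    hand_rt_ms = c(1, 2, 100, 7),
    eye_rt_ms = c(120, 130, 140, 100))
  cm <- condition_medians(meas, measure_cols = c("hand_rt_ms", "eye_rt_ms"))
  expect_equal(cm$median[cm$measure == "hand_rt_ms"], 2)  # flagged trial dropped
  expect_equal(cm$median[cm$measure == "eye_rt_ms"], 130)
  # eye measures use saccade-present trials only
  meas$saccade_present <- c(FALSE, FALSE, TRUE, TRUE)
  cm2 <- condition_medians(meas, measure_cols = c("hand_rt_ms", "eye_rt_ms"))
  expect_equal(cm2$median[cm2$measure == "eye_rt_ms"], 140)
  expect_equal(cm2$median[cm2$measure == "hand_rt_ms"], 2)
  # an all-flagged cell is missing
  meas$flag <- "signal_loss"
  cm3 <- condition_medians(meas, measure_cols = "hand_rt_ms")
  expect_equal(nrow(cm3[!is.na(cm3$median), ]), 0)
})

test_that("2x3 repeated-measures ANOVA has the right degrees of freedom", {
  set.seed(1)
  vals <- replicate(6, rnorm(13), simplify = FALSE)
  names(vals) <- c("high.low", "high.medium", "high.high",
                   "low.low", "low.medium", "low.high")
  an <- rm_anova_2x3(make_summaries(vals))
  tb <- tidy(an)
  expect_equal(tb$df1[tb$term == "certainty"], 1)
  expect_equal(tb$df2[tb$term == "certainty"], 12)
  expect_equal(tb$df1[tb$term == "urgency"], 2)
  expect_equal(tb$df2[tb$term == "urgency"], 24)
  expect_equal(tb$df2[tb$term == "certainty:urgency"], 24)
  expect_true(all(tb$p.value >= 0 & tb$p.value <= 1))
  expect_true(all(tb$pes >= 0 & tb$pes <= 1))
})

test_that("identical cells give F = 0 and a large effect is detected", {
  vals <- rep(list(c(1, 2, 3, 4, 5, 6, 7, 8)), 6)
  names(vals) <- c("high.low", "high.medium", "high.high",
                   "low.low", "low.medium", "low.high")
  an <- rm_anova_2x3(make_summaries(vals))
  expect_true(all(tidy(an)$statistic == 0))
  expect_true(all(tidy(an)$p.value == 1))
  # inject a certainty effect
  set.seed(2)
  vals2 <- lapply(setNames(nm = names(vals)), function(k) {
    rnorm(10, mean = if (startsWith(k, "high")) 0 else 5, sd = 1)
  })
  an2 <- rm_anova_2x3(make_summaries(vals2))
  tb2 <- tidy(an2)
  expect_lt(tb2$p.value[tb2$term == "certainty"], 0.001)
  expect_gt(tb2$pes[tb2$term == "certainty"], 0.5)
})

test_that("paired post hocs match the closed-form paired t", {
  set.seed(3)
  a <- rnorm(10, 1); b <- rnorm(10)
  s <- tibble::tibble(participant_id = rep(1:10, 2),
                      cell = rep(c("A", "B"), each = 10),
                      median = c(a, b))
  out <- posthoc_paired(s, list(c("A", "B")))
  d <- a - b
  t_exact <- mean(d) / (sd(d) / sqrt(10))
  expect_equal(out$statistic, t_exact, tolerance = 1e-9)
  expect_equal(out$cohens_d, mean(d) / sd(d), tolerance = 1e-9)
  expect_equal(out$p.adjust, out$p.value)  # single-contrast family
  # identical pairs: t = 0, p = 1
  s0 <- s; s0$median <- rep(a, 2)
  out0 <- posthoc_paired(s0, list(c("A", "B")))
  expect_equal(out0$statistic, 0)
  expect_equal(out0$p.adjust, 1)
  # Bonferroni multiplies and caps
  s3 <- tibble::tibble(participant_id = rep(1:10, 3),
                       cell = rep(c("A", "B", "C"), each = 10),
                       median = c(a, b, rnorm(10)))
  out3 <- posthoc_paired(s3, list(c("A", "B"), c("A", "C"), c("B", "C")))
  expect_equal(out3$p.adjust, pmin(out3$p.value * 3, 1))
  expect_error(posthoc_paired(s[c(1, 11), ], list(c("A", "B"))), "2 complete")
})

test_that("the mixed model recovers a near-deterministic eye-hand coupling", {
  set.seed(4)
  n <- 40
  trials <- tibble::tibble(
    participant_id = rep(1:8, each = n),
    certainty = sample(c("high", "low"), 8 * n, TRUE),
    urgency = sample(c("low", "medium", "high"), 8 * n, TRUE),
    flag = "none",
    eye_rt_ms = rnorm(8 * n, 135, 15))
  trials$hand_rt_ms <- trials$eye_rt_ms + rnorm(8 * n, 0, 3)
  fit <- suppressWarnings(fit_lmm(trials))
  tb <- tidy(fit)
  sl <- tb[tb$term == "eye", ]
  # slope per SD of the standardized predictor: cor * sd(outcome)
  expected <- cor(trials$eye_rt_ms, trials$hand_rt_ms) * sd(trials$hand_rt_ms)
  expect_equal(unname(sl$estimate), expected, tolerance = 0.05 * expected)
  expect_gt(sl$conf.low, 0)
  expect_lt(sl$p.value, 1e-6)
})

test_that("trialwise correlations recover known structure", {
  set.seed(5)
  n <- 90
  base <- tibble::tibble(
    participant_id = rep(1L, n), certainty = "high",
    urgency = rep(c("low", "medium", "high"), each = n / 3),
    flag = "none")
  perfect <- base
  perfect$eye_rt_ms <- rnorm(n, 135, 10)
  perfect$hand_rt_ms <- perfect$eye_rt_ms
  r1 <- trialwise_correlations(perfect)
  expect_equal(r1$r, rep(1, 3), tolerance = 1e-12)
  sparse <- perfect[1:4, ]
  r2 <- trialwise_correlations(sparse)
  expect_true(all(is.na(r2$r)))
})
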