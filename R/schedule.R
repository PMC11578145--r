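#' Default block allocation
#'
#' The session has six blocks: each jump-size condition (3 cm, 6 cm, mixed)
#' under high certainty (every trial jumps) and low certainty (60% of trials
#' jump, 40% continue down the midline). Per-block counts use the paradigm's
#' published per-urgency interception counts of 32 and 28 and total 960
#' trials with an exact 60/40 split in every low-certainty block:
#' high-certainty constant-size blocks run 32 jumps per urgency (96 trials),
#' the high-certainty mixed block 28 per urgency per size (168), low-certainty
#' constant-size blocks 28 jumps per urgency plus 56 no-jump trials (140) and
#' the low-certainty mixed block 32 per urgency per size plus 128 no-jump
#' trials (320).
#'
#' @return A tibble with one row per block: `certainty`, `jump_size_condition`,
#'   `jumps_per_urgency_per_size` and `n_nojump`.
#' @export
default_allocation <- function() {
  tibble::tibble(
    certainty = rep(c("high", "low"), each = 3),
    jump_size_condition = rep(c("3cm", "6cm", "mixed"), 2),
    jumps_per_urgency_per_size = c(32, 32, 28, 28, 28, 32),
    n_nojump = c(0, 0, 0, 56, 56, 128))
}

block_jump_count <- function(allocation) {
  n_sizes <- ifelse(allocation$jump_size_condition == "mixed", 2L, 1L)
  allocation$jumps_per_urgency_per_size * 3L * n_sizes
}

#' Build a full trial schedule
#'
#' Expands a block allocation into an ordered tibble of trial specifications.
#' Within every block, urgency levels appear equally often among jump trials,
#' left/right jump directions are balanced within each urgency (and jump size)
#' cell, and low-certainty blocks contain exactly the allocated number of
#' no-jump trials; trial order within a block is then shuffled. Blocks are
#' grouped by certainty (order set by `certainty_first`) and the order of
#' jump-size conditions within each certainty group is shuffled. The result is
#' deterministic for a fixed seed.
#'
#' @param config A [task_config()].
#' @param allocation Block allocation tibble, see [default_allocation()].
#' @param seed Integer seed for the shuffles.
#' @param certainty_first `"high"` or `"low"`: which certainty group runs first.
#' @return A tibble with one row per trial: `trial_id` (1-based, session-wide),
#'   `block_id`, `certainty`, `jump_size_condition`, `urgency` (`"none"` on
#'   no-jump trials), `jump_size` (cm, 0 on no-jump trials), `jump_direction`
#'   (-1 left, +1 right, 0 none) and `jump_onset_ms` (NA on no-jump trials).
#' @examples
#' sched <- build_schedule(task_config(), seed = 1)
#' nrow(sched)  # 960
#' @export
build_schedule <- function(config, allocation = default_allocation(), seed = 1L,
                           certainty_first = c("high", "low")) {
  stopifnot(inherits(config, "task_config"))
  certainty_first <- match.arg(certainty_first)
  req <- c("certainty", "jump_size_condition", "jumps_per_urgency_per_size", "n_nojump")
  if (!all(req %in% names(allocation))) {
    stop("`allocation` must have columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(allocation$jumps_per_urgency_per_size <= 0) ||
      any(allocation$jumps_per_urgency_per_size %% 2 != 0)) {
    stop("jump counts must be positive and even (left/right balance)", call. = FALSE)
  }
  n_jump <- block_jump_count(allocation)
  low <- allocation$certainty == "low"
  # low-certainty blocks must realize an exact 40% no-jump fraction
  if (any(allocation$n_nojump[!low] != 0)) {
    stop("high-certainty blocks cannot contain no-jump trials", call. = FALSE)
  }
  frac <- allocation$n_nojump[low] / (allocation$n_nojump[low] + n_jump[low])
  if (any(abs(frac - 0.4) > 1e-12)) {
    stop("allocation does not give an exact 40% no-jump fraction in every ",
         "low-certainty block", call. = FALSE)
  }

  sizes_for <- function(cond) {
    if (cond == "mixed") config$jump_sizes else
      config$jump_sizes[match(cond, paste0(config$jump_sizes, "cm"))]
  }

  set.seed(seed)
  cert_order <- if (certainty_first == "high") c("high", "low") else c("low", "high")
  blocks <- list()
  for (cert in cert_order) {
    rows <- which(allocation$certainty == cert)
    rows <- rows[sample.int(length(rows))]  # shuffle size-condition order
    blocks <- c(blocks, lapply(rows, function(i) allocation[i, ]))
  }

  out <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    al <- blocks[[b]]
    sizes <- sizes_for(al$jump_size_condition)
    per <- al$jumps_per_urgency_per_size
    jump <- tidyr::expand_grid(
      urgency = c("low", "medium", "high"),
      jump_size = sizes,
      jump_direction = c(-1, 1),
      rep = seq_len(per / 2))
    jump$rep <- NULL
    spec <- dplyr::bind_rows(
      jump,
      if (al$n_nojump > 0) {
        tibble::tibble(urgency = "none", jump_size = 0, jump_direction = 0,
                       .rows = al$n_nojump)
      })
    spec <- spec[sample.int(nrow(spec)), ]
    spec$block_id <- b
    spec$certainty <- al$certainty
    spec$jump_size_condition <- al$jump_size_condition
    out[[b]] <- spec
  }
  sched <- dplyr::bind_rows(out)
  sched$trial_id <- seq_len(nrow(sched))
  sched$jump_onset_ms <- ifelse(
    sched$urgency == "none", NA_real_,
    (config$target_start_height - config$jump_onset_heights[
      match(sched$urgency, c("low", "medium", "high"))]) / config$target_speed * 1000)
  sched[, c("trial_id", "block_id", "certainty", "jump_size_condition",
            "urgency", "jump_size", "jump_direction", "jump_onset_ms")]
}

#' Check the structural invariants of a schedule
#'
#' Verifies, by exact counting, that no-jump trials occur only in
#' low-certainty blocks at exactly 40% per block, that urgency levels are
#' equally frequent among jump trials within each block, and that jump
#' directions are balanced within each (block, urgency, size) cell.
#'
#' @param schedule A schedule tibble from [build_schedule()].
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_schedule <- function(schedule) {
  by_block <- split(schedule, schedule$block_id)
  for (bl in by_block) {
    nj <- sum(bl$urgency == "none")
    if (bl$certainty[1] == "high" && nj > 0) {
      stop("no-jump trials in a high-certainty block", call. = FALSE)
    }
    if (bl$certainty[1] == "low" && abs(nj / nrow(bl) - 0.4) > 1e-12) {
      stop("no-jump fraction is not exactly 40% in low-certainty block ",
           bl$block_id[1], call. = FALSE)
    }
    jump <- bl[bl$urgency != "none", ]
    cnt <- table(jump$urgency)
    if (length(unique(cnt)) != 1) {
      stop("urgency levels unbalanced in block ", bl$block_id[1], call. = FALSE)
    }
    dir_bal <- tapply(jump$jump_direction,
                      interaction(jump$urgency, jump$jump_size), sum)
    if (any(dir_bal != 0)) {
      stop("jump directions unbalanced in block ", bl$block_id[1], call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Target trajectory for one trial
#'
#' The target appears on the midline at `target_start_height` and descends at
#' constant speed; on jump trials it is displaced horizontally by
#' `jump_size * jump_direction` instantaneously at the jump onset and then
#' continues straight down. The trace ends when the bottom of the target
#' passes the bottom of the workspace.
#'
#' @param spec One schedule row (a one-row data frame or a list with
#'   `jump_size`, `jump_direction`, `jump_onset_ms`).
#' @param config A [task_config()].
#' @param dt_ms Sample interval in ms.
#' @return A tibble `t_ms`, `x_cm`, `y_cm`.
#' @export
target_trajectory <- function(spec, config, dt_ms = 1) {
  stopifnot(inherits(config, "task_config"))
  t_ms <- seq(0, trial_end_time(config), by = dt_ms)
  y <- config$target_start_height - config$target_speed * t_ms / 1000
  x <- numeric(length(t_ms))
  if (!is.null(spec$jump_size) && spec$jump_size > 0 && spec$jump_direction != 0) {
    x[t_ms >= spec$jump_onset_ms] <- spec$jump_size * spec$jump_direction
  }
  tibble::tibble(t_ms = t_ms, x_cm = x, y_cm = y)
}

#' Write / read a schedule as CSV
#'
#' One row per trial with the columns documented in [build_schedule()].
#'
#' @param schedule A schedule tibble.
#' @param path File path.
#' @return `write_schedule` returns `path` invisibly; `read_schedule` returns
#'   the schedule tibble.
#' @export
write_schedule <- function(schedule, path) {
  write.csv(schedule, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  out <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  out$jump_onset_ms <- as.numeric(out$jump_onset_ms)
  out
}
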