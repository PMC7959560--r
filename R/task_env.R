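#' Configure the two-step aversive learning task
#'
#' Defines the generative structure of the task: a first-stage choice between
#' two stimuli (`A`, `B`) leads probabilistically to one of two second-stage
#' states (`S2`, `S3`), where a second choice (`a`, `b`) is followed by a
#' pain (0) or no-pain (1) outcome. `A` leads to `S2` and `B` to `S3` on
#' common transitions (probability `p_common`); rare transitions invert the
#' mapping. Outcome (shock) probabilities drift across trials as independent
#' bounded random walks. Trials are organised in blocks, each addressed to a
#' single outcome recipient (`self` or `other`).
#'
#' @param p_common Probability of the common first-stage transition
#'   (default 0.7).
#' @param drift_scale Standard deviation of the per-trial Gaussian step of
#'   each shock-probability walk (default 0.2). Zero gives a frozen schedule;
#'   negative values are rejected.
#' @param prob_bounds Length-2 numeric, closed interval to which shock
#'   probabilities are reflected (default `c(0, 1)`).
#' @param n_blocks Number of blocks (default 4).
#' @param trials_per_block Trials per block (default 68).
#' @param recipients_schedule Optional character vector of block recipients,
#'   one of `"self"`/`"other"` per block; must be balanced. By default an
#'   alternating schedule is built from `first_recipient`.
#' @param first_recipient Recipient of the first block when
#'   `recipients_schedule` is `NULL` (counterbalancing flag).
#' @param init_prob_range Interval from which the four initial shock
#'   probabilities are drawn uniformly (default `c(0.25, 0.75)`).
#' @return An object of class `task_config`.
#' @examples
#' cfg <- task_config()
#' cfg$n_blocks * cfg$trials_per_block  # 272 trials
#' @export
task_config <- function(p_common = 0.7,
                        drift_scale = 0.2,
                        prob_bounds = c(0, 1),
                        n_blocks = 4,
                        trials_per_block = 68,
                        recipients_schedule = NULL,
                        first_recipient = c("self", "other"),
                        init_prob_range = c(0.25, 0.75)) {
  first_recipient <- match.arg(first_recipient)
  stopifnot(is.numeric(p_common), length(p_common) == 1,
            p_common > 0, p_common < 1)
  if (!is.numeric(drift_scale) || length(drift_scale) != 1 || drift_scale < 0)
    stop("`drift_scale` must be a single nonnegative number")
  stopifnot(length(prob_bounds) == 2, prob_bounds[1] >= 0,
            prob_bounds[2] <= 1, prob_bounds[1] < prob_bounds[2])
  stopifnot(n_blocks >= 1, trials_per_block >= 1)
  if (is.null(recipients_schedule)) {
    base <- c("self", "other")
    if (first_recipient == "other") base <- rev(base)
    recipients_schedule <- rep_len(base, n_blocks)
  }
  if (length(recipients_schedule) != n_blocks)
    stop("`recipients_schedule` must have one label per block")
  if (!all(recipients_schedule %in% c("self", "other")))
    stop("recipient labels must be 'self' or 'other'")
  if (sum(recipients_schedule == "self") * 2 != n_blocks)
    stop("recipient schedule must be balanced (equal self and other blocks)")
  structure(list(p_common = p_common,
                 drift_scale = drift_scale,
                 prob_bounds = prob_bounds,
                 n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 recipients_schedule = recipients_schedule,
                 init_prob_range = init_prob_range),
            class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("Two-step task configuration\n")
  cat(sprintf("  %d blocks x %d trials (%d total), P(common) = %.2f\n",
              x$n_blocks, x$trials_per_block,
              x$n_blocks * x$trials_per_block, x$p_common))
  cat(sprintf("  outcome drift sd = %.3g, bounds [%g, %g]\n",
              x$drift_scale, x$prob_bounds[1], x$prob_bounds[2]))
  cat("  block recipients:", paste(x$recipients_schedule, collapse = " "), "\n")
  invisible(x)
}

# Reflect values into [lo, hi] (fold at the boundaries until inside).
reflect_into <- function(x, lo, hi) {
  width <- hi - lo
  y <- (x - lo) %% (2 * width)
  lo + ifelse(y > width, 2 * width - y, y)
}

#' Generate a drifting shock-probability schedule
#'
#' Builds the trial-by-trial shock probabilities of the four second-stage
#' options (two states x two actions). Each trajectory is an independent
#' Gaussian random walk with step standard deviation `config$drift_scale`,
#' reflected at `config$prob_bounds` so probabilities never leave the
#' interval. Initial values are drawn uniformly from
#' `config$init_prob_range`.
#'
#' @param config A [task_config()].
#' @param rng_seed Optional integer seed; identical seeds give identical
#'   schedules.
#' @return A numeric matrix of class `outcome_schedule`, `total_trials` rows
#'   and 4 columns named `S2_a`, `S2_b`, `S3_a`, `S3_b`.
#' @export
make_outcome_schedule <- function(config, rng_seed = NULL) {
  stopifnot(inherits(config, "task_config"))
  n <- config$n_blocks * config$trials_per_block
  lo <- config$prob_bounds[1]
  hi <- config$prob_bounds[2]
  probs <- with_seed(rng_seed, {
    p0 <- runif(4, config$init_prob_range[1], config$init_prob_range[2])
    p0 <- pmin(pmax(p0, lo), hi)
    out <- matrix(NA_real_, n, 4)
    out[1, ] <- p0
    if (n > 1) {
      steps <- matrix(rnorm((n - 1) * 4, sd = config$drift_scale), n - 1, 4)
      for (t in 2:n) out[t, ] <- reflect_into(out[t - 1, ] + steps[t - 1, ], lo, hi)
    }
    out
  })
  colnames(probs) <- c("S2_a", "S2_b", "S3_a", "S3_b")
  class(probs) <- c("outcome_schedule", class(probs))
  probs
}

#' First-stage transition matrix
#'
#' Row `a` gives P(second-stage state | first-stage choice a): choice `A`
#' commonly leads to `S2`, choice `B` to `S3`.
#'
#' @param p_common Probability of the common transition.
#' @return A 2x2 matrix, rows `A`,`B`, columns `S2`,`S3`; rows sum to 1.
#' @export
transition_matrix <- function(p_common = 0.7) {
  m <- rbind(c(p_common, 1 - p_common), c(1 - p_common, p_common))
  dimnames(m) <- list(c("A", "B"), c("S2", "S3"))
  m
}

choice1_index <- function(choice1) {
  i <- match(as.character(choice1), c("A", "B"))
  if (anyNA(i)) stop("first-stage choice must be 'A' or 'B'")
  i
}

state2_index <- function(state2) {
  i <- match(as.character(state2), c("S2", "S3"))
  if (anyNA(i)) stop("second-stage state must be 'S2' or 'S3'")
  i
}

choice2_index <- function(choice2) {
  i <- match(as.character(choice2), c("a", "b"))
  if (anyNA(i)) stop("second-stage choice must be 'a' or 'b'")
  i
}

#' Sample a first-stage transition
#'
#' @param choice1 First-stage choice, `"A"` or `"B"`.
#' @param config A [task_config()].
#' @return List with `state2` (`"S2"` or `"S3"`) and `transition`
#'   (`"common"` or `"rare"`). Uses the current RNG stream.
#' @export
sample_transition <- function(choice1, config) {
  i <- choice1_index(choice1)
  common <- runif(1) < config$p_common
  mapped <- c("S2", "S3")[i]
  other <- c("S2", "S3")[3 - i]
  list(state2 = if (common) mapped else other,
       transition = if (common) "common" else "rare")
}

#' Sample a trial outcome from the schedule
#'
#' Outcomes follow the study's coding: 0 = pain (shock), 1 = no pain. The
#' scheduled value is the probability of a shock.
#'
#' @param state2 Second-stage state, `"S2"` or `"S3"`.
#' @param choice2 Second-stage choice, `"a"` or `"b"`.
#' @param trial_index 1-based row of the schedule.
#' @param schedule An [make_outcome_schedule()] matrix.
#' @return Integer outcome, 0 (pain) or 1 (no pain).
#' @export
sample_outcome <- function(state2, choice2, trial_index, schedule) {
  if (trial_index < 1 || trial_index > nrow(schedule))
    stop("`trial_index` out of range")
  col <- (state2_index(state2) - 1) * 2 + choice2_index(choice2)
  p_shock <- schedule[trial_index, col]
  as.integer(runif(1) >= p_shock)
}
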