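#' Initialise the learner's internal state
#'
#' Second-stage action values `q2` (2 states x 2 actions) and first-stage
#' model-free values `q1_mf` start at 0.5, the midpoint of the outcome
#' scale, so pain and no-pain are symmetric surprises at the start. No
#' previous first-stage choice is recorded.
#'
#' @return List with `q2` (2x2 matrix), `q1_mf` (length-2 vector), and
#'   `prev_choice1` (`NA` for none).
#' @export
init_state <- function() {
  list(q2 = matrix(0.5, 2, 2, dimnames = list(c("S2", "S3"), c("a", "b"))),
       q1_mf = c(A = 0.5, B = 0.5),
       prev_choice1 = NA_integer_)
}

#' Model-based first-stage values
#'
#' Prospective values computed from the known transition structure:
#' `QMB(a) = sum_s P(s | a) * max_a' q2(s, a')`.
#'
#' @param q2 2x2 matrix of second-stage values (states x actions).
#' @param transition 2x2 transition matrix, rows = first-stage choices,
#'   columns = states; rows must sum to 1 (tolerance 1e-9).
#' @return Length-2 vector of model-based values for choices `A`, `B`.
#' @export
model_based_values <- function(q2, transition) {
  if (any(abs(rowSums(transition) - 1) > 1e-9))
    stop("transition rows must sum to 1")
  best <- apply(q2, 1, max)
  as.vector(transition %*% best)
}

# Numerically stable softmax over a logit vector.
softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

# Recipient index: 1 = self, 2 = other.
recipient_index <- function(recipient) {
  i <- match(as.character(recipient), c("self", "other"))
  if (anyNA(i)) stop("recipient must be 'self' or 'other'")
  i
}

# Stage-1 choice probabilities from the canonical parameter vector.
stage1_probs_canonical <- function(state, par, rec_idx, transition) {
  omega <- if (rec_idx == 1) par[["omega_self"]] else par[["omega_other"]]
  rho <- if (rec_idx == 1) par[["rho_self"]] else par[["rho_other"]]
  qmb <- model_based_values(state$q2, transition)
  qnet <- omega * qmb + (1 - omega) * state$q1_mf
  persev <- numeric(2)
  if (!is.na(state$prev_choice1)) persev[state$prev_choice1] <- rho
  softmax(par[["beta1"]] * qnet + persev)
}

stage2_probs_canonical <- function(state, s2_idx, par) {
  softmax(par[["beta2"]] * state$q2[s2_idx, ])
}

#' First-stage choice probabilities
#'
#' Net first-stage values mix model-based and model-free values through the
#' recipient's model-based weight omega:
#' `Qnet(a) = omega * QMB(a) + (1 - omega) * q1_mf(a)`; choice follows a
#' softmax over `beta * Qnet(a) + rho * 1[a = previous choice]`, where rho
#' is the (recipient's) perseverance bonus.
#'
#' @param state An [init_state()] state.
#' @param params Named natural-space parameter vector for `spec`.
#' @param spec A [model_spec()] or registry name.
#' @param recipient `"self"` or `"other"`.
#' @param transition First-stage transition matrix
#'   (default [transition_matrix()] at 0.7).
#' @return Length-2 probability vector over choices `A`, `B` (sums to 1).
#' @export
choice_probabilities_stage1 <- function(state, params, spec,
                                        recipient = "self",
                                        transition = transition_matrix()) {
  spec <- get_model_spec(spec)
  par <- expand_params(check_params(params, spec), spec)
  p <- stage1_probs_canonical(state, par, recipient_index(recipient), transition)
  setNames(p, c("A", "B"))
}

#' Second-stage choice probabilities
#'
#' Softmax over the current state's second-stage values with the stage-2
#' inverse temperature (equal to `beta` under a single-beta model); no
#' perseverance term at the second stage.
#'
#' @inheritParams choice_probabilities_stage1
#' @param state2 `"S2"` or `"S3"`.
#' @return Length-2 probability vector over actions `a`, `b`.
#' @export
choice_probabilities_stage2 <- function(state, state2, params, spec) {
  spec <- get_model_spec(spec)
  par <- expand_params(check_params(params, spec), spec)
  setNames(stage2_probs_canonical(state, state2_index(state2), par), c("a", "b"))
}

# Canonical-space state update shared by simulation and likelihood.
update_state_canonical <- function(state, c1, s2, c2, outcome, par) {
  astar <- if (outcome == 1) par[["alpha_nopain"]] else par[["alpha_pain"]]
  q2_old <- state$q2[s2, c2]
  state$q2[s2, c2] <- q2_old + astar * (outcome - q2_old)
  state$q1_mf[c1] <- state$q1_mf[c1] +
    astar * (q2_old - state$q1_mf[c1]) +
    astar * par[["lambda"]] * (outcome - q2_old)
  state$prev_choice1 <- c1
  state
}

#' Update the learner's state after one trial
#'
#' SARSA-style updates with a valence-dependent learning rate
#' (`alpha_nopain` after no-pain outcomes, `alpha_pain` after pain):
#' the chosen second-stage value moves toward the outcome, and the chosen
#' first-stage model-free value is updated from the (pre-update)
#' second-stage value plus a lambda-weighted share of the outcome
#' prediction error. With lambda = 1 the first-stage update collapses to a
#' direct outcome update. The previous first-stage choice is recorded for
#' the perseverance term.
#'
#' @inheritParams choice_probabilities_stage1
#' @param trial List or one-row data frame with `choice1`, `state2`,
#'   `choice2`, `outcome` in the trial-table coding.
#' @return The updated state.
#' @export
update_after_trial <- function(state, trial, params, spec) {
  spec <- get_model_spec(spec)
  par <- expand_params(check_params(params, spec), spec)
  outcome <- as.integer(trial$outcome)
  if (!outcome %in% c(0L, 1L)) stop("outcome must be 0 (pain) or 1 (no pain)")
  update_state_canonical(state,
                         choice1_index(trial$choice1),
                         state2_index(trial$state2),
                         choice2_index(trial$choice2),
                         outcome, par)
}

#' Outcome prediction error
#'
#' `delta = outcome - expected value`; positive for unexpected pain
#' relief/avoidance (outcome 1 = no pain), negative for unexpected pain.
#'
#' @param q2_value Expected value of the chosen second-stage action, in
#'   `[0, 1]`.
#' @param outcome 0 (pain) or 1 (no pain).
#' @return The signed prediction error.
#' @export
outcome_prediction_error <- function(q2_value, outcome) {
  outcome - q2_value
}

#' State prediction error at the second stage
#'
#' Surprise about the second-stage state that followed the first-stage
#' choice: `1 - P(observed state | choice)`, i.e. `1 - p_common` after a
#' common transition and `p_common` after a rare one.
#'
#' @param transition_label `"common"` or `"rare"`.
#' @param p_common Probability of the common transition.
#' @return The state prediction error.
#' @export
state_prediction_error <- function(transition_label, p_common = 0.7) {
  label <- match.arg(as.character(transition_label), c("common", "rare"))
  if (label == "common") 1 - p_common else p_common
}

#' Simulate one agent through the task
#'
#' Samples both stage choices from the model's choice probabilities and
#' updates values after every trial. By default values persist across block
#' boundaries while the perseverance reference (`prev_choice1`) resets,
#' because blocks change recipient and stimuli.
#'
#' @param params Named natural-space parameters for `spec`.
#' @param spec A [model_spec()] or registry name.
#' @param config A [task_config()].
#' @param schedule An [make_outcome_schedule()] matrix matching `config`.
#' @param rng_seed Optional seed for reproducible simulation.
#' @param subject_id Identifier written into the trial table.
#' @param reset_values If `TRUE`, q-values also reset at block boundaries.
#' @return Data frame of trial records: `subject_id`, `block`,
#'   `trial_index` (1-based), `recipient`, `choice1`, `transition`,
#'   `state2`, `choice2`, `outcome` (0 pain / 1 no pain), `rt1` (`NA`;
#'   carried for schema fidelity, never simulated).
#' @export
simulate_agent <- function(params, spec, config = task_config(),
                           schedule = NULL, rng_seed = NULL,
                           subject_id = "sim", reset_values = FALSE) {
  spec <- get_model_spec(spec)
  par <- expand_params(check_params(params, spec), spec)
  if (is.null(schedule))
    schedule <- make_outcome_schedule(config, rng_seed = derive_seed(rng_seed, 1))
  n <- config$n_blocks * config$trials_per_block
  if (nrow(schedule) != n)
    stop("schedule length does not match the task configuration")
  trans <- transition_matrix(config$p_common)
  c1_codes <- c("A", "B"); s2_codes <- c("S2", "S3"); c2_codes <- c("a", "b")
  p_common <- config$p_common
  b1 <- par[["beta1"]]; b2 <- par[["beta2"]]
  ap <- par[["alpha_pain"]]; an <- par[["alpha_nopain"]]
  lam <- par[["lambda"]]
  rho2 <- c(par[["rho_self"]], par[["rho_other"]])
  om2 <- c(par[["omega_self"]], par[["omega_other"]])
  with_seed(rng_seed, {
    q2 <- matrix(0.5, 2, 2)
    q1 <- c(0.5, 0.5)
    c1v <- s2v <- c2v <- outv <- blockv <- integer(n)
    commonv <- logical(n)
    t_global <- 0L
    for (b in seq_len(config$n_blocks)) {
      rec_idx <- recipient_index(config$recipients_schedule[b])
      rho <- rho2[rec_idx]; om <- om2[rec_idx]
      prev <- 0L
      if (reset_values) { q2[] <- 0.5; q1[] <- 0.5 }
      for (tt in seq_len(config$trials_per_block)) {
        t_global <- t_global + 1L
        m1 <- max(q2[1, 1], q2[1, 2]); m2 <- max(q2[2, 1], q2[2, 2])
        qmb1 <- p_common * m1 + (1 - p_common) * m2
        qmb2 <- (1 - p_common) * m1 + p_common * m2
        l1 <- b1 * (om * qmb1 + (1 - om) * q1[1]) + if (prev == 1L) rho else 0
        l2 <- b1 * (om * qmb2 + (1 - om) * q1[2]) + if (prev == 2L) rho else 0
        mx <- max(l1, l2)
        pA <- exp(l1 - mx) / (exp(l1 - mx) + exp(l2 - mx))
        c1 <- 1L + (runif(1) >= pA)
        common <- runif(1) < p_common
        s2 <- if (common) c1 else 3L - c1
        sa <- b2 * q2[s2, 1]; sb <- b2 * q2[s2, 2]
        mx <- max(sa, sb)
        pa <- exp(sa - mx) / (exp(sa - mx) + exp(sb - mx))
        c2 <- 1L + (runif(1) >= pa)
        p_shock <- schedule[t_global, (s2 - 1L) * 2L + c2]
        outcome <- as.integer(runif(1) >= p_shock)
        c1v[t_global] <- c1; s2v[t_global] <- s2; c2v[t_global] <- c2
        outv[t_global] <- outcome; blockv[t_global] <- b
        commonv[t_global] <- common
        astar <- if (outcome == 1L) an else ap
        q2_old <- q2[s2, c2]
        q2[s2, c2] <- q2_old + astar * (outcome - q2_old)
        q1[c1] <- q1[c1] + astar * (q2_old - q1[c1]) +
          astar * lam * (outcome - q2_old)
        prev <- c1
      }
    }
    data.frame(subject_id = subject_id, block = blockv,
               trial_index = seq_len(n),
               recipient = config$recipients_schedule[blockv],
               choice1 = c1_codes[c1v],
               transition = ifelse(commonv, "common", "rare"),
               state2 = s2_codes[s2v], choice2 = c2_codes[c2v],
               outcome = outv, rt1 = NA_real_,
               stringsAsFactors = FALSE)
  })
}

# Encode a trial table into the integer matrix consumed by the likelihood
# engines: choice1, state2, choice2 in 1:2; outcome 0/1; recipient 1/2;
# block index.
encode_trials <- function(trials) {
  cbind(choice1 = choice1_index(trials$choice1),
        state2 = state2_index(trials$state2),
        choice2 = choice2_index(trials$choice2),
        outcome = as.integer(trials$outcome),
        recipient = recipient_index(trials$recipient),
        block = as.integer(trials$block))
}

# Pure-R likelihood path: shares the probability and update code with the
# simulator.
nll_r <- function(tm, par, p_common, reset_values = FALSE) {
  trans <- transition_matrix(p_common)
  state <- init_state()
  cur_block <- -1L
  ll <- 0
  for (i in seq_len(nrow(tm))) {
    if (tm[i, "block"] != cur_block) {
      cur_block <- tm[i, "block"]
      state$prev_choice1 <- NA_integer_
      if (reset_values) {
        state$q2[] <- 0.5
        state$q1_mf[] <- 0.5
      }
    }
    p1 <- stage1_probs_canonical(state, par, tm[i, "recipient"], trans)
    p2 <- stage2_probs_canonical(state, tm[i, "state2"], par)
    ll <- ll + log(p1[tm[i, "choice1"]]) + log(p2[tm[i, "choice2"]])
    state <- update_state_canonical(state, tm[i, "choice1"], tm[i, "state2"],
                                    tm[i, "choice2"], tm[i, "outcome"], par)
  }
  unname(-ll)
}

#' Negative log-likelihood of observed choices
#'
#' Minus the summed log-probabilities of both stage choices on every trial,
#' computed with the same choice-probability and update rules used by
#' [simulate_agent()]. The default engine is a compiled mirror of the R
#' reference path (the two agree to machine precision; see the test suite).
#'
#' @param trials Trial table ordered by block and trial index.
#' @param params Named natural-space parameters for `spec`.
#' @param spec A [model_spec()] or registry name.
#' @param p_common Probability of the common transition.
#' @param reset_values Reset q-values at block boundaries.
#' @param engine `"cpp"` (compiled) or `"r"` (reference).
#' @return Nonnegative scalar NLL.
#' @export
negative_log_likelihood <- function(trials, params, spec, p_common = 0.7,
                                    reset_values = FALSE,
                                    engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  spec <- get_model_spec(spec)
  if (NROW(trials) == 0) stop("empty trial list")
  par <- expand_params(check_params(params, spec), spec)
  tm <- encode_trials(trials)
  if (engine == "cpp") nll_canonical_cpp(tm, par, p_common, reset_values)
  else nll_r(tm, par, p_common, reset_values)
}
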