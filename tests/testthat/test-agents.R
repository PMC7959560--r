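test_that("initial state is neutral and has value semantics", {
  st <- init_state()
  expect_true(all(st$q2 == 0.5))
  expect_true(all(st$q1_mf == 0.5))
  expect_true(is.na(st$prev_choice1))
  st2 <- st
  st2$q2[1, 1] <- 0.9
  expect_equal(st$q2[1, 1], 0.5)
})

test_that("model-based values follow the prospective formula", {
  q2 <- rbind(c(0.8, 0.2), c(0.5, 0.5))
  expect_equal(model_based_values(q2, transition_matrix(0.7)),
               c(0.71, 0.59))
  # constant second-stage values collapse to that constant
  expect_equal(model_based_values(matrix(0.3, 2, 2), transition_matrix(0.7)),
               c(0.3, 0.3))
  # deterministic transition picks the best value of the mapped state
  expect_equal(model_based_values(q2, rbind(c(1, 0), c(0, 1))),
               c(0.8, 0.5))
  expect_error(model_based_values(q2, rbind(c(0.6, 0.3), c(0.3, 0.7))),
               "sum to 1")
})

test_that("stage-1 choice probabilities mix values, softmax, perseverance", {
  p5 <- c(alpha_pain = 0.3, alpha_nopain = 0.4, beta = 2, rho = 0,
          omega = 1 - 1e-12)
  st <- init_state()
  st$q2 <- rbind(c(0.8, 0.2), c(0.5, 0.5))
  # omega = 1, beta = 2: softmax over (0.71, 0.59)
  p <- choice_probabilities_stage1(st, p5, "win5")
  expect_equal(unname(p[1]), 1 / (1 + exp(-0.24)), tolerance = 1e-9)

  # beta = 0, rho = 0: flat choice
  p5b <- replace(p5, "beta", 1e-300)
  expect_equal(unname(choice_probabilities_stage1(st, p5b, "win5")),
               c(0.5, 0.5))

  # strong perseverance dominates equal net values
  st0 <- init_state()
  st0$prev_choice1 <- 1L
  p5c <- c(alpha_pain = 0.3, alpha_nopain = 0.4, beta = 1, rho = 50,
           omega = 0.5)
  expect_gt(choice_probabilities_stage1(st0, p5c, "win5")[1], 1 - 1e-9)

  # recipient-split omega selects the recipient's weight
  st$q1_mf <- c(0.2, 0.9)
  ps <- choice_probabilities_stage1(st, p6, "win6_omega_split", "self")
  po <- choice_probabilities_stage1(st, p6, "win6_omega_split", "other")
  expect_false(isTRUE(all.equal(ps, po)))
})

test_that("stage-2 probabilities are a softmax over the state's values", {
  st <- init_state()
  st$q2 <- rbind(c(0.7, 0.3), c(1, 0))
  p5 <- c(alpha_pain = 0.3, alpha_nopain = 0.4, beta = 3, rho = 0.2,
          omega = 0.5)
  p <- choice_probabilities_stage2(st, "S2", p5, "win5")
  expect_equal(unname(p[1]), plogis(3 * 0.4), tolerance = 1e-9)
  expect_equal(unname(p[1]), 0.7685, tolerance = 1e-4)
  # greedy limit
  p5h <- replace(p5, "beta", 500)
  expect_gt(choice_probabilities_stage2(st, "S3", p5h, "win5")[1], 1 - 1e-9)
})

test_that("trial updates use valence-dependent learning rates", {
  st <- init_state()
  trial <- list(choice1 = "A", state2 = "S2", choice2 = "a", outcome = 1)
  p5 <- c(alpha_pain = 0.2, alpha_nopain = 0.4, beta = 1, rho = 0,
          omega = 0.5)
  st1 <- update_after_trial(st, trial, p5, "win5")
  expect_equal(st1$q2[1, 1], 0.7)        # 0.5 + 0.4 * (1 - 0.5)
  expect_equal(st1$prev_choice1, 1L)

  # pain outcome with lambda = 1 collapses to a direct outcome update
  trial0 <- list(choice1 = "A", state2 = "S2", choice2 = "a", outcome = 0)
  st2 <- update_after_trial(st, trial0, p5, "win5")
  expect_equal(unname(st2$q1_mf[1]), 0.4)  # 0.5 + 0.2 * (0 - 0.5)

  # near-zero learning rates leave values unchanged
  p5z <- replace(replace(p5, "alpha_pain", 1e-15), "alpha_nopain", 1e-15)
  st3 <- update_after_trial(st, trial, p5z, "win5")
  expect_equal(st3$q2, st$q2, tolerance = 1e-12)
  expect_error(update_after_trial(st, list(choice1 = "A", state2 = "S2",
                                           choice2 = "a", outcome = 2),
                                  p5, "win5"), "outcome")
})

test_that("free lambda weights the stage-1 bootstrap", {
  # lambda < 1: stage-1 value moves toward q2_old plus lambda * delta
  p7 <- c(alpha_pain = 0.2, alpha_nopain = 0.4, beta1 = 1, beta2 = 1,
          lambda = 0.5, rho = 0, omega = 0.5)
  st <- init_state()
  st$q2[1, 1] <- 0.8
  trial <- list(choice1 = "A", state2 = "S2", choice2 = "a", outcome = 1)
  st1 <- update_after_trial(st, trial, p7, "daw7")
  # q1: 0.5 + 0.4*(0.8-0.5) + 0.4*0.5*(1-0.8) = 0.66
  expect_equal(unname(st1$q1_mf[1]), 0.66)
})

test_that("prediction errors follow the harm-avoidance coding", {
  expect_equal(outcome_prediction_error(0.3, 1), 0.7)
  expect_equal(outcome_prediction_error(0.3, 0), -0.3)
  expect_equal(outcome_prediction_error(1, 1), 0)
  expect_equal(state_prediction_error("common", 0.7), 0.3)
  expect_equal(state_prediction_error("rare", 0.7), 0.7)
  expect_equal(state_prediction_error("common", 1), 0)
})

test_that("likelihood equals the hand-enumeration oracle on short sequences", {
  specs <- list(win6 = "win6_omega_split", daw = "daw7")
  params <- list(
    win6 = p6,
    daw = c(alpha_pain = 0.25, alpha_nopain = 0.45, beta1 = 3, beta2 = 2,
            lambda = 0.6, rho = 0.3, omega = 0.4))
  canon <- list(
    win6 = list(alpha_pain = 0.3, alpha_nopain = 0.4, beta1 = 4, beta2 = 4,
                lambda = 1, rho_self = 0.2, rho_other = 0.2,
                omega_self = 0.55, omega_other = 0.45),
    daw = list(alpha_pain = 0.25, alpha_nopain = 0.45, beta1 = 3, beta2 = 2,
               lambda = 0.6, rho_self = 0.3, rho_other = 0.3,
               omega_self = 0.4, omega_other = 0.4))
  trs <- list(
    make_trials(c("A"), c("common"), c("a"), c(0)),
    make_trials(c("A", "B"), c("common", "rare"), c("a", "b"), c(0, 1),
                recipient = "other"),
    make_trials(c("A", "A", "B"), c("common", "rare", "common"),
                c("b", "a", "a"), c(1, 0, 1)))
  for (k in names(specs)) {
    for (tr in trs) {
      got_r <- negative_log_likelihood(tr, params[[k]], specs[[k]],
                                       engine = "r")
      got_c <- negative_log_likelihood(tr, params[[k]], specs[[k]],
                                       engine = "cpp")
      want <- do.call(oracle_nll, c(list(tr), canon[[k]]))
      expect_equal(got_r, want, tolerance = 1e-10)
      expect_equal(got_c, want, tolerance = 1e-10)
    }
  }
})

test_that("flat parameters give the chance-level likelihood", {
  tr <- make_trials("A", "common", "a", 1)
  pflat <- c(alpha_pain = 0.3, alpha_nopain = 0.3, beta = 1e-300, rho = 0,
             omega = 0.5)
  expect_equal(negative_log_likelihood(tr, pflat, "win5"), -2 * log(0.5),
               tolerance = 1e-9)
  expect_error(negative_log_likelihood(tr[0, ], pflat, "win5"), "empty")
})

test_that("compiled and reference likelihoods agree on long simulations", {
  cfg <- task_config()
  for (seed in 1:3) {
    tr <- simulate_agent(p6, "win6_omega_split", cfg, rng_seed = seed)
    expect_equal(
      negative_log_likelihood(tr, p6, "win6_omega_split", engine = "cpp"),
      negative_log_likelihood(tr, p6, "win6_omega_split", engine = "r"),
      tolerance = 1e-12)
  }
})

test_that("choice probabilities normalize and respect the omega limits", {
  set.seed(42)
  for (i in 1:25) {
    st <- init_state()
    st$q2 <- matrix(runif(4), 2, 2)
    st$q1_mf <- runif(2)
    st$prev_choice1 <- sample(c(NA, 1L, 2L), 1)
    pars <- c(alpha_pain = runif(1, 0.05, 0.95),
              alpha_nopain = runif(1, 0.05, 0.95),
              beta = runif(1, 0.1, 10), rho = rnorm(1),
              omega = runif(1, 0.02, 0.98))
    p1 <- choice_probabilities_stage1(st, pars, "win5")
    p2 <- choice_probabilities_stage2(st, "S3", pars, "win5")
    expect_equal(sum(p1), 1, tolerance = 1e-12)
    expect_equal(sum(p2), 1, tolerance = 1e-12)

    # omega -> 0: net values equal the model-free values
    trm <- transition_matrix(0.7)
    qmb <- model_based_values(st$q2, trm)
    w0 <- replace(pars, "omega", 1e-14)
    w1 <- replace(pars, "omega", 1 - 1e-14)
    b <- pars[["beta"]]
    pr <- numeric(2)
    if (!is.na(st$prev_choice1)) pr[st$prev_choice1] <- pars[["rho"]]
    soft <- function(x) exp(x - max(x)) / sum(exp(x - max(x)))
    expect_equal(unname(choice_probabilities_stage1(st, w0, "win5")),
                 soft(b * st$q1_mf + pr), tolerance = 1e-9)
    expect_equal(unname(choice_probabilities_stage1(st, w1, "win5")),
                 soft(b * qmb + pr), tolerance = 1e-9)
  }
})

test_that("values remain within [0, 1] over long simulations", {
  cfg <- task_config(n_blocks = 4, trials_per_block = 200)
  set.seed(3)
  for (i in 1:3) {
    pars <- c(alpha_pain = runif(1, 0.05, 0.95),
              alpha_nopain = runif(1, 0.05, 0.95),
              beta = runif(1, 0.5, 8), rho = rnorm(1, 0, 0.5),
              omega = runif(1, 0.05, 0.95))
    tr <- simulate_agent(pars, "win5", cfg, rng_seed = 100 + i)
    st <- init_state()
    ok <- TRUE
    for (j in seq_len(nrow(tr))) {
      st <- update_after_trial(st, list(choice1 = tr$choice1[j],
                                        state2 = tr$state2[j],
                                        choice2 = tr$choice2[j],
                                        outcome = tr$outcome[j]),
                               pars, "win5")
      ok <- ok && all(st$q2 >= 0, st$q2 <= 1, st$q1_mf >= 0, st$q1_mf <= 1)
    }
    expect_true(ok)
  }
})

test_that("generating parameters beat perturbed ones in likelihood", {
  cfg <- task_config()
  set.seed(8)
  diffs <- replicate(50, {
    tr <- simulate_agent(p6, "win6_omega_split", cfg,
                         rng_seed = sample.int(1e6, 1))
    pert <- p6 + c(0.25, -0.25, 2, 0.5, -0.3, 0.3)
    pert <- pmin(pmax(pert, c(0.01, 0.01, 0.1, -Inf, 0.01, 0.01)),
                 c(0.99, 0.99, Inf, Inf, 0.99, 0.99))
    negative_log_likelihood(tr, pert, "win6_omega_split") -
      negative_log_likelihood(tr, p6, "win6_omega_split")
  })
  expect_gt(mean(diffs), 0)
  expect_lt(t.test(diffs)$p.value, 0.01)
})

test_that("a random agent chooses each stimulus half the time", {
  cfg <- task_config(n_blocks = 4, trials_per_block = 500)
  pflat <- c(alpha_pain = 0.3, alpha_nopain = 0.3, beta = 1e-300, rho = 0,
             omega = 0.5)
  tr <- simulate_agent(pflat, "win5", cfg, rng_seed = 31)
  fA <- mean(tr$choice1 == "A")
  expect_lt(abs(fA - 0.5), 3 * sqrt(0.25 / nrow(tr)))
})

test_that("model registry exposes the expected family", {
  reg <- model_registry()
  expect_setequal(names(reg),
                  c("daw7", "win5", "win6_omega_split", "split7_rho_omega"))
  expect_equal(reg$daw7$n_params, 7)
  expect_equal(reg$win5$n_params, 5)
  expect_equal(reg$win6_omega_split$n_params, 6)
  expect_equal(reg$split7_rho_omega$n_params, 7)
  expect_equal(length(reg$win5$param_names), reg$win5$n_params)
  expect_error(get_model_spec("nope"), "unknown model")
})
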