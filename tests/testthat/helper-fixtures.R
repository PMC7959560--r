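# Shared fixtures and independent oracles for the test suite.

# Small task for fast tests: 2 blocks x 6 trials.
tiny_task <- function(...) {
  task_config(n_blocks = 2, trials_per_block = 6, ...)
}

# A hand-specifiable trial table (single block unless block given).
make_trials <- function(choice1, transition, choice2, outcome,
                        recipient = "self", block = 1L,
                        subject_id = "s1") {
  n <- length(choice1)
  state2 <- ifelse((choice1 == "A") == (transition == "common"), "S2", "S3")
  data.frame(subject_id = subject_id, block = rep_len(block, n),
             trial_index = seq_len(n),
             recipient = rep_len(recipient, n),
             choice1 = choice1, transition = transition, state2 = state2,
             choice2 = choice2, outcome = outcome, rt1 = NA_real_,
             stringsAsFactors = FALSE)
}

# Default parameter set for the recipient-split six-parameter model.
p6 <- c(alpha_pain = 0.3, alpha_nopain = 0.4, beta = 4, rho = 0.2,
        omega_self = 0.55, omega_other = 0.45)

# Independent hand-enumeration oracle for the likelihood on short
# sequences: recomputes every stage probability with plain arithmetic,
# written without reference to the package's engine code.
oracle_nll <- function(trials, alpha_pain, alpha_nopain, beta1, beta2,
                       lambda, rho_self, rho_other, omega_self, omega_other,
                       p_common = 0.7) {
  q2 <- matrix(0.5, 2, 2)   # rows S2, S3; cols a, b
  q1 <- c(0.5, 0.5)         # A, B
  prev <- 0L
  ll <- 0
  cur_block <- -1L
  for (i in seq_len(nrow(trials))) {
    if (trials$block[i] != cur_block) { cur_block <- trials$block[i]; prev <- 0L }
    self <- trials$recipient[i] == "self"
    om <- if (self) omega_self else omega_other
    rho <- if (self) rho_self else rho_other
    c1 <- if (trials$choice1[i] == "A") 1L else 2L
    s2 <- if (trials$state2[i] == "S2") 1L else 2L
    c2 <- if (trials$choice2[i] == "a") 1L else 2L
    r <- trials$outcome[i]
    qmb_A <- p_common * max(q2[1, ]) + (1 - p_common) * max(q2[2, ])
    qmb_B <- (1 - p_common) * max(q2[1, ]) + p_common * max(q2[2, ])
    qn <- om * c(qmb_A, qmb_B) + (1 - om) * q1
    logits <- beta1 * qn + rho * (seq_len(2) == prev)
    p1 <- exp(logits) / sum(exp(logits))
    p2 <- exp(beta2 * q2[s2, ]) / sum(exp(beta2 * q2[s2, ]))
    ll <- ll + log(p1[c1]) + log(p2[c2])
    a <- if (r == 1) alpha_nopain else alpha_pain
    q2_old <- q2[s2, c2]
    q2[s2, c2] <- q2[s2, c2] + a * (r - q2[s2, c2])
    q1[c1] <- q1[c1] + a * (q2_old - q1[c1]) + a * lambda * (r - q2_old)
    prev <- c1
  }
  -ll
}

# Brute-force Monte-Carlo oracle for exceedance probabilities: model
# frequencies r get a Dirichlet(alpha0) prior; draws are weighted by the
# marginal likelihood of the subjects' evidences under r (importance
# sampling with the prior as proposal), and the exceedance of model m is
# the weighted share of draws where r_m is largest.
oracle_exceedance <- function(log_evidence, n_outer = 20000, alpha0 = 1) {
  n <- nrow(log_evidence); m <- ncol(log_evidence)
  lw <- numeric(n_outer)
  amx <- integer(n_outer)
  for (b in seq_len(n_outer)) {
    r <- rgamma(m, alpha0); r <- r / sum(r)
    lw[b] <- sum(apply(log_evidence, 1, function(le) {
      mx <- max(le); mx + log(sum(r * exp(le - mx)))
    }))
    amx[b] <- which.max(r)
  }
  w <- exp(lw - max(lw))
  vapply(seq_len(m), function(k) sum(w[amx == k]), numeric(1)) / sum(w)
}
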