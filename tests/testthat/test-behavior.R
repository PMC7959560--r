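test_that("QC flags non-switchers and collinear regressors", {
  # always-stay subject: switch rate 0
  n <- 60
  stay_tr <- make_trials(rep("A", n), sample(c("common", "rare"), n, TRUE),
                         sample(c("a", "b"), n, TRUE),
                         rbinom(n, 1, 0.5))
  qc <- qc_subject(stay_tr)
  expect_false(qc$pass)
  expect_match(qc$reason, "switch rate")

  # well-behaved subject with ~30% switches and unrelated regressors
  set.seed(12)
  c1 <- character(n)
  c1[1] <- "A"
  for (i in 2:n) c1[i] <- if (runif(1) < 0.3) setdiff(c("A", "B"), c1[i - 1]) else c1[i - 1]
  good_tr <- make_trials(c1, sample(c("common", "rare"), n, TRUE),
                         sample(c("a", "b"), n, TRUE), rbinom(n, 1, 0.5))
  expect_true(qc_subject(good_tr)$pass)

  # switches occur only after pain-on-rare or no-pain-on-common trials:
  # outcome and transition correlate perfectly on switch trials
  outc <- rep(c(0, 1, 1, 0), 15)
  trans <- rep(c("rare", "common", "common", "common"), 15)
  c1 <- character(n)
  c1[1] <- "A"
  for (i in 2:n) {
    switch_now <- (outc[i - 1] == 0 && trans[i - 1] == "rare") ||
      (outc[i - 1] == 1 && trans[i - 1] == "common" && i %% 4 == 0)
    c1[i] <- if (switch_now) setdiff(c("A", "B"), c1[i - 1]) else c1[i - 1]
  }
  col_tr <- make_trials(c1, trans, rep(c("a", "b"), 30), outc)
  qc2 <- qc_subject(col_tr)
  expect_false(qc2$pass)
})

test_that("stay/switch regression recovers hand-built effects", {
  # deterministic model-free subject: stays iff previous outcome no pain
  set.seed(9)
  n <- 120
  outc <- rbinom(n, 1, 0.5)
  c1 <- character(n)
  c1[1] <- "A"
  for (i in 2:n) {
    det <- if (outc[i - 1] == 1) c1[i - 1] else setdiff(c("A", "B"), c1[i - 1])
    c1[i] <- if (runif(1) < 0.9) det else setdiff(c("A", "B"), det)
  }
  tr <- make_trials(c1, sample(c("common", "rare"), n, TRUE),
                    sample(c("a", "b"), n, TRUE), outc)
  sb <- stay_switch_regression(tr, regression_spec(
    terms = c("outcome", "transition", "outcome:transition")))
  expect_true(sb$converged)
  expect_gt(sb$coefficients[["outcome"]], 1)
  expect_lt(abs(sb$coefficients[["outcome:transition"]]),
            sb$coefficients[["outcome"]] / 2)

  # first trial of each block is excluded: 2 blocks of k trials give
  # 2 * (k - 1) analyzable rows
  cfg <- tiny_task()
  tr2 <- simulate_agent(p6, "win6_omega_split", cfg, rng_seed = 2)
  expect_equal(nrow(aversivetwostep:::prep_stay_data(tr2)),
               2 * (cfg$trials_per_block - 1))
})

test_that("group one-sample test matches the textbook formulas", {
  set.seed(11)
  x <- rnorm(36, 0.3, 0.5)
  gc <- group_one_sample(x)
  ht <- t.test(x)
  expect_equal(gc$t, unname(ht$statistic), tolerance = 1e-10)
  expect_equal(gc$p, ht$p.value, tolerance = 1e-10)
  expect_equal(gc$ci, unname(ht$conf.int), tolerance = 1e-10)
  expect_equal(gc$d, mean(x) / sd(x), tolerance = 1e-10)
  # d = t / sqrt(n) identity
  expect_equal(gc$d, gc$t / sqrt(length(x)), tolerance = 1e-9)
  for (i in 1:10) {
    y <- rnorm(sample(5:50, 1))
    g <- group_one_sample(y)
    expect_equal(g$d, g$t / sqrt(length(y)), tolerance = 1e-9)
  }
  expect_error(group_one_sample(rep(1, 10)), "zero variance")
  expect_error(group_one_sample(c(1, 2)), "at least 3")
})

test_that("JZS Bayes factors reproduce published default-prior values", {
  expect_equal(jzs_bf_one_sample(0.459, 36), 5.1, tolerance = 0.15 / 5.1)
  expect_equal(jzs_bf_one_sample(0.88, 36), 3.9, tolerance = 0.15 / 3.9)
  expect_equal(jzs_bf_two_sample(0.45, 100, 100), 5.90,
               tolerance = 0.15 / 5.9)
})

test_that("BF01 is maximal at t = 0 and decreases in |t|", {
  ts <- c(0, 0.25, 0.5, 1, 2, 4, 8)
  bfs <- vapply(ts, jzs_bf_one_sample, numeric(1), n = 36)
  expect_true(all(diff(bfs) < 0))
  expect_equal(bfs[1], max(bfs))
  expect_lt(jzs_bf_one_sample(50, 36), 1e-10)
  # symmetry in the two-sample group sizes
  expect_equal(jzs_bf_two_sample(0.8, 30, 50), jzs_bf_two_sample(0.8, 50, 30),
               tolerance = 1e-10)
  # two-sided: sign of t irrelevant
  expect_equal(jzs_bf_one_sample(-0.88, 36), jzs_bf_one_sample(0.88, 36),
               tolerance = 1e-10)
})

test_that("stay probability table reproduces hand counts", {
  # 9 trials, 8 analyzable transitions with known stays
  tr <- make_trials(
    c("A", "A", "B", "B", "A", "A", "A", "B", "B"),
    c("common", "rare", "common", "common", "rare", "common", "common",
      "rare", "common"),
    rep("a", 9),
    c(1, 1, 0, 1, 0, 1, 1, 0, 1))
  tab <- stay_probability_table(tr)
  cell <- function(o, t) tab$p_stay[tab$outcome_prev == o &
                                      tab$transition_prev == t &
                                      tab$recipient == "self"]
  # previous (no_pain, common): rows 2 (A->A stay), 5 (B->A switch),
  # 7 (A->A stay), 8 (A->B switch) -> 2/4
  expect_equal(cell("no_pain", "common"), 0.5)
  # previous (no_pain, rare): row 3 (A->B switch) -> 0
  expect_equal(cell("no_pain", "rare"), 0)
  # previous (pain, common): row 4 (B->B stay) -> 1
  expect_equal(cell("pain", "common"), 1)
  # previous (pain, rare): rows 6 (A->A stay) and 9 (B->B stay) -> 1
  expect_equal(cell("pain", "rare"), 1)
  expect_equal(sum(tab$n), 8)
  # no other-recipient trials: those cells undefined, not fabricated
  expect_true(all(is.na(tab$p_stay[tab$recipient == "other"])))

  # an agent that always repeats its first-stage choice
  always <- make_trials(rep("A", 20), rep("common", 20), rep("a", 20),
                        rbinom(20, 1, 0.5))
  tab2 <- stay_probability_table(always)
  expect_true(all(tab2$p_stay[tab2$n > 0] == 1))
})

test_that("pure-MF cohorts show the model-free stay pattern", {
  cs <- cohort_spec(n_subjects = 8,
                    group_means = c(omega_self = 1e-4, omega_other = 1e-4),
                    group_sds = c(omega_self = 1e-6, omega_other = 1e-6),
                    seed = 61)
  coh <- generate_cohort(cs)
  tab <- stay_probability_table(coh$trials)
  for (rec in c("self", "other")) {
    for (trs in c("common", "rare")) {
      stay_np <- tab$p_stay[tab$outcome_prev == "no_pain" &
                              tab$transition_prev == trs & tab$recipient == rec]
      stay_p <- tab$p_stay[tab$outcome_prev == "pain" &
                             tab$transition_prev == trs & tab$recipient == rec]
      expect_gt(stay_np, stay_p)
    }
  }
})

test_that("post hoc switch proportions detect the recipient asymmetry", {
  # hand-built 2-subject toy with known proportions
  mk_subj <- function(id, switch_pain_self, switch_pain_other) {
    blocks <- list(self = switch_pain_self, other = switch_pain_other)
    trs <- lapply(names(blocks), function(rec) {
      prob <- blocks[[rec]]
      n <- 41
      outc <- rep(c(0, 1), length.out = n)  # pain on odd trials
      c1 <- character(n)
      c1[1] <- "A"
      k <- 0L  # pain-event counter: switch on every (1/prob)-th pain event
      for (i in 2:n) {
        sw <- FALSE
        if (outc[i - 1] == 0) {
          k <- k + 1L
          sw <- k %% round(1 / prob) == 0
        }
        c1[i] <- if (sw) setdiff(c("A", "B"), c1[i - 1]) else c1[i - 1]
      }
      make_trials(c1, rep("common", n), rep("a", n), outc, recipient = rec,
                  block = if (rec == "self") 1L else 2L, subject_id = id)
    })
    do.call(rbind, trs)
  }
  trials <- rbind(mk_subj("s1", 0.5, 0.25), mk_subj("s2", 0.5, 0.25),
                  mk_subj("s3", 0.2, 0.1), mk_subj("s4", 0.2, 0.1))
  ph <- posthoc_switch_proportions(trials)
  ps <- ph$per_subject
  # hand count: 20 previous-pain rows per block; every 2nd/4th/5th/10th
  # pain event is followed by a switch
  expect_equal(ps$switch_pain_self, c(0.5, 0.5, 0.2, 0.2))
  expect_equal(ps$switch_pain_other, c(0.25, 0.25, 0.1, 0.1))
  # paired self-vs-other comparison on the hand-built proportions
  d0 <- ps$switch_pain_other - ps$switch_pain_self
  expect_equal(ph$after_pain$t, mean(d0) / (sd(d0) / sqrt(4)),
               tolerance = 1e-10)

  # paired t on a 2x2 toy matches the textbook formula
  x <- c(0.30, 0.40, 0.20, 0.35)
  y <- c(0.25, 0.30, 0.25, 0.20)
  d <- x - y
  gc <- group_paired(x, y)
  expect_equal(gc$t, mean(d) / (sd(d) / sqrt(4)), tolerance = 1e-10)
  expect_equal(gc$d, mean(d) / sd(d), tolerance = 1e-10)

  # identical behavior in both recipients: t = 0, BF01 at its maximum
  gc0 <- group_paired(c(1e-9, -1e-9, 1e-9, -1e-9), rep(0, 4))
  expect_equal(gc0$t, 0)
  expect_equal(gc0$bf01, jzs_bf_one_sample(0, 4), tolerance = 1e-6)
})

test_that("a recipient-split cohort yields more switching after pain for other", {
  cs <- cohort_spec(group_means = c(omega_self = 0.75, omega_other = 0.15),
                    seed = 71)
  coh <- generate_cohort(cs)
  ph <- posthoc_switch_proportions(coh$trials)
  expect_gt(mean(ph$per_subject$switch_pain_other -
                   ph$per_subject$switch_pain_self), 0)
})

test_that("balanced designs give nearly orthogonal regressors", {
  set.seed(3)
  n <- 4000
  dat <- data.frame(
    outcome = sample(c(-1, 1), n, TRUE),
    transition = sample(c(-1, 1), n, TRUE),
    recipient = rep(c(-1, 1), each = n / 2),
    trial = as.numeric(scale(seq_len(n))))
  x <- aversivetwostep:::design_matrix(dat, regression_spec())
  cors <- cor(x)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.05)
})

test_that("trial-number interactions stay null on stationary cohorts", {
  n_rep <- 60
  rejections <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cs <- cohort_spec(n_subjects = 14, seed = 8000 + r)
    coh <- generate_cohort(cs)
    cr <- fit_cohort_regression(coh$trials,
                                regression_spec(trial_interactions = TRUE))
    g <- group_one_sample(cr$betas[, "outcome:trial"])
    rejections[r] <- g$p < 0.05
  }
  # type-I error compatible with the nominal 5% level
  expect_lt(mean(rejections), 0.15)
  expect_gte(mean(rejections), 0)
})
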