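#' Specify the stay/switch logistic regression
#'
#' Per-subject logistic regression predicting whether the first-stage
#' choice repeats the previous trial's choice ("stay" = 1). Factors are
#' effect-coded: previous outcome (+1 no pain / -1 pain), previous
#' transition (+1 common / -1 rare), recipient (+1 self / -1 other). The
#' model-free signature is the outcome main effect; the model-based
#' signature is the outcome x transition interaction; recipient
#' differences appear in their interactions with recipient.
#'
#' @param terms Character vector of effect terms built from `outcome`,
#'   `transition`, `recipient`, `trial` and `:` interactions.
#' @param trial_interactions If `TRUE`, append the z-scored trial-number
#'   interactions `outcome:trial` and `outcome:recipient:trial`.
#' @return Object of class `regression_spec`.
#' @export
regression_spec <- function(terms = c("outcome", "transition", "recipient",
                                      "outcome:transition",
                                      "outcome:recipient",
                                      "transition:recipient",
                                      "outcome:transition:recipient"),
                            trial_interactions = FALSE) {
  if (trial_interactions)
    terms <- union(terms, c("outcome:trial", "outcome:recipient:trial"))
  allowed <- c("outcome", "transition", "recipient", "trial")
  parts <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  if (!all(parts %in% allowed))
    stop("terms must combine: ", paste(allowed, collapse = ", "))
  structure(list(terms = terms), class = "regression_spec")
}

# Lagged stay/switch data for one subject. The first trial of each block is
# dropped (no previous trial); predictors come from the previous trial.
prep_stay_data <- function(trials) {
  trials <- trials[order(trials$block, trials$trial_index), ]
  n_total <- nrow(trials)
  tz <- as.numeric(scale(trials$trial_index))
  out <- do.call(rbind, lapply(split(seq_len(n_total), trials$block), function(ix) {
    if (length(ix) < 2) return(NULL)
    cur <- ix[-1]; prev <- ix[-length(ix)]
    data.frame(
      stay = as.integer(trials$choice1[cur] == trials$choice1[prev]),
      outcome = ifelse(trials$outcome[prev] == 1, 1, -1),
      transition = ifelse(trials$transition[prev] == "common", 1, -1),
      recipient = ifelse(trials$recipient[cur] == "self", 1, -1),
      trial = tz[cur])
  }))
  rownames(out) <- NULL
  out
}

design_matrix <- function(stay_data, spec) {
  cols <- lapply(spec$terms, function(term) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    Reduce(`*`, stay_data[parts])
  })
  x <- do.call(cbind, cols)
  colnames(x) <- spec$terms
  x
}

#' Subject-level quality control
#'
#' Mirrors the behavioral exclusion rules: a subject fails when fewer than
#' 5% of analyzable trials are switches, or when the effect-coded previous
#' outcome and previous-transition regressors correlate above 0.8 in
#' absolute value on switch trials (either makes the stay/switch logistic
#' regression unidentifiable).
#'
#' @param trials Trial table for one subject.
#' @return List with `pass` (logical), `reason` (`NULL` when passing),
#'   `switch_rate`, and `switch_cor`.
#' @export
qc_subject <- function(trials) {
  sdat <- prep_stay_data(trials)
  switch_rate <- mean(sdat$stay == 0)
  sw <- sdat[sdat$stay == 0, ]
  switch_cor <- if (nrow(sw) >= 2 &&
                    var(sw$outcome) > 0 && var(sw$transition) > 0)
    cor(sw$outcome, sw$transition) else NA_real_
  if (switch_rate < 0.05)
    return(list(pass = FALSE, reason = sprintf(
      "switch rate %.3f below 0.05", switch_rate),
      switch_rate = switch_rate, switch_cor = switch_cor))
  if (is.na(switch_cor))
    return(list(pass = FALSE,
                reason = "outcome/transition regressors degenerate on switch trials",
                switch_rate = switch_rate, switch_cor = switch_cor))
  if (abs(switch_cor) > 0.8)
    return(list(pass = FALSE, reason = sprintf(
      "|cor(outcome, transition)| = %.2f on switch trials exceeds 0.8",
      abs(switch_cor)),
      switch_rate = switch_rate, switch_cor = switch_cor))
  list(pass = TRUE, reason = NULL,
       switch_rate = switch_rate, switch_cor = switch_cor)
}

#' Per-subject stay/switch logistic regression
#'
#' Maximum-likelihood logistic fit of stay (1) vs switch (0) on the
#' effect-coded design of a [regression_spec()].
#'
#' @param trials Trial table for one subject (should have passed
#'   [qc_subject()]).
#' @param spec A [regression_spec()].
#' @return List of class `subject_betas`: `subject_id`, `coefficients`
#'   (named, including `(Intercept)`), `converged`. Separation or
#'   non-convergence is reported through `converged = FALSE`, mirroring
#'   how such subjects were excluded at the group stage.
#' @export
stay_switch_regression <- function(trials, spec = regression_spec()) {
  sd_ <- prep_stay_data(trials)
  x <- design_matrix(sd_, spec)
  dat <- data.frame(stay = sd_$stay, x, check.names = FALSE)
  fml <- stats::as.formula(paste(
    "stay ~", paste(sprintf("`%s`", spec$terms), collapse = " + ")))
  fit <- suppressWarnings(glm(fml, family = binomial(), data = dat))
  cf <- coef(fit)
  names(cf) <- gsub("`", "", names(cf), fixed = TRUE)
  converged <- isTRUE(fit$converged) && all(is.finite(cf)) && all(abs(cf) < 15)
  structure(list(subject_id = trials$subject_id[1],
                 coefficients = cf, converged = converged),
            class = "subject_betas")
}

#' Stay/switch regression across a cohort
#'
#' Applies [qc_subject()] and [stay_switch_regression()] per subject and
#' collects coefficients for group-level tests. Subjects failing QC or not
#' converging are dropped, as in the study's exclusion procedure.
#'
#' @param trials Pooled trial table with `subject_id`.
#' @param spec A [regression_spec()].
#' @return List with `betas` (subjects x terms coefficient matrix,
#'   intercept included), `excluded` (named character vector of reasons),
#'   `spec`.
#' @export
fit_cohort_regression <- function(trials, spec = regression_spec()) {
  by_subj <- split_by_subject(trials)
  excluded <- character(0)
  rows <- list()
  for (id in names(by_subj)) {
    qc <- qc_subject(by_subj[[id]])
    if (!qc$pass) { excluded[id] <- qc$reason; next }
    sb <- stay_switch_regression(by_subj[[id]], spec)
    if (!sb$converged) { excluded[id] <- "regression did not converge"; next }
    rows[[id]] <- sb$coefficients
  }
  if (!length(rows)) stop("no subject passed QC / converged")
  list(betas = do.call(rbind, rows), excluded = excluded, spec = spec)
}

make_group_comparison <- function(ht, d, n, bf01) {
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, d = d,
                 ci = unname(ht$conf.int), bf01 = bf01, n = n),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("t(%g) = %.3f, p = %.4g, d = %.2f, 95%% CI [%.3f, %.3f], BF01 = %.2f\n",
              x$df, x$t, x$p, x$d, x$ci[1], x$ci[2], x$bf01))
  invisible(x)
}

#' One-sample group test with effect size and Bayes factor
#'
#' Two-tailed one-sample t-test against zero with Cohen's `d = mean/sd`
#' (so `d = t/sqrt(n)`), the 95% CI of the mean, and the JZS Bayes factor
#' for the null.
#'
#' @param values Per-subject statistics (n >= 3, non-constant).
#' @param cauchy_scale Prior scale for [jzs_bf_one_sample()].
#' @return Object of class `group_comparison` with fields `t`, `df`, `p`,
#'   `d`, `ci`, `bf01`, `n`.
#' @export
group_one_sample <- function(values, cauchy_scale = 0.707) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3) stop("need at least 3 finite values")
  if (sd(values) == 0)
    stop("values have zero variance; a t-test is undefined (check inputs)")
  ht <- t.test(values)
  make_group_comparison(ht, d = mean(values) / sd(values), n = n,
                        bf01 = jzs_bf_one_sample(unname(ht$statistic), n,
                                                 cauchy_scale))
}

#' Paired group test with effect size and Bayes factor
#'
#' Two-tailed paired t-test (`x - y`), Cohen's d on the paired differences,
#' and the JZS Bayes factor of the corresponding one-sample test.
#'
#' @param x,y Paired per-subject values.
#' @inheritParams group_one_sample
#' @return A `group_comparison`.
#' @export
group_paired <- function(x, y, cauchy_scale = 0.707) {
  ok <- is.finite(x) & is.finite(y)
  group_one_sample(x[ok] - y[ok], cauchy_scale = cauchy_scale)
}

#' Two-sample group test with effect size and Bayes factor
#'
#' Two-tailed pooled-variance t-test, Cohen's d with the pooled standard
#' deviation, and the JZS Bayes factor for the null.
#'
#' @param x,y Group samples.
#' @inheritParams group_one_sample
#' @return A `group_comparison` (df = `n1 + n2 - 2`).
#' @export
group_two_sample <- function(x, y, cauchy_scale = 0.707) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  stopifnot(length(x) >= 2, length(y) >= 2)
  ht <- t.test(x, y, var.equal = TRUE)
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
               (length(x) + length(y) - 2))
  make_group_comparison(ht, d = (mean(x) - mean(y)) / sp,
                        n = c(length(x), length(y)),
                        bf01 = jzs_bf_two_sample(unname(ht$statistic),
                                                 length(x), length(y),
                                                 cauchy_scale))
}

#' Stay probabilities by previous outcome, transition, and recipient
#'
#' Empirical probability of repeating the previous first-stage choice for
#' each cell of (previous outcome) x (previous transition) x (recipient),
#' with trial counts. Cells with no trials carry `NA` proportions.
#'
#' @param trials Trial table (one subject or pooled).
#' @return Data frame with 8 rows: `outcome_prev` (`"pain"`/`"no_pain"`),
#'   `transition_prev`, `recipient`, `p_stay`, `n`.
#' @export
stay_probability_table <- function(trials) {
  parts <- lapply(split_by_subject(trials), prep_stay_data)
  sd_ <- do.call(rbind, parts)
  grid <- expand.grid(outcome_prev = c("no_pain", "pain"),
                      transition_prev = c("common", "rare"),
                      recipient = c("self", "other"),
                      stringsAsFactors = FALSE)
  grid$p_stay <- NA_real_
  grid$n <- 0L
  for (i in seq_len(nrow(grid))) {
    sel <- sd_$outcome == ifelse(grid$outcome_prev[i] == "no_pain", 1, -1) &
      sd_$transition == ifelse(grid$transition_prev[i] == "common", 1, -1) &
      sd_$recipient == ifelse(grid$recipient[i] == "self", 1, -1)
    grid$n[i] <- sum(sel)
    if (grid$n[i] > 0) grid$p_stay[i] <- mean(sd_$stay[sel])
  }
  grid
}

#' Post hoc switch proportions after pain and after no pain
#'
#' For every subject, the proportion of switch choices following pain
#' outcomes and following no-pain outcomes, separately for self and other;
#' paired t-tests (other minus self) quantify the recipient difference for
#' each outcome type.
#'
#' @param trials Pooled trial table; subjects missing a condition are
#'   dropped with a warning.
#' @return List with `after_pain` and `after_no_pain`
#'   ([group_paired()] comparisons of other vs self) and `per_subject`
#'   (data frame of the four proportions per subject).
#' @export
posthoc_switch_proportions <- function(trials) {
  by_subj <- split_by_subject(trials)
  rows <- lapply(by_subj, function(tr) {
    sd_ <- prep_stay_data(tr)
    cell <- function(outc, rec) {
      sel <- sd_$outcome == outc & sd_$recipient == rec
      if (!any(sel)) NA_real_ else mean(sd_$stay[sel] == 0)
    }
    data.frame(subject_id = tr$subject_id[1],
               switch_pain_self = cell(-1, 1),
               switch_pain_other = cell(-1, -1),
               switch_nopain_self = cell(1, 1),
               switch_nopain_other = cell(1, -1))
  })
  ps <- do.call(rbind, rows)
  rownames(ps) <- NULL
  complete <- stats::complete.cases(ps[-1])
  if (any(!complete)) {
    warning(sum(!complete), " subject(s) lacking a condition dropped")
    ps <- ps[complete, ]
  }
  # identical behavior for both recipients gives all-zero differences; the
  # comparison is then a flat null (t = 0, BF01 at its maximum for n)
  paired_or_null <- function(x, y) {
    d <- x - y
    if (sd(d) == 0 && mean(d) == 0) {
      return(structure(list(t = 0, df = length(d) - 1, p = 1, d = 0,
                            ci = c(0, 0),
                            bf01 = jzs_bf_one_sample(0, length(d)),
                            n = length(d)),
                       class = "group_comparison"))
    }
    group_paired(x, y)
  }
  list(after_pain = paired_or_null(ps$switch_pain_other, ps$switch_pain_self),
       after_no_pain = paired_or_null(ps$switch_nopain_other,
                                      ps$switch_nopain_self),
       per_subject = ps)
}
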