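#' Parameter transforms between natural and unconstrained space
#'
#' Hierarchical fitting works in an unconstrained space where Gaussian
#' group priors are sensible: unit-interval parameters (learning rates,
#' omega) are logit-transformed, positive parameters (beta, lambda)
#' log-transformed, and perseverance (rho) is already unbounded.
#' `untransform_params()` inverts the map exactly.
#'
#' @param params Named natural-space vector for `spec` (strictly inside the
#'   open parameter ranges).
#' @param spec A [model_spec()] or registry name.
#' @return `transform_params()`: named numeric vector in transformed space;
#'   `untransform_params()`: named natural-space vector.
#' @export
transform_params <- function(params, spec) {
  spec <- get_model_spec(spec)
  p <- check_params(params, spec)
  out <- p
  unit <- grepl("^(alpha|omega)", names(p))
  pos <- grepl("^(beta|lambda)", names(p))
  out[unit] <- log(p[unit] / (1 - p[unit]))
  out[pos] <- log(p[pos])
  out
}

#' @rdname transform_params
#' @param x Named or unnamed numeric vector in transformed space, ordered
#'   as `spec$param_names`.
#' @export
untransform_params <- function(x, spec) {
  spec <- get_model_spec(spec)
  if (length(x) != spec$n_params)
    stop("transformed vector has wrong length for this model")
  out <- setNames(as.numeric(x), spec$param_names)
  unit <- grepl("^(alpha|omega)", spec$param_names)
  pos <- grepl("^(beta|lambda)", spec$param_names)
  out[unit] <- 1 / (1 + exp(-out[unit]))
  out[pos] <- exp(out[pos])
  out
}

#' Default group prior in transformed space
#'
#' Weakly informative independent Gaussian prior: mean 0 (i.e. 0.5 for
#' unit-interval parameters, 1 for positive ones), variance 6.25.
#'
#' @param spec A [model_spec()] or registry name.
#' @param mu,sigma2 Scalars or vectors recycled over parameters.
#' @return List with `mu` and `sigma2` vectors of length `n_params`.
#' @export
group_prior <- function(spec, mu = 0, sigma2 = 6.25) {
  spec <- get_model_spec(spec)
  list(mu = setNames(rep_len(mu, spec$n_params), spec$param_names),
       sigma2 = setNames(rep_len(sigma2, spec$n_params), spec$param_names))
}

# Nearest positive-definite projection by eigenvalue clipping.
nearest_pd <- function(h, min_eig = 1e-6) {
  h <- (h + t(h)) / 2
  e <- eigen(h, symmetric = TRUE)
  vals <- pmax(e$values, min_eig)
  e$vectors %*% (vals * t(e$vectors))
}

#' Maximum a posteriori fit for one subject
#'
#' Minimises `NLL(theta) - log N(theta; mu, diag(sigma2))` in transformed
#' space with BFGS from `n_restarts` jittered starts. Returns the best
#' optimum with its finite-difference Hessian, Laplace posterior variances,
#' and a Laplace approximation to the log model evidence
#' (the likelihood integrated over the group prior).
#'
#' @param trials Trial table for one subject.
#' @param spec A [model_spec()] or registry name.
#' @param prior A [group_prior()]; defaults to the weak prior.
#' @param n_restarts Number of jittered optimizer starts (default 5). Ties
#'   within 1e-6 of the best penalized objective are broken by lower NLL,
#'   then by smaller parameter norm.
#' @param start Optional transformed-space start for the first restart
#'   (used to warm-start EM iterations); remaining restarts jitter around
#'   the prior mean.
#' @param rng_seed Optional seed controlling the jitter.
#' @param p_common Transition probability used by the likelihood.
#' @param allow_negative_beta Diagnostic flag: when `TRUE`, beta is fitted
#'   on the identity (unbounded) scale so negative values are reachable.
#' @return List of class `subject_fit`: `map_transformed`, `map_natural`,
#'   `nll`, `penalized`, `hessian`, `posterior_var`, `log_evidence`
#'   (Laplace), `converged`.
#' @export
fit_map_subject <- function(trials, spec, prior = NULL, n_restarts = 5,
                            start = NULL, rng_seed = NULL, p_common = 0.7,
                            allow_negative_beta = FALSE) {
  spec <- get_model_spec(spec)
  if (NROW(trials) == 0) stop("empty trial list")
  if (is.null(prior)) prior <- group_prior(spec)
  k <- spec$n_params
  stopifnot(length(prior$mu) == k, length(prior$sigma2) == k,
            all(prior$sigma2 > 0))
  tm <- encode_trials(trials)
  beta_idx <- grepl("^beta", spec$param_names)
  unit_idx <- grepl("^(alpha|omega)", spec$param_names)
  pos_idx <- grepl("^(beta|lambda)", spec$param_names) &
    !(allow_negative_beta & beta_idx)
  ex <- param_expander(spec)
  prior_sd <- sqrt(prior$sigma2)
  to_natural <- function(x) {
    nat <- x
    nat[unit_idx] <- 1 / (1 + exp(-x[unit_idx]))
    nat[pos_idx] <- exp(x[pos_idx])
    nat
  }
  objective <- function(x) {
    nat <- to_natural(x)
    par <- ex$const
    par[ex$sel] <- nat[ex$idx[ex$sel]]
    nll_canonical_cpp(tm, par, p_common, FALSE) -
      sum(dnorm(x, prior$mu, prior_sd, log = TRUE))
  }
  starts <- with_seed(rng_seed, {
    s <- matrix(rep(prior$mu, n_restarts), nrow = n_restarts, byrow = TRUE)
    if (!is.null(start)) s[1, ] <- start
    if (n_restarts > 1)
      s[-1, ] <- s[-1, ] + matrix(rnorm((n_restarts - 1) * k,
                                        sd = 0.5 * sqrt(prior$sigma2)),
                                  n_restarts - 1, k, byrow = TRUE)
    s
  })
  best <- NULL
  any_ok <- FALSE
  for (i in seq_len(n_restarts)) {
    fit <- tryCatch(
      optim(starts[i, ], objective, method = "BFGS",
            control = list(maxit = 300)),
      error = function(e) NULL)
    if (is.null(fit))
      fit <- tryCatch(
        optim(starts[i, ], objective, method = "Nelder-Mead",
              control = list(maxit = 2000)),
        error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    any_ok <- TRUE
    if (is.null(best)) { best <- fit; next }
    dv <- fit$value - best$value
    if (dv < -1e-6) best <- fit
    else if (abs(dv) <= 1e-6 && sum(fit$par^2) < sum(best$par^2)) best <- fit
  }
  if (!any_ok) stop("MAP optimization failed on all restarts")
  x <- setNames(best$par, spec$param_names)
  h <- tryCatch(optimHess(x, objective), error = function(e) NULL)
  singular <- is.null(h) || !all(is.finite(h))
  if (singular) h <- diag(1 / prior$sigma2, k)
  hpd <- nearest_pd(h)
  pvar <- diag(solve(hpd))
  logdet <- determinant(hpd, logarithm = TRUE)$modulus[1]
  log_evidence <- -best$value + 0.5 * k * log(2 * pi) - 0.5 * logdet
  nat <- to_natural(x)
  structure(list(map_transformed = x,
                 map_natural = nat,
                 nll = best$value +
                   sum(dnorm(x, prior$mu, sqrt(prior$sigma2), log = TRUE)),
                 penalized = best$value,
                 hessian = hpd,
                 posterior_var = setNames(pvar, spec$param_names),
                 log_evidence = log_evidence,
                 hessian_singular = singular,
                 converged = best$convergence == 0),
            class = "subject_fit")
}

#' Split a pooled trial table into a per-subject list
#'
#' @param trials Trial table with a `subject_id` column.
#' @return Named list of per-subject trial tables, rows ordered by block
#'   and trial index.
#' @export
split_by_subject <- function(trials) {
  trials <- trials[order(trials$subject_id, trials$block, trials$trial_index), ]
  split(trials, trials$subject_id)
}

#' Hierarchical fit of a cohort by expectation-maximization
#'
#' Empirical-Bayes scheme: the E-step computes every subject's MAP estimate
#' and Laplace posterior variance under the current Gaussian group prior;
#' the M-step re-estimates the prior as `mu = mean(MAP)` and
#' `sigma2 = mean(MAP^2 + posterior variance) - mu^2` (floored at 1e-6).
#' Iterates until the largest change in `(mu, sigma2)` drops below `tol`.
#'
#' @param cohort Either a pooled trial table with a `subject_id` column or
#'   a named list of per-subject trial tables (at least 2 subjects).
#' @param spec A [model_spec()] or registry name.
#' @param max_iter Maximum EM iterations (default 30).
#' @param tol Convergence tolerance on prior parameters (default 1e-3).
#' @param rng_seed Seed controlling optimizer restarts.
#' @param n_restarts Optimizer restarts per subject and iteration.
#' @param n_mc_samples Prior draws for the integrated-BIC computation
#'   (passed to [compute_bic_int()]); set to 0 to skip.
#' @param p_common Transition probability used by the likelihood.
#' @param verbose Print per-iteration progress.
#' @return List of class `fit_result`: `spec`, `prior`, `subjects` (list of
#'   `subject_fit`), `subject_ids`, `trials` (the per-subject list),
#'   `penalized_posterior` trajectory (summed over subjects, one value per
#'   iteration), `n_em_iterations`, `converged`, and — unless skipped —
#'   `bic_int` and `subject_log_evidence`.
#' @export
em_hierarchical_fit <- function(cohort, spec, max_iter = 30, tol = 1e-3,
                                rng_seed = NULL, n_restarts = 3,
                                n_mc_samples = 1000, p_common = 0.7,
                                verbose = FALSE) {
  spec <- get_model_spec(spec)
  if (is.data.frame(cohort)) cohort <- split_by_subject(cohort)
  if (length(cohort) < 2) stop("hierarchical fitting needs at least 2 subjects")
  prior <- group_prior(spec)
  traj <- numeric(0)
  subjects <- NULL
  converged <- FALSE
  iter <- 0L
  maps_prev <- NULL
  for (iter in seq_len(max_iter)) {
    # after the first iteration, E-steps are warm-started at the previous
    # MAP; jittered restarts are only needed from the cold prior
    subjects <- lapply(seq_along(cohort), function(i)
      fit_map_subject(cohort[[i]], spec, prior,
                      n_restarts = if (iter == 1L) n_restarts else 1L,
                      start = if (iter == 1L) NULL else maps_prev[i, ],
                      rng_seed = derive_seed(rng_seed, iter * 1000L + i),
                      p_common = p_common))
    maps <- do.call(rbind, lapply(subjects, `[[`, "map_transformed"))
    maps_prev <- maps
    pvar <- do.call(rbind, lapply(subjects, `[[`, "posterior_var"))
    traj <- c(traj, -sum(vapply(subjects, `[[`, numeric(1), "penalized")))
    mu_new <- colMeans(maps)
    sigma2_new <- pmax(colMeans(maps^2 + pvar) - mu_new^2, 1e-6)
    delta <- max(abs(mu_new - prior$mu), abs(sigma2_new - prior$sigma2))
    prior <- list(mu = mu_new, sigma2 = sigma2_new)
    if (verbose)
      message(sprintf("EM iter %d: penalized log posterior %.3f, delta %.4g",
                      iter, traj[iter], delta))
    if (delta < tol) { converged <- TRUE; break }
  }
  fit <- structure(list(spec = spec, prior = prior, subjects = subjects,
                        subject_ids = names(cohort), trials = cohort,
                        penalized_posterior = traj,
                        n_em_iterations = iter, converged = converged),
                   class = "fit_result")
  if (n_mc_samples > 0) {
    bic <- compute_bic_int(fit, n_mc_samples = max(n_mc_samples, 100),
                           rng_seed = derive_seed(rng_seed, 999983L),
                           p_common = p_common)
    fit$bic_int <- bic$bic_int
    fit$subject_log_evidence <- bic$subject_log_evidence
  }
  fit
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Hierarchical fit of '%s' (%d subjects, %d EM iterations%s)\n",
              x$spec$name, length(x$subjects), x$n_em_iterations,
              if (x$converged) ", converged" else ", not converged"))
  est <- coef(x)
  cat("group means (natural space):\n")
  print(round(colMeans(est), 3))
  if (!is.null(x$bic_int)) cat(sprintf("BICint = %.1f\n", x$bic_int))
  invisible(x)
}

#' @export
coef.fit_result <- function(object, ...) {
  est <- do.call(rbind, lapply(object$subjects, `[[`, "map_natural"))
  rownames(est) <- object$subject_ids
  est
}

#' Integrated-BIC model evidence
#'
#' For each subject, the log model evidence is approximated by Monte-Carlo
#' integration of the choice likelihood over the fitted group prior:
#' `log mean_j exp(-NLL(theta_j))` for draws `theta_j ~ N(mu, diag(sigma2))`
#' (log-sum-exp stabilised). The group-level score is
#' `BICint = -2 * sum_s log evidence_s + (2 * n_params) * log(n_choices)`,
#' where `n_choices` counts every recorded choice (two per trial) and the
#' penalty counts the two group-level quantities (mean, variance) fitted
#' per free parameter.
#'
#' @param fit A `fit_result` from [em_hierarchical_fit()].
#' @param n_mc_samples Prior draws per subject (at least 100).
#' @param rng_seed Optional seed for the draws.
#' @param p_common Transition probability used by the likelihood.
#' @return List with `bic_int` and the per-subject `subject_log_evidence`
#'   vector used by [exceedance_probabilities()].
#' @export
compute_bic_int <- function(fit, n_mc_samples = 2000, rng_seed = NULL,
                            p_common = 0.7) {
  stopifnot(inherits(fit, "fit_result"))
  if (n_mc_samples < 100) stop("`n_mc_samples` must be at least 100")
  spec <- fit$spec
  k <- spec$n_params
  draws <- with_seed(rng_seed,
    matrix(rnorm(n_mc_samples * k, mean = rep(fit$prior$mu, each = n_mc_samples),
                 sd = rep(sqrt(fit$prior$sigma2), each = n_mc_samples)),
           n_mc_samples, k))
  unit_idx <- grepl("^(alpha|omega)", spec$param_names)
  pos_idx <- grepl("^(beta|lambda)", spec$param_names)
  ex <- param_expander(spec)
  pars <- lapply(seq_len(n_mc_samples), function(j) {
    nat <- draws[j, ]
    nat[unit_idx] <- 1 / (1 + exp(-nat[unit_idx]))
    nat[pos_idx] <- exp(nat[pos_idx])
    par <- ex$const
    par[ex$sel] <- nat[ex$idx[ex$sel]]
    par
  })
  log_ev <- vapply(fit$trials, function(trials) {
    tm <- encode_trials(trials)
    ll <- vapply(pars, function(par)
      -nll_canonical_cpp(tm, par, p_common, FALSE), numeric(1))
    m <- max(ll)
    m + log(mean(exp(ll - m)))
  }, numeric(1))
  n_choices <- 2 * sum(vapply(fit$trials, nrow, integer(1)))
  list(bic_int = -2 * sum(log_ev) + (2 * k) * log(n_choices),
       subject_log_evidence = log_ev)
}

#' Compare fitted models
#'
#' Collects per-model BICint scores and random-effects exceedance
#' probabilities from a set of hierarchical fits of the same cohort.
#'
#' @param fits Named list of `fit_result` objects (same subjects, same
#'   order) carrying `subject_log_evidence`.
#' @param rng_seed Seed for the exceedance Monte-Carlo step.
#' @return List of class `model_comparison` with `bic_int` (named vector),
#'   `exceedance` (named vector summing to 1), and `log_evidence`
#'   (subjects x models matrix).
#' @export
compare_models <- function(fits, rng_seed = NULL) {
  stopifnot(length(fits) >= 2)
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f) f$spec$name, character(1))
  lev <- vapply(fits, function(f) {
    if (is.null(f$subject_log_evidence))
      stop("fit lacks subject log evidences; run compute_bic_int()")
    f$subject_log_evidence
  }, numeric(length(fits[[1]]$subjects)))
  structure(list(
    bic_int = vapply(fits, `[[`, numeric(1), "bic_int"),
    exceedance = exceedance_probabilities(lev, rng_seed = rng_seed),
    log_evidence = lev), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  tab <- data.frame(model = colnames(x$log_evidence),
                    bic_int = round(x$bic_int, 1),
                    exceedance = round(x$exceedance, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}
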