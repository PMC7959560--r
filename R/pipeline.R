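#' Assemble a pipeline configuration
#'
#' Flat configuration driving [run_pipeline()]. Stages: `simulate`
#' (generate a synthetic cohort; otherwise `input` is read), `qc`,
#' `regress` (stay/switch regression + group tests), `fit` (hierarchical
#' fits of `models`), `compare` (BICint + exceedance over the fitted
#' models), `equivalence` (incentive-equivalence control simulation).
#'
#' @param out_dir Output directory (created if absent).
#' @param stages Character vector of stages to run, in order.
#' @param input Optional path to a trial CSV (used when `simulate` is not
#'   among the stages).
#' @param dialect Input dialect for [load_trials()].
#' @param models Model names to fit (must exist in [model_registry()]).
#' @param seed Master seed; every random stage derives its own stream.
#' @param n_subjects,trial_interactions,fit_options Forwarded to the
#'   respective stages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            stages = c("simulate", "qc", "regress"),
                            input = NULL,
                            dialect = "native",
                            models = "win6_omega_split",
                            seed = 1L,
                            n_subjects = 36,
                            trial_interactions = FALSE,
                            fit_options = list()) {
  known <- c("simulate", "qc", "regress", "fit", "compare", "equivalence")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  for (m in models) get_model_spec(m)  # validate before any computation
  if ("compare" %in% stages && length(models) < 2)
    stop("stage 'compare' needs at least 2 models")
  structure(list(out_dir = out_dir, stages = stages, input = input,
                 dialect = dialect, models = models, seed = as.integer(seed),
                 n_subjects = n_subjects,
                 trial_interactions = trial_interactions,
                 fit_options = fit_options),
            class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the configured stages on a synthetic or loaded cohort, writing
#' tidy CSV results, a JSON summary, and a run log (seeds and package
#' version) into `out_dir`. All floating-point outputs use 10 significant
#' digits so reruns with the same configuration are byte-identical.
#'
#' @param config A [pipeline_config()] or the path to a JSON file with the
#'   same fields.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- do.call(pipeline_config, jsonlite::read_json(config,
                                                           simplifyVector = TRUE))
  }
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  old_digits <- options(digits = 10)
  on.exit(options(old_digits))
  log_path <- file.path(config$out_dir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = log_path, append = TRUE)
  cat(sprintf("aversivetwostep %s | seed %d | stages: %s\n",
              as.character(utils::packageVersion("aversivetwostep")),
              config$seed, paste(config$stages, collapse = ", ")),
      file = log_path)
  summary <- list(seed = config$seed, stages = config$stages)
  fail <- function(stage, e) stop(sprintf("[stage %s] %s", stage,
                                          conditionMessage(e)), call. = FALSE)

  trials <- NULL
  if ("simulate" %in% config$stages) {
    tryCatch({
      cs <- cohort_spec(n_subjects = config$n_subjects,
                        model = config$models[1],
                        seed = derive_seed(config$seed, 1L))
      coh <- generate_cohort(cs)
      trials <- coh$trials
      write_trials(trials, file.path(config$out_dir, "cohort.csv"))
      write.csv(coh$truth, file.path(config$out_dir, "cohort_truth.csv"),
                row.names = FALSE)
      logline("simulate: %d subjects, %d trials", cs$n_subjects, nrow(trials))
    }, error = function(e) fail("simulate", e))
  } else {
    tryCatch({
      if (is.null(config$input)) stop("no input file and no simulate stage")
      trials <- load_trials(config$input, config$dialect)
      logline("load: %s (%d rows)", config$input, nrow(trials))
    }, error = function(e) fail("load", e))
  }

  if ("qc" %in% config$stages) {
    tryCatch({
      qc <- lapply(split_by_subject(trials), qc_subject)
      qdf <- data.frame(subject_id = names(qc),
                        pass = vapply(qc, `[[`, logical(1), "pass"),
                        switch_rate = vapply(qc, `[[`, numeric(1), "switch_rate"),
                        reason = vapply(qc, function(x)
                          if (is.null(x$reason)) "" else x$reason, character(1)))
      write.csv(qdf, file.path(config$out_dir, "qc.csv"), row.names = FALSE)
      summary$qc <- list(n_pass = sum(qdf$pass), n_fail = sum(!qdf$pass))
      logline("qc: %d pass / %d fail", sum(qdf$pass), sum(!qdf$pass))
    }, error = function(e) fail("qc", e))
  }

  if ("regress" %in% config$stages) {
    tryCatch({
      rs <- regression_spec(trial_interactions = config$trial_interactions)
      cr <- fit_cohort_regression(trials, rs)
      terms <- setdiff(colnames(cr$betas), "(Intercept)")
      rows <- lapply(terms, function(tm) {
        gc <- group_one_sample(cr$betas[, tm])
        cbind(group_comparison_row(tm, gc),
              estimate = mean(cr$betas[, tm]),
              se = sd(cr$betas[, tm]) / sqrt(nrow(cr$betas)))
      })
      res <- do.call(rbind, rows)
      write.csv(format(res, digits = 10),
                file.path(config$out_dir, "regression_group.csv"),
                row.names = FALSE)
      write.csv(format(stay_probability_table(trials), digits = 10),
                file.path(config$out_dir, "stay_table.csv"), row.names = FALSE)
      summary$regression <- setNames(
        lapply(seq_len(nrow(res)), function(i)
          list(t = res$t[i], p = res$p[i], d = res$d[i], bf01 = res$bf01[i])),
        res$term)
      logline("regress: %d subjects analyzed, %d excluded",
              nrow(cr$betas), length(cr$excluded))
    }, error = function(e) fail("regress", e))
  }

  fits <- list()
  if ("fit" %in% config$stages) {
    tryCatch({
      fo <- modifyList(list(max_iter = 10, tol = 0.005, n_restarts = 2,
                            n_mc_samples = 1000), config$fit_options)
      for (m in config$models) {
        fit <- em_hierarchical_fit(trials, m,
                                   max_iter = fo$max_iter, tol = fo$tol,
                                   rng_seed = derive_seed(config$seed, 2L),
                                   n_restarts = fo$n_restarts,
                                   n_mc_samples = fo$n_mc_samples)
        fits[[m]] <- fit
        write_fit_result(fit,
                         file.path(config$out_dir, paste0("fit_", m, ".json")),
                         file.path(config$out_dir, paste0("fit_", m, "_params.csv")))
        summary$fit[[m]] <- list(bic_int = fit$bic_int,
                                 converged = fit$converged,
                                 group_means = as.list(colMeans(coef(fit))))
        logline("fit %s: BICint %.1f (%d EM iterations)", m,
                fit$bic_int, fit$n_em_iterations)
      }
    }, error = function(e) fail("fit", e))
  }

  if ("compare" %in% config$stages) {
    tryCatch({
      cmp <- compare_models(fits, rng_seed = derive_seed(config$seed, 3L))
      write.csv(format(data.frame(model = names(cmp$bic_int),
                                  bic_int = cmp$bic_int,
                                  exceedance = as.numeric(cmp$exceedance)),
                       digits = 10),
                file.path(config$out_dir, "model_comparison.csv"),
                row.names = FALSE)
      summary$comparison <- list(bic_int = as.list(cmp$bic_int),
                                 exceedance = as.list(cmp$exceedance))
      logline("compare: best model %s", names(which.min(cmp$bic_int)))
    }, error = function(e) fail("compare", e))
  }

  if ("equivalence" %in% config$stages) {
    tryCatch({
      eq <- run_incentive_equivalence(seed = derive_seed(config$seed, 4L))
      summary$equivalence <- list(t = eq$comparison$t, df = eq$comparison$df,
                                  p = eq$comparison$p,
                                  bf01 = eq$comparison$bf01)
      logline("equivalence: t(%g) = %.3f, BF01 = %.2f", eq$comparison$df,
              eq$comparison$t, eq$comparison$bf01)
    }, error = function(e) fail("equivalence", e))
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(summary)
}
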