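trial_columns <- c("subject_id", "block", "trial_index", "recipient",
                   "choice1", "transition", "state2", "choice2",
                   "outcome", "rt1")

#' Write a trial table to CSV
#'
#' Serialises trials with the exact trial-record column names; missing
#' reaction times are written as empty fields. Rows are ordered by
#' subject, block, and trial index.
#'
#' @param trials Trial table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(trial_columns, names(trials))
  if (length(missing))
    stop("trial table lacks columns: ", paste(missing, collapse = ", "))
  trials <- trials[order(trials$subject_id, trials$block, trials$trial_index),
                   trial_columns]
  write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

# Map alternative value codings onto the native schema.
normalize_trials <- function(df) {
  recode <- function(x, from, to) {
    x <- as.character(x)
    i <- match(x, from)
    ifelse(is.na(i), x, to[i])
  }
  df$recipient <- recode(df$recipient, c("1", "2"), c("self", "other"))
  df$choice1 <- recode(df$choice1, c("1", "2"), c("A", "B"))
  df$transition <- recode(df$transition, c("1", "0"), c("common", "rare"))
  s2_codes <- unique(as.character(df$state2))
  if (all(s2_codes %in% c("2", "3"))) {
    # states numbered to match their names (2 = S2, 3 = S3)
    df$state2 <- recode(df$state2, c("2", "3"), c("S2", "S3"))
  } else {
    df$state2 <- recode(df$state2, c("1", "2"), c("S2", "S3"))
  }
  df$choice2 <- recode(df$choice2, c("1", "2"), c("a", "b"))
  df
}

validate_trials <- function(df, path) {
  checks <- list(
    recipient = df$recipient %in% c("self", "other"),
    choice1 = df$choice1 %in% c("A", "B"),
    transition = df$transition %in% c("common", "rare"),
    state2 = df$state2 %in% c("S2", "S3"),
    choice2 = df$choice2 %in% c("a", "b"),
    outcome = df$outcome %in% c(0L, 1L))
  # transition label must match the fixed mapping choice1 -> state2
  mapped <- ifelse(df$choice1 == "A", "S2", "S3")
  checks$transition_consistency <-
    (df$transition == "common") == (df$state2 == mapped)
  bad <- !Reduce(`&`, checks)
  if (any(bad)) {
    lines <- which(bad) + 1L  # header offset
    fields <- names(checks)[vapply(names(checks),
                                   function(f) any(!checks[[f]] & bad),
                                   logical(1))]
    stop(sprintf("%s: %d invalid row(s) (fields: %s) at line(s) %s",
                 path, sum(bad), paste(fields, collapse = ", "),
                 paste(utils::head(lines, 10), collapse = ", ")))
  }
  df
}

osf_column_map <- function() {
  read.csv(system.file("extdata", "osf_column_map.csv",
                       package = "aversivetwostep"),
           stringsAsFactors = FALSE)
}

#' Read a trial table from CSV
#'
#' Reads and validates trial records. The `native` dialect expects the
#' package's own column names; the `osf` dialect first renames columns via
#' the declared mapping table shipped in
#' `inst/extdata/osf_column_map.csv` (a data file meant to be aligned once
#' against the deposited dataset's header). Common alternative value codes
#' (numeric recipients/choices/states) are normalised; outcome must be 0
#' (pain) or 1 (no pain). Invalid rows are reported with their line
#' numbers.
#'
#' @param path CSV file path.
#' @param dialect `"native"` or `"osf"`.
#' @return Validated trial table ordered by subject, block, trial index.
#' @export
load_trials <- function(path, dialect = c("native", "osf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty trial file: ", path)
  if (dialect == "osf") {
    map <- osf_column_map()
    hit <- match(names(df), map$osf)
    names(df)[!is.na(hit)] <- map$native[hit[!is.na(hit)]]
  }
  missing <- setdiff(setdiff(trial_columns, "rt1"), names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  if (!"rt1" %in% names(df)) df$rt1 <- NA_real_
  df$rt1 <- suppressWarnings(as.numeric(df$rt1))
  df <- normalize_trials(df)
  df <- validate_trials(df[trial_columns], path)
  df$block <- as.integer(df$block)
  df$trial_index <- as.integer(df$trial_index)
  df$outcome <- as.integer(df$outcome)
  df[order(df$subject_id, df$block, df$trial_index), ]
}

#' Serialise a hierarchical fit
#'
#' Writes a structured JSON document (model, group prior, per-subject MAP
#' estimates and log evidences, BICint) and optionally a flat CSV of
#' per-subject natural-space parameters.
#'
#' @param fit A `fit_result`.
#' @param path_json Output JSON path.
#' @param path_csv Optional CSV path for the parameter table.
#' @return `path_json`, invisibly.
#' @export
write_fit_result <- function(fit, path_json, path_csv = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  est <- coef(fit)
  doc <- list(
    model = fit$spec$name,
    param_names = fit$spec$param_names,
    prior = list(mu = unname(fit$prior$mu), sigma2 = unname(fit$prior$sigma2)),
    n_em_iterations = fit$n_em_iterations,
    converged = fit$converged,
    bic_int = fit$bic_int,
    subjects = lapply(seq_along(fit$subjects), function(i) list(
      subject_id = fit$subject_ids[i],
      map_natural = as.list(fit$subjects[[i]]$map_natural),
      nll = fit$subjects[[i]]$nll,
      log_evidence_laplace = fit$subjects[[i]]$log_evidence,
      log_evidence_mc = if (!is.null(fit$subject_log_evidence))
        unname(fit$subject_log_evidence[i]) else NULL)))
  jsonlite::write_json(doc, path_json, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  if (!is.null(path_csv))
    write.csv(data.frame(subject_id = fit$subject_ids, est,
                         check.names = FALSE),
              path_csv, row.names = FALSE)
  invisible(path_json)
}

group_comparison_row <- function(term, gc) {
  data.frame(term = term, t = gc$t, df = gc$df, p = gc$p, d = gc$d,
             ci_low = gc$ci[1], ci_high = gc$ci[2], bf01 = gc$bf01)
}
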