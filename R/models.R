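#' Declare a hybrid learner model variant
#'
#' A model specification fixes which parameters of the hybrid
#' model-free/model-based learner are free, shared, or split. Modes:
#' * `learning_rate_mode`: `"single"` (one alpha) or `"valence"`
#'   (`alpha_pain`, `alpha_nopain` for pain vs no-pain outcomes);
#' * `beta_mode`: `"single"` (one inverse temperature for both stages) or
#'   `"stage"` (`beta1`, `beta2`);
#' * `lambda_mode`: `"free"` (eligibility weight fitted) or `"fixed1"`
#'   (lambda pinned at 1, collapsing the first-stage model-free update to a
#'   direct outcome update);
#' * `perseverance_mode`: `"shared"`, `"recipient"` (`rho_self`,
#'   `rho_other`), or `"absent"`;
#' * `omega_mode`: `"shared"` or `"recipient"` (`omega_self`,
#'   `omega_other`), the model-based weight.
#'
#' @param name Identifier for the variant.
#' @param learning_rate_mode,beta_mode,lambda_mode,perseverance_mode,omega_mode
#'   Modes as described above.
#' @return An object of class `model_spec` with derived `n_params` and
#'   `param_names`.
#' @seealso [model_registry()]
#' @export
model_spec <- function(name,
                       learning_rate_mode = c("valence", "single"),
                       beta_mode = c("single", "stage"),
                       lambda_mode = c("fixed1", "free"),
                       perseverance_mode = c("shared", "recipient", "absent"),
                       omega_mode = c("shared", "recipient")) {
  spec <- structure(list(
    name = as.character(name),
    learning_rate_mode = match.arg(learning_rate_mode),
    beta_mode = match.arg(beta_mode),
    lambda_mode = match.arg(lambda_mode),
    perseverance_mode = match.arg(perseverance_mode),
    omega_mode = match.arg(omega_mode)
  ), class = "model_spec")
  spec$param_names <- c(
    switch(spec$learning_rate_mode, single = "alpha",
           valence = c("alpha_pain", "alpha_nopain")),
    switch(spec$beta_mode, single = "beta", stage = c("beta1", "beta2")),
    switch(spec$lambda_mode, free = "lambda", fixed1 = NULL),
    switch(spec$perseverance_mode, shared = "rho",
           recipient = c("rho_self", "rho_other"), absent = NULL),
    switch(spec$omega_mode, shared = "omega",
           recipient = c("omega_self", "omega_other"))
  )
  spec$n_params <- length(spec$param_names)
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Hybrid learner model '%s' (%d free parameters)\n",
              x$name, x$n_params))
  cat("  parameters:", paste(x$param_names, collapse = ", "), "\n")
  invisible(x)
}

#' Registry of the model family
#'
#' The four variants compared in the analysis:
#' * `daw7` — full seven-parameter hybrid model: valence-split learning
#'   rates, stage-split inverse temperatures, free eligibility weight
#'   lambda, shared perseverance and shared model-based weight;
#' * `win5` — five-parameter reduction (`alpha_pain`, `alpha_nopain`,
#'   `beta`, `rho`, `omega`; lambda fixed at 1);
#' * `win6_omega_split` — as `win5` with the model-based weight split by
#'   recipient (`omega_self`, `omega_other`);
#' * `split7_rho_omega` — as `win5` with both perseverance and the
#'   model-based weight split by recipient.
#'
#' @return Named list of [model_spec()] objects.
#' @export
model_registry <- function() {
  list(
    daw7 = model_spec("daw7", "valence", "stage", "free", "shared", "shared"),
    win5 = model_spec("win5", "valence", "single", "fixed1", "shared", "shared"),
    win6_omega_split = model_spec("win6_omega_split", "valence", "single",
                                  "fixed1", "shared", "recipient"),
    split7_rho_omega = model_spec("split7_rho_omega", "valence", "single",
                                  "fixed1", "recipient", "recipient")
  )
}

#' Look up a model variant by name
#'
#' @param name One of the names in [model_registry()], or a `model_spec`
#'   (returned unchanged).
#' @return A `model_spec`.
#' @export
get_model_spec <- function(name) {
  if (inherits(name, "model_spec")) return(name)
  reg <- model_registry()
  if (!name %in% names(reg))
    stop(sprintf("unknown model '%s'; available: %s", name,
                 paste(names(reg), collapse = ", ")))
  reg[[name]]
}

# Natural-space range check for a named parameter vector under a spec.
check_params <- function(params, spec) {
  missing <- setdiff(spec$param_names, names(params))
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "))
  params <- params[spec$param_names]
  unit <- grepl("^(alpha|omega)", names(params))
  pos <- grepl("^(beta|lambda)", names(params))
  if (any(!is.finite(unlist(params))))
    stop("parameters must be finite")
  p <- unlist(params)
  if (any(p[unit] <= 0 | p[unit] >= 1))
    stop("learning rates and omega must lie strictly in (0, 1)")
  if (any(p[pos] <= 0))
    stop("beta and lambda must be strictly positive")
  p
}

# Precompute the map from a spec's parameter vector to the canonical
# 9-slot engine encoding: for each slot, either the index of the source
# parameter or a constant (lambda fixed at 1, absent rho = 0).
param_expander <- function(spec) {
  src <- c(
    alpha_pain = if (spec$learning_rate_mode == "single") "alpha" else "alpha_pain",
    alpha_nopain = if (spec$learning_rate_mode == "single") "alpha" else "alpha_nopain",
    beta1 = if (spec$beta_mode == "single") "beta" else "beta1",
    beta2 = if (spec$beta_mode == "single") "beta" else "beta2",
    lambda = if (spec$lambda_mode == "fixed1") NA else "lambda",
    rho_self = switch(spec$perseverance_mode, absent = NA, shared = "rho",
                      recipient = "rho_self"),
    rho_other = switch(spec$perseverance_mode, absent = NA, shared = "rho",
                       recipient = "rho_other"),
    omega_self = if (spec$omega_mode == "shared") "omega" else "omega_self",
    omega_other = if (spec$omega_mode == "shared") "omega" else "omega_other")
  idx <- match(src, spec$param_names)
  const <- c(alpha_pain = NA, alpha_nopain = NA, beta1 = NA, beta2 = NA,
             lambda = 1, rho_self = 0, rho_other = 0,
             omega_self = NA, omega_other = NA)
  list(idx = idx, const = const, sel = !is.na(idx))
}

# Expand a spec-level parameter vector to the canonical 9-slot vector used
# by the likelihood engines:
# (alpha_pain, alpha_nopain, beta1, beta2, lambda, rho_self, rho_other,
#  omega_self, omega_other)
expand_params <- function(params, spec) {
  p <- params
  g <- function(nm, default = NA_real_) {
    if (nm %in% names(p)) unname(p[[nm]]) else default
  }
  ap <- if (spec$learning_rate_mode == "single") g("alpha") else g("alpha_pain")
  an <- if (spec$learning_rate_mode == "single") g("alpha") else g("alpha_nopain")
  b1 <- if (spec$beta_mode == "single") g("beta") else g("beta1")
  b2 <- if (spec$beta_mode == "single") g("beta") else g("beta2")
  lam <- if (spec$lambda_mode == "fixed1") 1 else g("lambda")
  rs <- switch(spec$perseverance_mode,
               absent = 0, shared = g("rho"), recipient = g("rho_self"))
  ro <- switch(spec$perseverance_mode,
               absent = 0, shared = g("rho"), recipient = g("rho_other"))
  os <- if (spec$omega_mode == "shared") g("omega") else g("omega_self")
  oo <- if (spec$omega_mode == "shared") g("omega") else g("omega_other")
  c(alpha_pain = ap, alpha_nopain = an, beta1 = b1, beta2 = b2,
    lambda = lam, rho_self = rs, rho_other = ro,
    omega_self = os, omega_other = oo)
}
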