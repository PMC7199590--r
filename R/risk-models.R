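#' Base and RDW-enhanced logistic mortality models
#'
#' The base model regresses a mortality outcome (ICU, in-hospital or
#' 90-day) on age, sex, comorbidity-count category (dummy-coded, reference
#' "0 conditions"), SOFA score, and first documented PaO2/FiO2.  The
#' enhanced model adds the RDW value closest to the time of ARDS diagnosis.
#'
#' @name risk-models
NULL

OUTCOME_COLUMNS <- c(icu = "icu_death", hospital = "hosp_death",
                     day90 = "death_90d")

#' Specify a mortality model
#'
#' @param outcome `"icu"`, `"hospital"`, or `"day90"`.
#' @param include_rdw Logical; `TRUE` gives the enhanced model (base
#'   covariates plus baseline RDW).
#' @param covariates Optional ordered subset of the design terms (`age`,
#'   `male`, `comorbidity1`, `comorbidity2`, `comorbidity3plus`, `sofa`,
#'   `pf_ratio`); defaults to the full base model.  `include_rdw = TRUE`
#'   appends `rdw_baseline`.
#' @return An object of class `rdw_model_spec`.
#' @export
model_spec <- function(outcome = c("icu", "hospital", "day90"),
                       include_rdw = FALSE, covariates = NULL) {
  outcome <- match.arg(outcome)
  if (!is_flag(include_rdw)) stop_config("include_rdw must be TRUE or FALSE")
  terms <- covariates %||% setdiff(DESIGN_TERMS, "rdw_baseline")
  if (!all(terms %in% DESIGN_TERMS))
    stop_config("unknown covariate term(s): %s",
                paste(setdiff(terms, DESIGN_TERMS), collapse = ", "))
  if (include_rdw) terms <- union(terms, "rdw_baseline")
  else terms <- setdiff(terms, "rdw_baseline")
  structure(list(outcome = outcome, outcome_column = OUTCOME_COLUMNS[[outcome]],
                 terms = terms, include_rdw = include_rdw),
            class = "rdw_model_spec")
}

TERM_SOURCE <- c(age = "age", male = "sex", comorbidity1 = "comorbidity_category",
                 comorbidity2 = "comorbidity_category",
                 comorbidity3plus = "comorbidity_category", sofa = "sofa",
                 pf_ratio = "pf_ratio", rdw_baseline = "rdw_baseline")

# Design matrix with intercept for a spec; errors name any missing column.
spec_design <- function(cohort, spec) {
  needed <- unique(unname(TERM_SOURCE[spec$terms]))
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols) > 0L)
    stop_schema("cohort is missing covariate column(s): %s",
                paste(missing_cols, collapse = ", "))
  X <- covariate_design(cohort, spec$terms)
  cbind("(Intercept)" = 1, X)
}

#' Fit a logistic mortality model by maximum likelihood
#'
#' Fitting is iteratively reweighted least squares (via [stats::glm()] with
#' a binomial family), converged when the relative deviance change falls
#' below 1e-8, capped at 50 iterations (the fit is then flagged
#' unconverged rather than silently reported).
#'
#' @param cohort A validated cohort data frame.
#' @param spec An `rdw_model_spec`.
#' @return An object of class `rdw_logit` with elements `coefficients`,
#'   `covariance` (inverse Fisher information), `converged`, `n_used`,
#'   `deviance`, and the `spec`.
#' @export
fit_logistic <- function(cohort, spec) {
  if (!inherits(spec, "rdw_model_spec")) stop_config("spec must be an rdw_model_spec")
  cohort <- validate_cohort(cohort)
  y <- cohort[[spec$outcome_column]]
  if (length(y) == 0L) stop_degenerate("cannot fit a model on an empty cohort")
  if (all(y) || all(!y))
    stop_degenerate("outcome %s is constant (%d events in %d patients)",
                    spec$outcome_column, sum(y), length(y))
  X <- spec_design(cohort, spec)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop_degenerate("design matrix is rank deficient; collinear column(s): %s",
                    paste(aliased, collapse = ", "))
  }
  dat <- data.frame(..y = as.numeric(y), X[, -1L, drop = FALSE],
                    check.names = FALSE)
  fit <- glm(..y ~ ., family = binomial(), data = dat,
             control = glm.control(epsilon = 1e-8, maxit = 50))
  structure(list(coefficients = coef(fit),
                 covariance = vcov(fit),
                 converged = isTRUE(fit$converged),
                 n_used = length(y),
                 n_events = sum(y),
                 deviance = fit$deviance,
                 spec = spec),
            class = "rdw_logit")
}

#' Odds ratios with Wald 95\% confidence intervals
#'
#' @param model A converged `rdw_logit` fit.
#' @return A data frame with columns `term`, `or`, `ci_lower`, `ci_upper`
#'   (the intercept is excluded).
#' @export
odds_ratios <- function(model) {
  if (!inherits(model, "rdw_logit")) stop_config("model must be an rdw_logit fit")
  if (!model$converged)
    stop_degenerate("model did not converge; odds ratios are not reported")
  keep <- setdiff(names(model$coefficients), "(Intercept)")
  est <- model$coefficients[keep]
  se <- sqrt(diag(model$covariance)[keep])
  data.frame(term = keep,
             or = exp(est),
             ci_lower = exp(est - 1.96 * se),
             ci_upper = exp(est + 1.96 * se),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Predicted event probabilities
#'
#' @param model An `rdw_logit` fit.
#' @param cohort A cohort data frame carrying the covariates the model
#'   spec requires.
#' @return A numeric vector of probabilities, strictly inside (0, 1), one
#'   per cohort row.
#' @export
predict_probability <- function(model, cohort) {
  if (!inherits(model, "rdw_logit")) stop_config("model must be an rdw_logit fit")
  X <- spec_design(cohort, model$spec)
  clamp_prob(plogis(drop(X %*% model$coefficients[colnames(X)])))
}

#' @export
print.rdw_logit <- function(x, ...) {
  cat(sprintf("Logistic model for %s mortality (%s)\n", x$spec$outcome,
              if (x$spec$include_rdw) "base + RDW" else "base"))
  cat(sprintf("  n = %d, events = %d, deviance = %.2f, converged = %s\n",
              x$n_used, x$n_events, x$deviance, x$converged))
  if (x$converged) {
    or <- odds_ratios(x)
    cat(sprintf("  %-18s OR %5.2f (%.2f, %.2f)\n", or$term, or$or,
                or$ci_lower, or$ci_upper), sep = "")
  }
  invisible(x)
}
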