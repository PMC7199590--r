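#' Incremental value of an added biomarker: AUC, NRI, IDI
#'
#' Quantifies what baseline RDW adds to the clinical base model: the paired
#' difference in ROC area with a DeLong placement-value variance, the
#' category-free (continuous) net reclassification improvement, and the
#' integrated discrimination improvement, each with a 95\% confidence
#' interval and two-sided p-value.
#'
#' @name model-comparison
NULL

check_labels <- function(labels) {
  if (is.numeric(labels)) {
    if (any(!labels %in% c(0, 1)))
      stop_validation("labels must be logical or 0/1")
    labels <- labels == 1
  }
  if (!is.logical(labels) || anyNA(labels))
    stop_validation("labels must be logical or 0/1 without missing values")
  if (!any(labels) || all(labels))
    stop_degenerate("labels are single-class (%d events of %d); discrimination is undefined",
                    sum(labels), length(labels))
  labels
}

check_paired <- function(p_base, p_new, labels) {
  if (length(p_base) != length(labels) || length(p_new) != length(labels))
    stop_validation("p_base, p_new and labels must pair the same patients (lengths %d, %d, %d)",
                    length(p_base), length(p_new), length(labels))
  if (anyNA(p_base) || anyNA(p_new))
    stop_validation("predicted probabilities must not be missing")
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' The probability that a randomly chosen event patient is scored higher
#' than a randomly chosen non-event patient, counting ties as 1/2;
#' computed via midranks, which is exactly the mean over all
#' event x non-event pairs.
#'
#' @param scores Numeric risk scores, one per patient.
#' @param labels Event indicators (logical or 0/1); at least one event and
#'   one non-event.
#' @return The AUC, a scalar in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- check_labels(labels)
  if (length(scores) != length(labels))
    stop_validation("scores and labels must have equal length")
  if (anyNA(scores)) stop_validation("scores must not be missing")
  n1 <- sum(labels); n0 <- sum(!labels)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement values: V10[i] = P-hat(score of event i > non-event),
# V01[j] = P-hat(event > score of non-event j), ties counted 1/2.
placement_values <- function(scores, labels) {
  n1 <- sum(labels); n0 <- sum(!labels)
  r <- rank(scores)
  V10 <- (r[labels] - rank(scores[labels])) / n0
  V01 <- 1 - (r[!labels] - rank(scores[!labels])) / n1
  list(V10 = V10, V01 = V01)
}

#' Paired AUC comparison by the DeLong method
#'
#' Tests the difference between the ROC areas of two risk scores evaluated
#' on the same patients, using the nonparametric structural-components
#' (placement-value) estimate of the variance of the paired difference:
#' `var(delta) = var(V10_new - V10_base)/n_events +
#' var(V01_new - V01_base)/n_nonevents`.
#'
#' @param p_base,p_new Predicted risks from the two models, same patients
#'   in the same order.
#' @param labels Event indicators; at least two events and two non-events.
#' @return A list of class `rdw_delong`: `auc_base`, `auc_new`, `delta`,
#'   `se`, `ci` (95\%), `p_value`, `n_events`, `n_nonevents`.
#' @details When the two score vectors are identical the variance estimate
#'   collapses to zero; the difference is then reported as 0 with p = 1.
#' @export
delong_compare <- function(p_base, p_new, labels) {
  labels <- check_labels(labels)
  check_paired(p_base, p_new, labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 < 2L || n0 < 2L)
    stop_degenerate("DeLong comparison needs >= 2 events and >= 2 non-events")
  pb <- placement_values(p_base, labels)
  pn <- placement_values(p_new, labels)
  auc_base <- mean(pb$V10); auc_new <- mean(pn$V10)
  delta <- auc_new - auc_base
  v <- var(pn$V10 - pb$V10) / n1 + var(pn$V01 - pb$V01) / n0
  se <- sqrt(max(v, 0))
  if (se == 0) {
    p <- if (abs(delta) < 1e-15) 1 else 0
    ci <- c(delta, delta)
  } else {
    z <- delta / se
    p <- 2 * pnorm(-abs(z))
    ci <- delta + c(-1.96, 1.96) * se
  }
  structure(list(auc_base = auc_base, auc_new = auc_new, delta = delta,
                 se = se, ci = ci, p_value = p,
                 n_events = n1, n_nonevents = n0),
            class = "rdw_delong")
}

#' Continuous (category-free) net reclassification improvement
#'
#' The net proportion of events whose predicted risk rises under the new
#' model plus the net proportion of non-events whose predicted risk falls:
#' `NRI = [P(up|event) - P(down|event)] + [P(down|nonevent) - P(up|nonevent)]`.
#' Exact ties move in neither direction.  The asymptotic standard error is
#' `sqrt(v_e/n_e + v_ne/n_ne)` with
#' `v = p_up + p_down - (p_up - p_down)^2` within each outcome group.
#'
#' @param p_base,p_new Predicted risks from the two models, paired.
#' @param labels Event indicators.
#' @param variant `"net"` (default; both directions counted within each
#'   group) or `"gross"` (sum of the raw proportion of events moving up and
#'   non-events moving down, with the same SE; provided for comparison with
#'   the one-directional verbal definition sometimes quoted).
#' @param ci_method `"asymptotic"` or `"bootstrap"` (stratified percentile
#'   bootstrap of patients within outcome groups).
#' @param n_boot,seed Bootstrap replicates and seed (bootstrap method only).
#' @return A list of class `rdw_nri`: `nri`, `event_component`,
#'   `nonevent_component`, `se`, `ci`, `p_value`, counts.
#' @export
continuous_nri <- function(p_base, p_new, labels, variant = c("net", "gross"),
                           ci_method = c("asymptotic", "bootstrap"),
                           n_boot = 2000, seed = 1) {
  variant <- match.arg(variant)
  ci_method <- match.arg(ci_method)
  labels <- check_labels(labels)
  check_paired(p_base, p_new, labels)
  d <- p_new - p_base
  comp <- function(di, direction) {
    up <- mean(di > 0); down <- mean(di < 0)
    est <- if (direction > 0) up - down else down - up
    if (variant == "gross") est <- if (direction > 0) up else down
    v <- up + down - (up - down)^2
    c(est = est, v = v)
  }
  point <- function(d, labels) {
    ev <- comp(d[labels], +1); ne <- comp(d[!labels], -1)
    c(event = unname(ev["est"]), nonevent = unname(ne["est"]),
      v_e = unname(ev["v"]), v_ne = unname(ne["v"]))
  }
  n1 <- sum(labels); n0 <- sum(!labels)
  pt <- point(d, labels)
  total <- pt[["event"]] + pt[["nonevent"]]
  se <- sqrt(pt[["v_e"]] / n1 + pt[["v_ne"]] / n0)
  if (ci_method == "asymptotic") {
    ci <- total + c(-1.96, 1.96) * se
    p <- if (se == 0) (if (abs(total) < 1e-15) 1 else 0) else 2 * pnorm(-abs(total / se))
  } else {
    boots <- boot_stratified(d, labels, n_boot, seed, function(db, lb) {
      pb <- point(db, lb); pb[["event"]] + pb[["nonevent"]]
    })
    ci <- unname(quantile(boots, c(0.025, 0.975), type = 7))
    bse <- sd(boots)
    p <- if (bse == 0) (if (abs(total) < 1e-15) 1 else 0) else 2 * pnorm(-abs(total / bse))
    se <- bse
  }
  structure(list(nri = total, event_component = pt[["event"]],
                 nonevent_component = pt[["nonevent"]],
                 se = se, ci = ci, p_value = p, variant = variant,
                 n_events = n1, n_nonevents = n0),
            class = "rdw_nri")
}

#' Integrated discrimination improvement
#'
#' The increase in mean predicted risk among events minus the increase
#' among non-events when moving from the base to the new model.  The group
#' mean predictions under both models are reported alongside the total.
#'
#' @inheritParams continuous_nri
#' @return A list of class `rdw_idi`: `idi`, `mean_base_events`,
#'   `mean_new_events`, `mean_base_nonevents`, `mean_new_nonevents`, `se`,
#'   `ci`, `p_value`, counts.
#' @export
idi <- function(p_base, p_new, labels,
                ci_method = c("asymptotic", "bootstrap"),
                n_boot = 2000, seed = 1) {
  ci_method <- match.arg(ci_method)
  labels <- check_labels(labels)
  check_paired(p_base, p_new, labels)
  d <- p_new - p_base
  n1 <- sum(labels); n0 <- sum(!labels)
  est <- mean(d[labels]) - mean(d[!labels])
  se <- sqrt(var(d[labels]) / n1 + var(d[!labels]) / n0)
  if (ci_method == "asymptotic") {
    ci <- est + c(-1.96, 1.96) * se
    p <- if (is.na(se) || se == 0) (if (abs(est) < 1e-15) 1 else 0) else 2 * pnorm(-abs(est / se))
  } else {
    boots <- boot_stratified(d, labels, n_boot, seed,
                             function(db, lb) mean(db[lb]) - mean(db[!lb]))
    ci <- unname(quantile(boots, c(0.025, 0.975), type = 7))
    se <- sd(boots)
    p <- if (se == 0) (if (abs(est) < 1e-15) 1 else 0) else 2 * pnorm(-abs(est / se))
  }
  structure(list(idi = est,
                 mean_base_events = mean(p_base[labels]),
                 mean_new_events = mean(p_new[labels]),
                 mean_base_nonevents = mean(p_base[!labels]),
                 mean_new_nonevents = mean(p_new[!labels]),
                 se = se, ci = ci, p_value = p,
                 n_events = n1, n_nonevents = n0),
            class = "rdw_idi")
}

# Stratified (within events and non-events) percentile bootstrap over the
# per-patient risk differences.
boot_stratified <- function(d, labels, n_boot, seed, statistic) {
  ie <- which(labels); ine <- which(!labels)
  set.seed(seed)
  vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(ie, length(ie), replace = TRUE),
             sample(ine, length(ine), replace = TRUE))
    statistic(d[idx], labels[idx])
  }, numeric(1))
}

#' Compare base and RDW-enhanced models on one outcome
#'
#' Fits both nested logistic models on the cohort, computes in-sample
#' (apparent) predicted probabilities, and evaluates the paired AUC
#' difference, continuous NRI, and IDI, mirroring the reporting layout of
#' incremental-biomarker studies.
#'
#' @param cohort A validated cohort data frame.
#' @param outcome `"icu"`, `"hospital"`, or `"day90"`.
#' @param ci_method `"asymptotic"` or `"bootstrap"` for NRI and IDI.
#' @param n_boot,seed Bootstrap settings when `ci_method = "bootstrap"`.
#' @return An object of class `rdw_comparison` bundling the two fitted
#'   models, the AUCs, and the three comparison metrics.
#' @export
compare_models <- function(cohort, outcome = c("icu", "hospital", "day90"),
                           ci_method = c("asymptotic", "bootstrap"),
                           n_boot = 2000, seed = 1) {
  outcome <- match.arg(outcome)
  ci_method <- match.arg(ci_method)
  cohort <- validate_cohort(cohort)
  fit_base <- fit_logistic(cohort, model_spec(outcome, include_rdw = FALSE))
  fit_new <- fit_logistic(cohort, model_spec(outcome, include_rdw = TRUE))
  labels <- cohort[[OUTCOME_COLUMNS[[outcome]]]]
  p_base <- predict_probability(fit_base, cohort)
  p_new <- predict_probability(fit_new, cohort)
  structure(list(outcome = outcome,
                 fit_base = fit_base, fit_new = fit_new,
                 delong = delong_compare(p_base, p_new, labels),
                 nri = continuous_nri(p_base, p_new, labels,
                                      ci_method = ci_method,
                                      n_boot = n_boot, seed = seed),
                 idi = idi(p_base, p_new, labels, ci_method = ci_method,
                           n_boot = n_boot, seed = seed),
                 n_events = sum(labels), n_nonevents = sum(!labels)),
            class = "rdw_comparison")
}

#' @export
print.rdw_comparison <- function(x, ...) {
  d <- x$delong
  cat(sprintf("Added value of RDW for %s mortality (n = %d, events = %d)\n",
              x$outcome, x$n_events + x$n_nonevents, x$n_events))
  cat(sprintf("  AUC  base %.3f  +RDW %.3f  delta %.3f (%.3f, %.3f)  p = %.3g\n",
              d$auc_base, d$auc_new, d$delta, d$ci[1], d$ci[2], d$p_value))
  cat(sprintf("  NRI  %.3f (%.3f, %.3f)  p = %.3g  [events %+.3f, non-events %+.3f]\n",
              x$nri$nri, x$nri$ci[1], x$nri$ci[2], x$nri$p_value,
              x$nri$event_component, x$nri$nonevent_component))
  cat(sprintf("  IDI  %.3f (%.3f, %.3f)  p = %.3g\n",
              x$idi$idi, x$idi$ci[1], x$idi$ci[2], x$idi$p_value))
  invisible(x)
}
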