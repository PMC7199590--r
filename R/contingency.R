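#' Contingency-table association tests
#'
#' Chi-square and Fisher exact tests for the association between RDW
#' trajectory class and mortality: Pearson chi-square without continuity
#' correction, the exact 2x2 Fisher test under the point-probability
#' two-sided rule, and exact or Monte-Carlo conditional tests for larger
#' tables.
#'
#' @name contingency
NULL

as_contingency <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x != round(x)))
    stop_validation("contingency table must contain non-negative integer counts")
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop_validation("contingency table must be at least 2 x 2")
  if (sum(x) == 0) stop_validation("contingency table must have a positive total")
  x
}

check_margins <- function(x) {
  if (any(rowSums(x) == 0) || any(colSums(x) == 0))
    stop_degenerate("degenerate table: a row or column margin is zero")
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Uncorrected Pearson statistic `sum((O - E)^2 / E)` with expected counts
#' from the margins and `(R-1)(C-1)` degrees of freedom.
#'
#' @param table An R x C matrix of non-negative integer counts.
#' @return A list: `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_test <- function(table) {
  x <- as_contingency(table)
  check_margins(x)
  ct <- suppressWarnings(chisq.test(x, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, expected = ct$expected)
}

#' Fisher exact test for a 2 x 2 table
#'
#' Conditions on both margins; the two-sided p-value is the sum of
#' hypergeometric point probabilities not exceeding that of the observed
#' table (point-probability rule, with a 1e-7 relative tolerance against
#' floating-point ties).
#'
#' @param table A 2 x 2 matrix of non-negative integer counts.
#' @return A list: `p_value`, `point_prob` (probability of the observed
#'   table), `degenerate` (TRUE when a zero margin forces p = 1).
#' @export
fisher_exact_2x2 <- function(table) {
  x <- as_contingency(table)
  if (nrow(x) != 2L || ncol(x) != 2L)
    stop_validation("fisher_exact_2x2 needs a 2 x 2 table")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    warning("degenerate margin: only one table is consistent with the margins; p = 1",
            call. = FALSE)
    return(list(p_value = 1, point_prob = 1, degenerate = TRUE))
  }
  m <- sum(x[, 1]); nn <- sum(x[, 2]); k <- sum(x[1, ])
  support <- max(0L, k - nn):min(k, m)
  probs <- dhyper(support, m, nn, k)
  p_obs <- dhyper(x[1, 1], m, nn, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p_value = min(p, 1), point_prob = p_obs, degenerate = FALSE)
}

# log multivariate hypergeometric probability of a table given its margins
log_table_prob <- function(x) {
  sum(lgamma(rowSums(x) + 1)) + sum(lgamma(colSums(x) + 1)) -
    lgamma(sum(x) + 1) - sum(lgamma(x + 1))
}

# crude upper bound on the number of same-margin tables (product over the
# free (R-1) x (C-1) cells of each cell's own range)
table_count_bound <- function(x) {
  r <- rowSums(x); cc <- colSums(x)
  prod(outer(r[-length(r)], cc[-length(cc)], function(a, b) pmin(a, b) + 1))
}

#' Fisher exact test for an R x C table
#'
#' Exact conditional p-value (sum of probabilities of all same-margin
#' tables no more probable than the observed one), or a seeded Monte-Carlo
#' estimate drawing same-margin tables uniformly by Patefield's algorithm
#' (`1 + #{sampled tables at or below the observed probability}` over
#' `n_mc + 1`).
#'
#' @param table An R x C matrix of non-negative integer counts.
#' @param method `"exact"` or `"monte_carlo"`.
#' @param n_mc Number of Monte-Carlo tables (default 100,000).
#' @param seed Seed for the Monte-Carlo draw.
#' @param max_tables Enumeration bound for the exact method; tables whose
#'   same-margin family exceeds it raise an error directing the caller to
#'   the Monte-Carlo method.
#' @return A list: `p_value`, `method`, and for Monte-Carlo `n_mc` and the
#'   standard error `mc_se`.
#' @export
fisher_exact_rxc <- function(table, method = c("exact", "monte_carlo"),
                             n_mc = 1e5, seed = 1, max_tables = 1e7) {
  method <- match.arg(method)
  x <- as_contingency(table)
  check_margins(x)
  if (method == "exact") {
    if (nrow(x) == 2L && ncol(x) == 2L)
      return(list(p_value = fisher_exact_2x2(x)$p_value, method = "exact"))
    if (table_count_bound(x) > max_tables)
      stop_config(paste("same-margin family may exceed %g tables;",
                        "use method = 'monte_carlo'"), max_tables)
    list(p_value = fisher.test(x, workspace = 2e7)$p.value, method = "exact")
  } else {
    set.seed(seed)
    lp_obs <- log_table_prob(x)
    tables <- r2dtable(n_mc, rowSums(x), colSums(x))
    lp <- vapply(tables, log_table_prob, numeric(1))
    hits <- sum(lp <= lp_obs + 1e-7)
    p <- (1 + hits) / (n_mc + 1)
    list(p_value = p, method = "monte_carlo", n_mc = n_mc,
         mc_se = sqrt(p * (1 - p) / n_mc))
  }
}

#' Cross-tabulate trajectory class against mortality
#'
#' Joins a per-patient trajectory classification to a cohort's outcome and
#' builds the class x (died, survived) count table, plus the combined
#' late-direction 2 x 2 table (late-upward = uptrending + convex vs
#' late-downward = downtrending + concave).
#'
#' @param trajectories An `rdw_trajectories` object (or its
#'   `classification` data frame).
#' @param cohort A validated cohort data frame.
#' @param outcome Which mortality flag to tabulate (default in-hospital).
#' @return A list with `class_table` (5 x 2) and `late_table` (2 x 2).
#' @export
trajectory_mortality_table <- function(trajectories, cohort,
                                       outcome = c("hospital", "icu", "day90")) {
  outcome <- match.arg(outcome)
  cls <- if (inherits(trajectories, "rdw_trajectories"))
    trajectories$classification else trajectories
  cohort <- validate_cohort(cohort)
  idx <- match(cls$patient_id, cohort$patient_id)
  if (anyNA(idx))
    stop_validation("classified patient '%s' is absent from the cohort",
                    cls$patient_id[which(is.na(idx))[1L]])
  died <- cohort[[OUTCOME_COLUMNS[[outcome]]]][idx]
  keep <- cls$class != "excluded"
  klass <- factor(cls$class[keep], levels = TRAJECTORY_CLASSES)
  died <- died[keep]
  class_table <- cbind(died = tapply(died, klass, sum, default = 0L),
                       survived = tapply(!died, klass, sum, default = 0L))
  late <- LATE_DIRECTION[as.character(klass)]
  keep2 <- late != "not_applicable"
  late_table <- rbind(
    late_up = c(died = sum(died[keep2 & late == "late_up"]),
                survived = sum(!died[keep2 & late == "late_up"])),
    late_down = c(died = sum(died[keep2 & late == "late_down"]),
                  survived = sum(!died[keep2 & late == "late_down"])))
  list(class_table = class_table, late_table = late_table)
}
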