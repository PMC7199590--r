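#' End-to-end analysis pipeline and report
#'
#' Orchestrates simulate (or load) -> baseline description -> model fits ->
#' added-value comparison -> trajectory classification -> association
#' tests, and writes a machine-readable JSON report plus an aligned text
#' report.
#'
#' @name pipeline
NULL

#' Baseline characteristics split by ICU survival
#'
#' Means (SD) of age, baseline RDW, PaO2/FiO2 and SOFA, and counts
#' (percent) of sex and comorbidity categories, for ICU survivors,
#' non-survivors, and all patients.
#'
#' @param cohort A validated cohort data frame.
#' @return A data frame with one row per characteristic and columns for the
#'   three groups; single-patient groups report `NA` SDs.
#' @export
baseline_table <- function(cohort) {
  cohort <- validate_cohort(cohort)
  if (nrow(cohort) == 0L) stop_degenerate("baseline table needs a non-empty cohort")
  groups <- list(survivors = cohort[!cohort$icu_death, , drop = FALSE],
                 nonsurvivors = cohort[cohort$icu_death, , drop = FALSE],
                 all = cohort)
  mean_sd <- function(x) {
    if (length(x) == 0L) return("-")
    if (length(x) == 1L) return(sprintf("%.1f (NA)", x))
    sprintf("%.1f (%.1f)", mean(x), sd(x))
  }
  n_pct <- function(flag, n) {
    if (n == 0L) return("-")
    sprintf("%d (%.1f)", sum(flag), 100 * sum(flag) / n)
  }
  rows <- list(
    c("n", vapply(groups, nrow, integer(1))),
    c("Age (years), mean (SD)", vapply(groups, function(g) mean_sd(g$age), "")),
    c("Males, n (%)", vapply(groups, function(g) n_pct(g$sex == "male", nrow(g)), "")),
    c("Females, n (%)", vapply(groups, function(g) n_pct(g$sex == "female", nrow(g)), "")),
    c("RDW, mean (SD)", vapply(groups, function(g) mean_sd(g$rdw_baseline), "")),
    c("PaO2/FiO2 ratio, mean (SD)", vapply(groups, function(g) mean_sd(g$pf_ratio), "")),
    c("SOFA score, mean (SD)", vapply(groups, function(g) mean_sd(g$sofa), "")))
  for (lev in COMORBIDITY_LEVELS)
    rows[[length(rows) + 1L]] <-
      c(sprintf("Comorbid conditions %s, n (%%)", sub("3plus", ">=3", lev)),
        vapply(groups, function(g)
          n_pct(g$comorbidity_category == lev, nrow(g)), ""))
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("characteristic", "survivors", "nonsurvivors", "all")
  out
}

or_table_for <- function(cohort, outcome) {
  base <- odds_ratios(fit_logistic(cohort, model_spec(outcome, FALSE)))
  enh <- odds_ratios(fit_logistic(cohort, model_spec(outcome, TRUE)))
  list(base = base, enhanced = enh)
}

comparison_entry <- function(cmp) {
  list(auc = list(base = cmp$delong$auc_base, enhanced = cmp$delong$auc_new,
                  delta = cmp$delong$delta, ci = cmp$delong$ci,
                  p_value = cmp$delong$p_value),
       nri = list(total = cmp$nri$nri, event_component = cmp$nri$event_component,
                  nonevent_component = cmp$nri$nonevent_component,
                  ci = cmp$nri$ci, p_value = cmp$nri$p_value),
       idi = list(total = cmp$idi$idi,
                  mean_base_events = cmp$idi$mean_base_events,
                  mean_new_events = cmp$idi$mean_new_events,
                  mean_base_nonevents = cmp$idi$mean_base_nonevents,
                  mean_new_nonevents = cmp$idi$mean_new_nonevents,
                  ci = cmp$idi$ci, p_value = cmp$idi$p_value),
       n_events = cmp$n_events, n_nonevents = cmp$n_nonevents)
}

#' Run the full analysis pipeline
#'
#' In simulate mode, generates a synthetic cohort from a configuration
#' (path to YAML/JSON or an `rdw_config` list) and analyses it; in user
#' mode, reads a patient-level cohort CSV and a long RDW CSV.  Stages:
#' baseline table, base/enhanced odds-ratio tables and added-value
#' comparison for the three mortality outcomes, trajectory classification,
#' and trajectory-mortality association tests (chi-square and Fisher on
#' the 5 x 2 class table; chi-square and exact Fisher on the combined
#' late-direction 2 x 2).
#'
#' @param config Configuration list or path (simulate mode); ignored in
#'   user mode except for `seed`.
#' @param mode `"simulate"` or `"user"`.
#' @param cohort_csv,rdw_csv Input paths (user mode).
#' @param out_dir Output directory; created if missing.  Receives
#'   `report.json`, `report.txt`, and in simulate mode the generated
#'   `cohort.csv`, `rdw_long.csv` and `provenance.json`.
#' @param seed Optional override of the configured seed.
#' @param quiet Suppress per-stage progress messages.
#' @return The report bundle (list of class `rdw_report`), invisibly
#'   written to disk.
#' @export
run_pipeline <- function(config = default_config(), mode = c("simulate", "user"),
                         cohort_csv = NULL, rdw_csv = NULL,
                         out_dir = NULL, seed = NULL, quiet = FALSE) {
  mode <- match.arg(mode)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    say("stage %-12s done (%.2f s)", name, proc.time()[["elapsed"]] - t0)
    out
  }

  if (mode == "simulate") {
    if (is.character(config)) config <- read_config(config)
    config <- validate_config(config)
    if (!is.null(seed)) config$seed <- seed
    sim <- stage("simulate", generate_cohort(config))
    cohort <- sim$cohort
    rdw_long <- sim$rdw_long
  } else {
    if (is.null(cohort_csv) || is.null(rdw_csv))
      stop_config("user mode requires cohort_csv and rdw_csv paths")
    cohort <- stage("load", read_cohort(cohort_csv))
    rdw_long <- read_rdw_long(rdw_csv)
    config <- NULL
  }

  baseline <- stage("baseline", baseline_table(cohort))
  outcomes <- c("icu", "hospital", "day90")
  ors <- stage("fit", lapply(setNames(outcomes, outcomes),
                             function(o) or_table_for(cohort, o)))
  comparisons <- stage("compare", lapply(setNames(outcomes, outcomes),
                                         function(o) comparison_entry(
                                           compare_models(cohort, o))))
  traj <- stage("trajectories", classify_cohort(rdw_long))
  assoc <- stage("assoc", {
    tabs <- trajectory_mortality_table(traj, cohort, outcome = "hospital")
    # empty trajectory classes are dropped before testing; tables that are
    # still degenerate (a zero margin) are reported untested rather than
    # aborting the run
    trimmed <- tabs$class_table[rowSums(tabs$class_table) > 0, , drop = FALSE]
    safe <- function(expr) tryCatch(expr, rdwards_degenerate_error = function(e)
      list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
           note = conditionMessage(e)),
      rdwards_validation_error = function(e)
        list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
             note = conditionMessage(e)))
    list(
      class_table = tabs$class_table,
      class_chi_square = safe(chi_square_test(trimmed)[c("statistic", "df", "p_value")]),
      class_fisher = safe(fisher_exact_rxc(trimmed, method = "exact",
                                           max_tables = 1e9)["p_value"]),
      late_table = tabs$late_table,
      late_chi_square = safe(chi_square_test(tabs$late_table)[c("statistic", "df", "p_value")]),
      late_fisher = suppressWarnings(fisher_exact_2x2(tabs$late_table)["p_value"]))
  })

  provenance <- list(
    package = "rdwards",
    version = as.character(packageVersion("rdwards")),
    mode = mode,
    seed = if (!is.null(config)) config$seed else seed,
    config = config)
  bundle <- structure(list(
    baseline = baseline, odds_ratios = ors, comparisons = comparisons,
    trajectories = list(counts = as.list(traj$counts),
                        n_excluded = traj$n_excluded,
                        n_patients = traj$n_patients,
                        classification = traj$classification),
    association = assoc, provenance = provenance),
    class = "rdw_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (mode == "simulate") {
      write_cohort(cohort, file.path(out_dir, "cohort.csv"))
      write_rdw_long(rdw_long, file.path(out_dir, "rdw_long.csv"))
      jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           null = "null")
    }
    json_bundle <- bundle
    json_bundle$trajectories$classification <- NULL  # per-patient CSV below
    jsonlite::write_json(unclass(json_bundle), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", dataframe = "rows", matrix = "rowmajor")
    write.csv(traj$classification,
              file.path(out_dir, "trajectory_classification.csv"),
              row.names = FALSE, quote = FALSE)
    writeLines(format_text_report(bundle), file.path(out_dir, "report.txt"))
  }
  invisible(bundle)
}

# Human-readable report at the precision conventional for these tables
# (AUC 3 dp, OR 2 dp, percentages 1 dp); the JSON carries full precision.
format_text_report <- function(bundle) {
  out <- character()
  add <- function(...) out <<- c(out, sprintf(...))
  add("rdwards analysis report  (generated %s)", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  add("package version %s, seed %s", bundle$provenance$version,
      format(bundle$provenance$seed %||% NA))
  add("")
  add("-- Baseline characteristics by ICU survival --")
  b <- bundle$baseline
  add("%-32s %14s %14s %14s", "", "survivors", "nonsurvivors", "all")
  for (i in seq_len(nrow(b)))
    add("%-32s %14s %14s %14s", b$characteristic[i], b$survivors[i],
        b$nonsurvivors[i], b$all[i])
  add("")
  add("-- Odds ratios (95%% CI) --")
  for (o in names(bundle$odds_ratios)) {
    add("%s mortality:", o)
    tabs <- bundle$odds_ratios[[o]]
    base <- tabs$base; enh <- tabs$enhanced
    for (i in seq_len(nrow(enh))) {
      term <- enh$term[i]
      j <- match(term, base$term)
      bs <- if (is.na(j)) sprintf("%22s", "-")
            else sprintf("%5.2f (%.2f, %.2f)", base$or[j], base$ci_lower[j],
                         base$ci_upper[j])
      add("  %-18s base %22s   +RDW %5.2f (%.2f, %.2f)", term, bs,
          enh$or[i], enh$ci_lower[i], enh$ci_upper[i])
    }
  }
  add("")
  add("-- Added value of RDW --")
  for (o in names(bundle$comparisons)) {
    cm <- bundle$comparisons[[o]]
    add("%s mortality (events %d / %d):", o, cm$n_events,
        cm$n_events + cm$n_nonevents)
    add("  AUC  base %.3f  +RDW %.3f  delta %.3f (%.3f, %.3f)  p = %.3g",
        cm$auc$base, cm$auc$enhanced, cm$auc$delta, cm$auc$ci[1], cm$auc$ci[2],
        cm$auc$p_value)
    add("  NRI  %.3f (%.3f, %.3f)  p = %.3g  [died %+.1f%%, survived %+.1f%%]",
        cm$nri$total, cm$nri$ci[1], cm$nri$ci[2], cm$nri$p_value,
        100 * cm$nri$event_component, 100 * cm$nri$nonevent_component)
    add("  IDI  %.3f (%.3f, %.3f)  p = %.3g",
        cm$idi$total, cm$idi$ci[1], cm$idi$ci[2], cm$idi$p_value)
  }
  add("")
  add("-- RDW trajectories --")
  tr <- bundle$trajectories
  add("%d patients, %d excluded (< 4 measurements)", tr$n_patients, tr$n_excluded)
  n_cl <- sum(unlist(tr$counts))
  for (k in names(tr$counts))
    add("  %-8s %4d (%.1f%%)", k, tr$counts[[k]],
        if (n_cl > 0) 100 * tr$counts[[k]] / n_cl else 0)
  a <- bundle$association
  add("class x in-hospital mortality: chi-square %.3f (df %d), p = %.3g; Fisher p = %.3g",
      a$class_chi_square$statistic, a$class_chi_square$df,
      a$class_chi_square$p_value, a$class_fisher$p_value)
  add("late-up vs late-down: chi-square p = %.3g; Fisher p = %.3g",
      a$late_chi_square$p_value, a$late_fisher$p_value)
  out
}
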