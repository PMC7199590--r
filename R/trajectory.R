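#' Longitudinal RDW trajectory classification
#'
#' Each patient with at least `min_obs` RDW measurements gets an ordinary
#' least-squares fit `rdw = b0 + b1 t + b2 t^2` over days since ARDS
#' diagnosis.  If the quadratic term is statistically significant the
#' trajectory is concave (`b2 < 0`) or convex (`b2 > 0`); otherwise, if the
#' linear term is significant, uptrending (`b1 > 0`) or downtrending
#' (`b1 < 0`); otherwise no trend.  Convex and uptrending series rise late
#' in the stay (`late_up`); concave and downtrending series fall late
#' (`late_down`).
#'
#' @name trajectory
NULL

LATE_DIRECTION <- c(concave = "late_down", down = "late_down",
                    none = "not_applicable",
                    convex = "late_up", up = "late_up")

#' Classify one patient's RDW trajectory
#'
#' @param series A data frame with columns `time_days` and `rdw` (an
#'   optional `patient_id` column labels the result), or an element of
#'   [rdw_series_split()].
#' @param alpha Two-sided significance level for the coefficient t-tests
#'   (default 0.05).
#' @param min_obs Minimum number of measurements required for
#'   classification (default 4); fewer yields class `"excluded"`.
#' @return A one-row data frame: `patient_id`, `n_obs`, `b0`, `b1`, `b2`,
#'   `p_linear`, `p_quadratic`, `class`, `late_direction`, and
#'   `degenerate_times` (TRUE when exclusion was due to fewer than three
#'   distinct measurement times, which leaves the quadratic unidentified).
#' @details With an exact (zero-residual) fit the t-tests are undefined; a
#'   coefficient then counts as significant iff its magnitude exceeds
#'   1e-10.
#' @export
classify_trajectory <- function(series, alpha = 0.05, min_obs = 4) {
  if (!is.data.frame(series) ||
      !all(c("time_days", "rdw") %in% names(series)))
    stop_schema("series must be a data frame with time_days and rdw columns")
  if (!is_scalar_num(alpha) || alpha <= 0 || alpha >= 1)
    stop_config("alpha must lie strictly in (0, 1)")
  pid <- if ("patient_id" %in% names(series))
    as.character(series$patient_id[1L]) else NA_character_
  t <- series$time_days
  y <- series$rdw
  n <- length(y)
  row <- data.frame(patient_id = pid, n_obs = n, b0 = NA_real_,
                    b1 = NA_real_, b2 = NA_real_, p_linear = NA_real_,
                    p_quadratic = NA_real_, class = "excluded",
                    late_direction = "not_applicable",
                    degenerate_times = FALSE, stringsAsFactors = FALSE)
  if (n < min_obs) return(row)
  if (length(unique(t)) < 3L) {
    row$degenerate_times <- TRUE
    warning(sprintf(
      "patient %s: fewer than 3 distinct measurement times; quadratic trend unidentifiable, excluded",
      pid), call. = FALSE)
    return(row)
  }
  fit <- lm(y ~ t + I(t^2))
  b <- unname(coef(fit))
  row$b0 <- b[1]; row$b1 <- b[2]; row$b2 <- b[3]
  # exact fits trip summary.lm's "essentially perfect fit" warning; the
  # degenerate branch below handles that case deliberately
  s <- suppressWarnings(summary(fit))
  scale_y <- max(1, mean(abs(y)))
  if (s$sigma < 1e-8 * scale_y) {
    # exact fit: t-tests degenerate; "significant" = non-zero coefficient
    sig_quad <- abs(b[3]) > 1e-10
    sig_lin <- abs(b[2]) > 1e-10
    row$p_linear <- as.numeric(!sig_lin)
    row$p_quadratic <- as.numeric(!sig_quad)
  } else {
    ct <- s$coefficients
    row$p_linear <- ct["t", "Pr(>|t|)"]
    row$p_quadratic <- ct["I(t^2)", "Pr(>|t|)"]
    sig_quad <- row$p_quadratic <= alpha
    sig_lin <- row$p_linear <= alpha
  }
  row$class <- if (sig_quad) {
    if (b[3] < 0) "concave" else "convex"
  } else if (sig_lin) {
    if (b[2] > 0) "up" else "down"
  } else "none"
  row$late_direction <- LATE_DIRECTION[[row$class]]
  row
}

#' Classify every patient in a long RDW table
#'
#' @param rdw_long A validated long measurement table (or anything
#'   [validate_rdw_long()] accepts).
#' @param alpha,min_obs Passed to [classify_trajectory()].
#' @return A list of class `rdw_trajectories`: `classification` (one row
#'   per patient), `counts` (named count over the five trend classes),
#'   `n_excluded`, `n_patients`.
#' @export
classify_cohort <- function(rdw_long, alpha = 0.05, min_obs = 4) {
  if (nrow(rdw_long) == 0L) {
    counts <- setNames(integer(length(TRAJECTORY_CLASSES)), TRAJECTORY_CLASSES)
    return(structure(list(
      classification = classify_trajectory(
        data.frame(time_days = 1, rdw = 1))[0, ],
      counts = counts, n_excluded = 0L, n_patients = 0L),
      class = "rdw_trajectories"))
  }
  rdw_long <- validate_rdw_long(rdw_long)
  ids <- unique(rdw_long$patient_id)
  rows <- lapply(ids, function(id) {
    sub <- rdw_long[rdw_long$patient_id == id, , drop = FALSE]
    classify_trajectory(sub, alpha = alpha, min_obs = min_obs)
  })
  classification <- do.call(rbind, rows)
  rownames(classification) <- NULL
  counts <- vapply(TRAJECTORY_CLASSES,
                   function(k) sum(classification$class == k), integer(1))
  structure(list(classification = classification, counts = counts,
                 n_excluded = sum(classification$class == "excluded"),
                 n_patients = length(ids)),
            class = "rdw_trajectories")
}

#' @export
print.rdw_trajectories <- function(x, ...) {
  cat(sprintf("RDW trajectory classification: %d patients (%d excluded, < min measurements)\n",
              x$n_patients, x$n_excluded))
  n <- sum(x$counts)
  for (k in TRAJECTORY_CLASSES)
    cat(sprintf("  %-8s %4d (%4.1f%%)\n", k, x$counts[[k]],
                if (n > 0) 100 * x$counts[[k]] / n else 0))
  invisible(x)
}

#' Cohort-level mixed model for RDW over time
#'
#' Maximum-likelihood fit of `rdw ~ time + time^2` with correlated random
#' intercepts and time slopes per patient, as a cohort-level description of
#' the longitudinal RDW process (per-patient classification uses separate
#' per-patient fits; see [classify_trajectory()]).
#'
#' @param rdw_long A validated long measurement table with at least two
#'   patients.
#' @return A list of class `rdw_mixed`: `fixed_effects` (intercept, time,
#'   time squared), `var_intercept`, `var_slope`, `cov_intercept_slope`,
#'   `cor_intercept_slope`, `var_residual`, `n_patients`, `n_obs`, and the
#'   underlying `lme4` fit in `fit`.
#' @export
fit_mixed_model <- function(rdw_long) {
  rdw_long <- validate_rdw_long(rdw_long)
  n_pat <- length(unique(rdw_long$patient_id))
  if (n_pat < 2L)
    stop_degenerate("random-effect variances are unidentifiable with %d patient(s); need >= 2",
                    n_pat)
  dat <- data.frame(y = rdw_long$rdw, t = rdw_long$time_days,
                    id = rdw_long$patient_id)
  fit <- lme4::lmer(y ~ t + I(t^2) + (1 + t | id), data = dat, REML = FALSE,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(g, v1, v2 = NA) {
    hit <- vc$grp == g & vc$var1 %in% v1 &
      (is.na(v2) & is.na(vc$var2) | !is.na(vc$var2) & vc$var2 %in% v2)
    if (any(hit)) vc$vcov[hit][1] else NA_real_
  }
  var_int <- get_vc("id", "(Intercept)")
  var_slope <- get_vc("id", "t")
  cov_is <- get_vc("id", "(Intercept)", "t")
  structure(list(
    fixed_effects = setNames(as.numeric(lme4::fixef(fit)),
                             c("intercept", "time", "time2")),
    var_intercept = var_int, var_slope = var_slope,
    cov_intercept_slope = cov_is,
    cor_intercept_slope = if (var_int > 0 && var_slope > 0)
      cov_is / sqrt(var_int * var_slope) else NA_real_,
    var_residual = vc$vcov[vc$grp == "Residual"][1],
    n_patients = n_pat, n_obs = nrow(rdw_long), fit = fit),
    class = "rdw_mixed")
}
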