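# Independent oracles and fixture builders used across the suite.

# AUC by exhaustive pair counting (independent of the midrank estimator).
auc_pairs_oracle <- function(scores, labels) {
  ev <- scores[as.logical(labels)]
  ne <- scores[!as.logical(labels)]
  total <- 0
  for (a in ev) for (b in ne)
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  total / (length(ev) * length(ne))
}

# Two-sided Fisher 2x2 p by direct enumeration with binomial coefficients
# (independent of dhyper).
fisher2x2_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  prob <- function(k) exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1))
  probs <- vapply(support, prob, numeric(1))
  p_obs <- prob(a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pearson chi-square statistic straight from the textbook formula.
chisq_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Quadratic OLS via explicit normal equations, with t-test p-values.
ols_quadratic_oracle <- function(t, y) {
  X <- cbind(1, t, t^2)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  df <- length(y) - 3L
  s2 <- sum(resid^2) / df
  se <- sqrt(diag(s2 * solve(XtX)))
  tval <- drop(beta) / se
  list(coefficients = drop(beta), se = se,
       p_values = 2 * pt(-abs(tval), df))
}

# Small fully-valid cohort built by hand (deterministic).
make_cohort_fixture <- function(n = 12) {
  set.seed(421)
  icu <- rep(c(TRUE, FALSE, FALSE), length.out = n)
  hosp <- icu | rep(c(FALSE, TRUE, FALSE), length.out = n)
  data.frame(
    patient_id = sprintf("F%03d", seq_len(n)),
    age = seq(25, 85, length.out = n),
    sex = rep(c("male", "female"), length.out = n),
    comorbidity_category = rep(c("0", "1", "2", "3plus"), length.out = n),
    sofa = rep(c(4, 9, 14, 19), length.out = n),
    pf_ratio = seq(60, 320, length.out = n),
    rdw_baseline = seq(12, 21, length.out = n),
    icu_death = icu, hosp_death = hosp, death_90d = hosp,
    stringsAsFactors = FALSE)
}

# Cohort realising a 2x2 exposure/outcome table via a single binary
# predictor (male); remaining covariates held harmless but valid.
make_2x2_cohort <- function(events_exposed, nonevents_exposed,
                            events_unexposed, nonevents_unexposed) {
  n <- events_exposed + nonevents_exposed + events_unexposed + nonevents_unexposed
  male <- c(rep(TRUE, events_exposed + nonevents_exposed),
            rep(FALSE, events_unexposed + nonevents_unexposed))
  death <- c(rep(TRUE, events_exposed), rep(FALSE, nonevents_exposed),
             rep(TRUE, events_unexposed), rep(FALSE, nonevents_unexposed))
  data.frame(
    patient_id = sprintf("T%03d", seq_len(n)),
    age = 60, sex = ifelse(male, "male", "female"),
    comorbidity_category = "0", sofa = 10, pf_ratio = 150,
    rdw_baseline = 15,
    icu_death = death, hosp_death = death, death_90d = death,
    stringsAsFactors = FALSE)
}

# Generator settings used when a test needs clearly separable trajectories.
strong_signal_config <- function(n, seed) {
  cfg <- default_config(n = n, seed = seed)
  cfg$trajectory$sigma <- 0.1
  cfg$trajectory$n_meas_fixed <- 10
  cfg
}
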