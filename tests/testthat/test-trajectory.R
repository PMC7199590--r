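test_that("degenerate and noiseless series classify by the exact-fit rule", {
  const6 <- data.frame(patient_id = "a", time_days = 0:5, rdw = rep(14.2, 6))
  res <- classify_trajectory(const6)
  expect_identical(res$class, "none")
  expect_identical(res$late_direction, "not_applicable")

  line <- data.frame(patient_id = "b", time_days = 0:5, rdw = 14 + 0.2 * (0:5))
  res <- classify_trajectory(line)
  expect_identical(res$class, "up")
  expect_identical(res$late_direction, "late_up")
  expect_equal(res$b1, 0.2, tolerance = 1e-10)

  para <- data.frame(patient_id = "c", time_days = 0:5,
                     rdw = 14 + 0.5 * (0:5) - 0.08 * (0:5)^2)
  expect_identical(classify_trajectory(para)$class, "concave")
})

test_that("short or time-degenerate series are excluded, with a flag", {
  three <- data.frame(patient_id = "a", time_days = 0:2, rdw = c(14, 15, 16))
  expect_identical(classify_trajectory(three)$class, "excluded")

  two_times <- data.frame(patient_id = "b", time_days = c(0, 0.5, 0.5, 0),
                          rdw = c(14, 15, 15.2, 14.4))
  expect_warning(res <- classify_trajectory(two_times), "distinct")
  expect_identical(res$class, "excluded")
  expect_true(res$degenerate_times)
})

test_that("per-patient coefficients and p-values match a normal-equations oracle", {
  set.seed(5150)
  t <- sort(runif(10, 0, 10))
  y <- 14 + 0.5 * t - 0.05 * t^2 + rnorm(10, 0, 0.1)
  res <- classify_trajectory(data.frame(patient_id = "o", time_days = t, rdw = y))
  oracle <- ols_quadratic_oracle(t, y)
  expect_equal(c(res$b0, res$b1, res$b2), unname(oracle$coefficients),
               tolerance = 1e-8)
  expect_equal(res$p_linear, unname(oracle$p_values[2]), tolerance = 1e-8)
  expect_equal(res$p_quadratic, unname(oracle$p_values[3]), tolerance = 1e-8)
})

test_that("classification survives RDW shifts and time rescaling", {
  set.seed(61)
  classes <- c("concave", "down", "none", "convex", "up")
  for (k in classes) {
    tr <- strong_signal_config(1, 1)$trajectory
    gen <- generate_rdw_series(k, tr, seed = 600 + match(k, classes), n_obs = 10)
    s <- cbind(gen$series, patient_id = "p")
    base <- classify_trajectory(s)

    shifted <- s; shifted$rdw <- shifted$rdw + 5
    expect_identical(classify_trajectory(shifted)$class, base$class)

    scaled <- s; scaled$time_days <- scaled$time_days * 24  # days -> hours
    res <- classify_trajectory(scaled)
    expect_identical(res$class, base$class)
    expect_equal(res$b1, base$b1 / 24, tolerance = 1e-8)
    expect_equal(res$b2, base$b2 / 24^2, tolerance = 1e-8)
  }
})

test_that("cohort classification counts are complete and consistent", {
  empty <- classify_cohort(data.frame(patient_id = character(),
                                      time_days = numeric(), rdw = numeric()))
  expect_true(all(empty$counts == 0L))
  expect_identical(empty$n_patients, 0L)

  const_set <- data.frame(patient_id = rep(c("a", "b", "c"), each = 5),
                          time_days = rep(0:4, 3), rdw = 15)
  cl <- classify_cohort(const_set)
  expect_identical(unname(cl$counts["none"]), 3L)
  expect_identical(sum(cl$counts), 3L)

  sim <- generate_cohort(default_config(n = 120, seed = 202))
  cl <- classify_cohort(sim$rdw_long)
  expect_identical(sum(cl$counts) + cl$n_excluded, cl$n_patients)
  expect_identical(cl$n_patients, length(unique(sim$rdw_long$patient_id)))
  expect_true(all(cl$classification$class[cl$classification$n_obs < 4] == "excluded"))
})

test_that("strong-signal cohorts recover the generating class mixture", {
  cfg <- strong_signal_config(1000, 11)
  sim <- generate_cohort(cfg)
  cl <- classify_cohort(sim$rdw_long)
  shares <- cl$counts / sum(cl$counts)
  mix <- cfg$trajectory$mixture[names(shares)]
  # alpha-level leakage is structural: a truly stable series goes
  # significant ~alpha-often at each of the two tests, so the dominant
  # no-trend class bleeds a few points into the four trend classes
  for (k in c("concave", "down", "convex", "up"))
    expect_lt(abs(shares[[k]] - mix[[k]]), 0.06)
  expect_lt(abs(shares[["none"]] - mix[["none"]]), 0.08)
})

test_that("the cohort-level mixed model recovers variance components", {
  set.seed(77)
  n_pat <- 200; n_obs <- 8
  id <- rep(sprintf("p%03d", 1:n_pat), each = n_obs)
  t <- rep(seq(0, 14, length.out = n_obs), n_pat)
  b0i <- rnorm(n_pat, 15, 1)          # var_intercept = 1
  b1i <- rnorm(n_pat, 0.1, 0.2)      # var_slope = 0.04
  y <- b0i[rep(1:n_pat, each = n_obs)] + b1i[rep(1:n_pat, each = n_obs)] * t +
    0.01 * t^2 + rnorm(n_pat * n_obs, 0, 0.5)   # var_residual = 0.25
  fit <- fit_mixed_model(data.frame(patient_id = id, time_days = t, rdw = y))
  expect_lt(abs(fit$var_intercept - 1) / 1, 0.25)
  expect_lt(abs(fit$var_slope - 0.04) / 0.04, 0.25)
  expect_lt(abs(fit$var_residual - 0.25) / 0.25, 0.25)
  expect_equal(unname(fit$fixed_effects["time2"]), 0.01, tolerance = 0.01)
  expect_true(abs(fit$cor_intercept_slope) <= 1)
})

test_that("mixed model degenerates gracefully and rejects single patients", {
  expect_error(fit_mixed_model(data.frame(patient_id = "only",
                                          time_days = 0:5, rdw = 14 + (0:5) / 10)),
               class = "rdwards_degenerate_error")

  # no between-patient variance: fixed effects approach the pooled OLS fit
  set.seed(88)
  id <- rep(sprintf("p%02d", 1:40), each = 6)
  t <- rep(seq(0, 10, length.out = 6), 40)
  y <- 15 + 0.2 * t - 0.01 * t^2 + rnorm(240, 0, 0.3)
  fit <- fit_mixed_model(data.frame(patient_id = id, time_days = t, rdw = y))
  ols <- lm(y ~ t + I(t^2))
  se <- summary(ols)$coefficients[, "Std. Error"]
  expect_true(all(abs(fit$fixed_effects - coef(ols)) < 2 * se))
})
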