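test_that("intercept calibration matches closed forms when slopes vanish", {
  cfg <- default_config(n = 100, seed = 3)
  cfg$outcome$coefficients[] <- 0
  expect_equal(calibrate_intercept(cfg, target_rate = 0.5), 0, tolerance = 0.01)
  expect_equal(calibrate_intercept(cfg, target_rate = 0.355), qlogis(0.355),
               tolerance = 0.01)
  expect_error(calibrate_intercept(cfg, target_rate = 1.2),
               class = "rdwards_config_error")
})

test_that("calibrated intercept reproduces the target ICU rate at scale", {
  cfg <- default_config(n = 50000, seed = 5)
  cfg$generate_series <- FALSE
  sim <- generate_cohort(cfg)
  expect_equal(mean(sim$cohort$icu_death), 0.355, tolerance = 0.01)
})

test_that("zero-slope generator hits a logit-specified death rate", {
  cfg <- default_config(n = 10000, seed = 9)
  cfg$generate_series <- FALSE
  cfg$outcome$coefficients[] <- 0
  cfg$outcome$intercept <- qlogis(0.5)
  sim <- generate_cohort(cfg)
  expect_equal(mean(sim$cohort$icu_death), 0.5, tolerance = 0.015)
})

test_that("an empty configuration yields empty, well-typed outputs", {
  sim <- generate_cohort(default_config(n = 0, seed = 1))
  expect_identical(nrow(sim$cohort), 0L)
  expect_identical(nrow(sim$rdw_long), 0L)
  expect_identical(nrow(sim$trajectory_truth), 0L)
})

test_that("generation is deterministic and prefix-stable in n", {
  cfg <- default_config(n = 60, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  big <- generate_cohort(default_config(n = 90, seed = 42))
  expect_identical(big$cohort[1:60, ], a$cohort)
  expect_identical(big$rdw_long[seq_len(nrow(a$rdw_long)), ], a$rdw_long)

  other <- generate_cohort(default_config(n = 60, seed = 43))
  expect_false(identical(other$cohort, a$cohort))
})

test_that("generated cohorts satisfy all record invariants", {
  for (seed in c(2, 12, 22)) {
    sim <- generate_cohort(default_config(n = 200, seed = seed))
    expect_silent(validate_cohort(sim$cohort))
    expect_true(all(sim$cohort$age >= 18 & sim$cohort$age <= 100))
    expect_true(all(sim$cohort$sofa >= 0 & sim$cohort$sofa <= 24))
    expect_true(all(sim$cohort$pf_ratio >= 40 & sim$cohort$pf_ratio <= 400))
    expect_true(all(sim$cohort$rdw_baseline >= 11 & sim$cohort$rdw_baseline <= 30))
    expect_true(all(sim$rdw_long$rdw > 0))
    # nesting (also re-checked by validate_cohort)
    expect_true(all(!sim$cohort$icu_death | sim$cohort$hosp_death))
    expect_true(all(!sim$cohort$hosp_death | sim$cohort$death_90d))
  }
})

test_that("default cohort of 318 lands inside binomial bounds of the target rates", {
  sim <- generate_cohort(default_config(n = 318, seed = 1))
  icu_rate <- mean(sim$cohort$icu_death)
  half_width <- 2.576 * sqrt(0.355 * 0.645 / 318)   # binomial 99% bounds
  expect_lt(abs(icu_rate - 0.355), half_width)
  hosp_rate <- mean(sim$cohort$hosp_death)
  expect_lt(abs(hosp_rate - 0.44), 2.576 * sqrt(0.44 * 0.56 / 318))
  # about 85.5% of patients should have >= 4 RDW measurements (272/318)
  n_meas <- table(sim$rdw_long$patient_id)
  expect_equal(unname(mean(n_meas >= 4)), 272 / 318, tolerance = 0.06)
})

test_that("series generation respects class-specific coefficient signs", {
  tr <- default_config()$trajectory
  for (seed in 1:25) {
    co <- function(k) generate_rdw_series(k, tr, seed = seed)$coefficients
    expect_lt(co("concave")["b2"], 0)
    expect_gt(co("convex")["b2"], 0)
    up <- co("up"); down <- co("down"); none <- co("none")
    expect_gt(up["b1"], 0); expect_identical(unname(up["b2"]), 0)
    expect_lt(down["b1"], 0); expect_identical(unname(down["b2"]), 0)
    expect_identical(unname(none[c("b1", "b2")]), c(0, 0))
  }
})

test_that("noiseless series follow their deterministic trend exactly", {
  tr <- default_config()$trajectory
  tr$sigma <- 0
  tr$b0 <- 14; tr$b1 <- 0.2; tr$times <- 0:9
  up <- generate_rdw_series("up", tr, seed = 1)
  expect_equal(up$series$rdw, seq(14.0, 15.8, by = 0.2), tolerance = 1e-12)

  tr$b1 <- NULL; tr$times <- 0:5
  none <- generate_rdw_series("none", tr, seed = 1)
  expect_equal(none$series$rdw, rep(14, 6), tolerance = 1e-12)
})

test_that("a strongly concave generated series is recovered by classification", {
  tr <- strong_signal_config(1, 1)$trajectory
  gen <- generate_rdw_series("concave", tr, seed = 77, n_obs = 12)
  res <- classify_trajectory(cbind(gen$series, patient_id = "p1"))
  expect_identical(res$class, "concave")
  expect_lt(res$b2, 0)
})

test_that("class-linked mortality mode reproduces class-conditional rates", {
  cfg <- default_config(n = 8000, seed = 31)
  cfg$outcome$mode <- "class-linked"
  cfg$generate_series <- FALSE
  sim <- generate_cohort(cfg)
  expect_silent(validate_cohort(sim$cohort))
  truth <- sim$trajectory_truth
  rates <- cfg$outcome$class_mortality
  for (k in names(rates)) {
    sel <- truth$class == k
    expect_lt(abs(mean(sim$cohort$hosp_death[sel]) - rates[[k]]),
              3 * sqrt(0.25 / sum(sel)))
  }
  expect_equal(mean(sim$cohort$icu_death), 0.355, tolerance = 0.02)
})

test_that("invalid configurations are rejected with a config error", {
  cfg <- default_config()
  cfg$trajectory$mixture["none"] <- 0.9
  expect_error(validate_config(cfg), "mixture", class = "rdwards_config_error")
  cfg2 <- default_config()
  cfg2$covariates$age$sd <- -1
  expect_error(validate_config(cfg2), class = "rdwards_config_error")
  cfg3 <- default_config()
  cfg3$n <- -5
  expect_error(validate_config(cfg3), "'n'", class = "rdwards_config_error")
})
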