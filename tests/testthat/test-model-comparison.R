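test_that("AUC matches closed cases and the exhaustive pair-counting oracle", {
  expect_equal(auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.4, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  expect_equal(auc(c(0.8, 0.7, 0.6, 0.5, 0.4), c(1, 0, 1, 0, 0)), 5 / 6)

  set.seed(301)
  for (rep in 1:15) {
    n <- sample(5:200, 1)
    scores <- round(runif(n), 2)           # rounding forces ties
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    expect_equal(auc(scores, labels), auc_pairs_oracle(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(auc(1:4, c(1, 1, 1, 1)), class = "rdwards_degenerate_error")
})

test_that("DeLong comparison is exact under identity and antisymmetric", {
  set.seed(11)
  p <- runif(40); y <- runif(40) < 0.45
  res <- delong_compare(p, p, y)
  expect_equal(res$delta, 0)
  expect_equal(res$p_value, 1)

  q <- plogis(qlogis(p) + rnorm(40, 0, 0.4))
  fwd <- delong_compare(p, q, y)
  bwd <- delong_compare(q, p, y)
  expect_equal(fwd$delta, -bwd$delta, tolerance = 1e-12)
  expect_equal(fwd$se, bwd$se, tolerance = 1e-12)
  expect_equal(fwd$p_value, bwd$p_value, tolerance = 1e-12)
  expect_equal(fwd$delta, fwd$auc_new - fwd$auc_base, tolerance = 1e-15)
  expect_true(fwd$ci[1] <= fwd$delta && fwd$delta <= fwd$ci[2])

  expect_error(delong_compare(p, q[-1], y), class = "rdwards_validation_error")
})

test_that("DeLong AUCs and variance agree with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(21)
  n <- 120
  y <- runif(n) < 0.4
  p_base <- plogis(rnorm(n, ifelse(y, 0.7, 0), 1))
  p_new <- plogis(qlogis(p_base) + rnorm(n, ifelse(y, 0.3, 0), 0.5))
  res <- delong_compare(p_base, p_new, y)
  ref <- pROC::roc.test(
    pROC::roc(y, p_base, quiet = TRUE), pROC::roc(y, p_new, quiet = TRUE),
    method = "delong", paired = TRUE)
  expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-9)
  expect_equal(res$auc_base, as.numeric(ref$roc1$auc), tolerance = 1e-12)
  expect_equal(res$auc_new, as.numeric(ref$roc2$auc), tolerance = 1e-12)
})

test_that("DeLong SE tracks a paired-bootstrap SE of the AUC difference", {
  set.seed(33)
  n <- 50
  y <- c(rep(TRUE, 20), rep(FALSE, 30))
  lp <- ifelse(y, 1, 0) + rnorm(n)
  p_base <- plogis(lp)
  p_new <- plogis(lp + rnorm(n, ifelse(y, 0.4, -0.1), 0.8))
  res <- delong_compare(p_base, p_new, y)
  boots <- replicate(10000, {
    idx <- sample.int(n, n, replace = TRUE)
    yy <- y[idx]
    if (!any(yy) || all(yy)) NA_real_
    else auc(p_new[idx], yy) - auc(p_base[idx], yy)
  })
  expect_lt(abs(res$se - sd(boots, na.rm = TRUE)) / sd(boots, na.rm = TRUE), 0.15)
})

test_that("DeLong comparison is continuous as the model difference vanishes", {
  set.seed(41)
  p <- runif(60); y <- runif(60) < 0.5
  tiny <- delong_compare(p, clamp_p <- pmin(pmax(p + rnorm(60, 0, 1e-9), 0), 1), y)
  expect_lt(abs(tiny$delta), 1e-6)
  expect_lt(tiny$se, 1e-6)
  expect_true(tiny$ci[1] <= 0 && tiny$ci[2] >= 0)
})

test_that("continuous NRI reproduces hand-enumerated cases and handles ties", {
  # events move up twice; non-events split one up / one down
  p_base <- c(0.3, 0.4, 0.2, 0.6)
  p_new <- c(0.4, 0.5, 0.1, 0.7)
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  res <- continuous_nri(p_base, p_new, labels)
  expect_equal(res$event_component, 1.0)
  expect_equal(res$nonevent_component, 0.0)
  expect_equal(res$nri, 1.0)
  expect_equal(res$se, sqrt(0 / 2 + 1 / 2), tolerance = 1e-12)

  same <- continuous_nri(p_base, p_base, labels)
  expect_equal(same$nri, 0)
  expect_equal(same$p_value, 1)

  # exact ties count in neither direction
  tied <- continuous_nri(c(0.2, 0.3, 0.5, 0.6), c(0.2, 0.4, 0.5, 0.5),
                         c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(tied$event_component, 0.5)     # one tie, one up
  expect_equal(tied$nonevent_component, 0.5)  # one tie, one down

  # gross variant counts only the favourable directions
  gross <- continuous_nri(p_base, p_new, labels, variant = "gross")
  expect_equal(gross$event_component, 1.0)
  expect_equal(gross$nonevent_component, 0.5)
})

test_that("IDI reproduces hand-computed means and the identity case", {
  p_base <- c(0.3, 0.4, 0.2, 0.6)
  p_new <- c(0.45, 0.45, 0.3, 0.5)
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  res <- idi(p_base, p_new, labels)
  expect_equal(res$idi, (0.45 - 0.35) - (0.40 - 0.40), tolerance = 1e-12)
  expect_equal(res$mean_base_events, 0.35)
  expect_equal(res$mean_new_events, 0.45)
  expect_equal(res$mean_base_nonevents, 0.40)
  expect_equal(res$mean_new_nonevents, 0.40)

  same <- idi(p_base, p_base, labels)
  expect_equal(same$idi, 0)
  expect_equal(same$p_value, 1)
})

test_that("NRI, IDI and AUC delta all flip sign when models are swapped", {
  set.seed(55)
  n <- 80
  y <- runif(n) < 0.4
  p_base <- runif(n)
  p_new <- clamp_vec <- pmin(pmax(p_base + rnorm(n, 0.05, 0.1), 0.001), 0.999)
  expect_equal(continuous_nri(p_base, p_new, y)$nri,
               -continuous_nri(p_new, p_base, y)$nri, tolerance = 1e-12)
  expect_equal(idi(p_base, p_new, y)$idi, -idi(p_new, p_base, y)$idi,
               tolerance = 1e-12)
  expect_equal(delong_compare(p_base, p_new, y)$delta,
               -delong_compare(p_new, p_base, y)$delta, tolerance = 1e-12)

  nri <- continuous_nri(p_base, p_new, y)
  expect_true(abs(nri$event_component) <= 1 && abs(nri$nonevent_component) <= 1)
  expect_true(nri$nri >= -2 && nri$nri <= 2)
  expect_true(nri$ci[1] <= nri$nri && nri$nri <= nri$ci[2])
  ii <- idi(p_base, p_new, y)
  expect_true(ii$ci[1] <= ii$idi && ii$idi <= ii$ci[2])
})

test_that("comparison metrics are invariant to patient reordering", {
  sim <- generate_cohort(default_config(n = 250, seed = 61))
  cmp <- compare_models(sim$cohort, "icu")
  set.seed(4)
  shuffled <- sim$cohort[sample.int(nrow(sim$cohort)), ]
  cmp2 <- compare_models(shuffled, "icu")
  expect_equal(cmp$delong$delta, cmp2$delong$delta, tolerance = 1e-10)
  expect_equal(cmp$nri$nri, cmp2$nri$nri, tolerance = 1e-10)
  expect_equal(cmp$idi$idi, cmp2$idi$idi, tolerance = 1e-10)
})

test_that("bootstrap intervals bracket the point estimates", {
  sim <- generate_cohort(default_config(n = 200, seed = 71))
  cmp <- compare_models(sim$cohort, "hospital", ci_method = "bootstrap",
                        n_boot = 300, seed = 5)
  expect_true(cmp$nri$ci[1] <= cmp$nri$nri && cmp$nri$nri <= cmp$nri$ci[2])
  expect_true(cmp$idi$ci[1] <= cmp$idi$idi && cmp$idi$idi <= cmp$idi$ci[2])
  # deterministic under the same seed
  cmp2 <- compare_models(sim$cohort, "hospital", ci_method = "bootstrap",
                         n_boot = 300, seed = 5)
  expect_identical(cmp$nri$ci, cmp2$nri$ci)
})
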