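test_that("product-limit estimate matches hand calculation", {
  # three subjects, all events at t = 1, 2, 3: S = 2/3, 1/3, 0
  km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3L, 2L, 1L))
  # all censored: S is identically 1 (no event times)
  km0 <- km_estimate(c(5, 8, 2), c(FALSE, FALSE, FALSE))
  expect_equal(nrow(km0), 0)
  expect_equal(km_survival_at(km0, c(1, 10)), c(1, 1))
  # censoring at an event time keeps the subject at risk there
  km2 <- km_estimate(c(2, 2, 4), c(TRUE, FALSE, TRUE))
  expect_equal(km2$n_risk, c(3L, 1L))
  expect_equal(km2$survival, c(2 / 3, 0))
  expect_error(km_estimate(c(0, 1), c(TRUE, TRUE)),
               class = "herbsurv_data_error")
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(2)
  t_all <- sample(1:40, 200, replace = TRUE)
  km <- km_estimate(t_all, rep(TRUE, 200))
  for (tt in c(5, 10, 20, 39)) {
    expect_equal(km_survival_at(km, tt), mean(t_all > tt))
  }
})

test_that("KM and Greenwood variance match the survival package", {
  skip_if_not_installed("survival")
  fx <- tied_survival_fixture(n = 200, seed = 77)
  km <- km_estimate(fx$time, fx$event)
  sf <- survival::survfit(survival::Surv(fx$time, fx$event) ~ 1)
  sm <- summary(sf, times = km$time)
  expect_lt(max(abs(km$survival - sm$surv)), 1e-12)
  keep <- km$survival > 0
  expect_lt(max(abs(sqrt(km$greenwood_var[keep]) - sm$std.err[keep])),
            1e-12)
})

test_that("log-rank: degenerate and oracle cases", {
  # identical time/event vectors in both groups
  time <- rep(c(2, 4, 6, 8), 2)
  ev <- rep(c(TRUE, TRUE, FALSE, TRUE), 2)
  grp <- rep(c(0, 1), each = 4)
  lr <- logrank_test(time, ev, grp)
  expect_equal(lr$chi2, 0)
  expect_equal(lr$p, 1)
  # label swap invariance
  fx <- tied_survival_fixture(n = 150, seed = 41)
  g <- fx$x[, "x1"]
  lr1 <- logrank_test(fx$time, fx$event, g)
  lr2 <- logrank_test(fx$time, fx$event, 1 - g)
  expect_equal(lr1$chi2, lr2$chi2)
  skip_if_not_installed("survival")
  sd1 <- survival::survdiff(survival::Surv(fx$time, fx$event) ~ g)
  expect_equal(lr1$chi2, sd1$chisq, tolerance = 1e-10)
  expect_error(logrank_test(fx$time, fx$event, rep(1, 150)),
               class = "herbsurv_data_error")
})

test_that("Cox fit matches an established implementation on tied data", {
  skip_if_not_installed("survival")
  fx <- tied_survival_fixture(n = 300, seed = 11)
  for (tie in c("efron", "breslow")) {
    f <- cox_fit(fx$time, fx$event, fx$x, ties = tie)
    cf <- survival::coxph(
      survival::Surv(fx$time, fx$event) ~ fx$x, ties = tie)
    expect_lt(max(abs(f$coefficients - unname(coef(cf)))), 1e-6)
    expect_lt(max(abs(f$se - unname(sqrt(diag(vcov(cf)))))), 1e-6)
    expect_equal(f$loglik, cf$loglik[2], tolerance = 1e-8)
  }
  expect_identical(cox_fit(fx$time, fx$event, fx$x)$coefficients,
                   cox_fit(fx$time, fx$event, fx$x)$coefficients)
})

test_that("Efron and Breslow coincide exactly on tie-free data", {
  set.seed(9)
  n <- 150
  x <- cbind(z = rnorm(n))
  time <- rexp(n, 0.1 * exp(0.5 * x[, 1])) + runif(n, 0, 1e-4)
  ev <- rbinom(n, 1, 0.7) == 1
  fe <- cox_fit(time, ev, x, ties = "efron")
  fb <- cox_fit(time, ev, x, ties = "breslow")
  expect_equal(fe$coefficients, fb$coefficients, tolerance = 1e-12)
  expect_lt(fe$score_norm, 1e-6)
})

test_that("Cox recovers a rate ratio of 2 and nulls a permuted covariate", {
  set.seed(15)
  n <- 5000
  g <- rep(c(0, 1), each = n / 2)
  time <- rexp(n, 0.01 * 2^g)
  f <- cox_fit(time, rep(TRUE, n), cbind(g = g))
  expect_equal(unname(f$hr["g"]), 2, tolerance = 0.12)
  perm <- sample(g)
  f0 <- cox_fit(time, rep(TRUE, n), cbind(g = perm))
  expect_lt(abs(f0$coefficients[["g"]]), 3 * f0$se[["g"]] + 0.02)
  expect_error(cox_fit(time, rep(FALSE, n), cbind(g = g)),
               class = "herbsurv_data_error")
  expect_error(cox_fit(time, rep(TRUE, n), cbind(g = rep(1, n))),
               class = "herbsurv_data_error")
})

test_that("cause-specific subsetting removes other-cause deaths entirely", {
  co <- tibble::tibble(
    patient_id = sprintf("P%d", 1:6),
    followup_days = c(100, 200, 300, 400, 500, 600),
    event = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
    cause_category = c("circulatory", "neoplasms", "infections_parasites",
                       "none", "other", "none"))
  out <- cause_specific_subset(co)
  expect_equal(nrow(out), 4)  # the neoplasm and other-cause deaths are gone
  expect_false(any(out$patient_id %in% c("P2", "P5")))
  expect_equal(out$event, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("mortality analysis wires curves, log-rank and Cox together", {
  b <- generate_bundle(claims_config(n_patients = 4000, seed = 3))
  co <- build_cohort(b)$cohort
  m <- fit_logistic_ps(co)
  mc <- matched_cohort(co, match_1_to_k(m, seed = 3))
  res <- run_mortality_analysis(mc, "all_cause")
  expect_named(res$curves, c("chm_user", "non_user"))
  expect_s3_class(res$adjusted, "cox_fit")
  expect_lt(res$adjusted$hr[["chm_use"]], 1)
  expect_equal(res$adjusted$n, nrow(mc))
  # cause-specific bookkeeping: n equals subjects minus other-cause deaths
  res2 <- run_mortality_analysis(mc, "infect_circ")
  other <- sum(mc$event &
                 !(mc$cause_category %in% c("infections_parasites",
                                            "circulatory")))
  expect_equal(res2$adjusted$n, nrow(mc) - other)
  # subgroup restricts to the subtype subset only
  res3 <- run_mortality_analysis(mc, "all_cause", subgroup = "cns_infection")
  expect_equal(nrow(res3$data),
               sum(grepl("cns_infection", mc$neuro_subtypes)))
  # interval adjustment adds a covariate
  res4 <- run_mortality_analysis(mc, "all_cause", adjust_interval = TRUE)
  expect_true("interval" %in% names(res4$adjusted$coefficients))
})
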