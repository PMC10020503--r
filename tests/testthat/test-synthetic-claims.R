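test_that("invalid configs are rejected with the offending field named", {
  expect_error(claims_config(), class = "herbsurv_config_error")
  expect_error(claims_config(100, age_band_probs = c(0.5, 0.5, 0.1)),
               regexp = "age_band_probs", class = "herbsurv_config_error")
  expect_error(claims_config(100, p_female = 1.5),
               regexp = "p_female", class = "herbsurv_config_error")
  expect_error(claims_config(100, baseline_hazard_rate = 0),
               regexp = "baseline_hazard_rate",
               class = "herbsurv_config_error")
  bad_pairs <- tibble::tibble(x = "NOPE", y = "HQ", co_boost = 2)
  expect_error(claims_config(100, planted_pairs = bad_pairs),
               regexp = "NOPE", class = "herbsurv_config_error")
})

test_that("bundles are reproducible and stable under cohort growth", {
  cfg <- claims_config(n_patients = 150, seed = 99)
  b1 <- generate_bundle(cfg)
  b2 <- generate_bundle(cfg)
  expect_identical(b1$patients, b2$patients)
  expect_identical(b1$diagnoses, b2$diagnoses)
  expect_identical(b1$prescriptions, b2$prescriptions)
  expect_identical(b1$deaths, b2$deaths)
  # per-patient substreams: enlarging the cohort leaves earlier patients
  # untouched
  b3 <- generate_bundle(claims_config(n_patients = 200, seed = 99))
  first <- b1$patients$id
  expect_identical(b3$prescriptions[b3$prescriptions$patient_id %in% first, ],
                   b1$prescriptions)
  expect_identical(b3$deaths[b3$deaths$patient_id %in% first, ], b1$deaths)
})

test_that("bundle invariants hold on a generated cohort", {
  b <- generate_bundle(claims_config(n_patients = 400, seed = 7))
  expect_silent(validate_bundle(b))
  cfg <- b$provenance$config
  all_dates <- c(b$diagnoses$date, b$prescriptions$date, b$deaths$date)
  expect_true(all(all_dates >= cfg$study_start & all_dates <= cfg$study_end))
  chm <- b$prescriptions[b$prescriptions$class == "CHM", ]
  expect_true(all(chm$daily_dose_g > 0))
  expect_true(all(chm$days >= 1))
  art <- b$prescriptions[b$prescriptions$class != "CHM", ]
  expect_true(all(art$ddd_amount > 0))
})

test_that("the survival law matches exp(-rate * t) when all log-HRs are zero", {
  cfg <- claims_config(
    n_patients = 4000, seed = 13,
    log_hr = c(chm_use = 0, age_30_40 = 0, age_ge40 = 0, female = 0,
               cci_1_2 = 0, cci_ge3 = 0),
    baseline_hazard_rate = 4e-4)
  b <- generate_bundle(cfg)
  # time from each subject's own index clock, straight off the generator
  tr <- b$provenance$truth
  end <- cfg$study_end
  keep <- tr$index_date <= end
  tr <- tr[keep, ]
  ev <- !is.na(tr$death_date)
  time <- ifelse(ev, as.integer(tr$death_date) - as.integer(tr$index_date),
                 as.integer(end) - as.integer(tr$index_date))
  ok <- time > 0
  km <- km_estimate(time[ok], ev[ok])
  for (tt in c(200, 500, 1000)) {
    s_hat <- km_survival_at(km, tt)
    s_true <- exp(-4e-4 * tt)
    i <- max(which(km$time <= tt))
    se <- sqrt(km$greenwood_var[i])
    expect_lt(abs(s_hat - s_true), 3.5 * se + 0.01)
  }
})

test_that("transaction-only streams recover planted joint structure", {
  catalog <- dense_catalog()
  # single product: every transaction is exactly that product
  one <- tibble::tibble(code = "A", kind = "single_herb", propensity = 0.5,
                        mean_dose_g = 1, mean_days_rx = 7)
  rx1 <- generate_transactions_only(one, NULL, 50, seed = 1)
  ts1 <- build_transactions(rx1)
  expect_equal(ts1$n_total, 50)
  expect_identical(unique(ts1$items$product_code), "A")
  expect_equal(nrow(top_rules(ts1, k = Inf)), 0)
  # planted boost of 4 is recovered within sampling error
  pp <- tibble::tibble(x = "A", y = "B", co_boost = 4)
  rx <- generate_transactions_only(catalog, pp, 50000, seed = 3)
  ts <- build_transactions(rx)
  rules <- top_rules(ts, k = Inf)
  ab <- rules[rules$x %in% c("A", "B") & rules$y %in% c("A", "B"), ]
  expect_equal(nrow(ab), 1)
  expect_lt(abs(ab$lift - 4), 0.3)
  # co_boost = 1 means independence: lift near 1
  pp1 <- tibble::tibble(x = "A", y = "B", co_boost = 1)
  ts0 <- build_transactions(
    generate_transactions_only(catalog, pp1, 50000, seed = 3))
  r0 <- top_rules(ts0, k = Inf)
  ab0 <- r0[r0$x %in% c("A", "B") & r0$y %in% c("A", "B"), ]
  expect_lt(abs(ab0$lift - 1), 0.35)
  # planted pair absent from catalog
  expect_error(
    generate_transactions_only(catalog,
                               tibble::tibble(x = "ZZ", y = "B",
                                              co_boost = 2),
                               100, seed = 1),
    class = "herbsurv_config_error")
  expect_error(generate_transactions_only(catalog[0, ], NULL, 10, seed = 1),
               class = "herbsurv_config_error")
})

test_that("disjoint planted pairs with boost >= 3 rank top-5 by joint frequency", {
  # three product-disjoint pairs at realistic marginals and boosts; the
  # four-outcome draw plants the joint probability exactly for such pairs
  pairs <- tibble::tibble(x = c("HL", "SZRT", "JG"),
                          y = c("HQ", "YJT", "GC"),
                          co_boost = c(4.81, 7.81, 3.0))
  rx <- generate_transactions_only(default_herb_catalog(), pairs,
                                   n_transactions = 15000, seed = 17)
  ts <- build_transactions(rx)
  expect_gte(ts$n_total, 10000)
  rules <- top_rules(ts, k = 5)
  top_keys <- paste(rules$x, rules$y)
  for (i in seq_len(nrow(pairs))) {
    key1 <- paste(pairs$x[i], pairs$y[i])
    key2 <- paste(pairs$y[i], pairs$x[i])
    expect_true(key1 %in% top_keys || key2 %in% top_keys, info = key1)
  }
})

test_that("bundles round-trip through CSV", {
  b <- generate_bundle(claims_config(n_patients = 60, seed = 3))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  b2 <- read_bundle(dir)
  expect_equal(as.data.frame(b2$patients), as.data.frame(b$patients))
  expect_equal(as.data.frame(b2$diagnoses), as.data.frame(b$diagnoses))
  expect_equal(as.data.frame(b2$prescriptions),
               as.data.frame(b$prescriptions))
  expect_equal(as.data.frame(b2$deaths), as.data.frame(b$deaths))
  expect_equal(b2$provenance$planted_counts, b$provenance$planted_counts)
})
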