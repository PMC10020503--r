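# Seeded synthetic claims generator.
#
# Emits the four claims tables (patients, diagnoses, prescriptions, deaths)
# with the statistical structure the downstream pipeline assumes: HIV/AIDS
# case streams satisfying (or deliberately failing) the
# 1-inpatient-or-3-outpatient rule, neurological-disease streams in four
# subtypes, CHM prescription baskets with planted pair co-occurrence,
# antiretroviral dispensing with defined daily doses, and death times from
# an exponential proportional-hazards model with a planted exposure effect.
# Every patient draws from an independent substream derived from the master
# seed by a fixed counter scheme, so enlarging the cohort never perturbs
# earlier patients.

#' Default herb catalog for the synthetic generator
#'
#' Eleven named products mirroring the frequently dispensed single herbs and
#' formulas of Taiwanese CHM practice (Huang Qin, Gan Cao, Huang Lian,
#' Jie Geng, Huang Bai, Ye Jiao Teng, Da Huang, and the formulas LDXGT,
#' BXXXT, GGT, SZRT), plus forty generic background herbs that stand in for
#' the long tail of the pharmacopeia so that almost every patient-day visit
#' dispenses at least one product. `propensity` is the per-transaction
#' inclusion probability.
#'
#' @return tibble with columns `code`, `kind`, `propensity`, `mean_dose_g`,
#'   `mean_days_rx`.
#' @export
default_herb_catalog <- function() {
  named <- tibble::tribble(
    ~code,    ~kind,         ~propensity, ~mean_dose_g, ~mean_days_rx,
    "HQ",     "single_herb", 0.0755,      2.0,          7,
    "GC",     "single_herb", 0.0732,      1.1,          7,
    "DaH",    "single_herb", 0.0716,      1.0,          7,
    "JG",     "single_herb", 0.0632,      1.1,          7,
    "HL",     "single_herb", 0.0541,      1.0,          7,
    "YJT",    "single_herb", 0.0439,      1.0,          7,
    "HB",     "single_herb", 0.0380,      1.1,          7,
    "LDXGT",  "formula",     0.0622,     12.0,          7,
    "BXXXT",  "formula",     0.0552,     11.0,          7,
    "GGT",    "formula",     0.0529,     11.0,          7,
    "SZRT",   "formula",     0.0380,     12.0,          7)
  filler <- tibble::tibble(
    code = sprintf("HRB%02d", 1:40),
    kind = "single_herb",
    propensity = 0.075,
    mean_dose_g = 1.5,
    mean_days_rx = 7)
  dplyr::bind_rows(named, filler)
}

#' Default planted co-prescription pairs
#'
#' The five pairs whose joint inclusion probability is boosted above
#' independence, with boosts equal to the lift values the analysis should
#' recover (antecedent listed first).
#'
#' @return tibble with columns `x`, `y`, `co_boost`.
#' @export
default_planted_pairs <- function() {
  tibble::tribble(
    ~x,     ~y,    ~co_boost,
    "HL",   "HQ",  4.81,
    "SZRT", "YJT", 7.81,
    "GC",   "HQ",  2.23,
    "JG",   "GC",  2.67,
    "HB",   "HL",  5.81)
}

#' Configuration for the synthetic claims generator
#'
#' Defaults describe a plausible Taiwanese HIV/AIDS claims cohort observed
#' 2008--2019 with case onset 2010--2017: a predominantly male cohort,
#' ~30% developing neurological disease, ~40% of those touching CHM (60%
#' of whom accumulate the 14 prescription-days that define exposure), and
#' death hazards following a proportional-hazards model whose true log
#' hazard ratios default to the adjusted estimates the pipeline is designed
#' to recover (CHM effect ln 0.30). See the methods vignette for the
#' rationale behind every default.
#'
#' @param n_patients number of patients to simulate.
#' @param study_start,study_end calendar bounds of the observation window.
#' @param hiv_onset_years first/last calendar year of HIV/AIDS case onset.
#' @param p_female probability of female sex.
#' @param age_band_probs probabilities of age bands <30, 30--40, >=40 at
#'   neurological diagnosis; must sum to 1.
#' @param p_neuro_given_hiv probability an HIV/AIDS patient develops
#'   neurological disease.
#' @param neuro_subtype_probs probabilities over the four subtypes
#'   (CNS infection, cognitive, vasculopathy, peripheral neuropathy).
#' @param p_chm_exposed baseline probability of any CHM exposure (entered
#'   on the logit scale together with `exposure_log_or`).
#' @param exposure_log_or named log odds ratios tilting CHM exposure by
#'   covariate (planted confounding); names among `age_30_40`, `age_ge40`,
#'   `female`, `cci_1_2`, `cci_ge3`.
#' @param chm_days_distribution list with `p_heavy` (probability an exposed
#'   patient follows the heavy prescription law, which places mass at/above
#'   14 cumulative days) and `heavy_visits_mean` (mean CHM visits per year
#'   under the heavy law). Light patients receive a single one-product
#'   visit and stay below 14 days.
#' @param index_duration_lognorm `c(meanlog, sdlog)` of the log-normal days
#'   from HIV to neurological diagnosis (default matches mean 786 / SD 804).
#' @param baseline_hazard_rate events per person-day for the reference
#'   stratum (male, <30, CCI 0, no CHM).
#' @param log_hr named true log hazard ratios: `chm_use`, `age_30_40`,
#'   `age_ge40`, `female`, `cci_1_2`, `cci_ge3`.
#' @param cause_probs distribution over death-cause categories conditional
#'   on death; names must be the eight categories of [categorize_cause()].
#' @param cci_count_probs distribution of the number of distinct Charlson
#'   categories present before HIV diagnosis (names "0","1",...).
#' @param p_neuro_before_hiv,p_missing_demo,p_malignancy probabilities of
#'   planting, per patient, the corresponding exclusion-cascade traffic.
#' @param p_fail_visit_rule probability an HIV stream deliberately fails
#'   the 1-inpatient-or-3-outpatient rule (two outpatient visits only).
#' @param nonuser_lag_days day offset after neurological diagnosis at which
#'   a non-user's death clock starts (the generator-side landmark).
#' @param herb_catalog see [default_herb_catalog()].
#' @param planted_pairs see [default_planted_pairs()]; `co_boost = 1` means
#'   independence.
#' @param seed master seed; per-patient substreams are derived from it.
#' @return validated object of class `claims_config`.
#' @export
claims_config <- function(n_patients,
                          study_start = "2008-01-01",
                          study_end = "2019-12-31",
                          hiv_onset_years = c(2010, 2017),
                          p_female = 0.045,
                          age_band_probs = c(lt30 = 0.33, b30to40 = 0.38,
                                             ge40 = 0.29),
                          p_neuro_given_hiv = 0.30,
                          neuro_subtype_probs = c(cns_infection = 0.45,
                                                  cognitive = 0.32,
                                                  vasculopathy = 0.10,
                                                  peripheral_neuropathy = 0.13),
                          p_chm_exposed = 0.40,
                          exposure_log_or = c(age_30_40 = -0.25,
                                              age_ge40 = -0.60,
                                              female = -0.20,
                                              cci_1_2 = 0.30,
                                              cci_ge3 = 0.35),
                          chm_days_distribution = list(p_heavy = 0.6,
                                                       heavy_visits_mean = 6),
                          index_duration_lognorm = c(meanlog = 6.309,
                                                     sdlog = 0.846),
                          baseline_hazard_rate = 1.2e-4,
                          log_hr = c(chm_use = log(0.30),
                                     age_30_40 = log(1.26),
                                     age_ge40 = log(3.79),
                                     female = log(2.80),
                                     cci_1_2 = log(1.38),
                                     cci_ge3 = log(1.91)),
                          cause_probs = c(infections_parasites = 0.35,
                                          circulatory = 0.16,
                                          endocrine_metabolic = 0.08,
                                          hepatitis_liver = 0.08,
                                          respiratory = 0.08,
                                          genitourinary = 0.04,
                                          neoplasms = 0.06,
                                          other = 0.15),
                          cci_count_probs = c(`0` = 0.76, `1` = 0.13,
                                              `2` = 0.05, `3` = 0.03,
                                              `4` = 0.02, `5` = 0.01),
                          p_neuro_before_hiv = 0.05,
                          p_missing_demo = 0.002,
                          p_malignancy = 0.01,
                          p_fail_visit_rule = 0.02,
                          nonuser_lag_days = 90,
                          herb_catalog = default_herb_catalog(),
                          planted_pairs = default_planted_pairs(),
                          seed = 1L) {
  if (missing(n_patients) || length(n_patients) != 1 || n_patients < 1)
    stop_config("`n_patients` must be a positive integer")
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  if (!(study_start < study_end))
    stop_config("`study_start` must precede `study_end`")
  for (nm in c("p_female", "p_neuro_given_hiv", "p_chm_exposed",
               "p_neuro_before_hiv", "p_missing_demo", "p_malignancy",
               "p_fail_visit_rule")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1)
      stop_config("`%s` must be a probability", nm)
  }
  assert_prob_vector(age_band_probs, "age_band_probs", 3)
  assert_prob_vector(neuro_subtype_probs, "neuro_subtype_probs", 4)
  assert_prob_vector(cause_probs, "cause_probs")
  assert_prob_vector(cci_count_probs, "cci_count_probs")
  if (!setequal(names(cause_probs),
                c("infections_parasites", "circulatory",
                  "endocrine_metabolic", "hepatitis_liver", "respiratory",
                  "genitourinary", "neoplasms", "other")))
    stop_config("`cause_probs` must name the eight cause categories")
  if (baseline_hazard_rate <= 0)
    stop_config("`baseline_hazard_rate` must be strictly positive")
  needed <- c("chm_use", "age_30_40", "age_ge40", "female",
              "cci_1_2", "cci_ge3")
  if (!all(needed %in% names(log_hr)))
    stop_config("`log_hr` must name: %s", paste(needed, collapse = ", "))
  if (!all(names(exposure_log_or) %in% setdiff(needed, "chm_use")))
    stop_config("`exposure_log_or` has unknown covariate names")
  cat <- tibble::as_tibble(herb_catalog)
  if (nrow(cat) == 0)
    stop_config("`herb_catalog` must contain at least one product")
  if (!all(c("code", "kind", "propensity", "mean_dose_g",
             "mean_days_rx") %in% names(cat)))
    stop_config("`herb_catalog` is missing required columns")
  if (anyDuplicated(cat$code))
    stop_config("`herb_catalog` codes must be unique")
  if (any(cat$propensity <= 0 | cat$propensity >= 1))
    stop_config("`herb_catalog` propensities must lie in (0, 1)")
  if (any(cat$mean_dose_g <= 0) || any(cat$mean_days_rx < 1))
    stop_config("`herb_catalog` doses/days must be positive")
  pp <- tibble::as_tibble(planted_pairs)
  if (nrow(pp) > 0) {
    if (!all(c("x", "y", "co_boost") %in% names(pp)))
      stop_config("`planted_pairs` needs columns x, y, co_boost")
    miss <- setdiff(c(pp$x, pp$y), cat$code)
    if (length(miss) > 0)
      stop_config("`planted_pairs` references products not in catalog: %s",
                  paste(unique(miss), collapse = ", "))
    if (any(pp$co_boost <= 0))
      stop_config("`planted_pairs` co_boost must be strictly positive")
    px <- cat$propensity[match(pp$x, cat$code)]
    py <- cat$propensity[match(pp$y, cat$code)]
    cc <- pp$co_boost * px * py
    if (any(cc > pmin(px, py)) || any(px + py - cc > 1))
      stop_config("`planted_pairs` co_boost too large for the marginals")
  }
  p_plant <- p_neuro_before_hiv + p_missing_demo + p_malignancy
  if (p_plant > 1)
    stop_config("planted exclusion probabilities sum to more than 1")
  if (chm_days_distribution$p_heavy < 0 || chm_days_distribution$p_heavy > 1)
    stop_config("`chm_days_distribution$p_heavy` must be a probability")
  if (chm_days_distribution$heavy_visits_mean < 1)
    stop_config("`chm_days_distribution$heavy_visits_mean` must be >= 1")
  structure(list(
    n_patients = as.integer(n_patients),
    study_start = study_start, study_end = study_end,
    hiv_onset_years = hiv_onset_years,
    p_female = p_female, age_band_probs = age_band_probs,
    p_neuro_given_hiv = p_neuro_given_hiv,
    neuro_subtype_probs = neuro_subtype_probs,
    p_chm_exposed = p_chm_exposed, exposure_log_or = exposure_log_or,
    chm_days_distribution = chm_days_distribution,
    index_duration_lognorm = index_duration_lognorm,
    baseline_hazard_rate = baseline_hazard_rate, log_hr = log_hr,
    cause_probs = cause_probs, cci_count_probs = cci_count_probs,
    p_neuro_before_hiv = p_neuro_before_hiv,
    p_missing_demo = p_missing_demo, p_malignancy = p_malignancy,
    p_fail_visit_rule = p_fail_visit_rule,
    nonuser_lag_days = nonuser_lag_days,
    herb_catalog = cat, planted_pairs = pp, seed = as.integer(seed)),
    class = "claims_config")
}

#' @export
print.claims_config <- function(x, ...) {
  cat("<claims_config>", x$n_patients, "patients,",
      format(x$study_start), "to", format(x$study_end),
      "| seed", x$seed, "\n")
  invisible(x)
}

# --- basket machinery -------------------------------------------------------

# Precompute the planted-pair draw parameters against a catalog.
.basket_setup <- function(catalog, pairs) {
  p <- catalog$propensity
  names(p) <- catalog$code
  in_pair <- rep(FALSE, nrow(catalog))
  pr <- NULL
  if (!is.null(pairs) && nrow(pairs) > 0) {
    ix <- match(pairs$x, catalog$code)
    iy <- match(pairs$y, catalog$code)
    cxy <- pairs$co_boost * p[ix] * p[iy]
    pr <- list(ix = ix, iy = iy, c = unname(cxy),
               px = unname(p[ix]), py = unname(p[iy]))
    in_pair[c(ix, iy)] <- TRUE
  }
  list(p = unname(p), codes = catalog$code, in_pair = in_pair, pairs = pr)
}

# One basket: products in planted pairs are drawn through a four-outcome
# scheme that fixes the joint probability at co_boost * px * py while
# preserving both marginals exactly; remaining products are independent
# Bernoulli draws. Pairs sharing a product are applied sequentially (their
# inclusions OR together), which slightly inflates shared marginals.
.draw_basket <- function(setup) {
  incl <- logical(length(setup$p))
  pr <- setup$pairs
  if (!is.null(pr)) {
    u <- runif(length(pr$c))
    both <- u < pr$c
    xonly <- !both & u < pr$px
    yonly <- !both & !xonly & u < pr$px + pr$py - pr$c
    incl[pr$ix[both | xonly]] <- TRUE
    incl[pr$iy[both | yonly]] <- TRUE
  }
  free <- !setup$in_pair
  incl[free] <- runif(sum(free)) < setup$p[free]
  which(incl)
}

# --- generator --------------------------------------------------------------

#' Generate a synthetic claims bundle
#'
#' Deterministic given the config (including its seed). See
#' [claims_config()] for the data-generating model. The returned bundle
#' carries a `provenance` element echoing the config, a per-patient truth
#' table, and the planted exclusion-cascade counts (computed from the
#' generator's own bookkeeping, with events after death removed, applying
#' the same first-applicable-bin precedence the cohort builder uses).
#'
#' @param config a [claims_config()].
#' @return object of class `claims_bundle`: list with tibbles `patients`,
#'   `diagnoses`, `prescriptions`, `deaths`, and `provenance`.
#' @export
generate_bundle <- function(config) {
  if (!inherits(config, "claims_config"))
    stop_config("`config` must be a claims_config object")
  cfg <- config
  d0 <- as.integer(cfg$study_start)
  d_end <- as.integer(cfg$study_end)
  hiv_lo <- as.integer(as.Date(sprintf("%d-01-01", cfg$hiv_onset_years[1])))
  hiv_hi <- as.integer(as.Date(sprintf("%d-12-31", cfg$hiv_onset_years[2])))
  setup <- .basket_setup(cfg$herb_catalog, cfg$planted_pairs)
  cat_days <- cfg$herb_catalog$mean_days_rx
  cat_dose <- cfg$herb_catalog$mean_dose_g
  cat_kind <- cfg$herb_catalog$kind
  cat_codes <- cfg$herb_catalog$code
  lor <- cfg$exposure_log_or
  lhr <- cfg$log_hr
  cause_names <- names(cfg$cause_probs)
  cause_pool <- list(
    infections_parasites = c("B20", "A41.9", "A15.0"),
    circulatory = c("I21.9", "I63.9", "I50.0"),
    endocrine_metabolic = c("E11.9", "E87.2"),
    hepatitis_liver = c("B18.2", "K74.6"),
    respiratory = c("J18.9", "J96.0"),
    genitourinary = c("N17.9", "N18.9"),
    neoplasms = c("C22.9", "C85.9"),
    other = c("R99", "W19", "X59"))
  hiv_pool <- c("042", "042.0", "043.1", "044.9")
  neuro_pool <- list(
    cns_infection = c("013.0", "047.9", "320.9", "323.9"),
    cognitive = c("294.0", "332.0", "345.1", "780.31"),
    vasculopathy = c("433.1", "434.9", "436", "437.0"),
    peripheral_neuropathy = c("354.0", "356.9", "357.4", "355.9"))
  subtype_names <- names(cfg$neuro_subtype_probs)
  # pre-HIV comorbidity palette: one representative code per Charlson
  # category, chosen so no two palette codes share a category after the
  # scoring hierarchy and none collides with the neurological or
  # malignancy code sets
  cci_palette <- c("410.0", "428.0", "440.0", "496", "714.0",
                   "531.0", "571.5", "250.0", "585")
  oi_codes <- c("136.3", "078.5", "011.9", "112.4", "117.5", "031.2")
  oi_probs <- c(0.12, 0.04, 0.035, 0.03, 0.05, 0.02)
  cci_counts <- as.integer(names(cfg$cci_count_probs))
  age_lo <- c(20, 30.05, 40.05); age_hi <- c(29.7, 39.7, 64.5)
  cd <- cfg$chm_days_distribution

  n <- cfg$n_patients
  pat <- vector("list", n); dia <- vector("list", n)
  rx <- vector("list", n); dth <- vector("list", n)
  truth <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(substream_seed(cfg$seed, i))
    pid <- sprintf("P%06d", i)
    female <- runif(1) < cfg$p_female
    band <- sample.int(3, 1, prob = cfg$age_band_probs)
    age <- runif(1, age_lo[band], age_hi[band])
    hiv_day <- floor(runif(1, hiv_lo, hiv_hi + 1))
    u <- runif(1)
    plant <- if (u < cfg$p_neuro_before_hiv) "neuro_before_hiv"
      else if (u < cfg$p_neuro_before_hiv + cfg$p_missing_demo) "missing_demo"
      else if (u < cfg$p_neuro_before_hiv + cfg$p_missing_demo +
                 cfg$p_malignancy) "malignancy"
      else "none"
    fail_visit <- runif(1) < cfg$p_fail_visit_rule

    # HIV case stream
    if (fail_visit) {
      hiv_days_v <- hiv_day + c(0L, 40L)
      hiv_set <- c("outpatient", "outpatient")
    } else if (runif(1) < 0.3) {
      hiv_days_v <- hiv_day
      hiv_set <- "inpatient"
    } else {
      hiv_days_v <- hiv_day + c(0L, 30L + floor(runif(1, 0, 60)),
                                150L + floor(runif(1, 0, 150)))
      hiv_set <- rep("outpatient", 3)
    }
    hiv_codes_v <- sample(hiv_pool, length(hiv_days_v), replace = TRUE)

    # comorbidity before HIV
    k_cci <- sample(cci_counts, 1, prob = cfg$cci_count_probs)
    k_cci <- min(k_cci, length(cci_palette))
    cci_codes_v <- if (k_cci > 0) sample(cci_palette, k_cci) else character()
    cci_days_v <- if (k_cci > 0)
      hiv_day - floor(runif(k_cci, 30, 700)) else integer()
    cci_group <- if (k_cci == 0) "0" else if (k_cci <= 2) "1-2" else "ge3"

    # neurological disease
    has_neuro <- runif(1) < cfg$p_neuro_given_hiv
    neuro_day <- NA_integer_
    if (plant == "neuro_before_hiv") {
      has_neuro <- TRUE
      neuro_day <- hiv_day - floor(runif(1, 60, 400))
    } else if (has_neuro) {
      dur <- max(30, round(exp(rnorm(1, cfg$index_duration_lognorm[1],
                                     cfg$index_duration_lognorm[2]))))
      neuro_day <- hiv_day + as.integer(dur)
      if (neuro_day > d_end - 30L) has_neuro <- FALSE
    }
    neuro_days_v <- integer(); neuro_set <- character()
    neuro_codes_v <- character(); subtype <- NA_character_
    if (has_neuro) {
      subtype <- subtype_names[sample.int(4, 1,
                                          prob = cfg$neuro_subtype_probs)]
      if (runif(1) < 0.3) {
        neuro_days_v <- neuro_day
        neuro_set <- "inpatient"
      } else {
        neuro_days_v <- neuro_day + c(0L, 45L + floor(runif(1, 0, 60)),
                                      180L + floor(runif(1, 0, 120)))
        neuro_set <- rep("outpatient", 3)
      }
      neuro_codes_v <- sample(neuro_pool[[subtype]], length(neuro_days_v),
                              replace = TRUE)
    }

    # opportunistic infections between HIV and neuro diagnosis
    oi_days_v <- integer(); oi_codes_v <- character()
    if (has_neuro && plant != "neuro_before_hiv" && neuro_day > hiv_day + 20L) {
      hit <- runif(6) < oi_probs
      if (any(hit)) {
        oi_codes_v <- oi_codes[hit]
        oi_days_v <- hiv_day + floor(runif(sum(hit), 10,
                                           max(neuro_day - hiv_day - 1, 11)))
      }
    }

    # malignancy plant (any time in study after HIV)
    mal_days_v <- integer(); mal_codes_v <- character()
    if (plant == "malignancy") {
      anchor <- if (has_neuro) max(neuro_day, hiv_day) else hiv_day
      mal_days_v <- min(anchor + 100L, d_end - 1L)
      mal_codes_v <- "162.9"
    }

    # CHM exposure
    z_lor <- c(age_30_40 = as.numeric(band == 2),
               age_ge40 = as.numeric(band == 3),
               female = as.numeric(female),
               cci_1_2 = as.numeric(cci_group == "1-2"),
               cci_ge3 = as.numeric(cci_group == "ge3"))
    p_exp <- stats::plogis(stats::qlogis(cfg$p_chm_exposed) +
                             sum(lor * z_lor[names(lor)]))
    exposed <- has_neuro && plant != "neuro_before_hiv" &&
      runif(1) < p_exp
    chm_day_v <- integer(); chm_code_i <- integer(); chm_days_rx <- integer()
    if (exposed) {
      if (runif(1) < cd$p_heavy) {
        nv <- 1L + stats::rpois(1, cd$heavy_visits_mean - 1)
        vdays <- neuro_day + sort(sample.int(365, min(nv, 365)) - 1L)
        for (vd in vdays) {
          items <- .draw_basket(setup)
          if (length(items) == 0) next
          chm_day_v <- c(chm_day_v, rep(vd, length(items)))
          chm_code_i <- c(chm_code_i, items)
          chm_days_rx <- c(chm_days_rx,
                           pmax(1L, cat_days[items] +
                                  sample(-3:3, length(items),
                                         replace = TRUE)))
        }
      } else {
        vd <- neuro_day + sample.int(365, 1) - 1L
        item <- sample.int(length(cat_codes), 1, prob = setup$p)
        chm_day_v <- vd; chm_code_i <- item
        chm_days_rx <- sample(3:10, 1)
      }
    }
    chm_dose_v <- if (length(chm_code_i) > 0)
      pmax(0.1, round(cat_dose[chm_code_i] *
                        runif(length(chm_code_i), 0.7, 1.3), 1))
      else numeric()

    # ART dispensing during the index duration
    art_hi <- if (has_neuro && plant != "neuro_before_hiv")
      min(neuro_day, d_end) else min(hiv_day + 730L, d_end)
    n_art <- 1L + stats::rpois(1, 2)
    art_day_v <- if (art_hi > hiv_day)
      floor(runif(n_art, hiv_day, art_hi + 1)) else rep(hiv_day, n_art)
    art_class_v <- sample(c("NRTI", "PI", "NNRTI", "INSTI", "COMBINED_ART"),
                          n_art, replace = TRUE,
                          prob = c(0.30, 0.25, 0.15, 0.10, 0.20))
    art_ddd_v <- round(runif(n_art, 30, 120), 1)

    # exposure status and index date from the realized prescriptions
    chm_total <- sum(chm_days_rx)
    user <- chm_total >= 14
    index_day <- if (user) {
      .chm_index_day(chm_day_v, chm_days_rx, 14L)
    } else if (has_neuro && plant != "neuro_before_hiv") {
      neuro_day + as.integer(cfg$nonuser_lag_days)
    } else {
      hiv_day + as.integer(cfg$nonuser_lag_days)
    }

    # death from the exponential proportional-hazards law
    lp <- lhr[["chm_use"]] * user +
      lhr[["age_30_40"]] * (band == 2) + lhr[["age_ge40"]] * (band == 3) +
      lhr[["female"]] * female +
      lhr[["cci_1_2"]] * (cci_group == "1-2") +
      lhr[["cci_ge3"]] * (cci_group == "ge3")
    death_day <- NA_integer_; cause <- NA_character_; cause_code <- NA_character_
    if (index_day <= d_end) {
      t_ev <- stats::rexp(1, cfg$baseline_hazard_rate * exp(lp))
      cand <- index_day + as.integer(ceiling(t_ev))
      if (cand <= d_end) {
        death_day <- cand
        cause <- sample(cause_names, 1, prob = cfg$cause_probs)
        cause_code <- sample(cause_pool[[cause]], 1)
      }
    }

    # truncate events after death
    keep_until <- if (is.na(death_day)) d_end else death_day
    kd <- function(v) v <= keep_until
    hk <- kd(hiv_days_v); nk <- kd(neuro_days_v); ok <- kd(oi_days_v)
    mk <- kd(mal_days_v); ck <- kd(chm_day_v); ak <- kd(art_day_v)
    cck <- kd(cci_days_v)

    # recompute qualification and exposure on the surviving rows
    hiv_q <- any(hiv_set[hk] == "inpatient") ||
      sum(hiv_set[hk] == "outpatient") >= 3
    neuro_q <- any(nk) && (any(neuro_set[nk] == "inpatient") ||
                             sum(neuro_set[nk] == "outpatient") >= 3)
    chm_total_kept <- sum(chm_days_rx[ck])
    user_kept <- chm_total_kept >= 14
    identified <- hiv_q && !fail_visit && neuro_q

    missing_sex <- FALSE; missing_birth <- FALSE
    if (plant == "missing_demo") {
      if (runif(1) < 0.5) missing_sex <- TRUE else missing_birth <- TRUE
    }
    anchor_day <- if (has_neuro) neuro_day else hiv_day
    birth_day <- anchor_day - as.integer(round(age * 365.25))

    bin <- NA_character_
    if (identified) {
      bin <- if (plant == "neuro_before_hiv") "neuro_before_hiv"
        else if (plant == "missing_demo") "missing_age_sex"
        else if (chm_total_kept >= 1 && chm_total_kept < 14) "low_chm"
        else if (plant == "malignancy") "malignancy"
        else "retained"
    }

    pat[[i]] <- list(id = pid,
                     sex = if (missing_sex) NA_character_
                           else if (female) "F" else "M",
                     birth_day = if (missing_birth) NA_integer_
                                 else birth_day)
    dg_day <- c(cci_days_v[cck], hiv_days_v[hk], neuro_days_v[nk],
                oi_days_v[ok], mal_days_v[mk])
    dg_set <- c(rep("outpatient", sum(cck)), hiv_set[hk], neuro_set[nk],
                rep("outpatient", sum(ok)), rep("outpatient", sum(mk)))
    dg_code <- c(cci_codes_v[cck], hiv_codes_v[hk], neuro_codes_v[nk],
                 oi_codes_v[ok], mal_codes_v[mk])
    dia[[i]] <- list(patient_id = rep(pid, length(dg_day)), date = dg_day,
                     setting = dg_set, code = dg_code)
    rx_day <- c(chm_day_v[ck], art_day_v[ak])
    n_chm <- sum(ck)
    rx[[i]] <- list(
      patient_id = rep(pid, length(rx_day)), date = rx_day,
      class = c(rep("CHM", n_chm), art_class_v[ak]),
      product_code = c(cat_codes[chm_code_i[ck]],
                       if (any(ak)) paste0("ART_", art_class_v[ak])
                       else character()),
      product_kind = c(cat_kind[chm_code_i[ck]], rep("art", sum(ak))),
      days = c(chm_days_rx[ck], rep(30L, sum(ak))),
      daily_dose_g = c(chm_dose_v[ck], rep(NA_real_, sum(ak))),
      ddd_amount = c(rep(NA_real_, n_chm), art_ddd_v[ak]))
    if (!is.na(death_day))
      dth[[i]] <- list(patient_id = pid, date = death_day,
                       cause_code = cause_code, icd_version = 10L)
    truth[[i]] <- list(patient_id = pid, identified = identified,
                       plant = plant, bin = bin,
                       age_band = c("lt30", "30to40", "ge40")[band],
                       female = female, cci_group = cci_group,
                       chm_user = user_kept, chm_days = chm_total_kept,
                       neuro_day = neuro_day, index_day = index_day,
                       death_day = death_day, cause = cause)
  }

  as_day <- function(x) as.Date(x, origin = "1970-01-01")
  cl <- function(lst, f) unlist(lapply(lst, `[[`, f), use.names = FALSE)
  patients <- tibble::tibble(
    id = cl(pat, "id"), sex = cl(pat, "sex"),
    birth_date = as_day(cl(pat, "birth_day")))
  diagnoses <- tibble::tibble(
    patient_id = cl(dia, "patient_id"), date = as_day(cl(dia, "date")),
    setting = cl(dia, "setting"), icd_version = 9L, code = cl(dia, "code"))
  prescriptions <- tibble::tibble(
    patient_id = cl(rx, "patient_id"), date = as_day(cl(rx, "date")),
    class = cl(rx, "class"), product_code = cl(rx, "product_code"),
    product_kind = cl(rx, "product_kind"), days = as.integer(cl(rx, "days")),
    daily_dose_g = cl(rx, "daily_dose_g"), ddd_amount = cl(rx, "ddd_amount"))
  dth <- dth[!vapply(dth, is.null, logical(1))]
  deaths <- if (length(dth) > 0) {
    tibble::tibble(
      patient_id = cl(dth, "patient_id"), date = as_day(cl(dth, "date")),
      cause_code = cl(dth, "cause_code"),
      icd_version = as.integer(cl(dth, "icd_version")))
  } else {
    tibble::tibble(patient_id = character(), date = as.Date(character()),
                   cause_code = character(), icd_version = integer())
  }
  truth_tbl <- tibble::tibble(
    patient_id = cl(truth, "patient_id"),
    identified = cl(truth, "identified"), plant = cl(truth, "plant"),
    bin = cl(truth, "bin"), age_band = cl(truth, "age_band"),
    female = cl(truth, "female"), cci_group = cl(truth, "cci_group"),
    chm_user = cl(truth, "chm_user"), chm_days = cl(truth, "chm_days"),
    neuro_date = as_day(cl(truth, "neuro_day")),
    index_date = as_day(cl(truth, "index_day")),
    death_date = as_day(cl(truth, "death_day")), cause = cl(truth, "cause"))
  planted <- table(factor(truth_tbl$bin[truth_tbl$identified],
                          levels = c("neuro_before_hiv", "missing_age_sex",
                                     "low_chm", "malignancy", "retained")))
  bundle <- structure(list(
    patients = patients, diagnoses = diagnoses,
    prescriptions = prescriptions, deaths = deaths,
    provenance = list(config = cfg,
                      planted_counts = as.list(planted),
                      truth = truth_tbl)),
    class = "claims_bundle")
  validate_bundle(bundle)
  bundle
}

# running day on which cumulative prescription days first reach `threshold`,
# consuming rows in date order; returns the day after it (the index date)
.chm_index_day <- function(days_vec_dates, days_supplied, threshold = 14L) {
  o <- order(days_vec_dates)
  d <- days_vec_dates[o]; s <- days_supplied[o]
  cum <- cumsum(s)
  j <- which(cum >= threshold)[1]
  prev <- if (j == 1) 0L else cum[j - 1]
  reached <- d[j] + (threshold - prev) - 1L
  as.integer(reached + 1L)
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>", nrow(x$patients), "patients,",
      nrow(x$diagnoses), "diagnoses,", nrow(x$prescriptions),
      "prescriptions,", nrow(x$deaths), "deaths\n")
  invisible(x)
}

#' Validate a claims bundle's structural invariants
#'
#' Checks unique patient ids, foreign-key integrity, at most one death per
#' patient with no post-death events, positive prescription days, positive
#' CHM doses and ART DDD amounts, and all dates within the study window
#' when provenance is present.
#'
#' @param bundle a `claims_bundle`.
#' @return the bundle, invisibly; signals a data error on violation.
#' @export
validate_bundle <- function(bundle) {
  b <- bundle
  need <- c("patients", "diagnoses", "prescriptions", "deaths")
  if (!all(need %in% names(b)))
    stop_data("bundle is missing tables: %s",
              paste(setdiff(need, names(b)), collapse = ", "))
  if (anyDuplicated(b$patients$id))
    stop_data("duplicate patient ids")
  ids <- b$patients$id
  for (tb in c("diagnoses", "prescriptions", "deaths")) {
    bad <- setdiff(unique(b[[tb]]$patient_id), ids)
    if (length(bad) > 0)
      stop_data("table %s: unresolved patient ids (e.g. %s)", tb, bad[1])
  }
  if (anyDuplicated(b$deaths$patient_id))
    stop_data("more than one death row for a patient")
  if (nrow(b$prescriptions) > 0) {
    if (any(b$prescriptions$days < 1))
      stop_data("prescription days must be >= 1")
    chm <- b$prescriptions$class == "CHM"
    if (any(is.na(b$prescriptions$daily_dose_g[chm])) ||
        any(b$prescriptions$daily_dose_g[chm] <= 0))
      stop_data("CHM rows must have daily_dose_g > 0")
    art <- !chm
    if (any(is.na(b$prescriptions$ddd_amount[art])) ||
        any(b$prescriptions$ddd_amount[art] <= 0))
      stop_data("ART rows must have ddd_amount > 0")
  }
  if (nrow(b$deaths) > 0) {
    dd <- setNames(as.integer(b$deaths$date), b$deaths$patient_id)
    for (tb in c("diagnoses", "prescriptions")) {
      t <- b[[tb]]
      m <- dd[t$patient_id]
      bad <- !is.na(m) & as.integer(t$date) > m
      if (any(bad))
        stop_data("table %s: events dated after death (e.g. patient %s)",
                  tb, t$patient_id[bad][1])
    }
  }
  invisible(bundle)
}

#' Generate a bare transaction stream
#'
#' Lightweight fixture generator for the co-prescription miner: draws
#' patient-day baskets from a catalog with optional planted pairs until
#' `n_transactions` non-empty baskets exist. Each basket is one transaction
#' under its own synthetic patient id.
#'
#' @param catalog herb catalog tibble (see [default_herb_catalog()]).
#' @param planted_pairs tibble `x`, `y`, `co_boost`, or `NULL`.
#' @param n_transactions number of (non-empty) transactions to emit.
#' @param seed integer seed.
#' @return tibble of CHM prescription rows.
#' @export
generate_transactions_only <- function(catalog, planted_pairs = NULL,
                                       n_transactions, seed = 1L) {
  if (missing(n_transactions) || n_transactions < 1)
    stop_config("`n_transactions` must be >= 1")
  cat <- tibble::as_tibble(catalog)
  if (nrow(cat) == 0) stop_config("`herb_catalog` must not be empty")
  if (!is.null(planted_pairs) && nrow(tibble::as_tibble(planted_pairs)) > 0) {
    pp <- tibble::as_tibble(planted_pairs)
    miss <- setdiff(c(pp$x, pp$y), cat$code)
    if (length(miss) > 0)
      stop_config("`planted_pairs` references products not in catalog: %s",
                  paste(unique(miss), collapse = ", "))
  } else pp <- NULL
  setup <- .basket_setup(cat, pp)
  set.seed(as.integer(seed))
  out_code <- vector("list", n_transactions)
  made <- 0L; attempts <- 0L
  max_attempts <- 1000L * n_transactions
  while (made < n_transactions) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop_config("catalog too sparse: could not fill %d transactions",
                  n_transactions)
    items <- .draw_basket(setup)
    if (length(items) == 0) next
    made <- made + 1L
    out_code[[made]] <- items
  }
  len <- lengths(out_code)
  tid <- rep(seq_len(n_transactions), len)
  items <- unlist(out_code)
  base_day <- as.integer(as.Date("2014-01-01"))
  tibble::tibble(
    patient_id = sprintf("T%07d", tid),
    date = as.Date(base_day + (tid %% 365L), origin = "1970-01-01"),
    class = "CHM",
    product_code = cat$code[items],
    product_kind = cat$kind[items],
    days = pmax(1L, as.integer(cat$mean_days_rx[items])),
    daily_dose_g = cat$mean_dose_g[items],
    ddd_amount = NA_real_)
}

#' Write a claims bundle to CSV files
#'
#' Writes `patients.csv`, `diagnoses.csv`, `prescriptions.csv`,
#' `deaths.csv` (UTF-8, ISO-8601 dates, header row) and a
#' `provenance.json` sidecar with the generator settings and planted
#' counts.
#'
#' @param bundle a `claims_bundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tb in c("patients", "diagnoses", "prescriptions", "deaths")) {
    write.csv(bundle[[tb]], file.path(dir, paste0(tb, ".csv")),
              row.names = FALSE, na = "")
  }
  prov <- bundle$provenance
  if (!is.null(prov)) {
    cfg <- prov$config
    cfg$herb_catalog <- as.data.frame(cfg$herb_catalog)
    cfg$planted_pairs <- as.data.frame(cfg$planted_pairs)
    cfg$study_start <- format(cfg$study_start)
    cfg$study_end <- format(cfg$study_end)
    jsonlite::write_json(
      list(config = unclass(cfg), planted_counts = prov$planted_counts),
      file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  invisible(dir)
}

#' Read a claims bundle from CSV files
#'
#' Inverse of [write_bundle()] (the provenance truth table is not
#' round-tripped). The schema is validated on read.
#'
#' @param dir directory containing the four CSV tables.
#' @return a `claims_bundle`.
#' @export
read_bundle <- function(dir) {
  rd <- function(nm, classes) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(f)) stop_data("missing table file: %s", f)
    tibble::as_tibble(read.csv(f, colClasses = classes, na.strings = ""))
  }
  patients <- rd("patients", c(id = "character", sex = "character",
                               birth_date = "Date"))
  diagnoses <- rd("diagnoses", c(patient_id = "character", date = "Date",
                                 setting = "character",
                                 icd_version = "integer", code = "character"))
  prescriptions <- rd("prescriptions",
                      c(patient_id = "character", date = "Date",
                        class = "character", product_code = "character",
                        product_kind = "character", days = "integer",
                        daily_dose_g = "numeric", ddd_amount = "numeric"))
  deaths <- rd("deaths", c(patient_id = "character", date = "Date",
                           cause_code = "character",
                           icd_version = "integer"))
  prov_file <- file.path(dir, "provenance.json")
  prov <- if (file.exists(prov_file)) jsonlite::read_json(prov_file) else NULL
  bundle <- structure(list(patients = patients, diagnoses = diagnoses,
                           prescriptions = prescriptions, deaths = deaths,
                           provenance = prov),
                      class = "claims_bundle")
  validate_bundle(bundle)
  bundle
}
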