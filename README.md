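# herbsurv

Claims-based survival and co-prescription analysis of Chinese herbal
medicine (CHM) cohorts.

Retrospective cohort studies built on national claims databases ask, for
a chronic disease population, whether patients exposed to adjunct CHM
therapy die at a lower rate than comparable unexposed patients, and
which herbal products are co-prescribed as a core pattern. The
motivating setting is HIV/AIDS patients who develop neurological disease
(CNS infections, cognitive disorders, vasculopathy, peripheral
neuropathy). The raw material is four flat claims tables — patients,
diagnosis events, prescriptions, deaths — and the analysis is:

1. **Cohort construction.** HIV/AIDS cases require ≥1 inpatient or ≥3
   outpatient visits with ICD-9-CM 042–044 within a year (onset
   2010–2017), then a neurological diagnosis under the same visit rule.
   An exclusion cascade removes neuro-before-HIV patients, missing
   demographics, patients with 1–13 cumulative CHM days in the year
   after neurological diagnosis, and any malignancy. CHM users (≥14
   cumulative days) are indexed the day after the 14th prescription day;
   non-users are landmarked at the median user lag. Covariates: age
   band, sex, Charlson comorbidity index (Quan ICD-9-CM mapping),
   per-class antiretroviral DDDs, opportunistic-infection flags.
2. **1:2 propensity matching** (logistic model on sex, age band, CCI,
   index duration; greedy nearest-neighbour on the logit scale, caliper
   0.2 SD, without replacement).
3. **Survival analysis**, written from first principles: Kaplan–Meier
   with Greenwood variance, two-group log-rank, and Cox proportional
   hazards (Newton–Raphson, Efron ties) — crude and adjusted
   (CHM + age band + sex + Charlson group), for all-cause mortality and
   for infections/parasites + circulatory mortality with other-cause
   deaths removed.
4. **Co-prescription mining.** Transactions are patient-days; for a
   product pair, support = 100·f(X∧Y)/N, confidence(X→Y) =
   100·f(X∧Y)/f(X), lift = confidence/p(Y). Rules are oriented with the
   rarer product as antecedent, ranked by joint frequency, and assembled
   into a network whose connected components are the CHM clusters.

Because real claims data of this kind are access-restricted, the package
ships a seeded synthetic claims generator (`claims_config()`,
`generate_bundle()`) that plants known truths — proportional-hazards
effects, co-prescription pair boosts, exclusion-cascade traffic — so
every stage can be tested against what was planted.

## Worked example

```r
library(herbsurv)

cfg <- claims_config(n_patients = 5000, seed = 42)
b   <- generate_bundle(cfg)
built <- build_cohort(b)
built$exclusions
#> neuro_before_hiv  missing_age_sex          low_chm       malignancy death_before_index
#>              251                7              160                5                  0

co <- built$cohort           # 1026 retained subjects, 278 CHM users
ps <- fit_logistic_ps(co)
ms <- match_1_to_k(ps, k = 2, seed = 42)
ms
#> <matched_set> 274 users matched 1: 2 ( 4 unmatched ), caliper 0.06917

mc  <- matched_cohort(co, ms)
res <- run_mortality_analysis(mc, "all_cause")
res$adjusted
#> <cox_fit> n = 822, events = 175, ties = efron, iter = 6
#>              coef     HR lower95 upper95     se      p
#> chm_use   -1.4493 0.2347  0.1482  0.3719 0.2348 0.0000
#> age_30_40  0.5946 1.8123  1.2183  2.6959 0.2026 0.0033
#> age_ge40   1.6183 5.0447  3.3114  7.6851 0.2148 0.0000
#> female     1.9231 6.8419  3.9450 11.8660 0.2809 0.0000
#> cci_1_2    0.4038 1.4975  1.0178  2.2034 0.1970 0.0404
#> cci_ge3    1.1069 3.0250  1.8164  5.0378 0.2602 0.0000
```

The matched cohort of 822 subjects had 175 deaths; the adjusted hazard
ratio for CHM use, 0.23 (95% CI 0.15–0.37), recovers the planted
protective effect (true HR 0.30, within Monte-Carlo error at this cohort
size), and the age, sex and comorbidity effects recover their planted
values in the same way. At this scale the 5,000-patient bundle holds
only ~1,700 CHM transactions, so the co-prescription statistics are
noisy; rule arithmetic itself is exact. Feeding the transaction counts
of a published top rule (antecedent in 399 transactions, consequent in
557, jointly in 145, of 7,376 total):

```r
s <- rule_stats(freq_x = 399, freq_y = 557, freq_xy = 145, n_total = 7376)
round_half_up(c(s$support_pct, s$confidence_pct, s$lift), 2)
#> [1]  1.97 36.34  4.81
```

i.e. the pair co-occurs in 1.97% of all prescriptions, 36.34% of
antecedent prescriptions include the consequent, and the pair co-occurs
4.81 times more often than independence predicts.

`run_pipeline(cfg, "out/")` runs everything above end to end and writes
cohort.csv, exclusions.json, matched.csv, balance tables, Kaplan–Meier
curves, crude/adjusted Cox tables, rules.csv, the network as GraphML +
JSON, and an md5 manifest. A thin command-line wrapper lives at
`inst/cli/herbsurv.R`.

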