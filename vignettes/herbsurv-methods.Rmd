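---
title: "Methods: claims-based survival and co-prescription analysis with herbsurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: claims-based survival and co-prescription analysis with herbsurv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbsurv)
```

## The study design herbsurv implements

herbsurv packages the analysis pattern of claims-based retrospective
cohort studies of Chinese herbal medicine (CHM) use, with HIV/AIDS
patients who develop neurological disease as the motivating cohort. The
pipeline has five stages, each an exported module: a synthetic claims
generator, a cohort builder, propensity-score matching, survival
analysis, and co-prescription rule mining with a network summary. Real
national claims databases of this kind are access-restricted, so the
generator is a first-class component: it produces data with exactly the
statistical structure the downstream stages assume, which is what makes
planted-truth recovery tests possible.

## Cohort construction

**Case rules.** A diagnosis qualifies when, within 365 days of a matched
diagnosis event, the patient has at least one inpatient or at least three
outpatient visits carrying a matching code (`diagnosis_onset()`). Onset
is the date of the first matched event opening a qualifying window. The
HIV/AIDS case set is ICD-9-CM 042–044 with onset restricted to calendar
years 2010–2017; the four neurological subtype sets (CNS infection,
cognitive disorder, vasculopathy, peripheral neuropathy) are shipped as
editable YAML files under `inst/extdata/codes/`. Code matching is
prefix-based at the rubric level — a listed 3-digit code includes all its
sub-rubrics — which is the convention of Taiwanese claims research, where
these lists originate.

**Exclusion cascade.** Identified patients pass through, in order:
neurological disease before HIV diagnosis; missing age or sex; 1–13
cumulative CHM prescription days in the year after neurological
diagnosis; any malignancy (ICD-9-CM 140–208) during the study period.
Each excluded patient lands in the first applicable bin, so bins are
disjoint and, together with the retained cohort, partition the identified
patients.

**Exposure and index date.** Patients accumulating at least 14 CHM
prescription days in the year after neurological diagnosis are CHM users;
their index date is the day after the running total of prescription days
first reaches 14 (rows consumed in date order, a d-day prescription
covering its start date and the d − 1 following days). "At least 14"
resolves an ambiguity between an exclusion rule phrased as "fewer than
14" and a user definition phrased as "more than 14"; the threshold is the
`chm_user_min_days` argument if a different reading is wanted. Non-users
have no CHM at any time in the study period, and the source design never
says when their follow-up clock starts. We landmark them at the
neurological diagnosis date plus the cohort median user lag
(`nonuser_index = "median_lag"`, or a fixed day count). This avoids
granting non-users follow-up from an undefined date and limits immortal
time bias: a user must survive to their own index date, so non-users are
required to survive to a comparable landmark, and non-users dying before
it are excluded under an explicit `death_before_index` bin appended after
the four cascade bins.

**Covariates.** Age band (<30, 30–40, ≥40) is computed at neurological
diagnosis; the reference date is not stated in the source design, and the
neurological diagnosis is the event that defines the cohort. The Charlson
comorbidity index uses Quan's ICD-9-CM mapping, shipped as a plain CSV,
scored on diagnoses strictly before HIV onset with the standard
hierarchy (complicated diabetes over uncomplicated, severe over mild
liver disease, metastatic over localised cancer). Status V-codes are
omitted from the shipped table because the code grammar is numeric; this
drops only transplant/dialysis markers, which matter little before an
HIV diagnosis in this age range. The Charlson comorbidity *number* —
the covariate used for adjustment, grouped 0 / 1–2 / ≥3 — is the count of
distinct categories after the hierarchy. Cumulative antiretroviral
defined daily doses are summed per class (NRTI, PI, NNRTI, INSTI,
combined) over the index duration (HIV to neurological diagnosis).
Opportunistic-infection flags are any matching code before the index
date.

**Cause of death.** Death codes map to eight categories through
chapter-level ranges (infections and parasites; circulatory; endocrine,
nutritional and metabolic; viral hepatitis and liver; respiratory;
genitourinary; neoplasms; other), with hepatitis/liver tested first
because its codes nest inside the infectious-disease chapter. The exact
code list behind the original categorisation is not public; chapter
ranges are the transparent reconstruction. The cause-specific analysis
(`cause_specific_subset()`) keeps deaths from the selected categories as
events, keeps censored subjects, and *removes* subjects dying of other
causes — deliberately reproducing the source design rather than treating
other-cause death as censoring or fitting a competing-risks model. A
Fine–Gray analysis is out of scope; the removal design overstates
absolute risk but is the comparison the anchor estimates refer to.

## Propensity matching

Exposure is modelled by from-scratch Newton–Raphson logistic regression
of CHM use on sex, age band (indicator-coded, since the analysis treats
age in bands), CCI score and index duration; convergence requires the
maximum score component below 1e−8. Matching is greedy 1:2
nearest-neighbour on the logit of the propensity score, without
replacement, users processed in random order under the run seed, with a
caliper of 0.2 standard deviations of the logit score — the standard
recommendation when no caliper is reported. Users lacking two in-caliper
controls are dropped, which reproduces the kind of user attrition seen
in matched claims cohorts. `balance_table()` reports standardized mean
differences before and after matching; under the generator's planted
confounding, post-matching SMDs fall below 0.1.

## Survival machinery

The estimators are written from first principles and checked against an
established implementation in the test suite:

* **Kaplan–Meier** product-limit estimate over distinct event times with
  Greenwood variance; subjects censored at an event time remain at risk
  there.
* **Log-rank** two-group statistic with hypergeometric variance,
  referred to chi-square with one degree of freedom.
* **Cox proportional hazards** by Newton–Raphson on the partial
  likelihood with step-halving; Efron tie handling by default (ties are
  ubiquitous with day-resolution claims), Breslow optionally — the two
  coincide exactly on tie-free data. Convergence requires the largest
  score component below 1e−9 (at most 60 iterations); Wald confidence
  intervals use the inverse observed information with the 0.975 normal
  quantile. Matched-set correlation is ignored in the default fit, as in
  the source analyses, which report plain Cox models after matching.

The adjusted model covariates are CHM use, age band, sex and Charlson
comorbidity number group; `adjust_interval = TRUE` adds the days from
neurological diagnosis to index date (the sensitivity adjustment), and
`subgroup = "cns_infection"` restricts to a neurological subtype.
Follow-up of zero days (death on the index date) is set to half a day so
the risk set is well defined.

## Co-prescription mining

A *transaction* is one patient-day prescription event; its item set is
the distinct CHM products dispensed that day. This is the only reading
under which the printed support formula (joint frequency over total
prescriptions) is coherent with a total prescription count. For a
product pair, support = 100·freq(X∧Y)/N, confidence(X→Y) =
100·freq(X∧Y)/freq(X), and lift = confidence/p(Y); lift is symmetric in
the pair and exceeds 1 exactly when the joint count exceeds its
independence expectation. Rules are oriented with the rarer product as
antecedent — the direction that maximises confidence, and the one
consistent with every printed example — with lexicographic tie-breaks.
Only pairs are mined; higher-order itemsets are not reported by the
analyses this package mirrors, and the catalog sizes involved make
exhaustive pair counting trivial, so no Apriori-style pruning is needed.
Percent columns and lift are rendered at two decimals with half-up
rounding, matching the printed tables; full precision is kept
internally. The network places products as nodes (sized by prescription
frequency, typed single herb vs formula, carrying total dispensed grams)
and supra-threshold pairs as edges (support, lift, joint frequency);
clusters are connected components, which reproduce the known two-cluster
structure of the motivating analysis — a community-detection algorithm
would be needed only for denser rule sets.

## The synthetic claims generator

`claims_config()` holds every data-generating parameter. The defaults
describe a plausible Taiwanese HIV/AIDS claims cohort observed
2008–2019; where the motivating study reports a quantity, the default
matches it, and where it does not, the value is a documented choice of
realism:

* **Demographics.** 4.5% female; age bands <30/30–40/≥40 with
  probabilities 0.33/0.38/0.29 (the reported cohort mix); age drawn
  uniformly within band and anchored at the neurological diagnosis date.
* **Disease flow.** HIV onset uniform over 2010–2017, qualifying streams
  emitted as one inpatient or three outpatient visits (2% of patients
  deliberately fail the rule); 30% of patients develop neurological
  disease after a log-normal index duration matched to mean 786 / SD 804
  days (the reported moments; the distribution family is an assumption,
  flagged as such); subtype mix 0.45/0.32/0.10/0.13, weighted toward CNS
  infections and cognitive disorders as reported.
* **Exposure.** Baseline CHM exposure probability 0.40, tilted on the
  logit scale by `exposure_log_or` (users younger, slightly higher CCI —
  the direction of the reported pre-match imbalance); 60% of exposed
  patients follow a heavy prescription law (mean six CHM visits in the
  first year) that lands at or above the 14-day threshold, the rest a
  single light visit below it, so the low-CHM exclusion bin is always
  populated.
* **Baskets.** Each visit draws products from the herb catalog
  (eleven named products at the reported marginal frequencies plus forty
  background herbs standing in for the long tail of the pharmacopeia,
  keeping almost every visit non-empty). Planted pairs are drawn through
  a four-outcome scheme that fixes the joint probability at
  `co_boost · pX · pY` while preserving both marginals exactly;
  `co_boost = 1` is independence. When pairs share a product the draws
  compose sequentially and shared marginals inflate — the default five
  pairs (which mirror the known top co-prescriptions, boosts set to
  their lifts) share three products, so exact-recovery properties are
  stated for product-disjoint pairs.
* **Mortality.** Death times are exponential with rate
  `baseline_hazard_rate · exp(lp)`, `lp` the sum of true log hazard
  ratios over CHM use, age band, sex and CCI group; defaults equal the
  motivating study's adjusted estimates (CHM ln 0.30, age ≥40 ln 3.79,
  female ln 2.80, …). The baseline rate 1.2e−4 events/person-day gives a
  reference-stratum annual mortality near 4% and cohort-level five-year
  mortality around 25–30%, severe but defensible for this population,
  and large enough that a 20,000-patient bundle yields several hundred
  matched-cohort deaths — the scale at which the hazard-ratio recovery
  checks are statistically meaningful. Each subject's death clock starts
  at their own index date (users: the 14-day accrual point; non-users: a
  90-day landmark), so exposure status never depends on surviving
  exposure accrual; with the memoryless exponential law the cohort
  builder's slightly different landmark does not bias the hazard ratio.
  Causes are drawn so that roughly half of deaths are infectious or
  circulatory, as reported. Events after death are truncated, and the
  generator recomputes every eligibility attribute on the truncated
  stream so its planted bookkeeping matches what the tables actually
  contain.
* **Determinism.** Every patient draws from a substream seeded by a
  fixed counter scheme on the master seed, so bundles are byte-identical
  under the same config and enlarging the cohort never perturbs earlier
  patients.

What the generator does *not* emulate: care-seeking behaviour, clinic
specialties, seasonal prescribing, dose titration, ICD-10-era diagnosis
coding, or real NHIRD field layouts. Passing recovery tests on this
generator shows the pipeline is correct and calibrated under its stated
assumptions — proportional hazards, exposure defined by a day-count
threshold, transaction-level co-prescription — not that those
assumptions hold in any particular real database.

## Numerical choices and degenerate inputs

Rounding for table rendering is half-up at two decimals (base `round()`
is banker's). The logistic and Cox fitters detect singular information
matrices (naming collinear covariates), perfect separation, and monotone
likelihood (|coefficient| > 15 triggers a warning). Zero expected cells
fail the chi-square test with advice to merge categories; zero pooled
variance fails the t-test. Empty prescription streams yield empty
transaction sets; thresholds excluding all network nodes yield an empty
graph with a warning. The pipeline orchestrator removes partial outputs
on failure and writes an md5 manifest of every artifact, so identical
config + seed reproduces identical checksums.

## Problem sizes used in the shipped checks

The test suite exercises oracle equivalence on 200–500-subject fixtures
and 10,000-transaction streams, log-rank type-I calibration on 2,000
null replicates of 100 subjects, adjusted log-hazard-ratio bias on 100
replicates of 5,000 subjects, and end-to-end hazard-ratio recovery on a
single 20,000-patient bundle matched 1:2 — sizes at which Monte-Carlo
error is small relative to the tolerances being asserted while the whole
suite stays comfortably runnable on a laptop.

## Known limitations

* The cause-of-death categorisation uses chapter ranges, not the
  original (non-public) code list; rare codes may be classified
  differently.
* The cause-specific design removes other-cause deaths, so its absolute
  risks are not interpretable as crude cumulative incidences; only the
  relative comparisons are meaningful.
* Greedy matching without replacement depends on the processing order
  (seeded); optimal or full matching is out of scope.
* The generator's exponential event law cannot represent
  non-proportional hazards; a Weibull shape knob would be the natural
  extension.
* Planted-pair joint probabilities are exact only for product-disjoint
  pairs.
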