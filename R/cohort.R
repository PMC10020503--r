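# Cohort construction: case identification, exclusion cascade, exposure and
# index-date assignment, covariate derivation, cause-of-death
# categorisation.

#' Earliest qualifying onset date under the visit rule
#'
#' A diagnosis qualifies when, within `window_days` of some matched event,
#' there is at least `min_inpatient` inpatient visit or at least
#' `min_outpatient` outpatient visits carrying a matching code. The onset is
#' the date of the first matched event opening a qualifying window.
#'
#' @param events data frame with columns `date`, `setting`, `code`.
#' @param cs a [code_set()].
#' @param window_days window length in days (half-open, `[d, d + window)`).
#' @param min_inpatient,min_outpatient visit-count thresholds.
#' @return a `Date`, or `NULL` when no window qualifies.
#' @export
diagnosis_onset <- function(events, cs, window_days = 365,
                            min_inpatient = 1, min_outpatient = 3) {
  if (is.null(events) || nrow(events) == 0) return(NULL)
  hit <- match_code(events$code, cs)
  if (!any(hit)) return(NULL)
  ev <- events[hit, , drop = FALSE]
  ev <- ev[order(ev$date), , drop = FALSE]
  d <- as.integer(ev$date)
  inpt <- ev$setting == "inpatient"
  for (j in seq_along(d)) {
    w <- d >= d[j] & d < d[j] + window_days
    if (sum(w & inpt) >= min_inpatient ||
        sum(w & !inpt) >= min_outpatient) {
      return(as.Date(d[j], origin = "1970-01-01"))
    }
  }
  NULL
}

#' Classify neurological disease onset and subtypes
#'
#' Applies [diagnosis_onset()] per subtype code set to events dated on or
#' after `after`. The neurological onset is the earliest qualifying subtype
#' onset; the subtype set contains every subtype qualifying at any time.
#'
#' @param events data frame with columns `date`, `setting`, `code`.
#' @param after restrict to events on/after this date (HIV onset); `NULL`
#'   for no restriction.
#' @param subtype_sets named list of [code_set()]s, one per subtype.
#' @param ... passed to [diagnosis_onset()].
#' @return list with `neuro_date` (`Date` or `NULL`) and `subtypes`
#'   (character vector, possibly empty).
#' @export
classify_neuro <- function(events, after = NULL, subtype_sets, ...) {
  ev <- events
  if (!is.null(after) && nrow(ev) > 0)
    ev <- ev[ev$date >= after, , drop = FALSE]
  onsets <- lapply(subtype_sets, function(cs) diagnosis_onset(ev, cs, ...))
  has <- !vapply(onsets, is.null, logical(1))
  if (!any(has)) return(list(neuro_date = NULL, subtypes = character()))
  list(neuro_date = min(do.call(c, onsets[has])),
       subtypes = names(subtype_sets)[has])
}

#' Cumulative CHM prescription days in a window
#'
#' Sums the `days` column over CHM prescriptions dated in
#' `[start, start + window_days)`. Overlapping prescriptions are summed,
#' not merged.
#'
#' @param prescriptions data frame of CHM rows with `date` and `days`.
#' @param start window start date.
#' @param window_days window length.
#' @return integer day count.
#' @export
cumulative_chm_days <- function(prescriptions, start, window_days = 365) {
  if (is.null(prescriptions) || nrow(prescriptions) == 0) return(0L)
  if (any(prescriptions$days < 0)) stop_data("negative prescription days")
  d <- as.integer(prescriptions$date)
  s <- as.integer(as.Date(start))
  in_win <- d >= s & d < s + window_days
  as.integer(sum(prescriptions$days[in_win]))
}

#' Assign CHM exposure status and (for users) the index date
#'
#' Cumulative CHM days of at least `min_days` in the year after
#' neurological diagnosis defines a user, whose index date is the day after
#' the running total of prescription days first reaches `min_days`.
#' Patients with no CHM at any time are non-users (their index date is
#' assigned at cohort level, see [build_cohort()]); patients with 1 to
#' `min_days - 1` days are flagged for exclusion.
#'
#' @param chm_prescriptions CHM rows for one patient (`date`, `days`).
#' @param neuro_date the neurological diagnosis date.
#' @param min_days user threshold (default 14).
#' @param window_days accrual window (default 365).
#' @return list with `status` (`"chm_user"`, `"non_user"`,
#'   `"exclude_low_chm"`) and `index_date` (`Date` or `NULL`).
#' @export
assign_exposure <- function(chm_prescriptions, neuro_date, min_days = 14,
                            window_days = 365) {
  total_any <- if (is.null(chm_prescriptions)) 0L
               else nrow(chm_prescriptions)
  days_in_win <- cumulative_chm_days(chm_prescriptions, neuro_date,
                                     window_days)
  if (days_in_win >= min_days) {
    s <- as.integer(as.Date(neuro_date))
    d <- as.integer(chm_prescriptions$date)
    in_win <- d >= s & d < s + window_days
    idx <- .chm_index_day(d[in_win], chm_prescriptions$days[in_win],
                          as.integer(min_days))
    return(list(status = "chm_user",
                index_date = as.Date(idx, origin = "1970-01-01")))
  }
  if (total_any == 0) return(list(status = "non_user", index_date = NULL))
  list(status = "exclude_low_chm", index_date = NULL)
}

#' Charlson comorbidity index before a reference date
#'
#' Scores diagnoses strictly before `before` against the shipped Quan
#' ICD-9-CM Charlson mapping. Standard hierarchy rules apply (complicated
#' diabetes supersedes uncomplicated, severe liver supersedes mild,
#' metastatic disease supersedes localised malignancy). The comorbidity
#' *number* is the count of distinct categories after the hierarchy,
#' grouped 0 / 1--2 / >=3.
#'
#' @param events diagnosis rows (`date`, `code`).
#' @param before reference date (HIV onset); only earlier events count.
#' @param map Charlson mapping tibble (default [charlson_map()]).
#' @return list with `score` (weighted sum), `n_categories`, and `group`
#'   (`"0"`, `"1-2"`, `"ge3"`).
#' @export
compute_cci <- function(events, before, map = charlson_map()) {
  prior <- if (is.null(events) || nrow(events) == 0) events
           else events[events$date < as.Date(before), , drop = FALSE]
  sets <- .charlson_sets(map)
  cats <- character()
  if (!is.null(prior) && nrow(prior) > 0) {
    for (cat_name in names(sets)) {
      if (any(match_code(prior$code, sets[[cat_name]])))
        cats <- c(cats, cat_name)
    }
  }
  if (all(c("diabetes", "diabetes_complicated") %in% cats))
    cats <- setdiff(cats, "diabetes")
  if (all(c("mild_liver", "severe_liver") %in% cats))
    cats <- setdiff(cats, "mild_liver")
  if (all(c("malignancy", "metastatic") %in% cats))
    cats <- setdiff(cats, "malignancy")
  w <- unique(map[, c("category", "weight")])
  score <- sum(w$weight[match(cats, w$category)])
  k <- length(cats)
  list(score = as.numeric(score), n_categories = k,
       group = if (k == 0) "0" else if (k <= 2) "1-2" else "ge3")
}

# compile (and cache) one code_set per Charlson category
.charlson_sets <- function(map) {
  if (!is.null(.charlson_env$sets) && identical(.charlson_env$sets_map, map))
    return(.charlson_env$sets)
  sets <- lapply(split(map$pattern, map$category), function(p) {
    code_set("charlson", p)
  })
  .charlson_env$sets <- sets
  .charlson_env$sets_map <- map
  sets
}

#' Cumulative antiretroviral DDDs per class over an interval
#'
#' @param art_rows prescription rows with `class` and `ddd_amount`.
#' @param from,to inclusive date interval (the index duration).
#' @return named numeric vector over NRTI, PI, NNRTI, INSTI, COMBINED_ART
#'   plus `total`.
#' @export
cumulative_ddd <- function(art_rows, from, to) {
  classes <- c("NRTI", "PI", "NNRTI", "INSTI", "COMBINED_ART")
  out <- setNames(numeric(length(classes)), classes)
  if (!is.null(art_rows) && nrow(art_rows) > 0) {
    if (as.Date(from) > as.Date(to)) stop_data("`from` must be <= `to`")
    keep <- art_rows$date >= as.Date(from) & art_rows$date <= as.Date(to) &
      art_rows$class %in% classes
    if (any(keep)) {
      agg <- tapply(art_rows$ddd_amount[keep], art_rows$class[keep], sum)
      out[names(agg)] <- agg
    }
  }
  c(out, total = sum(out))
}

#' Build the analysis cohort from a claims bundle
#'
#' Applies, in order: the HIV/AIDS case rule (1 inpatient or 3 outpatient
#' visits within a year, onset within `hiv_onset_years`); the neurological
#' disease case rule; then the exclusion cascade — neurological disease
#' before HIV, missing age or sex, 1--13 cumulative CHM days in the year
#' after neurological diagnosis, any malignancy during the study period —
#' each patient falling into the first applicable bin. CHM users are
#' indexed the day after their 14th cumulative prescription day; non-users
#' are indexed at their neurological diagnosis plus the cohort median user
#' lag (a landmark; non-users dying before it fall into a final
#' `death_before_index` bin). Covariates (age band at neurological
#' diagnosis, CCI before HIV, per-class cumulative ART DDDs over the index
#' duration, opportunistic-infection flags before index) and the death
#' cause category complete each row.
#'
#' @param bundle a `claims_bundle` (or anything [validate_bundle()]
#'   accepts).
#' @param code_sets named list from [default_code_sets()].
#' @param chm_user_min_days user threshold (default 14; `>= 14` is a user).
#' @param nonuser_index `"median_lag"` (default) or a fixed day count added
#'   to the neurological diagnosis date.
#' @param hiv_onset_years allowed HIV onset calendar years.
#' @param study_end administrative censoring date.
#' @return list with `cohort` (tibble, one row per retained subject) and
#'   `exclusions` (named integer vector over the cascade bins).
#' @export
build_cohort <- function(bundle,
                         code_sets = default_code_sets(),
                         chm_user_min_days = 14,
                         nonuser_index = "median_lag",
                         hiv_onset_years = c(2010, 2017),
                         study_end = as.Date("2019-12-31")) {
  validate_bundle(bundle)
  study_end <- as.Date(study_end)
  dia_split <- split(as.data.frame(bundle$diagnoses),
                     bundle$diagnoses$patient_id)
  rx <- as.data.frame(bundle$prescriptions)
  chm_split <- split(rx[rx$class == "CHM", , drop = FALSE],
                     rx$patient_id[rx$class == "CHM"])
  art_split <- split(rx[rx$class != "CHM", , drop = FALSE],
                     rx$patient_id[rx$class != "CHM"])
  deaths <- bundle$deaths
  death_date <- setNames(deaths$date, deaths$patient_id)
  death_cause <- setNames(
    categorize_cause(deaths$cause_code, deaths$icd_version),
    deaths$patient_id)
  subtype_sets <- code_sets[c("cns_infection", "cognitive", "vasculopathy",
                              "peripheral_neuropathy")]
  bins <- c("neuro_before_hiv", "missing_age_sex", "low_chm", "malignancy",
            "death_before_index")
  tally <- setNames(integer(length(bins)), bins)
  rows <- list()
  pat_sex <- setNames(bundle$patients$sex, bundle$patients$id)
  pat_birth <- setNames(as.integer(bundle$patients$birth_date),
                        bundle$patients$id)

  for (pid in bundle$patients$id) {
    ev <- dia_split[[pid]]
    if (is.null(ev)) next
    hiv_date <- diagnosis_onset(ev, code_sets$hiv)
    if (is.null(hiv_date)) next
    yr <- as.integer(format(hiv_date, "%Y"))
    if (yr < hiv_onset_years[1] || yr > hiv_onset_years[2]) next
    any_neuro <- classify_neuro(ev, after = NULL, subtype_sets)
    if (is.null(any_neuro$neuro_date)) next
    # identified: HIV case with neurological disease; now the cascade
    if (any_neuro$neuro_date < hiv_date) {
      tally["neuro_before_hiv"] <- tally["neuro_before_hiv"] + 1L
      next
    }
    p_sex <- pat_sex[[pid]]
    p_birth <- pat_birth[[pid]]
    if (is.na(p_sex) || is.na(p_birth)) {
      tally["missing_age_sex"] <- tally["missing_age_sex"] + 1L
      next
    }
    post <- classify_neuro(ev, after = hiv_date, subtype_sets)
    if (is.null(post$neuro_date)) {
      # qualifies only through pre-HIV events that were not strictly
      # earlier than HIV onset; treat as neuro-before-HIV traffic
      tally["neuro_before_hiv"] <- tally["neuro_before_hiv"] + 1L
      next
    }
    neuro_date <- post$neuro_date
    chm <- chm_split[[pid]]
    exposure <- assign_exposure(chm, neuro_date,
                                min_days = chm_user_min_days)
    if (exposure$status == "exclude_low_chm") {
      tally["low_chm"] <- tally["low_chm"] + 1L
      next
    }
    if (any(match_code(ev$code, code_sets$malignancy))) {
      tally["malignancy"] <- tally["malignancy"] + 1L
      next
    }
    cci <- compute_cci(ev, hiv_date)
    age <- floor((as.integer(neuro_date) - p_birth) / 365.25)
    rows[[length(rows) + 1L]] <- list(
      patient_id = pid, sex = p_sex,
      age = age,
      age_band = if (age < 30) "lt30" else if (age < 40) "30to40"
                 else "ge40",
      hiv_date = hiv_date, neuro_date = neuro_date,
      neuro_subtypes = paste(post$subtypes, collapse = ";"),
      index_duration_days = days_between(hiv_date, neuro_date),
      chm_user = exposure$status == "chm_user",
      index_date = if (is.null(exposure$index_date)) as.Date(NA)
                   else exposure$index_date,
      cci_score = cci$score, cci_n = cci$n_categories,
      cci_group = cci$group)
  }

  cohort <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  if (nrow(cohort) == 0)
    return(list(cohort = cohort, exclusions = tally))

  # landmark index date for non-users
  user_lag <- days_between(cohort$neuro_date[cohort$chm_user],
                           cohort$index_date[cohort$chm_user])
  lag_days <- if (identical(nonuser_index, "median_lag")) {
    if (length(user_lag) > 0) as.integer(round(median(user_lag))) else 0L
  } else as.integer(nonuser_index)
  nu <- !cohort$chm_user
  cohort$index_date[nu] <- cohort$neuro_date[nu] + lag_days

  # deaths, follow-up, per-class DDDs, opportunistic infections
  dd <- death_date[cohort$patient_id]
  cc <- death_cause[cohort$patient_id]
  died <- !is.na(dd)
  pre_index_death <- died & dd < as.integer(cohort$index_date)
  if (any(pre_index_death)) {
    tally["death_before_index"] <- sum(pre_index_death)
    cohort <- cohort[!pre_index_death, , drop = FALSE]
    dd <- dd[!pre_index_death]; cc <- cc[!pre_index_death]
    died <- died[!pre_index_death]
  }
  cohort$event <- died
  cohort$followup_days <- ifelse(
    died, as.integer(dd) - as.integer(cohort$index_date),
    as.integer(study_end) - as.integer(cohort$index_date))
  cohort$cause_category <- ifelse(died, cc, "none")

  ddd_mat <- t(vapply(seq_len(nrow(cohort)), function(r) {
    cumulative_ddd(art_split[[cohort$patient_id[r]]],
                   cohort$hiv_date[r], cohort$neuro_date[r])
  }, numeric(6)))
  colnames(ddd_mat) <- paste0("ddd_",
                              tolower(c("NRTI", "PI", "NNRTI", "INSTI",
                                        "COMBINED_ART", "total")))
  cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(ddd_mat))

  oi_sets <- code_sets$opportunistic
  oi_mat <- t(vapply(seq_len(nrow(cohort)), function(r) {
    ev <- dia_split[[cohort$patient_id[r]]]
    pre <- ev[ev$date < cohort$index_date[r], , drop = FALSE]
    vapply(oi_sets, function(cs) any(match_code(pre$code, cs)), logical(1))
  }, logical(length(oi_sets))))
  colnames(oi_mat) <- paste0("oi_", names(oi_sets))
  cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(oi_mat))

  list(cohort = cohort, exclusions = tally)
}
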