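# Shared fixtures and independent oracles, built in code.

# diagnosis event table
ev_tbl <- function(dates, setting, code) {
  data.frame(date = as.Date(dates), setting = setting, code = code,
             stringsAsFactors = FALSE)
}

# CHM prescription rows
chm_rows <- function(patient_id, dates, product_code, days = 7,
                     daily_dose_g = 1, kind = "single_herb") {
  tibble::tibble(patient_id = patient_id, date = as.Date(dates),
                 class = "CHM", product_code = product_code,
                 product_kind = kind,
                 days = as.integer(days), daily_dose_g = daily_dose_g,
                 ddd_amount = NA_real_)
}

# dense test catalog: `extra` filler herbs keep almost every drawn basket
# non-empty so planted-pair lifts are not deflated by empty-basket
# conditioning
dense_catalog <- function(planted = c("A", "B"), p_planted = 0.05,
                          extra = 80, p_extra = 0.075) {
  tibble::tibble(
    code = c(planted, sprintf("F%02d", seq_len(extra))),
    kind = "single_herb",
    propensity = c(rep(p_planted, length(planted)), rep(p_extra, extra)),
    mean_dose_g = 1, mean_days_rx = 7)
}

# brute-force pair tally over a transaction set (independent oracle)
brute_pair_counts <- function(ts) {
  tx <- split(ts$items$product_code, ts$items$tid)
  prods <- sort(unique(ts$items$product_code))
  out <- list()
  for (i in seq_along(prods)) {
    for (j in seq_len(i - 1)) {
      a <- prods[j]; b <- prods[i]
      n <- sum(vapply(tx, function(s) a %in% s && b %in% s, logical(1)))
      if (n > 0)
        out[[length(out) + 1]] <- data.frame(a = a, b = b, freq_xy = n)
    }
  }
  if (length(out) == 0)
    return(data.frame(a = character(), b = character(),
                      freq_xy = integer()))
  do.call(rbind, out)
}

# union-find connected components (independent oracle)
uf_components <- function(nodes, edges) {
  parent <- setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (k in seq_len(nrow(edges))) {
    ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  split(nodes, roots)
}

# the five printed top co-prescription rules, as a rules tibble
printed_rules <- function() {
  tibble::tibble(
    x = c("HL", "SZRT", "GC", "JG", "HB"),
    y = c("HQ", "YJT", "HQ", "GC", "HL"),
    freq_x = c(399L, 280L, 540L, 466L, 280L),
    freq_y = c(557L, 324L, 557L, 540L, 399L),
    freq_xy = c(145L, 96L, 91L, 91L, 88L),
    support_pct = 100 * c(145, 96, 91, 91, 88) / 7376,
    confidence_pct = 100 * c(145, 96, 91, 91, 88) /
      c(399, 280, 540, 466, 280),
    lift = (100 * c(145, 96, 91, 91, 88) / c(399, 280, 540, 466, 280)) /
      (100 * c(557, 324, 557, 540, 399) / 7376))
}

# small survival fixture with heavy ties
tied_survival_fixture <- function(n = 300, seed = 11) {
  set.seed(seed)
  x1 <- rbinom(n, 1, 0.5)
  x2 <- rnorm(n)
  t_ev <- round(rexp(n, 0.1 * exp(0.7 * x1 - 0.3 * x2))) + 1
  cens <- round(rexp(n, 0.05)) + 1
  list(time = pmin(t_ev, cens), event = t_ev <= cens,
       x = cbind(x1 = x1, x2 = x2))
}

# small cohort tibble for the propensity model
ps_cohort_fixture <- function(n = 500, seed = 5, confounded = TRUE) {
  set.seed(seed)
  age_band <- sample(c("lt30", "30to40", "ge40"), n, TRUE,
                     prob = c(0.4, 0.35, 0.25))
  sex <- ifelse(rbinom(n, 1, 0.06) == 1, "F", "M")
  cci <- rpois(n, 0.5)
  dur <- round(runif(n, 30, 2500))
  lp <- if (confounded)
    -0.8 - 0.5 * (age_band == "ge40") + 0.3 * (age_band == "30to40") +
      0.25 * cci - 0.0002 * dur
  else rep(-0.8, n)
  tibble::tibble(patient_id = sprintf("P%04d", seq_len(n)),
                 chm_user = runif(n) < plogis(lp),
                 sex = sex, age_band = age_band, cci_score = cci,
                 index_duration_days = dur)
}
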