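# Survival machinery implemented from first principles: product-limit
# estimator with Greenwood variance, two-group log-rank test, and Cox
# partial-likelihood fitting by Newton-Raphson with Efron (default) or
# Breslow tie handling.

#' Kaplan-Meier product-limit estimate
#'
#' Subjects censored at an event time are counted at risk at that time.
#'
#' @param time positive follow-up times.
#' @param event logical (or 0/1) event indicators.
#' @return object of class `km_curve`: tibble with `time` (distinct event
#'   times, increasing), `n_risk`, `n_event`, `survival`, `greenwood_var`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0) stop_data("no subjects")
  if (any(time <= 0)) stop_data("non-positive follow-up time")
  event <- as.logical(event)
  et <- sort(unique(time[event]))
  if (length(et) == 0) {
    out <- tibble::tibble(time = numeric(), n_risk = integer(),
                          n_event = integer(), survival = numeric(),
                          greenwood_var = numeric())
    return(structure(out, class = c("km_curve", class(out)), n = length(time)))
  }
  n_risk <- vapply(et, function(t) sum(time >= t), integer(1))
  n_event <- vapply(et, function(t) sum(time == t & event), integer(1))
  frac <- 1 - n_event / n_risk
  surv <- cumprod(frac)
  gw_terms <- n_event / (n_risk * (n_risk - n_event))
  gw_terms[!is.finite(gw_terms)] <- 0  # S drops to 0; variance undefined
  greenwood_var <- surv^2 * cumsum(gw_terms)
  out <- tibble::tibble(time = et, n_risk = n_risk, n_event = n_event,
                        survival = surv, greenwood_var = greenwood_var)
  structure(out, class = c("km_curve", class(out)), n = length(time))
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param curve a `km_curve`.
#' @param t times at which to read off the step function.
#' @return survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  vapply(t, function(tt) {
    i <- which(curve$time <= tt)
    if (length(i) == 0) 1 else curve$survival[max(i)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic: the observed-minus-expected event count of
#' one group summed over distinct event times, scaled by its
#' hypergeometric variance; referred to the chi-square distribution with
#' one degree of freedom.
#'
#' @param time follow-up times.
#' @param event event indicators.
#' @param group two-level group labels.
#' @return list with `chi2`, `df`, `p`, and the per-group observed and
#'   expected event counts.
#' @export
logrank_test <- function(time, event, group) {
  g <- as.factor(group)
  if (nlevels(g) != 2) stop_data("log-rank requires exactly two groups")
  if (any(tabulate(g, 2) == 0)) stop_data("one group is empty")
  event <- as.logical(event)
  et <- sort(unique(time[event]))
  O <- E <- V <- 0
  g1 <- g == levels(g)[1]
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(time == t & event); d1 <- sum(time == t & event & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (V > 0) (O - E)^2 / V else 0
  list(chi2 = chi2, df = 1L, p = pchisq(chi2, 1, lower.tail = FALSE),
       observed = c(O, sum(event) - O), expected = c(E, sum(event) - E))
}

#' Cox proportional-hazards fit
#'
#' Maximises the partial likelihood by Newton-Raphson with step-halving.
#' Ties are handled by the Efron correction by default (Breslow
#' optionally); the two coincide on tie-free data. Wald confidence
#' intervals and p-values use the inverse observed information.
#'
#' @param time follow-up times.
#' @param event event indicators.
#' @param x covariate matrix (or data frame coerced to numeric columns).
#' @param ties `"efron"` or `"breslow"`.
#' @param tol convergence tolerance on the maximum absolute score.
#' @param max_iter iteration cap.
#' @return object of class `cox_fit` with `coefficients`, `covariance`,
#'   `hr`, `ci_low`, `ci_high`, `se`, `p`, `loglik0`, `loglik`,
#'   `score_norm`, `iter`, `ties`, `n`, `n_events`.
#' @export
cox_fit <- function(time, event, x, ties = c("efron", "breslow"),
                    tol = 1e-9, max_iter = 60) {
  ties <- match.arg(ties)
  x <- as.matrix(as.data.frame(x))
  storage.mode(x) <- "double"
  event <- as.logical(event)
  if (sum(event) < 1) stop_data("no events")
  const <- apply(x, 2, function(col) diff(range(col)) == 0)
  if (any(const))
    stop_data("constant covariate(s): %s",
              paste(colnames(x)[const], collapse = ", "))
  p <- ncol(x); n <- nrow(x)
  beta <- rep(0, p)
  ll_at <- function(beta) .cox_loglik(time, event, x, beta, ties)
  cur <- ll_at(beta)
  loglik0 <- cur$loglik
  iter <- 0
  repeat {
    iter <- iter + 1
    step <- tryCatch(solve(cur$info, cur$score),
                     error = function(e)
                       stop_data("singular information matrix (collinear covariates?)"))
    halving <- 0
    repeat {
      cand_beta <- beta + step
      cand <- ll_at(cand_beta)
      if (is.finite(cand$loglik) &&
          cand$loglik >= cur$loglik - 1e-9 * (abs(cur$loglik) + 1)) break
      step <- step / 2
      halving <- halving + 1
      if (halving > 30)
        stop_data("Cox fit failed to improve at iteration %d", iter)
    }
    beta <- cand_beta; cur <- cand
    if (max(abs(cur$score)) < tol) break
    if (iter >= max_iter) {
      warning(sprintf(
        "Cox fit did not converge in %d iterations (|score| = %.3e)",
        max_iter, max(abs(cur$score))))
      break
    }
  }
  if (any(abs(beta) > 15))
    warning(sprintf("monotone likelihood suspected for covariate(s): %s",
                    paste(colnames(x)[abs(beta) > 15], collapse = ", ")))
  cov <- solve(cur$info)
  se <- sqrt(diag(cov))
  z <- qnorm(0.975)
  fit <- list(coefficients = setNames(beta, colnames(x)),
              covariance = cov,
              se = setNames(se, colnames(x)),
              hr = setNames(exp(beta), colnames(x)),
              ci_low = setNames(exp(beta - z * se), colnames(x)),
              ci_high = setNames(exp(beta + z * se), colnames(x)),
              p = setNames(2 * pnorm(-abs(beta / se)), colnames(x)),
              loglik0 = loglik0, loglik = cur$loglik,
              score_norm = max(abs(cur$score)), iter = iter,
              ties = ties, n = n, n_events = sum(event))
  class(fit) <- "cox_fit"
  fit
}

# Partial log-likelihood, score and information at beta.
# Processes distinct event times in decreasing order while accumulating
# risk-set sums S0 = sum(exp(eta)), S1 = sum(x exp(eta)),
# S2 = sum(x x' exp(eta)); the Efron correction subtracts l/d of the tied
# group's sums from the denominator for l = 0, ..., d-1.
.cox_loglik <- function(time, event, x, beta, ties) {
  p <- ncol(x)
  eta <- drop(x %*% beta)
  w <- exp(eta)
  ord <- order(time, decreasing = TRUE)
  t_s <- time[ord]; e_s <- event[ord]; w_s <- w[ord]
  eta_s <- eta[ord]
  x_s <- x[ord, , drop = FALSE]
  # rows sharing a time value are contiguous in the decreasing sort; the
  # risk set at that value is the prefix through the end of its run
  runs <- rle(t_s)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  S0 <- 0; S1 <- numeric(p); S2 <- matrix(0, p, p)
  loglik <- 0; score <- numeric(p); info <- matrix(0, p, p)
  for (j in seq_along(runs$values)) {
    idx <- run_start[j]:run_end[j]
    ww <- w_s[idx]
    xr <- x_s[idx, , drop = FALSE]
    S0 <- S0 + sum(ww)
    S1 <- S1 + colSums(xr * ww)
    S2 <- S2 + crossprod(xr * sqrt(ww))
    ev <- e_s[idx]
    if (!any(ev)) next
    dd <- idx[ev]
    d <- length(dd)
    wd <- w_s[dd]
    xd <- x_s[dd, , drop = FALSE]
    S0d <- sum(wd)
    S1d <- colSums(xd * wd)
    S2d <- crossprod(xd * sqrt(wd))
    loglik <- loglik + sum(eta_s[dd])
    score <- score + colSums(xd)
    for (l in seq_len(d) - 1) {
      f <- if (ties == "efron") l / d else 0
      phi0 <- S0 - f * S0d
      phi1 <- S1 - f * S1d
      phi2 <- S2 - f * S2d
      loglik <- loglik - log(phi0)
      score <- score - phi1 / phi0
      info <- info + phi2 / phi0 - tcrossprod(phi1 / phi0)
    }
  }
  list(loglik = loglik, score = score, info = info)
}

#' Restrict a cohort to selected death-cause categories
#'
#' Subjects dying of a listed category keep their event; alive or censored
#' subjects are retained with `event = FALSE`; subjects dying of any other
#' category are removed from the data entirely (the cause-specific design
#' of the source analysis, as opposed to competing-risks censoring).
#'
#' @param cohort cohort tibble with `event` and `cause_category`.
#' @param categories cause categories treated as the event.
#' @return the filtered cohort with `event` redefined.
#' @export
cause_specific_subset <- function(cohort,
                                  categories = c("infections_parasites",
                                                 "circulatory")) {
  drop <- cohort$event & !(cohort$cause_category %in% categories)
  out <- cohort[!drop, , drop = FALSE]
  out$event <- out$event & out$cause_category %in% categories
  out
}

#' Run the mortality analysis on a matched cohort
#'
#' Produces per-group Kaplan-Meier curves, the log-rank test, one crude
#' Cox model per covariate block, and the adjusted Cox model (CHM use, age
#' band, sex, Charlson comorbidity group; optionally the
#' neuro-to-index interval as an extra adjustment, and optionally
#' restricted to a neurological subtype).
#'
#' @param cohort analysis rows (e.g. the matched cohort): needs
#'   `chm_user`, `age_band`, `sex`, `cci_group`, `followup_days`, `event`,
#'   `cause_category`, `neuro_subtypes`, and (for `adjust_interval`)
#'   `neuro_date`/`index_date`.
#' @param outcome `"all_cause"` or `"infect_circ"`.
#' @param adjust_interval also adjust for days from neurological diagnosis
#'   to index date.
#' @param subgroup optional neurological subtype filter
#'   (e.g. `"cns_infection"`).
#' @param ties tie handling for [cox_fit()].
#' @return list with `data`, `curves` (per exposure group), `logrank`,
#'   `crude` (list of `cox_fit`), `adjusted` (`cox_fit`).
#' @export
run_mortality_analysis <- function(cohort,
                                   outcome = c("all_cause", "infect_circ"),
                                   adjust_interval = FALSE,
                                   subgroup = NULL,
                                   ties = "efron") {
  outcome <- match.arg(outcome)
  dat <- cohort
  if (!is.null(subgroup))
    dat <- dat[grepl(subgroup, dat$neuro_subtypes), , drop = FALSE]
  if (outcome == "infect_circ")
    dat <- cause_specific_subset(dat)
  time <- pmax(dat$followup_days, 0.5)
  event <- dat$event
  X <- cbind(chm_use = as.numeric(dat$chm_user),
             age_30_40 = as.numeric(dat$age_band == "30to40"),
             age_ge40 = as.numeric(dat$age_band == "ge40"),
             female = as.numeric(dat$sex == "F"),
             cci_1_2 = as.numeric(dat$cci_group == "1-2"),
             cci_ge3 = as.numeric(dat$cci_group == "ge3"))
  if (adjust_interval)
    X <- cbind(X, interval = days_between(dat$neuro_date, dat$index_date))
  curves <- list(
    chm_user = km_estimate(time[dat$chm_user], event[dat$chm_user]),
    non_user = km_estimate(time[!dat$chm_user], event[!dat$chm_user]))
  lr <- logrank_test(time, event, dat$chm_user)
  blocks <- list(chm_use = "chm_use",
                 age = c("age_30_40", "age_ge40"),
                 female = "female",
                 cci = c("cci_1_2", "cci_ge3"))
  crude <- lapply(blocks, function(cols) {
    tryCatch(cox_fit(time, event, X[, cols, drop = FALSE], ties = ties),
             error = function(e) e)
  })
  adjusted <- cox_fit(time, event, X, ties = ties)
  list(data = dat, curves = curves, logrank = lr, crude = crude,
       adjusted = adjusted, outcome = outcome)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, ties = %s, iter = %d\n",
              x$n, x$n_events, x$ties, x$iter))
  tab <- data.frame(coef = x$coefficients, HR = x$hr,
                    lower95 = x$ci_low, upper95 = x$ci_high,
                    se = x$se, p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' Render a Cox model table
#'
#' Crude and adjusted hazard ratios side by side in the layout of the
#' source tables (HR, 95% CI, p; aHR, 95% CI, p), p-values floored at
#' `<0.001`.
#'
#' @param crude list of crude `cox_fit`s (possibly errors, skipped).
#' @param adjusted the adjusted `cox_fit`.
#' @return tibble, one row per covariate.
#' @export
cox_table <- function(crude, adjusted) {
  fmt <- function(fit, nm) {
    if (inherits(fit, "error") || !(nm %in% names(fit$hr)))
      return(c(NA, NA, NA, NA_character_))
    c(fit$hr[nm], fit$ci_low[nm], fit$ci_high[nm], format_p(fit$p[nm]))
  }
  nm_all <- names(adjusted$coefficients)
  rows <- lapply(nm_all, function(nm) {
    cr <- NULL
    for (f in crude) {
      if (!inherits(f, "error") && nm %in% names(f$hr)) { cr <- f; break }
    }
    cvals <- fmt(cr, nm); avals <- fmt(adjusted, nm)
    tibble::tibble(covariate = nm,
                   hr = as.numeric(cvals[1]),
                   hr_low = as.numeric(cvals[2]),
                   hr_high = as.numeric(cvals[3]), hr_p = cvals[4],
                   ahr = as.numeric(avals[1]),
                   ahr_low = as.numeric(avals[2]),
                   ahr_high = as.numeric(avals[3]), ahr_p = avals[4])
  })
  dplyr::bind_rows(rows)
}
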