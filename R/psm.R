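# Propensity-score estimation (Newton-Raphson logistic regression) and
# greedy 1:k nearest-neighbour matching on the logit scale with a caliper.

#' Fit the propensity-score logistic model
#'
#' Maximum-likelihood logistic regression of CHM exposure on the matching
#' covariates (sex, age band, CCI score, index duration by default),
#' fitted by Newton-Raphson. Convergence when the maximum absolute score
#' component falls below `tol`.
#'
#' @param cohort cohort tibble with `chm_user` and the covariate columns.
#' @param covariates character vector naming covariates; `age_band` and
#'   any character/factor column expand to indicator columns against their
#'   first level.
#' @param tol score tolerance (default 1e-8).
#' @param max_iter iteration cap (default 50).
#' @return object of class `propensity_model` with `coefficients`,
#'   `fitted_scores` (named by `patient_id`), `logit_scores`, `chm_user`,
#'   `iter`, `score_norm`.
#' @export
fit_logistic_ps <- function(cohort,
                            covariates = c("sex", "age_band", "cci_score",
                                           "index_duration_days"),
                            tol = 1e-8, max_iter = 50) {
  y <- as.numeric(cohort$chm_user)
  if (length(unique(y)) < 2)
    stop_data("need at least one CHM user and one non-user")
  X <- .ps_design(cohort, covariates)
  if (any(!complete.cases(X)))
    stop_data("missing covariate values")
  n <- nrow(X); p <- ncol(X)
  beta <- numeric(p)
  iter <- 0
  repeat {
    iter <- iter + 1
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(X, y - mu))
    W <- mu * (1 - mu)
    info <- crossprod(X * W, X)
    step <- tryCatch(solve(info, score), error = function(e) {
      qrX <- qr(X)
      dep <- colnames(X)[qrX$pivot[seq_len(ncol(X)) > qrX$rank]]
      stop_data("singular information matrix; collinear covariates: %s",
                paste(dep, collapse = ", "))
    })
    beta <- beta + step
    if (max(abs(score)) < tol) break
    if (any(abs(beta) > 30) ||
        (iter > 5 && all(mu < 1e-12 | mu > 1 - 1e-12)))
      stop_data(paste("perfect separation detected; consider exact",
                      "matching without a propensity model"))
    if (iter >= max_iter) {
      warning(sprintf("logistic fit did not converge in %d iterations",
                      max_iter))
      break
    }
  }
  eta <- drop(X %*% beta)
  ids <- cohort$patient_id %||% as.character(seq_len(n))
  structure(list(coefficients = setNames(beta, colnames(X)),
                 fitted_scores = setNames(stats::plogis(eta), ids),
                 logit_scores = setNames(eta, ids),
                 chm_user = setNames(as.logical(y), ids),
                 iter = iter, score_norm = max(abs(drop(
                   crossprod(X, y - stats::plogis(eta))))),
                 covariates = covariates),
            class = "propensity_model")
}

# design matrix: intercept + numeric columns as-is + indicator expansion
# for character/factor/logical columns (first level is the reference)
.ps_design <- function(cohort, covariates) {
  cols <- list(intercept = rep(1, nrow(cohort)))
  for (cv in covariates) {
    v <- cohort[[cv]]
    if (is.null(v)) stop_data("covariate `%s` not found", cv)
    if (is.numeric(v)) {
      cols[[cv]] <- v
    } else {
      lv <- sort(unique(as.character(v)))
      for (l in lv[-1])
        cols[[paste0(cv, "_", l)]] <- as.numeric(v == l)
    }
  }
  do.call(cbind, cols)
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("<propensity_model>", length(x$fitted_scores), "subjects,",
      sum(x$chm_user), "users; converged in", x$iter, "iterations\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Greedy 1:k propensity-score matching
#'
#' Users are processed in random order (under `seed`); each is matched
#' without replacement to its `k` nearest non-users by absolute difference
#' in logit propensity, all within the caliper
#' `caliper_sd_mult * SD(logit PS)`. Users with fewer than `k` in-caliper
#' candidates are left unmatched and consume no controls.
#'
#' @param model a `propensity_model`.
#' @param k controls per user (default 2).
#' @param caliper_sd_mult caliper width in SDs of the logit propensity
#'   score (default 0.2).
#' @param seed integer seed for the user processing order.
#' @return object of class `matched_set`: `triples` tibble (`user_id`,
#'   `control_id_1`, ..., `control_id_k`), `unmatched_users`, `caliper`.
#' @export
match_1_to_k <- function(model, k = 2, caliper_sd_mult = 0.2, seed = 1L) {
  stopifnot(inherits(model, "propensity_model"))
  lg <- model$logit_scores
  users <- names(lg)[model$chm_user]
  ctrls <- names(lg)[!model$chm_user]
  caliper <- caliper_sd_mult * sd(lg)
  set.seed(as.integer(seed))
  users <- sample(users)
  avail <- setNames(rep(TRUE, length(ctrls)), ctrls)
  c_lg <- lg[ctrls]
  triples <- vector("list", length(users))
  unmatched <- character()
  for (ui in seq_along(users)) {
    u <- users[ui]
    d <- abs(c_lg - lg[[u]])
    ok <- avail & d <= caliper
    if (sum(ok) < k) {
      unmatched <- c(unmatched, u)
      next
    }
    pick <- names(sort(d[ok]))[seq_len(k)]
    avail[pick] <- FALSE
    triples[[ui]] <- c(u, pick)
  }
  triples <- triples[!vapply(triples, is.null, logical(1))]
  tr <- if (length(triples) > 0) {
    m <- do.call(rbind, triples)
    colnames(m) <- c("user_id", paste0("control_id_", seq_len(k)))
    tibble::as_tibble(m)
  } else {
    warning("no users could be matched")
    tibble::as_tibble(matrix(character(), ncol = k + 1,
                             dimnames = list(NULL,
                               c("user_id",
                                 paste0("control_id_", seq_len(k))))))
  }
  structure(list(triples = tr, unmatched_users = unmatched,
                 caliper = caliper, k = k),
            class = "matched_set")
}

#' @export
print.matched_set <- function(x, ...) {
  cat("<matched_set>", nrow(x$triples), "users matched 1:", x$k,
      "(", length(x$unmatched_users), "unmatched ), caliper",
      signif(x$caliper, 4), "\n")
  invisible(x)
}

#' Matched subject ids (users plus their controls)
#'
#' @param matched a `matched_set`.
#' @return character vector of all matched subject ids.
#' @export
matched_ids <- function(matched) {
  unlist(matched$triples, use.names = FALSE)
}

#' Subset a cohort to the matched subjects
#'
#' @param cohort cohort tibble with `patient_id`.
#' @param matched a `matched_set`.
#' @return the matched rows of `cohort`.
#' @export
matched_cohort <- function(cohort, matched) {
  cohort[cohort$patient_id %in% matched_ids(matched), , drop = FALSE]
}

#' Standardized mean difference
#'
#' SMD between two samples of a numeric (or 0/1) covariate:
#' difference in means over the pooled standard deviation
#' `sqrt((s1^2 + s0^2)/2)`.
#'
#' @param x1,x0 numeric vectors (users, controls).
#' @return the absolute standardized mean difference.
#' @export
smd <- function(x1, x0) {
  s <- sqrt((var(x1) + var(x0)) / 2)
  if (s == 0) return(0)
  abs(mean(x1) - mean(x0)) / s
}

#' Covariate balance of a matched set
#'
#' Per-covariate user/control summaries with standardized mean
#' differences, before and after matching. Categorical covariates are
#' expanded to level indicators.
#'
#' @param matched a `matched_set`.
#' @param cohort the full cohort tibble.
#' @param covariates covariates to summarise.
#' @return tibble with columns `covariate`, `smd_before`, `smd_after`,
#'   `mean_user`, `mean_control` (post-matching).
#' @export
balance_table <- function(matched, cohort,
                          covariates = c("sex", "age_band", "cci_score",
                                         "index_duration_days")) {
  if (nrow(matched$triples) == 0) stop_data("empty matched set")
  mc <- matched_cohort(cohort, matched)
  expand <- function(dat) {
    out <- list()
    for (cv in covariates) {
      v <- dat[[cv]]
      if (is.numeric(v)) out[[cv]] <- v
      else for (l in sort(unique(as.character(cohort[[cv]]))))
        out[[paste0(cv, "_", l)]] <- as.numeric(v == l)
    }
    tibble::as_tibble(out)
  }
  full_x <- expand(cohort); m_x <- expand(mc)
  u_full <- cohort$chm_user; u_m <- mc$chm_user
  tibble::tibble(
    covariate = names(full_x),
    smd_before = vapply(names(full_x), function(cv)
      smd(full_x[[cv]][u_full], full_x[[cv]][!u_full]), numeric(1)),
    smd_after = vapply(names(m_x), function(cv)
      smd(m_x[[cv]][u_m], m_x[[cv]][!u_m]), numeric(1)),
    mean_user = vapply(names(m_x), function(cv)
      mean(m_x[[cv]][u_m]), numeric(1)),
    mean_control = vapply(names(m_x), function(cv)
      mean(m_x[[cv]][!u_m]), numeric(1)))
}
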