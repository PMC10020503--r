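# Baseline-characteristics table, its two-group tests, and the pipeline
# orchestrator.

#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic without continuity correction,
#' df = (r - 1)(c - 1). Delegates to [stats::chisq.test()].
#'
#' @param tab matrix of counts (groups in rows).
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_counts == 0))
    stop_data("zero expected cell count; merge sparse categories")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Unpaired two-sample t-test
#'
#' Pooled-variance Student's t by default; Welch's correction behind
#' `equal_variance = FALSE`. Delegates to [stats::t.test()].
#'
#' @param x,y the two samples.
#' @param equal_variance pooled (Student) vs Welch.
#' @return list with `statistic`, `df`, `p`.
#' @export
t_test_unpaired <- function(x, y, equal_variance = TRUE) {
  if (length(x) < 2 || length(y) < 2)
    stop_data("each arm needs at least two observations")
  if (equal_variance &&
      sum((x - mean(x))^2) + sum((y - mean(y))^2) == 0)
    stop_data("zero pooled variance")
  tt <- t.test(x, y, var.equal = equal_variance)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Baseline characteristics table with two-group tests
#'
#' Summarises the cohort by CHM exposure: age bands, sex, index duration,
#' cumulative ART DDDs (total and per class), CCI score, Charlson
#' comorbidity number group, and the six opportunistic-infection flags.
#' Categorical rows use the chi-square test, continuous rows the unpaired
#' Student's t-test.
#'
#' @param cohort cohort tibble (pre- or post-matching).
#' @return tibble with `characteristic`, `type`, `summary_user`,
#'   `summary_nonuser`, `test`, `statistic`, `p`, `p_label`.
#' @export
baseline_table <- function(cohort) {
  u <- cohort$chm_user
  cat_row <- function(name, v) {
    tab <- table(factor(u, levels = c(TRUE, FALSE)), v)
    ct <- tryCatch(chi_square_test(tab), error = function(e)
      list(statistic = NA_real_, df = NA, p = NA_real_))
    fmt <- function(r) paste(sprintf("%s:%d(%.1f%%)", colnames(tab), r,
                                     100 * r / max(sum(r), 1)),
                             collapse = " ")
    tibble::tibble(characteristic = name, type = "categorical",
                   summary_user = fmt(tab[1, ]),
                   summary_nonuser = fmt(tab[2, ]),
                   test = "chi_square", statistic = ct$statistic, p = ct$p)
  }
  num_row <- function(name, v) {
    tt <- tryCatch(t_test_unpaired(v[u], v[!u]), error = function(e)
      list(statistic = NA_real_, df = NA, p = NA_real_))
    fmt <- function(z) sprintf("%.2f ± %.2f", mean(z), sd(z))
    tibble::tibble(characteristic = name, type = "continuous",
                   summary_user = fmt(v[u]), summary_nonuser = fmt(v[!u]),
                   test = "t_test", statistic = tt$statistic, p = tt$p)
  }
  rows <- list(
    cat_row("age_band", factor(cohort$age_band,
                               levels = c("lt30", "30to40", "ge40"))),
    cat_row("sex", cohort$sex),
    num_row("index_duration_days", cohort$index_duration_days),
    num_row("ddd_total", cohort$ddd_total),
    num_row("ddd_nrti", cohort$ddd_nrti),
    num_row("ddd_pi", cohort$ddd_pi),
    num_row("ddd_nnrti", cohort$ddd_nnrti),
    num_row("ddd_insti", cohort$ddd_insti),
    num_row("ddd_combined_art", cohort$ddd_combined_art),
    num_row("cci_score", cohort$cci_score),
    cat_row("cci_group", factor(cohort$cci_group,
                                levels = c("0", "1-2", "ge3"))))
  for (oi in grep("^oi_", names(cohort), value = TRUE))
    rows[[length(rows) + 1]] <- cat_row(oi, factor(cohort[[oi]],
                                                   levels = c(FALSE, TRUE)))
  out <- dplyr::bind_rows(rows)
  out$p_label <- ifelse(is.na(out$p), NA_character_, format_p(out$p))
  out
}

#' Run the full pipeline
#'
#' Generate (or read) a claims bundle, build the cohort, fit and match the
#' propensity model, compute baseline tables, run the mortality analyses
#' (all-cause and cause-specific), mine co-prescription rules among
#' matched CHM users, and write every artifact plus a checksum manifest.
#' Deterministic given the config seed.
#'
#' @param config a [claims_config()] (the bundle is generated), or a
#'   directory path containing a bundle written by [write_bundle()].
#' @param outdir output directory.
#' @param psm list of matching options: `k`, `caliper_sd_mult`.
#' @param survival_opts list: `outcomes` (subset of `"all_cause"`,
#'   `"infect_circ"`), `subgroup`, `adjust_interval`.
#' @param arm_opts list: `top_k`, `node_min_freq`, `edge_min_support_pct`.
#' @param seed seed for the stochastic stages outside the generator
#'   (matching order); defaults to the config seed.
#' @param write_bundle_csv also write the four bundle tables under
#'   `outdir/data/`.
#' @return invisibly, the manifest (named md5 checksums of every artifact).
#' @export
run_pipeline <- function(config, outdir,
                         psm = list(k = 2, caliper_sd_mult = 0.2),
                         survival_opts = list(outcomes = c("all_cause",
                                                           "infect_circ"),
                                              subgroup = NULL,
                                              adjust_interval = FALSE),
                         arm_opts = list(top_k = 5, node_min_freq = 1,
                                         edge_min_support_pct = 0),
                         seed = NULL,
                         write_bundle_csv = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  on_fail <- function(e) {
    unlink(file.path(outdir, written))
    stop(e)
  }
  tryCatch({
    if (inherits(config, "claims_config")) {
      bundle <- generate_bundle(config)
      seed <- seed %||% config$seed
    } else if (is.character(config) && dir.exists(config)) {
      bundle <- read_bundle(config)
      seed <- seed %||% 1L
    } else {
      stop_config("`config` must be a claims_config or a bundle directory")
    }
    if (write_bundle_csv) {
      write_bundle(bundle, file.path(outdir, "data"))
      written <- c(written, file.path("data",
                                      c("patients.csv", "diagnoses.csv",
                                        "prescriptions.csv", "deaths.csv",
                                        "provenance.json")))
    }
    emit_csv <- function(obj, name) {
      write.csv(obj, file.path(outdir, name), row.names = FALSE, na = "")
      written <<- c(written, name)
    }
    emit_json <- function(obj, name) {
      jsonlite::write_json(obj, file.path(outdir, name), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      written <<- c(written, name)
    }

    built <- build_cohort(bundle)
    emit_csv(built$cohort, "cohort.csv")
    emit_json(as.list(built$exclusions), "exclusions.json")

    model <- fit_logistic_ps(built$cohort)
    matched <- match_1_to_k(model, k = psm$k %||% 2,
                            caliper_sd_mult = psm$caliper_sd_mult %||% 0.2,
                            seed = seed)
    emit_csv(matched$triples, "matched.csv")
    emit_csv(balance_table(matched, built$cohort), "balance.csv")
    mc <- matched_cohort(built$cohort, matched)
    emit_csv(baseline_table(built$cohort), "baseline_included.csv")
    emit_csv(baseline_table(mc), "baseline_matched.csv")

    for (outc in survival_opts$outcomes %||% "all_cause") {
      res <- run_mortality_analysis(
        mc, outcome = outc,
        adjust_interval = isTRUE(survival_opts$adjust_interval),
        subgroup = survival_opts$subgroup)
      for (grp in names(res$curves)) {
        cv <- res$curves[[grp]]
        emit_csv(tibble::as_tibble(cv),
                 sprintf("km_%s_%s.csv", outc, grp))
      }
      emit_json(list(chi2 = res$logrank$chi2, p = res$logrank$p),
                sprintf("logrank_%s.json", outc))
      emit_csv(cox_table(res$crude, res$adjusted),
               sprintf("cox_%s.csv", outc))
    }

    user_rx <- bundle$prescriptions[
      bundle$prescriptions$class == "CHM" &
        bundle$prescriptions$patient_id %in%
          mc$patient_id[mc$chm_user], , drop = FALSE]
    if (nrow(user_rx) > 0) {
      ts <- build_transactions(user_rx)
      rules <- top_rules(ts, k = arm_opts$top_k %||% 5)
      emit_csv(render_rules(rules, user_rx), "rules.csv")
      gr <- build_graph(rules, user_rx,
                        node_min_freq = arm_opts$node_min_freq %||% 1,
                        edge_min_support_pct =
                          arm_opts$edge_min_support_pct %||% 0)
      write_graph_files(gr, file.path(outdir, "network.graphml"),
                        file.path(outdir, "network.json"))
      written <- c(written, "network.graphml", "network.json")
    }

    manifest <- as.list(tools::md5sum(file.path(outdir, written)))
    names(manifest) <- written
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(manifest)
  }, error = on_fail)
}
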