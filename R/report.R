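#' Stratified outcome analysis of a cohort
#'
#' Builds, for a chosen stratifier, the response contingency table (strata
#' by end-of-treatment complete metabolic response, excluding patients
#' without an evaluable response), its exact Fisher test, per-stratum
#' Kaplan-Meier fits of progression-free survival, the log-rank test, the
#' Mantel-Haenszel hazard ratio, survival estimates at `surv_time` months
#' and the reverse-censor median potential follow-up.
#'
#' @param cohort Cohort tibble with columns `patient`, `emr`, `mrd`,
#'   `eot_response` (values `CMR`, `PR`, `PD/ED` or `NA`), `baseline_hge`,
#'   `ripi`, `pfs_months`, `pfs_event`, `os_months`, `os_event`.
#' @param stratifier One of `"emr"` (early molecular response), `"mrd"`,
#'   `"burden"` (baseline burden at or above `burden_cutoff_log10` log10
#'   hGE/mL) or `"ripi"`.
#' @param burden_cutoff_log10 Baseline-burden cutoff, log10 hGE/mL.
#' @param surv_time Time (months) at which to report survival estimates.
#' @return An `outcome_report`: list with `stratifier`, `contingency`
#'   (counts of CMR / non-CMR by stratum), `cmr_rates`, `fisher`,
#'   `km` (named list of [km_fit()]s), `logrank`, `hazard_ratio`,
#'   `surv_at_time`, `median_followup`, `n`.
#' @export
#' @examples
#' sc <- simulate_cohort(clinical_sim_spec(n_patients = 60), seed = 11)
#' rep <- stratify_and_report(sc$cohort, "emr")
#' tidy(rep)
stratify_and_report <- function(cohort,
                                stratifier = c("emr", "mrd", "burden", "ripi"),
                                burden_cutoff_log10 = 2.5, surv_time = 24) {
  stratifier <- match.arg(stratifier)
  strata <- switch(
    stratifier,
    emr = factor(ifelse(cohort$emr, "EMR", "no EMR"),
                 levels = c("EMR", "no EMR")),
    mrd = factor(cohort$mrd, levels = c("negative", "positive")),
    burden = factor(ifelse(log10(cohort$baseline_hge) >= burden_cutoff_log10,
                           "high burden", "low burden"),
                    levels = c("low burden", "high burden")),
    ripi = factor(cohort$ripi, levels = c("good", "poor"))
  )
  keep <- !is.na(strata)
  co <- cohort[keep, ]
  strata <- droplevels(strata[keep])
  tab <- table(strata)
  if (length(tab) < 2 || any(tab < 2)) {
    warn(sprintf("Stratifier '%s' does not define two strata with >= 2 patients; tests skipped.",
                 stratifier))
    return(structure(list(stratifier = stratifier, n = nrow(co),
                          strata_counts = tab, contingency = NULL,
                          cmr_rates = NULL, fisher = NULL, km = NULL,
                          logrank = NULL, hazard_ratio = NULL,
                          surv_at_time = NULL, median_followup = NULL),
                     class = "outcome_report"))
  }

  evaluable <- !is.na(co$eot_response)
  cmr <- co$eot_response == "CMR"
  cont <- table(strata[evaluable],
                factor(ifelse(cmr[evaluable], "CMR", "not CMR"),
                       levels = c("CMR", "not CMR")))
  cmr_rates <- tibble::tibble(
    stratum = rownames(cont),
    n_evaluable = unname(rowSums(cont)),
    n_cmr = unname(cont[, "CMR"]),
    cmr_rate = unname(cont[, "CMR"] / rowSums(cont))
  )
  fisher <- if (all(dim(cont) == c(2L, 2L)) && all(rowSums(cont) > 0)) {
    fisher_exact_2x2(unclass(cont))
  } else NULL

  co$.stratum <- strata
  km <- lapply(levels(strata), function(lv) {
    km_fit(co[co$.stratum == lv, ], "pfs_months", "pfs_event")
  })
  names(km) <- levels(strata)
  lr <- logrank_test(co, "pfs_months", "pfs_event", ".stratum")
  hr <- mh_hazard_ratio(co, "pfs_months", "pfs_event", ".stratum")
  s_at <- tibble::tibble(
    stratum = levels(strata),
    time = surv_time,
    surv = unname(vapply(km, function(f) surv_at(f, surv_time), numeric(1))),
    median_survival = unname(vapply(km, function(f) f$median, numeric(1)))
  )
  fup <- reverse_km_followup(co, "os_months", "os_event")

  structure(
    list(stratifier = stratifier, n = nrow(co), strata_counts = tab,
         contingency = cont, cmr_rates = cmr_rates, fisher = fisher,
         km = km, logrank = lr, hazard_ratio = hr, surv_at_time = s_at,
         median_followup = fup$median_followup),
    class = "outcome_report"
  )
}

#' @export
print.outcome_report <- function(x, ...) {
  cat("<outcome_report> stratifier:", x$stratifier, "(n =", x$n, ")\n")
  if (is.null(x$contingency)) return(invisible(x))
  print(x$contingency)
  if (!is.null(x$fisher)) {
    cat(sprintf("Fisher exact p = %.4g\n", x$fisher$p_value))
  }
  cat(sprintf("Log-rank p = %.4g; HR (%s vs %s) = %.3g [%.3g, %.3g]\n",
              x$logrank$p_value, x$hazard_ratio$group_a,
              x$hazard_ratio$group_b, x$hazard_ratio$hr,
              x$hazard_ratio$conf_low, x$hazard_ratio$conf_high))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.outcome_report <- function(x, ...) {
  if (is.null(x$contingency)) {
    return(tibble::tibble(stratifier = x$stratifier, n = x$n))
  }
  x$cmr_rates |>
    dplyr::left_join(x$surv_at_time, by = "stratum") |>
    dplyr::mutate(
      stratifier = x$stratifier,
      fisher_p = if (is.null(x$fisher)) NA_real_ else x$fisher$p_value,
      logrank_p = x$logrank$p_value,
      hr = x$hazard_ratio$hr,
      hr_conf_low = x$hazard_ratio$conf_low,
      hr_conf_high = x$hazard_ratio$conf_high,
      median_followup = x$median_followup
    ) |>
    dplyr::relocate("stratifier")
}

#' @exportS3Method generics::glance
glance.outcome_report <- function(x, ...) {
  tibble::tibble(
    stratifier = x$stratifier, n = x$n,
    fisher_p = if (is.null(x$fisher)) NA_real_ else x$fisher$p_value,
    logrank_p = if (is.null(x$logrank)) NA_real_ else x$logrank$p_value,
    hr = if (is.null(x$hazard_ratio)) NA_real_ else x$hazard_ratio$hr,
    median_followup = x$median_followup %||% NA_real_
  )
}
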