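#' Simulate a clinical cohort with EMR-dependent outcomes
#'
#' Generates a per-patient outcome table and a longitudinal ctDNA burden
#' series. Each patient attains early molecular response (EMR) with
#' probability `spec$emr_fraction`; EMR patients drop their burden by at
#' least 2 log10 at the early (cycle 1) draw, non-EMR patients by less.
#' Progression and death times are exponential with stratum-specific hazards
#' and administratively censored at `spec$censor_time` months.
#'
#' @param spec A [clinical_sim_spec()].
#' @param seed Integer seed.
#' @return A list of class `sim_cohort` with `cohort` (one row per patient:
#'   `patient`, `emr`, `eot_response`, `mrd`, `baseline_hge`, `ldh_uln`,
#'   `ripi`, `pfs_months`, `pfs_event`, `os_months`, `os_event`) and `burden`
#'   (per-timepoint true burden series: `patient`, `timepoint`, `day`,
#'   `hge_per_ml`).
#' @export
#' @examples
#' sc <- simulate_cohort(clinical_sim_spec(n_patients = 40), seed = 3)
#' dplyr::count(sc$cohort, emr, eot_response)
simulate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "clinical_sim_spec"))
  withr::local_seed(seed)
  n <- spec$n_patients

  emr <- runif(n) < spec$emr_fraction
  baseline <- rlnorm(n, spec$baseline_meanlog, spec$baseline_sdlog)
  # LDH roughly tracks log burden (the correlation the baseline analysis uses)
  ldh <- pmax(0.3, 0.25 * log10(baseline) + rnorm(n, 0.2, 0.35))
  ripi <- sample(c("good", "poor"), n, replace = TRUE, prob = c(6, 11))

  drop_early <- ifelse(emr, runif(n, 2, 4), runif(n, 0, 1.5))
  early <- baseline * 10^(-drop_early)
  eot <- ifelse(emr, baseline * 10^(-runif(n, 3.5, 5)),
                baseline * 10^(-runif(n, 0.2, 2.5)))
  late <- ifelse(emr, 0, eot * 10^(runif(n, -0.5, 0.5)))

  cmr_prob <- ifelse(emr, spec$cmr_prob_emr, spec$cmr_prob_no_emr)
  cmr <- runif(n) < cmr_prob
  other <- sample(c("PR", "PD/ED"), n, replace = TRUE, prob = c(2, 5))
  eot_response <- ifelse(cmr, "CMR", other)

  haz <- ifelse(emr, spec$hazard_emr, spec$hazard_no_emr)
  t_pfs <- rexp(n, haz)
  pfs_event <- t_pfs <= spec$censor_time
  pfs_months <- pmin(t_pfs, spec$censor_time)
  haz_os <- ifelse(emr, spec$os_hazard_emr, spec$os_hazard_no_emr)
  t_os <- t_pfs + rexp(n, haz_os)   # death follows progression
  os_event <- t_os <= spec$censor_time
  os_months <- pmin(t_os, spec$censor_time)

  # MRD monitored in patients reaching CMR; positivity presages progression
  monitored <- cmr & runif(n) < 0.85
  mrd <- rep(NA_character_, n)
  mrd[monitored] <- ifelse(pfs_event[monitored] & runif(sum(monitored)) < 0.7,
                           "positive", "negative")

  cohort <- tibble::tibble(
    patient = sprintf("P%02d", seq_len(n)),
    emr = emr,
    eot_response = eot_response,
    mrd = mrd,
    baseline_hge = baseline,
    ldh_uln = ldh,
    ripi = ripi,
    pfs_months = pfs_months,
    pfs_event = pfs_event,
    os_months = os_months,
    os_event = os_event
  )
  burden <- tibble::tibble(
    patient = rep(cohort$patient, each = 4L),
    timepoint = rep(c("baseline", "early", "eot", "remission"), n),
    day = rep(c(0L, 10L, 150L, 270L), n),
    hge_per_ml = as.numeric(rbind(baseline, early, eot, late))
  )
  structure(list(cohort = cohort, burden = burden, spec = spec,
                 seed = as.integer(seed)),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> ", nrow(x$cohort), " patients (",
      sum(x$cohort$emr), " EMR)\n", sep = "")
  invisible(x)
}
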