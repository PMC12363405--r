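# ctDNA burden quantification, molecular response and MRD classification.
#
# Burden follows the CAPP-Seq convention: plasma cfDNA mass is converted to
# haploid genome equivalents (hGE) at 3.3 pg per haploid genome and scaled
# by the mean variant allele fraction over tracked tumour reporters:
#   hGE/mL = (cfDNA ng/mL * 1000 / 3.3) * mean VAF.
# EMR is a >= 2 log10 reduction in burden between baseline and the early
# on-treatment draw (boundary inclusive).

#' Convert mean reporter VAF and cfDNA concentration to ctDNA burden
#'
#' @param mean_vaf Mean variant allele fraction over tracked reporters.
#' @param cfdna_ng_per_ml Plasma cfDNA concentration in ng per mL.
#' @param pg_per_hge Mass of one haploid genome equivalent in pg.
#' @return Numeric burden in hGE/mL (vectorised).
#' @export
#' @examples
#' quantify_burden(0.10, 10)  # 303.03 hGE/mL
quantify_burden <- function(mean_vaf, cfdna_ng_per_ml, pg_per_hge = 3.3) {
  if (any(mean_vaf < 0, na.rm = TRUE) || any(cfdna_ng_per_ml < 0, na.rm = TRUE) ||
      pg_per_hge <= 0) {
    abort("Burden inputs must be non-negative (pg_per_hge positive).")
  }
  (cfdna_ng_per_ml * 1000 / pg_per_hge) * mean_vaf
}

#' Quantify ctDNA burden for a table of samples
#'
#' @param samples Tibble with columns `patient`, `timepoint`, `day`,
#'   `cfdna_ng_per_ml`, `mean_vaf` (mean VAF over reporters with non-missing
#'   genotyping).
#' @param pg_per_hge Mass per haploid genome equivalent (pg).
#' @return Input tibble with `hge_per_ml`, `log10_hge` (`NA` when burden is
#'   0) and `detected` appended.
#' @export
quantify_samples <- function(samples, pg_per_hge = 3.3) {
  stopifnot(all(c("patient", "timepoint", "cfdna_ng_per_ml", "mean_vaf")
                %in% names(samples)))
  samples |>
    dplyr::mutate(
      hge_per_ml = quantify_burden(.data$mean_vaf, .data$cfdna_ng_per_ml,
                                   pg_per_hge),
      log10_hge = dplyr::if_else(.data$hge_per_ml > 0,
                                 log10(.data$hge_per_ml), NA_real_),
      detected = .data$hge_per_ml > 0
    )
}

#' Classify early molecular response (EMR)
#'
#' EMR is a reduction of at least `threshold_log10` (default 2) log10 in
#' ctDNA burden between the baseline and early (cycle 1) samples, boundary
#' inclusive. An undetected early sample is imputed at `floor_hge` before
#' the log change is computed; a patient whose baseline is undetected is
#' unevaluable. Early draws outside the expected day window (the assay's
#' early samples were drawn a median of 10 days into cycle 1, range 7-22)
#' trigger a warning only.
#'
#' @param samples Output of [quantify_samples()] containing `baseline` and
#'   `early` timepoints per patient.
#' @param floor_hge Imputation floor for undetected samples, hGE/mL.
#' @param threshold_log10 log10 reduction defining EMR.
#' @param day_window Acceptable early-draw day range (inclusive).
#' @return One row per patient: `patient`, `baseline_hge`, `early_hge`,
#'   `delta_log10` (baseline minus early, positive = reduction), `emr`
#'   (`NA` when unevaluable).
#' @export
#' @examples
#' s <- tibble::tibble(
#'   patient = "P01", timepoint = c("baseline", "early"), day = c(0, 10),
#'   cfdna_ng_per_ml = c(33, 33), mean_vaf = c(0.1, 0.001))
#' classify_emr(quantify_samples(s))
classify_emr <- function(samples, floor_hge = 1, threshold_log10 = 2,
                         day_window = c(7, 22)) {
  stopifnot(all(c("patient", "timepoint", "hge_per_ml") %in% names(samples)))
  .assert_pos(floor_hge, "floor_hge")
  wide <- samples |>
    dplyr::filter(.data$timepoint %in% c("baseline", "early")) |>
    dplyr::select("patient", "timepoint", "hge_per_ml",
                  dplyr::any_of("day")) |>
    tidyr::pivot_wider(id_cols = "patient", names_from = "timepoint",
                       values_from = c("hge_per_ml", dplyr::any_of("day")))
  if ("day_early" %in% names(wide)) {
    off <- !is.na(wide$day_early) &
      (wide$day_early < day_window[1] | wide$day_early > day_window[2])
    if (any(off)) {
      warn(sprintf("%d early sample(s) drawn outside day window [%g, %g].",
                   sum(off), day_window[1], day_window[2]))
    }
  }
  wide |>
    dplyr::mutate(
      baseline_hge = .data$hge_per_ml_baseline,
      early_hge = .data$hge_per_ml_early,
      early_imputed = dplyr::if_else(is.na(.data$early_hge), NA_real_,
                                     pmax(.data$early_hge, floor_hge)),
      delta_log10 = dplyr::if_else(
        !is.na(.data$baseline_hge) & .data$baseline_hge > 0,
        log10(.data$baseline_hge) - log10(.data$early_imputed),
        NA_real_),
      emr = .data$delta_log10 >= threshold_log10
    ) |>
    dplyr::select("patient", "baseline_hge", "early_hge", "delta_log10",
                  "emr")
}

#' Call measurable residual disease (MRD)
#'
#' MRD is positive when either evidence route fires:
#' (a) the aggregate one-sided binomial test of summed alt molecules over
#' summed informative molecules across reporters against the background rate
#' gives p <= `alpha` *and* at least two distinct reporters carry at least
#' one alt molecule, or (b) at least `min_phased_molecules` consensus
#' molecules carry both members of a tracked phased pair. The sample is
#' unevaluable when fewer than `min_informative` informative molecules were
#' genotyped in total (or no reporter could be genotyped).
#'
#' @param tracked_geno A [genotype_tracked()] tibble for the sample's
#'   reporters (after any CHIP-style exclusions).
#' @param error_model An [estimate_background_error()] model.
#' @param phased_support Double-alt molecule count over tracked phased pairs
#'   (e.g. `sum(detect_phased_pairs(...)$n_both_alt)`), or a
#'   [detect_phased_pairs()] tibble.
#' @param alpha Significance level of the aggregate test.
#' @param min_phased_molecules Phased-evidence threshold for route (b).
#' @param min_informative Evaluability floor on total informative molecules.
#' @param exclude Optional tibble (`chrom`, `pos`) of reporters to drop
#'   before testing (e.g. suspected clonal-haematopoiesis variants).
#' @return One-row tibble: `status` (positive / negative / unevaluable),
#'   `p_aggregate`, `n_alt`, `n_informative`, `n_reporters`,
#'   `n_reporters_positive`, `n_phased_molecules`.
#' @export
call_mrd <- function(tracked_geno, error_model, phased_support = 0L,
                     alpha = 0.05, min_phased_molecules = 1L,
                     min_informative = 1000L, exclude = NULL) {
  stopifnot(inherits(error_model, "error_model"))
  if (is.data.frame(phased_support)) {
    phased_support <- sum(phased_support$n_both_alt)
  }
  g <- tracked_geno
  if (!is.null(exclude) && nrow(exclude)) {
    g <- dplyr::anti_join(g, exclude, by = c("chrom", "pos"))
  }
  g <- dplyr::filter(g, !is.na(.data$vaf))
  n_inf <- sum(g$informative)
  if (nrow(g) == 0 || n_inf < min_informative) {
    return(tibble::tibble(status = "unevaluable", p_aggregate = NA_real_,
                          n_alt = sum(g$alt_count), n_informative = n_inf,
                          n_reporters = nrow(g),
                          n_reporters_positive = sum(g$alt_count > 0),
                          n_phased_molecules = as.integer(phased_support)))
  }
  n_alt <- sum(g$alt_count)
  p <- binom_tail(n_alt, n_inf, error_model$rate)
  pos_a <- p <= alpha && sum(g$alt_count > 0) >= 2
  pos_b <- phased_support >= min_phased_molecules
  tibble::tibble(
    status = if (pos_a || pos_b) "positive" else "negative",
    p_aggregate = p,
    n_alt = n_alt,
    n_informative = n_inf,
    n_reporters = nrow(g),
    n_reporters_positive = sum(g$alt_count > 0),
    n_phased_molecules = as.integer(phased_support)
  )
}

#' Run a dilution-series sensitivity / limit-of-detection analysis
#'
#' For each mix fraction and replicate: simulate a two-individual admixture
#' over `n_sites` discordant SNP sites ([simulate_dilution()]), collapse UMI
#' families, estimate the background error rate from the 2 x `n_sites`
#' flanking bases, genotype the interrogated sites, and score a site as
#' detected when its alt molecule count is at least `min_alt` and its
#' one-sided binomial tail against the pooled background rate is at or below
#' `alpha / n_sites` (Bonferroni over interrogated sites).
#'
#' @param mix_fractions Numeric vector of spike fractions (descending by
#'   convention); 0 probes the familywise false-positive behaviour.
#' @param replicates Replicates per fraction.
#' @param config A [sim_config()]; `n_molecules` is the per-site molecule
#'   count and `seed` anchors the replicate seed stream.
#' @param n_sites Number of discordant sites.
#' @param b_het_fraction Fraction of discordant sites heterozygous in the
#'   spiked individual (default 0: hom-alt, expected VAF = mix fraction).
#' @param min_family,majority_frac Consensus parameters.
#' @param alpha Familywise significance level for detection.
#' @param min_alt Minimum alt molecules for detection.
#' @return An `lod_report`: list with `per_fraction` (tibble: `fraction`,
#'   `n_sites`, `mean_detected`, `detection_rate`, `mean_vaf_detected`,
#'   `mean_background`), `replicates` (per-replicate detail),
#'   `sensitivity` (lowest fraction with >= 95% mean detection, `NA` if
#'   none) and the parameters used.
#' @export
run_dilution_series <- function(mix_fractions, replicates, config,
                                n_sites = 101L, b_het_fraction = 0,
                                min_family = 3L, majority_frac = 2 / 3,
                                alpha = 0.05, min_alt = 2L) {
  stopifnot(inherits(config, "sim_config"))
  gts <- dilution_genotypes(config$panel, n_sites, b_het_fraction,
                            seed = derive_seed(config$seed, 1L))
  rep_rows <- list()
  for (fi in seq_along(mix_fractions)) {
    f <- mix_fractions[fi]
    for (r in seq_len(replicates)) {
      cfg_r <- config
      cfg_r$seed <- derive_seed(config$seed, fi * 1000L + r)
      sam <- simulate_dilution(cfg_r, gts$a, gts$b, f, n_sites)
      grouped <- group_umi_families(sam$reads)
      cons <- collapse_families(grouped, sam$deviations, config$panel,
                                min_family = min_family,
                                majority_frac = majority_frac)
      sites <- sam$truth$sites
      flanks <- tibble::tibble(
        chrom = rep(sites$chrom, 2L),
        pos = c(sites$pos - 1L, sites$pos + 1L)
      )
      em <- estimate_background_error(cons, flanks, config$panel)
      pu <- build_pileup(cons, config$panel,
                         positions = sites |> dplyr::select("chrom", "pos"))
      geno <- genotype_tracked(pu, sites |>
                                 dplyr::select("chrom", "pos", "ref", "alt"))
      p_site <- binom_tail(geno$alt_count, geno$informative, em$rate)
      is_det <- geno$alt_count >= min_alt & p_site <= alpha / n_sites
      vaf_det <- if (any(is_det)) mean(geno$vaf[is_det]) else NA_real_
      rep_rows[[length(rep_rows) + 1L]] <- tibble::tibble(
        fraction = f, replicate = r, n_sites = n_sites,
        detected = sum(is_det),
        mean_vaf_detected = vaf_det,
        mean_informative = mean(geno$informative),
        background = em$rate
      )
    }
  }
  reps <- dplyr::bind_rows(rep_rows)
  per_fraction <- reps |>
    dplyr::summarise(
      n_sites = .data$n_sites[1],
      mean_detected = mean(.data$detected),
      detection_rate = mean(.data$detected) / .data$n_sites[1],
      mean_vaf_detected = mean(.data$mean_vaf_detected, na.rm = TRUE),
      mean_informative = mean(.data$mean_informative),
      mean_background = mean(.data$background),
      .by = "fraction"
    ) |>
    dplyr::arrange(dplyr::desc(.data$fraction))
  hit <- per_fraction |>
    dplyr::filter(.data$fraction > 0,
                  .data$detection_rate >= 0.95)
  structure(
    list(per_fraction = per_fraction, replicates = reps,
         sensitivity = if (nrow(hit)) min(hit$fraction) else NA_real_,
         n_sites = as.integer(n_sites), alpha = alpha,
         min_family = as.integer(min_family), min_alt = as.integer(min_alt)),
    class = "lod_report"
  )
}

#' @export
print.lod_report <- function(x, ...) {
  cat("<lod_report> sensitivity threshold:",
      if (is.na(x$sensitivity)) "not reached" else
        sprintf("%.4g (>=95%% of %d sites)", x$sensitivity, x$n_sites), "\n")
  print(x$per_fraction)
  invisible(x)
}
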