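#' Simulation configuration for synthetic cfDNA samples
#'
#' Bundles every knob of the read-level generator. Defaults describe the
#' assay being emulated: 10-nt UMIs, mononucleosomal fragment sizes
#' (truncated normal, mean 167 bp, sd 40, bounded to \[50, 400\]),
#' overdispersed PCR family sizes (shifted negative binomial, minimum 1),
#' and a raw per-base sequencing error rate of 0.3%.
#'
#' @param panel A [sim_panel()] object supplying targets, backbone and
#'   reference sequence.
#' @param seed Integer seed; all randomness in sample generation flows from it.
#' @param n_molecules Unique source molecules. For [simulate_sample()] this is
#'   the per-sample total spread across gene targets; for [simulate_dilution()]
#'   it is the number of molecules covering each interrogated SNP site.
#' @param family_mean,family_disp Mean and dispersion of the shifted
#'   negative-binomial UMI family-size distribution: size = 1 + NB with mean
#'   `family_mean - 1` and size parameter `family_disp`.
#' @param per_base_error Probability that any sequenced base is misread
#'   (uniform over the three other bases).
#' @param fragment_mean,fragment_sd,fragment_min,fragment_max Fragment length
#'   model (truncated normal, bp).
#' @param umi_length UMI length; the assay uses 10-nt UMIs and the pipeline
#'   requires exactly 10.
#'
#' @return A `sim_config` list.
#' @export
#' @examples
#' pan <- sim_panel(n_genes = 2, gene_bp = 500, n_backbone = 6, seed = 1)
#' cfg <- sim_config(pan, seed = 42, n_molecules = 500)
sim_config <- function(panel, seed = 1L, n_molecules = 20000L,
                       family_mean = 4, family_disp = 2,
                       per_base_error = 0.003,
                       fragment_mean = 167, fragment_sd = 40,
                       fragment_min = 50, fragment_max = 400,
                       umi_length = 10L) {
  stopifnot(inherits(panel, "cfdna_panel"))
  if (nrow(panel$targets) == 0 && is.null(panel$backbone)) {
    abort("`panel` has no targets.")
  }
  .assert_prob(per_base_error, "per_base_error")
  .assert_pos(n_molecules, "n_molecules")
  if (family_mean < 1) abort("`family_mean` must be >= 1 (families have >= 1 read).")
  .assert_pos(family_disp, "family_disp")
  .assert_pos(c(fragment_mean, fragment_sd, fragment_min, fragment_max), "fragment lengths")
  if (fragment_min > fragment_max) abort("`fragment_min` must be <= `fragment_max`.")
  if (as.integer(umi_length) != 10L) {
    abort("`umi_length` must be 10: the assay design and readers assume 10-nt UMIs.")
  }
  structure(
    list(
      panel = panel, seed = as.integer(seed),
      n_molecules = as.integer(n_molecules),
      family_mean = family_mean, family_disp = family_disp,
      per_base_error = per_base_error,
      fragment_mean = fragment_mean, fragment_sd = fragment_sd,
      fragment_min = fragment_min, fragment_max = fragment_max,
      umi_length = 10L
    ),
    class = "sim_config"
  )
}

#' Ground-truth specification for a simulated sample
#'
#' Describes what is planted in a sample: somatic variants (optionally grouped
#' into in-cis phase groups), the germline genotype of the contributing
#' individual at backbone loci, and copy-number segments.
#'
#' @param variants Tibble with columns `chrom`, `pos`, `alt`, `vaf` and
#'   optionally `phase_group` (variants sharing a non-`NA` phase group are
#'   planted in cis on the same molecules). `ref` is taken from the panel.
#' @param germline Tibble with columns `chrom`, `pos`, `genotype`
#'   (0 = hom-ref, 1 = het, 2 = hom-alt) and optionally `alt`.
#' @param cnv_segments Tibble with columns `chrom`, `start`, `end`, `copies`
#'   (total tumour copy number, >= 0).
#' @param cis_prob Probability that a non-anchor member of a phase group
#'   co-occurs on the tumour haplotype of a carrier molecule (1 = strict cis).
#'
#' @return A `truth_set` list.
#' @export
truth_set <- function(variants = NULL, germline = NULL, cnv_segments = NULL,
                      cis_prob = 1) {
  .assert_prob(cis_prob, "cis_prob")
  if (!is.null(variants) && nrow(variants)) {
    stopifnot(all(c("chrom", "pos", "alt", "vaf") %in% names(variants)))
    if (any(variants$vaf < 0 | variants$vaf > 1)) abort("variant `vaf` must lie in [0, 1].")
    if (!"phase_group" %in% names(variants)) variants$phase_group <- NA_integer_
    bad <- variants |>
      dplyr::summarise(s = sum(.data$vaf), .by = c("chrom", "pos")) |>
      dplyr::filter(.data$s > 1)
    if (nrow(bad)) {
      abort("Overlapping variants at one locus with VAF sum > 1; rejecting configuration.")
    }
    ph <- dplyr::filter(variants, !is.na(.data$phase_group))
    if (nrow(ph)) {
      grp <- ph |>
        dplyr::summarise(
          nchrom = dplyr::n_distinct(.data$chrom),
          span = max(.data$pos) - min(.data$pos),
          .by = "phase_group"
        )
      if (any(grp$nchrom > 1) || any(grp$span > 100)) {
        abort("Phase-group members must lie on one chromosome within 100 bp.")
      }
    }
  }
  if (!is.null(germline) && nrow(germline)) {
    stopifnot(all(c("chrom", "pos", "genotype") %in% names(germline)))
    if (!all(germline$genotype %in% 0:2)) abort("`genotype` must be 0, 1 or 2.")
  }
  if (!is.null(cnv_segments) && nrow(cnv_segments)) {
    stopifnot(all(c("chrom", "start", "end", "copies") %in% names(cnv_segments)))
    if (any(cnv_segments$copies < 0)) abort("`copies` must be >= 0.")
    ov <- cnv_segments |>
      dplyr::arrange(.data$chrom, .data$start) |>
      dplyr::mutate(prev_end = dplyr::lag(.data$end), .by = "chrom") |>
      dplyr::filter(!is.na(.data$prev_end) & .data$start <= .data$prev_end)
    if (nrow(ov)) abort("`cnv_segments` must be non-overlapping.")
  }
  structure(
    list(variants = variants, germline = germline,
         cnv_segments = cnv_segments, cis_prob = cis_prob),
    class = "truth_set"
  )
}

#' Clinical cohort simulation specification
#'
#' Parameters for [simulate_cohort()]. Defaults are calibrated to the cohort
#' structure this package emulates: 17 patients of whom 8/17 attain early
#' molecular response (EMR), progression hazards implying a median PFS of
#' ~4.6 months without EMR and a hazard ratio of ~0.11 with EMR,
#' administrative censoring at 50 months of potential follow-up, and
#' log-normal baseline burden with median ~531 hGE/mL and IQR ~280-2072.
#'
#' @param n_patients Number of patients.
#' @param emr_fraction Probability a patient attains EMR.
#' @param hazard_emr,hazard_no_emr Exponential progression hazards (events per
#'   month) by EMR stratum.
#' @param os_hazard_emr,os_hazard_no_emr Exponential death hazards per month.
#' @param censor_time Administrative censoring time in months.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters (natural log)
#'   of baseline burden in hGE/mL.
#' @param cmr_prob_emr,cmr_prob_no_emr Probability of end-of-treatment
#'   complete metabolic response by stratum.
#' @return A `clinical_sim_spec` list.
#' @export
clinical_sim_spec <- function(n_patients = 17L, emr_fraction = 8 / 17,
                              hazard_emr = 0.0165, hazard_no_emr = 0.152,
                              os_hazard_emr = 0.008, os_hazard_no_emr = 0.05,
                              censor_time = 50,
                              baseline_meanlog = log(531), baseline_sdlog = 1.48,
                              cmr_prob_emr = 1, cmr_prob_no_emr = 0.125) {
  .assert_prob(emr_fraction, "emr_fraction")
  .assert_prob(cmr_prob_emr, "cmr_prob_emr")
  .assert_prob(cmr_prob_no_emr, "cmr_prob_no_emr")
  .assert_pos(c(hazard_emr, hazard_no_emr, os_hazard_emr, os_hazard_no_emr),
              "hazard rates")
  .assert_pos(censor_time, "censor_time")
  .assert_pos(n_patients, "n_patients")
  structure(
    list(n_patients = as.integer(n_patients), emr_fraction = emr_fraction,
         hazard_emr = hazard_emr, hazard_no_emr = hazard_no_emr,
         os_hazard_emr = os_hazard_emr, os_hazard_no_emr = os_hazard_no_emr,
         censor_time = censor_time,
         baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
         cmr_prob_emr = cmr_prob_emr, cmr_prob_no_emr = cmr_prob_no_emr),
    class = "clinical_sim_spec"
  )
}
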