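#' Generate a bundled small end-to-end test dataset
#'
#' Builds, from one seed, everything [run_pipeline()] consumes: a small
#' panel bundle, per-patient germline VCF, UMI-tagged SAM reads for four
#' simulated patients at four timepoints (two patients with a deep early
#' molecular response, two without), one two-individual dilution sample,
#' three CNV-neutral normal backbone profiles plus one profile carrying a
#' one-copy chr17p loss, a sample sheet, a 17-patient clinical cohort table
#' with the response structure the package's outcome layer is designed
#' around (8 EMR patients, all CMR; 9 non-EMR with 1 CMR, 2 PR, 5 PD/ED and
#' 1 unevaluable), and a ready-to-run `config.yaml`.
#'
#' The fixture is intentionally shallow (about 4000 molecules per sample)
#' so it generates in seconds; its `config.yaml` relaxes the depth-dependent
#' thresholds accordingly.
#'
#' @param dir Output directory.
#' @param seed Integer seed; regeneration with the same seed is
#'   byte-identical.
#' @param n_molecules Source molecules per plasma sample.
#' @return `dir`, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1L, n_molecules = 4000L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- sim_panel(n_genes = 6, gene_bp = 800, n_backbone = 60,
                     backbone_flank = 150, seed = derive_seed(seed, 1L))
  write_panel(panel, file.path(dir, "panel"))

  patients <- sprintf("P%02d", 1:4)
  germ <- purrr::map(seq_along(patients), function(i) {
    hwe_genotypes(panel, seed = derive_seed(seed, 10L + i)) |>
      dplyr::select("chrom", "pos", "genotype")
  }) |> setNames(patients)
  dil <- dilution_genotypes(panel, n_sites = 20,
                            seed = derive_seed(seed, 30L))
  write_vcf_genotypes(c(germ, list(INDIV_A = dil$a, INDIV_B = dil$b)),
                      panel, file.path(dir, "germline.vcf"))

  # three somatic reporters per patient, two of them a cis pair 60 bp apart
  truth_for <- function(i) {
    tg <- panel$targets[((i - 1L) %% nrow(panel$targets)) + c(1L, 2L), ]
    pos <- c(tg$start[1] + 200L, tg$start[1] + 260L, tg$start[2] + 400L)
    chrom <- c(tg$chrom[1], tg$chrom[1], tg$chrom[2])
    ref <- ref_base(panel, chrom, pos)
    v <- tibble::tibble(
      chrom = chrom, pos = pos,
      # deterministic alternative allele: the next base cyclically
      alt = BASES[match(ref, BASES) %% 4L + 1L],
      vaf = c(0.20, 0.20, 0.10),
      phase_group = c(1L, 1L, NA_integer_)
    )
    truth_set(variants = v, germline = germ[[i]])
  }
  tf <- list(  # per-patient tumour fraction by timepoint
    c(baseline = 1, early = 0.002, eot = 0, remission = 0),     # EMR
    c(baseline = 1, early = 0.001, eot = 0, remission = 0.05),  # EMR, MRD+
    c(baseline = 1, early = 0.6, eot = 0.4, remission = 0.3),   # no EMR
    c(baseline = 1, early = 0.5, eot = 0.2, remission = 0.1)    # no EMR
  )
  days <- c(baseline = 0L, early = 10L, eot = 150L, remission = 270L)
  cfdna <- c(baseline = 35, early = 20, eot = 8, remission = 6)

  reads_dir <- file.path(dir, "reads")
  dir.create(reads_dir, showWarnings = FALSE)
  sheet <- list()
  for (i in seq_along(patients)) {
    tr <- truth_for(i)
    for (tp in names(days)) {
      cfg <- sim_config(panel, seed = derive_seed(seed, 100L + 10L * i +
                                                    match(tp, names(days))),
                        n_molecules = n_molecules, family_mean = 3.5,
                        fragment_max = 250)
      s <- simulate_sample(cfg, tr, tumour_fraction = tf[[i]][[tp]])
      sam <- file.path(reads_dir, sprintf("%s_%s.sam", patients[i], tp))
      write_sam(s, sam)
      sheet[[length(sheet) + 1L]] <- tibble::tibble(
        patient = patients[i], timepoint = tp, day = days[[tp]],
        cfdna_ng_per_ml = cfdna[[tp]], sam = sam
      )
    }
  }
  readr::write_csv(dplyr::bind_rows(sheet), file.path(dir, "samples.csv"))

  # one dilution sample (5% spike over 20 sites)
  dcfg <- sim_config(panel, seed = derive_seed(seed, 200L), n_molecules = 300,
                     fragment_max = 250)
  dsam <- simulate_dilution(dcfg, dil$a, dil$b, mix_fraction = 0.05,
                            n_sites = 20)
  write_sam(dsam, file.path(reads_dir, "dilution_0.05.sam"))
  readr::write_tsv(dsam$truth$sites, file.path(dir, "dilution_sites.tsv"))

  # normal profiles and a chr17p one-copy loss for the CNV layer
  norm_dir <- file.path(dir, "normals")
  dir.create(norm_dir, showWarnings = FALSE)
  normal_paths <- purrr::map_chr(1:3, function(k) {
    cfg <- sim_config(panel, seed = derive_seed(seed, 300L + k))
    prof <- simulate_cnv_sample(cfg, tumour_fraction = 0,
                                depth_per_locus = 500)
    fp <- file.path(norm_dir, sprintf("normal%d.tsv", k))
    readr::write_tsv(prof, fp)
    fp
  })
  loss_cfg <- sim_config(panel, seed = derive_seed(seed, 310L))
  loss <- simulate_cnv_sample(
    loss_cfg,
    cnv_segments = tibble::tibble(chrom = "chr17", start = 1, end = 5e7,
                                  copies = 1),
    tumour_fraction = 0.6, depth_per_locus = 500
  )
  readr::write_tsv(loss, file.path(dir, "cnv_17p_loss.tsv"))

  write_cohort(fixture_cohort(), file.path(dir, "cohort.csv"))

  cfg_yaml <- list(
    paths = list(
      panel_dir = file.path(dir, "panel"),
      sample_sheet = file.path(dir, "samples.csv"),
      germline_vcf = file.path(dir, "germline.vcf"),
      cohort_csv = file.path(dir, "cohort.csv"),
      normal_profiles = as.list(normal_paths),
      out_dir = file.path(dir, "out")
    ),
    # fixture-depth thresholds; see package vignette
    mrd = list(min_informative = 10L),
    cnv = list(min_loci = 2L, min_ref_depth = 20),
    identity = list(min_depth = 4L, min_loci = 15L),
    seed = as.integer(seed)
  )
  yaml::write_yaml(cfg_yaml, file.path(dir, "config.yaml"))
  invisible(dir)
}

# the 17-patient outcome table: 8 EMR all CMR; 9 non-EMR with 1 CMR, 2 PR,
# 5 PD/ED (4 progressions + 1 early death) and 1 without an evaluable EOT
# response; non-EMR median PFS ~4.6 months, potential follow-up 50 months
fixture_cohort <- function() {
  tibble::tibble(
    patient = sprintf("C%02d", 1:17),
    emr = c(rep(TRUE, 8), rep(FALSE, 9)),
    eot_response = c(rep("CMR", 8),
                     "CMR", "PR", "PR", "PD/ED", "PD/ED", "PD/ED", "PD/ED",
                     "PD/ED", NA),
    mrd = c("positive", rep("negative", 7),
            "negative", NA, NA, NA, NA, NA, NA, NA, "negative"),
    baseline_hge = c(520, 310, 2100, 150, 890, 410, 260, 1500,
                     640, 980, 330, 2800, 450, 1200, 170, 760, 540),
    ldh_uln = c(1.1, 0.8, 2.4, 0.7, 1.6, 1.0, 0.9, 2.0,
                1.3, 1.7, 0.9, 2.9, 1.1, 1.9, 0.8, 1.5, 1.2),
    ripi = c("good", "poor", "poor", "good", "poor", "good", "poor", "poor",
             "poor", "good", "poor", "poor", "good", "poor", "good", "poor",
             "poor"),
    pfs_months = c(30, 50, 50, 50, 40, 50, 50, 50,
                   50, 8, 10, 2, 3, 4, 4.57, 1.5, 6),
    pfs_event = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                  FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    os_months = c(50, 50, 50, 50, 45, 50, 50, 50,
                  50, 12, 14, 4, 5, 7, 8, 1.5, 10),
    os_event = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                 FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  )
}
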