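# generator correctness: bookkeeping, planted-allele frequencies, error
# rates, fragment/family-size distributions, dilution and CNV expectations

test_that("simulated sample bookkeeping reconciles with emitted reads", {
  pan <- small_panel(seed = 11)
  cfg <- sim_config(pan, seed = 21, n_molecules = 800, per_base_error = 0,
                    fragment_max = 250)
  v <- variants_at(pan, 1, c(100, 160), vaf = c(0.5, 0.3))
  tr <- truth_set(variants = v |> dplyr::select(-ref))
  s <- simulate_sample(cfg, tr)

  expect_equal(nrow(s$reads), sum(s$molecules$family_size))
  expect_true(all(s$molecules$family_size >= 1))
  # coordinates inside captured windows
  widx <- plasmamrd:::window_index(pan, s$reads$chrom, s$reads$start)
  expect_false(anyNA(widx))
  expect_true(all(s$reads$end <= pan$windows$end[widx]))
  # with zero sequencing error every read deviation is an inherited allele
  exp_dev <- s$reads |>
    dplyr::select(read_id, molecule_id) |>
    dplyr::inner_join(s$molecule_alleles, by = "molecule_id",
                      relationship = "many-to-many") |>
    dplyr::arrange(read_id, pos)
  got <- s$deviations |> dplyr::arrange(read_id, pos)
  expect_equal(got$read_id, exp_dev$read_id)
  expect_equal(got$pos, exp_dev$pos)
  expect_equal(got$base, exp_dev$base)
})

test_that("planted VAF is recovered within the exact binomial interval", {
  pan <- small_panel(seed = 12, n_backbone = 0)
  cfg <- sim_config(pan, seed = 31, n_molecules = 1000, per_base_error = 0,
                    fragment_max = 250)
  v <- variants_at(pan, 1, 300, vaf = 0.5)
  s <- simulate_sample(cfg, truth_set(variants = v |> dplyr::select(-ref)))
  covering <- sum(s$molecules$chrom == v$chrom & s$molecules$start <= v$pos &
                    s$molecules$end >= v$pos)
  alt <- sum(s$molecule_alleles$pos == v$pos)
  ci <- stats::binom.test(alt, covering)$conf.int
  expect_gt(0.5, ci[1])
  expect_lt(0.5, ci[2])
})

test_that("tumour fraction scales planted alleles down to zero", {
  pan <- small_panel(seed = 13, n_backbone = 0)
  cfg <- sim_config(pan, seed = 41, n_molecules = 300, per_base_error = 0,
                    fragment_max = 250)
  v <- variants_at(pan, 1, 300, vaf = 0.4)
  s0 <- simulate_sample(cfg, truth_set(variants = v |> dplyr::select(-ref)),
                        tumour_fraction = 0)
  expect_identical(nrow(s0$molecule_alleles), 0L)
  expect_identical(nrow(s0$deviations), 0L)
})

test_that("empirical mismatch rate matches the configured per-base error", {
  pan <- small_panel(seed = 14, n_backbone = 0)
  e <- 0.003
  cfg <- sim_config(pan, seed = 51, n_molecules = 2000, per_base_error = e,
                    fragment_max = 250)
  s <- simulate_sample(cfg, truth_set())   # variant-free
  total <- sum(s$reads$end - s$reads$start + 1)
  # an error can reproduce the reference base at rate 0 here (all flips move
  # away from ref at variant-free sites), so deviations count errors exactly
  rate <- nrow(s$deviations) / total
  se <- sqrt(e * (1 - e) / total)
  expect_lt(abs(rate - e), 3 * se)
})

test_that("family sizes and fragment lengths follow the configured model", {
  pan <- small_panel(seed = 15, n_backbone = 0, gene_bp = 900)
  cfg <- sim_config(pan, seed = 61, n_molecules = 4000, per_base_error = 0)
  s <- simulate_sample(cfg, truth_set())
  m <- cfg$family_mean
  sd_fam <- sqrt(m - 1 + (m - 1)^2 / cfg$family_disp)
  expect_lt(abs(mean(s$molecules$family_size) - m),
            3 * sd_fam / sqrt(nrow(s$molecules)))
  len <- s$molecules$end - s$molecules$start + 1
  expect_true(all(len >= 1 & len <= cfg$fragment_max))
})

test_that("conflicting variants at one locus are rejected", {
  pan <- small_panel(seed = 16)
  v <- variants_at(pan, 1, c(100, 100), vaf = c(0.6, 0.6))
  v$alt <- c("A", "C")[match(v$alt, unique(v$alt))]
  expect_error(truth_set(variants = v |> dplyr::select(-ref)),
               "VAF sum")
})

test_that("dilution admixture hits the expected minor-allele fractions", {
  pan <- small_panel(seed = 17, n_backbone = 24, flank = 200)
  cfg <- sim_config(pan, seed = 71, n_molecules = 600, per_base_error = 0,
                    fragment_max = 300)
  gts <- dilution_genotypes(pan, n_sites = 10)

  # mix 0: no B molecules, no alt alleles at all without sequencing error
  s0 <- simulate_dilution(cfg, gts$a, gts$b, mix_fraction = 0, n_sites = 10)
  expect_identical(nrow(s0$molecule_alleles), 0L)
  expect_true(all(s0$molecules$source == "A"))

  # mix 0.5 at B hom-alt sites: expected VAF 0.5
  s5 <- simulate_dilution(cfg, gts$a, gts$b, mix_fraction = 0.5, n_sites = 10)
  vaf_obs <- nrow(s5$molecule_alleles) / nrow(s5$molecules)
  expect_lt(abs(vaf_obs - 0.5), 3 * sqrt(0.25 / nrow(s5$molecules)))
  # bookkeeping: every alt allele sits on a B molecule at its own site
  src <- s5$molecules$source[match(s5$molecule_alleles$molecule_id,
                                   s5$molecules$molecule_id)]
  expect_true(all(src == "B"))
})

test_that("dilution expected alt-molecule count matches generator draws", {
  pan <- small_panel(seed = 18, n_backbone = 24, flank = 200)
  cfg <- sim_config(pan, seed = 81, n_molecules = 5000, per_base_error = 0,
                    fragment_max = 300)
  gts <- dilution_genotypes(pan, n_sites = 8)
  s <- simulate_dilution(cfg, gts$a, gts$b, mix_fraction = 0.002, n_sites = 8)
  # hom-alt spike: expected alt molecules per site = n * mix = 10
  per_site <- s$molecule_alleles |>
    dplyr::count(chrom, pos) |>
    dplyr::right_join(s$truth$sites |> dplyr::select(chrom, pos),
                      by = c("chrom", "pos")) |>
    dplyr::mutate(n = dplyr::coalesce(n, 0L))
  expect_equal(nrow(per_site), 8)
  total <- sum(per_site$n)
  expect_lt(abs(total - 8 * 10), 3 * sqrt(8 * 10))
  expect_error(simulate_dilution(cfg, gts$a, gts$a, 0.1, 8), "discordant")
})

test_that("CNV sample depths and allele fractions follow the copy model", {
  pan <- sim_panel(n_genes = 1, gene_bp = 300, n_backbone = 220, seed = 19)
  cfg <- sim_config(pan, seed = 91)
  segs <- tibble::tibble(chrom = "chr1", start = 1, end = 5e7, copies = 1)

  neutral <- simulate_cnv_sample(cfg, tumour_fraction = 0,
                                 depth_per_locus = 2000)
  expect_true(all(neutral$expected_rel_depth == 1))

  full <- simulate_cnv_sample(cfg, segs, tumour_fraction = 1,
                              depth_per_locus = 2000)
  in_seg <- full$chrom == "chr1" & full$arm == "p"
  expect_true(all(full$expected_rel_depth[in_seg] == 0.5))
  expect_lt(abs(log2(mean(full$depth[in_seg]) / 2000) - (-1)), 0.1)

  half <- simulate_cnv_sample(cfg, segs, tumour_fraction = 0.5,
                              depth_per_locus = 3000)
  het <- half$genotype == 1 & half$chrom == "chr1" & half$arm == "p"
  baf <- half$alt_count[het] / half$depth[het]
  # minor-allele fraction 1/3 whichever haplotype was lost
  minor <- pmin(baf, 1 - baf)
  expect_lt(abs(mean(minor) - 1 / 3), 0.05)
})

test_that("simulated cohorts respect censoring and the EMR burden drop", {
  spec <- clinical_sim_spec(n_patients = 120)
  sc <- simulate_cohort(spec, seed = 5)
  expect_true(all(sc$cohort$pfs_months <= spec$censor_time))
  expect_true(all(sc$cohort$os_months <= spec$censor_time))
  drops <- sc$burden |>
    tidyr::pivot_wider(id_cols = patient, names_from = timepoint,
                       values_from = hge_per_ml) |>
    dplyr::left_join(sc$cohort |> dplyr::select(patient, emr), by = "patient")
  d <- log10(drops$baseline) - log10(drops$early)
  expect_true(all(d[drops$emr] >= 2))
  expect_true(all(d[!drops$emr] < 2))
  # round-trips through the cohort reader
  fp <- withr::local_tempfile(fileext = ".csv")
  write_cohort(sc$cohort, fp)
  back <- read_cohort(fp)
  expect_equal(as.data.frame(back), as.data.frame(sc$cohort),
               tolerance = 1e-12)
})

test_that("large simulated cohorts recover the designed hazard ratio", {
  spec <- clinical_sim_spec(n_patients = 2000, emr_fraction = 0.5,
                            hazard_emr = 0.015, hazard_no_emr = 0.15)
  sc <- simulate_cohort(spec, seed = 17)
  hr <- mh_hazard_ratio(sc$cohort |>
                          dplyr::mutate(grp = ifelse(emr, "EMR", "no EMR")),
                        "pfs_months", "pfs_event", "grp")
  expect_gt(hr$hr, 0.08)
  expect_lt(hr$hr, 0.125)
})
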