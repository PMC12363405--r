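# pileup construction, somatic calling, tracked genotyping, phasing and
# variant-set comparison

make_cons <- function(pan, s, min_family = 3) {
  g <- group_umi_families(s$reads)
  collapse_families(g, s$deviations, pan, min_family = min_family)
}

test_that("pileup counts molecules by base and matches generator truth", {
  pan <- small_panel(seed = 40, n_backbone = 0)
  cfg <- sim_config(pan, seed = 10, n_molecules = 700, per_base_error = 0,
                    fragment_max = 250)
  v <- variants_at(pan, 1, 300, vaf = 0.3)
  s <- simulate_sample(cfg, truth_set(variants = v |> dplyr::select(-ref)))
  cons <- make_cons(pan, s)
  pu <- build_pileup(cons, pan, positions = v |> dplyr::select(chrom, pos))
  expect_identical(nrow(pu), 1L)
  expect_identical(pu$informative, pu$depth)   # no masking without errors
  surviving <- s$molecules |>
    dplyr::filter(family_size >= 3, chrom == v$chrom, start <= v$pos,
                  end >= v$pos)
  expect_identical(pu$depth, nrow(surviving))
  alt_col <- paste0("n_", tolower(v$alt))
  exp_alt <- s$molecule_alleles |>
    dplyr::filter(pos == v$pos,
                  molecule_id %in% surviving$molecule_id) |>
    nrow()
  expect_identical(pu[[alt_col]], exp_alt)
  ref_col <- paste0("n_", tolower(pu$ref))
  expect_identical(pu[[ref_col]] + exp_alt, pu$depth)
})

test_that("somatic calling applies count, significance and buccal rules", {
  pu <- tibble::tibble(
    chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
    ref = "A",
    n_a = c(4950L, 4950L, 2750L, 5000L),
    n_c = c(50L, 50L, 2250L, 0L),
    n_g = 0L, n_t = 0L, n_n = 0L,
    depth = 5000L, informative = 5000L
  )
  em <- structure(list(rate = 2.5e-4, floored = FALSE), class = "error_model")
  buccal <- tibble::tibble(chrom = "chr1", pos = c(100L, 300L),
                           alt = "C", vaf = c(0, 0.45))
  expect_warning(
    calls <- call_somatic(pu, buccal, em, alpha = 0.05, n_tests = 148200),
    "germline-unevaluable"
  )
  # VAF 1% at background 2.5e-4: binomial tail survives Bonferroni easily
  expect_identical(calls$status[calls$pos == 100L], "somatic")
  # buccal VAF 0.45 -> germline
  expect_identical(calls$status[calls$pos == 300L], "germline")
  # no buccal row -> germline-unevaluable, retained
  expect_identical(calls$status[calls$pos == 200L], "germline-unevaluable")
  # zero alt molecules are never candidates
  expect_false(400L %in% calls$pos)
  expect_equal(calls$p_value[calls$pos == 100L],
               pbinom(49, 5000, 2.5e-4, lower.tail = FALSE))
})

test_that("raising the background rate never adds somatic calls", {
  pu <- tibble::tibble(
    chrom = "chr1", pos = seq(100L, 1000L, by = 100L), ref = "A",
    n_a = 4990L, n_c = c(2:6, 8L, 10L, 15L, 20L, 30L),
    n_g = 0L, n_t = 0L, n_n = 0L, depth = 5000L, informative = 5000L
  )
  buccal <- tidyr::crossing(pu |> dplyr::select(chrom, pos), alt = "C") |>
    dplyr::mutate(vaf = 0)
  em_lo <- structure(list(rate = 1e-5, floored = FALSE),
                     class = "error_model")
  em_hi <- structure(list(rate = 1e-3, floored = FALSE),
                     class = "error_model")
  n_lo <- sum(call_somatic(pu, buccal, em_lo, n_tests = 1e5)$status == "somatic")
  n_hi <- sum(call_somatic(pu, buccal, em_hi, n_tests = 1e5)$status == "somatic")
  expect_gte(n_lo, n_hi)
})

test_that("tracked genotyping is threshold-free and distinguishes 0 from missing", {
  pan <- small_panel(seed = 41, n_backbone = 0)
  tg <- pan$targets[1, ]
  tracked <- tibble::tibble(
    chrom = tg$chrom, pos = tg$start + c(50L, 560L),
    ref = ref_base(pan, tg$chrom, tg$start + c(50L, 560L))
  ) |> dplyr::mutate(alt = vapply(ref, function(r)
    setdiff(c("A", "C", "G", "T"), r)[1], ""))
  # molecules cover only the first site
  reads <- group_umi_families(
    mk_reads(tg$chrom, tg$start, 200, "ACGTACGTAC", n = 4))
  cons <- collapse_families(reads, tibble::tibble(read_id = integer(),
                                                  chrom = character(),
                                                  pos = integer(),
                                                  base = character()), pan)
  pu <- build_pileup(cons, pan, positions = tracked |>
                       dplyr::select(chrom, pos))
  geno <- genotype_tracked(pu, tracked)
  expect_equal(geno$vaf[1], 0)            # covered, zero alt
  expect_true(is.na(geno$vaf[2]))         # uncovered: missing, not zero
  expect_identical(geno$alt_count[2], 0L)
})

test_that("a simulated VAF decay series recovers its log-linear slope", {
  pan <- small_panel(seed = 42, n_backbone = 0)
  v <- variants_at(pan, 1, 300, vaf = 0.4)
  tfs <- 2^-(0:5)
  vafs <- purrr::map_dbl(seq_along(tfs), function(i) {
    cfg <- sim_config(pan, seed = 500 + i, n_molecules = 4000,
                      per_base_error = 0, fragment_max = 250)
    s <- simulate_sample(cfg, truth_set(variants = v |> dplyr::select(-ref)),
                         tumour_fraction = tfs[i])
    cons <- make_cons(pan, s)
    pu <- build_pileup(cons, pan, positions = v |> dplyr::select(chrom, pos))
    genotype_tracked(pu, tracked = v)$vaf
  })
  fit <- stats::lm(log2(vafs) ~ seq_along(tfs))
  ci <- stats::confint(fit)[2, ]
  expect_gt(-1, ci[1])   # true halving slope inside the fitted CI
  expect_lt(-1, ci[2])
})

test_that("phased pairs obey the 100 bp window and support counting", {
  pan <- small_panel(seed = 43, n_backbone = 0)
  cfg <- sim_config(pan, seed = 7, n_molecules = 900, per_base_error = 0,
                    fragment_max = 250)
  v_near <- variants_at(pan, 1, c(100, 150), vaf = 0.3, phase_group = 1L)
  v_far <- variants_at(pan, 2, c(100, 260), vaf = 0.3)   # 160 bp apart
  v <- dplyr::bind_rows(v_near, v_far)
  s <- simulate_sample(cfg, truth_set(variants = v |> dplyr::select(-ref)))
  cons <- make_cons(pan, s)
  pp <- detect_phased_pairs(cons, v)
  expect_identical(nrow(pp), 1L)
  expect_identical(pp$distance, 50L)
  # support equals the generator's double-carrier count among survivors
  surviving <- s$molecules$molecule_id[s$molecules$family_size >= 3]
  truth_both <- s$molecule_alleles |>
    dplyr::filter(pos %in% v_near$pos, molecule_id %in% surviving) |>
    dplyr::count(molecule_id) |>
    dplyr::filter(n == 2) |>
    nrow()
  expect_identical(pp$n_both_alt, truth_both)
  expect_true(pp$n_both_alt <= pp$n_covering)
})

test_that("variant-set comparison reduces to set algebra", {
  mkset <- function(pos) tibble::tibble(chrom = "chr1", pos = pos,
                                        ref = "A", alt = "T")
  same <- compare_variant_sets(mkset(1:10), mkset(1:10))
  expect_equal(same$shared, 10)
  expect_equal(same$concordance, 1)
  disj <- compare_variant_sets(mkset(1:5), mkset(6:10))
  expect_equal(disj$shared, 0)
  withr::with_seed(99, {
    for (i in 1:5) {
      a <- sample(1:40, 15)
      b <- sample(1:40, 20)
      got <- compare_variant_sets(mkset(a), mkset(b))
      expect_equal(got$shared, length(intersect(a, b)))
      expect_equal(got$plasma_only, length(setdiff(a, b)))
      expect_equal(got$tissue_only, length(setdiff(b, a)))
      expect_equal(got$concordance, length(intersect(a, b)) / length(b))
    }
  })
})

test_that("variant-free samples rarely yield somatic calls", {
  pan <- small_panel(seed = 44, n_backbone = 8, flank = 200)
  clean <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(pan, seed = 9000 + r, n_molecules = 900,
                      per_base_error = 0.003, fragment_max = 300)
    s <- simulate_sample(cfg, truth_set())
    cons <- make_cons(pan, s)
    bb <- pan$backbone
    flanks <- tibble::tibble(chrom = rep(bb$chrom, 2),
                             pos = c(bb$pos - 1L, bb$pos + 1L))
    em <- estimate_background_error(cons, flanks, pan)
    pu <- build_pileup(cons, pan)
    buccal <- tidyr::crossing(pu |> dplyr::select(chrom, pos),
                              alt = c("A", "C", "G", "T")) |>
      dplyr::mutate(vaf = 0)
    calls <- call_somatic(pu, buccal, em, alpha = 0.05,
                          n_tests = panel_size_bp(pan))
    if (sum(calls$status == "somatic") == 0) clean <- clean + 1L
  }
  expect_gte(clean, n_rep - 2L)
})
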