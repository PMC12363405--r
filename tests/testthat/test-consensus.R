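# UMI grouping, consensus voting and background error estimation

test_that("reads sharing position and UMI form one family", {
  pan <- small_panel(seed = 30, n_backbone = 0)
  st <- pan$targets$start[1]
  reads <- mk_reads(pan$targets$chrom[1], st, 100, "AAAAAAAAAA", n = 5)
  g <- group_umi_families(reads)
  expect_identical(dplyr::n_distinct(g$family_id), 1L)
  expect_identical(nrow(g), 5L)
})

test_that("UMI tolerance merges near-identical UMIs directionally", {
  pan <- small_panel(seed = 30, n_backbone = 0)
  st <- pan$targets$start[1]
  reads <- dplyr::bind_rows(
    mk_reads(pan$targets$chrom[1], st, 100, "AAAAAAAAAA", n = 4),
    mk_reads(pan$targets$chrom[1], st, 100, "AAAAAAAAAT", n = 1,
             id_start = 5L)
  )
  g0 <- group_umi_families(reads, umi_tolerance = 0)
  expect_identical(sort(as.integer(table(g0$family_id))), c(1L, 4L))
  g1 <- group_umi_families(reads, umi_tolerance = 1)
  expect_identical(dplyr::n_distinct(g1$family_id), 1L)
  # far UMIs never merge
  reads2 <- dplyr::bind_rows(
    mk_reads(pan$targets$chrom[1], st, 100, "AAAAAAAAAA", n = 4),
    mk_reads(pan$targets$chrom[1], st, 100, "CCAAAAAAAT", n = 1,
             id_start = 5L)
  )
  expect_identical(dplyr::n_distinct(
    group_umi_families(reads2, umi_tolerance = 1)$family_id), 2L)
  # the directional size rule blocks merging two large families
  reads3 <- dplyr::bind_rows(
    mk_reads(pan$targets$chrom[1], st, 100, "AAAAAAAAAA", n = 4),
    mk_reads(pan$targets$chrom[1], st, 100, "AAAAAAAAAT", n = 4,
             id_start = 5L)
  )
  expect_identical(dplyr::n_distinct(
    group_umi_families(reads3, umi_tolerance = 1)$family_id), 2L)
})

test_that("non-10nt UMIs are excluded with a warning", {
  pan <- small_panel(seed = 30, n_backbone = 0)
  st <- pan$targets$start[1]
  reads <- dplyr::bind_rows(
    mk_reads(pan$targets$chrom[1], st, 100, "AAAAAAAAAA", n = 2),
    mk_reads(pan$targets$chrom[1], st, 100, "AAAA", n = 1, id_start = 3L)
  )
  expect_warning(g <- group_umi_families(reads), "UMI length")
  expect_identical(nrow(g), 2L)
})

test_that("error-free grouping recovers the generator's family partition", {
  pan <- small_panel(seed = 31, n_backbone = 0)
  cfg <- sim_config(pan, seed = 77, n_molecules = 500, per_base_error = 0,
                    fragment_max = 250)
  s <- simulate_sample(cfg, truth_set())
  g <- group_umi_families(s$reads)
  # each family maps to exactly one source molecule and vice versa
  map <- g |> dplyr::distinct(family_id, molecule_id)
  expect_identical(nrow(map), dplyr::n_distinct(g$family_id))
  expect_identical(nrow(map), dplyr::n_distinct(g$molecule_id))
})

test_that("consensus voting applies the family-size and majority rules", {
  pan <- small_panel(seed = 32, n_backbone = 0)
  ch <- pan$targets$chrom[1]
  st <- pan$targets$start[1]
  p <- st + 50L
  ref <- ref_base(pan, ch, p)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]

  # family of 2 is discarded at min_family = 3
  r2 <- group_umi_families(mk_reads(ch, st, 100, "GGGGGGGGGG", n = 2))
  c2 <- collapse_families(r2, tibble::tibble(read_id = integer(),
                                             chrom = character(),
                                             pos = integer(),
                                             base = character()),
                          pan, min_family = 3)
  expect_identical(nrow(c2$molecules), 0L)

  # 4/5 discordant member outvoted
  r5 <- group_umi_families(mk_reads(ch, st, 100, "GGGGGGGGGG", n = 5))
  dev <- tibble::tibble(read_id = 1L, chrom = ch, pos = p, base = alt)
  c5 <- collapse_families(r5, dev, pan, min_family = 3)
  expect_identical(nrow(c5$molecules), 1L)
  expect_identical(nrow(c5$calls), 0L)   # majority is reference

  # 2/2 split is masked to N
  r4 <- group_umi_families(mk_reads(ch, st, 100, "GGGGGGGGGG", n = 4))
  dev4 <- tibble::tibble(read_id = 1:2, chrom = ch, pos = p, base = alt)
  c4 <- collapse_families(r4, dev4, pan, min_family = 3)
  expect_identical(c4$calls$base, "N")

  # 3/4 alt wins at the 2/3 threshold
  dev3 <- tibble::tibble(read_id = 1:3, chrom = ch, pos = p, base = alt)
  c3 <- collapse_families(r4, dev3, pan, min_family = 3)
  expect_identical(c3$calls$base, alt)
})

test_that("collapse matches an exhaustive vote oracle on small inputs", {
  pan <- small_panel(seed = 33, n_backbone = 0)
  cfg <- sim_config(pan, seed = 88, n_molecules = 6, per_base_error = 0.05,
                    family_mean = 3, fragment_max = 120)
  for (seed in c(1, 2, 3, 4, 5)) {
    cfg$seed <- seed
    s <- simulate_sample(cfg, truth_set())
    g <- group_umi_families(s$reads)
    got <- collapse_families(g, s$deviations, pan, min_family = 2)
    exp <- oracle_collapse(g, s$deviations, pan, min_family = 2)
    expect_equal(
      got$calls |> dplyr::arrange(molecule_id, pos),
      exp |> dplyr::arrange(molecule_id, pos),
      ignore_attr = TRUE
    )
  }
})

test_that("error-free consensus equals generator truth exactly", {
  pan <- small_panel(seed = 34)
  cfg <- sim_config(pan, seed = 99, n_molecules = 600, per_base_error = 0,
                    fragment_max = 250)
  v <- variants_at(pan, 1, c(100, 150), vaf = c(0.4, 0.2))
  s <- simulate_sample(cfg, truth_set(variants = v |> dplyr::select(-ref)))
  g <- group_umi_families(s$reads)
  cons <- collapse_families(g, s$deviations, pan, min_family = 3)
  expect_identical(nrow(cons$molecules),
                   sum(s$molecules$family_size >= 3))
  # consensus alt calls = planted alleles of surviving molecules
  surviving <- s$molecules$molecule_id[s$molecules$family_size >= 3]
  exp_calls <- s$molecule_alleles |>
    dplyr::filter(molecule_id %in% surviving) |>
    dplyr::count(chrom, pos, base) |>
    dplyr::arrange(chrom, pos, base)
  got_calls <- cons$calls |>
    dplyr::count(chrom, pos, base) |>
    dplyr::arrange(chrom, pos, base)
  expect_equal(as.data.frame(got_calls), as.data.frame(exp_calls))
})

test_that("background error model pools, floors and excludes germline sites", {
  pan <- small_panel(seed = 35, n_backbone = 12)
  bb <- pan$backbone
  ch <- bb$chrom[1]
  win <- plasmamrd:::window_index(pan, ch, bb$pos[1])
  st <- pan$windows$start[win]
  reads <- group_umi_families(mk_reads(ch, st, 250, "ACGTACGTAC", n = 4))
  cons <- collapse_families(reads, tibble::tibble(read_id = integer(),
                                                  chrom = character(),
                                                  pos = integer(),
                                                  base = character()),
                            pan, min_family = 3)
  flanks <- tibble::tibble(chrom = ch, pos = bb$pos[1] + c(-1L, 1L))
  em <- estimate_background_error(cons, flanks, pan)
  expect_true(em$floored)
  expect_equal(em$rate, 0.5 / em$total_molecules)
  expect_identical(em$n_sites, 2L)

  # germline-variant sites are excluded with a warning
  germ <- tibble::tibble(chrom = ch, pos = bb$pos[1] + 1L, genotype = 1L)
  expect_warning(em2 <- estimate_background_error(cons, flanks, pan,
                                                  germline = germ),
                 "germline")
  expect_identical(em2$n_sites, 1L)

  # explicit alt counts divide exactly
  alt <- setdiff(c("A", "C", "G", "T"), ref_base(pan, ch, bb$pos[1] + 1L))[1]
  cons$calls <- tibble::tibble(molecule_id = cons$molecules$molecule_id[1],
                               chrom = ch, pos = bb$pos[1] + 1L, base = alt)
  em3 <- estimate_background_error(cons, flanks, pan)
  site <- em3$per_site[em3$per_site$pos == bb$pos[1] + 1L, ]
  expect_equal(site$rate, 1 / site$informative)
})

test_that("consensus suppresses raw errors and is monotone in family size", {
  pan <- small_panel(seed = 36, n_backbone = 16, flank = 200)
  cfg <- sim_config(pan, seed = 55, n_molecules = 1200,
                    per_base_error = 0.01, fragment_max = 300)
  gts <- dilution_genotypes(pan, n_sites = 16)
  s <- simulate_dilution(cfg, gts$a, gts$b, mix_fraction = 0, n_sites = 16)
  g <- group_umi_families(s$reads)
  raw_rate <- nrow(s$deviations) / sum(s$reads$end - s$reads$start + 1)
  flanks <- tibble::tibble(chrom = rep(s$truth$sites$chrom, 2),
                           pos = c(s$truth$sites$pos - 1L,
                                   s$truth$sites$pos + 1L))
  em3 <- estimate_background_error(
    collapse_families(g, s$deviations, pan, min_family = 3), flanks, pan)
  em5 <- estimate_background_error(
    collapse_families(g, s$deviations, pan, min_family = 5), flanks, pan)
  expect_lt(em3$rate, raw_rate / 10)
  se <- sqrt(em3$rate / em3$total_molecules)
  expect_lte(em5$rate, em3$rate + 2 * se + 1e-6)
})
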