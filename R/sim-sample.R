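# Read-level cfDNA sample simulation.
#
# Reads are represented sparsely: fragment coordinates plus a `deviations`
# table of (read_id, pos, base) where the read differs from the panel
# reference. Full sequences are materialised only at SAM I/O boundaries
# (see write_sam()/read_sam()), which keeps deep per-site simulations cheap
# without changing anything observable.

# expand molecules into PCR/sequencing reads and apply per-base errors
amplify_and_sequence <- function(molecules, mol_alleles, config) {
  n_reads_per <- molecules$family_size
  n_reads <- sum(n_reads_per)
  ridx <- rep.int(seq_len(nrow(molecules)), n_reads_per)
  rep_no <- sequence(n_reads_per)
  reads <- tibble::tibble(
    read_id = seq_len(n_reads),
    qname = paste0("M", molecules$molecule_id[ridx], ":R", rep_no, ":",
                   molecules$umi[ridx]),
    chrom = molecules$chrom[ridx],
    start = molecules$start[ridx],
    end = molecules$end[ridx],
    strand = molecules$strand[ridx],
    umi = molecules$umi[ridx],
    molecule_id = molecules$molecule_id[ridx]
  )

  # inherited molecule alleles propagate to every member read
  if (!is.null(mol_alleles) && nrow(mol_alleles)) {
    rd <- data.table(read_id = reads$read_id, molecule_id = reads$molecule_id)
    al <- as.data.table(mol_alleles)
    inh <- merge(rd, al, by = "molecule_id", allow.cartesian = TRUE)
    inherited <- tibble::tibble(read_id = inh$read_id, chrom = inh$chrom,
                                pos = inh$pos, base = inh$base)
  } else {
    inherited <- tibble::tibble(read_id = integer(), chrom = character(),
                                pos = integer(), base = character())
  }

  lens <- reads$end - reads$start + 1L
  n_err_read <- if (config$per_base_error > 0) {
    rbinom(n_reads, size = lens, prob = config$per_base_error)
  } else integer(n_reads)

  if (sum(n_err_read) > 0) {
    er <- rep.int(seq_len(n_reads), n_err_read)
    n_err <- length(er)
    ep <- reads$start[er] + as.integer(floor(runif(n_err) * lens[er]))
    err <- tibble::tibble(read_id = reads$read_id[er],
                          chrom = reads$chrom[er], pos = ep) |>
      dplyr::distinct(.data$read_id, .data$pos, .keep_all = TRUE)
    # base before the error: an inherited allele if present, else reference
    err <- err |>
      dplyr::left_join(inherited, by = c("read_id", "chrom", "pos")) |>
      dplyr::mutate(
        cur = dplyr::coalesce(.data$base,
                              ref_base(config$panel, .data$chrom, .data$pos)),
        base = other_base(.data$cur)
      ) |>
      dplyr::select("read_id", "chrom", "pos", "base")
    # errors override inherited alleles at the same read base
    deviations <- dplyr::bind_rows(err, inherited) |>
      dplyr::distinct(.data$read_id, .data$chrom, .data$pos,
                      .keep_all = TRUE)
  } else {
    deviations <- inherited
  }

  if (nrow(deviations)) {
    deviations <- deviations |>
      dplyr::mutate(ref = ref_base(config$panel, .data$chrom, .data$pos)) |>
      dplyr::filter(.data$base != .data$ref) |>
      dplyr::select("read_id", "chrom", "pos", "base")
  }

  ord <- order(reads$chrom, reads$start, reads$read_id)
  reads <- reads[ord, ]
  list(reads = reads, deviations = deviations)
}

# assign somatic / germline alleles to molecules given a truth set
plant_alleles <- function(molecules, truth, config, tumour_fraction) {
  panel <- config$panel
  rows <- list()

  germ <- truth$germline
  if (!is.null(germ) && nrow(germ)) {
    if (!"alt" %in% names(germ) && !is.null(panel$backbone)) {
      germ <- dplyr::left_join(
        germ, panel$backbone |> dplyr::select("chrom", "pos", "alt"),
        by = c("chrom", "pos")
      )
    }
    germ <- dplyr::filter(germ, .data$genotype > 0, !is.na(.data$alt))
    if (nrow(germ)) {
      md <- data.table(mid = molecules$molecule_id, chrom = molecules$chrom,
                       s = molecules$start, e = molecules$end)
      gd <- data.table(chrom = germ$chrom, gpos = germ$pos,
                       alt = germ$alt, genotype = germ$genotype)
      cov <- md[gd, on = .(chrom, s <= gpos, e >= gpos),
                .(mid = x.mid, chrom = i.chrom, pos = i.gpos,
                  alt = i.alt, genotype = i.genotype),
                nomatch = NULL, allow.cartesian = TRUE]
      if (nrow(cov)) {
        keep <- runif(nrow(cov)) < cov$genotype / 2
        rows[[length(rows) + 1L]] <- tibble::tibble(
          molecule_id = cov$mid[keep], chrom = cov$chrom[keep],
          pos = cov$pos[keep], base = cov$alt[keep], origin = "germline"
        )
      }
    }
  }

  vars <- truth$variants
  if (!is.null(vars) && nrow(vars)) {
    vars <- vars |>
      dplyr::mutate(
        veff = .data$vaf * tumour_fraction,
        grp = dplyr::if_else(is.na(.data$phase_group),
                             -dplyr::row_number(),  # singleton pseudo-groups
                             as.integer(.data$phase_group))
      ) |>
      dplyr::arrange(.data$grp, .data$chrom, .data$pos)
    md <- data.table(mid = molecules$molecule_id, chrom = molecules$chrom,
                     s = molecules$start, e = molecules$end)
    for (g in unique(vars$grp)) {
      vg <- vars[vars$grp == g, ]
      vd <- data.table(chrom = vg$chrom, vpos = vg$pos, alt = vg$alt,
                       veff = vg$veff, member = seq_len(nrow(vg)))
      cov <- md[vd, on = .(chrom, s <= vpos, e >= vpos),
                .(mid = x.mid, chrom = i.chrom, pos = i.vpos, alt = i.alt,
                  veff = i.veff, member = i.member),
                nomatch = NULL, allow.cartesian = TRUE]
      if (!nrow(cov)) next
      va <- vg$veff[1]
      mids <- unique(cov$mid)
      carrier <- setNames(runif(length(mids)) < va, as.character(mids))
      is_car <- carrier[as.character(cov$mid)]
      p_keep <- numeric(nrow(cov))
      anchor <- cov$member == 1L
      p_keep[anchor & is_car] <- 1
      if (nrow(vg) > 1L) {
        cis <- truth$cis_prob
        sec <- !anchor
        p_keep[sec & is_car] <- cis
        # off-haplotype rate preserving each member's marginal VAF
        q <- ifelse(cov$veff[sec & !is_car] * (1 - cis) > 0 & va < 1,
                    pmin(1, cov$veff[sec & !is_car] * (1 - cis) / (1 - va)), 0)
        p_keep[sec & !is_car] <- q
      }
      keep <- runif(nrow(cov)) < p_keep
      if (any(keep)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          molecule_id = cov$mid[keep], chrom = cov$chrom[keep],
          pos = cov$pos[keep], base = cov$alt[keep], origin = "somatic"
        )
      }
    }
  }

  if (!length(rows)) {
    return(tibble::tibble(molecule_id = integer(), chrom = character(),
                          pos = integer(), base = character(),
                          origin = character()))
  }
  out <- dplyr::bind_rows(rows)
  # a somatic alt planted on top of a germline alt at one locus cannot occur
  # (validated VAF sums); still deduplicate defensively
  dplyr::distinct(out, .data$molecule_id, .data$chrom, .data$pos,
                  .keep_all = TRUE)
}

new_cfdna_sample <- function(reads, deviations, molecules, molecule_alleles,
                             truth, config, extra = list()) {
  structure(
    c(list(reads = reads, deviations = deviations, molecules = molecules,
           molecule_alleles = molecule_alleles, truth = truth,
           config = config), extra),
    class = "cfdna_sample"
  )
}

#' @export
print.cfdna_sample <- function(x, ...) {
  cat("<cfdna_sample> ", nrow(x$molecules), " source molecules, ",
      nrow(x$reads), " reads, ", nrow(x$molecule_alleles),
      " planted molecule alleles\n", sep = "")
  invisible(x)
}

#' Simulate one UMI-tagged cfDNA plasma sample
#'
#' Draws source cfDNA molecules across the panel (placement proportional to
#' captured window width, fragment lengths from the configured truncated
#' normal), plants germline and somatic alleles per the truth set (phase-group
#' members co-occur in cis on the tumour haplotype), amplifies each molecule
#' into a UMI read family, and sequencing-errs each read base independently.
#' The per-molecule truth tables are returned alongside the reads so that
#' every downstream computation can be checked against generator bookkeeping.
#'
#' @param config A [sim_config()].
#' @param truth A [truth_set()]; somatic VAFs are scaled by `tumour_fraction`.
#' @param tumour_fraction Scaling in \[0, 1\] applied to all somatic VAFs.
#' @return A `cfdna_sample`: list with tibbles `reads` (coordinate-sorted),
#'   `deviations` (read bases differing from reference), `molecules`,
#'   `molecule_alleles`, plus the `truth` and `config` used.
#' @export
#' @examples
#' pan <- sim_panel(n_genes = 1, gene_bp = 400, n_backbone = 0, seed = 2)
#' cfg <- sim_config(pan, seed = 9, n_molecules = 200, per_base_error = 0)
#' tr <- truth_set(variants = tibble::tibble(
#'   chrom = pan$targets$chrom, pos = pan$targets$start + 200L,
#'   alt = "N", vaf = 0.5))
#' tr$variants$alt <- setdiff(c("A", "C"), ref_base(pan, tr$variants$chrom,
#'   tr$variants$pos))[1]
#' s <- simulate_sample(cfg, tr)
simulate_sample <- function(config, truth = truth_set(), tumour_fraction = 1) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "truth_set"))
  .assert_prob(tumour_fraction, "tumour_fraction")
  withr::local_seed(config$seed)
  panel <- config$panel

  w <- panel$windows
  wid <- w$end - w$start + 1L
  n <- config$n_molecules
  iv <- sample.int(nrow(w), n, replace = TRUE, prob = wid)
  len <- pmin(as.integer(round(rtrunc_norm(
    n, config$fragment_mean, config$fragment_sd,
    config$fragment_min, config$fragment_max))), wid[iv])
  start <- w$start[iv] + as.integer(floor(runif(n) * (wid[iv] - len + 1L)))
  molecules <- tibble::tibble(
    molecule_id = seq_len(n),
    chrom = w$chrom[iv],
    start = start,
    end = start + len - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    umi = rand_umis(n, config$umi_length),
    family_size = 1L + rnbinom(n, mu = config$family_mean - 1,
                               size = config$family_disp)
  )

  mol_alleles <- plant_alleles(molecules, truth, config, tumour_fraction)
  seqd <- amplify_and_sequence(molecules, mol_alleles, config)
  new_cfdna_sample(seqd$reads, seqd$deviations, molecules, mol_alleles,
                   truth, config,
                   extra = list(tumour_fraction = tumour_fraction))
}

#' Simulate a two-individual dilution (spike-in) series sample
#'
#' Emulates the admixture experiment used to establish assay sensitivity:
#' DNA from individual B is mixed into individual A at `mix_fraction`, and
#' reads are generated over SNP sites where the genotypes are discordant with
#' B contributing the minor allele. Each interrogated site receives
#' `config$n_molecules` source molecules; each molecule is drawn from B with
#' probability `mix_fraction` and carries B's allele per its genotype
#' (expected minor-allele VAF: `mix_fraction / 2` at B-het sites,
#' `mix_fraction` at B-hom sites).
#'
#' @param config A [sim_config()]; the panel must carry a SNP backbone.
#' @param genotypes_a,genotypes_b Tibbles (`chrom`, `pos`, `genotype`) for the
#'   background (A) and spiked (B) individuals; see [dilution_genotypes()].
#' @param mix_fraction Spike fraction in \[0, 0.5\].
#' @param n_sites Number of discordant sites to interrogate.
#' @return A `cfdna_sample` whose `truth` gains `sites` (the interrogated
#'   loci) and whose `molecules` carry a `source` column ("A"/"B").
#' @export
simulate_dilution <- function(config, genotypes_a, genotypes_b,
                              mix_fraction, n_sites = 101L) {
  stopifnot(inherits(config, "sim_config"))
  if (mix_fraction < 0 || mix_fraction > 0.5) {
    abort("`mix_fraction` must lie in [0, 0.5].")
  }
  panel <- config$panel
  if (is.null(panel$backbone)) abort("Panel has no SNP backbone.")
  withr::local_seed(config$seed)

  disc <- dplyr::inner_join(
    genotypes_a |> dplyr::select("chrom", "pos", ga = "genotype"),
    genotypes_b |> dplyr::select("chrom", "pos", gb = "genotype"),
    by = c("chrom", "pos")
  ) |>
    dplyr::filter(.data$ga == 0, .data$gb > 0) |>
    dplyr::inner_join(panel$backbone, by = c("chrom", "pos"))
  if (nrow(disc) == 0) abort("No discordant sites between the two genotypes.")
  if (nrow(disc) < n_sites) {
    abort(sprintf("Only %d discordant sites available; %d requested.",
                  nrow(disc), n_sites))
  }
  sites <- disc[seq_len(n_sites), ]

  widx <- window_index(panel, sites$chrom, sites$pos)
  n_per <- config$n_molecules
  n <- n_per * n_sites
  si <- rep.int(seq_len(n_sites), rep(n_per, n_sites))
  len <- as.integer(round(rtrunc_norm(
    n, config$fragment_mean, config$fragment_sd,
    config$fragment_min, config$fragment_max)))
  wlo <- panel$windows$start[widx[si]]
  whi <- panel$windows$end[widx[si]]
  spos <- sites$pos[si]
  lo <- pmax(wlo, spos - len + 1L)
  hi <- pmin(spos, whi - len + 1L)
  start <- lo + as.integer(floor(runif(n) * (hi - lo + 1L)))
  src_b <- runif(n) < mix_fraction
  molecules <- tibble::tibble(
    molecule_id = seq_len(n),
    chrom = sites$chrom[si],
    start = start,
    end = start + len - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    umi = rand_umis(n, config$umi_length),
    family_size = 1L + rnbinom(n, mu = config$family_mean - 1,
                               size = config$family_disp),
    site = si,
    source = dplyr::if_else(src_b, "B", "A")
  )

  gt <- ifelse(src_b, sites$gb[si], sites$ga[si])
  carries <- runif(n) < gt / 2
  mol_alleles <- tibble::tibble(
    molecule_id = molecules$molecule_id[carries],
    chrom = sites$chrom[si][carries],
    pos = sites$pos[si][carries],
    base = sites$alt[si][carries],
    origin = "germline"
  )

  seqd <- amplify_and_sequence(molecules, mol_alleles, config)
  truth <- truth_set(germline = NULL)
  truth$sites <- sites
  truth$mix_fraction <- mix_fraction
  new_cfdna_sample(seqd$reads, seqd$deviations, molecules, mol_alleles,
                   truth, config, extra = list(mix_fraction = mix_fraction))
}

#' Hardy-Weinberg genotypes over the SNP backbone
#'
#' @param panel A [sim_panel()] with a backbone.
#' @param seed Integer seed.
#' @return Tibble `chrom`, `pos`, `alt`, `maf`, `genotype` (0/1/2).
#' @export
hwe_genotypes <- function(panel, seed = 1L) {
  stopifnot(inherits(panel, "cfdna_panel"), !is.null(panel$backbone))
  withr::local_seed(seed)
  panel$backbone |>
    dplyr::mutate(genotype = rbinom(dplyr::n(), 2L, .data$maf)) |>
    dplyr::select("chrom", "pos", "alt", "maf", "genotype")
}

#' Genotype pair for a dilution series
#'
#' Constructs two individuals whose genotypes are discordant at the first
#' `n_sites` backbone loci with individual B contributing the minor allele
#' (hom-ref in A). By default B is homozygous-alt at every discordant site,
#' so the expected spiked VAF equals the mix fraction; `b_het_fraction`
#' makes a share of the discordant sites heterozygous in B instead.
#'
#' @param panel A [sim_panel()] with a backbone of at least `n_sites` loci.
#' @param n_sites Number of discordant sites.
#' @param b_het_fraction Fraction of discordant sites heterozygous in B.
#' @param seed Seed for choosing which sites are het when
#'   `b_het_fraction > 0`.
#' @return List with tibbles `a` and `b` of (`chrom`, `pos`, `genotype`).
#' @export
dilution_genotypes <- function(panel, n_sites = 101L, b_het_fraction = 0,
                               seed = 1L) {
  stopifnot(inherits(panel, "cfdna_panel"), !is.null(panel$backbone))
  .assert_prob(b_het_fraction, "b_het_fraction")
  bb <- panel$backbone
  if (nrow(bb) < n_sites) abort("Backbone smaller than `n_sites`.")
  withr::local_seed(seed)
  ga <- bb |> dplyr::select("chrom", "pos") |> dplyr::mutate(genotype = 0L)
  gb <- ga
  g_site <- rep(2L, n_sites)
  n_het <- round(b_het_fraction * n_sites)
  if (n_het > 0) g_site[sample.int(n_sites, n_het)] <- 1L
  gb$genotype[seq_len(n_sites)] <- g_site
  list(a = ga, b = gb)
}

#' Simulate backbone depth and allele counts under copy-number change
#'
#' Generates the per-locus quantities the copy-number module consumes:
#' consensus-molecule depth (Poisson around `depth_per_locus` scaled by the
#' expected relative depth `(1 - tf) + tf * copies / 2`) and ref/alt allele
#' counts at each locus, with the allele ratio implied by the copy state
#' (the gained or lost haplotype is chosen at random per heterozygous locus).
#'
#' @param config A [sim_config()]; only the panel and seed are used.
#' @param cnv_segments Tibble (`chrom`, `start`, `end`, `copies`) of
#'   non-overlapping tumour copy-number segments; loci outside segments are
#'   diploid.
#' @param tumour_fraction Tumour fraction in \[0, 1\].
#' @param depth_per_locus Expected consensus depth at a diploid locus.
#' @param genotypes Optional germline genotype tibble (`chrom`, `pos`,
#'   `genotype`); defaults to a Hardy-Weinberg draw.
#' @return A `backbone_profile` tibble: `chrom`, `pos`, `arm`, `genotype`,
#'   `depth`, `ref_count`, `alt_count`, `true_copies`, `expected_rel_depth`.
#' @export
simulate_cnv_sample <- function(config, cnv_segments = NULL,
                                tumour_fraction = 0, depth_per_locus = 1000,
                                genotypes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  .assert_prob(tumour_fraction, "tumour_fraction")
  panel <- config$panel
  if (is.null(panel$backbone)) abort("Panel has no SNP backbone.")
  truth_set(cnv_segments = cnv_segments)   # validates non-overlap, copies >= 0
  withr::local_seed(config$seed)

  bb <- panel$backbone
  if (is.null(genotypes)) {
    genotypes <- hwe_genotypes(panel, seed = derive_seed(config$seed, 7L))
  }
  prof <- bb |>
    dplyr::left_join(genotypes |> dplyr::select("chrom", "pos", "genotype"),
                     by = c("chrom", "pos")) |>
    dplyr::mutate(genotype = dplyr::coalesce(.data$genotype, 0L),
                  copies = 2)
  if (!is.null(cnv_segments) && nrow(cnv_segments)) {
    pd <- as.data.table(prof[, c("chrom", "pos")])
    pd[, i := .I]
    sd_ <- as.data.table(cnv_segments)
    hit <- pd[sd_, on = .(chrom, pos >= start, pos <= end),
              .(i = x.i, copies = i.copies), nomatch = NULL]
    prof$copies[hit$i] <- hit$copies
  }

  tf <- tumour_fraction
  prof <- prof |>
    dplyr::mutate(
      expected_rel_depth = (1 - tf) + tf * .data$copies / 2,
      depth = rpois(dplyr::n(), depth_per_locus * .data$expected_rel_depth)
    )

  # alt-allele copy number in the tumour at het loci: the affected haplotype
  # is the alt-bearing one with probability 1/2
  g <- prof$genotype
  c_tum <- prof$copies
  alt_tum <- numeric(nrow(prof))
  alt_tum[g == 2] <- c_tum[g == 2]
  het <- which(g == 1)
  if (length(het)) {
    affected_alt <- runif(length(het)) < 0.5
    extra <- c_tum[het] - 2            # signed copy change of one haplotype
    alt_tum[het] <- 1 + ifelse(affected_alt, extra, 0)
    alt_tum[het] <- pmax(0, pmin(alt_tum[het], c_tum[het]))
  }
  af <- ((1 - tf) * g / 2 * 2 + tf * alt_tum) / ((1 - tf) * 2 + tf * c_tum)
  af[!is.finite(af)] <- 0
  prof$alt_count <- rbinom(nrow(prof), prof$depth, af)
  prof$ref_count <- prof$depth - prof$alt_count
  prof$true_copies <- prof$copies
  out <- prof |>
    dplyr::select("chrom", "pos", "arm", "genotype", "depth", "ref_count",
                  "alt_count", "true_copies", "expected_rel_depth")
  class(out) <- c("backbone_profile", class(out))
  out
}
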