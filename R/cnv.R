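# Copy-number log2 ratios, arm-level calling, LOH and identity QC over the
# SNP backbone.

# attach the containing chromosome arm to each locus when absent
annotate_arm <- function(profile, arms) {
  if ("arm" %in% names(profile)) return(profile)
  pd <- as.data.table(profile[, c("chrom", "pos")])
  pd[, i := .I]
  ad <- as.data.table(arms)
  hit <- ad[pd, on = .(chrom, start <= pos, end >= pos),
            .(i = i.i, arm = x.arm), nomatch = NA]
  profile$arm <- hit$arm[order(hit$i)]
  profile
}
#
# Depths are library-size normalised (divided by the per-sample median
# backbone depth); the reference profile is the per-locus median over a
# panel of CNV-neutral normals. The expected log2 ratio of a clonal
# one-copy loss at tumour fraction tf is log2(1 - tf/2).

#' Compute per-locus log2 depth ratios against a panel of normals
#'
#' @param sample_profile A `backbone_profile` tibble (`chrom`, `pos`,
#'   `depth`, and `ref_count`/`alt_count` when available), e.g. from
#'   [simulate_cnv_sample()] or [backbone_genotype_calls()].
#' @param reference_profiles List of at least three backbone-profile tibbles
#'   from CNV-neutral samples.
#' @param min_ref_depth Loci whose median normal depth falls below this are
#'   masked (`log2_ratio = NA`).
#' @return The sample profile with `baf` (alt / (ref + alt), `NA` at zero
#'   depth), `norm_depth`, `ref_depth` (normalised reference median) and
#'   `log2_ratio` appended; class `backbone_profile`.
#' @export
compute_log2_ratios <- function(sample_profile, reference_profiles,
                                min_ref_depth = 50) {
  if (!is.list(reference_profiles) || is.data.frame(reference_profiles) ||
      length(reference_profiles) < 3) {
    abort("`reference_profiles` must be a list of >= 3 normal profiles.")
  }
  norm1 <- function(p) {
    p |>
      dplyr::select("chrom", "pos", "depth") |>
      dplyr::mutate(nd = .data$depth / median(.data$depth))
  }
  ref <- purrr::imap(reference_profiles, \(p, i) {
    norm1(p) |> dplyr::mutate(.id = i)
  }) |>
    dplyr::bind_rows() |>
    dplyr::summarise(ref_norm = median(.data$nd),
                     ref_depth_raw = median(.data$depth),
                     .by = c("chrom", "pos"))

  out <- sample_profile |>
    dplyr::mutate(norm_depth = .data$depth / median(.data$depth)) |>
    dplyr::left_join(ref, by = c("chrom", "pos")) |>
    dplyr::mutate(
      log2_ratio = dplyr::if_else(
        !is.na(.data$ref_norm) & .data$ref_depth_raw >= min_ref_depth &
          .data$ref_norm > 0 & .data$norm_depth > 0,
        log2(.data$norm_depth / .data$ref_norm), NA_real_)
    )
  if (all(c("ref_count", "alt_count") %in% names(out))) {
    out <- out |>
      dplyr::mutate(baf = dplyr::if_else(
        .data$ref_count + .data$alt_count > 0,
        .data$alt_count / (.data$ref_count + .data$alt_count), NA_real_))
  }
  if (!inherits(out, "backbone_profile")) {
    class(out) <- c("backbone_profile", class(out))
  }
  out
}

#' Arm-level copy-number segmentation and calling
#'
#' Calls each chromosome arm gain / neutral / loss from the median locus
#' log2 ratio: a call requires the median beyond the threshold *and* a
#' one-sample sign test across the arm's loci at p <= `alpha`. Arms with
#' fewer than `min_loci` usable loci are not called.
#'
#' @param profile A [compute_log2_ratios()] result.
#' @param arms Arm table (`chrom`, `arm`, `start`, `end`), e.g.
#'   `panel$arms`.
#' @param gain_threshold,loss_threshold Median log2 thresholds.
#' @param min_loci Minimum usable loci per arm.
#' @param alpha Sign-test significance level.
#' @return Tibble of `segment_call`s: `chrom`, `arm`, `start`, `end`,
#'   `n_loci`, `median_log2`, `p_sign`, `call` in
#'   {gain, neutral, loss, not-called}.
#' @export
segment_and_call <- function(profile, arms, gain_threshold = 0.3,
                             loss_threshold = -0.3, min_loci = 5L,
                             alpha = 0.05) {
  stopifnot(all(c("chrom", "arm", "start", "end") %in% names(arms)))
  profile <- annotate_arm(profile, arms)
  usable <- profile |> dplyr::filter(!is.na(.data$log2_ratio),
                                     !is.na(.data$arm))
  stats_tbl <- usable |>
    dplyr::summarise(
      n_loci = dplyr::n(),
      median_log2 = median(.data$log2_ratio),
      n_pos = sum(.data$log2_ratio > 0),
      n_neg = sum(.data$log2_ratio < 0),
      .by = c("chrom", "arm")
    )
  arms |>
    dplyr::left_join(stats_tbl, by = c("chrom", "arm")) |>
    dplyr::mutate(
      n_loci = dplyr::coalesce(.data$n_loci, 0L),
      p_sign = purrr::map2_dbl(.data$n_pos, .data$n_neg, \(a, b) {
        if (is.na(a) || a + b == 0) return(NA_real_)
        stats::binom.test(a, a + b, 0.5)$p.value
      }),
      call = dplyr::case_when(
        .data$n_loci < min_loci ~ "not-called",
        .data$median_log2 >= gain_threshold & .data$p_sign <= alpha ~ "gain",
        .data$median_log2 <= loss_threshold & .data$p_sign <= alpha ~ "loss",
        TRUE ~ "neutral"
      )
    ) |>
    dplyr::select("chrom", "arm", "start", "end", "n_loci", "median_log2",
                  "p_sign", "call")
}

#' Detect loss of heterozygosity from B-allele fractions
#'
#' For each arm, computes the mean absolute deviation of the B-allele
#' fraction from 0.5 at germline-heterozygous loci. LOH is flagged when the
#' mean deviation reaches `dev_threshold` with at least `min_het` usable het
#' loci; arms with fewer het loci are unevaluable. At a clonal one-copy loss
#' (tumour fraction 1) the BAF collapses to 0 or 1; at tumour fraction 0.5
#' the minor-allele fraction is 1/3 (deviation ~0.167).
#'
#' @param profile A [compute_log2_ratios()] result with a `baf` column.
#' @param het_loci Tibble (`chrom`, `pos`) of loci heterozygous in the
#'   matched germline (buccal) sample.
#' @param arms Arm table as in [segment_and_call()].
#' @param dev_threshold Mean |BAF - 0.5| at or above which LOH is flagged.
#' @param min_het Minimum het loci per arm.
#' @return Tibble: `chrom`, `arm`, `n_het`, `mean_baf_dev`, `loh`
#'   (logical, `NA` = unevaluable).
#' @export
detect_loh <- function(profile, het_loci, arms, dev_threshold = 0.15,
                       min_het = 5L) {
  stopifnot("baf" %in% names(profile))
  profile <- annotate_arm(profile, arms)
  het <- profile |>
    dplyr::semi_join(dplyr::distinct(het_loci, .data$chrom, .data$pos),
                     by = c("chrom", "pos")) |>
    dplyr::filter(!is.na(.data$baf))
  stats_tbl <- het |>
    dplyr::summarise(n_het = dplyr::n(),
                     mean_baf_dev = mean(abs(.data$baf - 0.5)),
                     .by = c("chrom", "arm"))
  arms |>
    dplyr::left_join(stats_tbl, by = c("chrom", "arm")) |>
    dplyr::mutate(
      n_het = dplyr::coalesce(.data$n_het, 0L),
      loh = dplyr::if_else(.data$n_het >= min_het,
                           .data$mean_baf_dev >= dev_threshold, NA)
    ) |>
    dplyr::select("chrom", "arm", "n_het", "mean_baf_dev", "loh")
}

#' Call backbone genotypes from per-locus allele counts
#'
#' Bins the observed VAF at each backbone locus into hom-ref (< 0.1), het
#' (0.1-0.9) and hom-alt (> 0.9) calls; loci below `min_depth` are left
#' uncalled.
#'
#' @param profile Tibble with `chrom`, `pos`, `ref_count`, `alt_count` (a
#'   `backbone_profile`) or `depth` + `alt_count`.
#' @param min_depth Minimum molecule depth for a call.
#' @return Tibble `chrom`, `pos`, `depth`, `vaf`, `genotype_call`
#'   (0/1/2, `NA` below depth).
#' @export
backbone_genotype_calls <- function(profile, min_depth = 20L) {
  d <- if ("depth" %in% names(profile)) profile$depth else
    profile$ref_count + profile$alt_count
  vaf <- ifelse(d > 0, profile$alt_count / d, NA_real_)
  tibble::tibble(
    chrom = profile$chrom, pos = profile$pos, depth = d, vaf = vaf,
    genotype_call = dplyr::case_when(
      d < min_depth | is.na(vaf) ~ NA_integer_,
      vaf < 0.1 ~ 0L,
      vaf > 0.9 ~ 2L,
      TRUE ~ 1L
    )
  )
}

#' Genotype concordance between two samples (identity QC)
#'
#' Compares backbone genotype calls between two samples over loci co-called
#' at depth >= `min_depth`. Unrelated individuals at ~0.5-MAF backbone SNPs
#' concord at about Hardy-Weinberg expectation (~0.375), far below the
#' mislabel threshold; a sample against itself concords at 1.
#'
#' @param sample_a,sample_b Genotype-call tibbles from
#'   [backbone_genotype_calls()] (or any tibble with `chrom`, `pos`,
#'   `genotype_call`, `depth`).
#' @param min_depth Minimum depth in both samples.
#' @param min_loci Minimum co-called loci; below it the comparison is
#'   unevaluable.
#' @param mislabel_threshold Concordance below which the pair is flagged.
#' @return One-row tibble: `n_loci`, `concordance`, `mislabel` (logical,
#'   `NA` when unevaluable), `evaluable`.
#' @export
genotype_concordance <- function(sample_a, sample_b, min_depth = 20L,
                                 min_loci = 100L, mislabel_threshold = 0.80) {
  j <- dplyr::inner_join(
    sample_a |> dplyr::select("chrom", "pos", ga = "genotype_call",
                              da = "depth"),
    sample_b |> dplyr::select("chrom", "pos", gb = "genotype_call",
                              db = "depth"),
    by = c("chrom", "pos")
  ) |>
    dplyr::filter(!is.na(.data$ga), !is.na(.data$gb),
                  .data$da >= min_depth, .data$db >= min_depth)
  n <- nrow(j)
  if (n < min_loci) {
    return(tibble::tibble(n_loci = n, concordance = NA_real_,
                          mislabel = NA, evaluable = FALSE))
  }
  conc <- mean(j$ga == j$gb)
  tibble::tibble(n_loci = n, concordance = conc,
                 mislabel = conc < mislabel_threshold, evaluable = TRUE)
}
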