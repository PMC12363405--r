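# Somatic variant discovery and tracking on consensus molecules.
#
# Discovery is binomial: at each candidate site the alt consensus-molecule
# count is tested against the pooled background error rate with a one-sided
# exact binomial tail, Bonferroni-corrected over the targeted footprint.
# Tumour/normal subtraction uses the buccal (germline) VAF. Tracked-variant
# genotyping is threshold-free. SNVs only: the assay's reportable variants
# are substitutions, which keeps the pileup model exact.

#' Pile up consensus molecules
#'
#' Counts consensus molecules by base at each queried position. Positions at
#' which no molecule deviates from the reference yield pure-reference rows.
#'
#' @param cons A [collapse_families()] result.
#' @param panel The [sim_panel()] (reference bases; positions outside its
#'   windows are skipped).
#' @param positions Optional tibble (`chrom`, `pos`); defaults to every
#'   position carrying at least one non-reference consensus call.
#' @return A tibble with one row per (chrom, pos): `ref`, per-base counts
#'   `n_a`, `n_c`, `n_g`, `n_t`, mask count `n_n`, `depth` (covering
#'   molecules) and `informative` (= depth - n_n).
#' @export
build_pileup <- function(cons, panel, positions = NULL) {
  stopifnot(inherits(cons, "consensus_set"))
  if (is.null(positions)) {
    positions <- dplyr::distinct(cons$calls, .data$chrom, .data$pos)
  }
  positions <- dplyr::distinct(positions, .data$chrom, .data$pos) |>
    dplyr::mutate(ref = ref_base(panel, .data$chrom, .data$pos)) |>
    dplyr::filter(!is.na(.data$ref))
  if (!nrow(positions)) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), n_a = integer(), n_c = integer(),
                          n_g = integer(), n_t = integer(), n_n = integer(),
                          depth = integer(), informative = integer()))
  }
  mols <- cons$molecules
  positions$depth <- span_coverage(mols$chrom, mols$start, mols$end,
                                   positions$chrom, positions$pos)
  counts <- cons$calls |>
    dplyr::semi_join(positions, by = c("chrom", "pos")) |>
    dplyr::count(.data$chrom, .data$pos, .data$base) |>
    tidyr::pivot_wider(names_from = "base", values_from = "n",
                       values_fill = 0L)
  for (b in c("A", "C", "G", "T", "N")) {
    if (!b %in% names(counts)) counts[[b]] <- integer(nrow(counts))
  }
  out <- positions |>
    dplyr::left_join(counts, by = c("chrom", "pos")) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(c("A", "C", "G", "T", "N")),
                                ~ dplyr::coalesce(.x, 0L)))
  # reference count = covering molecules minus masked minus alternative calls
  alt_sum <- out$A + out$C + out$G + out$T
  ref_count <- out$depth - out$N - alt_sum
  for (b in c("A", "C", "G", "T")) {
    out[[b]] <- out[[b]] + ifelse(out$ref == b, ref_count, 0L)
  }
  out |>
    dplyr::transmute(
      .data$chrom, .data$pos, .data$ref,
      n_a = .data$A, n_c = .data$C, n_g = .data$G, n_t = .data$T,
      n_n = .data$N, .data$depth,
      informative = .data$depth - .data$N
    ) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Call somatic variants against a background error model
#'
#' A site is called somatic when the strongest alternative base has at least
#' `min_alt` supporting consensus molecules, its one-sided exact binomial
#' tail against the background rate survives Bonferroni correction over
#' `n_tests` positions, and the buccal (normal) VAF at the site is below
#' `germline_threshold`. Candidates failing the test are flagged `artifact`;
#' candidates with buccal support are flagged `germline`; candidates without
#' buccal coverage are retained as `germline-unevaluable` with a warning.
#'
#' @param pileup A [build_pileup()] tibble covering candidate positions.
#' @param germline Buccal evidence: tibble (`chrom`, `pos`, `alt`, `vaf`).
#'   Sites absent from the table count as lacking buccal coverage.
#' @param error_model An [estimate_background_error()] model.
#' @param alpha Family-wise significance level.
#' @param min_alt Minimum alt molecule count.
#' @param germline_threshold Buccal VAF at or above which the site is
#'   germline.
#' @param n_tests Number of tested positions for Bonferroni correction
#'   (default: the targeted panel footprint in bp is a sensible choice;
#'   here the number of pileup rows when not supplied).
#' @return Tibble of candidate calls: `chrom`, `pos`, `ref`, `alt`,
#'   `alt_count`, `informative`, `vaf`, `p_value` (uncorrected),
#'   `p_adjusted`, `status` in {somatic, germline, germline-unevaluable,
#'   artifact}.
#' @export
call_somatic <- function(pileup, germline, error_model, alpha = 0.05,
                         min_alt = 2L, germline_threshold = 0.20,
                         n_tests = NULL) {
  stopifnot(inherits(error_model, "error_model"))
  if (error_model$rate <= 0) abort("Background rate must be positive (floored).")
  n_tests <- n_tests %||% nrow(pileup)

  base_cols <- c(A = "n_a", C = "n_c", G = "n_g", T = "n_t")
  cnt <- as.matrix(pileup[, base_cols])
  colnames(cnt) <- names(base_cols)
  ref_idx <- match(pileup$ref, names(base_cols))
  cnt_alt <- cnt
  cnt_alt[cbind(seq_len(nrow(cnt)), ref_idx)] <- -1L
  alt_idx <- max.col(cnt_alt, ties.method = "first")
  out <- pileup |>
    dplyr::mutate(
      alt = names(base_cols)[alt_idx],
      alt_count = cnt[cbind(dplyr::row_number(), alt_idx)],
      vaf = dplyr::if_else(.data$informative > 0,
                           .data$alt_count / .data$informative, NA_real_)
    ) |>
    dplyr::filter(.data$alt_count >= min_alt) |>
    dplyr::mutate(
      p_value = binom_tail(.data$alt_count, .data$informative,
                           error_model$rate),
      p_adjusted = pmin(1, .data$p_value * n_tests)
    )
  if (!nrow(out)) {
    return(out |> dplyr::mutate(status = character()) |>
             dplyr::select("chrom", "pos", "ref", "alt", "alt_count",
                           "informative", "vaf", "p_value", "p_adjusted",
                           "status"))
  }
  out <- out |>
    dplyr::left_join(
      germline |> dplyr::select("chrom", "pos", "alt",
                                buccal_vaf = "vaf"),
      by = c("chrom", "pos", "alt")
    ) |>
    dplyr::mutate(
      status = dplyr::case_when(
        .data$p_adjusted > alpha ~ "artifact",
        is.na(.data$buccal_vaf) ~ "germline-unevaluable",
        .data$buccal_vaf >= germline_threshold ~ "germline",
        TRUE ~ "somatic"
      )
    )
  n_uneval <- sum(out$status == "germline-unevaluable")
  if (n_uneval > 0) {
    warn(sprintf(
      "%d significant call(s) without buccal coverage retained as germline-unevaluable.",
      n_uneval))
  }
  out |>
    dplyr::select("chrom", "pos", "ref", "alt", "alt_count", "informative",
                  "vaf", "p_value", "p_adjusted", "status") |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Genotype tracked reporter variants (threshold-free)
#'
#' Reports alt and informative molecule counts for every tracked variant
#' irrespective of significance. A covered site with zero alt molecules has
#' VAF 0; an uncovered site has VAF `NA` (missing, distinct from zero).
#'
#' @param pileup A [build_pileup()] tibble that includes the tracked
#'   positions.
#' @param tracked Tibble (`chrom`, `pos`, `ref`, `alt`) of reporter variants
#'   (typically the baseline somatic set).
#' @return Tibble `chrom`, `pos`, `ref`, `alt`, `alt_count`, `informative`,
#'   `vaf`.
#' @export
genotype_tracked <- function(pileup, tracked) {
  if (!nrow(tracked)) abort("`tracked` must contain at least one variant.")
  base_cols <- c(A = "n_a", C = "n_c", G = "n_g", T = "n_t")
  j <- tracked |>
    dplyr::distinct(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::left_join(pileup |> dplyr::select(-"ref"), by = c("chrom", "pos"))
  m <- as.matrix(j[, unname(base_cols)])
  ac <- m[cbind(seq_len(nrow(j)), match(j$alt, names(base_cols)))]
  j |>
    dplyr::mutate(
      alt_count = as.integer(dplyr::coalesce(ac, 0L)),
      informative = dplyr::coalesce(.data$informative, 0L),
      vaf = dplyr::if_else(.data$informative > 0,
                           .data$alt_count / .data$informative, NA_real_)
    ) |>
    dplyr::select("chrom", "pos", "ref", "alt", "alt_count", "informative",
                  "vaf")
}

#' Detect phased (in-cis) variant pairs
#'
#' Evaluates every unordered pair of somatic variants lying on one
#' chromosome within `max_distance` bp and counts consensus molecules whose
#' calls carry both alternative alleles, together with the number of
#' molecules informatively covering both positions. Joint observation of two
#' variants on one molecule is far less likely to arise from independent
#' errors than a single-site call, which is what makes phased pairs useful
#' for sensitive residual-disease detection.
#'
#' @param cons A [collapse_families()] result.
#' @param variants Tibble (`chrom`, `pos`, `alt`) of variants from one
#'   sample.
#' @param max_distance Maximum pair distance in bp (inclusive, 1-based
#'   positions).
#' @param min_support Minimum double-alt molecule count for a pair to be
#'   reported.
#' @return Tibble `chrom`, `pos_a`, `alt_a`, `pos_b`, `alt_b`, `distance`,
#'   `n_both_alt`, `n_covering`.
#' @export
detect_phased_pairs <- function(cons, variants, max_distance = 100L,
                                min_support = 1L) {
  stopifnot(inherits(cons, "consensus_set"))
  v <- variants |>
    dplyr::distinct(.data$chrom, .data$pos, .data$alt) |>
    dplyr::arrange(.data$chrom, .data$pos)
  if (nrow(v) < 2) {
    return(tibble::tibble(chrom = character(), pos_a = integer(),
                          alt_a = character(), pos_b = integer(),
                          alt_b = character(), distance = integer(),
                          n_both_alt = integer(), n_covering = integer()))
  }
  pairs <- dplyr::inner_join(
    v |> dplyr::rename(pos_a = "pos", alt_a = "alt"),
    v |> dplyr::rename(pos_b = "pos", alt_b = "alt"),
    by = "chrom", relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$pos_a < .data$pos_b,
                  .data$pos_b - .data$pos_a <= max_distance) |>
    dplyr::mutate(distance = .data$pos_b - .data$pos_a)
  if (!nrow(pairs)) {
    return(pairs |> dplyr::mutate(n_both_alt = integer(),
                                  n_covering = integer()))
  }

  mols <- cons$molecules
  calls <- cons$calls
  res <- purrr::pmap(pairs, function(chrom, pos_a, alt_a, pos_b, alt_b, ...) {
    span <- mols$chrom == chrom & mols$start <= pos_a & mols$end >= pos_b
    ids <- mols$molecule_id[span]
    n_at <- function(p) calls$molecule_id[calls$chrom == chrom &
                                            calls$pos == p &
                                            calls$base == "N"]
    masked <- union(n_at(pos_a), n_at(pos_b))
    covering <- setdiff(ids, masked)
    alt_at <- function(p, a) calls$molecule_id[calls$chrom == chrom &
                                                 calls$pos == p &
                                                 calls$base == a]
    both <- intersect(intersect(alt_at(pos_a, alt_a), alt_at(pos_b, alt_b)),
                      covering)
    tibble::tibble(n_both_alt = length(both), n_covering = length(covering))
  }) |> dplyr::bind_rows()
  dplyr::bind_cols(pairs, res) |>
    dplyr::filter(.data$n_both_alt >= min_support)
}

#' Compare plasma and tissue variant sets
#'
#' Variant identity is (chrom, pos, ref, alt). Both sets are restricted to
#' panel genes before comparison; concordance is the fraction of in-panel
#' tissue variants also detected in plasma.
#'
#' @param plasma_calls,tissue_calls Tibbles with columns `chrom`, `pos`,
#'   `ref`, `alt` and optionally `gene`.
#' @param panel_genes Optional character vector of panel gene names; when
#'   given and the call tables carry a `gene` column, both sets are filtered
#'   to it.
#' @return One-row tibble: `shared`, `plasma_only`, `tissue_only`,
#'   `concordance` (shared / in-panel tissue calls; `NA` when no tissue
#'   calls).
#' @export
compare_variant_sets <- function(plasma_calls, tissue_calls,
                                 panel_genes = NULL) {
  key <- c("chrom", "pos", "ref", "alt")
  restrict <- function(x) {
    x <- dplyr::distinct(x, dplyr::pick(dplyr::all_of(
      intersect(c(key, "gene"), names(x)))))
    if (!is.null(panel_genes) && "gene" %in% names(x)) {
      x <- dplyr::filter(x, .data$gene %in% panel_genes)
    }
    dplyr::distinct(x, dplyr::pick(dplyr::all_of(key)))
  }
  p <- restrict(plasma_calls)
  t <- restrict(tissue_calls)
  shared <- nrow(dplyr::inner_join(p, t, by = key))
  tibble::tibble(
    shared = shared,
    plasma_only = nrow(p) - shared,
    tissue_only = nrow(t) - shared,
    concordance = if (nrow(t) > 0) shared / nrow(t) else NA_real_
  )
}
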