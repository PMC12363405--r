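# UMI family grouping, consensus calling and background error estimation.
#
# The family key is (chromosome, unclipped 5' start, strand, UMI). Consensus
# is a per-position plurality vote over family members: the winning base is
# emitted when its fraction reaches `majority_frac`, otherwise the position
# is masked to N. Only families of at least `min_family` members contribute
# consensus molecules, and each retained molecule counts once downstream
# regardless of family size.

#' Group UMI-tagged reads into families
#'
#' Partitions reads by (chromosome, 5' start position, strand, UMI). With
#' `umi_tolerance = 1`, UMIs at the same position within Hamming distance 1
#' are merged directionally: the smaller family is absorbed into the larger
#' when `size_small <= size_large / 2 + 1`.
#'
#' Reads whose UMI is not exactly 10 nt are excluded with a warning.
#'
#' @param reads Tibble with columns `read_id`, `chrom`, `start`, `end`,
#'   `strand`, `umi` (as produced by [simulate_sample()] or [read_sam()]).
#' @param umi_tolerance 0 (exact UMIs) or 1 (directional Hamming-1 merge).
#' @return The read tibble with an integer `family_id` column appended.
#' @export
group_umi_families <- function(reads, umi_tolerance = 0L) {
  stopifnot(all(c("chrom", "start", "end", "strand", "umi") %in% names(reads)))
  if (!umi_tolerance %in% c(0L, 1L)) abort("`umi_tolerance` must be 0 or 1.")
  bad <- nchar(reads$umi) != 10L
  if (any(bad)) {
    warn(sprintf("%d read(s) with UMI length != 10 excluded.", sum(bad)))
    reads <- reads[!bad, ]
  }
  pos5 <- ifelse(reads$strand == "+", reads$start, reads$end)
  key <- paste(reads$chrom, pos5, reads$strand, reads$umi, sep = "\r")
  fam <- match(key, unique(key))

  if (umi_tolerance == 1L) {
    poskey <- paste(reads$chrom, pos5, reads$strand, sep = "\r")
    fam_sizes <- tabulate(fam)
    fam_tbl <- tibble::tibble(fam = fam, poskey = poskey, umi = reads$umi) |>
      dplyr::distinct(.data$fam, .keep_all = TRUE) |>
      dplyr::mutate(size = fam_sizes[.data$fam])
    remap <- seq_len(max(fam))
    for (pk in unique(fam_tbl$poskey[duplicated(fam_tbl$poskey)])) {
      sub <- fam_tbl[fam_tbl$poskey == pk, ]
      sub <- sub[order(-sub$size, sub$umi), ]
      if (nrow(sub) < 2) next
      um <- strsplit(sub$umi, "")
      for (i in seq(2L, nrow(sub))) {
        for (j in seq_len(i - 1L)) {
          tgt <- remap[sub$fam[j]]   # follow earlier merges
          if (sum(um[[i]] != um[[j]]) <= 1L &&
              sub$size[i] <= sub$size[j] / 2 + 1) {
            remap[sub$fam[i]] <- tgt
            break
          }
        }
      }
    }
    fam <- remap[fam]
  }

  reads$family_id <- match(fam, unique(fam))
  reads
}

#' Collapse UMI families into consensus molecules
#'
#' Families with fewer than `min_family` members are discarded. At each
#' position the consensus is the plurality base when its fraction among
#' covering members reaches `majority_frac`; otherwise N. Positions at which
#' no member deviates from the reference are reference by construction and
#' need not be enumerated, so by default only positions with at least one
#' mismatching member are evaluated; pass `positions` to restrict (or extend)
#' evaluation explicitly.
#'
#' @param reads Output of [group_umi_families()] (must carry `family_id`).
#' @param deviations Tibble (`read_id`, `chrom`, `pos`, `base`) of read bases
#'   differing from the reference.
#' @param panel The [sim_panel()] supplying reference bases.
#' @param min_family Minimum family size retained (the assay collapses
#'   families of 3 or more members).
#' @param majority_frac Minimum winning-base fraction; below it the position
#'   is masked to N.
#' @param positions Optional tibble (`chrom`, `pos`) restricting evaluation.
#' @return A `consensus_set`: list with `molecules` (tibble `molecule_id`,
#'   `chrom`, `start`, `end`, `strand`, `umi`, `family_size`) and `calls`
#'   (tibble `molecule_id`, `chrom`, `pos`, `base` for every position whose
#'   consensus is not the reference base, N included).
#' @export
collapse_families <- function(reads, deviations, panel, min_family = 3L,
                              majority_frac = 2 / 3, positions = NULL) {
  stopifnot("family_id" %in% names(reads))
  if (min_family < 1) abort("`min_family` must be >= 1.")
  .assert_prob(majority_frac, "majority_frac")

  fam_size <- tabulate(reads$family_id)
  kept <- reads[fam_size[reads$family_id] >= min_family, ]
  if (!nrow(kept)) {
    return(structure(
      list(molecules = tibble::tibble(molecule_id = integer(),
                                      chrom = character(), start = integer(),
                                      end = integer(), strand = character(),
                                      umi = character(),
                                      family_size = integer()),
           calls = tibble::tibble(molecule_id = integer(),
                                  chrom = character(), pos = integer(),
                                  base = character()),
           min_family = as.integer(min_family),
           majority_frac = majority_frac),
      class = "consensus_set"))
  }

  kdt <- data.table(family_id = kept$family_id, chrom = kept$chrom,
                    start = kept$start, end = kept$end,
                    strand = kept$strand, umi = kept$umi)
  msum <- kdt[, .(start = min(start), end = max(end), family_size = .N),
              by = .(family_id, chrom, strand)]
  # representative UMI: the modal member UMI (ties broken lexically)
  ucnt <- kdt[, .N, by = .(family_id, umi)]
  data.table::setorder(ucnt, family_id, -N, umi)
  urep <- ucnt[!duplicated(ucnt$family_id)]
  msum <- merge(msum, urep[, c("family_id", "umi")], by = "family_id")
  molecules <- tibble::tibble(
    molecule_id = msum$family_id, chrom = msum$chrom, start = msum$start,
    end = msum$end, strand = msum$strand, umi = msum$umi,
    family_size = msum$family_size
  ) |>
    dplyr::arrange(.data$chrom, .data$start, .data$molecule_id)

  calls <- consensus_votes(kept, deviations, panel, majority_frac, positions)
  structure(list(molecules = molecules, calls = calls,
                 min_family = as.integer(min_family),
                 majority_frac = majority_frac),
            class = "consensus_set")
}

# plurality vote kernel (data.table); returns non-reference consensus calls
consensus_votes <- function(kept, deviations, panel, majority_frac,
                            positions = NULL) {
  empty <- tibble::tibble(molecule_id = integer(), chrom = character(),
                          pos = integer(), base = character())
  if (!nrow(kept)) return(empty)
  dev <- deviations[deviations$read_id %in% kept$read_id, , drop = FALSE]
  if (is.null(positions)) {
    positions <- dplyr::distinct(dev, .data$chrom, .data$pos)
  }
  if (!nrow(positions)) return(empty)

  # only positions where some member deviates can yield a non-reference
  # consensus, so restrict the kernel to (family, position) keys with votes
  rd <- data.table(read_id = kept$read_id, family_id = kept$family_id,
                   chrom = kept$chrom, s = kept$start, e = kept$end)
  pd <- data.table(chrom = positions$chrom, p = positions$pos)
  dv <- as.data.table(dev)[pd, on = .(chrom, pos = p), nomatch = NULL]
  dv <- merge(dv, rd[, c("read_id", "family_id")], by = "read_id")
  if (!nrow(dv)) return(empty)
  votes <- dv[, .(v = .N), by = .(family_id, chrom, pos, base)]

  # members of those families covering the voted position
  vk <- unique(votes[, c("family_id", "chrom", "pos")])
  rj <- rd[vk, on = .(family_id, chrom), allow.cartesian = TRUE]
  rj <- rj[s <= pos & e >= pos]
  n_cov <- rj[, .(n = .N), by = .(family_id, chrom, pos)]

  alt_sum <- votes[, .(alt_sum = sum(v)), by = .(family_id, chrom, pos)]
  data.table::setorder(votes, family_id, chrom, pos, -v, base)
  top <- votes[!duplicated(votes[, c("family_id", "chrom", "pos")])]
  agg <- merge(merge(n_cov, alt_sum, by = c("family_id", "chrom", "pos")),
               top[, .(family_id, chrom, pos, top_base = base, top_alt = v)],
               by = c("family_id", "chrom", "pos"))
  ref_votes <- agg$n - agg$alt_sum
  winner <- data.table::fifelse(ref_votes >= agg$top_alt, "ref", agg$top_base)
  wfrac <- pmax(ref_votes, agg$top_alt) / agg$n
  call <- data.table::fifelse(wfrac >= majority_frac, winner, "N")
  keep_row <- call != "ref"
  tibble::tibble(molecule_id = agg$family_id[keep_row],
                 chrom = agg$chrom[keep_row],
                 pos = agg$pos[keep_row], base = call[keep_row])
}

#' @export
print.consensus_set <- function(x, ...) {
  cat("<consensus_set> ", nrow(x$molecules), " consensus molecules (min family ",
      x$min_family, "), ", sum(x$calls$base != "N"), " non-reference calls, ",
      sum(x$calls$base == "N"), " masked positions\n", sep = "")
  invisible(x)
}

#' Estimate the background error rate from variant-free flanking sites
#'
#' Pools, across designated SNP-flanking sites, the count of consensus
#' molecules carrying the most frequent alternative base over the total
#' informative molecules. Sites carrying a germline variant in any
#' contributing individual are excluded with a warning. When no alternative
#' molecule is observed at all, the pooled rate is floored at
#' `0.5 / total molecules` so downstream binomial tests remain defined.
#'
#' @param cons A [collapse_families()] result.
#' @param flanking_sites Tibble (`chrom`, `pos`) of variant-free sites
#'   (conventionally the bases 5' and 3' of each interrogated SNP).
#' @param panel The [sim_panel()].
#' @param germline Optional tibble (`chrom`, `pos`, `genotype`) of germline
#'   genotypes; sites with `genotype > 0` are excluded.
#' @return An `error_model`: list with pooled `rate`, `floored` flag,
#'   `n_sites`, `total_molecules`, `alt_molecules` and a `per_site` tibble.
#' @export
estimate_background_error <- function(cons, flanking_sites, panel,
                                      germline = NULL) {
  stopifnot(inherits(cons, "consensus_set"))
  sites <- dplyr::distinct(flanking_sites, .data$chrom, .data$pos)
  if (!is.null(germline) && nrow(germline)) {
    gv <- germline |> dplyr::filter(.data$genotype > 0)
    before <- nrow(sites)
    sites <- dplyr::anti_join(sites, gv, by = c("chrom", "pos"))
    if (nrow(sites) < before) {
      warn(sprintf("%d flanking site(s) overlapping germline variants excluded.",
                   before - nrow(sites)))
    }
  }
  if (!nrow(sites)) abort("No usable flanking sites.")

  mols <- cons$molecules
  cover <- span_coverage(mols$chrom, mols$start, mols$end,
                         sites$chrom, sites$pos)
  calls <- dplyr::semi_join(cons$calls, sites, by = c("chrom", "pos"))
  n_call <- calls |>
    dplyr::summarise(
      n_n = sum(.data$base == "N"),
      alt = if (any(.data$base != "N")) {
        max(table(.data$base[.data$base != "N"]))
      } else 0L,
      .by = c("chrom", "pos")
    )
  per_site <- sites |>
    dplyr::mutate(total = cover) |>
    dplyr::left_join(n_call, by = c("chrom", "pos")) |>
    dplyr::mutate(
      n_n = dplyr::coalesce(.data$n_n, 0L),
      alt = as.integer(dplyr::coalesce(.data$alt, 0L)),
      informative = .data$total - .data$n_n,
      rate = dplyr::if_else(.data$informative > 0,
                            .data$alt / .data$informative, NA_real_)
    ) |>
    dplyr::select("chrom", "pos", "informative", "alt", "rate")

  total <- sum(per_site$informative)
  alt_total <- sum(per_site$alt)
  if (total == 0) abort("No informative molecules at flanking sites.")
  floored <- alt_total == 0
  rate <- if (floored) 0.5 / total else alt_total / total
  structure(list(rate = rate, floored = floored, n_sites = nrow(per_site),
                 total_molecules = total, alt_molecules = alt_total,
                 per_site = per_site),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf(
    "<error_model> pooled background %.3g (%d alt / %d molecules over %d sites%s)\n",
    x$rate, x$alt_molecules, x$total_molecules, x$n_sites,
    if (x$floored) "; floored" else ""))
  invisible(x)
}
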