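# shared builders for small simulated datasets

small_panel <- function(seed = 101, n_genes = 2, gene_bp = 600,
                        n_backbone = 12, flank = 150) {
  sim_panel(n_genes = n_genes, gene_bp = gene_bp, n_backbone = n_backbone,
            backbone_flank = flank, seed = seed)
}

# somatic variants at fixed offsets into gene targets, alt guaranteed != ref
variants_at <- function(panel, target_idx, offsets, vaf,
                        phase_group = NA_integer_) {
  tg <- panel$targets[target_idx, ]
  chrom <- tg$chrom
  pos <- tg$start + as.integer(offsets)
  ref <- ref_base(panel, chrom, pos)
  tibble::tibble(
    chrom = chrom, pos = pos,
    ref = ref,
    alt = vapply(ref, function(r) setdiff(c("A", "C", "G", "T"), r)[1], ""),
    vaf = vaf,
    phase_group = phase_group
  )
}

# reads tibble built by hand for consensus unit tests (all plus strand)
mk_reads <- function(chrom, start, len, umi, n = 1L, strand = "+",
                     id_start = 1L) {
  k <- max(length(chrom), length(start), length(umi), n)
  tibble::tibble(
    read_id = seq.int(id_start, length.out = k),
    chrom = rep_len(chrom, k),
    start = rep_len(as.integer(start), k),
    end = rep_len(as.integer(start + len - 1L), k),
    strand = rep_len(strand, k),
    umi = rep_len(umi, k)
  )
}

# exhaustive per-position vote oracle, independent of collapse_families()
oracle_collapse <- function(reads, deviations, panel, min_family = 3L,
                            majority_frac = 2 / 3) {
  out <- list()
  for (f in unique(reads$family_id)) {
    mem <- reads[reads$family_id == f, ]
    if (nrow(mem) < min_family) next
    pos_all <- unique(unlist(mapply(seq, mem$start, mem$end,
                                    SIMPLIFY = FALSE)))
    for (p in sort(pos_all)) {
      covering <- mem[mem$start <= p & mem$end >= p, ]
      ref <- ref_base(panel, covering$chrom[1], p)
      bases <- vapply(covering$read_id, function(rid) {
        d <- deviations[deviations$read_id == rid & deviations$pos == p, ]
        if (nrow(d)) d$base[1] else ref
      }, "")
      tab <- sort(table(bases), decreasing = TRUE)
      win <- names(tab)[1]
      # ties involving the reference resolve to the reference
      if (ref %in% names(tab) && tab[[ref]] == max(tab)) win <- ref
      frac <- max(tab) / nrow(covering)
      call <- if (frac >= majority_frac) win else "N"
      if (call != ref) {
        out[[length(out) + 1L]] <- tibble::tibble(
          molecule_id = f, chrom = covering$chrom[1], pos = p, base = call)
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(molecule_id = integer(), chrom = character(),
                   pos = integer(), base = character())
}

# brute-force phased-pair oracle over consensus molecules
oracle_phased <- function(cons, variants, panel, max_distance = 100L) {
  v <- dplyr::arrange(dplyr::distinct(variants, chrom, pos, alt), chrom, pos)
  mols <- cons$molecules
  calls <- cons$calls
  rows <- list()
  if (nrow(v) >= 2) {
    for (i in seq_len(nrow(v) - 1L)) {
      for (j in seq.int(i + 1L, nrow(v))) {
        if (v$chrom[i] != v$chrom[j]) next
        dist <- abs(v$pos[j] - v$pos[i])
        if (dist > max_distance) next
        n_both <- 0L; n_cov <- 0L
        for (m in seq_len(nrow(mols))) {
          if (mols$chrom[m] != v$chrom[i] || mols$start[m] > v$pos[i] ||
              mols$end[m] < v$pos[j]) next
          base_at <- function(p) {
            d <- calls[calls$molecule_id == mols$molecule_id[m] &
                         calls$pos == p, ]
            if (nrow(d)) d$base[1] else ref_base(panel, v$chrom[i], p)
          }
          bi <- base_at(v$pos[i]); bj <- base_at(v$pos[j])
          if (bi == "N" || bj == "N") next
          n_cov <- n_cov + 1L
          if (bi == v$alt[i] && bj == v$alt[j]) n_both <- n_both + 1L
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          chrom = v$chrom[i], pos_a = v$pos[i], pos_b = v$pos[j],
          n_both_alt = n_both, n_covering = n_cov)
      }
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(chrom = character(), pos_a = integer(), pos_b = integer(),
                   n_both_alt = integer(), n_covering = integer())
}
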