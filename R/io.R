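# File-format boundaries. Internally everything is 1-based inclusive;
# BED is written/read as 0-based half-open, SAM/VCF as 1-based. Parsing of
# the standard formats is delegated to Rsamtools (SAM via BAM conversion),
# rtracklayer (BED), vcfR (VCF) and Biostrings (FASTA).

# SAM -------------------------------------------------------------------------

# materialise read sequences from the sparse representation
materialise_seq <- function(reads, deviations, panel) {
  widx <- window_index(panel, reads$chrom, reads$start)
  if (anyNA(widx)) abort("Read outside panel windows; cannot materialise.")
  off <- reads$start - panel$windows$start[widx] + 1L
  seqs <- stringr::str_sub(panel$windows$seq[widx], off,
                           off + (reads$end - reads$start))
  if (nrow(deviations)) {
    dev <- deviations |>
      dplyr::inner_join(
        tibble::tibble(read_id = reads$read_id, idx = seq_len(nrow(reads)),
                       rstart = reads$start),
        by = "read_id"
      ) |>
      dplyr::mutate(o = .data$pos - .data$rstart + 1L) |>
      dplyr::group_by(.data$read_id) |>
      dplyr::mutate(.round = dplyr::row_number()) |>
      dplyr::ungroup()
    # vectorised substring assignment handles one deviation per read at a
    # time; reads with several deviations need several rounds
    for (r in sort(unique(dev$.round))) {
      d <- dev[dev$.round == r, ]
      stringr::str_sub(seqs[d$idx], d$o, d$o) <- d$base
    }
  }
  seqs
}

#' Write reads to a SAM file
#'
#' Emits coordinate-sorted single-end alignments with all-match CIGARs and
#' the UMI in the `RX` tag (the read name also carries the UMI as its final
#' `:`-separated field, the common fallback dialect).
#'
#' @param sample A `cfdna_sample`, or a list with `reads` and `deviations`
#'   tibbles.
#' @param path Output path.
#' @param panel The [sim_panel()] (reference sequence and chromosome sizes).
#' @return `path`, invisibly.
#' @export
write_sam <- function(sample, path, panel = sample$config$panel) {
  reads <- sample$reads |> dplyr::arrange(.data$chrom, .data$start)
  seqs <- materialise_seq(reads, sample$deviations, panel)
  chroms <- names(panel$chrom_lengths)
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", chroms, as.integer(panel$chrom_lengths)),
    "@RG\tID:sim\tSM:sim"
  )
  flag <- ifelse(reads$strand == "-", 16L, 0L)
  rec <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*\tRX:Z:%s",
                 reads$qname, flag, reads$chrom, reads$start,
                 reads$end - reads$start + 1L, seqs, reads$umi)
  writeLines(c(header, rec), path)
  invisible(path)
}

#' Read UMI-tagged reads from a SAM/BAM file
#'
#' Converts SAM text to BAM with Rsamtools and scans it back, recovering the
#' UMI from the `RX` tag or, failing that, from the final `:`-separated
#' field of the read name. Per-base deviations from the panel reference are
#' reconstructed by sequence comparison (alignments are expected to be
#' simple all-match records, as this pipeline's simulator emits).
#'
#' @param path SAM or BAM path.
#' @param panel The [sim_panel()] the reads were simulated against.
#' @return List with `reads` and `deviations` tibbles in the internal
#'   representation.
#' @export
read_sam <- function(path, panel) {
  if (!file.exists(path)) abort(sprintf("No such reads file: %s", path))
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) path else {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  }
  sc <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "seq"),
      tag = "RX"
    )
  )[[1]]
  seqs <- as.character(sc$seq)
  umi <- sc$tag$RX
  if (is.null(umi)) umi <- rep(NA_character_, length(seqs))
  fallback <- is.na(umi)
  if (any(fallback)) {
    umi[fallback] <- sub(".*:", "", sc$qname[fallback])
  }
  reads <- tibble::tibble(
    read_id = seq_along(seqs),
    qname = sc$qname,
    chrom = as.character(sc$rname),
    start = sc$pos,
    end = sc$pos + nchar(seqs) - 1L,
    strand = ifelse(bitwAnd(sc$flag, 16L) > 0L, "-", "+"),
    umi = umi
  )
  widx <- window_index(panel, reads$chrom, reads$start)
  off <- reads$start - panel$windows$start[widx] + 1L
  refs <- stringr::str_sub(panel$windows$seq[widx], off,
                           off + (reads$end - reads$start))
  # one pass over the concatenated bytes, then map mismatch offsets back to
  # their reads via the cumulative read lengths
  lens <- nchar(seqs)
  raw_s <- charToRaw(paste(seqs, collapse = ""))
  raw_r <- charToRaw(paste(refs, collapse = ""))
  mm <- which(raw_s != raw_r)
  if (length(mm)) {
    cum <- cumsum(lens)
    ridx <- findInterval(mm - 1L, cum) + 1L
    off <- mm - c(0L, cum)[ridx]          # 1-based offset within the read
    deviations <- tibble::tibble(
      read_id = ridx,
      chrom = reads$chrom[ridx],
      pos = reads$start[ridx] + off - 1L,
      base = rawToChar(raw_s[mm], multiple = TRUE)
    )
  } else {
    deviations <- tibble::tibble(read_id = integer(), chrom = character(),
                                 pos = integer(), base = character())
  }
  list(reads = reads, deviations = deviations)
}

# BED -------------------------------------------------------------------------

#' Write intervals to BED (0-based half-open)
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (1-based inclusive)
#'   and optionally a name column (`gene` or `name`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  nm <- if ("gene" %in% names(intervals)) intervals$gene
        else if ("name" %in% names(intervals)) intervals$name
        else "."
  readr::write_tsv(
    tibble::tibble(chrom = intervals$chrom,
                   start = intervals$start - 1L,
                   end = intervals$end,
                   name = nm),
    path, col_names = FALSE
  )
  invisible(path)
}

#' Read a BED file into 1-based inclusive intervals
#'
#' @param path BED path.
#' @return Tibble `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such BED file: %s", path))
  gr <- rtracklayer::import(path, format = "BED")
  df <- as.data.frame(gr)
  tibble::tibble(
    chrom = as.character(df$seqnames),
    start = df$start,   # rtracklayer already converts to 1-based
    end = df$end,
    name = if ("name" %in% names(df)) df$name else NA_character_
  )
}

# VCF -------------------------------------------------------------------------

#' Write germline genotypes to VCF v4.2
#'
#' @param genotypes Named list of per-individual genotype tibbles
#'   (`chrom`, `pos`, `genotype` 0/1/2); all individuals must share loci.
#' @param panel The [sim_panel()] (ref/alt alleles at backbone loci).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(genotypes, panel, path) {
  stopifnot(is.list(genotypes), length(genotypes) >= 1, !is.null(panel$backbone))
  loci <- panel$backbone
  gt_str <- c("0/0", "0/1", "1/1")
  cols <- purrr::map(genotypes, function(g) {
    m <- dplyr::left_join(loci |> dplyr::select("chrom", "pos"), g,
                          by = c("chrom", "pos"))
    gt_str[dplyr::coalesce(m$genotype, 0L) + 1L]
  })
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(panel$chrom_lengths),
            as.integer(panel$chrom_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", names(genotypes)), collapse = "\t")
  )
  body <- do.call(paste, c(
    list(loci$chrom, loci$pos, sprintf("SNP%04d", seq_len(nrow(loci))),
         loci$ref, loci$alt, ".", "PASS", ".", "GT"),
    cols, list(sep = "\t")
  ))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read germline genotypes from a VCF
#'
#' @param path VCF path.
#' @return Named list of per-individual tibbles (`chrom`, `pos`, `ref`,
#'   `alt`, `genotype`).
#' @export
read_vcf_genotypes <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such VCF file: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fx <- v@fix
  base <- tibble::tibble(chrom = fx[, "CHROM"],
                         pos = as.integer(fx[, "POS"]),
                         ref = fx[, "REF"], alt = fx[, "ALT"])
  purrr::map(colnames(gt), function(ind) {
    g <- gt[, ind]
    dose <- stringr::str_count(g, "1")
    dose[is.na(g)] <- NA_integer_
    base |> dplyr::mutate(genotype = as.integer(dose))
  }) |> setNames(colnames(gt))
}

# cohort / tables -------------------------------------------------------------

cohort_cols <- function() {
  readr::cols(
    patient = readr::col_character(),
    emr = readr::col_logical(),
    eot_response = readr::col_character(),
    mrd = readr::col_character(),
    baseline_hge = readr::col_double(),
    ldh_uln = readr::col_double(),
    ripi = readr::col_character(),
    pfs_months = readr::col_double(),
    pfs_event = readr::col_logical(),
    os_months = readr::col_double(),
    os_event = readr::col_logical()
  )
}

#' Write / read the clinical cohort table
#'
#' @param cohort Cohort tibble (see [stratify_and_report()] for the schema).
#' @param path CSV path.
#' @return `write_cohort()`: `path`, invisibly. `read_cohort()`: the cohort
#'   tibble with typed columns.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such cohort file: %s", path))
  readr::read_csv(path, col_types = cohort_cols(), na = c("", "NA"))
}

# panel bundle ----------------------------------------------------------------

#' Write / read a panel bundle
#'
#' Serialises a [sim_panel()] to plain-text files in `dir`: `targets.bed`
#' and `backbone.bed` (0-based half-open), `backbone.tsv` (alleles and
#' allele frequencies), `reference.fa` (sequence of every captured window,
#' named `chrom:start-end` 1-based) and `arms.tsv`.
#'
#' @param panel A [sim_panel()].
#' @param dir Directory (created if needed).
#' @return `write_panel()`: `dir` invisibly; `read_panel()`: a
#'   `cfdna_panel`.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bed(panel$targets, file.path(dir, "targets.bed"))
  if (!is.null(panel$backbone)) {
    write_bed(panel$backbone |>
                dplyr::transmute(.data$chrom, start = .data$pos,
                                 end = .data$pos,
                                 name = sprintf("SNP%04d", dplyr::row_number())),
              file.path(dir, "backbone.bed"))
    readr::write_tsv(panel$backbone, file.path(dir, "backbone.tsv"))
  }
  readr::write_tsv(panel$arms, file.path(dir, "arms.tsv"))
  seqs <- Biostrings::DNAStringSet(panel$windows$seq)
  names(seqs) <- sprintf("%s:%d-%d|%s|%s", panel$windows$chrom,
                         panel$windows$start, panel$windows$end,
                         panel$windows$kind, panel$windows$name)
  Biostrings::writeXStringSet(seqs, file.path(dir, "reference.fa"))
  readr::write_tsv(
    tibble::tibble(chrom = names(panel$chrom_lengths),
                   length = as.integer(panel$chrom_lengths),
                   backbone_flank = panel$backbone_flank),
    file.path(dir, "chroms.tsv")
  )
  invisible(dir)
}

#' @rdname write_panel
#' @export
read_panel <- function(dir) {
  fa <- file.path(dir, "reference.fa")
  if (!file.exists(fa)) abort(sprintf("No panel reference at %s", fa))
  seqs <- Biostrings::readDNAStringSet(fa)
  meta <- stringr::str_match(names(seqs),
                             "^(\\S+?):(\\d+)-(\\d+)\\|(\\w+)\\|(\\S+)$")
  windows <- tibble::tibble(
    chrom = meta[, 2], start = as.integer(meta[, 3]),
    end = as.integer(meta[, 4]), kind = meta[, 5], name = meta[, 6],
    seq = unname(as.character(seqs))
  )
  targets <- read_bed(file.path(dir, "targets.bed")) |>
    dplyr::rename(gene = "name")
  backbone <- NULL
  bb_path <- file.path(dir, "backbone.tsv")
  if (file.exists(bb_path)) {
    backbone <- readr::read_tsv(bb_path, col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_integer(),
      ref = readr::col_character(), alt = readr::col_character(),
      maf = readr::col_double(), arm = readr::col_character()
    ))
  }
  arms <- readr::read_tsv(file.path(dir, "arms.tsv"),
                          col_types = readr::cols())
  chroms <- readr::read_tsv(file.path(dir, "chroms.tsv"),
                            col_types = readr::cols())
  structure(
    list(targets = targets, backbone = backbone, windows = windows,
         arms = arms,
         chrom_lengths = setNames(chroms$length, chroms$chrom),
         backbone_flank = chroms$backbone_flank[1], seed = NA_integer_),
    class = "cfdna_panel"
  )
}
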