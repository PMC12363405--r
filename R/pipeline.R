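# End-to-end orchestration: files in, report tables out. The YAML config is
# flat-keyed by stage; every value has a default so a minimal config only
# names its input paths.

pipeline_defaults <- function() {
  list(
    paths = list(panel_dir = NULL, sample_sheet = NULL, germline_vcf = NULL,
                 cohort_csv = NULL, normal_profiles = character(),
                 out_dir = "pipeline_out"),
    consensus = list(min_family = 3L, majority_frac = 2 / 3,
                     umi_tolerance = 0L),
    calling = list(alpha = 0.05, min_alt = 2L, germline_threshold = 0.20),
    quant = list(pg_per_hge = 3.3, floor_hge = 1, emr_threshold_log10 = 2),
    mrd = list(alpha = 0.05, min_phased_molecules = 1L,
               min_informative = 1000L),
    cnv = list(gain_threshold = 0.3, loss_threshold = -0.3, min_loci = 5L,
               min_ref_depth = 50),
    identity = list(min_depth = 20L, min_loci = 100L,
                    mislabel_threshold = 0.80),
    seed = 1L
  )
}

#' Assemble a pipeline run configuration
#'
#' @param config A YAML file path or a named list; entries override the
#'   documented defaults stage by stage.
#' @return A `run_config` list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("No such config file: %s", config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- modifyList(pipeline_defaults(), config)
  .assert_prob(cfg$calling$alpha, "calling$alpha")
  .assert_prob(cfg$consensus$majority_frac, "consensus$majority_frac")
  .assert_prob(cfg$calling$germline_threshold, "calling$germline_threshold")
  .assert_pos(cfg$quant$pg_per_hge, "quant$pg_per_hge")
  structure(cfg, class = "run_config")
}

gene_of <- function(panel, chrom, pos) {
  idx <- window_index(panel, chrom, pos)
  out <- rep(NA_character_, length(pos))
  ok <- !is.na(idx) & panel$windows$kind[idx] == "gene"
  out[ok] <- panel$windows$name[idx[ok]]
  out
}

# Buccal evidence table for candidate sites. The germline VCF is treated as
# the normal-sample truth over the panel: a recorded genotype implies buccal
# VAF genotype/2 for that alt allele; any other allele at a covered panel
# site is absent in the normal (VAF 0).
buccal_evidence <- function(sites, germ_tbl) {
  sites <- dplyr::distinct(sites, .data$chrom, .data$pos)
  tidyr::crossing(sites, alt = BASES) |>
    dplyr::left_join(
      germ_tbl |> dplyr::select("chrom", "pos", g_alt = "alt", "genotype"),
      by = c("chrom", "pos")
    ) |>
    dplyr::mutate(
      vaf = dplyr::if_else(!is.na(.data$genotype) & .data$alt == .data$g_alt,
                           dplyr::coalesce(.data$genotype, 0L) / 2, 0)
    ) |>
    dplyr::select("chrom", "pos", "alt", "vaf")
}

#' Run the full ctDNA analysis pipeline
#'
#' Reads the panel bundle, sample sheet, germline VCF and cohort CSV named
#' in the config; per sample performs UMI grouping, consensus collapse and
#' background-error estimation; discovers somatic variants on each
#' patient's baseline sample (tumour/normal against the germline VCF);
#' genotypes the tracked reporters at every timepoint; quantifies burden
#' and classifies EMR; calls MRD on remission samples (phased-pair evidence
#' included); runs backbone copy-number and LOH calling when a panel of
#' normal profiles is configured; checks sample identity against the
#' germline genotypes; and runs the EMR-stratified outcome analysis on the
#' cohort table. All result tables are written to `paths$out_dir` together
#' with a run manifest, and returned invisibly.
#'
#' @param config A [run_config()] (or anything it accepts).
#' @return Invisibly, a named list of the result tibbles.
#' @export
run_pipeline <- function(config) {
  cfg <- run_config(config)
  p <- cfg$paths
  for (need in c("panel_dir", "sample_sheet", "germline_vcf", "cohort_csv")) {
    if (is.null(p[[need]])) abort(sprintf("Config is missing paths$%s.", need))
    if (!file.exists(p[[need]])) {
      abort(sprintf("Input path does not exist: %s (paths$%s)", p[[need]], need))
    }
  }
  out_dir <- p$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  on_fail <- function(e) {
    unlink(written)
    abort(sprintf("Pipeline failed (%s); partial outputs removed.",
                  conditionMessage(e)), parent = e)
  }

  tryCatch({
    panel <- read_panel(p$panel_dir)
    sheet <- readr::read_csv(p$sample_sheet, col_types = readr::cols())
    need_cols <- c("patient", "timepoint", "day", "cfdna_ng_per_ml", "sam")
    if (!all(need_cols %in% names(sheet))) {
      abort(sprintf("Sample sheet must have columns: %s",
                    paste(need_cols, collapse = ", ")))
    }
    germ <- read_vcf_genotypes(p$germline_vcf)
    inform(sprintf("[pipeline] %d samples, %d germline individuals",
                   nrow(sheet), length(germ)))

    # per-sample consensus ----------------------------------------------------
    cons_list <- purrr::pmap(sheet, function(patient, timepoint, day,
                                             cfdna_ng_per_ml, sam, ...) {
      rd <- read_sam(sam, panel)
      n_in <- nrow(rd$reads)
      grouped <- group_umi_families(rd$reads, cfg$consensus$umi_tolerance)
      cons <- collapse_families(grouped, rd$deviations, panel,
                                min_family = cfg$consensus$min_family,
                                majority_frac = cfg$consensus$majority_frac)
      inform(sprintf(
        "[consensus] %s/%s: %d reads in, %d families, %d molecules kept (%d reads in short families filtered)",
        patient, timepoint, n_in, dplyr::n_distinct(grouped$family_id),
        nrow(cons$molecules), n_in - sum(cons$molecules$family_size)))
      cons
    })
    names(cons_list) <- paste(sheet$patient, sheet$timepoint, sep = "|")

    bb_pos <- panel$backbone |> dplyr::select("chrom", "pos")
    flanks <- tibble::tibble(chrom = rep(bb_pos$chrom, 2L),
                             pos = c(bb_pos$pos - 1L, bb_pos$pos + 1L))

    # baseline discovery per patient ------------------------------------------
    patients <- unique(sheet$patient)
    tracked_list <- list(); phased_list <- list(); var_rows <- list()
    error_models <- list()
    for (pt in patients) {
      key <- paste(pt, "baseline", sep = "|")
      if (!key %in% names(cons_list)) next
      cons <- cons_list[[key]]
      g_tbl <- germ[[pt]]
      if (is.null(g_tbl)) abort(sprintf("No germline genotypes for %s.", pt))
      em <- estimate_background_error(cons, flanks, panel, germline = g_tbl)
      error_models[[pt]] <- em
      pu <- build_pileup(cons, panel)
      calls <- call_somatic(pu, buccal_evidence(pu, g_tbl),
                            em, alpha = cfg$calling$alpha,
                            min_alt = cfg$calling$min_alt,
                            germline_threshold = cfg$calling$germline_threshold,
                            n_tests = panel_size_bp(panel))
      var_rows[[pt]] <- calls |> dplyr::mutate(patient = pt,
                                               gene = gene_of(panel, .data$chrom,
                                                              .data$pos))
      somatic <- calls |> dplyr::filter(.data$status == "somatic")
      tracked_list[[pt]] <- somatic |>
        dplyr::select("chrom", "pos", "ref", "alt")
      phased_list[[pt]] <- detect_phased_pairs(cons, somatic)
      inform(sprintf("[call] %s: %d candidates, %d somatic, %d phased pairs",
                     pt, nrow(calls), nrow(somatic),
                     nrow(phased_list[[pt]])))
    }

    # longitudinal genotyping + quantification --------------------------------
    quant_rows <- list(); ribbon_rows <- list(); mrd_rows <- list()
    for (i in seq_len(nrow(sheet))) {
      pt <- sheet$patient[i]; tp <- sheet$timepoint[i]
      cons <- cons_list[[paste(pt, tp, sep = "|")]]
      tracked <- tracked_list[[pt]]
      if (is.null(tracked) || !nrow(tracked)) next
      pu <- build_pileup(cons, panel,
                         positions = tracked |> dplyr::select("chrom", "pos"))
      geno <- genotype_tracked(pu, tracked)
      ribbon_rows[[length(ribbon_rows) + 1L]] <- geno |>
        dplyr::mutate(patient = pt, timepoint = tp, day = sheet$day[i],
                      gene = gene_of(panel, .data$chrom, .data$pos))
      quant_rows[[length(quant_rows) + 1L]] <- tibble::tibble(
        patient = pt, timepoint = tp, day = sheet$day[i],
        cfdna_ng_per_ml = sheet$cfdna_ng_per_ml[i],
        n_reporters = sum(!is.na(geno$vaf)),
        mean_vaf = mean(geno$vaf, na.rm = TRUE)
      )
      if (tp %in% c("remission", "late", "mrd")) {
        pp_base <- phased_list[[pt]]
        pp_now <- detect_phased_pairs(cons, tracked)
        if (!is.null(pp_base) && nrow(pp_base)) {
          pp_now <- dplyr::semi_join(
            pp_now, pp_base, by = c("chrom", "pos_a", "pos_b"))
        } else pp_now <- pp_now[0, ]
        mrd_rows[[length(mrd_rows) + 1L]] <-
          call_mrd(geno, error_models[[pt]], phased_support = pp_now,
                   alpha = cfg$mrd$alpha,
                   min_phased_molecules = cfg$mrd$min_phased_molecules,
                   min_informative = cfg$mrd$min_informative) |>
          dplyr::mutate(patient = pt, timepoint = tp, .before = 1)
      }
    }
    quant <- dplyr::bind_rows(quant_rows) |>
      dplyr::mutate(mean_vaf = dplyr::if_else(is.nan(.data$mean_vaf),
                                              NA_real_, .data$mean_vaf)) |>
      quantify_samples(pg_per_hge = cfg$quant$pg_per_hge)
    emr <- classify_emr(quant, floor_hge = cfg$quant$floor_hge,
                        threshold_log10 = cfg$quant$emr_threshold_log10)
    mrd <- dplyr::bind_rows(mrd_rows)

    # CNV / LOH over the backbone ---------------------------------------------
    cnv_segments <- tibble::tibble()
    if (length(p$normal_profiles) >= 3) {
      normals <- purrr::map(p$normal_profiles, function(np) {
        readr::read_tsv(np, col_types = readr::cols())
      })
      cnv_rows <- list()
      for (pt in patients) {
        cons <- cons_list[[paste(pt, "baseline", sep = "|")]]
        pu <- build_pileup(cons, panel, positions = bb_pos)
        prof <- pu |>
          dplyr::inner_join(panel$backbone, by = c("chrom", "pos"),
                            suffix = c("", ".bb")) |>
          dplyr::mutate(
            alt_count = purrr::pmap_int(
              list(.data$n_a, .data$n_c, .data$n_g, .data$n_t, .data$alt),
              \(a, c, g, t, altb) c(A = a, C = c, G = g, T = t)[[altb]]),
            depth = .data$informative,
            ref_count = .data$depth - .data$alt_count
          ) |>
          dplyr::select("chrom", "pos", "depth", "ref_count", "alt_count")
        lr <- compute_log2_ratios(prof, normals,
                                  min_ref_depth = cfg$cnv$min_ref_depth)
        segs <- segment_and_call(lr, panel$arms,
                                 gain_threshold = cfg$cnv$gain_threshold,
                                 loss_threshold = cfg$cnv$loss_threshold,
                                 min_loci = cfg$cnv$min_loci)
        het <- germ[[pt]] |> dplyr::filter(.data$genotype == 1L)
        loh <- detect_loh(lr, het, panel$arms, min_het = cfg$cnv$min_loci)
        cnv_rows[[pt]] <- segs |>
          dplyr::left_join(loh |> dplyr::select("chrom", "arm", "n_het",
                                                "mean_baf_dev", "loh"),
                           by = c("chrom", "arm")) |>
          dplyr::mutate(patient = pt, .before = 1)
      }
      cnv_segments <- dplyr::bind_rows(cnv_rows)
    }

    # identity QC --------------------------------------------------------------
    id_rows <- list()
    for (i in seq_len(nrow(sheet))) {
      pt <- sheet$patient[i]; tp <- sheet$timepoint[i]
      cons <- cons_list[[paste(pt, tp, sep = "|")]]
      pu <- build_pileup(cons, panel, positions = bb_pos)
      prof <- pu |>
        dplyr::inner_join(panel$backbone, by = c("chrom", "pos"),
                          suffix = c("", ".bb")) |>
        dplyr::mutate(
          alt_count = purrr::pmap_int(
            list(.data$n_a, .data$n_c, .data$n_g, .data$n_t, .data$alt),
            \(a, c, g, t, altb) c(A = a, C = c, G = g, T = t)[[altb]]),
          depth = .data$informative
        )
      obs <- backbone_genotype_calls(prof, min_depth = cfg$identity$min_depth)
      expd <- germ[[pt]] |>
        dplyr::transmute(.data$chrom, .data$pos, depth = 1e6L,
                         genotype_call = .data$genotype)
      id_rows[[length(id_rows) + 1L]] <-
        genotype_concordance(obs, expd, min_depth = cfg$identity$min_depth,
                             min_loci = cfg$identity$min_loci,
                             mislabel_threshold = cfg$identity$mislabel_threshold) |>
        dplyr::mutate(patient = pt, timepoint = tp, .before = 1)
    }
    identity_qc <- dplyr::bind_rows(id_rows)

    # outcomes -----------------------------------------------------------------
    cohort <- read_cohort(p$cohort_csv)
    outcome <- stratify_and_report(cohort, "emr")

    variants <- dplyr::bind_rows(var_rows)
    comut <- variants |>
      dplyr::filter(.data$status == "somatic", !is.na(.data$gene)) |>
      dplyr::distinct(.data$patient, .data$gene) |>
      dplyr::mutate(mutated = 1L) |>
      tidyr::pivot_wider(names_from = "patient", values_from = "mutated",
                         values_fill = 0L)
    ribbon <- dplyr::bind_rows(ribbon_rows)
    phased <- purrr::imap(phased_list, \(x, pt) dplyr::mutate(x, patient = pt,
                                                              .before = 1)) |>
      dplyr::bind_rows()

    # write tables -------------------------------------------------------------
    emit <- function(x, file, writer = readr::write_tsv) {
      fp <- file.path(out_dir, file)
      writer(x, fp)
      written <<- c(written, fp)
      fp
    }
    emit(variants, "variants.tsv")
    emit(quant, "sample_quant.csv", readr::write_csv)
    emit(emr, "emr.csv", readr::write_csv)
    if (nrow(mrd)) emit(mrd, "mrd.csv", readr::write_csv)
    if (nrow(cnv_segments)) emit(cnv_segments, "cnv_segments.tsv")
    emit(identity_qc, "identity_qc.csv", readr::write_csv)
    emit(tidy(outcome), "outcomes.csv", readr::write_csv)
    emit(comut, "comutation.tsv")
    emit(ribbon, "ribbon.tsv")
    if (nrow(phased)) emit(phased, "phased_pairs.tsv")
    manifest <- c(
      sprintf("plasmamrd %s (R %s.%s)", as.character(packageVersion("plasmamrd")),
              R.version$major, R.version$minor),
      sprintf("config_hash: %s", hash(cfg[setdiff(names(cfg), "paths")])),
      sprintf("seed: %d", cfg$seed),
      sprintf("samples: %d; patients: %d", nrow(sheet), length(patients))
    )
    writeLines(manifest, file.path(out_dir, "manifest.txt"))
    written <- c(written, file.path(out_dir, "manifest.txt"))

    invisible(list(variants = variants, quant = quant, emr = emr, mrd = mrd,
                   cnv_segments = cnv_segments, identity_qc = identity_qc,
                   outcome = outcome, comutation = comut, ribbon = ribbon,
                   phased = phased))
  }, error = on_fail)
}
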