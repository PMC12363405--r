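#' Build a synthetic hybrid-capture panel
#'
#' Constructs the targeted design the simulator and pipeline operate on: a set
#' of gene-level capture targets, a genome-wide SNP backbone used for
#' copy-number and sample-identity analysis, and the reference sequence under
#' every targeted window. Coordinates live on a synthetic genome of 22
#' chromosomes (100 Mb each, p arm = first 50 Mb) so that arm-level
#' copy-number segmentation has a well-defined arm table.
#'
#' Defaults mirror a 42-gene lymphoma design totalling ~148.2 kbp with a
#' 1040-locus SNP backbone; tests typically build much smaller panels.
#'
#' @param n_genes Number of gene targets.
#' @param gene_bp Width of each gene target in bp.
#' @param n_backbone Number of backbone SNP loci.
#' @param backbone_flank Half-width of the captured window centred on each
#'   backbone SNP (bp). Must exceed the maximum fragment length used in
#'   simulation so fragments fit inside the window.
#' @param backbone_maf Population minor-allele frequency assigned to every
#'   backbone SNP (backbone designs select common SNPs; ~0.5 maximises
#'   fingerprinting information).
#' @param seed Integer seed fixing the reference sequence and locus placement.
#'
#' @return An object of class `cfdna_panel`: a list with tibbles `targets`
#'   (chrom, start, end, gene; 1-based inclusive), `backbone`
#'   (chrom, pos, ref, alt, maf, arm), `windows` (all captured intervals with
#'   their reference sequence), `arms`, and `chrom_lengths`.
#' @export
#' @examples
#' pan <- sim_panel(n_genes = 4, gene_bp = 600, n_backbone = 24, seed = 7)
#' pan$targets
sim_panel <- function(n_genes = 42L, gene_bp = 3529L, n_backbone = 1040L,
                      backbone_flank = 200L, backbone_maf = 0.5, seed = 20201L) {
  stopifnot(n_genes >= 1, gene_bp >= 50, n_backbone >= 0)
  .assert_prob(backbone_maf, "backbone_maf")
  withr::local_seed(seed)

  chroms <- paste0("chr", 1:22)
  chrom_lengths <- setNames(rep(1e8, 22), chroms)
  arms <- tibble::tibble(
    chrom = rep(chroms, each = 2),
    arm = rep(c("p", "q"), 22),
    start = rep(c(1, 5e7 + 1), 22),
    end = rep(c(5e7, 1e8), 22)
  )

  # gene targets: round-robin over chromosomes, parked in the q arm well away
  # from the backbone sampling region
  g_chrom <- chroms[(seq_len(n_genes) - 1L) %% 22L + 1L]
  slot <- (seq_len(n_genes) - 1L) %/% 22L
  g_start <- as.integer(5.5e7 + slot * 1e5)
  targets <- tibble::tibble(
    chrom = g_chrom,
    start = g_start,
    end = g_start + as.integer(gene_bp) - 1L,
    gene = sprintf("GENE%02d", seq_len(n_genes))
  )

  # backbone SNPs: distributed over all 44 arms on an even grid with jitter,
  # p-arm region [5, 45] Mb, q-arm region [60, 95] Mb (disjoint from genes)
  backbone <- NULL
  if (n_backbone > 0) {
    n_arm <- rep(n_backbone %/% 44L, 44L)
    extra <- n_backbone %% 44L
    if (extra > 0) n_arm[seq_len(extra)] <- n_arm[seq_len(extra)] + 1L
    bb <- purrr::pmap_dfr(
      list(arms$chrom, arms$arm, n_arm),
      function(ch, arm, k) {
        if (k == 0) return(NULL)
        lo <- if (arm == "p") 5e6 else 6e7
        hi <- if (arm == "p") 4.5e7 else 9.5e7
        grid <- seq(lo, hi, length.out = k + 2L)[-c(1L, k + 2L)]
        pos <- as.integer(round(grid + runif(k, -1000, 1000)))
        tibble::tibble(chrom = ch, pos = pos, arm = arm)
      }
    )
    backbone <- bb |>
      dplyr::mutate(maf = backbone_maf) |>
      dplyr::arrange(match(.data$chrom, chroms), .data$pos)
  }

  windows <- dplyr::bind_rows(
    targets |> dplyr::select("chrom", "start", "end") |>
      dplyr::mutate(kind = "gene", name = targets$gene),
    if (!is.null(backbone)) {
      tibble::tibble(
        chrom = backbone$chrom,
        start = backbone$pos - as.integer(backbone_flank),
        end = backbone$pos + as.integer(backbone_flank),
        kind = "backbone",
        name = sprintf("SNP%04d", seq_len(nrow(backbone)))
      )
    }
  )
  widths <- windows$end - windows$start + 1L
  windows$seq <- vapply(
    widths,
    function(w) paste(sample(BASES, w, replace = TRUE), collapse = ""),
    character(1)
  )

  out <- list(
    targets = targets,
    backbone = backbone,
    windows = windows,
    arms = arms,
    chrom_lengths = chrom_lengths,
    backbone_flank = as.integer(backbone_flank),
    seed = as.integer(seed)
  )
  class(out) <- "cfdna_panel"
  if (!is.null(backbone)) {
    out$backbone$ref <- ref_base(out, backbone$chrom, backbone$pos)
    out$backbone$alt <- other_base(out$backbone$ref)
    out$backbone <- out$backbone |>
      dplyr::select("chrom", "pos", "ref", "alt", "maf", "arm")
  }
  out
}

#' @export
print.cfdna_panel <- function(x, ...) {
  cat("<cfdna_panel> ", nrow(x$targets), " gene targets (",
      sum(x$targets$end - x$targets$start + 1L), " bp), ",
      if (is.null(x$backbone)) 0L else nrow(x$backbone),
      " backbone SNPs\n", sep = "")
  invisible(x)
}

# locate the captured window containing each (chrom, pos); NA when untargeted
window_index <- function(panel, chrom, pos) {
  chrom <- rep_len(chrom, length(pos))
  w <- panel$windows
  idx <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    wi <- which(w$chrom == ch)
    if (!length(wi)) next
    o <- wi[order(w$start[wi])]
    at <- which(chrom == ch)
    j <- findInterval(pos[at], w$start[o])
    ok <- j >= 1L & pos[at] <= w$end[o[pmax(j, 1L)]]
    idx[at[ok]] <- o[j[ok]]
  }
  idx
}

#' Reference base lookup on a synthetic panel
#'
#' @param panel A [sim_panel()] object.
#' @param chrom,pos Parallel vectors of 1-based positions.
#' @return Character vector of reference bases (`NA` outside targeted windows).
#' @export
ref_base <- function(panel, chrom, pos) {
  idx <- window_index(panel, chrom, pos)
  out <- rep(NA_character_, length(pos))
  ok <- !is.na(idx)
  if (any(ok)) {
    off <- pos[ok] - panel$windows$start[idx[ok]] + 1L
    out[ok] <- stringr::str_sub(panel$windows$seq[idx[ok]], off, off)
  }
  out
}

#' Total targeted footprint of a panel in bp
#'
#' Used as the default number of hypotheses for Bonferroni correction during
#' somatic variant discovery.
#' @param panel A [sim_panel()] object.
#' @return Integer number of targeted bases.
#' @export
panel_size_bp <- function(panel) {
  sum(panel$windows$end - panel$windows$start + 1L)
}
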