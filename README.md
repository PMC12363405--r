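# plasmamrd

Circulating tumour DNA (ctDNA) analysis for aggressive B-cell lymphoma at
desk scale: error-corrected variant detection from UMI-tagged reads, ctDNA
burden quantification, early-molecular-response (EMR) and
measurable-residual-disease (MRD) classification, copy-number and
loss-of-heterozygosity analysis over a genome-wide SNP backbone with
genotype-based sample-identity QC, and the survival statistics that link
molecular response to clinical outcome. A synthetic cfDNA generator with
full ground-truth bookkeeping drives validation of every stage.

The package is written for analysts building or evaluating tumour-informed
liquid-biopsy MRD assays: every user-facing function takes a data frame and
returns a tibble, fitted objects have `tidy()`/`glance()` methods, and
result types plot with `autoplot()`.

## The model in brief

**Error correction.** Reads sharing (chromosome, 5′ position, strand, UMI)
form a family descended from one cfDNA molecule. Families with ≥ 3 members
are collapsed by per-position plurality vote (winning fraction ≥ 2/3, else
`N`), giving one consensus molecule per source fragment. The residual
background rate is estimated by pooling, over the bases flanking each
backbone SNP, the most frequent alternative consensus call:

    rate = Σ alt molecules / Σ informative molecules   (floored at 0.5/Σ when 0)

**Variant detection.** At each candidate site with ≥ 2 alt molecules, the
one-sided exact binomial tail P(X ≥ alt | n = informative, p = rate) is
Bonferroni-corrected over the targeted footprint; surviving sites are
subtracted against the buccal (normal) genotype (germline if buccal
VAF ≥ 0.20). Two somatic variants ≤ 100 bp apart observed on the same
consensus molecule form a *phased pair* — joint errors are quadratically
unlikely, which sharpens MRD detection.

**Burden and response.** Plasma cfDNA mass converts to haploid genome
equivalents at 3.3 pg/hGE and scales by the mean reporter VAF:

    hGE/mL = (cfDNA ng/mL × 1000 / 3.3) × mean VAF

EMR is a ≥ 2 log₁₀ burden reduction between baseline and the early
(cycle 1) draw, boundary inclusive, with undetected samples imputed at a
1 hGE/mL floor. MRD is positive when the aggregate binomial test over all
reporters fires with ≥ 2 positive reporters, or when ≥ 1 consensus molecule
carries both members of a tracked phased pair.

**Copy number and identity.** Backbone depths, library-size normalised and
divided by a ≥ 3-sample panel of normals, give per-locus log₂ ratios; arms
are called gain/loss at |median| ≥ 0.3 plus a sign test, and LOH flags mean
|BAF − 0.5| ≥ 0.15 at germline-het loci. Genotype concordance across
samples (hom-ref/het/hom-alt by VAF bins) detects mislabelled specimens:
unrelated individuals concord at ≈ 0.375 under Hardy–Weinberg, far below
the 0.80 flag threshold.

**Outcomes.** Kaplan–Meier product-limit curves, the log-rank test, the
Mantel–Haenszel hazard ratio, reverse-censor median follow-up, the exact
Fisher 2×2 test and Pearson correlation are implemented from first
principles and cross-checked against independent references in the test
suite.

## Worked example

Simulate a baseline plasma sample with three somatic reporters (two in
cis), collapse UMI families, estimate the background, call variants and
quantify burden:

```r
library(plasmamrd)
library(dplyr)

panel  <- sim_panel(n_genes = 4, gene_bp = 800, n_backbone = 40, seed = 7)
config <- sim_config(panel, seed = 42, n_molecules = 4000,
                     per_base_error = 0.003, fragment_max = 300)
reporters <- tibble(
  chrom = panel$targets$chrom[1],
  pos   = panel$targets$start[1] + c(150L, 210L, 500L),
  vaf   = c(0.20, 0.20, 0.10),
  phase_group = c(1L, 1L, NA))
reporters$alt <- vapply(ref_base(panel, reporters$chrom, reporters$pos),
                        \(r) setdiff(c("A","C","G","T"), r)[1], "")
truth    <- truth_set(variants = reporters,
                      germline = hwe_genotypes(panel, seed = 3) |>
                        select(chrom, pos, genotype))
baseline <- simulate_sample(config, truth, tumour_fraction = 1)

cons <- collapse_families(group_umi_families(baseline$reads),
                          baseline$deviations, panel)
cons
#> <consensus_set> 2596 consensus molecules (min family 3), 690 non-reference calls, 15 masked positions

flanks <- tibble(chrom = rep(panel$backbone$chrom, 2),
                 pos   = c(panel$backbone$pos - 1L, panel$backbone$pos + 1L))
bg <- estimate_background_error(cons, flanks, panel, germline = truth$germline)
bg
#> <error_model> pooled background 0.000166 (0 alt / 3019 molecules over 80 sites; floored)
```

With no alternative call at 80 variant-free flanking sites, the background
is floored at 0.5/3019 ≈ 1.7 × 10⁻⁴ per molecule — the raw 0.3% per-base
error has been suppressed well over an order of magnitude. Somatic calling
then recovers the planted reporters (the third, at VAF 0.10 under ~40×
consensus depth, drops below the 2-molecule floor in this shallow run —
depth, not the test, is limiting):

```r
# buccal (normal) evidence: the germline genotypes imply the expected
# normal VAF for every candidate site and allele
pileup <- build_pileup(cons, panel)
buccal <- tidyr::crossing(distinct(pileup, chrom, pos),
                          alt = c("A", "C", "G", "T")) |>
  left_join(truth$germline |>
              inner_join(panel$backbone |> select(chrom, pos, g_alt = alt),
                         by = c("chrom", "pos")),
            by = c("chrom", "pos")) |>
  mutate(vaf = ifelse(!is.na(genotype) & alt == g_alt, genotype / 2, 0)) |>
  select(chrom, pos, alt, vaf)

somatic <- call_somatic(pileup, buccal, bg,
                        n_tests = panel_size_bp(panel)) |>
  filter(status == "somatic")
somatic
#> # A tibble: 2 × 10
#>   chrom      pos ref   alt   alt_count informative   vaf  p_value p_adjusted
#> 1 chr1  55000150 C     A             6          37 0.162 4.78e-17   9.19e-13
#> 2 chr1  55000210 A     C             7          39 0.179 5.23e-20   1.01e-15

detect_phased_pairs(cons, somatic)
#> # A tibble: 1 × 8
#>   chrom    pos_a alt_a    pos_b alt_b distance n_both_alt n_covering
#> 1 chr1  55000150 A     55000210 C           60          5         28

tracked <- genotype_tracked(build_pileup(cons, panel, positions = somatic),
                            somatic)
quantify_burden(mean(tracked$vaf), cfdna_ng_per_ml = 23.1)
#> [1] 1195.773   # hGE/mL
```

The headline contingency of the outcome layer — 8/8 EMR patients in
complete metabolic response versus 1/8 evaluable non-EMR patients:

```r
fisher_exact_2x2(matrix(c(8, 1, 0, 7), 2))
#> <fisher_exact> two-sided p = 0.001399, odds ratio = Inf
```

`make_fixtures()` writes a complete miniature study (panel bundle, SAM
reads for 4 patients × 4 timepoints, germline VCF, dilution sample, CNV
profiles, 17-patient cohort CSV and a `config.yaml`), and
`run_pipeline()` executes every stage end-to-end from those files.

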