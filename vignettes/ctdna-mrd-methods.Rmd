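---
title: "Methods: error-corrected ctDNA quantification, molecular response and MRD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: error-corrected ctDNA quantification, molecular response and MRD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmamrd)
```

# The problem

In aggressive B-cell lymphoma, short tumour-derived DNA fragments circulate
in plasma (ctDNA) alongside a much larger background of normal cell-free
DNA. Deep targeted sequencing of that plasma can profile the tumour's
somatic mutations without a biopsy, quantify disease burden, and — sampled
longitudinally — detect treatment failure within the first therapy cycle
(early molecular response, EMR) or measurable residual disease (MRD) in
clinical remission. The limiting factor is the sequencing error rate: a
relapse signal at a variant allele fraction (VAF) of 0.1–0.001% sits far
below the ~0.1–1% raw substitution error of the instrument. This package
implements the full analysis chain that makes such measurements
interpretable, together with a ground-truth simulator used to validate
every stage.

# Error correction by UMI consensus

Each source cfDNA molecule is tagged before amplification with a 10-nt
unique molecular identifier (UMI). Reads sharing the key
*(chromosome, unclipped 5′ position, strand, UMI)* form a family descended
from one molecule ([group_umi_families()]). Two conventions are supported
for carrying the UMI — the SAM `RX` tag and the final `:`-separated field
of the read name — because both occur in practice.

`collapse_families()` discards families with fewer than `min_family = 3`
members and takes, at every position, the plurality base among covering
members; the winner is emitted only when its fraction reaches
`majority_frac = 2/3`, otherwise the position is masked to `N`. Ties
involving the reference resolve to the reference (and in any case a tie
cannot reach the 2/3 threshold), so the scheme never fabricates a base:
positions with ambiguous evidence are masked rather than called. Each
surviving consensus molecule counts once downstream regardless of its
family size, which is what makes molecule counts interpretable as unique
genome equivalents. For a family of three, a consensus error requires two
members to carry the *same* substitute base, so the residual rate scales
roughly as the square of the per-base error divided by three — 0.3% raw
error drops to the 10⁻⁶–10⁻⁵ range, consistent with what the test suite
measures.

The UMI merge tolerance defaults to 0 (exact); with `umi_tolerance = 1`,
UMIs at one position within Hamming distance 1 merge directionally (the
smaller family is absorbed when its size is at most half the larger plus
one). Exact matching is the default because the simulator's UMIs are
error-free unless the user models UMI errors explicitly.

## The background error model

Because the residual consensus error is assay- and batch-specific, it is
estimated from the data: at the bases immediately 5′ and 3′ of each
backbone SNP (sites expected to be variant-free; sites carrying a germline
variant in any contributing individual are excluded), the most frequent
alternative consensus call is counted and pooled:

$$\hat p = \frac{\sum_\text{sites}\text{alt molecules}}{\sum_\text{sites}\text{informative molecules}},$$

floored at $0.5/\sum$ when no alternative molecule is seen so that
downstream binomial tests remain defined. Pooling is the default because
per-site depths rarely support stable per-site rates; the per-site table is
returned for inspection.

# Variant detection and phasing

Somatic discovery (`call_somatic()`) tests each candidate site (≥ 2 alt
molecules) with the one-sided exact binomial tail
$P(X \ge \text{alt} \mid n = \text{informative}, p = \hat p)$ and a
Bonferroni correction over the targeted footprint (~148 kb at the default
panel scale). Discovery is deliberately conservative; longitudinal
monitoring of known reporters (`genotype_tracked()`) is threshold-free, as
is standard for tumour-informed MRD designs. Tumour/normal subtraction
uses the buccal genotype: buccal VAF ≥ 0.20 flags a call germline, and a
significant call without buccal coverage is retained but flagged
`germline-unevaluable`. An uncovered tracked site reports a *missing* VAF,
distinct from an observed zero.

Two somatic variants no more than 100 bp apart (1-based positions,
inclusive) that appear on the *same* consensus molecule form a phased pair
(`detect_phased_pairs()`). Since independent consensus errors at two sites
co-occur on one molecule with probability on the order of $\hat p^2$, a
single double-mutant molecule is strong evidence of tumour DNA — this is
the mechanism by which phased variants buy sensitivity below the
single-site limit of detection.

# Burden, EMR and MRD

Burden conversion follows the convention of the deep-sequencing
liquid-biopsy literature: one haploid genome equivalent (hGE) weighs
~3.3 pg, so

$$\text{hGE/mL} = \frac{\text{cfDNA ng/mL} \times 1000}{3.3}\times \overline{\text{VAF}},$$

with the mean taken over tracked reporters with non-missing genotyping.
Published hGE/mL values rarely come with an explicit formula; this
CAPP-Seq-style definition is the package's single most material
convention, and both the constant and the mean-vs-median choice are
exposed as arguments. Mean (not median) VAF is used to match that
literature.

EMR (`classify_emr()`) is a reduction of ≥ 2 log₁₀ between baseline and
the early cycle-1 draw, boundary inclusive. An undetected early sample is
imputed at a fixed floor (default 1 hGE/mL) before the log change —
a reproducible absolute floor rather than a depth-dependent limit of
detection; a depth-dependent alternative can be had by passing
`0.5/informative × cfDNA hGE` as the floor. Early draws outside day 7–22
of cycle 1 only warn, since the draw day is a scheduling fact, not an
analysis parameter. A patient with an undetected baseline is unevaluable.

MRD (`call_mrd()`) is positive via either route:

* **(a) aggregate route** — the one-sided binomial test of summed alt over
  summed informative molecules across all reporters against the background
  rate at p ≤ 0.05, *and* at least two distinct reporters with ≥ 1 alt
  molecule. The two-reporter guard suppresses single-site artifacts that
  survive the aggregate test when one deep site dominates.
* **(b) phased route** — at least one consensus molecule (configurable)
  carrying both members of a tracked phased pair.

Route (b) operationalises the qualitative observation that phased variants
can be leveraged for sensitivity; no published algorithm was available to
copy, so the single-molecule threshold is an explicit design choice of
this package. Samples with fewer than 1000 informative molecules in total
(configurable) are unevaluable rather than negative. Reporters suspected
to derive from clonal haematopoiesis (e.g. a TP53 variant at stable high
VAF across all timepoints and present in the normal compartment) are
removed via an explicit `exclude` list; automated CHIP classification is
deliberately not attempted.

# The dilution (spike-in) analysis

`run_dilution_series()` emulates the two-individual admixture experiment
that establishes analytical sensitivity: DNA from individual B spiked into
A at known fractions, interrogated at SNP sites where B contributes the
minor allele. By default the discordant sites are hom-ref in A and hom-alt
in B, so the expected spiked VAF equals the mix fraction — with the
default design a 0.2% mix yields measured VAFs averaging ~0.2%, and about
10 alt molecules per site at 5000 consensus molecules of depth
(`b_het_fraction` makes a share of sites heterozygous in B instead, VAF =
mix/2). Detection at a site requires ≥ 2 alt molecules and a binomial tail
at or below α/n_sites against the pooled background estimated from the
2 × n_sites flanking bases, so a zero mix probes familywise false-positive
behaviour. The reported sensitivity threshold is the smallest fraction
with ≥ 95% mean site detection.

# Copy number, LOH and identity QC

Backbone depths are library-size normalised (per-sample median), divided
by the per-locus median of ≥ 3 CNV-neutral normal profiles, and logged:
a clonal one-copy loss at tumour fraction *tf* sits at
$\log_2(1 - tf/2)$, a one-copy gain at $\log_2(1 + tf/2)$. Segmentation is
arm-level — the assay's copy-number findings are arm/segment scale and a
1040-locus backbone gives ~20–25 loci per arm, too few for change-point
methods to add value — with a call requiring both |median log₂| ≥ 0.3
(customary targeted-panel thresholds) and a one-sample sign test at
p ≤ 0.05 across the arm's loci, and at least 5 usable loci. LOH is flagged
when the mean |BAF − 0.5| at germline-heterozygous loci reaches 0.15
(a clonal one-copy loss at tf = 0.5 gives minor-allele fraction 1/3,
deviation ≈ 0.167). Tumour fraction is not jointly estimated; the expected
log₂ formulas are exposed for validation only.

Identity QC bins each backbone locus at molecule depth ≥ 20 into
hom-ref (< 0.1), het (0.1–0.9) and hom-alt (> 0.9) calls and compares
samples over co-called loci. For unrelated individuals at MAF-0.5 SNPs the
Hardy–Weinberg expectation of agreement is
$0.25^2 + 0.5^2 + 0.25^2 + \ldots \approx 0.375$, so the mislabel flag at
concordance < 0.80 separates cleanly; fewer than 100 co-called loci is
unevaluable.

# Outcome statistics

The survival layer is implemented from first principles so that every
number is auditable: the product-limit estimator with events preceding
censorings at tied times (median = first time the curve reaches 0.5); the
log-rank test with hypergeometric variance on 1 df (p = 1 with a warning
when there are no events); reverse-censor Kaplan–Meier for median
potential follow-up; the exact Fisher 2×2 test by hypergeometric
enumeration with the "probability ≤ observed" two-sided rule (which
reproduces p = 0.0014 for the 8/8-vs-1/8 response table); and Pearson
correlation.

For the hazard ratio two estimators are provided. The default is the
classical Mantel–Haenszel stratified rate ratio over the 2×2 table at each
event time, $\sum d_A n_B/n \,/\, \sum d_B n_A/n$, which is consistent
under proportional hazards even for strong effects (a simulated true ratio
of 0.1 at n = 2000 is recovered to within a few percent). The
observed/expected ratio $(O_A/E_A)/(O_B/E_B)$ — common in clinical
software output — is available as `method = "oe"`; it agrees near 1 but is
attenuated toward 1 for extreme ratios (measured ~0.18–0.24 at a true
0.1), which is why it is not the default. Confidence intervals use the
log-scale approximation SE = √(1/E_A + 1/E_B). `stratify_and_report()`
assembles the response contingency (patients without an evaluable
end-of-treatment response are excluded, matching the convention that makes
1/8 the non-EMR complete-response rate), per-stratum fits, tests and
24-month survival estimates for the EMR, MRD, baseline-burden
(2.5 log₁₀ hGE/mL) and clinical-risk stratifiers.

# What the simulator emulates — and what it does not

`simulate_sample()` draws source molecules across the captured panel with
truncated-normal fragment lengths (mean 167 bp, sd 40, bounded to
[50, 400] — the canonical mononucleosomal cfDNA size), amplifies each into
a UMI family with shifted negative-binomial size (minimum 1; overdispersed
PCR duplication), plants germline alleles per genotype and somatic alleles
at VAF × tumour-fraction with phase-group members strictly in cis by
default, and flips each sequenced base independently at the configured
per-base error (default 0.3%). Reads are emitted pre-aligned with simple
all-match records: alignment is upstream of this package's scope, and
keeping the aligner out of the loop isolates the computations under test.
All randomness flows from a single seed with deterministic per-sample
substreams. Internally reads are stored as fragment coordinates plus
deviations from the panel reference; sequences are materialised only at
SAM boundaries, which is what lets the deep per-site simulations run on a
single CPU.

Deliberately not modelled: quality-score-dependent or context-dependent
error profiles, indels, duplex (double-strand) UMI chemistry, GC and
fragment-length capture bias, UMI collisions between distinct molecules at
one position beyond what random 10-mers imply. Passing tests therefore
demonstrate the correctness of the *computations* under a clean error
model, not the field performance of any particular chemistry; on real
data, context-specific artifact modes (e.g. oxidative damage) would add a
site-specific component the pooled background model only partially
absorbs.

The clinical simulator (`simulate_cohort()`) draws EMR status, log-normal
baseline burden calibrated to a median of ~531 hGE/mL with IQR ~280–2072,
exponential progression and death times with stratum hazards (defaults
0.0165 and 0.152 per month, implying a hazard ratio of ~0.11 and a no-EMR
median PFS of ~4.6 months) and administrative censoring at 50 months of
potential follow-up. It exists to give the outcome layer designed truth;
it does not model time-varying hazards or cure fractions.

# Problem sizes and numerical choices

The validation suite runs everything at desk scale, chosen so the full
suite completes comfortably on one CPU:

* spike-in: 101 discordant SNP sites × ~7800 molecules per site
  (≈ 5000 surviving consensus molecules at the default family-size model),
  10 replicates at a 0.2% mix;
* error suppression: 50 sites × 3000 molecules at 0.3% per-base error;
* parameter recovery: 100 replicates at ~500 consensus molecules per
  reporter for VAFs 0.10/0.01/0.002 — a depth chosen from the exact
  Clopper–Pearson coverage computation so the pooled interval coverage is
  comfortably conservative; the deep-depth 0.2% detection property is
  exercised by the spike-in analysis instead;
* copy number: 440 backbone loci (10 per arm) at 1500× consensus depth;
* survival cross-checks: 50 random datasets (n ≤ 100) against the
  reference implementation at 10⁻⁶, exhaustive Fisher agreement for all
  2×2 margins up to N = 30, and 500 null replicates (n = 200) for the
  log-rank size;
* the bundled end-to-end fixture: 4 patients × 4 timepoints at 4000
  molecules per sample, with its `config.yaml` relaxing the
  depth-dependent floors (MRD evaluability, identity-QC depth and locus
  counts, CNV locus minimum) to match that shallowness.

Degenerate inputs are handled explicitly rather than by convention:
zero-coverage tracked sites are missing, not zero; an all-reference vote
below the majority threshold masks to `N`; a Fisher table with a
degenerate margin has p = 1; a zero-event log-rank warns and returns
p = 1; a zero-event group degrades the hazard ratio to a one-sided
interval with a warning; the background rate is floored so binomial tails
are always defined.

# Known limitations

* SNVs only — indels and structural variants are out of scope, which keeps
  the pileup model exact but means the reporter set on real data would be
  a subset of what a full caller provides.
* Single-strand consensus only; duplex designs would lower the background
  further than modelled here.
* The hGE/mL formula and the phased-MRD threshold are declared
  conventions, not reproductions of an undisclosed implementation;
  sensitivity to both is exposed through arguments.
* Arm-level copy-number calling cannot see focal events smaller than an
  arm's locus spacing.
* The identity-QC Hardy–Weinberg expectation assumes the design's
  common-SNP backbone; a backbone with low-MAF sites would raise the
  unrelated-concordance baseline toward the mislabel threshold.
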