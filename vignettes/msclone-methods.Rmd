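---
title: "Genomic relatedness of multiple synchronous tumours: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic relatedness of multiple synchronous tumours: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When a patient presents with two or three synchronous lung tumours, the
clinical stakes hinge on whether they are independent primary tumours
(potentially curable by resection) or a primary with intrapulmonary
metastases (systemic disease). Clinical criteria classify such cases by
anatomy; `msclone` implements the genomic route: tumours that arose
independently from different progenitor cells accumulate essentially
disjoint somatic mutations, whereas a metastasis retains the truncal
mutations of its founder. The package takes per-tumour somatic call sets,
copy-number segment tables and a reference sequence, and produces a
per-patient verdict with the supporting evidence.

```{r, eval = FALSE}
library(msclone)
reports <- run_pipeline(run_config(sim = sim_config(seed = 1),
                                   out_dir = "msclone_out"))
```

## Somatic variant filtering

Call sets are assumed to come from a paired tumour/normal pipeline with the
caller's built-in filters already applied; `msclone` applies the published
post-caller rule sets on top, exactly as printed, including which
comparisons are strict:

* VarScan-side SNVs: normal depth ≥ 10, tumour depth ≥ 4, tumour VAF ≥ 10%,
  somatic p < 10⁻⁴ (strict).
* MuTect-side SNVs: tumour depth ≥ 15, normal depth ≥ 6, variant on both
  strands, tumour VAF ≥ 10%, normal VAF exactly 0, position absent from the
  dbSNP panel.
* Indels: depth > 5 in both samples, per-allele mismatch rate < 0.5,
  per-allele mapping quality > 20, median offset from read ends > 5 bp.
* Structural variants: ≥ 5 clipped reads spanning the breakpoint pair and
  ≥ 1 clipped read at each end.

Strand support and dbSNP membership are boolean fields on the input record:
the package consumes call tables, not alignments, so these facts must be
computed upstream. "Coverage" in the VarScan rule is read as total depth at
the site. Filters are pure subset operations — records pass unchanged, in
order — which is what makes the brute-force oracle tests in
`tests/testthat/` exact.

SNV lists from the two callers are combined by mutation identity
(contig, position, ref, alt) in three modes: `union` (the default analysis
set), `intersection`, and `expanded_confident` (all validated mutations
plus everything called by both callers).

## Shared-mutation clonality

Two tumours *share* a mutation when they carry the identical substitution
at the same coordinate. `classify_pair()` applies a decision rule that
mirrors the case-by-case reasoning used in practice:

1. Recurrent hotspot mutations (e.g. EGFR p.L858R, which can be acquired
   independently by unrelated tumours under convergent selection) are
   excluded first.
2. No remaining shared mutation → `independent`.
3. At least `min_shared` (default 2) shared non-hotspot mutations *and* a
   shared fraction ≥ `min_fraction` (default 0.05) → `clonally_related`.
4. Exactly one shared non-hotspot mutation: its weight is judged by a
   two-sided Fisher test of the series' sharing rate against a reference
   cohort of unrelated tumours (default 20 shared of 8,413 exonic
   mutations). Non-significant sharing (p ≥ `alpha`, default 0.05) →
   `independent`; otherwise `indeterminate`.

The thresholds are operating defaults of this package, not published
constants; they are config-exposed and every branch taken is recorded in
the `evidence` notes of the verdict. The shared fraction inside
`classify_pair()` is computed against the *smaller* of the two totals so
that the verdict is invariant under swapping the arguments;
`shared_fraction()` itself defaults to the first argument's total (the
putative primary), with all four denominators available.

Two cohort-comparison tests are provided with the published counts as
defaults: `hotspot_prevalence_test()` (series hotspot prevalence vs a
large external cohort) and `shared_mutation_rate_test()` (series pairwise
sharing rate vs unrelated-tumour sharing). All 2×2 tests use the two-sided
minimum-likelihood Fisher rule, delegated to `stats::fisher.test()` and
checked in the test suite against exhaustive hypergeometric enumeration.

## Mutation spectra and APOBEC enrichment

Substitutions are normalised onto the pyrimidine strand into the six
classes C>A, C>G, C>T, T>A, T>C, T>G; 96-class trinucleotide spectra add
the flanking bases (reverse-complemented together with purine references).
Spectrum differences between tumours are tested on the 2×6 table with an
exact test (network algorithm up to a table total of 200, Monte-Carlo with
a fixed seed above), and spectrum similarity with Pearson correlation of
the class fractions.

APOBEC cytidine deaminases preferentially mutate cytosine in TpCpW
(W ∈ {A, T}); on the opposite strand this reads WpGpA. Enrichment is

E = (mutations_TCW / mutations_CorG) / (context_TCW / context_CorG)

where `mutations_TCW` counts mutated C/G in motif restricted to the
APOBEC-type substitutions (C>T, C>G and their strand images),
`mutations_CorG` counts *all* mutated C/G (any substitution — the
asymmetry is deliberate and follows the published definition), and the two
context counts accumulate motifs and C/G bases over the 41-nucleotide
window centred on every mutated C/G. E = 1 under motif-blind targeting;
significance comes from a two-sided Fisher test of the in/out-of-motif
split of mutations against that of context sites.

Two numerical choices matter here:

* **Motif membership at window edges.** A motif whose central C/G lies in
  the window counts even when its single-base flank falls just outside;
  membership is evaluated against the full reference, not the window
  substring. Counting on the truncated substring silently discards 2 of 41
  motif positions per window and biases E upward by roughly 10% under
  uniform targeting.
* **Residual centre bias.** The two bases adjacent to a window's central
  C/G can never themselves be motif centres (their flank is a C or G, not
  T/W/A), which depresses the context ratio slightly; under uniform
  targeting E is therefore biased upward by about 5% with the default
  simulation GC of 0.40. This is a structural property of the windowed
  estimator, shared with the published method; the calibration tests
  account for it by using large mutation counts (10,000) so that
  Monte-Carlo spread does not add to the structural offset.

Windows are truncated at contig ends (the truncation count is reported),
and overlapping windows of nearby mutations accumulate independently.

## Copy-number correlation clonality

Segment-level log2 ratios are consumed directly (probe-level processing
and segmentation are upstream concerns). Gains are segments with
log2 > 0.3, losses < −0.3, both strict. For relatedness, all samples'
segments are partitioned at the union of their breakpoints
(`IRanges::disjoin`), giving a region-by-sample matrix in which every
sample is constant within each region; uncovered cells are masked and
excluded pairwise from correlations rather than zero-filled, which would
inflate similarity.

The published likelihood-ratio construction against a background
distribution is not fully specified, so `msclone` implements an empirical
exceedance test: the background is the distribution of all inter-patient
pair correlations, and an intra-patient pair is flagged CN-related when
its correlation strictly exceeds a configurable background percentile
(default 95th). Intra-patient pairs are excluded from the background. A
percentile of 1.0 is treated as vacuous (nothing is flagged), and a
degenerate background (no spread) is reported as such rather than used.
Correlations are unweighted by default; region-length weighting is
available.

Recurrent-region annotation merges adjacent same-call segments first, then
labels a segment with a recurrent amplified/lost region when the overlap
covers at least 50% (inclusive) of the region's length and the direction
matches.

## The synthetic cohort generator

Every statistical claim in the test suite is made against cohorts with
known ground truth from `simulate_cohort()`. The generator emulates:

* patients with 2–3 tumours, each either all-independent or containing one
  founder/metastasis pair; truncal mutations are chosen per founder
  mutation with probability `trunk_fraction` (default 0.26, matching the
  one observed metastatic pair: 52 of 198 mutations shared) and copied
  identically into the metastasis, which is topped up with private
  mutations so every tumour carries exactly `n_mutations` SNVs;
* smoking-status spectra: C>A-dominated weights for former smokers,
  C>T-dominated for never smokers;
* an APOBEC process targeting TCW sites. `apobec_intensity` is defined as
  the *target fold-enrichment*: the per-site sampling weight is solved
  from the reference's motif fraction f as w = i(1−f)/(1−if), which
  reduces to uniform placement at i = 1. A plain per-site rate multiplier
  would saturate (E = i/(1+(i−1)f) ≈ 2.2 at i = 3 for f ≈ 0.18) and could
  never recover the requested enrichment;
* designated hotspot sites (deterministic positions on the reference,
  a T>G transversion analogous to EGFR p.L858R) acquired independently by
  each tumour with probability `hotspot_rate` — reproducing the scenario
  of unrelated tumours sharing only a hotspot;
* sequencing evidence spanning the filter boundaries: Poisson depths
  (mean 60, the exome-like default), Beta(6, 14) tumour VAFs, occasional
  contaminated-normal VAFs, strand failures, dbSNP flags and a log-uniform
  somatic p-value, so that roughly 4% of true records fail the combined
  filters;
* copy-number profiles as 200 equal bins with Gaussian segment noise
  (sd 0.1) and gain/loss events of ±0.8 log2 units over runs of bins; a
  metastasis inherits `share_fraction` (default 0.8) of its founder's
  events;
* two shared deletions between founder and metastasis among otherwise
  private structural variants.

Mutation sites never collide between tumours of the same patient except
through truncal copying or hotspot acquisition, so the zero-sharing null
is exact within a patient. Patients use seed + patient index as their RNG
stream, making each patient independently reproducible. Across patients,
site collisions are possible — as in real cohorts, where unrelated tumours
occasionally share an exonic mutation.

What the generator does *not* model: read-level data (no FASTQ/BAM, no
sequencing-error process), subclonal structure beyond the single
trunk/private split, indel/SV sharing beyond the fixed deletion copies, a
realistic genome (a single i.i.d. contig, default GC 0.40), mutation-rate
heterogeneity along the genome, and germline variation. Passing the
recovery tests therefore demonstrates that the inference logic is correct
under its stated model, not that the thresholds are optimal on real
tumours.

## Problem sizes and reproducibility

The bundled tests and the acceptance script use deliberately modest sizes
chosen to make the statistical bounds sharp: a 500 kb reference with
10,000 mutations per tumour for enrichment calibration (100 seeds), 200
simulated tumour pairs at the hardest configured corner (trunk fraction
0.15, 60 mutations) for classification recovery, 50 four-patient cohorts
for copy-number recovery, and exhaustive Fisher enumeration up to table
total 40. All randomness flows through explicit seeds; rerunning any
pipeline configuration reproduces byte-identical reports.

## Known limitations

* The verdict thresholds (`min_shared`, `min_fraction`, `alpha`) are
  policy, calibrated only in the sense that they comfortably separate the
  simulated regimes; real cohorts with low purity or shallow coverage may
  need different settings.
* E_TCW inherits the ~5% structural upward bias of the windowed context
  estimator described above.
* The CN background test needs at least two patients and benefits from
  many; with few inter-patient pairs the empirical percentile is coarse.
* Hotspot handling is list-based; an incomplete hotspot list shifts
  single-shared-mutation pairs toward `indeterminate` rather than
  `independent`.
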