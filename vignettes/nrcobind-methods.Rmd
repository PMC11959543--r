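---
title: "Models and methods behind nrcobind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nrcobind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nrcobind` analyses two transcription-factor cistromes measured by
replicated ChIP-seq in the same cell state, together with a
four-condition RNA-seq design, coactivator (MED1) occupancy, ATAC
accessibility, and direct/inverted-repeat response-element models. This
vignette records the statistical models, the tunable parameters, the
synthetic-data generator, and the design choices made where the design
was genuinely open. It states no empirical result that the package's
tests or acceptance script do not themselves compute.

## Coordinates and containers

All intervals are 0-based, half-open (BED convention); GTF input
(1-based, inclusive) is converted on read. Overlap always means at least
one shared base; adjacent intervals do not overlap. The interval algebra
is backed by IRanges behind the `region_set` contract, and all overlap
and merge operations are property-tested against an independent O(n²)
brute-force oracle.

## Consensus peaks

Summits are extended ±`flank` (default 100 bp, so binding regions are
uniformly 200 bp). Within one dataset, summits closer than `min_dist`
(default 200 bp) are merged; the new summit is the center of the two
summits, rounded down, and the merge is applied iteratively left to right
per chromosome until no pair violates the rule — the published procedure
states only the pairwise rule, so the chain order had to be fixed; after
sorting, left-to-right is deterministic and order-independent. Merging is
performed within each dataset before the cross-replicate comparison (the
methods text orders the steps this way; the alternative order was not
described).

A region is a two-replicate consensus peak if its extended summit region
overlaps the other replicate's summit regions, or — fallback — the other
replicate's narrowPeaks (peak callers sometimes detect a region without
resolving a summit in one replicate). For k-replicate sets, a merged
envelope is kept when supported by at least `min_overlap` replicate sets
(2 of 3 for MED1; 3 for the pooled 12-sample set).

Occupancy is normalized by dividing each sample's per-region RPKM by that
sample's 90th percentile over all regions. The quantile uses linear
interpolation between order statistics (R type 7); the source procedure
does not name a quantile method, so the choice is recorded in the output
(`p90` per sample). Normalization is invariant to per-sample
multiplicative scaling, which the tests assert.

## Cistrome classification

The two consensus sets are compared symmetrically: regions of either set
overlapping the other are pooled and merged into common envelopes (which
can exceed 200 bp); the remainders are exclusive. Common envelopes are
classified by the ratio r of replicate-mean normalized A signal to B
signal: r > 1.5 A-dominant, r < 0.66 B-dominant, otherwise similarly
occupied. Two boundary decisions are deliberate and documented because
they change counts: (i) ratios exactly equal to a cutoff fall in the
middle cluster (closed middle interval); (ii) the cutoffs are taken
verbatim as 1.5 and 0.66 rather than forced symmetric (1/1.5 ≈ 0.667).
Signal is quantified on the merged envelope, not on the original 200-bp
members, since the ranking that defines the clusters is over envelopes.
Zero-B regions with nonzero A get ratio +Inf (A-dominant); regions with
zero signal for both factors are excluded with a warning.

## Gene annotation and enrichment

Nearest-gene annotation measures the distance from the region center to
the TSS; the minimal absolute distance wins, ties go to the
lexicographically smaller gene id, and the sign is strand-aware (negative
= upstream). TSS-window membership (±25 kb) uses the region *center*, not
any-overlap: common envelopes are wider than exclusive regions, and a
center rule keeps each region's window count independent of its width —
the published rule is unstated, so this divergence risk is documented.
Observed/expected enrichment uses expected(cluster, set) = (window region
total) × (cluster size / all clustered regions); consequently the
count-weighted mean ratio per gene set is exactly 1, which the tests
assert.

## Differential expression and cooperative induction

The DE gate is sequential: (1) low-expression filter — mean normalized
count ≥ 1.0 in at least one condition (the source excluded "genes
expressed at low levels" without quantifying; the threshold is
configurable); (2) one-way ANOVA over the four conditions with BH
adjustment (padj < 0.05); (3) Tukey HSD per ligand-vs-vehicle contrast
(p < 0.05), computed from the ANOVA mean square with the studentized
range distribution; (4) fold change vs vehicle ≥ 1.5 up or ≤ 0.66 down,
with pseudocount 1. Counts are library-size normalized (per-sample
scaling to the mean library size); the original normalization lived
inside a commercial package and is unrecoverable, so a plain CPM-style
scaling was chosen — every label is invariant to global scaling.

Cooperative upregulation (per gene upregulated by at least one single
ligand): the more effective single ligand is the one with the larger
replicate-mean normalized expression (fold change would be equivalent
since vehicle is shared); a Welch t-test compares combined vs that
ligand's replicates, and the combined/single ratio must reach 1.5
(inclusive). The t-test is one-sided (greater): the tested hypothesis is
directional (an *increase* over the best single treatment), and the
one-sided form makes the conjunction "FC > 1 AND p ≤ 0.05" call an
α-level fraction under the null; a two-sided p with the FC gate would
call α/2. The protein-coding subset is flagged from GTF biotypes.

A subtlety worth recording: under a fully exchangeable null (A, D and
combined all equal), choosing the *maximum* of two noisy single-ligand
means makes the test conservative (well below α). The α-level statement
holds for the null the test actually targets — combined equal to an
unambiguous best single — and the null-calibration tests simulate exactly
that configuration.

## Differential occupancy

The replicate-aware differential test (the stand-in for DiffBind/edgeR)
is a t-test on log2(normalized count + 1) with BH correction across
regions, flagged at FDR ≤ 0.05. The default variant moderates the
per-region pooled variance by empirical Bayes (limma's `squeezeVar`),
adding the estimated prior degrees of freedom to the residual ones. This
deviation from a plain per-region Welch test is deliberate and was forced
by arithmetic: with 2–3 replicates per group a Welch test has 2–4 degrees
of freedom, its p-values are floored near 10⁻³, and BH at FDR ≤ 0.05 with
~10% affected regions can reject nothing — no effect size fixes that.
Borrowing strength across regions is exactly why the field's tools use
shared dispersion models. The plain Welch variant remains available
(`method = "welch"`), and the interface isolates the test so an NB-GLM
could be swapped in.

Cooperative MED1 recruitment follows the published rule verbatim: per
region of the pooled consensus, the more effective single treatment is
the larger replicate mean; cooperative ⇔ FC over it > 1 (any increase —
taken literally) and one-sided t-test p ≤ 0.05, uncorrected (the per
region tests were applied without multiplicity correction).

## Response elements

PWMs are column-stochastic 4×L matrices with half-site and spacer
annotations. DRk/IRk variants derive from a DR5 seed by copying the
half-sites, setting k spacer columns to uniform 0.25 (the minimal
assumption reading of "modifying the spacer bases" — spacer bases become
score-neutral), and, for IRs, reverse-complementing the *downstream*
half-site (flipping the upstream one gives the reverse-complement family
and identical two-strand scan results). Scoring is log2(p/0.25) against a
uniform background with per-cell pseudocount 0.008 before normalization;
N scores 0; both strands are scanned and ties resolve to the lowest
coordinate, plus strand first.

Thresholds are never copied from elsewhere; they are calibrated as the
smallest observed best score t such that the fraction of control regions
reaching t is at most the target rate (5%), ties resolved toward fewer
positives. Controls are n = 5000 random size-matched regions (resampled
sizes, uniform placement, >50% N rejected). Genome-wide mapping emits
every window at or above threshold, collapsing overlapping same-strand
hits to the best scorer so prevalence counts regions, not windows. The
middle base of even-length motifs is the lower-middle position
(start + ⌊(len−1)/2⌋). Motif-pair configurations classify the DR3 against
its nearest DR1/2/5 (by middle-base distance, ties to the higher score)
by shared bases: ≥7 largely, 1–6 partially, 0 non-overlapping.

The packaged seed matrix (`inst/extdata/dr5_halfsite_synthetic.motif`) is
a *synthetic* canonical AGGTCA-half-site DR5 model: the original study's
seed (a public database matrix refined by de novo discovery on its own
peaks) cannot be reconstructed offline, and the toolkit accepts any seed
PWM file. The threshold-calibration acceptance property does not depend
on the seed matrix.

## The synthetic study

The generator emulates the study design, not raw reads: no FASTQ,
fragment-length or mappability modeling. Its defaults are the stated
world of the validation suite:

* **Genome**: 4 chromosomes × 5 Mb, i.i.d. bases at GC 0.41. Sequence is
  only generated when motif planting is requested; all count and
  coordinate artifacts are sequence-free. The size keeps accidental
  overlap between random noise peaks and the other replicate's support
  near 3%, safely below the 5% rejection budget of the consensus
  property.
* **Binding sites**: 1500 regions split 14% A-only / 21% common / 65%
  B-only (the published category shares), the common set divided
  1343:1571:637 into A-dominant / similar / B-dominant. True A:B ratios
  are 2.5 / 1.0 / 0.4 with lognormal jitter (σ = 0.1) clamped inside the
  class interval; `ratio_jitter_sd = 0` plus `noiseless = TRUE` gives the
  exact-recovery world used by the dominance test. Counts are negative
  binomial (dispersion 0.05 — a typical replicate CV of ~22% for ChIP
  RPKM at strong peaks), with a 3× multiplicative ligand effect over
  vehicle. Summits jitter between replicates with σ = 10 bp; noise peaks
  (150 per factor and replicate) appear in exactly one replicate by
  construction; 20 true sites per factor carry only narrowPeak support in
  replicate 2, exercising the consensus fallback.
* **Expression**: 2000 genes, up-sets scaled from the published
  537/91/158 (150 A-only / 30 both / 50 D-only), 80 down, 40 cooperative
  (25 from the both-set, 15 single-only — cooperation without dual
  regulation occurs in the emulated data too). Baselines are lognormal
  (meanlog log 100, sdlog 0.8); single-ligand effect 3×; non-cooperative
  combined mean = max(single means) (additive-saturation); cooperative
  combined mean = 2.0 × max(single). RNA-seq dispersion is 0.01
  (per-replicate CV ≈ 10–12%), the clean end of cell-line triplicates:
  a closed-form Welch power calculation (n = 3 vs 3, one-sided α = 0.05,
  ratio 2.0) shows per-gene power ≈ 90% requires CV ≲ 0.12, and the
  validation contract demands ≥ 80% recall, so the stated world must be a
  clean experiment. These values were fixed a priori and not revisited.
* **MED1/ATAC**: MED1 baseline 50, responsive effect 2.5×, cooperative
  combined = 1.8 × best single; cooperative probability 0.3 at common vs
  0.05 at exclusive sites (producing the overrepresentation pattern).
  ATAC openness 0.85 (common) vs 0.5 (exclusive), open-site signal 30 vs
  15.
* **Determinism**: every artifact draws from its own substream (seed
  derived from the master seed and the artifact name), so adding an
  artifact never perturbs the others; identical seeds give bit-identical
  outputs.

What a green test establishes — and what it does not: the generator has
independent sites, symmetric NB noise, no GC or mappability bias, no
fragment-level structure, and planted effects of homogeneous size. Green
recovery tests therefore validate the *logic and calibration* of the
callers, not their performance on real immunoprecipitation data, whose
dispersions, batch structure and peak-shape artifacts are harsher.

## Numerical choices and degenerate inputs

Pseudocount 1 for all expression fold changes; ratio +Inf (not NaN) when
a single-ligand mean is zero in the cooperative caller, which still
requires the t-test to pass; P90 = 0 aborts normalization; empty clusters
produce warnings and NA rows rather than errors; narrowPeak summit
offset −1 imputes the region midpoint and flags it; chromosome-edge
truncation of extended summits warns. Seeds everywhere are plain R
integer seeds kept below 2³¹.

## Known limitations

Real RPKM computation from alignments is out of scope (tables are
inputs); the DE gate assumes homoscedastic ANOVA on normalized counts
rather than a count model; the PWM background is uniform (no dinucleotide
model); IR variants share the DR threshold-calibration machinery but
seed-PWM asymmetries are not re-estimated; and the pair workflow assumes
both cistromes come from the same assembly.
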