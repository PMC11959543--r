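# nrcobind

Downstream analysis of **two nuclear-receptor cistromes measured in the
same cells** — e.g. RARα (activated by a retinoid) and VDR (activated by
1,25-dihydroxyvitamin D₃) in differentiated monocytic cells. Many
regulatory regions are bound by both receptors; `nrcobind` quantifies that
overlap and asks whether the shared regions drive the convergence and
cooperation of the two signaling pathways.

The package is aimed at computational biologists who have replicate
ChIP-seq peak calls (summits + narrowPeaks), per-region count tables, a
four-condition RNA-seq experiment (vehicle / ligand A / ligand D /
combined, 3 replicates each), coactivator (MED1) ChIP-seq, and ATAC-seq
peak sets — and want a tested, deterministic reimplementation of the full
downstream workflow.

## What it computes

* **Consensus peaks** — summits extended ±100 bp; summits closer than
  200 bp merged at their center; a region is consensus if found in both
  replicates, or with a summit in one and a narrowPeak in the other;
  k-replicate sets use a `minOverlap` rule. Occupancy is normalized by
  each dataset's 90th-percentile RPKM.
* **Cistrome classification** — symmetric common/exclusive split
  (mergeBed semantics), then dominance clusters of the common regions by
  the normalized occupancy ratio *r* = A/B:
  A-dominant (*r* > 1.5), similarly occupied (0.66 ≤ *r* ≤ 1.5),
  B-dominant (*r* < 0.66); plus ATAC accessibility categories.
* **Gene annotation** — nearest-gene profiles, TSS ± 25 kb window
  membership, and observed/expected enrichment per (cluster, gene-set)
  cell, with expected = window total × cluster share.
* **Differential expression and cooperativity** — low-expression filter →
  one-way ANOVA + Benjamini–Hochberg → Tukey HSD per ligand-vs-vehicle
  contrast → 1.5 / 0.66 fold cutoffs; a gene is *cooperatively*
  upregulated when combined/(more effective single) ≥ 1.5 with a t-test
  p ≤ 0.05.
* **Differential occupancy & cooperative MED1 recruitment** —
  variance-moderated t-tests on log2 normalized counts (BH, FDR ≤ 0.05);
  a region recruits MED1 cooperatively when combined > best single with
  FC > 1 and p ≤ 0.05.
* **Response-element toolkit** — DRk/IRk position weight matrices derived
  from a DR5 seed (spacer replaced by uniform columns, one half-site
  reverse-complemented for IRs); log2-odds scanning of both strands;
  score thresholds calibrated to a 5% positive rate on 5 000 random
  size-matched control sequences; motif prevalence, DR1/2/5 × DR3
  co-occurrence, and overlap configurations of motif pairs
  (≥7 shared bases = largely overlapping, 1–6 partial, 0 none).
* **Synthetic studies** — a deterministic generator with known ground
  truth for every caller (see the methods vignette).

## Worked example

```r
library(nrcobind)

cfg   <- sim_config(seed = 11)          # 1500 regions, 2000 genes
study <- simulate_study(cfg)
cs    <- study$truth$chrom_sizes

cons <- lapply(c(A = "A", B = "B"), function(f) {
  reps <- lapply(study$chip$summits[[f]], function(s)
    merge_close_summits(extend_summits(s, 100, cs), 200, 100, cs))
  consensus_two_reps(reps[[1]], reps[[2]],
                     study$chip$narrow[[f]][[1]],
                     study$chip$narrow[[f]][[2]])
})
run_pair_analysis(cons$A, cons$B)$counts
#> $a_only   [1] 212
#> $common   [1] 315
#> $b_only   [1] 977
```

212 regions are bound only by factor A, 977 only by factor B, and 315 are
common envelopes — recovering the planted 210/315/975 category structure
(the two extra exclusive regions are surviving single-replicate noise
peaks). Calling the cooperative-gene workflow:

```r
norm  <- normalize_libsize(study$expr$counts)
calls <- de_gate(norm, study$expr$design)
coop  <- cooperative_caller(norm, study$expr$design, calls,
                            study$expr$biotypes)
sum(coop$cooperative)
#> [1] 37
```

37 of the 40 planted cooperative genes are recovered with no false
positives (recall 0.925 at these defaults).

## Command line

```sh
exec/nrcobind simulate --seed 9 --out study/ --small
exec/nrcobind consensus --rep1 study/A_rep1_summits.bed \
    --rep2 study/A_rep2_summits.bed --out consA.bed
exec/nrcobind pair --a consA.bed --b consB.bed --out pair.json
exec/nrcobind motif-derive --seed-motif inst/extdata/dr5_halfsite_synthetic.motif \
    --spacer 3 --out dr3.motif
```
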