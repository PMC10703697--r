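---
title: "Methods: scanning aberrant somatic hypermutation in paired lymphoma genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning aberrant somatic hypermutation in paired lymphoma genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ashmscan)
```

## The problem

Activation-induced cytidine deaminase (AID) normally mutates immunoglobulin
genes during affinity maturation, but it also strays to other loci —
aberrant somatic hypermutation (aSHM). In follicular lymphoma (FL) that
transforms into double-hit lymphoma (DHL), paired longitudinal genomes let
one separate mutations present at the indolent stage from those acquired
during transformation. `ashmscan` implements the analysis layer for such
cohorts: a post-filter cascade for somatic variant calls, regulatory
annotation (super-enhancers, histone-mark partitions, TADs, A/B
compartments), stage-differential enrichment statistics, enhancer-retargeting
(ER) candidate ranking, and the exact small-sample statistics these analyses
lean on. Because real paired lymphoma WGS is access-controlled, the package
ships a fully seeded synthetic-cohort generator whose planted effects act as
ground truth for every downstream stage.

## Variant post-filtering

Candidate calls (assumed to come from a paired empirical-Bayes caller) pass
through an ordered cascade; the first failing gate is recorded per rejected
variant, so `|kept| + |rejected| = |input|` always holds and ledgers are
reproducible:

1. caller posterior gate (`posterior_p < 1e-6`),
2. nontumor support (`>= 2` supporting reads in the matched normal rejects),
3. optional germline exclusion list and low-complexity mask (BED),
4. high-quality tumor support (`< 5` HQ reads rejects) and strand bias,
5. allele fraction (`< 20%` rejects; `< 10%` for declared low-purity samples),
6. nontumor depth (`< 15` rejects),
7. edge-of-read: rejected only when *every* supporting read places the
   variant within 25% of the read length from a read end.

Two gates are under-specified in the source methodology and are therefore
parameters with documented defaults. *Strand bias* uses the common
conservative heuristic: fail when at least 5 supporting reads exist and at
least 95% sit on one strand. *Filter order* follows the listed order above;
the data do not identify which gate "caused" a rejection when several would
fire, so first-failure attribution is a bookkeeping convention, chosen
because it makes ledgers stable and testable. Samples without a matched
normal skip gates 2 and 6 entirely.

## Regulatory annotation

All interval work uses BED conventions (0-based, half-open); a 1-based point
`p` overlaps `[s, e)` iff `s <= p - 1 < e`. The interval algebra is written
in-package and property-tested against per-base-pair brute-force oracles.

Super-enhancers are called ROSE-style from H3K27ac peaks: peaks fully inside
±2.5 kb of a TSS are removed (toggleable), peaks with gaps strictly below
12.5 kb are stitched, and stitched regions are ranked by aggregate signal.
Both axes are min–max rescaled to `[0, 1]` and the discrete tangent is
estimated by consecutive secants of width one rank; the cutoff is the signal
at the upper end of the first secant whose slope *exceeds* 1, and every
region at or above the cutoff is super. Consequences of the strict
inequality: a perfectly linear rank-signal curve (every secant slope exactly
1) flags nothing, and a single extreme outlier flags exactly itself. The
12.5 kb / 2.5 kb / slope-1 constants come from the original ROSE algorithm
(the methodology we follow names the method without restating parameters)
and are all configurable.

`partition_mark_regions()` splits H3K27ac and H3K4me3 into three disjoint
classes (enhancer-only, promoter-only, promoter-within-enhancer); the
classes conserve base pairs exactly, which is asserted as a property test.

## Enrichment statistics

**Anchored density profiles** (TSS, peak midpoints, TAD boundaries) bin each
sample's mutations by signed distance to the nearest anchor. The
normalization in the source figures is stated only as "normalized and
averaged over the cohort"; the default here divides each sample's in-window
counts by its total (a proportion vector), then averages within stage. This
removes per-sample load differences so FL and DHL *shapes* are comparable; a
mutations-per-Mb mode is available when absolute density matters. TSS
distances are strand-aware with upstream negative; TAD-boundary distances are
negative inside the TAD, and nested TADs are dropped so only outermost
boundaries anchor.

**Kataegis** is detected as maximal runs of at least 6 mutations with
consecutive intermutation distances at most 1 kb — the standard literature
definition, since none is given in the source. Both thresholds are
arguments.

**The 3-kb segment scan** tiles the genome, keeps segments with at least 5
pooled mutations, and tests each with a one-sided binomial: is the DHL count,
out of the segment total, larger than the genome-wide DHL proportion?
Benjamini–Hochberg controls the FDR at 5%. The test is unnamed in the source;
the binomial against the global proportion was chosen because it respects
unequal stage loads without per-segment contingency margins (a per-segment
Fisher mode is provided). In longitudinal cohorts DHL samples carry their
FL mutations forward, so when variants bear the generator's `acquired` flag,
the scan counts only transformation-acquired DHL mutations — this mirrors an
analysis of mutations "acquired upon transformation" and keeps the null
proportion interpretable.

## Enhancer-retargeting candidates

All unordered gene pairs whose TSSs share a TAD are scored on three lists:
mean expression of the higher-expressed member (descending), mean expression
of the lower-expressed member (descending), and the Spearman correlation
between the two. The aggregate follows the central-limit rank-aggregation
statistic: with mean rank `Rbar` over `m` lists of `n` items,

    z = (Rbar - (n + 1) / 2) / sqrt((n^2 - 1) / (12 m)),  p = pnorm(z).

Orientation choices the source leaves open: correlation ranks enter *signed*
with the most negative first (ER of a shared enhancer implies anticorrelated
promoters, as in the motivating PAX5/ZCCHC7 pair); the pair universe is
restricted to expressed genes (nonzero variance), because Spearman is
undefined on constants; and pairs are canonically oriented so gene A is the
higher-expressed member. A single scorable pair is degenerate (no ranking
information) and gets `p = 0.5` by convention. Hypermutation flags come from
significant segment-scan segments by default, or from a user BED; a pair is
flagged when either gene's promoter window (±2 kb) or body overlaps a locus.

## Cohort statistics

`fisher_exact_2x2()` enumerates the full hypergeometric support; the
two-sided p is the minimum-likelihood rule (sum of point probabilities not
exceeding the observed one), which reproduces the printed 0.0023 on the
cohort's reconstructed copy-gain table ([[0, 9], [6, 2]]).
`wilcoxon_signed_rank()` uses the exact sign-assignment distribution up to
n = 25 — computed by dynamic programming over doubled ranks, so average
ranks from ties are exact too — and a tie-corrected normal approximation
above; zero differences are discarded by default (classic Wilcoxon; Pratt is
available; the source does not state its choice). The per-protein two-way
ANOVA fits genotype × label with interaction via model-comparison sums of
squares (type II, identical to the classical balanced decomposition for the
balanced 3+3 design; unbalanced input warns). Proteins with zero variance
everywhere get p = 1 by the zero-SS convention. The proteome shift analysis
selects proteins at FDR-adjusted genotype p < 0.01, signs them by the
difference of (ALT, OPP+) and (WT, OPP+) cell means — OPP+ carries the
nascent-proteome signal — and tests tumor-suppressor association with
downregulation by two-sided Fisher.

## The synthetic world

The generator states one fixed world; its defaults are not tuning knobs.

* **Genome**: one 10 Mb chromosome, 60 non-overlapping genes with simple
  UTR/exon structure, 500 kb TADs with 20 kb gaps, alternating 1 Mb A/B
  compartments. 20% of genes are "SE genes": their promoters carry a wide
  (4 kb) H3K4me3 peak embedded in a high-signal H3K27ac cluster, so the
  K4me3 ∩ K27ac intersection defines the aSHM footprints.
* **Mutation rates** are piecewise constant. Background is 10 mutations/Mb
  per sample; aSHM footprints are hypermutated at 300/Mb in *both* stages —
  aSHM demonstrably operates already at the FL stage — and the DHL-acquired
  footprint rate is multiplied by the enrichment fold (default 10). The
  10 Mb toy genome stands in for the regulatory-dense fraction of a genome,
  so ~100 background mutations per FL sample is the right order for an FL
  regulatory compartment. These values were fixed a priori by a power
  argument: with 8 patients and a 3-kb scan, a detectable footprint needs
  roughly 15–20 pooled DHL-acquired mutations against ~2 FL mutations, which
  the fold-10 world provides while the fold-1 world leaves hotspot segments
  exactly exchangeable between stages (so they qualify for testing but stay
  null — making the calibration test informative rather than vacuous).
* **DHL superset structure**: each DHL sample carries all of its patient's
  FL variants (re-sequenced at the DHL allele-fraction model) plus acquired
  ones, flagged `acquired`.
* **Kataegis**: 2 clusters of 8 mutations with gaps ≤ 500 bp are planted per
  DHL sample (DHL-only by default — the source shows DHL-specific clusters
  and gives no FL quantification, so FL clustering is a configuration, not a
  default). A *null* cohort for scan calibration must therefore also set
  `n_clusters = 0`: planted DHL-only clusters are genuine signal.
* **Read-level evidence** is simulated directly (depth ~ Poisson(60), AF by
  a truncated normal per stage, binomial strand split, uniform edge
  fractions) rather than via synthetic reads, because the cascade consumes
  summaries only. Clean variants are clamped to pass every gate; a fixed 10%
  of variants per sample is deliberately generated to violate exactly one
  gate (cycling through the active gates), so the cascade's ledger can be
  checked against the generator's truth table exactly.
* **Expression**: Gaussian per gene over cell lines; the planted pair is a
  Gaussian copula with Pearson parameter `2 sin(pi * rho / 6)` so its
  *Spearman* correlation targets `rho`, and both members get the two highest
  mean expressions (top quartile by construction).
* **Proteome**: 400 proteins × (WT/ALT × OPP±) × 3 replicates; effect
  proteins shift only in (ALT, OPP+) by ±1.5 log2 units over replicate noise
  of 0.2 — values set by power computation (F ≈ 40 for the genotype factor)
  and consistent with typical log-scale MS replicate scatter; downshifted
  effects are annotated TSP, upshifted oncoprotein.

What a green test does *not* establish: the generator has no sequence
context (no AID WRCY hotspot motifs, no trinucleotide signatures), no
mutation clustering beyond the planted kataegis, uniform placement within
rate regions, independent samples within a stage, and Gaussian expression
noise. Results on real cohorts depend on those features; the tests establish
correctness of the *procedures*, not effect sizes in real data.

## Numerical and degenerate-input choices

* Fisher two-sided uses a `1 + 1e-7` relative tolerance when comparing point
  probabilities (the standard guard against floating-point ties).
* Wilcoxon exact p-values are rational (counts over `2^n`); the normal branch
  applies a 0.5 continuity correction.
* `call_superenhancers()` refuses fewer than 3 stitched regions; an
  all-equal-signal input flags nothing (cutoff `Inf`).
* Segment scans with no qualifying segment return an empty table, not an
  error; samples with no in-window mutations are skipped from profiles with
  a recorded warning; samples without SE mutations are excluded from the
  compartment split likewise.
* Expression and intensity matrices with missing values are refused outright
  (no silent imputation).
* All generators restore the caller's RNG state; identical seeds give
  byte-identical fixture bundles (checksum-tested).

## Known limitations

The SAVI-style empirical-Bayes caller itself, alignment, CNV/SV calling from
reads, Hi-C processing, signature fitting and motif analysis are out of
scope; TAD/compartment tracks are consumed as files. The ER rank aggregation
assumes lists of equal length with every pair ranked in all three lists. The
kataegis detector is a run rule, not a changepoint model, and inherits the
usual sensitivity to the IMD threshold at cluster borders.
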