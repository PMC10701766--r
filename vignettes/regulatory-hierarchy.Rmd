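---
title: "Mapping super-enhancer and cooperative-enhancer hierarchies from H3K27ac peaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping super-enhancer and cooperative-enhancer hierarchies from H3K27ac peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sescape)
library(dplyr)
```

## The analysis in one paragraph

`sescape` implements the downstream arm of a tumor-cohort H3K27ac ChIP-seq
study: starting from per-sample peak calls that carry input-normalized
signal densities, it builds the consensus occupancy landscape across
samples, separates super-enhancers (SEs) from classical enhancers (ENHs) by
a ROSE-style ranked-signal cutoff, classifies genes by how many distinct
classical enhancers converge on them (five or more defines a *cooperative*
target), infers candidate upstream transcription factors in two steps
(regulon over-representation, then motif validation against a
shuffled-genome background), and closes with the statistics that summarize
the biology: the expression hierarchy across regulatory-element classes,
correlation-based sample clustering, and clinical 2x2 associations.  A
synthetic cohort generator with planted ground truth makes every stage
testable end to end without any external data.

## Consensus occupancy and annotation

Peaks are half-open, 0-based BED intervals.  `consensus_peaks()` merges all
samples' peaks into candidate footprints and keeps those detected (>= 1
overlapping base) in at least `min_overlap = 2` samples — the merged
footprint is reported, not the intersection, mirroring the cited occupancy
tools' default.  Overlap is strand-blind because H3K27ac is an unstranded
mark.  `annotate_peaks()` assigns exactly one feature class per peak with
precedence TSS > 5'UTR > 3'UTR > Exon > Intron > Downstream >
DistalIntergenic, decided by the *peak midpoint*; full-span classification
of broad peaks would be ambiguous across classes, and the midpoint rule is
deterministic.  The promoter window is TSS +/- 3 kb and Downstream covers
300 bp past the gene end.  Nearest genes are tied-broken by lexicographic
gene id so reruns are bit-identical.

## Super-enhancer calling

`call_superenhancers()` composes four stages:

1. **Promoter exclusion** — a constituent peak is dropped only when its
   *full span* lies inside TSS +/- 3 kb of any gene (a peak straddling the
   window edge survives).  Exclusion happens before stitching, following
   the reference algorithm's order.
2. **Stitching** — peaks separated by at most 12.5 kb merge into one
   candidate element; stitching at gap 0 reduces to plain interval merging
   and is monotone in the gap.
3. **Scoring** — element signal is the sum over constituents of
   `max(0, chip_density - input_density) * length`.  The floor is applied
   per constituent, not per element, so a constituent whose input exceeds
   its ChIP cannot cancel genuine signal elsewhere in the element.
4. **Cutoff** — signals are sorted ascending and rescaled with their ranks
   to the unit square.  The threshold is the signal at the point where the
   unit-slope line is tangent to the rescaled curve, i.e. the point of
   maximal depth below the diagonal.  For a convex hockey-stick curve this
   coincides with the first rank at which the discrete slope crosses 1 from
   below; we use the global tangent criterion rather than a literal
   first-crossing scan because multiplicative noise makes the discrete
   slope of the high-signal tail dip below 1 between adjacent elements,
   and a crossing-based rule then cuts far into the tail.  If no discrete
   slope strictly exceeds 1 (a linear ramp, or all-equal signals) there are
   no super-enhancers.  The partition is invariant to rescaling all
   signals by a positive constant.

Group-level calls pool per-sample peaks with `pool_peaks()`: consensus
footprints scored with the mean ChIP and input densities of the
contributing sample peaks.  `map_targets()` reports the union of three
relations per element — `overlapping` (gene body), `proximal` (TSS within
50 kb of the element boundary; the 50 kb default is the reference gene
mapper's, the study reports no value), and `closest` (exactly one per
element, ties by gene id).

## Cooperative enhancers

`count_res_per_gene()` counts *distinct elements* per gene — a gene reached
by one element via two relations counts that element once — with SEs and
classical enhancers tallied separately.  `classify_cooperative()` splits
genes into `single` (1 ENH), `multi` (2 to k-1) and `cooperative` (>= k,
default k = 5); k is an explicit parameter so the threshold choice is
auditable.  Group-specific element sets (`group_specific()`) are
class-matched — an SE is compared only against SEs, an ENH only against
ENHs — because specificity counts are reported per class.

## Two-step upstream-TF inference

**Step 1.** `regulon_overrepresentation()` tests each TF's regulon against
the target-gene list with the hypergeometric upper tail, BH-adjusted, q <
0.1.  Membership is direction-agnostic: activating versus repressing edges
are not distinguished.

**Step 2.** `scan_pwm()` scores every window on both strands with a
log2-odds PWM and converts scores to *exact* p-values via
`score_distribution()`: per-position scores are integerized at a 0.001
granularity (rounding error at most 0.0005 per position) and convolved by
dynamic programming across positions, giving `P(score >= s)` for every
achievable score under an i.i.d. background estimated from the genome
(zero-order model).  BH is applied per PWM across *all scanned windows* of
the analyzed region set — the scanning tool the field uses adjusts within
one motif's scan, and the study states only the 0.1 cutoff.  Windows
containing N are skipped.

The background null comes from `shuffle_background()`: one same-length,
same-chromosome region per input region, placed uniformly over the exact
set of valid start positions (those leaving the region clear of every
excluded interval and all previously placed backgrounds).  We compute that
valid space by interval arithmetic and sample it exactly, rather than
rejection-sampling: the uniformity is then by construction, and a
configuration with a single remaining slot is solved deterministically
instead of hanging or failing.

`tf_enrichment()` marks a region *bound* when it contains >= 1 retained
hit on either strand, forms the 2x2 bound/unbound x RE/background table per
TF, and tests it with the Pearson chi-squared statistic *without* Yates
correction (the common default in the cited analysis environment; a
`correct` flag exposes the choice).  TFs are ranked by binding difference
(percentage-point difference in bound regions) and selected when q < 0.1
*and* the difference is positive — significant depletion is never
"enriched".

## Closing statistics

* `fisher_exact_two_sided()` uses the minimum-likelihood two-sided
  convention (the one that reproduces the printed clinical p-values); an
  enumeration oracle checks it exhaustively for table totals up to 40.
* `wilcoxon_rank_sum()` enumerates exactly for tie-free samples up to
  n = 25 and otherwise uses the normal approximation with midranks, tie
  and continuity corrections.
* `expression_hierarchy()` assigns genes to classes with precedence SE >
  cooperative > classical (the study does not state how doubly targeted
  genes were handled; precedence is flag-controlled via the input sets),
  averages expression over the selected group's samples, and runs the three
  pairwise Wilcoxon tests with BH across the three.
* `expressed_filter()` defaults to mean > 0 on normalized counts — the
  study never defines "expressed", so the weakest defensible threshold is
  the default and the value is a parameter.
* `cluster_samples()` uses log2(x+1), 1 - Pearson correlation between
  samples and average linkage.  The study does not report its
  transform/distance/linkage; this combination is standard for ChIP-seq
  occupancy and is configurable.  The implementation reproduces the
  *procedure class*, not the patient clustering itself, which depends on
  the deposited data.

## The synthetic cohort and what it does (not) show

`synthetic_cohort()` is the package's study stand-in: 17 primary-tumor (PT)
and 12 distant-metastasis (DM) samples — the cohort retained after quality
filtering in the emulated design — over a 4 x 2.6 Mb genome at GC 0.41 with
80 spaced gene models.  Planted structure, with defaults chosen once as
field-plausible values (the study reports no per-sample peak counts or
signal distributions, so these are free parameters):

* 8 SEs of 4 x 1.5 kb constituents spaced 4 kb apart (within one stitching
  reach), calibrated so the mean SE element signal is 10x the mean
  classical-enhancer signal;
* 10 cooperative genes, each wired to 5 enhancers placed > 12.5 kb apart
  (so they never stitch into one element) within the 50 kb proximity
  window;
* 20 classical single-enhancer genes and 30 PT-only enhancers (the
  emulated cohort has more PT-exclusive than DM-exclusive peaks, and the
  PT group needs an occupancy signature of its own for clustering);
* lognormal signal (ChIP mean 3, input mean 0.5 per base, sdlog 0.25) with
  per-sample multiplicative noise, Bernoulli(0.8) per-sample detection
  with two samples per group always forced — so the minOverlap = 2
  consensus rule is exercised non-trivially and group-specific elements
  provably appear in >= 2 samples of their group and 0 of the other;
* one driver PWM (width 10, near-deterministic consensus) planted into SE
  sequence at 0.8 instances/kb on random strands, plus two unplanted
  decoys; a regulon library whose driver regulon is the SE target genes
  plus 30% noise;
* expression 2^N(mu, 1) with class means 8 > 6 > 4 (log2 units, baseline
  2), and a clinical table whose aggressive-level odds are 6x higher in the
  DM-like cluster.

Two groups (PT, DM) are generated rather than the study's three observed
clusters: the clinical contrast the study tests is a two-cluster contrast,
and two groups exercise every downstream contract; `k_clusters` remains a
parameter.  All generators are pure functions of (config, seed): child RNG
streams are derived from the master seed by fixed offsets, so adding a
generator never perturbs the others, and identical seeds give byte-identical
files via `write_cohort()`.

What passing the recovery tests does **not** show: real H3K27ac peaks have
irregular widths and signal autocorrelation, real enhancer-gene wiring is
3D (the generator is purely linear-distance based), motif instances in real
SEs are degenerate rather than consensus copies, and real cohorts carry
batch structure.  The synthetic tests demonstrate correctness of the
algorithms under their stated model, not biological validity on patient
data.

## Numerical choices and degenerate inputs

* Score integerization granularity 0.001 bits; p-values are clamped into
  (0, 1] against floating drift in the cumulated tail.
* Rank ties in SE calling break by genomic coordinate; nearest-gene and
  closest-gene ties break by gene id.
* All-equal signals yield zero super-enhancers by convention; an empty
  peak set after promoter exclusion returns an empty call with a warning.
* A constant sample vector makes the correlation distance undefined:
  `cluster_samples()` fails naming the sample rather than guessing.
* Degenerate clinical 2x2 tables (constant feature) are flagged and given
  p = 1.
* Chi-squared tables with a zero margin have identical bound fractions by
  construction and are assigned statistic 0, p = 1.

## Calibration test design

Problem sizes in the test suite are chosen to keep the full run in a few
minutes while leaving each check statistically meaningful: 20 seeded
cohorts for parameter recovery; 500 null simulations for the Wilcoxon
type-I error (expected in [0.03, 0.07] at nominal 0.05); 500 placements for
background uniformity (chi-squared GOF).  The clinical-null calibration
(Fisher p under odds = 1) is run at 400 samples x 200 seeds: Fisher's exact
p-values are discrete and conservative, so at cohort-scale n a literal
uniformity test rejects for reasons that have nothing to do with the
generator — at n = 400 the support is dense enough for a distributional
comparison, and the conservative direction (rejection rate at or below
nominal) holds at any n.

## Known limitations

* The SE cutoff assumes a convex ranked-signal curve; concave curves (many
  high, few low signals) put the tangent point at the low end.
* Target mapping is within-chromosome only; an element on a gene-free
  chromosome has no `closest` gene.
* One background region per RE (1:1 shuffle); averaging over repeated
  shuffles is left to the caller by re-seeding.
* The regulon test treats regulons as plain gene sets; signed
  (activation/repression) regulons are collapsed.
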