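---
title: "Methods: windowed local-ancestry scans for adaptive introgression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed local-ancestry scans for adaptive introgression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introgscan)
```

## The problem

European pig breeds carry substantial Chinese ancestry, introduced
deliberately in the 18th–19th centuries to improve production traits.
Where such introgressed haplotypes were subsequently favoured by
selection, they should occur at high local frequency in the recipient
genome. `introgscan` implements a scan for such regions in an admixed
recipient population (the motivating case is Danish Duroc, with Meishan,
Bamaxiang and European wild boar — MS, BMX, EUW — as donor panels):

1. per-SNP donor copying proportions (the reduced output of a
   chromosome-painting analysis) are averaged in non-overlapping 50-kb
   windows;
2. windows with **more than 50% Chinese ancestry** (mean MS + BMX
   proportion, strict inequality) are candidate regions of adaptive
   introgression;
3. windows whose **Meishan–Bamaxiang FST falls in the top 5% of the
   empirical window distribution** are excluded, since strong MS–BMX
   differentiation at a window suggests introgression in the other
   direction (Europe into one Chinese breed) rather than shared Chinese
   ancestry;
4. QTL enrichment inside candidate regions is tested with a circular
   rotation permutation; and
5. regional haplotype structure is displayed by clustering haplotypes
   against a recipient-population consensus.

The scan deliberately targets windows with a *high proportion* of
introgressed ancestry rather than windows with a formally significant
selection statistic; no per-region significance is attached.

## Hudson FST

For two populations at a biallelic site with sample allele frequencies
$p_1 = r_1/n_1$, $p_2 = r_2/n_2$:

$$\hat F_{ST} \;=\; \frac{(p_1-p_2)^2 \;-\; \dfrac{p_1(1-p_1)}{n_1-1} \;-\;
\dfrac{p_2(1-p_2)}{n_2-1}}{p_1(1-p_2) + p_2(1-p_1)}.$$

This is the canonical two-population Hudson estimator with the unbiased
within-population correction. Sites with fewer than two called alleles
in either population, or a zero denominator (jointly monomorphic), are
undefined. Site values may be negative; the estimate is averaged,
unweighted, over the defined sites of each 50-kb window, and **negative
window averages are clamped to 0** (true FST lies in $[0,1]$). Clamping
at window level only — never per site — keeps the window mean unbiased
around 0 for undifferentiated regions while keeping reported tracks in
range. The Duroc–Chinese track is the arithmetic mean of the
Duroc–Meishan and Duroc–Bamaxiang window values.

The empirical quantile used for the extreme-FST exclusion is computed
with linear interpolation between closest order statistics
(`quantile(type = 7)`), over SNP-bearing windows only; windows without
SNPs carry no information in a scan built on SNP averages, so they are
excluded from quantiles and from candidate calling, and they terminate
region extension.

## Candidate windows and top-region extension

`call_candidates()` applies the two filters with the inequalities read
literally: ancestry strictly above 0.5, FST *not strictly above* the
quantile threshold. `extend_top_regions()` builds the highest-ancestry
regions for one donor: seed on the highest remaining window
(coordinate order breaks ties), extend in both directions while the
next window on the same chromosome has donor ancestry **at least 0.5**
and is not extreme-FST, stop otherwise; keep the first five regions
with at least two windows, ranked by seed-window ancestry. Two
deliberate asymmetries are documented here because the two rules are
phrased differently in the field's practice: the candidate filter is
strict (`> 0.5`), while extension continues through exactly-50% windows
(the stop rule is "next window with *less than* 50%"). Ranking is by
seed ancestry rather than region length; length is reported so users
who prefer the longest regions can re-rank.

## QTL filtering, deduplication and the rotation test

QTL records pass a two-stage filter whose audit mirrors database
bookkeeping: (1) drop linkage-mapped records (uncertain genomic
locations); (2) drop records on non-autosomes — including unknown
chromosome names — or spanning more than 1 Mb. The peak is the interval
midpoint (`floor((start+end)/2)`). Records identical in (trait group,
chromosome, start, end) count once; the key includes the trait group,
so the same interval annotated in two groups contributes to both
per-group counts and twice to the all-traits tally (the group-ignoring
tally is also reported, since the convention is genuinely ambiguous).

The null model concatenates the autosomes, in layout order, into a
circular sequence of 50-kb windows and moves the whole candidate set by
one uniformly drawn rotation offset per permutation, preserving the
candidate windows' relative spacing and hence their correlation
structure; peaks stay fixed. Choices that matter:

* **Whole-window offsets**, not base pairs: rotated regions remain
  unions of grid windows and membership stays exact at the circle seam.
* **Offset 0 excluded** from the draws, so the null never
  tautologically contains the observation (rotation by 0 reproduces the
  observed count, which the tests verify).
* **Empirical p = r/n** (fraction of null counts ≥ observed), matching
  p-values that are exact multiples of 1/n.
* **Shared offsets across scopes**: the all-traits test and the five
  per-group tests reuse one stream of rotations, so group results are
  comparable under identical nulls; the group nulls sum, draw by draw,
  to the all-traits null.

An empty candidate set yields an undefined p with a reason rather than
an error, so pipelines on permissive thresholds complete.

## Haplotype clustering display

For a region, phased haplotypes are coded 0/1 against the VCF reference
allele and compared to the **majority consensus of a reference
population** (ties to allele 0; a per-haplotype minimum-distance
variant is available behind a flag). Distance is the Hamming count of
differing SNPs. Haplotypes are grouped by average-linkage hierarchical
clustering on pairwise Hamming distances; the tree is cut at a
configurable height, default 0, which makes display blocks the classes
of *identical* haplotypes. Blocks are ordered by increasing mean
distance to the consensus, rows within blocks by distance then input
order. The default makes the whole ordering exactly reproducible by
brute force (the tests enumerate it for small inputs) while guaranteeing
identical haplotypes are adjacent; the original display tool's exact
within-cluster order is not recoverable, so a stated deterministic rule
was chosen over a faithful imitation. The tested artifact is the
ordered structure; rendering is a thin `image()` layer.

## The synthetic generator

No sequencing data ships with the package; `sim_config()` +
`simulate_dataset()` generate a study in which every downstream answer
is known.

* **Donor panels.** Sites are placed uniformly at the configured
  density; ancestral alternate-allele frequencies are Uniform(0.05,
  0.95); donor frequencies follow a two-level Balding–Nichols tree
  (Beta draws with drift $F$): ancestral → Asian branch → MS and BMX;
  ancestral → EUW. The shared Asian branch makes MS and BMX mutually
  closer than either is to EUW, reproducing the qualitative relation
  that the two Chinese donors' ancestry profiles are nearly
  interchangeable. Defaults $F_{MS} = F_{BMX} = 0.15$,
  $F_{EUW} = 0.3$, Asian branch half the MS/BMX mean.
* **Recipients.** Ancestry along each haplotype is a Markov tract
  process: exponential tract lengths with rate `switch_rate_per_bp`
  (default 5e-7, i.e. 2-Mb mean tracts — the order implied by a
  ~50-generation admixture history at ~1e-8 crossovers/bp/generation;
  the history is not calibrated further and the rate is an explicit
  knob), tract donors drawn from the stationary triple (default 0.12,
  0.13, 0.75 — the recipient-genome averages of the motivating study).
  Inside planted sweep regions the boosted donor is drawn with its
  boosted probability, the others sharing the remainder
  proportionally. Alleles are copied from one random donor haplotype
  per tract, re-chosen at each switch, preserving within-tract
  haplotype structure for the clustering module.
* **Truth track.** The delivered per-SNP proportions are the
  across-haplotype donor fractions — i.e. painting with zero inference
  error — optionally blurred by Dirichlet noise around the truth
  (concentration configurable; default none). Tests therefore separate
  pipeline error from painting error; passing them says nothing about
  the accuracy of any painting software on real data.
* **QTL table.** Record counts, a linkage-mapped fraction (default
  0.349), five trait groups at the observed tally proportions, capped
  lognormal lengths (default meanlog log(2e4), sdlog 1.5, cap 1 Mb,
  matching a ~24-kb mean with a 40 bp–1 Mb range), a small decoy
  fraction on a non-autosomal chromosome to exercise the filters, and
  an `enrichment_rho` fraction of association peaks planted uniformly
  inside sweep regions.
* Haplotype-count defaults (60/12/30 donors, 180 recipients) mirror
  the motivating study's sample sizes; the genome itself is scaled to
  18 autosomes × 5 Mb.

All randomness flows from the master seed; sub-operations use
consecutive derived seeds through a save/restore RNG scope, so each
stage is independently reproducible and nothing leaks into the
session's RNG.

What the generator does **not** emulate: coalescent recombination maps
and mutation models, phasing/imputation error, painting uncertainty
(unless Dirichlet noise is switched on), linked selection, or sex
chromosomes beyond the decoy label.

## Numerical conventions and degenerate inputs

* Coordinates: 0-based half-open internally and in BED outputs;
  1-based inclusive in SNP/QTL tables on disk. A SNP at 1-based
  position $p$ belongs to window $\lfloor (p-1)/50000 \rfloor$.
* Terminal short windows are retained, so window counts equal
  $\sum_c \lceil L_c / 50000 \rceil$.
* Peak-in-region membership is half-open: start boundary counts, end
  boundary does not.
* Ties: equal seed ancestry → earlier coordinate; consensus ties →
  allele 0; equal display distance → input order.
* Degenerate inputs reject with informative messages rather than
  guessing: ancestry rows that do not sum to 1 (line numbers), SNPs
  beyond chromosome ends, unphased or missing genotypes (sample
  named), quantiles outside (0,1), zero expected sites, planting
  without sweep regions.

## Problem sizes used by the test suite

The packaged fixture is 2 chromosomes × 500 kb with 9 donor + 8
recipient samples. Property and calibration tests use, as the
package's own choices: 1,000 random sites for the estimator oracle;
100 random circles of ≤ 20 windows against exhaustive rotation; 400
uniform-peak replicates at 500 permutations for type-I calibration; an
18 × 5 Mb genome with nine 500-kb sweeps (boost 0.95) and 50 replicate
QTL draws at `enrichment_rho = 0.3` for recovery and power.

## Known limitations

* The scan consumes painting output; it does not infer local ancestry
  itself, and its accuracy on real data is bounded by the painting's.
* The permutation preserves the candidate set's internal spacing but
  not any spatial autocorrelation of the QTL density itself.
* The five-region selection reports seed-ancestry ranking only;
  a length-based ranking may pick different regions.
* Hudson FST here is the two-population estimator; multi-population
  statistics and haplotype-based selection scans are out of scope.
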