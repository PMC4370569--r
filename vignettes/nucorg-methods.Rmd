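---
title: "Methods: enrichment, occupancy and nuclear-zone statistics in nucorg"
author: "nucorg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enrichment, occupancy and nuclear-zone statistics in nucorg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucorg)
```

`nucorg` implements three statistical assays used to characterize how a
chromatin remodeler organizes fission-yeast chromatin at subtelomeres, tRNA
genes and LTR retrotransposon relics, plus a synthetic-data generator that
makes every stage testable without external data. This vignette is the
package's own account of the models, the parameters that matter, and the
design choices made where the underlying methodology left them open.

## Coordinate frame and annotation handling

All genomic objects are `GenomicRanges` containers validated against a
`Seqinfo` layout. Internally the package uses the native `GRanges`
convention (1-based, closed intervals); GFF3 is read and written natively
and BED conversion happens at the `rtracklayer` boundary. We chose this over
a 0-based half-open internal convention because it removes a conversion
layer between the in-memory objects and the Bioconductor ecosystem while
preserving the same abutment semantics: an interval starting one bp past
another's end does not overlap it, and membership requires at least one
shared bp. Strand is ignored for probe membership, since tiling probes are
unstranded.

Annotation reclassification applies four substring-matching rules, in
order: records matching `LTRTF2` become class `LTR`; protein-coding
records matching `Tf2` become class `Tf2`; records matching
`origin_of_replication` become `origin`; records whose `external_name`
attribute matches `intron` become `intron`. Matching is by fixed substring
over the retained annotation attributes (configurable via
`default_reclass_rules()`), and the operation is idempotent. The packaged
subtelomeric domains for *S. pombe* (`subtelomere_regions_pombe()`) are the
four chromosome-end regions of chromosomes I and II; their endpoints are
read as 1-based inclusive coordinates — the source coordinates do not state
their convention, so this reading is flagged here rather than silently
assumed. Under it the four domains total 380,689 bp.

## Signal tracks

A probe track is an ordered set of probe intervals with a signal value and
a per-probe uniqueness flag. Probes with multiple genomic matches are
excluded from all statistics by `filter_unique()` (the full track is kept
for visualization); the synthetic generator marks all probes unique. Log2
enrichment ratios are computed probe-wise as
$\log_2\frac{x_i + c}{y_i + c}$ with pseudocount $c = 0$ by default —
tracks are assumed already positive and normalized, as produced by array
preprocessing upstream of this package; $c$ is exposed because the handling
of zero or negative normalized values is not standardized. Targets at a
fold threshold $f$ are probes with ratio strictly greater than $\log_2 f$
("more than $f$-fold"); equality is excluded, a choice documented here
because the source wording does not address it.

Boxplot summaries use type-7 (linear interpolation) quartiles and Tukey
whiskers at 1.5 IQR clamped to the data. "Standard parameters" for
boxplots can mean several quartile rules; fixing and documenting one keeps
summaries reproducible.

## The circular permutation test

For a class of probes (mask $m$) and signal $x$, the statistic is the mean
difference
$$T = \overline{x}_{m} - \overline{x}_{\neg m}.$$
The null hypothesis is positional: the class occupies an arbitrary
rotational alignment relative to the signal. Each permutation draws one
uniform offset per chromosome and rotates the membership labels circularly
along the probe index, leaving the values fixed. This preserves the
within-chromosome spatial autocorrelation of the signal — the reason a
probe-label permutation would be anticonservative — while breaking the
feature–signal alignment. The sampled p-value is smoothed,
$$p = \frac{1 + \#\{|T^\ast| \ge |T|\}}{B + 1},$$
so zero is never reported, and ties with the observed statistic count as
extreme (conservative). The default is $B = 1000$ and a two-sided
alternative on $|T|$; one-sided alternatives are available because
directional enrichment is usually the question of interest.

The rotation granularity (probe index) and the number of permutations are
exposed as configuration: the upstream description of the method does not
state either, so both are documented unknowns rather than hidden constants.
Two rotation modes exist: independent per-chromosome offsets (default, the
standard construction for positional nulls) and a single joint offset over
the concatenated genome. `exhaustive_test()` enumerates every combination
of per-chromosome offsets once — the identity always counts itself, so
$p \ge 1/N$ — and serves as the exact oracle against which the sampled test
is validated.

## Paired occupancy comparison

Per-feature occupancy is the mean per-base coverage over the feature
interval (default), making features of different lengths comparable; raw
or length-normalized read counts are available by flag since the upstream
"average number of reads" phrasing does not state length normalization.

The between-genotype comparison is described in its source as a "paired,
two-sided Mann-Whitney U test", which is self-contradictory (the
Mann-Whitney U test is unpaired). We read "paired" as controlling and
implement the Wilcoxon signed-rank test on per-feature differences, the
standard paired rank test; the unpaired test is provided for comparison
(`unpaired_rank_test()`) but is not the default. Zero differences are
dropped (Wilcoxon's original treatment) and tied absolute differences are
mid-ranked. For up to 25 pairs the p-value is exact: the null distribution
of the positive-rank sum under random signs is built by convolution over
the (doubled, hence integer) midranks, which is algebraically identical to
enumerating all $2^n$ sign patterns but costs $O(n^2 \max r)$; tests verify
it against literal $2^n$ enumeration for $n \le 10$ and against
`psignrank` when there are no ties. Beyond 25 pairs a normal approximation
with tie-corrected variance $\sigma^2 = \sum_i r_i^2/4$ is used, without
continuity correction; exact and approximate p agree within 0.01 at
$n = 30$ in the test suite. Two-sidedness is defined symmetrically,
$P(|W - \mu| \ge |w - \mu|)$, which keeps the test invariant under
swapping the two conditions.

## The nuclear zone assay

The nucleus is modeled as a sphere — implied by scoring with a single
measured radius — and each spot's distance to the envelope is normalized by
that radius, $d = \mathrm{dist}/R \in [0, 1]$. Cutting the ball into $n$
shells of equal volume puts boundaries at
$$d_k = 1 - \left(\frac{n-k}{n}\right)^{1/3}, \qquad k = 1, \dots, n-1;$$
for $n = 3$: $d_1 = 1 - (2/3)^{1/3} \approx 0.12642$ and
$d_2 = 1 - (1/3)^{1/3} \approx 0.30664$. A spot on a boundary is assigned
to the more peripheral zone (the source is silent on ties; peripheral
assignment is the conservative choice for an assay asking whether loci are
peripheral). Whether the original assay used these analytic cutoffs or an
empirical calibration is not stated; the analytic cutoffs are what "equal
volume zones" defines, and a Monte-Carlo oracle in the tests confirms
uniform points in the ball land in each zone with frequency $1/n$.

Strain pairs are compared with Pearson's chi-square on the
$2 \times n$ zone-count table, $df = n - 1$, without Yates correction
(undefined beyond $2 \times 2$, and uncorrected even there for
consistency). Upstream image-processing steps (deconvolution, removal of
the top and bottom z-stacks) happen before the measurements this module
consumes; optical sectioning is deliberately not modeled.

## The synthetic-data generator

The generator produces inputs with the statistical structure the analyses
assume, at toy scale:

* **Genome and features.** Chromosome-end subtelomeric domains, plus
  feature classes placed uniformly without overlap, or within 2 kb of the
  subtelomere borders for LTR-style placement. Byte-identical outputs under
  a fixed seed.
* **Probe signal.** Per chromosome, a stationary lag-1 autoregressive
  process with marginal sd $\sigma$ (default 0.5 log2 units) and
  autocorrelation $\rho$ (default 0.7). AR(1) is the minimal model of the
  tiling-probe spatial autocorrelation the circular permutation null exists
  to respect; $\rho = 0.7$ gives the strong local correlation typical of
  overlapping-fragment hybridization signal. The class effect $\Delta$ is
  added to the log2 ratio of member probes; the condition track is
  `control * 2^ratio`, so `log2_ratio()` recovers the simulated ratio
  exactly.
* **Occupancy counts.** Negative binomial per feature (default mean 100,
  dispersion 10 — overdispersed, as sequencing-derived counts are), with
  condition B's mean scaled by the fold parameter; `dispersion = Inf`
  recovers the Poisson limit.
* **Spots.** Zone drawn from per-strain probabilities, then the normalized
  distance drawn by inverse CDF of the $r^2$ (volume-uniform) radial
  density within the zone's shell, so the `"uniform"` preset is exactly
  uniform in the ball. The wild-type preset `c(0.75, 0.15, 0.10)` encodes
  the ~75% peripheral fraction typical of anchored telomeres. Nuclear radii
  are uniform on 0.9–1.3 um.

What the generator does *not* emulate — probe-specific affinity and array
normalization artifacts, GATC-fragment resolution of DamID, nucleosome
positioning within features, oblate nuclei and optical sectioning — bounds
what passing tests show: they validate the statistical machinery and its
calibration under the assumed structure, not robustness to instrument
effects upstream of this package's inputs.

## Numerical choices and degenerate inputs

Extremeness comparisons use a relative tolerance of $10^{-12}$ so that
floating-point ties count as "at least as extreme". Rotation member-sums
are computed by index arithmetic in chunks of ~2e6 matrix cells to bound
memory. Degenerate masks (all or no members), all-zero paired differences,
empty uniqueness-filtered tracks, zones with zero expected counts and
infeasible feature placements all raise informative errors rather than
returning silent values. Reports embed the seed, a config hash and input
checksums; identical inputs and seed reproduce byte-identical TSV/JSON.

## Problem sizes in the test suite

The packaged checks run at sizes chosen to make sampling error small
relative to the asserted tolerances: 30,000 Monte-Carlo points for zone
geometry; 100 random instances (up to ~8,100 enumerable offsets, 10,000
sampled permutations each) for the sampled-vs-exhaustive agreement; 200
replicates per test for type-I calibration at $\alpha = 0.05$ against the
exact binomial 99% interval; 200 replicates of 5,000-probe tracks for
effect recovery within $\pm 0.1$; and 100 random toy genomes for the
interval-overlap oracle.

## Limitations

The permutation unit is the probe, not the base pair; on very non-uniform
probe grids the two differ. The zone assay assumes a spherical nucleus and
a single radius per cell. The paired rank test's exact mode is limited to
25 pairs (beyond which the tie-corrected normal approximation is used),
and the chi-square comparison relies on its asymptotic distribution —
with fewer than ~5 expected spots per zone, pool zones first.
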