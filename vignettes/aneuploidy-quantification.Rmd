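---
title: "Quantifying aneuploidy from copy-number profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying aneuploidy from copy-number profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneuploidr)
```

## The problem

When a cell loses p53 function it tends to accumulate chromosomal
copy-number changes — whole-chromosome and arm-level gains and losses,
occasionally whole-genome doubling (WGD) or chromothripsis. Phenotypes that
have historically been attributed to specific mutant p53 proteins
("gain-of-function" activities) can instead track the *degree of
aneuploidy* a clone happens to have acquired. Testing that hypothesis
requires a quantification pipeline: turn noisy probe-level log2-ratio
(logR) measurements into segments, summarize each sample's alteration
burden relative to its parental clone, classify samples into
aneuploid-high/low groups, and relate those groups to expression,
genotype, and survival. This package implements that pipeline end to end,
together with a synthetic-data generator that provides ground truth for
every stage.

## Coordinate system

All signals live on a shared coordinate system: a `genome_model`
(chromosomes with lengths and centromere positions; an embedded
hg38-like table of 22 autosomes + X is the default, with a `scale`
argument) and a `bin_grid` of fixed-width half-open bins. Internally all
coordinates are 0-based half-open; SEG files are read and written 1-based
inclusive, the ecosystem convention. Two deliberate choices:

* **Bins never span centromeres.** Arm-level statistics are then exact
  sums of bins, which matters because group comparisons are performed per
  chromosome arm.
* **The default working genome is scaled.** `build_genome(scale = 0.1)`
  gives a ~240 Mb genome with realistic relative chromosome sizes. All
  statistics that matter are either scale-invariant (FGA, correlations,
  classifications) or length-weighted per Mb (the aneuploidy score), so
  conclusions transfer; the simulations in the tests and the acceptance
  script use this scale (20-sample cohorts, 1 Mb bins, 20 probes/Mb) so
  they run in seconds.

## Segmentation

Probe-level logR tracks are segmented per chromosome by penalized
recursive binary splitting. The cost of a segmentation is

$$\sum_i (x_i - \bar{x}_{s(i)})^2 + \lambda \cdot \#\text{segments},$$

a split is accepted only when it lowers this cost and both children
retain at least `min_probes` probes, and after recursion adjacent
segments whose means differ by less than `delta` are merged. Segment
means are plain probe means (no shrinkage), and segment boundaries sit at
midpoints between flanking probes.

Defaults, with units and rationale:

* `min_probes = 5` — a segment must be supported by at least five probes.
* `lambda = 0.1` (logR² units) — a step of size $d$ between flanks of
  $n_1, n_2$ probes reduces the residual sum of squares by
  $\frac{n_1 n_2}{n_1 + n_2} d^2$; at the design point (0.3-logR step,
  five probes per side, probe noise sd 0.1) that is 0.225, comfortably
  above the penalty, while noise-only fluctuations at sd 0.1 typically
  yield reductions below 0.1.
* `delta = 0.05` (logR units) — merges spurious near-equal neighbors.

Because greedy binary splitting can place a boundary a probe or two away
from the penalized optimum, a refinement pass re-optimizes each
breakpoint between its flanking neighbors, and each adjacent *pair* of
breakpoints jointly, until stable. The test suite verifies on randomly
generated stepped signals that the refined output coincides with the
exact dynamic-programming optimum of the same cost — the DP oracle is
coded independently in the tests and is never the production path. The
deterministic tie-break is leftmost split; there is no outlier-smoothing
pre-pass, a documented difference from array-vendor pipelines.

## Aneuploidy metrics

**Parental-relative profiles.** Segmented profiles are projected onto the
bin grid (length-weighted means) and the parental clone's binned profile
is subtracted bin-wise. Alterations the whole lineage inherited from the
parental line cancel; scores reflect *acquired* changes only.

**Aneuploidy score (AS).** The sum of absolute segmented log ratios of
the relative profile. The published statistic's unit is not fixed, so
three weighting modes exist: `per_Mb` (default; each bin weighted by its
length in Mb — invariant to bin width and probe density), `per_bin`, and
`per_segment`. The choice affects only the absolute scale, not sample
ordering under a fixed segmentation, which is why printed quantile
boundaries from any particular array pipeline are treated as
pipeline-specific and are not reproduction targets here.

**Fraction of genome altered (FGA).** The length of segments with
$|\text{logR}| > 0.2$ divided by the total segmented length. The
inequality is strict: a segment at exactly 0.2 does not count.

**Quartile classes.** Samples at or below the first quartile of the
cohort statistic are `aneuploid_low`, at or above the third quartile
`aneuploid_high`, the rest `intermediate`. Quartiles use the linear
interpolation definition (`stats::quantile` type 7) and are inclusive at
both boundaries — source conventions differ between strict and inclusive
at the printed boundaries, and inclusiveness keeps groups non-empty for
small cohorts. Identical values across a cohort yield all-intermediate
with a warning.

**Frequency tracks and arm tests.** Gain/loss calls per bin reuse the 0.2
threshold (chosen for consistency with the FGA definition). Per-arm group
comparisons take the bin-length-weighted mean logR per sample per arm and
apply a two-sided two-sample t-test — Welch by default (safer under
unequal variances; a pooled mode exists for fidelity to the classical
Student test) — with Benjamini–Hochberg adjustment across arms and a
flag at adjusted p < 0.1. Note that with few samples per group, BH
control is on the false discovery *rate*: in a cohort with one strongly
shifted arm, occasional additional flags among null arms are expected at
about the nominal rate, which is what the calibration tests assert.

**Dosage.** Average chromosomal copy number is $2 \cdot 2^{m}$ where $m$
is the length-weighted mean logR of the chromosome. Average expression
per chromosome is the mean of $\log_2(x+1)$-transformed values over the
chromosome's genes (the transform is configurable; log stabilizes
variance and makes the dosage slope interpretable). Genes with zero
counts in every sample are excluded before averaging. The Pearson
correlation between the two, across samples, is the dosage statistic;
zero variance on either axis yields a flagged "undefined" result rather
than NaN.

## TP53 classification

Tumor mode: a sample with sequencing data but no TP53 records beyond
silent/noncoding is WT; a single missense record is missense; a single
nonsense, frameshift, or splice-site record (stop-gain is canonically
folded into nonsense) is truncating; any in-frame indel, or more than one
non-silent alteration of any mix — including two truncating records — is
excluded with the corresponding reason. Cell-line mode differs only in
that not-assayed is unused. Decisions taken where the source rules are
silent:

* A missense record accompanied only by silent records is missense
  (silent calls are ignored symmetrically for WT and mutant samples).
* Splice-*region* variants are not truncating; only proper splice-site
  records are.
* Unclassifiable records ("other", e.g. translation start site) are
  ignored like silent ones, so every excluded sample carries one of the
  two documented exclusion reasons.

Cohort filters drop individuals with multiple tumor samples, then whole
cohorts with fewer than 20 missense individuals or below 10% missense
frequency (denominator: all classified samples in the cohort). Every
exclusion is reported with its rule.

## Survival stratification

Kaplan–Meier estimation and the unweighted log-rank test are delegated to
the `survival` package (`survfit`/`survdiff`) behind small typed
wrappers; the test suite cross-checks the log-rank statistic against an
independently coded hypergeometric computation to 1e-10. Within each
TP53 class, samples are split into FGA quartiles — per class by default,
which keeps Q1/Q4 group sizes balanced across classes; a pooled mode is
provided because the source wording is ambiguous — intermediate quartiles
are dropped, and Q1 vs Q4 are compared per class, alongside a
genotype-level comparison. Ties follow the standard convention (events
before censorings at equal times). No Cox model is fitted.

## The synthetic-data generator

The generator is first-class, tested code; it emulates:

* **Karyotypes** starting from CN = 2 everywhere: WGD (probability 0.2 by
  default, applied first, baseline ploidy 4), then Poisson(3) events per
  sample, weighted 40% whole-chromosome, 30% arm, 25% focal, 5%
  chromothripsis, at ±1 copy by default. Chromothripsis is a two-state
  alternating process along one chromosome with exactly `n_switches`
  state changes and uniformly drawn run lengths. Copy numbers are clamped
  at 0 with a warning. Event counts per passage are free parameters, not
  calibrated to any measured rate — no quantitative acquisition rate is
  available to calibrate against.
* **Probe signals**: uniform probe placement (default 20/Mb on the scaled
  genome), $\log_2(\text{CN}/2)$ per bin (floored at CN 0.25 so
  homozygous deletions stay finite) plus Gaussian noise (sd 0.1,
  CytoScan-like), then genome-wide **median**-centering. Median (not
  mean) centering reproduces a key property of array normalization: a
  pure WGD sample renders as logR ≈ 0 everywhere and is invisible to the
  score — which is exactly why orthogonal ploidy measurements (metaphase
  spreads, PI staining) are needed to detect tetraploidy in real data.
* **Expression**: gene means $\mu_g (\text{CN}/2)^{s}$ with
  negative-binomial counts (constant dispersion across genes for
  simplicity; Poisson at dispersion 0). Baseline means are constant by
  default (`base_sdlog = 0`) so closed-form ratio checks are exact; a
  lognormal spread is available.
* **Mutation tables**: per-sample classes drawn from a stated mix, with
  hotspot missense protein changes (R175H, R273H, …),
  nonsense/frameshift/splice-site truncating records, multi-alteration
  and in-frame cases, and silent-only WT samples; ground-truth labels are
  returned.
* **Survival**: exponential event times with hazard
  $h_0 \cdot \text{HR}^{[\text{FGA Q4}]}$ and independent exponential
  censoring. Defaults $h_0 = 1/1500$ per day and censoring $1/3000$ per
  day give progression-free-survival-like curves over a ~5-year window;
  HR defaults to 2 (cohort analyses in this literature report clearly
  separated but moderate hazard differences), and the power analyses in
  the acceptance checks use HR = 3 explicitly.
* **Growth curves**: $N_0 2^{t/T_d}$ with multiplicative lognormal noise,
  inverted exactly by `doubling_time()` at zero noise.

What the generator does **not** emulate: subclonal mixtures,
allele-specific copy number (BAF), GC/wave artifacts, outlier probes,
correlated gene-level expression programs, and cohort-level covariates.
Passing tests therefore demonstrate correctness of the statistical
machinery under a clean generative model, not robustness to every
artifact of real arrays.

## Numerical choices and degenerate inputs

* Quantile type 7 (linear interpolation) everywhere; boundary-inclusive
  classification.
* Strict inequality at the FGA threshold.
* Segmentation tie-breaks: leftmost split; refinement accepts only strict
  cost improvements (tolerance 1e-12).
* Degenerate inputs are first-class: empty profiles, chromosomes with
  fewer than `min_probes` probes (single segment + warning), all-equal
  cohort statistics (all intermediate + warning), zero-variance dosage
  vectors (flagged undefined), non-growing growth curves (flagged, not an
  error), all-censored survival groups (flat curve at 1), width/length
  caliper swaps (warning + swap).

## Problem sizes

The shipped tests and the acceptance script use: 40-probe signals for the
exact-DP comparisons (50 replicates); a 1/10-scale genome with 1 Mb bins,
20 probes/Mb and 20 samples for end-to-end burden recovery; three
50 Mb chromosomes, 80 genes each, 20 samples and 100 seeds for the dosage
contrast; 500 replicates for arm-test calibration, 1,000 for log-rank
size, 100 for power at HR = 3 with 500 per arm; and 10,000 samples for
TP53 mix recovery. These sizes were chosen so each check is statistically
informative yet the whole suite completes in about a minute.

## Known limitations

* The aneuploidy score's absolute scale depends on the weighting mode and
  segmentation settings; only orderings and classifications are
  comparable across pipelines.
* Binary segmentation with refinement matches the exact DP optimum on
  well-separated steps; pathological signals (many sub-`min_probes`
  features) can still differ from the global optimum.
* Integer copy-number calling is limited to the $2 \cdot 2^{m}$
  transform; there is no GISTIC-style focal-peak detection and no
  allele-specific analysis.
* The survival module fits no regression models; confounding between FGA
  and genotype must be addressed by the stratified design itself.
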