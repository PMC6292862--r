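---
title: "Haplotype mixed-model GWAS and read-depth CNV discovery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype mixed-model GWAS and read-depth CNV discovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplocnv)
```

## The problem

In beef cattle raised on pasture, a long or pendulous navel predisposes to
injury and infection; navel length at yearling is scored visually (1-5) in
indicine (*Bos indicus*) breeding programs. Mapping its genetic basis is a
quantitative-genetics problem with a twist: the causal variant may be a
copy-number variant (CNV) that SNP arrays cannot see directly, so discovery
must chain together several kinds of evidence. `haplocnv` implements that
chain as reusable, tested components:

1. a **haplotype sliding-window GWAS** under a leave-one-chromosome-out
   (LOCO) mixed linear model with AI-REML variance components;
2. **read-depth coverage profiling** of sequenced animals grouped by the
   number of copies of the associated haplotype, with 1-kbp median
   smoothing and copy-gain calling;
3. a **tandem-duplication read-pair test** (outward-facing pairs with
   inserts about the length of the duplicated unit);
4. **SNP probe-intensity analysis** (log R ratio with GC-wave correction)
   showing why the array missed the CNV;
5. **qPCR relative quantification** by the 2^-ddCt method for wet-lab
   validation;
6. a **founder-mosaic simulator** that generates all of these inputs with
   known ground truth.

## The association model

For each pseudo-marker (a haplotype allele of a window of L consecutive
phased markers, coded 0/1/2 copies per animal) the model is

$$ y = 1_n\mu + x b + u + e, \qquad
   y \sim N(1_n\mu + xb,\; G\sigma^2_u + I\sigma^2_e) $$

where $y$ are deregressed EBVs, $x$ the standardized haplotype counts, and
$G$ the SNP-based genomic relationship matrix built from centered dosages,
$G = ZZ' / 2\sum_j p_j(1-p_j)$, **excluding every SNP on the chromosome of
the tested window** (LOCO), so the polygenic term cannot absorb the tested
signal. Fitting is two-step, once per chromosome: AI-REML on the reduced
model (no pseudo-marker) estimates $(\sigma^2_u, \sigma^2_e)$; every window
on that chromosome is then tested by GLS under the fitted covariance. One
eigendecomposition $G = UDU'$ per chromosome rotates the model so each
marker test is $O(n)$; `gls_scan()` is verified against a dense
$V^{-1}$ oracle to 1e-8 and collapses to OLS when $\hat\sigma^2_u = 0$.
Significance uses the Wald $\chi^2_1$ upper tail and a Bonferroni
family-wise threshold $\alpha/N$. Windows tied with the top p-value at 3
significant figures can be merged into a consensus allele
(`merge_tied_windows()`), requiring exact agreement on the L-1 shared
markers.

AI-REML details: parameters start at half the phenotypic variance each,
components are floored at $10^{-6}\mathrm{var}(y)$, the AI step is
step-halved and falls back to a monotone EM-type update whenever it fails
to increase the restricted likelihood, and convergence is
$|\Delta\ell| < 10^{-8}$ within 200 iterations. Non-convergence is flagged,
never silent.

## Deregression and weights

EBVs enter the GWAS as deregressed pseudo-phenotypes. The default "simple"
mode divides out shrinkage (`debv = ebv / r2`) because parent-average
inputs are rarely available; the "full" mode removes the parent-average
contribution by back-solving the standard two-equation mixed-model system
(`lambda = (1-h2)/h2`, information contents from the reliability
identities). Records are filtered at accuracy (`sqrt(r2)`) >= 0.70, and the
secondary-trait screen can weight records by
$w = (1-h^2) / ((c + (1-r^2)/r^2)\,h^2)$ with $c = 0.5$ by default (the
fraction of genetic variance not captured by markers); both $h^2$ and $c$
are configuration, since no published values exist for these traits.

## Read-depth CNV analysis

Per-base coverage is normalized as $N_{\mathrm{reads}}/C$. $C$ defaults to
the per-sample *median* of the profiled track: over a region whose
copy-variable segment is a small fraction of the whole, the median equals
the copy-neutral coverage and, unlike the mean, is not inflated by the CNV
itself; a genome-wide mean can be supplied instead. Group profiles average
per-base coverage within haplotype-count groups first, then take medians of
1-kbp bins anchored at the region start (last partial bin kept). Gain calls
are maximal runs of bins with any group median >= 1.5 (midway between
neutral 1.0 and one extra copy at 1.5 on the diploid scale) of total length
>= 2 kbp; per-group fold change is the median of in-call bin medians.
Cross-population comparison classifies a population neutral when its
in-region fold lies within 1 +/- 0.25, gain at >= 1.5, ambiguous between.
Interval lengths are reported as `(end - start)/1000` kbp (half-open).

## Tandem-duplication signature

A fragment spanning the junction between adjacent copies of a tandem repeat
projects onto the reference as a pair whose reads face *outward* (leftmost
on the minus strand) with an apparent insert close to the repeat-unit
length. `classify_pairs()` calls a pair discordant-outward when it is
outward-oriented and its insert exceeds `insert_mean + 3 insert_sd`;
`tandem_dup_vote()` declares a tandem duplication when >= 3 such pairs span
the candidate region and their median insert is within 25% of the region
length. The support threshold and SD multiplier are configuration; the
study this emulates reported only "several" supporting pairs.

## Probe intensities and GC waves

For each SNP, theta = $2/\pi \cdot \mathrm{atan2}(y, x)$ places a sample
between the canonical genotype cluster centroids; expected intensity
$R_\mathrm{exp}$ is linearly interpolated over theta between flanking
centroids and clamped outside the outer clusters (extrapolation could turn
negative). LRR = $\log_2(R_\mathrm{obs}/R_\mathrm{exp})$. Waviness removal
regresses each sample's LRR on %GC of 1-Mbp marker-centered windows
(truncated at contig ends, N bases excluded from numerator and denominator)
and keeps residuals; the operation is idempotent and exactly orthogonalizes
LRR to %GC. A constant %GC regressor degenerates to mean-centering.

## qPCR

Relative quantification assumes doubling per cycle:
$\Delta Ct = \overline{Ct}_\mathrm{cnv} - \overline{Ct}_\mathrm{ref}$ per
sample, $\Delta\Delta Ct$ against a designated copy-neutral calibrator, and
$RQ = 2^{-\Delta\Delta Ct}$. Replicates are aggregated by the arithmetic
mean; a replicate SD above 0.5 Ct flags (never drops) the sample. Group
summaries report mean +/- sample SD ordered 0/1/2/control.

## The simulator and what it does (not) emulate

`simulate_phased_population()` builds each haplotype as a mosaic of a small
founder pool, switching founders with probability `recomb_rate_per_marker`
at each interval. One founder carries the 9-marker tag haplotype
`TCCTCCAAC`; its sampling weight on the tag chromosome is iteratively
re-adjusted until the realized tag frequency is within 0.02 of the target
(0.165 by default). Diploid CNVR copy number is
`2 * baseline_copies_per_chrom + extra_copies_per_tag_chrom * tag_count`
(default 4 and 1: all indicine samples share a baseline gain, tag
chromosomes add more), while taurine controls carry exactly 2 copies.

Two calibration choices deserve explanation:

* **LD scale.** Defaults are 4 founders and a switch rate of 0.05 per
  5-kbp marker interval, so haplotype-sharing correlation decays on the
  tens-of-kbp scale that sliding-window mapping resolution depends on.
  After the 5-95% frequency filter the median number of tested haplotype
  alleles per six-marker window is 4. A single-draw mosaic cannot
  simultaneously reproduce low *raw* window diversity and short-range LD;
  we prioritize the LD scale because it controls where the top window can
  land.
* **Polygenic background.** The simulated panel compresses a ~500k-marker
  genome into 5,000 markers, which would inflate the share of polygenic
  variance taggable by any single window by two orders of magnitude if
  polygenic effects were attached to the panel markers: individual founder
  segments would become QTLs larger than the focal CNV, contradicting the
  single-QTL landscape this scenario represents. The default therefore
  draws the polygenic term as an *unlinked* background (independent animal
  effects), keeping per-window background variance negligible as it is on
  a real high-density panel; `polygenic = "panel"` restores marker-attached
  effects for studies of that regime. A consequence is that the default
  scenario exercises no cryptic-relatedness confounding; the mixed model's
  variance-absorption is validated separately by the h2-recovery
  experiment.

EBVs are generated from the definitional property of reliability
(`EBV = r2 * BV + e`, `var(e) = r2(1-r2) var(BV)`), with reliabilities
uniform on [0.5, 0.9] — a plausible post-accuracy-filter range. The
realized polygenic variance is rescaled to exactly its target so that
recovery experiments measure estimator error, not simulation noise. The
default CNV effect is sized analytically so the standardized tag count
explains `cnv_var_frac` (2%) of the pseudo-phenotype variance:
`per_count = sqrt(f * h2 * E[1/r2] / (2p(1-p)))` with `E[1/r2]` the mean
inverse reliability of the uniform range.

Sequencing depth is per-base Poisson at `mean_depth * copies/2` (9x
diploid by default, read length 100, insert 400 +/- 50); read pairs are
drawn from the tandem-duplicated allele sequence and projected back to the
single-copy reference, discarding reads that would map discontiguously
across a junction (as an aligner would clip them). Probe intensities scale
cluster R by `copies/2` and multiply by `2^(wave + noise)` where the wave
is a sinusoid in phase with the reference's GC composition (amplitude 0.2
LRR units by default). qPCR cycle thresholds follow
`Ct = a - log2(copies) + N(0, 0.3)`.

Not emulated: sequencing errors, mapping ambiguity, array batch effects,
selection or mutation demography, regional variation in haplotype
diversity, and relatedness confounding (see above). Passing tests on this
generator therefore demonstrate the *algorithms*, not robustness to every
artifact of real data.

## Problem sizes and the localization experiment

The reference scenario used by the experiments is 500 animals, 5
chromosomes of 1,000 markers at 5-kbp spacing, tag frequency 0.165, CNV
effect at 2% of pseudo-phenotype variance; 20 seeded replicates. At this
size a full GWAS replicate (QC, window coding, deregression, 5 LOCO
AI-REML fits and ~15,000 GLS tests) runs in ~10 s.

One property deserves a frank statement. With the effect at 2% of variance
and n = 500, the tag's Wald non-centrality is about
$n f/(1-f) \approx 10$, whereas the maximum of ~15,000 null tests sits
around 13-16; the most significant window can therefore coincide with the
tag span only in a minority of replicates, and
`localization_experiment()` reports rates near 0.15. This is a power
ceiling of the scaled-down scenario, not an implementation limit: the
original signal (p ~ 1e-9 at n ~ 2,000) has non-centrality ~42, and
re-running the identical experiment with the variance fraction rescaled to
preserve that non-centrality at n = 500 (`cnv_var_frac = 0.0775`)
localizes the tag in 20/20 replicates with top p-values on the 1e-9 scale.
Both rates are computed by `scripts/acceptance.R`.

## Numerical conventions and edge cases

* Coordinates are 1-based inclusive in all TSVs; BED output is 0-based
  half-open, converted only at the I/O boundary.
* Standardization of haplotype counts and `variance_explained()` use
  population (denominator n) moments.
* p-values are floored at the smallest positive double; zero-variance
  pseudo-markers are skipped with a warning.
* Ties among top windows are declared at 3 significant figures of p.
* Chromosome labels are opaque strings ordered by appearance; X/Y/XY/MT
  are dropped by label during QC.
* All generators take explicit seeds and save/restore the global RNG
  state; identical seeds give bit-identical outputs.
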