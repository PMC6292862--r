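# haplocnv

Haplotype-based mixed-model GWAS and read-depth copy-number discovery for
livestock genomics.

## What it is for

Visual scores of navel length in indicine beef cattle are heritable, and
the strongest known association maps to a haplotype that tags a tandem
copy-number variant (CNV) invisible to single-SNP GWAS and to SNP-array
intensity segmentation. `haplocnv` implements the full evidence chain that
resolves such a signal, for anyone mapping quantitative traits with
pseudo-phenotypes (deregressed EBVs) in structured populations:

* **Haplotype sliding-window GWAS** under the LOCO mixed linear model
  `y = 1μ + xb + u + e`, `y ~ N(1μ + xb, Gσ²u + Iσ²e)`, where `x` counts
  copies (0/1/2) of a window haplotype allele, and `G` is the SNP genomic
  relationship matrix `ZZ'/2Σp(1−p)` excluding the tested chromosome.
  Variance components by AI-REML (EM fallback, monotone in the restricted
  likelihood); per-window tests by GLS after one eigendecomposition per
  chromosome; Bonferroni control `α/N`; tied top windows merge into a
  consensus allele.
* **Deregression** of EBVs (`debv = ebv/r²`, or full parent-average
  removal), accuracy filtering, and regression weights
  `(1−h²)/((c+(1−r²)/r²)h²)`.
* **Read-depth CNV calling**: per-base coverage normalized by sample
  coverage, group means by haplotype count, 1-kbp bin medians, gain calls
  at fold ≥ 1.5, cross-breed copy-neutral comparison.
* **Tandem-duplication read-pair test**: outward-oriented pairs with
  apparent insert ≈ unit length.
* **Probe-intensity analysis**: LRR from canonical-cluster interpolation,
  GC-wave correction by per-sample regression on %GC.
* **qPCR 2^−ΔΔCt** relative quantification with triplicates and a
  copy-neutral calibrator.
* **A founder-mosaic simulator** generating every input (phased genotypes,
  EBVs with reliabilities, per-base depth, read pairs, X/Y intensities,
  qPCR plates, reference FASTA) with known ground truth.

File formats: PLINK-1 bed/bim/fam, Oxford haps/sample, SAM text, BED,
FASTA, and plain TSVs. All TSV coordinates are 1-based inclusive; BED is
0-based half-open.

## Worked example

Simulate the demo scenario (150 animals, 2 chromosomes) and run the whole
pipeline:

```r
library(haplocnv)
pl <- run_pipeline(demo_config(seed = 1))

pl$top[, c("chrom", "start_bp", "end_bp", "allele", "freq", "p")]
#>      chrom start_bp end_bp allele freq            p
#> 1397     2   755000 795000 TCTCAC 0.18 4.410157e-07

pl$cnv_calls
#>   chrom start_bp end_bp classification fold_0 fold_1 fold_2
#> 1     2   799923 805922           gain      4    4.5      5

pl$sv_vote$verdict
#> [1] "tandem_duplication"

pl$qpcr_summary
#>     group n   mean_rq     sd_rq flagged
#> 1       0 4 4.3669108 0.3838144   FALSE
#> 2       1 4 4.6628298 1.2347595   FALSE
#> 3       2 4 5.2792711 0.5368012   FALSE
#> 4 control 4 0.9588648 0.1438782   FALSE
```

Reading the output: the scan's top window coincides exactly with the
simulated 9-marker tag span (755–795 kbp on chromosome 2; the six retained
markers straddle QC-dropped ones, so the window is wider than 25 kbp and
its allele string subsets the tag letters), at haplotype frequency 0.18
and `variance_explained()` of 17% against a simulated 20%. The depth stage
calls a ~6-kbp gain whose per-group folds rise with tag count (4 → 4.5 → 5
on the normalized scale where 1.0 is diploid-average); the read-pair vote
classifies the gain as a tandem duplication; and qPCR relative
quantification is ~copies/2 per group (8/9/10 copies → ~4/4.7/5.3) with
taurine controls near 1.

The reference experiment scale (500 animals, 5 × 1,000 markers) and every
tunable threshold are documented in the methods vignette
(`vignettes/haplotype-gwas-cnv-discovery.Rmd`).

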