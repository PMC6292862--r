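#' Simulation scenario configuration
#'
#' Bundles every parameter of the synthetic cattle-genomics scenario: a
#' founder-mosaic phased SNP population carrying a 9-marker tag haplotype, a
#' linked multi-copy CNV region with a baseline copy gain in all indicine
#' samples plus extra copies co-segregating with the tag, polygenic breeding
#' values observed through EBVs of known reliability, Poisson read depth
#' proportional to local copy number, tandem-duplication read pairs, SNP probe
#' intensities with GC waves, and qPCR plates.
#'
#' Defaults describe the reference scenario used throughout the package's
#' tests: 500 animals, 5 chromosomes of 1,000 markers at 5 kbp spacing,
#' a tag haplotype at frequency 0.165 on the last chromosome, a 6,210-bp CNV
#' at 4 baseline copies per chromosome plus 1 extra copy per tag chromosome,
#' and a CNV effect sized so the standardized tag count explains about 2% of
#' the pseudo-phenotype variance.
#'
#' @param n_samples Number of diploid animals.
#' @param n_markers Total marker count (split evenly across chromosomes).
#' @param n_chromosomes Number of autosomes.
#' @param founder_count Size of the founder haplotype pool.
#' @param recomb_rate_per_marker Per-interval probability that a sample
#'   haplotype switches founder template.
#' @param marker_spacing Base pairs between adjacent markers.
#' @param tag_locus Integer vector of 9 global marker indices forming the tag
#'   haplotype span; default centers it on the last chromosome.
#' @param tag_target_freq Target population frequency of the tag haplotype.
#' @param cnvr_span Length-2 bp interval (start, end; half-open length
#'   end - start) of the CNV region on the tag chromosome; default places a
#'   6,210-bp unit shortly downstream of the tag span.
#' @param baseline_copies_per_chrom CNVR copies on every indicine chromosome
#'   regardless of tag status (>= 1; the reference carries 1).
#' @param extra_copies_per_tag_chrom Additional CNVR copies on each
#'   tag-carrying chromosome (integer >= 0).
#' @param h2 Heritability of the trait, i.e. variance of true breeding values
#'   on the unit phenotypic scale.
#' @param cnv_effect Trait units per diploid CNVR copy. `NULL` sizes it so
#'   the tag explains `cnv_var_frac` of pseudo-phenotype variance.
#' @param cnv_var_frac Target variance fraction used when `cnv_effect` is
#'   `NULL`.
#' @param reliability_range Range `[low, high]` in (0,1] from which EBV
#'   reliabilities are drawn uniformly.
#' @param mean_depth Mean sequencing depth (reads per base) at diploid copy
#'   number 2.
#' @param read_len Read length in bp.
#' @param insert_mean,insert_sd Sequencing insert (fragment) size moments, bp.
#' @param gc_wave_amplitude Amplitude, in LRR units, of the sinusoidal
#'   GC-correlated intensity wave.
#' @param intensity_noise_sd Gaussian LRR-scale noise added to probe
#'   intensities.
#' @param qpcr_sd Replicate-level Ct standard deviation.
#' @param seed Integer seed; all generators derive their streams from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 500L,
                       n_markers = 5000L,
                       n_chromosomes = 5L,
                       founder_count = 4L,
                       recomb_rate_per_marker = 0.05,
                       marker_spacing = 5000L,
                       tag_locus = NULL,
                       tag_target_freq = 0.165,
                       cnvr_span = NULL,
                       baseline_copies_per_chrom = 4L,
                       extra_copies_per_tag_chrom = 1L,
                       h2 = 0.3,
                       cnv_effect = NULL,
                       cnv_var_frac = 0.02,
                       reliability_range = c(0.5, 0.9),
                       mean_depth = 9,
                       read_len = 100L,
                       insert_mean = 400,
                       insert_sd = 50,
                       gc_wave_amplitude = 0.2,
                       intensity_noise_sd = 0.05,
                       qpcr_sd = 0.3,
                       seed = 1L) {
  counts <- c(n_samples = n_samples, n_markers = n_markers,
              n_chromosomes = n_chromosomes, founder_count = founder_count,
              marker_spacing = marker_spacing, read_len = read_len)
  if (any(counts < 1) || any(counts != floor(counts))) {
    stop("all counts must be positive integers", call. = FALSE)
  }
  if (n_markers %% n_chromosomes != 0) {
    stop("`n_markers` must be divisible by `n_chromosomes`", call. = FALSE)
  }
  stop_if_not_scalar_prob(recomb_rate_per_marker, "recomb_rate_per_marker")
  stop_if_not_scalar_prob(tag_target_freq, "tag_target_freq",
                          lo = 0.05, hi = 0.95, open_lo = TRUE, open_hi = TRUE)
  stop_if_not_scalar_prob(h2, "h2", open_lo = TRUE, open_hi = TRUE)
  stopifnot(length(reliability_range) == 2L,
            reliability_range[1] > 0, reliability_range[2] <= 1,
            reliability_range[1] <= reliability_range[2])
  stopifnot(mean_depth > 0, insert_mean > 0, insert_sd > 0,
            baseline_copies_per_chrom >= 1,
            extra_copies_per_tag_chrom >= 0,
            extra_copies_per_tag_chrom == floor(extra_copies_per_tag_chrom),
            gc_wave_amplitude >= 0, intensity_noise_sd >= 0, qpcr_sd >= 0)

  m_chr <- n_markers %/% n_chromosomes
  chrom_labels <- as.character(seq_len(n_chromosomes))
  tag_chrom <- chrom_labels[n_chromosomes]
  if (is.null(tag_locus)) {
    first_on_chrom <- (n_chromosomes - 1L) * m_chr + 1L
    mid <- first_on_chrom + m_chr %/% 2L
    tag_locus <- seq.int(mid, mid + 8L)
  }
  tag_locus <- as.integer(tag_locus)
  if (length(tag_locus) != 9L || any(diff(tag_locus) != 1L)) {
    stop("`tag_locus` must be 9 consecutive marker indices", call. = FALSE)
  }
  chrom_of <- function(i) chrom_labels[(i - 1L) %/% m_chr + 1L]
  if (length(unique(chrom_of(tag_locus))) != 1L) {
    stop("`tag_locus` must not span a chromosome boundary", call. = FALSE)
  }
  pos_of <- function(i) as.integer(((i - 1L) %% m_chr + 1L)) * marker_spacing
  if (is.null(cnvr_span)) {
    # anchor deliberately off the kbp grid, as real breakpoints are; at the
    # default 5-kbp marker spacing the unit straddles exactly two array SNPs
    start <- pos_of(tag_locus[9L]) + 4923L
    cnvr_span <- c(start, start + 6210L)
  }
  stopifnot(length(cnvr_span) == 2L, cnvr_span[1] < cnvr_span[2])
  if (chrom_of(tag_locus[1L]) != tag_chrom) tag_chrom <- chrom_of(tag_locus[1L])

  if (is.null(cnv_effect)) {
    # Size the effect so that var(std tag count * effect) is cnv_var_frac of
    # the pseudo-phenotype variance: debv = EBV / r2 has variance
    # var(BV) * E[1/r2]; with var(BV) = h2 and tag-count variance 2p(1-p).
    lo <- reliability_range[1]; hi <- reliability_range[2]
    e_inv_r2 <- if (hi > lo) (log(hi) - log(lo)) / (hi - lo) else 1 / lo
    p <- tag_target_freq
    per_count <- sqrt(cnv_var_frac * h2 * e_inv_r2 / (2 * p * (1 - p)))
    ec <- max(1L, as.integer(extra_copies_per_tag_chrom))
    cnv_effect <- per_count / ec
  }

  cfg <- list(
    n_samples = as.integer(n_samples), n_markers = as.integer(n_markers),
    n_chromosomes = as.integer(n_chromosomes),
    founder_count = as.integer(founder_count),
    recomb_rate_per_marker = recomb_rate_per_marker,
    marker_spacing = as.integer(marker_spacing),
    tag_locus = tag_locus, tag_chrom = tag_chrom,
    tag_target_freq = tag_target_freq,
    cnvr_span = as.numeric(cnvr_span),
    baseline_copies_per_chrom = as.integer(baseline_copies_per_chrom),
    extra_copies_per_tag_chrom = as.integer(extra_copies_per_tag_chrom),
    h2 = h2, cnv_effect = cnv_effect, cnv_var_frac = cnv_var_frac,
    reliability_range = as.numeric(reliability_range),
    mean_depth = mean_depth, read_len = as.integer(read_len),
    insert_mean = insert_mean, insert_sd = insert_sd,
    gc_wave_amplitude = gc_wave_amplitude,
    intensity_noise_sd = intensity_noise_sd,
    qpcr_sd = qpcr_sd, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_samples, "samples,", x$n_markers, "markers on",
      x$n_chromosomes, "chromosomes\n")
  cat("  tag haplotype: chrom", x$tag_chrom, "markers",
      x$tag_locus[1], "-", x$tag_locus[9],
      sprintf("target freq %.3f", x$tag_target_freq), "\n")
  cat(sprintf("  CNVR: %s:%d-%d (%.1f kbp), %d baseline + %d per tag chrom\n",
              x$tag_chrom, x$cnvr_span[1], x$cnvr_span[2],
              (x$cnvr_span[2] - x$cnvr_span[1]) / 1000,
              x$baseline_copies_per_chrom, x$extra_copies_per_tag_chrom))
  cat(sprintf("  h2 %.2f, cnv effect %.4f / copy, seed %d\n",
              x$h2, x$cnv_effect, x$seed))
  invisible(x)
}
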