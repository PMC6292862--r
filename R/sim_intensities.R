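#' Simulate a reference sequence with sinusoidal GC composition
#'
#' Base composition varies along each chromosome as
#' `P(GC at pos) = gc_base + gc_amp * sin(2 pi pos / gc_period)`, generated
#' in 1-kbp chunks. The same sinusoid drives the intensity waves injected by
#' [simulate_intensities()], so LRR and local %GC are correlated, as in
#' arrays affected by genomic waves.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param gc_base,gc_amp Mean and amplitude of the GC fraction sinusoid.
#' @param gc_period Wavelength in bp (default 2 Mbp).
#' @param seed Integer seed.
#' @return A `Biostrings::DNAStringSet`; the wave parameters are attached as
#'   attributes `gc_period`, `gc_base`, `gc_amp`.
#' @export
simulate_reference <- function(chrom_lengths, gc_base = 0.42, gc_amp = 0.16,
                               gc_period = 2e6, seed = 1L) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 0),
            gc_base - gc_amp > 0, gc_base + gc_amp < 1)
  with_seed(seed, {
    seqs <- vapply(names(chrom_lengths), function(ch) {
      len <- chrom_lengths[[ch]]
      nchunk <- ceiling(len / 1000)
      chunks <- vapply(seq_len(nchunk), function(k) {
        mid <- (k - 0.5) * 1000
        g <- gc_base + gc_amp * sin(2 * pi * mid / gc_period)
        nb <- min(1000L, len - (k - 1L) * 1000L)
        paste(sample(c("A", "T", "G", "C"), nb, replace = TRUE,
                     prob = c((1 - g) / 2, (1 - g) / 2, g / 2, g / 2)),
              collapse = "")
      }, "")
      paste(chunks, collapse = "")
    }, "")
    out <- Biostrings::DNAStringSet(seqs)
    attr(out, "gc_period") <- gc_period
    attr(out, "gc_base") <- gc_base
    attr(out, "gc_amp") <- gc_amp
    out
  })
}

#' Simulate SNP probe intensities with canonical clusters and GC waves
#'
#' Each SNP gets fixed canonical cluster centroids (theta_AA < theta_AB <
#' theta_BB with per-cluster R values). A sample's theta sits at its
#' genotype's cluster theta; its total intensity is the cluster R scaled by
#' `local_copies / 2` (local diploid copy number from the ground truth at
#' SNPs inside the CNV region, 2 elsewhere), multiplied by
#' `2^(wave + noise)`: an additive LRR-scale sinusoidal wave (amplitude
#' `cfg$gc_wave_amplitude`, in phase with the reference's GC sinusoid) plus
#' Gaussian LRR noise (`cfg$intensity_noise_sd`).
#'
#' @param geno A `phased_geno`.
#' @param truth Ground truth aligned with `geno$samples`.
#' @param cfg A [sim_config()].
#' @param fasta Reference from [simulate_reference()] (supplies the wave
#'   phase); must contain every simulated chromosome.
#' @param chroms Chromosomes to simulate (default: the tag chromosome only).
#' @param seed Optional seed overriding `cfg$seed + 3`.
#' @return List: `intensities` (snp, sample, x, y), `clusters` (snp,
#'   theta_aa, r_aa, theta_ab, r_ab, theta_bb, r_bb), `map` (snp, chrom,
#'   pos).
#' @export
simulate_intensities <- function(geno, truth, cfg, fasta,
                                 chroms = NULL, seed = NULL) {
  stopifnot(inherits(geno, "phased_geno"), inherits(cfg, "sim_config"))
  if (!identical(truth$sample, geno$samples)) {
    stop("truth is not aligned to the genotype samples", call. = FALSE)
  }
  chroms <- chroms %||% cfg$tag_chrom
  names(fasta) <- sub("\\s.*$", "", names(fasta))
  miss <- setdiff(chroms, names(fasta))
  if (length(miss) > 0L) {
    stop("FASTA is missing chromosome(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  period <- attr(fasta, "gc_period") %||% 2e6
  with_seed(seed %||% (cfg$seed + 3L), {
    sel <- which(geno$map$chrom %in% chroms)
    map <- geno$map[sel, , drop = FALSE]
    m <- length(sel)
    n <- length(geno$samples)
    D <- dosages(geno)[, sel, drop = FALSE]

    theta_k <- cbind(runif(m, 0.05, 0.15), runif(m, 0.45, 0.55),
                     runif(m, 0.85, 0.95))
    r_base <- runif(m, 1.5, 2.5)
    r_k <- r_base * matrix(runif(3L * m, 0.9, 1.1), ncol = 3L)
    clusters <- data.frame(snp = map$id,
                           theta_aa = theta_k[, 1L], r_aa = r_k[, 1L],
                           theta_ab = theta_k[, 2L], r_ab = r_k[, 2L],
                           theta_bb = theta_k[, 3L], r_bb = r_k[, 3L],
                           stringsAsFactors = FALSE)

    in_cnvr <- map$chrom == cfg$tag_chrom &
      map$pos >= cfg$cnvr_span[1] & map$pos < cfg$cnvr_span[2]
    wave <- cfg$gc_wave_amplitude * sin(2 * pi * map$pos / period)

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      gt <- D[i, ] + 1L                    # 1 = AA, 2 = AB, 3 = BB
      th <- theta_k[cbind(seq_len(m), gt)]
      r_cl <- r_k[cbind(seq_len(m), gt)]
      copies_local <- ifelse(in_cnvr, truth$copies[i], 2)
      r_obs <- r_cl * (copies_local / 2) *
        2^(wave + rnorm(m, 0, cfg$intensity_noise_sd))
      ratio <- tan(th * pi / 2)
      x <- r_obs / (1 + ratio)
      y <- r_obs - x
      rows[[i]] <- data.frame(snp = map$id, sample = geno$samples[i],
                              x = x, y = y, stringsAsFactors = FALSE)
    }
    list(intensities = do.call(rbind, rows), clusters = clusters,
         map = data.frame(snp = map$id, chrom = map$chrom, pos = map$pos,
                          stringsAsFactors = FALSE))
  })
}
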