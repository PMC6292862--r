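#' Simulate a phased SNP population as founder-haplotype mosaics
#'
#' Generates `2 * n_samples` haplotypes per chromosome as mosaics of a small
#' founder pool: each haplotype copies one founder and switches to a randomly
#' chosen founder with probability `recomb_rate_per_marker` at every marker
#' interval. This reproduces the window-scale haplotype sharing (linkage
#' disequilibrium) that sliding-window association testing relies on, without
#' a full coalescent model.
#'
#' One founder carries the 9-marker tag haplotype `TCCTCCAAC` across
#' `cfg$tag_locus`; its sampling weight on the tag chromosome is re-adjusted
#' until the realized population frequency of the tag haplotype is within
#' 0.02 of `cfg$tag_target_freq`. All other founders are guaranteed not to
#' match the tag pattern. Each sample's diploid copy number at the CNV region
#' is `2 * baseline_copies_per_chrom + extra_copies_per_tag_chrom * tag_count`.
#'
#' @param cfg A [sim_config()].
#' @return A list with components:
#'   \describe{
#'     \item{geno}{A `phased_geno` object: `samples`, a marker `map`
#'       (id, chrom, pos, allele_a, allele_b, call_rate, maf, gentrain) and
#'       the haplotype matrix `H` (`2n x m`, 0 = allele_a, 1 = allele_b;
#'       sample `i` occupies rows `2i-1` and `2i`).}
#'     \item{truth}{Ground-truth data frame: sample, tag_count (0/1/2),
#'       copies (diploid CNVR copy number), breed. Attributes record the tag
#'       pattern, realized tag frequency, tag span and CNVR interval.}
#'   }
#' @export
simulate_phased_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, simulate_phased_population_impl(cfg))
}

TAG_PATTERN <- c("T", "C", "C", "T", "C", "C", "A", "A", "C")

simulate_phased_population_impl <- function(cfg) {
  n <- cfg$n_samples
  m <- cfg$n_markers
  n_chr <- cfg$n_chromosomes
  m_chr <- m %/% n_chr
  fc <- cfg$founder_count
  r <- cfg$recomb_rate_per_marker

  chrom <- rep(as.character(seq_len(n_chr)), each = m_chr)
  pos <- rep(seq_len(m_chr) * cfg$marker_spacing, times = n_chr)
  tag_idx <- cfg$tag_locus
  tag_chr <- chrom[tag_idx[1L]]

  # biallelic letters; tag markers carry the tag letter as allele B
  bases <- c("A", "C", "G", "T")
  allele_b <- sample(bases, m, replace = TRUE)
  allele_b[tag_idx] <- TAG_PATTERN
  allele_a <- vapply(allele_b, function(b) sample(setdiff(bases, b), 1L), "")

  # founder pool: founder 1 is the tag carrier
  founders <- matrix(rbinom(fc * m, 1L, 0.5), nrow = fc, ncol = m)
  founders[1L, tag_idx] <- 1L
  if (fc > 1L) {
    for (f in 2L:fc) {
      if (all(founders[f, tag_idx] == 1L)) {
        flip <- sample(tag_idx, 1L)
        founders[f, flip] <- 0L
      }
    }
  }

  gen_chrom <- function(cols, w) {
    mc <- length(cols)
    fchr <- founders[, cols, drop = FALSE]
    H <- matrix(0L, nrow = 2L * n, ncol = mc)
    for (h in seq_len(2L * n)) {
      sw <- if (r > 0) which(runif(mc - 1L) < r) else integer(0)
      seg_len <- diff(c(0L, sw, mc))
      fid <- sample.int(fc, length(seg_len), replace = TRUE, prob = w)
      H[h, ] <- fchr[cbind(rep.int(fid, seg_len), seq_len(mc))]
    }
    H
  }

  uniform_w <- rep(1 / fc, fc)
  H <- matrix(0L, nrow = 2L * n, ncol = m)
  tag_cols <- which(chrom == tag_chr)
  tag_local <- match(tag_idx, tag_cols)

  for (c_lab in unique(chrom)) {
    cols <- which(chrom == c_lab)
    if (c_lab != tag_chr) {
      H[, cols] <- gen_chrom(cols, uniform_w)
    }
  }

  # tag chromosome: reweight founder 1 until the realized tag frequency lands
  # within +/- 0.02 of target (skipped for the degenerate one-founder pool)
  target <- cfg$tag_target_freq
  if (fc == 1L) {
    H[, tag_cols] <- gen_chrom(tag_cols, uniform_w)
    realized <- 1
  } else {
    intact <- (1 - r)^(length(tag_idx) - 1L)
    w1 <- min(0.95, target / max(intact, 1e-6))
    realized <- NA_real_
    for (try in seq_len(25L)) {
      w <- c(w1, rep((1 - w1) / (fc - 1L), fc - 1L))
      Hc <- gen_chrom(tag_cols, w)
      is_tag <- rowSums(Hc[, tag_local, drop = FALSE] == 1L) == length(tag_idx)
      realized <- mean(is_tag)
      if (abs(realized - target) <= 0.02) {
        H[, tag_cols] <- Hc
        break
      }
      w1 <- min(0.999, max(0.001, w1 * target / max(realized, 1e-4)))
      if (try == 25L) {
        stop(sprintf(
          "could not reach tag haplotype frequency %.3f after 25 retries (achieved %.3f)",
          target, realized), call. = FALSE)
      }
    }
  }

  is_tag_hap <- rowSums(H[, tag_idx, drop = FALSE] == 1L) == length(tag_idx)
  tag_count <- is_tag_hap[seq(1L, 2L * n, by = 2L)] +
    is_tag_hap[seq(2L, 2L * n, by = 2L)]
  copies <- 2L * cfg$baseline_copies_per_chrom +
    cfg$extra_copies_per_tag_chrom * tag_count

  samples <- sprintf("NEL%04d", seq_len(n))
  af_b <- colMeans(H)
  maf <- pmin(af_b, 1 - af_b)
  call_rate <- rbeta(m, 40, 1)
  gentrain <- rbeta(m, 20, 2)
  # the tag panel is defined on post-QC markers; keep its span QC-clean
  call_rate[tag_idx] <- pmax(call_rate[tag_idx], 0.99)
  gentrain[tag_idx] <- pmax(gentrain[tag_idx], 0.90)

  map <- data.frame(
    id = sprintf("M%s_%06d", chrom, pos),
    chrom = chrom, pos = pos,
    allele_a = allele_a, allele_b = allele_b,
    call_rate = call_rate, maf = maf, gentrain = gentrain,
    stringsAsFactors = FALSE
  )

  geno <- new_phased_geno(samples, map, H)

  truth <- data.frame(
    sample = samples,
    tag_count = as.integer(tag_count),
    copies = as.integer(copies),
    breed = "indicine",
    stringsAsFactors = FALSE
  )
  attr(truth, "tag_pattern") <- paste(TAG_PATTERN, collapse = "")
  attr(truth, "tag_freq_realized") <- mean(is_tag_hap)
  attr(truth, "tag_span_bp") <- c(pos[tag_idx[1L]], pos[tag_idx[9L]])
  attr(truth, "tag_chrom") <- tag_chr
  attr(truth, "cnvr_span") <- cfg$cnvr_span

  list(geno = geno, truth = truth)
}

#' Ground truth for copy-neutral control animals
#'
#' Taurine controls carry exactly two CNVR copies and no tag haplotype.
#'
#' @param n_samples Number of control animals.
#' @param breed Breed label for the controls.
#' @return A ground-truth data frame compatible with the sequencing, probe
#'   intensity and qPCR generators.
#' @export
control_truth <- function(n_samples, breed = "taurine") {
  data.frame(
    sample = sprintf("%s%04d", toupper(substr(breed, 1, 3)), seq_len(n_samples)),
    tag_count = 0L,
    copies = 2L,
    breed = breed,
    stringsAsFactors = FALSE
  )
}
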