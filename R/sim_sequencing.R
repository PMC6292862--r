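#' Simulate per-base read depth and read pairs over a CNV region
#'
#' Depth: per-base read counts are Poisson with rate
#' `mean_depth * local_copies / 2`, where local diploid copy number equals
#' each sample's `copies` inside the CNV unit (half-open
#' `[cnvr_start, cnvr_end)`) and 2 elsewhere.
#'
#' Read pairs: fragments are drawn from each chromosome's *tandem-duplicated
#' allele sequence* (the CNV unit repeated `copies_per_chrom` times in situ)
#' and their read coordinates are projected back onto the reference, which
#' carries a single copy of the unit. Fragments spanning a repeat junction
#' therefore project as apparently long, outward-facing (-/+) pairs whose
#' inferred insert is close to the unit length, while copy-neutral material
#' yields inward (+/-) pairs with insert ~ Normal(insert_mean, insert_sd).
#' Reads that would map discontiguously across a junction are discarded, as
#' an aligner would soft-clip them.
#'
#' @param truth Ground-truth data frame (sample, tag_count, copies; see
#'   [simulate_phased_population()] / [control_truth()]).
#' @param cfg A [sim_config()].
#' @param region Length-2 bp interval to profile; must contain
#'   `cfg$cnvr_span` and be longer than `insert_mean`. Default: the CNV unit
#'   plus 30 kbp of copy-neutral flank on each side.
#' @param seed Optional seed overriding `cfg$seed + 2`.
#' @return A list: `region`, `chrom`, `depth` (`bases x samples` integer
#'   matrix, row 1 = `region[1]`), `pairs` (sample, chrom, left_pos,
#'   right_pos, left_strand, right_strand, inferred_insert), `samples`.
#' @export
simulate_coverage_and_pairs <- function(truth, cfg, region = NULL,
                                        seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  cnvr <- cfg$cnvr_span
  region <- region %||% c(cnvr[1] - 30000, cnvr[2] + 30000)
  stopifnot(length(region) == 2L, region[1] < region[2])
  if (region[2] - region[1] <= cfg$insert_mean) {
    stop("region must be longer than the mean insert size", call. = FALSE)
  }
  if (region[1] > cnvr[1] || region[2] < cnvr[2]) {
    stop("region must contain the CNV span", call. = FALSE)
  }
  with_seed(seed %||% (cfg$seed + 2L), {
    n <- nrow(truth)
    rl <- cfg$read_len
    unit_len <- cnvr[2] - cnvr[1]
    reg_len <- as.integer(region[2] - region[1] + 1)
    off <- as.integer(cnvr[1] - region[1])   # 0-based unit start offset
    pos0 <- as.integer(region[1])

    in_cnvr <- seq_len(reg_len) > off & seq_len(reg_len) <= off + unit_len

    depth <- matrix(0L, nrow = reg_len, ncol = n,
                    dimnames = list(NULL, truth$sample))
    lam_neutral <- cfg$mean_depth
    for (i in seq_len(n)) {
      lam <- rep(lam_neutral, reg_len)
      lam[in_cnvr] <- cfg$mean_depth * truth$copies[i] / 2
      depth[, i] <- rpois(reg_len, lam)
    }

    hap_copies <- per_chrom_copies(truth, cfg)
    pair_rows <- vector("list", n)
    for (i in seq_len(n)) {
      pr <- lapply(hap_copies[[i]], function(ch_copies) {
        sim_hap_pairs(ch_copies, reg_len, off, unit_len, pos0, cfg)
      })
      pr <- do.call(rbind, pr)
      if (!is.null(pr) && nrow(pr) > 0L) pr$sample <- truth$sample[i]
      pair_rows[[i]] <- pr
    }
    pairs <- do.call(rbind, pair_rows)
    if (is.null(pairs)) {
      pairs <- data.frame(sample = character(), chrom = character(),
                          left_pos = integer(), right_pos = integer(),
                          left_strand = character(), right_strand = character(),
                          inferred_insert = integer())
    } else {
      pairs <- pairs[, c("sample", "chrom", "left_pos", "right_pos",
                         "left_strand", "right_strand", "inferred_insert")]
      rownames(pairs) <- NULL
    }
    list(region = region, chrom = cfg$tag_chrom, depth = depth,
         pairs = pairs, samples = truth$sample)
  })
}

# split a sample's diploid CNVR copy number into per-chromosome unit counts;
# tag-carrying chromosomes receive the extra copies
per_chrom_copies <- function(truth, cfg) {
  e <- cfg$extra_copies_per_tag_chrom
  lapply(seq_len(nrow(truth)), function(i) {
    tc <- truth$tag_count[i]
    base_total <- truth$copies[i] - e * tc
    b1 <- ceiling(base_total / 2)
    b2 <- base_total - b1
    c(b1 + e * (tc >= 1L), b2 + e * (tc == 2L))
  })
}

# fragments from one chromosome whose CNV unit appears `copies` times
sim_hap_pairs <- function(copies, reg_len, off, unit_len, pos0, cfg) {
  rl <- cfg$read_len
  allele_len <- reg_len + (copies - 1L) * unit_len
  n_frag <- rpois(1L, cfg$mean_depth / 2 * allele_len / (2 * rl))
  if (n_frag == 0L) return(NULL)
  flen <- pmax(2L * rl, as.integer(round(
    rnorm(n_frag, cfg$insert_mean, cfg$insert_sd))))
  fs <- floor(runif(n_frag, 1, allele_len - flen + 1))
  # allele coordinate -> reference 0-based offset
  arr_len <- copies * unit_len
  proj <- function(a) {
    ifelse(a <= off, a - 1,
           ifelse(a <= off + arr_len, off + (a - off - 1) %% unit_len,
                  a - (copies - 1L) * unit_len - 1))
  }
  r1s <- proj(fs); r1e <- proj(fs + rl - 1L)
  r2s <- proj(fs + flen - rl); r2e <- proj(fs + flen - 1L)
  # keep reads whose reference projection is contiguous (aligners would
  # soft-clip reads straddling a repeat junction)
  ok <- (r1e - r1s == rl - 1L) & (r2e - r2s == rl - 1L)
  if (!any(ok)) return(NULL)
  p1 <- r1s[ok]; p2 <- r2s[ok]
  left_is_r1 <- p1 <= p2
  left_pos <- pos0 + ifelse(left_is_r1, p1, p2)
  right_pos <- pos0 + ifelse(left_is_r1, p2, p1)
  # read 1 (fragment left end) is +, read 2 is -
  left_strand <- ifelse(left_is_r1, "+", "-")
  right_strand <- ifelse(left_is_r1, "-", "+")
  inferred_insert <- right_pos + rl - 1L - left_pos + 1L
  data.frame(chrom = cfg$tag_chrom, left_pos = as.integer(left_pos),
             right_pos = as.integer(right_pos),
             left_strand = left_strand, right_strand = right_strand,
             inferred_insert = as.integer(inferred_insert),
             stringsAsFactors = FALSE)
}
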