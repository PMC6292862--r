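# Reproducible study-condition experiments: each runs the full pipeline on
# freshly simulated data and measures a recovery property of the method.

#' Localization experiment: does the scan find the tag haplotype?
#'
#' For each replicate, simulates the reference scenario (500 animals, 5
#' chromosomes of 1,000 markers, tag haplotype near frequency 0.165, CNV
#' effect sized to ~2% of pseudo-phenotype variance), runs marker QC,
#' six-marker window coding, phenotype deregression with the 0.70 accuracy
#' filter and the LOCO mixed-model scan, and records whether the most
#' significant pseudo-marker window overlaps the true 9-marker tag span.
#'
#' @param n_reps Number of seeded replicates (default 20).
#' @param seed Base seed; replicate `i` uses `seed * 1000 + i`.
#' @param cfg_overrides Named list of [sim_config()] overrides (testing
#'   hook; the default empty list is the reference scenario).
#' @return Data frame, one row per replicate: seed, top window coordinates,
#'   top p, realized tag frequency, `overlaps_tag`.
#' @export
localization_experiment <- function(n_reps = 20L, seed = 1L,
                                    cfg_overrides = list()) {
  rows <- lapply(seq_len(n_reps), function(i) {
    cfg <- do.call(sim_config,
                   c(list(seed = seed * 1000L + i), cfg_overrides))
    sim <- simulate_phased_population(cfg)
    geno <- apply_marker_qc(sim$geno)
    win <- build_windows(geno, 6L)
    pm <- code_pseudo_markers(geno, win)
    ph <- simulate_phenotypes(geno, sim$truth, cfg)
    dr <- cbind(ph, deregress(ph$ebv, ph$r2))
    kept <- accuracy_filter(dr, 0.70)
    sub <- match(kept$sample, geno$samples)
    gw <- hap_gwas(geno, pm, kept$debv, sample_subset = sub)
    top <- gw$results[which.min(gw$results$p), ]
    span <- attr(sim$truth, "tag_span_bp")
    data.frame(
      seed = cfg$seed, chrom = top$chrom,
      start_bp = top$start_bp, end_bp = top$end_bp, p = top$p,
      b_hat = top$b_hat,
      var_explained = variance_explained(top$b_hat, kept$debv),
      n_tests = gw$n_tests,
      tag_freq = attr(sim$truth, "tag_freq_realized"),
      overlaps_tag = top$chrom == attr(sim$truth, "tag_chrom") &
        top$end_bp >= span[1] & top$start_bp <= span[2],
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Null-calibration experiment: p-value uniformity with no genetic effect
#'
#' Simulates the reference scenario with the CNV effect removed and a
#' near-zero heritability so the pseudo-phenotype is essentially noise, runs
#' the full scan, and tests the p-values against Uniform(0,1) by
#' Kolmogorov-Smirnov. The KS test is applied to a decorrelated subset (the
#' first haplotype allele of every `spacing`-th window): complementary
#' alleles of a two-allele window share an identical p-value and overlapping
#' windows are LD-correlated, and under such dependence a whole-scan KS test
#' rejects even for a perfectly calibrated method — marginal calibration is
#' the property of interest.
#'
#' @param seed Simulation seed.
#' @param spacing Marker spacing between sampled windows (default 50,
#'   beyond the haplotype-sharing correlation range of the generator).
#' @return List: `p_values` (decorrelated subset), `ks_p` (KS test
#'   p-value), `lambda_gc` (genomic-control inflation factor over the full
#'   scan), `n_tests` (size of the subset), `n_tests_total`.
#' @export
null_pvalue_experiment <- function(seed = 1L, spacing = 50L) {
  cfg <- sim_config(cnv_effect = 0, h2 = 0.01, seed = seed)
  sim <- simulate_phased_population(cfg)
  geno <- apply_marker_qc(sim$geno)
  win <- build_windows(geno, 6L)
  pm <- code_pseudo_markers(geno, win)
  ph <- simulate_phenotypes(geno, sim$truth, cfg)
  dr <- cbind(ph, deregress(ph$ebv, ph$r2))
  kept <- accuracy_filter(dr, 0.70)
  sub <- match(kept$sample, geno$samples)
  gw <- hap_gwas(geno, pm, kept$debv, sample_subset = sub)
  res <- gw$results
  first_allele <- !duplicated(res$win_id)
  spaced <- (res$start_idx %% spacing) == 0L
  p_sub <- res$p[first_allele & spaced]
  ks <- stats::ks.test(p_sub, "punif")
  list(p_values = p_sub, ks_p = ks$p.value,
       lambda_gc = stats::median(res$wald) / stats::qchisq(0.5, 1L),
       n_tests = length(p_sub), n_tests_total = gw$n_tests)
}

#' Depth-recovery experiment: group folds and CNV span from read depth
#'
#' Simulates Poisson read depth at 9x mean coverage for three haplotype-count
#' groups whose mean diploid CNVR copy numbers are 8, 9.2 and 10.4
#' (normalized folds 4.0, 4.6, 5.2 — a baseline copy gain of 4 units per
#' chromosome plus extra tag-linked copies, with the fractional group means
#' realized by integer per-animal copies), runs normalization, group
#' profiling, 1-kbp median smoothing and gain calling, and returns the
#' called region with its per-group folds next to the truth.
#'
#' @param seed Simulation seed.
#' @param n_per_group Animals per haplotype-count group (default 5).
#' @param flank Copy-neutral flank on each side of the CNV unit, bp
#'   (default 97,000, so the unit occupies ~3% of the profiled region).
#' @return List: `call` (called region + folds), `true_span`,
#'   `true_folds`, `bin_size`, `vote` (tandem-duplication verdict on the
#'   called region), `n_outward_neutral` (outward pairs seen in a
#'   copy-neutral control set).
#' @export
depth_recovery_experiment <- function(seed = 1L, n_per_group = 5L,
                                      flank = 97000) {
  cfg <- sim_config(seed = seed)
  # integer per-animal copies averaging 8 / 9.2 / 10.4 per group
  g1 <- c(rep(9L, n_per_group - ceiling(n_per_group / 5)),
          rep(10L, ceiling(n_per_group / 5)))
  g2 <- c(rep(10L, n_per_group - 2L * ceiling(n_per_group / 5)),
          rep(11L, 2L * ceiling(n_per_group / 5)))
  truth <- data.frame(
    sample = sprintf("SEQ%03d", seq_len(3L * n_per_group)),
    tag_count = rep(0:2, each = n_per_group),
    copies = c(rep(8L, n_per_group), g1, g2),
    breed = "indicine", stringsAsFactors = FALSE)
  region <- c(cfg$cnvr_span[1] - flank, cfg$cnvr_span[2] + flank)
  cov <- simulate_coverage_and_pairs(truth, cfg, region = region,
                                     seed = seed)
  C <- sample_coverage(cov$depth)
  norm <- normalize_coverage(cov$depth, C)
  prof <- group_profile(norm, truth$tag_count, region[1],
                        chrom = cov$chrom)
  calls <- call_gain_regions(prof)
  vote <- if (nrow(calls) > 0L) {
    tandem_dup_vote(cov$pairs, c(calls$start_bp[1L], calls$end_bp[1L]),
                    insert_mean = cfg$insert_mean,
                    insert_sd = cfg$insert_sd)
  } else NULL
  ctrl <- control_truth(4L)
  cov0 <- simulate_coverage_and_pairs(ctrl, cfg, region = region,
                                      seed = seed + 1L)
  cl0 <- classify_pairs(cov0$pairs, cfg$insert_mean, cfg$insert_sd)
  list(call = calls,
       true_span = cfg$cnvr_span,
       true_folds = c(`0` = 4.0, `1` = 4.6, `2` = 5.2),
       bin_size = 1000L,
       vote = vote,
       n_outward_neutral = sum(cl0$class == "discordant_outward"),
       n_pairs_neutral = nrow(cl0))
}
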