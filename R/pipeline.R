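#' Demo-scale simulation configuration
#'
#' A compact scenario (150 animals, 2 chromosomes of 300 markers) used by
#' the end-to-end pipeline examples and integration tests; every stage runs
#' in seconds. The CNV effect is set to 20% of pseudo-phenotype variance —
#' inflated relative to the reference scenario — so that the miniature
#' sample still contains a detectable association signal; the recovery
#' experiments use the reference [sim_config()] conditions instead.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
demo_config <- function(seed = 1L, ...) {
  sim_config(n_samples = 150L, n_markers = 600L, n_chromosomes = 2L,
             cnv_var_frac = 0.2, seed = seed, ...)
}

#' Run the full discovery pipeline on simulated data
#'
#' Executes, in order: population simulation, marker QC, haplotype windows
#' and pseudo-marker coding, phenotype simulation and deregression with
#' accuracy filtering, the LOCO mixed-model GWAS, consensus-allele merging
#' of tied top windows (opt-in), read-depth CNV profiling and gain calling
#' with a taurine copy-neutral comparison, the tandem-duplication read-pair
#' vote, probe-intensity LRR analysis with GC-wave correction, qPCR
#' relative quantification, and a pleiotropy screen against two simulated
#' null traits. Returns every stage's output plus a provenance log
#' (config hash, seed, and sample/marker counts surviving each filter).
#'
#' @param cfg A [sim_config()]; default [demo_config()].
#' @param window_size Haplotype window size in markers (default 6).
#' @param freq_min,freq_max Haplotype frequency bounds (defaults 0.05, 0.95).
#' @param min_accuracy Minimum deregressed-EBV accuracy (default 0.70).
#' @param alpha Family-wise error rate (default 0.05).
#' @param merge_ties Merge tied top windows into a consensus allele
#'   (default TRUE).
#' @param n_sequenced Number of animals with simulated sequence data
#'   (default 21, balanced across tag-count groups as far as possible).
#' @param n_controls Number of taurine copy-neutral controls (default 4).
#' @param outdir Optional directory; when given, stage outputs are written
#'   as TSV/BED/PLINK files stamped with the config hash.
#' @return A named list of stage outputs with a `provenance` entry.
#' @export
run_pipeline <- function(cfg = demo_config(), window_size = 6L,
                         freq_min = 0.05, freq_max = 0.95,
                         min_accuracy = 0.70, alpha = 0.05,
                         merge_ties = TRUE, n_sequenced = 21L,
                         n_controls = 4L, outdir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  hash <- config_hash(unclass(cfg))
  prov <- list(config_hash = hash, seed = cfg$seed, counts = list())
  note <- function(k, v) prov$counts[[k]] <<- v

  # --- simulate -------------------------------------------------------
  sim <- simulate_phased_population(cfg)
  note("samples_simulated", length(sim$geno$samples))
  note("markers_simulated", nrow(sim$geno$map))
  note("tag_freq_realized", attr(sim$truth, "tag_freq_realized"))

  # --- qc -------------------------------------------------------------
  geno <- apply_marker_qc(sim$geno)
  note("markers_post_qc", nrow(geno$map))

  # --- windows --------------------------------------------------------
  win <- build_windows(geno, window_size)
  pm <- code_pseudo_markers(geno, win, freq_min, freq_max)
  note("windows", nrow(win$windows))
  note("pseudo_markers_tested", ncol(pm$counts))

  # --- phenotypes + deregression -------------------------------------
  ph <- simulate_phenotypes(geno, sim$truth, cfg)
  dr <- cbind(ph, deregress(ph$ebv, ph$r2))
  kept <- accuracy_filter(dr, min_accuracy)
  note("samples_post_accuracy_filter", nrow(kept))
  sub <- match(kept$sample, geno$samples)

  # --- gwas -----------------------------------------------------------
  gwas <- hap_gwas(geno, pm, kept$debv, alpha = alpha, sample_subset = sub)
  top <- gwas$results[which.min(gwas$results$p), ]
  note("bonferroni_threshold", gwas$threshold)

  # --- consensus ------------------------------------------------------
  consensus <- NULL
  if (merge_ties) {
    tied <- top_tied_windows(gwas)
    tied_chr <- tied[tied$chrom == top$chrom, , drop = FALSE]
    if (all(diff(sort(tied_chr$start_idx)) == 1L)) {
      consensus <- merge_tied_windows(tied_chr$allele, tied_chr$start_idx,
                                      geno$map)
    }
  }

  # --- cnv depth ------------------------------------------------------
  by_group <- split(seq_len(nrow(sim$truth)), sim$truth$tag_count)
  seq_idx <- utils::head(sort(unlist(lapply(by_group, function(ii) {
    utils::head(ii, ceiling(n_sequenced / length(by_group)))
  }))), n_sequenced)
  seq_truth <- sim$truth[seq_idx, , drop = FALSE]
  cov_nel <- simulate_coverage_and_pairs(seq_truth, cfg)
  C <- sample_coverage(cov_nel$depth)
  norm <- normalize_coverage(cov_nel$depth, C)
  profile <- group_profile(norm, seq_truth$tag_count, cov_nel$region[1],
                           chrom = cov_nel$chrom)
  calls <- call_gain_regions(profile)
  note("cnv_calls", nrow(calls))

  ctrl <- control_truth(n_controls)
  cov_tau <- simulate_coverage_and_pairs(ctrl, cfg, seed = cfg$seed + 20L)
  prof_tau <- group_profile(
    normalize_coverage(cov_tau$depth, sample_coverage(cov_tau$depth)),
    ctrl$breed, cov_tau$region[1], chrom = cov_tau$chrom)
  breed_cmp <- if (nrow(calls) > 0L) {
    copy_neutral_comparison(
      list(nellore = profile, taurine = prof_tau),
      c(calls$start_bp[1L], calls$end_bp[1L]))
  } else NULL

  # --- sv scan --------------------------------------------------------
  sv <- if (nrow(calls) > 0L) {
    tandem_dup_vote(cov_nel$pairs, c(calls$start_bp[1L], calls$end_bp[1L]),
                    insert_mean = cfg$insert_mean, insert_sd = cfg$insert_sd)
  } else NULL

  # --- probe intensity ------------------------------------------------
  tag_cols <- geno$map$chrom == cfg$tag_chrom
  chrom_len <- max(geno$map$pos[tag_cols]) + 10000L
  fasta <- simulate_reference(stats::setNames(chrom_len, cfg$tag_chrom),
                              seed = cfg$seed + 5L)
  inten <- simulate_intensities(geno, sim$truth[match(geno$samples,
                                                      sim$truth$sample), ],
                                cfg, fasta)
  lrr_df <- compute_lrr(inten$intensities, inten$clusters)
  Lmat <- matrix(lrr_df$lrr, nrow = nrow(inten$map),
                 dimnames = list(inten$map$snp, NULL))
  gc <- gc_window_content(fasta, inten$map$chrom, inten$map$pos,
                          window = min(1e6, chrom_len))
  Lcorr <- gc_correct(Lmat, gc)
  lrr_profile <- group_lrr_profile(
    Lcorr, sim$truth$tag_count[match(geno$samples, sim$truth$sample)],
    inten$map, cnvr = cfg$cnvr_span)
  note("markers_in_cnvr", attr(lrr_profile, "n_markers_in_cnvr"))

  # --- qpcr -----------------------------------------------------------
  qp_truth <- rbind(
    do.call(rbind, lapply(split(seq_truth, seq_truth$tag_count),
                          utils::head, 4L)),
    control_truth(n_controls))
  plate <- simulate_qpcr(qp_truth, cfg)
  rq <- delta_delta_ct(plate$wells, plate$calibrator)
  qpcr_summary <- qpcr_group_summary(rq, plate$groups)

  # --- pleiotropy screen against two simulated null traits ------------
  extra <- with_seed(cfg$seed + 6L, {
    data.frame(trait_null_a = stats::rnorm(nrow(kept)),
               trait_null_b = stats::rnorm(nrow(kept)))
  })
  tag_pm <- paste0(top$win_id, ":", top$allele)
  top_counts <- pm$counts[sub, match(top$pm_id, colnames(pm$counts))]
  weights <- garrick_weight(kept$r2_debv, cfg$h2)
  pleio <- pleiotropy_screen(extra, top_counts, weights)

  bundle <- list(config = cfg, truth = sim$truth, geno = geno,
                 windows = win, pseudo_markers = pm, phenotypes = kept,
                 gwas = gwas, top = top, consensus = consensus,
                 coverage_profile = profile, cnv_calls = calls,
                 breed_comparison = breed_cmp, sv_vote = sv,
                 lrr_profile = lrr_profile, qpcr = rq,
                 qpcr_summary = qpcr_summary, pleiotropy = pleio,
                 provenance = prov)

  if (!is.null(outdir)) write_pipeline_outputs(bundle, outdir, cov_nel)
  bundle
}

write_pipeline_outputs <- function(bundle, outdir, cov_nel) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- bundle$provenance$config_hash
  stamp <- function(df) {
    attr(df, "config_hash") <- hash
    df
  }
  tsv <- function(df, name) {
    f <- file.path(outdir, name)
    con <- file(f, "w")
    writeLines(paste0("# config_hash=", hash), con)
    utils::write.table(stamp(df), con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  tsv(bundle$gwas$results, "gwas_results.tsv")
  tsv(bundle$phenotypes, "phenotypes.tsv")
  tsv(bundle$truth, "ground_truth.tsv")
  tsv(bundle$qpcr, "qpcr_rq.tsv")
  tsv(bundle$qpcr_summary, "qpcr_summary.tsv")
  tsv(bundle$pleiotropy, "pleiotropy.tsv")
  if (nrow(bundle$cnv_calls) > 0L) {
    write_bed(bundle$cnv_calls, file.path(outdir, "cnv_calls.bed"))
    tsv(bundle$cnv_calls, "cnv_calls.tsv")
  }
  write_plink(bundle$geno, file.path(outdir, "genotypes"))
  write_sam_pairs(cov_nel$pairs, file.path(outdir, "readpairs.sam"),
                  read_len = bundle$config$read_len)
  invisible(outdir)
}
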