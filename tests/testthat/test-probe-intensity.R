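test_that("expected R interpolates between canonical clusters and clamps", {
  th <- c(0.1, 0.5, 0.9); r <- c(2, 3, 2.4)
  expect_equal(expected_r(0.5, th, r), 3)            # knot is exact
  expect_equal(expected_r(0.3, th, r), 2.5)          # linear midpoint
  expect_equal(expected_r(0.95, th, r), 2.4)         # clamp beyond BB
  expect_equal(expected_r(0.01, th, r), 2)           # clamp before AA
  expect_error(expected_r(0.5, c(0.1, 0.1, 0.9), r), "degenerate")
})

test_that("LRR is the log2 intensity ratio with NA on bad probes", {
  expect_equal(lrr(2, 2), 0)
  expect_equal(lrr(4, 2), 1)
  expect_warning(v <- lrr(c(2, 0), c(2, 2)), "non-positive")
  expect_true(is.na(v[2]))
  # scale invariance of the ratio
  expect_equal(lrr(3 * 1.7, 2 * 1.7), lrr(3, 2))
})

test_that("noiseless intensities give exact LRR from copy number", {
  cfg <- sim_config(n_samples = 20L, n_markers = 60L, n_chromosomes = 1L,
                    tag_locus = 20:28, gc_wave_amplitude = 0,
                    intensity_noise_sd = 0, seed = 8L)
  sim <- simulate_phased_population(cfg)
  fasta <- simulate_reference(
    stats::setNames(max(sim$geno$map$pos) + 1000L, cfg$tag_chrom), seed = 1L)
  inten <- simulate_intensities(sim$geno, sim$truth, cfg, fasta)
  lr <- compute_lrr(inten$intensities, inten$clusters)
  pos <- inten$map$pos[match(lr$snp, inten$map$snp)]
  in_cnvr <- pos >= cfg$cnvr_span[1] & pos < cfg$cnvr_span[2]
  copies <- sim$truth$copies[match(lr$sample, sim$truth$sample)]
  # outside the CNVR: exactly 0; inside: exactly log2(copies / 2)
  expect_equal(lr$lrr[!in_cnvr], rep(0, sum(!in_cnvr)), tolerance = 1e-12)
  expect_equal(lr$lrr[in_cnvr], log2(copies[in_cnvr] / 2),
               tolerance = 1e-12)
})

test_that("GC correction removes an injected wave and is idempotent", {
  cfg <- sim_config(n_samples = 30L, n_markers = 500L, n_chromosomes = 1L,
                    tag_locus = 200:208, gc_wave_amplitude = 0.2,
                    intensity_noise_sd = 0.05, seed = 14L)
  sim <- simulate_phased_population(cfg)
  len <- max(sim$geno$map$pos) + 1000L
  fasta <- simulate_reference(stats::setNames(len, cfg$tag_chrom),
                              gc_period = 5e5, seed = 2L)
  inten <- simulate_intensities(sim$geno, sim$truth, cfg, fasta)
  lr <- compute_lrr(inten$intensities, inten$clusters)
  L <- matrix(lr$lrr, nrow = nrow(inten$map))
  gc <- gc_window_content(fasta, inten$map$chrom, inten$map$pos,
                          window = 1e5)
  pre <- mean(abs(apply(L, 2L, cor, y = gc)))
  Lc <- gc_correct(L, gc)
  post <- mean(abs(apply(Lc, 2L, cor, y = gc)))
  expect_gt(pre, 0.5)
  expect_lt(post, 0.05)
  expect_lt(max(abs(gc_correct(Lc, gc) - Lc)), 1e-10)
})

test_that("a constant GC regressor degenerates to mean-centering", {
  L <- matrix(c(0.1, 0.3, -0.2, 0.4), ncol = 1)
  gc <- rep(100, 4)   # e.g. an all-G chromosome
  expect_equal(gc_correct(L, gc), L - mean(L), ignore_attr = TRUE)
  # zero-amplitude wave: slope is null within its standard error
  set.seed(9)
  y <- rnorm(200, sd = 0.05); g <- runif(200, 30, 60)
  fit <- summary(lm(y ~ g))$coefficients
  expect_lt(abs(fit[2, 1]), 3 * fit[2, 2])
  expect_equal(as.numeric(gc_correct(matrix(y), g)),
               unname(residuals(lm(y ~ g))), tolerance = 1e-12)
})

test_that("group LRR profiles count CNVR markers and order by copies", {
  cfg <- sim_config(n_samples = 40L, n_markers = 60L, n_chromosomes = 1L,
                    tag_locus = 20:28, gc_wave_amplitude = 0,
                    intensity_noise_sd = 0.02, seed = 15L)
  sim <- simulate_phased_population(cfg)
  fasta <- simulate_reference(
    stats::setNames(max(sim$geno$map$pos) + 1000L, cfg$tag_chrom), seed = 3L)
  inten <- simulate_intensities(sim$geno, sim$truth, cfg, fasta)
  lr <- compute_lrr(inten$intensities, inten$clusters)
  L <- matrix(lr$lrr, nrow = nrow(inten$map))
  prof <- group_lrr_profile(L, sim$truth$tag_count, inten$map,
                            cnvr = cfg$cnvr_span)
  # the default layout places exactly two array SNPs inside the 6.2-kbp unit
  expect_identical(attr(prof, "n_markers_in_cnvr"), 2L)
  # in-CNVR group means are ordered with copy number
  in_cnvr <- prof$pos >= cfg$cnvr_span[1] & prof$pos < cfg$cnvr_span[2]
  groups_present <- intersect(c("0", "1", "2"),
                              as.character(unique(sim$truth$tag_count)))
  if (length(groups_present) == 3L) {
    mm <- colMeans(prof[in_cnvr, paste0("mean_", groups_present)])
    expect_true(all(diff(mm) > 0))
  }
  # single group: profile equals the plain marker mean
  one <- group_lrr_profile(L, rep("all", ncol(L)), inten$map)
  expect_equal(one$mean_all,
               rowMeans(L)[order(inten$map$pos)], ignore_attr = TRUE)
})

test_that("a missing chromosome in the FASTA is reported by name", {
  fasta <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGT"))
  expect_error(gc_window_content(fasta, "chr9", 4, 8), "chr9")
})
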