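cfg_seq <- sim_config(seed = 2L)

test_that("copy-neutral samples give flat depth and inward pairs only", {
  ctrl <- control_truth(3)
  cov <- simulate_coverage_and_pairs(ctrl, cfg_seq, seed = 41L)
  # mean depth within 3 SE of the configured mean
  for (j in 1:3) {
    m <- mean(cov$depth[, j])
    se <- sd(cov$depth[, j]) / sqrt(nrow(cov$depth))
    expect_lt(abs(m - cfg_seq$mean_depth), 3 * se + 0.02)
  }
  cl <- classify_pairs(cov$pairs, cfg_seq$insert_mean, cfg_seq$insert_sd)
  expect_identical(sum(cl$class == "discordant_outward"), 0L)
  # false-positive rate bound: no outward calls at all without a junction
  expect_lt(mean(cl$class == "discordant_outward"), 1e-3)
})

test_that("an 8-copy CNVR at 9x depth shows ~4x normalized coverage", {
  tr <- data.frame(sample = "S1", tag_count = 0L, copies = 8L,
                   breed = "indicine")
  cov <- simulate_coverage_and_pairs(tr, cfg_seq, seed = 42L)
  span <- cfg_seq$cnvr_span
  rows <- (span[1] - cov$region[1] + 1):(span[2] - cov$region[1])
  norm <- normalize_coverage(cov$depth[, 1], cfg_seq$mean_depth)
  m <- mean(norm[rows])
  # Poisson error of the in-CNVR mean at rate 4 * mean_depth
  se <- sqrt(4 / cfg_seq$mean_depth / length(rows))
  expect_lt(abs(m - 4), 4 * se)
})

test_that("tandem junction fragments project as outward long pairs", {
  tr <- data.frame(sample = "S1", tag_count = 2L, copies = 10L,
                   breed = "indicine")
  cov <- simulate_coverage_and_pairs(tr, cfg_seq, seed = 43L)
  cl <- classify_pairs(cov$pairs, cfg_seq$insert_mean, cfg_seq$insert_sd)
  out <- cl[cl$class == "discordant_outward", ]
  expect_gt(nrow(out), 10L)
  unit <- cfg_seq$cnvr_span[2] - cfg_seq$cnvr_span[1]
  expect_lt(abs(median(out$inferred_insert) - unit), 0.25 * unit)
  # long-range projections are overwhelmingly outward (junction recall)
  far <- cl[cl$right_pos - cl$left_pos > 1000, ]
  expect_gte(mean(far$class == "discordant_outward"), 0.95)
})

test_that("pair classification follows orientation and insert bands", {
  p <- data.frame(left_pos = c(100, 100, 100, 500),
                  right_pos = c(500, 6300, 520, 500),
                  left_strand = c("+", "-", "-", "+"),
                  right_strand = c("-", "+", "+", "-"),
                  inferred_insert = c(400, 6200, 420, 0))
  cl <- classify_pairs(p, insert_mean = 400, insert_sd = 50, k = 3)
  expect_identical(cl$class,
                   c("concordant", "discordant_outward",
                     "discordant_other", "discordant_other"))
  expect_error(classify_pairs(p, 400, 0), "insert_sd")
})

test_that("tandem-duplication vote needs support and insert agreement", {
  region <- c(10000, 16210)
  good <- data.frame(left_pos = rep(10000, 5), right_pos = rep(16000, 5),
                     left_strand = "-", right_strand = "+",
                     inferred_insert = c(6000, 6100, 6210, 6300, 5900))
  v <- tandem_dup_vote(good, region, insert_mean = 400, insert_sd = 50)
  expect_identical(v$verdict, "tandem_duplication")
  expect_identical(v$n_outward, 5L)
  # min_support above the available pairs: unresolved
  v2 <- tandem_dup_vote(good, region, min_support = 10L,
                        insert_mean = 400, insert_sd = 50)
  expect_identical(v2$verdict, "unresolved")
  # outward pairs with the wrong insert scale: unresolved
  bad <- good; bad$inferred_insert <- rep(2000, 5)
  v3 <- tandem_dup_vote(bad, region, insert_mean = 400, insert_sd = 50)
  expect_identical(v3$verdict, "unresolved")
  # no pairs at all
  v4 <- tandem_dup_vote(good[0, ], region, insert_mean = 400,
                        insert_sd = 50)
  expect_identical(v4$n_outward, 0L)
  expect_identical(v4$verdict, "unresolved")
})

test_that("sequencing simulation validates its region and reproduces", {
  tr <- control_truth(1)
  expect_error(
    simulate_coverage_and_pairs(tr, cfg_seq,
                                region = cfg_seq$cnvr_span + c(5000, 5000)),
    "contain")
  expect_error(
    simulate_coverage_and_pairs(
      tr, cfg_seq, region = c(cfg_seq$cnvr_span[1], cfg_seq$cnvr_span[1] + 100)),
    "insert|contain")
  a <- simulate_coverage_and_pairs(tr, cfg_seq, seed = 77L)
  b <- simulate_coverage_and_pairs(tr, cfg_seq, seed = 77L)
  expect_identical(a$depth, b$depth)
  expect_identical(a$pairs, b$pairs)
})
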