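make_wells <- function(...) {
  # ... = named vectors: sample -> c(cnv reps, ref reps) of length 6
  args <- list(...)
  do.call(rbind, lapply(names(args), function(s) {
    data.frame(sample = s, target = rep(c("cnv", "reference"), each = 3),
               replicate = rep(1:3, 2), ct = args[[s]],
               stringsAsFactors = FALSE)
  }))
}

test_that("the calibrator has RQ exactly 1 and plate offsets cancel", {
  wells <- make_wells(cal = c(21, 21, 21, 20, 20, 20),
                      s1 = c(20, 20, 20, 22, 22, 22))
  rq <- delta_delta_ct(wells, "cal")
  expect_equal(rq$rq[rq$sample == "cal"], 1)
  # s1: dCt = -2, calibrator dCt = 1, ddCt = -3, RQ = 8
  expect_equal(rq$rq[rq$sample == "s1"], 8)
  # adding a constant to every Ct changes nothing
  wells2 <- wells; wells2$ct <- wells2$ct + 3.7
  expect_equal(delta_delta_ct(wells2, "cal")$rq, rq$rq)
  expect_error(delta_delta_ct(wells, "nope"), "absent")
})

test_that("noiseless simulation yields RQ = copies / 2 exactly", {
  cfg <- sim_config(qpcr_sd = 0, seed = 3L)
  tr <- rbind(
    data.frame(sample = c("n8", "n10"), tag_count = c(0L, 2L),
               copies = c(8L, 10L), breed = "indicine"),
    control_truth(2))
  plate <- simulate_qpcr(tr, cfg)
  rq <- delta_delta_ct(plate$wells, plate$calibrator)
  expect_equal(rq$rq[rq$sample == "n8"], 4)
  expect_equal(rq$rq[rq$sample == "n10"], 5)
  expect_equal(rq$rq[rq$sample == plate$calibrator], 1)
  expect_error(simulate_qpcr(transform(tr, copies = 0L), cfg), "copy")
})

test_that("noisy RQ is unbiased within 10% over seeds", {
  cfg <- sim_config(qpcr_sd = 0.3, seed = 1L)
  tr <- rbind(data.frame(sample = "s8", tag_count = 0L, copies = 8L,
                         breed = "indicine"),
              control_truth(1))
  rqs <- vapply(1:20, function(s) {
    plate <- simulate_qpcr(tr, cfg, seed = 1000L + s)
    rq <- delta_delta_ct(plate$wells, plate$calibrator)
    rq$rq[rq$sample == "s8"]
  }, 0)
  expect_lt(abs(mean(rqs) - 4) / 4, 0.10)
})

test_that("replicate scatter flags samples without dropping them", {
  wells <- make_wells(cal = c(20, 20, 20, 19, 19, 19),
                      noisy = c(18, 19.5, 21, 20, 20, 20))
  rq <- delta_delta_ct(wells, "cal", sd_flag_threshold = 0.5)
  expect_true(rq$flagged[rq$sample == "noisy"])
  expect_false(rq$flagged[rq$sample == "cal"])
  expect_identical(nrow(rq), 2L)
})

test_that("group summaries order groups and handle singletons", {
  rq <- data.frame(sample = paste0("s", 1:7),
                   rq = c(4.1, 3.9, 4.6, 4.8, 5.2, 1.0, 1.1))
  groups <- data.frame(sample = paste0("s", 1:7),
                       group = c("0", "0", "1", "1", "2",
                                 "control", "control"))
  sm <- qpcr_group_summary(rq, groups)
  expect_identical(sm$group, c("0", "1", "2", "control"))
  expect_equal(sm$mean_rq[1], 4.0)
  expect_equal(sm$sd_rq[sm$group == "2"], 0)     # singleton: SD 0, flagged
  expect_true(sm$flagged[sm$group == "2"])
  expect_equal(sm$sd_rq[sm$group == "0"], sd(c(4.1, 3.9)))
  # identical RQs give SD 0
  sm2 <- qpcr_group_summary(data.frame(sample = c("a", "b"),
                                       rq = c(2, 2)),
                            data.frame(sample = c("a", "b"), group = "0"))
  expect_equal(sm2$sd_rq, 0)
})

test_that("simulated group means increase with copy number", {
  cfg <- sim_config(qpcr_sd = 0.3, seed = 6L)
  tr <- rbind(
    data.frame(sample = sprintf("g0_%d", 1:4), tag_count = 0L,
               copies = 8L, breed = "indicine"),
    data.frame(sample = sprintf("g1_%d", 1:4), tag_count = 1L,
               copies = 9L, breed = "indicine"),
    data.frame(sample = sprintf("g2_%d", 1:4), tag_count = 2L,
               copies = 10L, breed = "indicine"),
    control_truth(4))
  plate <- simulate_qpcr(tr, cfg)
  rq <- delta_delta_ct(plate$wells, plate$calibrator)
  sm <- qpcr_group_summary(rq, plate$groups)
  mr <- sm$mean_rq[match(c("control", "0", "1", "2"), sm$group)]
  expect_true(all(diff(mr) > 0))
})
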