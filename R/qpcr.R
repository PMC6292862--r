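#' Simulate a qPCR plate from ground-truth copy numbers
#'
#' Each sample is assayed in triplicate for a target amplicon inside the CNV
#' and a single-copy reference amplicon. Cycle thresholds follow the
#' doubling model: `Ct_target = a - log2(copies) + N(0, qpcr_sd)` per
#' replicate and `Ct_reference = a - log2(2) + noise`. The calibrator is a
#' designated copy-neutral sample (2 copies).
#'
#' @param truth Ground truth (sample, copies, tag_count, breed); must
#'   include at least one copy-neutral (2-copy) sample to serve as
#'   calibrator.
#' @param cfg A [sim_config()] (uses `qpcr_sd`).
#' @param calibrator Sample id of the calibrator; default: the first 2-copy
#'   sample.
#' @param n_replicates Replicates per sample-target (default 3).
#' @param seed Optional seed overriding `cfg$seed + 4`.
#' @return List: `wells` (sample, target, replicate, ct), `calibrator`,
#'   `groups` (sample, group: tag count for indicine samples, "control"
#'   otherwise).
#' @export
simulate_qpcr <- function(truth, cfg, calibrator = NULL, n_replicates = 3L,
                          seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(truth$copies <= 0)) {
    stop("zero or negative copy number has no defined Ct", call. = FALSE)
  }
  neutral <- truth$sample[truth$copies == 2L]
  calibrator <- calibrator %||% neutral[1L]
  if (is.na(calibrator) || !calibrator %in% truth$sample) {
    stop("no copy-neutral calibrator sample available", call. = FALSE)
  }
  with_seed(seed %||% (cfg$seed + 4L), {
    a <- 30
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      data.frame(
        sample = truth$sample[i],
        target = rep(c("cnv", "reference"), each = n_replicates),
        replicate = rep(seq_len(n_replicates), 2L),
        ct = c(a - log2(truth$copies[i]) +
                 rnorm(n_replicates, 0, cfg$qpcr_sd),
               a - 1 + rnorm(n_replicates, 0, cfg$qpcr_sd)),
        stringsAsFactors = FALSE)
    })
    groups <- data.frame(
      sample = truth$sample,
      group = ifelse(truth$breed == "indicine",
                     as.character(truth$tag_count), "control"),
      stringsAsFactors = FALSE)
    list(wells = do.call(rbind, rows), calibrator = calibrator,
         groups = groups)
  })
}

#' Relative quantification by the 2^-ddCt method
#'
#' Per sample, `dCt = mean(Ct_cnv) - mean(Ct_reference)`;
#' `ddCt = dCt_sample - dCt_calibrator`; `RQ = 2^-ddCt` (amplification
#' efficiency fixed at 2, the method's namesake assumption). Samples whose
#' replicate SD exceeds `sd_flag_threshold` for either target are flagged
#' but not dropped.
#'
#' @param wells Data frame: sample, target ("cnv"/"reference"), ct (one row
#'   per replicate).
#' @param calibrator Sample id of the calibrator (must carry both targets).
#' @param sd_flag_threshold Replicate-SD flag threshold in Ct units
#'   (default 0.5).
#' @return Data frame: sample, dct, ddct, rq, flagged. RQ of the calibrator
#'   is exactly 1.
#' @export
delta_delta_ct <- function(wells, calibrator, sd_flag_threshold = 0.5) {
  stopifnot(all(c("sample", "target", "ct") %in% names(wells)))
  if (!calibrator %in% wells$sample) {
    stop("calibrator sample '", calibrator, "' absent from the plate",
         call. = FALSE)
  }
  agg <- stats::aggregate(ct ~ sample + target, data = wells,
                          FUN = function(v) c(m = mean(v), s = stats::sd(v),
                                              n = length(v)))
  agg <- data.frame(sample = agg$sample, target = agg$target,
                    mean = agg$ct[, "m"], sd = agg$ct[, "s"],
                    n = agg$ct[, "n"], stringsAsFactors = FALSE)
  if (any(agg$n < 2L)) {
    warning("sample-target(s) with fewer than 2 usable replicates")
  }
  samples <- unique(wells$sample)
  cnv <- agg[agg$target == "cnv", ]
  ref <- agg[agg$target == "reference", ]
  if (!all(samples %in% cnv$sample) || !all(samples %in% ref$sample)) {
    stop("every sample needs both the cnv and the reference target",
         call. = FALSE)
  }
  dct <- cnv$mean[match(samples, cnv$sample)] -
    ref$mean[match(samples, ref$sample)]
  ddct <- dct - dct[match(calibrator, samples)]
  flagged <- pmax(cnv$sd[match(samples, cnv$sample)],
                  ref$sd[match(samples, ref$sample)], na.rm = TRUE) >
    sd_flag_threshold
  data.frame(sample = samples, dct = dct, ddct = ddct, rq = 2^(-ddct),
             flagged = flagged | is.na(flagged), stringsAsFactors = FALSE)
}

#' Group summary of relative quantification values
#'
#' Arithmetic mean and sample SD (denominator n-1) of RQ per group, ordered
#' 0 / 1 / 2 / control then any remaining labels. Single-sample groups
#' report SD 0 and are flagged.
#'
#' @param rq Data frame from [delta_delta_ct()] (sample, rq).
#' @param groups Data frame: sample, group.
#' @return Data frame: group, n, mean_rq, sd_rq, flagged.
#' @export
qpcr_group_summary <- function(rq, groups) {
  g <- groups$group[match(rq$sample, groups$sample)]
  if (anyNA(g)) stop("group assignment missing for some samples",
                     call. = FALSE)
  pref <- c("0", "1", "2", "control")
  lev <- c(intersect(pref, unique(g)), setdiff(unique(g), pref))
  rows <- lapply(lev, function(l) {
    v <- rq$rq[g == l]
    data.frame(group = l, n = length(v), mean_rq = mean(v),
               sd_rq = if (length(v) > 1L) stats::sd(v) else 0,
               flagged = length(v) < 2L, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
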