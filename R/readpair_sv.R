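#' Classify read pairs by orientation and inferred insert size
#'
#' A pair is `discordant_outward` when the leftmost-aligned read is on the
#' minus strand and the rightmost on the plus strand (both reads facing the
#' outer sides of the implied insert) *and* the inferred insert exceeds
#' `insert_mean + k * insert_sd` — the signature left by fragments spanning
#' the junction of a tandem duplication. A `concordant` pair is inward (+/-)
#' with insert within `k` SDs. Everything else (including zero-length
#' same-position pairs) is `discordant_other`.
#'
#' @param pairs Data frame with left_pos, right_pos, left_strand,
#'   right_strand, inferred_insert.
#' @param insert_mean,insert_sd Library insert size moments (`insert_sd > 0`).
#' @param k SD multiplier for insert discordance (default 3).
#' @return `pairs` with an added `class` column.
#' @export
classify_pairs <- function(pairs, insert_mean, insert_sd, k = 3) {
  stopifnot(insert_sd > 0)
  outward <- pairs$left_strand == "-" & pairs$right_strand == "+"
  inward <- pairs$left_strand == "+" & pairs$right_strand == "-"
  long <- pairs$inferred_insert > insert_mean + k * insert_sd
  within <- abs(pairs$inferred_insert - insert_mean) <= k * insert_sd
  zero <- pairs$left_pos == pairs$right_pos
  cls <- rep("discordant_other", nrow(pairs))
  cls[inward & within & !zero] <- "concordant"
  cls[outward & long & !zero] <- "discordant_outward"
  pairs$class <- cls
  pairs
}

#' Vote on a tandem-duplication signature over a candidate region
#'
#' The region (typically a depth-based CNV call) is classified as a tandem
#' duplication when at least `min_support` discordant-outward pairs span it
#' and their median inferred insert is within `insert_tol` (default 25%) of
#' the region length — the geometry expected when structurally identical
#' repeats are arranged in tandem.
#'
#' @param pairs Read pairs, classified or not (then `insert_mean`,
#'   `insert_sd`, `k` are used to classify).
#' @param region Length-2 bp interval of the candidate call.
#' @param min_support Minimum number of supporting outward pairs (default 3).
#' @param insert_tol Relative tolerance between median discordant insert and
#'   region length (default 0.25).
#' @param insert_mean,insert_sd,k Passed to [classify_pairs()] when `pairs`
#'   has no `class` column.
#' @return List: `verdict` ("tandem_duplication" or "unresolved"),
#'   `n_outward`, `median_insert`, `region_length`.
#' @export
tandem_dup_vote <- function(pairs, region, min_support = 3L,
                            insert_tol = 0.25, insert_mean = NULL,
                            insert_sd = NULL, k = 3) {
  stopifnot(length(region) == 2L, region[1] <= region[2])
  if (is.null(pairs$class)) {
    stopifnot(!is.null(insert_mean), !is.null(insert_sd))
    pairs <- classify_pairs(pairs, insert_mean, insert_sd, k)
  }
  span <- pairs$class == "discordant_outward" &
    pairs$left_pos <= region[2] & pairs$right_pos >= region[1]
  n_out <- sum(span)
  med <- if (n_out > 0L) stats::median(pairs$inferred_insert[span]) else
    NA_real_
  reg_len <- region[2] - region[1]
  verdict <- if (n_out >= min_support && !is.na(med) &&
                 abs(med - reg_len) <= insert_tol * reg_len) {
    "tandem_duplication"
  } else "unresolved"
  list(verdict = verdict, n_outward = n_out, median_insert = med,
       region_length = reg_len)
}
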