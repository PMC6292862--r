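#' Normalize raw per-base read counts by sample coverage
#'
#' Per-base normalized coverage is `N_reads / C`, where `C` is the sample's
#' average coverage; 1.0 then approximates the diploid-average state.
#'
#' @param raw Vector or `bases x samples` matrix of raw per-base read counts.
#' @param C Sample coverage: a positive scalar, or one value per column of
#'   `raw`.
#' @return Normalized track, same shape as `raw`.
#' @export
normalize_coverage <- function(raw, C) {
  if (any(C <= 0)) stop("sample coverage C must be positive", call. = FALSE)
  if (is.matrix(raw)) {
    stopifnot(length(C) %in% c(1L, ncol(raw)))
    sweep(raw, 2L, C, `/`)
  } else {
    stopifnot(length(C) == 1L)
    raw / C
  }
}

#' Sample coverage from a raw depth track
#'
#' The median (default) is robust to a copy-variable segment occupying a
#' small fraction of the profiled region; the mean matches the genome-wide
#' average definition when the track itself is overwhelmingly copy-neutral.
#'
#' @param raw Vector or `bases x samples` matrix of raw per-base counts.
#' @param method `"median"` or `"mean"`.
#' @return Scalar or per-sample vector of coverages.
#' @export
sample_coverage <- function(raw, method = c("median", "mean")) {
  method <- match.arg(method)
  f <- if (method == "median") stats::median else mean
  if (is.matrix(raw)) apply(raw, 2L, f) else f(raw)
}

#' Group-wise windowed coverage profile
#'
#' Averages normalized per-base coverage within groups of samples (haplotype
#' count 0/1/2, or breed), then takes the median of the group-mean curve in
#' consecutive bins tiling the region from its start (the last partial bin
#' is kept). The median step smooths outlying bases.
#'
#' @param norm `bases x samples` matrix of normalized coverage; row `i` is
#'   position `region_start + i - 1`.
#' @param groups Group label per sample (length `ncol(norm)`).
#' @param region_start 1-based bp position of the first row.
#' @param bin_size Bin width in bp (default 1000).
#' @param chrom Chromosome label carried through to calls.
#' @return A `coverage_profile`: bin table (bin_start, bin_end) plus a
#'   `bins x groups` matrix of bin medians and the group-mean curves.
#' @export
group_profile <- function(norm, groups, region_start, bin_size = 1000L,
                          chrom = NA_character_) {
  stopifnot(is.matrix(norm), ncol(norm) == length(groups), bin_size >= 1L)
  groups <- as.character(groups)
  lev <- unique(groups)
  sizes <- table(groups)[lev]
  if (any(sizes == 0L)) {
    warning("empty group(s) dropped: ",
            paste(lev[sizes == 0L], collapse = ", "))
    lev <- lev[sizes > 0L]
  }
  nb <- ceiling(nrow(norm) / bin_size)
  bin_of <- rep(seq_len(nb), each = bin_size, length.out = nrow(norm))
  gmean <- vapply(lev, function(g) {
    rowMeans(norm[, groups == g, drop = FALSE])
  }, numeric(nrow(norm)))
  med <- vapply(lev, function(g) {
    as.numeric(tapply(gmean[, g], bin_of, stats::median))
  }, numeric(nb))
  med <- matrix(med, nrow = nb, dimnames = list(NULL, lev))
  bin_start <- region_start + (seq_len(nb) - 1L) * bin_size
  bin_end <- pmin(bin_start + bin_size - 1L,
                  region_start + nrow(norm) - 1L)
  structure(list(chrom = chrom, region_start = region_start,
                 region_end = region_start + nrow(norm) - 1L,
                 bin_size = as.integer(bin_size),
                 bin_start = bin_start, bin_end = bin_end,
                 medians = med, group_mean = gmean, groups = lev),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("<coverage_profile>", x$chrom,
      sprintf("%d-%d,", x$region_start, x$region_end),
      nrow(x$medians), "bins x", length(x$groups), "groups\n")
  invisible(x)
}

#' Call copy-gain regions from a windowed coverage profile
#'
#' A gain is a maximal run of consecutive bins in which at least one group's
#' bin median reaches `gain_threshold`, with total length at least
#' `min_len`. The per-group fold change of a call is the median of that
#' group's bin medians inside the call.
#'
#' @param profile A `coverage_profile`.
#' @param gain_threshold Normalized-coverage threshold declaring a gained
#'   bin (default 1.5, midway between the neutral 1.0 and a single extra
#'   copy at 1.5 on the diploid scale).
#' @param min_len Minimum call length in bp (default 2000).
#' @return Data frame of calls: chrom, start_bp, end_bp, classification and
#'   one `fold_<group>` column per group. Zero rows when nothing is called.
#' @export
call_gain_regions <- function(profile, gain_threshold = 1.5,
                              min_len = 2000L) {
  stopifnot(inherits(profile, "coverage_profile"))
  hit <- apply(profile$medians >= gain_threshold, 1L, any)
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in which(r$values)) {
    b0 <- starts[i]; b1 <- ends[i]
    s <- profile$bin_start[b0]; e <- profile$bin_end[b1]
    if (e - s + 1L < min_len) next
    folds <- apply(profile$medians[b0:b1, , drop = FALSE], 2L, stats::median)
    row <- data.frame(chrom = profile$chrom, start_bp = s, end_bp = e,
                      classification = "gain", stringsAsFactors = FALSE)
    for (g in profile$groups) row[[paste0("fold_", g)]] <- folds[[g]]
    out[[length(out) + 1L]] <- row
  }
  if (length(out) == 0L) {
    res <- data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), classification = character(),
                      stringsAsFactors = FALSE)
    for (g in profile$groups) res[[paste0("fold_", g)]] <- numeric()
    return(res)
  }
  do.call(rbind, out)
}

#' Interval length in kbp
#'
#' Half-open length convention: `(end - start) / 1000`, rounded to one
#' decimal.
#'
#' @param start_bp,end_bp Interval bounds in bp (`start <= end`).
#' @return Length in kbp at one decimal.
#' @export
interval_length_kbp <- function(start_bp, end_bp) {
  stopifnot(all(start_bp <= end_bp))
  round((end_bp - start_bp) / 1000, 1L)
}

#' Classify populations as copy-gained or copy-neutral at a region
#'
#' For each population's coverage profile, the in-region fold change is the
#' median of its bin medians over bins overlapping the region (taking the
#' maximum across that population's groups). A population is "neutral" when
#' the fold lies within `1 +/- tol`, "gain" when it reaches
#' `gain_threshold`, otherwise "ambiguous".
#'
#' @param profiles Named list of `coverage_profile` objects, one per
#'   population.
#' @param region Length-2 bp interval (start, end) previously called in at
#'   least one population.
#' @param gain_threshold Fold declaring a gain (default 1.5).
#' @param tol Half-width of the neutral band around 1 (default 0.25).
#' @return Data frame: population, fold, classification.
#' @export
copy_neutral_comparison <- function(profiles, region, gain_threshold = 1.5,
                                    tol = 0.25) {
  stopifnot(length(region) == 2L, region[1] <= region[2])
  rows <- lapply(names(profiles), function(popn) {
    pr <- profiles[[popn]]
    sel <- pr$bin_end >= region[1] & pr$bin_start <= region[2]
    if (!any(sel)) stop("region does not overlap the profile of ", popn,
                        call. = FALSE)
    fold <- max(apply(pr$medians[sel, , drop = FALSE], 2L, stats::median))
    cls <- if (abs(fold - 1) <= tol) "neutral"
           else if (fold >= gain_threshold) "gain"
           else "ambiguous"
    data.frame(population = popn, fold = fold, classification = cls,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
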