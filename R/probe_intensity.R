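#' Expected total intensity from canonical genotype clusters
#'
#' Piecewise-linear interpolation of cluster R over cluster theta: a sample's
#' expected R at angle `theta` is interpolated between the two flanking
#' canonical centroids (AA, AB, BB) and clamped to the nearest centroid's R
#' outside `[theta_AA, theta_BB]` (extrapolation could produce meaningless
#' negative intensities).
#'
#' @param theta Sample theta value(s), `2/pi * atan2(y, x)`, in `[0, 1]`.
#' @param theta_k Length-3 increasing vector of cluster thetas (AA, AB, BB).
#' @param r_k Length-3 vector of cluster R values.
#' @return Expected R at each `theta`.
#' @export
expected_r <- function(theta, theta_k, r_k) {
  stopifnot(length(theta_k) == 3L, length(r_k) == 3L)
  if (any(diff(theta_k) <= 0)) {
    stop("degenerate clusters: thetas must be strictly increasing",
         call. = FALSE)
  }
  stats::approx(theta_k, r_k, xout = theta, rule = 2L)$y
}

#' Log R ratio
#'
#' `LRR = log2(R_observed / R_expected)`; non-positive inputs yield `NA`
#' with a warning rather than an error, so single bad probes do not abort a
#' whole-array computation.
#'
#' @param r_obs,r_exp Observed and expected total intensities.
#' @return LRR value(s).
#' @export
lrr <- function(r_obs, r_exp) {
  bad <- !(r_obs > 0 & r_exp > 0)
  if (any(bad)) {
    warning(sum(bad), " non-positive intensity value(s) set to NA")
  }
  out <- rep(NA_real_, length(r_obs))
  out[!bad] <- log2(r_obs[!bad] / r_exp[!bad])
  out
}

#' Compute per-sample LRR from X/Y intensities and canonical clusters
#'
#' @param intensities Data frame: snp, sample, x, y.
#' @param clusters Data frame: snp, theta_aa, r_aa, theta_ab, r_ab,
#'   theta_bb, r_bb.
#' @return `intensities` with added theta, r, r_expected and lrr columns.
#' @export
compute_lrr <- function(intensities, clusters) {
  stopifnot(all(c("snp", "sample", "x", "y") %in% names(intensities)))
  m <- match(intensities$snp, clusters$snp)
  if (anyNA(m)) stop("clusters missing for some SNPs", call. = FALSE)
  theta <- 2 / pi * atan2(intensities$y, intensities$x)
  r <- intensities$x + intensities$y
  r_exp <- numeric(nrow(intensities))
  for (j in unique(m)) {
    sel <- which(m == j)
    cl <- clusters[j, ]
    r_exp[sel] <- expected_r(theta[sel],
                             c(cl$theta_aa, cl$theta_ab, cl$theta_bb),
                             c(cl$r_aa, cl$r_ab, cl$r_bb))
  }
  out <- intensities
  out$theta <- theta
  out$r <- r
  out$r_expected <- r_exp
  out$lrr <- lrr(r, r_exp)
  out
}

#' Percent GC in windows centered on markers
#'
#' For each marker, %GC of the `window`-bp window centered on its position
#' (truncated at chromosome ends); N bases are excluded from both numerator
#' and denominator. Markers whose window is all N give `NA` with a warning.
#'
#' @param fasta A `Biostrings::DNAStringSet` (or path to a FASTA file).
#' @param chrom,pos Marker chromosome labels and 1-based positions.
#' @param window Total window width in bp (default 1e6).
#' @return Percent GC (0-100) per marker.
#' @export
gc_window_content <- function(fasta, chrom, pos, window = 1e6) {
  if (is.character(fasta)) fasta <- Biostrings::readDNAStringSet(fasta)
  names(fasta) <- sub("\\s.*$", "", names(fasta))
  miss <- setdiff(unique(chrom), names(fasta))
  if (length(miss) > 0L) {
    stop("FASTA is missing chromosome(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  half <- floor(window / 2)
  out <- numeric(length(pos))
  for (ch in unique(chrom)) {
    seqc <- fasta[[ch]]
    len <- length(seqc)
    sel <- which(chrom == ch)
    st <- pmax(1, pos[sel] - half)
    en <- pmin(len, pos[sel] + half)
    v <- Biostrings::Views(seqc, start = st, end = en)
    f <- Biostrings::letterFrequency(v, c("G", "C", "A", "T"))
    acgt <- rowSums(f)
    gc <- rowSums(f[, c("G", "C"), drop = FALSE])
    out[sel] <- ifelse(acgt > 0, 100 * gc / acgt, NA_real_)
  }
  if (anyNA(out)) warning(sum(is.na(out)), " marker(s) with all-N windows")
  out
}

#' GC-wave correction of LRR values
#'
#' Per sample, ordinary least squares of LRR on marker %GC; the residuals
#' are the waviness-normalized LRR values. With a constant %GC regressor the
#' correction degenerates to mean-centering. The operation is idempotent.
#'
#' @param L `markers x samples` matrix of LRR values (NAs tolerated).
#' @param gc %GC per marker (from [gc_window_content()]).
#' @return Matrix of corrected LRR values, same shape as `L`.
#' @export
gc_correct <- function(L, gc) {
  if (!is.matrix(L)) L <- matrix(L, ncol = 1L)
  stopifnot(nrow(L) == length(gc))
  keep <- !is.na(gc)
  out <- L
  for (j in seq_len(ncol(L))) {
    y <- L[, j]
    ok <- keep & !is.na(y)
    if (sum(ok) < 2L) next
    if (var_n(gc[ok]) == 0) {
      out[ok, j] <- y[ok] - mean(y[ok])
    } else {
      fit <- stats::lm.fit(cbind(1, gc[ok]), y[ok])
      out[ok, j] <- fit$residuals
    }
  }
  out
}

#' Group-mean LRR profile over a region
#'
#' Marker-wise mean of (corrected) LRR within groups of samples, restricted
#' to a region and ordered by position; reports how many array markers fall
#' inside a CNV region of interest.
#'
#' @param L `markers x samples` LRR matrix.
#' @param groups Group label per sample.
#' @param map Data frame (snp, chrom, pos) aligned with the rows of `L`.
#' @param region Length-2 bp interval to profile (default: all markers).
#' @param cnvr Optional length-2 bp interval; markers inside it are counted.
#' @return Data frame snp, chrom, pos plus one `mean_<group>` column per
#'   group; attribute `n_markers_in_cnvr` when `cnvr` is given.
#' @export
group_lrr_profile <- function(L, groups, map, region = NULL, cnvr = NULL) {
  stopifnot(nrow(map) == nrow(L), ncol(L) == length(groups))
  sel <- if (is.null(region)) rep(TRUE, nrow(map)) else
    map$pos >= region[1] & map$pos <= region[2]
  lev <- unique(as.character(groups))
  out <- map[sel, c("snp", "chrom", "pos"), drop = FALSE]
  for (g in lev) {
    out[[paste0("mean_", g)]] <-
      rowMeans(L[sel, groups == g, drop = FALSE], na.rm = TRUE)
  }
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(cnvr)) {
    attr(out, "n_markers_in_cnvr") <-
      sum(out$pos >= cnvr[1] & out$pos <= cnvr[2])
  }
  out
}
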