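#' Haplotype GWAS with a leave-one-chromosome-out mixed model
#'
#' Runs the full two-step association analysis: for every chromosome, (1)
#' variance components are estimated once by [aireml()] on the reduced
#' (no-haplotype) model under the GRM built from all SNPs *except* those on
#' that chromosome, then (2) every pseudo-marker on the chromosome is tested
#' by [gls_scan()] under the fitted covariance. The LOCO discipline is
#' recorded in an audit table.
#'
#' @param geno A QC-filtered `phased_geno` (supplies SNP dosages for the GRM).
#' @param pm A `pseudo_markers` object from [code_pseudo_markers()].
#' @param y Phenotype vector aligned with `pm$samples` (deregressed EBVs).
#' @param alpha Family-wise error rate for the Bonferroni threshold.
#' @param sample_subset Optional logical/integer index selecting the
#'   phenotyped samples (applied to genotypes and counts alike).
#' @return A `hap_gwas` object: `results` (per pseudo-marker chrom, window
#'   span, allele, freq, b_hat, se, wald, p, bonferroni_pass), `vc_by_chrom`,
#'   `n_tests`, `threshold`, and the LOCO `audit` table.
#' @export
hap_gwas <- function(geno, pm, y, alpha = 0.05, sample_subset = NULL) {
  stopifnot(inherits(geno, "phased_geno"), inherits(pm, "pseudo_markers"))
  counts <- pm$counts
  D <- dosages(geno)
  if (!is.null(sample_subset)) {
    D <- D[sample_subset, , drop = FALSE]
    counts <- counts[sample_subset, , drop = FALSE]
  }
  stopifnot(length(y) == nrow(D))

  parts <- grm_parts(D, geno$map$chrom)
  chroms <- unique(pm$info$chrom)
  res <- list(); vcs <- list(); audit <- list()
  for (ch in chroms) {
    g <- build_loco_grm(parts = parts, exclude_chrom = ch)
    eg <- eigen(g$K, symmetric = TRUE)
    vc <- aireml(y, g, eigen_grm = eg)
    sel <- pm$info$chrom == ch
    res[[ch]] <- gls_scan(y, counts[, sel, drop = FALSE], vc,
                          grm = g, eigen_grm = eg,
                          info = pm$info[sel, , drop = FALSE])
    vcs[[ch]] <- vc
    audit[[ch]] <- data.frame(chrom = ch, excluded_chrom = ch,
                              n_markers_used = g$n_markers_used,
                              sigma2_u = vc$sigma2_u, sigma2_e = vc$sigma2_e,
                              converged = vc$converged,
                              stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  n_tests <- nrow(results)
  thr <- bonferroni_threshold(n_tests, alpha)
  results$bonferroni_pass <- results$p < thr
  structure(list(results = results, vc_by_chrom = vcs, n_tests = n_tests,
                 alpha = alpha, threshold = thr,
                 audit = do.call(rbind, audit)),
            class = "hap_gwas")
}

#' @export
print.hap_gwas <- function(x, ...) {
  cat("<hap_gwas>", x$n_tests, "pseudo-markers tested; Bonferroni threshold",
      format(x$threshold, digits = 3), "\n")
  top <- x$results[which.min(x$results$p), ]
  cat(sprintf("  top: %s %s p = %.3g\n", top$win_id, top$allele, top$p))
  invisible(x)
}

#' Windows tied as most significant
#'
#' Identifies the set of pseudo-markers whose p-values equal the minimum
#' p-value when both are rounded to `digits` significant figures (ties at
#' output precision).
#'
#' @param gwas A `hap_gwas` object (or its `results` data frame).
#' @param digits Significant figures at which ties are declared (default 3).
#' @return The tied rows of the results table, ordered by window start.
#' @export
top_tied_windows <- function(gwas, digits = 3L) {
  res <- if (inherits(gwas, "hap_gwas")) gwas$results else gwas
  ps <- signif(res$p, digits)
  tied <- res[ps == min(ps), , drop = FALSE]
  tied[order(tied$chrom, tied$start_idx), , drop = FALSE]
}

#' Re-run the haplotype scan across window sizes
#'
#' Sensitivity analysis of the association signal to the haplotype length:
#' rebuilds windows and pseudo-markers and re-runs [hap_gwas()] at each
#' window size (1 marker = single-SNP mode).
#'
#' @param geno A QC-filtered `phased_geno`.
#' @param y Phenotype vector.
#' @param sizes Window sizes in markers (default `c(1, 5, 10)`).
#' @param freq_min,freq_max Haplotype frequency bounds.
#' @param alpha Family-wise error rate.
#' @return Named list of `hap_gwas` objects, one per window size.
#' @export
window_size_sensitivity <- function(geno, y, sizes = c(1L, 5L, 10L),
                                    freq_min = 0.05, freq_max = 0.95,
                                    alpha = 0.05) {
  out <- list()
  for (L in sizes) {
    win <- build_windows(geno, L)
    pm <- code_pseudo_markers(geno, win, freq_min, freq_max)
    out[[as.character(L)]] <- hap_gwas(geno, pm, y, alpha = alpha)
  }
  out
}
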