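#' Per-chromosome partial GRM components
#'
#' One pass over the dosage matrix producing, for every chromosome, the
#' centered cross-product numerator and the `2 * sum(p(1-p))` denominator, so
#' that every leave-one-chromosome-out GRM is obtained by subtraction.
#'
#' @param D `n x m` dosage matrix (0/1/2 copies of allele B).
#' @param chrom Length-m chromosome label vector.
#' @return A `grm_parts` list with per-chromosome numerators, denominators
#'   and marker counts.
#' @export
grm_parts <- function(D, chrom) {
  stopifnot(is.matrix(D), ncol(D) == length(chrom))
  p <- colMeans(D) / 2
  labs <- unique(chrom)
  num <- list(); den <- numeric(length(labs)); nmk <- integer(length(labs))
  names(den) <- labs; names(nmk) <- labs
  for (ch in labs) {
    j <- which(chrom == ch)
    Z <- sweep(D[, j, drop = FALSE], 2L, 2 * p[j])
    num[[ch]] <- tcrossprod(Z)
    den[ch] <- 2 * sum(p[j] * (1 - p[j]))
    nmk[ch] <- length(j)
  }
  structure(list(num = num, den = den, n_markers = nmk, labs = labs),
            class = "grm_parts")
}

#' Leave-one-chromosome-out genomic relationship matrix
#'
#' Computes the SNP-based GRM `Z Z' / (2 sum p(1-p))` from centered dosages,
#' excluding all markers on `exclude_chrom` (the chromosome of the haplotype
#' being tested) so that the polygenic term never absorbs the tested signal.
#'
#' @param D `n x m` dosage matrix; ignored when `parts` is supplied.
#' @param chrom Length-m chromosome labels; ignored when `parts` is supplied.
#' @param exclude_chrom Chromosome label to leave out, or `NULL` for the
#'   whole-genome GRM.
#' @param parts Optional precomputed [grm_parts()].
#' @return A `grm` object: `K` (n x n matrix), `excluded_chrom`,
#'   `n_markers_used`, `denominator`.
#' @export
build_loco_grm <- function(D = NULL, chrom = NULL, exclude_chrom = NULL,
                           parts = NULL) {
  if (is.null(parts)) parts <- grm_parts(D, chrom)
  labs <- parts$labs
  use <- if (is.null(exclude_chrom)) labs else setdiff(labs, exclude_chrom)
  if (length(use) == 0L) {
    stop("all markers lie on the excluded chromosome; no GRM can be built",
         call. = FALSE)
  }
  num <- Reduce(`+`, parts$num[use])
  den <- sum(parts$den[use])
  if (den <= 0) stop("GRM denominator 2*sum(p(1-p)) is zero", call. = FALSE)
  structure(list(K = num / den,
                 excluded_chrom = exclude_chrom,
                 n_markers_used = sum(parts$n_markers[use]),
                 denominator = den),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("<grm>", nrow(x$K), "x", ncol(x$K), "from", x$n_markers_used,
      "markers",
      if (!is.null(x$excluded_chrom))
        paste0("(excluding chromosome ", x$excluded_chrom, ")") else "",
      "\n")
  invisible(x)
}
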