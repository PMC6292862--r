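#' Simulate breeding values and EBVs with known reliability
#'
#' True breeding values are the sum of a polygenic term (a linear combination
#' of centered SNP dosages, rescaled so its realized variance equals
#' `h2 - var(cnv term)`) and a copy-number term `cnv_effect * copies`, so the
#' tag haplotype is only a proxy for the causal diploid copy number. EBVs are
#' then generated to satisfy the definitional property of reliability
#' (squared accuracy): `EBV = r2 * BV + e` with `var(e) = r2 (1 - r2) var(BV)`,
#' giving `cor(EBV, BV)^2 = r2` in expectation. Reliabilities are drawn
#' uniformly from `cfg$reliability_range`.
#'
#' @param geno A `phased_geno` from [simulate_phased_population()].
#' @param truth Matching ground-truth data frame (needs a `copies` column).
#' @param cfg The [sim_config()] used to generate them.
#' @param polygenic How the polygenic term is generated. `"unlinked"` (the
#'   default) draws independent animal effects, representing the summed
#'   effects of the vast untyped background genome: on a compressed
#'   simulated panel this keeps the per-window share of polygenic variance
#'   negligible, as it is on a real high-density array, so the focal CNV is
#'   the only window-scale QTL. `"panel"` builds the polygenic term from
#'   the typed markers themselves (`D %*% a`); on a compressed panel this
#'   makes individual founder segments sizeable QTLs in their own right.
#' @param seed Optional seed overriding `cfg$seed + 1`.
#' @return Data frame: sample, bv (true breeding value), ebv, r2. The true
#'   variance components on the phenotypic scale are attached as attributes
#'   `sigma2_u` (= h2) and `sigma2_e` (= 1 - h2).
#' @export
simulate_phenotypes <- function(geno, truth, cfg,
                                polygenic = c("unlinked", "panel"),
                                seed = NULL) {
  polygenic <- match.arg(polygenic)
  stopifnot(inherits(geno, "phased_geno"), inherits(cfg, "sim_config"))
  if (!identical(truth$sample, geno$samples)) {
    stop("truth is not aligned to the genotype samples", call. = FALSE)
  }
  stop_if_not_scalar_prob(cfg$h2, "h2", open_lo = TRUE, open_hi = TRUE)
  with_seed(seed %||% (cfg$seed + 1L), {
    n <- length(geno$samples)
    cnv_term <- cfg$cnv_effect * truth$copies
    var_cnv <- var_n(cnv_term)
    sigma_g2 <- max(cfg$h2 - var_cnv, 0.05 * cfg$h2)

    g <- if (polygenic == "panel") {
      D <- dosages(geno)
      as.numeric(D %*% rnorm(ncol(D)))
    } else {
      rnorm(n)
    }
    g <- g - mean(g)
    sg <- sd_n(g)
    if (sg > 0) g <- g * sqrt(sigma_g2) / sg

    bv <- g + cnv_term
    lo <- cfg$reliability_range[1]; hi <- cfg$reliability_range[2]
    r2 <- if (hi > lo) runif(n, lo, hi) else rep(lo, n)
    vb <- var_n(bv)
    ebv <- r2 * bv + rnorm(n, sd = sqrt(pmax(r2 * (1 - r2) * vb, 0)))

    out <- data.frame(sample = geno$samples, bv = bv, ebv = ebv, r2 = r2,
                      stringsAsFactors = FALSE)
    attr(out, "sigma2_u") <- cfg$h2
    attr(out, "sigma2_e") <- 1 - cfg$h2
    out
  })
}
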