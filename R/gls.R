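#' Per-pseudo-marker generalized least squares association scan
#'
#' For each pseudo-marker, fits `y = 1 mu + x b + u + e` by GLS under
#' `V = G sigma_u^2 + I sigma_e^2`, with `x` the haplotype counts
#' standardized to mean 0 and (population) SD 1. One eigendecomposition of
#' the GRM rotates the problem to a diagonal covariance, after which each
#' marker test is linear time. The Wald statistic `(b/se)^2` is referred to
#' the upper tail of a chi-square with 1 df.
#'
#' @param y Phenotype vector (deregressed EBVs).
#' @param counts `n x K` matrix of haplotype counts (0/1/2), one column per
#'   pseudo-marker.
#' @param vc A `variance_components` fit (estimated once per chromosome on
#'   the reduced, no-marker model).
#' @param grm The LOCO `grm` (or plain matrix) used for `vc`.
#' @param eigen_grm Optional precomputed eigendecomposition of the GRM.
#' @param info Optional data frame (one row per column of `counts`) carried
#'   through to the output.
#' @return Data frame with b_hat, se, wald, p (plus `info` columns).
#'   Zero-variance pseudo-markers are skipped with a warning.
#' @export
gls_scan <- function(y, counts, vc, grm = NULL, eigen_grm = NULL,
                     info = NULL) {
  if (is.vector(counts)) counts <- matrix(counts, ncol = 1L)
  n <- length(y)
  stopifnot(nrow(counts) == n)
  if (!is.null(info)) stopifnot(nrow(info) == ncol(counts))

  mu <- colMeans(counts)
  s <- sqrt(colMeans(counts^2) - mu^2)
  keep <- s > 0
  if (any(!keep)) {
    warning(sum(!keep), " zero-variance pseudo-marker(s) skipped")
    counts <- counts[, keep, drop = FALSE]
    mu <- mu[keep]; s <- s[keep]
    if (!is.null(info)) info <- info[keep, , drop = FALSE]
  }
  if (ncol(counts) == 0L) stop("no testable pseudo-markers", call. = FALSE)
  X <- sweep(sweep(counts, 2L, mu), 2L, s, `/`)

  if (is.null(eigen_grm)) {
    K <- if (inherits(grm, "grm")) grm$K else grm
    stopifnot(!is.null(K))
    eigen_grm <- eigen(K, symmetric = TRUE)
  }
  U <- eigen_grm$vectors
  d <- pmax(eigen_grm$values, 0)
  w <- 1 / (vc$sigma2_u * d + vc$sigma2_e)

  yt <- as.numeric(crossprod(U, y))
  ot <- as.numeric(crossprod(U, rep(1, n)))
  Xt <- crossprod(U, X)

  a11 <- sum(ot^2 * w)
  a1y <- sum(ot * w * yt)
  a1x <- as.numeric(crossprod(Xt, w * ot))
  axx <- as.numeric(crossprod(Xt^2, w))
  axy <- as.numeric(crossprod(Xt, w * yt))

  det <- a11 * axx - a1x^2
  b <- (a11 * axy - a1x * a1y) / det
  se <- sqrt(a11 / det)
  wald <- (b / se)^2
  p <- stats::pchisq(wald, df = 1L, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)

  out <- data.frame(b_hat = b, se = se, wald = wald, p = p)
  if (!is.null(info)) out <- cbind(info, out)
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected per-test significance threshold
#'
#' @param n_tests Number of tests performed (>= 1).
#' @param alpha Family-wise error rate (default 0.05).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  stopifnot(n_tests >= 1, alpha > 0, alpha <= 1)
  alpha / n_tests
}

#' Percent of phenotypic variance explained by a standardized effect
#'
#' With `x` standardized to unit (population) variance, the locus variance is
#' `b_hat^2`, reported as a percentage of `var(y)` (denominator n).
#'
#' @param b_hat Effect estimate on the standardized-count scale.
#' @param y Phenotype vector.
#' @return Percent of variance explained.
#' @export
variance_explained <- function(b_hat, y) {
  vy <- var_n(y)
  if (vy == 0) stop("phenotype variance is zero", call. = FALSE)
  100 * b_hat^2 / vy
}

#' Regression screen of a haplotype against additional traits
#'
#' Regresses each trait's deregressed EBVs onto raw haplotype counts with an
#' intercept, by ordinary and (when weights are supplied) weighted least
#' squares; two-sided t-test p-values, significance read at nominal p < 0.05.
#'
#' @param traits Data frame or matrix, one column per trait, rows aligned
#'   with `counts`.
#' @param counts Haplotype count vector (0/1/2), raw scale.
#' @param weights Optional vector or one-column-per-trait matrix of
#'   regression weights.
#' @return Data frame: trait, mode ("unweighted"/"weighted"), n, estimate,
#'   se, t, p. A constant trait yields estimate 0 with p reported as 1.
#' @export
pleiotropy_screen <- function(traits, counts, weights = NULL) {
  traits <- as.data.frame(traits)
  stopifnot(nrow(traits) == length(counts))
  if (nrow(traits) < 3L) stop("need at least 3 observations", call. = FALSE)
  one_fit <- function(yy, ww, mode, trait) {
    ok <- stats::complete.cases(yy, counts)
    yv <- yy[ok]; xv <- counts[ok]
    if (length(yv) < 3L) stop("need at least 3 observations", call. = FALSE)
    if (var_n(yv) == 0 || var_n(xv) == 0) {
      return(data.frame(trait = trait, mode = mode, n = length(yv),
                        estimate = 0, se = NA_real_, t = NA_real_, p = 1))
    }
    fit <- if (is.null(ww)) stats::lm(yv ~ xv)
           else stats::lm(yv ~ xv, weights = ww[ok])
    cf <- summary(fit)$coefficients
    data.frame(trait = trait, mode = mode, n = length(yv),
               estimate = cf[2L, 1L], se = cf[2L, 2L], t = cf[2L, 3L],
               p = cf[2L, 4L])
  }
  rows <- list()
  for (j in seq_along(traits)) {
    tn <- names(traits)[j]
    rows[[length(rows) + 1L]] <- one_fit(traits[[j]], NULL, "unweighted", tn)
    if (!is.null(weights)) {
      wj <- if (is.matrix(weights) || is.data.frame(weights))
        as.data.frame(weights)[[j]] else weights
      rows[[length(rows) + 1L]] <- one_fit(traits[[j]], wj, "weighted", tn)
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p < 0.05
  rownames(out) <- NULL
  out
}
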