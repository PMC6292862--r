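#' Deregress an estimated breeding value
#'
#' Converts an EBV with reliability r2 into a deregressed pseudo-phenotype.
#' In `"simple"` mode (the default, used when no parent-average information
#' is available) the shrinkage is divided out directly: `debv = ebv / r2`,
#' and the reliability of the deregressed proof is taken as r2 itself.
#' `"full"` mode additionally removes the parent-average contribution by
#' back-solving the standard two-equation mixed-model system for the
#' parent-average and individual information contents.
#'
#' @param ebv Estimated breeding value (trait units). Vectorized.
#' @param r2 Reliability of the EBV, in (0, 1].
#' @param mode `"simple"` or `"full"`.
#' @param pa,pa_r2 Parent average EBV and its reliability (`"full"` mode).
#' @param h2 Trait heritability (`"full"` mode).
#' @return A data frame with columns `debv` and `r2_debv`.
#' @export
deregress <- function(ebv, r2, mode = c("simple", "full"),
                      pa = NULL, pa_r2 = NULL, h2 = NULL) {
  mode <- match.arg(mode)
  if (any(r2 <= 0) || any(r2 > 1)) {
    stop("reliability r2 must lie in (0, 1]", call. = FALSE)
  }
  if (mode == "simple") {
    return(data.frame(debv = ebv / r2, r2_debv = r2))
  }
  stopifnot(!is.null(pa), !is.null(pa_r2), !is.null(h2))
  stop_if_not_scalar_prob(h2, "h2", open_lo = TRUE, open_hi = TRUE)
  if (any(pa_r2 < 0) || any(pa_r2 >= 0.5)) {
    stop("parent-average reliability must lie in [0, 0.5)", call. = FALSE)
  }
  if (any(r2 <= pa_r2)) {
    stop("individual reliability must exceed the parent-average reliability",
         call. = FALSE)
  }
  lambda <- (1 - h2) / h2
  n <- length(ebv)
  debv <- numeric(n); r2_debv <- numeric(n)
  for (i in seq_len(n)) {
    alpha <- 1 / (0.5 - pa_r2[i])
    delta <- (0.5 - pa_r2[i]) / (1 - r2[i])
    zz_pa <- lambda * (0.5 * alpha - 4) +
      0.5 * lambda * sqrt(alpha^2 + 16 / delta)
    zz_i <- delta * zz_pa + 2 * lambda * (2 * delta - 1)
    lhs <- matrix(c(zz_pa + 4 * lambda, -2 * lambda,
                    -2 * lambda, zz_i + 2 * lambda), 2L, 2L)
    rhs <- lhs %*% c(pa[i], ebv[i])
    debv[i] <- rhs[2L] / zz_i
    r2_debv[i] <- 1 - lambda / (zz_i + lambda)
  }
  data.frame(debv = debv, r2_debv = r2_debv)
}

#' Filter pseudo-phenotype records on accuracy
#'
#' Accuracy is the square root of reliability; records with accuracy at or
#' above the threshold are retained (boundary inclusive).
#'
#' @param records Data frame with an `r2_debv` (or `r2`) reliability column.
#' @param min_accuracy Minimum accuracy (default 0.70).
#' @return The retained rows.
#' @export
accuracy_filter <- function(records, min_accuracy = 0.70) {
  r2 <- records$r2_debv %||% records$r2
  if (is.null(r2)) stop("records must carry an r2_debv or r2 column",
                        call. = FALSE)
  records[sqrt(r2) >= min_accuracy, , drop = FALSE]
}

#' Regression weight for a deregressed record
#'
#' `w = (1 - h2) / ((c + (1 - r2) / r2) * h2)`, where `c` is the fraction of
#' genetic variance not accounted for by markers. Weights are used in the
#' weighted regression screen of secondary traits.
#'
#' @param r2 Reliability of the deregressed proof, in (0, 1]. Vectorized.
#' @param h2 Trait heritability in (0, 1).
#' @param c Fraction of genetic variance not captured by markers, in [0, 1);
#'   default 0.5.
#' @return Numeric weight(s), strictly positive.
#' @export
garrick_weight <- function(r2, h2, c = 0.5) {
  stop_if_not_scalar_prob(h2, "h2", open_lo = TRUE, open_hi = TRUE)
  stop_if_not_scalar_prob(c, "c", open_hi = TRUE)
  if (any(r2 <= 0) || any(r2 > 1)) {
    stop("reliability r2 must lie in (0, 1]", call. = FALSE)
  }
  denom <- (c + (1 - r2) / r2) * h2
  if (any(denom <= 0)) {
    stop("degenerate weight: c = 0 with r2 = 1 gives an infinite weight",
         call. = FALSE)
  }
  (1 - h2) / denom
}
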