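# All REML quantities are computed in the eigenbasis of G: with
# G = U diag(d) U', V = sigma_u^2 G + sigma_e^2 I is diagonal after rotating
# y and the intercept by U', so every trace and quadratic form costs O(n).

reml_pieces <- function(theta, d, xt, yt) {
  v <- theta[1L] * d + theta[2L]
  w <- 1 / v
  xwx <- sum(xt * xt * w)
  xwy <- sum(xt * yt * w)
  ywy <- sum(yt * yt * w)
  ypy <- ywy - xwy^2 / xwx
  ll <- -0.5 * (sum(log(v)) + log(xwx) + ypy)
  py <- w * yt - w * xt * (xwy / xwx)
  list(v = v, w = w, xwx = xwx, ll = ll, py = py)
}

apply_p <- function(v, w, xt, xwx) {
  w * v - w * xt * (sum(xt * w * v) / xwx)
}

#' REML log-likelihood of the intercept-only animal model
#'
#' Log restricted likelihood (up to an additive constant) of
#' `y ~ N(1 mu, G sigma_u^2 + I sigma_e^2)`; exposed so variance-component
#' surfaces can be inspected and gridded.
#'
#' @param sigma2_u,sigma2_e Variance components (both > 0).
#' @param y Phenotype vector.
#' @param grm A `grm` object or plain relationship matrix.
#' @param eigen_grm Optional precomputed `eigen(K, symmetric = TRUE)`.
#' @return The REML log-likelihood value.
#' @export
reml_loglik <- function(sigma2_u, sigma2_e, y, grm, eigen_grm = NULL) {
  K <- if (inherits(grm, "grm")) grm$K else grm
  eg <- eigen_grm %||% eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  yt <- as.numeric(crossprod(eg$vectors, y))
  xt <- as.numeric(crossprod(eg$vectors, rep(1, length(y))))
  reml_pieces(c(sigma2_u, sigma2_e), d, xt, yt)$ll
}

#' Estimate variance components by AI-REML
#'
#' Fits `y ~ N(1 mu, G sigma_u^2 + I sigma_e^2)` by average-information
#' restricted maximum likelihood. Each iteration proposes the AI update
#' (score vector `-(tr(P Vdot_i) - y'P Vdot_i P y)/2`, AI matrix
#' `y'P Vdot_i P Vdot_j P y / 2`); when the AI step fails to increase the
#' restricted log-likelihood the update falls back to a monotone EM-type
#' step. Components are floored at `floor_frac * var(y)`.
#'
#' @param y Phenotype vector (n >= 10).
#' @param grm A `grm` object (or plain symmetric matrix) aligned with `y`.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Maximum iterations.
#' @param floor_frac Variance floor as a fraction of `var(y)`.
#' @param eigen_grm Optional precomputed eigendecomposition of the GRM.
#' @return A `variance_components` list: sigma2_u, sigma2_e, h2, loglik,
#'   iterations, converged.
#' @export
aireml <- function(y, grm, tol = 1e-8, max_iter = 200L, floor_frac = 1e-6,
                   eigen_grm = NULL) {
  K <- if (inherits(grm, "grm")) grm$K else grm
  n <- length(y)
  stopifnot(n >= 10L, nrow(K) == n)
  eg <- eigen_grm %||% eigen(K, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values), 1)) {
    stop("GRM is not positive semidefinite within tolerance", call. = FALSE)
  }
  d <- pmax(eg$values, 0)
  yt <- as.numeric(crossprod(eg$vectors, y))
  xt <- as.numeric(crossprod(eg$vectors, rep(1, n)))

  vy <- stats::var(y)
  floor_v <- floor_frac * vy
  theta <- c(u = 0.5 * vy, e = 0.5 * vy)
  pc <- reml_pieces(theta, d, xt, yt)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    w <- pc$w; py <- pc$py; xwx <- pc$xwx
    tr_pg <- sum(w * d) - sum(w^2 * d * xt^2) / xwx
    tr_p <- sum(w) - sum(w^2 * xt^2) / xwx
    score <- -0.5 * c(tr_pg - sum(d * py^2), tr_p - sum(py^2))
    a <- d * py
    pa <- apply_p(a, w, xt, xwx)
    pb <- apply_p(py, w, xt, xwx)
    ai <- 0.5 * matrix(c(sum(a * pa), sum(a * pb),
                         sum(py * pa), sum(py * pb)), 2L, 2L)
    cand <- NULL
    delta <- tryCatch(solve(ai, score), error = function(e) NULL)
    if (!is.null(delta)) {
      # step-halve the AI proposal until the likelihood improves
      for (h in 0:4) {
        th_try <- pmax(theta + delta / 2^h, floor_v)
        pc_try <- reml_pieces(th_try, d, xt, yt)
        if (is.finite(pc_try$ll) && pc_try$ll >= pc$ll - 1e-12) {
          cand <- list(theta = th_try, pc = pc_try)
          break
        }
      }
    }
    if (is.null(cand)) {
      # monotone EM-type fallback: theta_i <- theta_i * y'P Vdot P y / tr(P Vdot)
      th_em <- pmax(c(theta[1L] * sum(d * py^2) / max(tr_pg, 1e-300),
                      theta[2L] * sum(py^2) / max(tr_p, 1e-300)), floor_v)
      pc_em <- reml_pieces(th_em, d, xt, yt)
      if (!is.finite(pc_em$ll)) break
      cand <- list(theta = th_em, pc = pc_em)
    }
    dll <- cand$pc$ll - pc$ll
    theta <- cand$theta
    pc <- cand$pc
    if (abs(dll) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("AI-REML did not converge in ", max_iter, " iterations")
  }
  structure(list(sigma2_u = unname(theta[1L]), sigma2_e = unname(theta[2L]),
                 h2 = unname(theta[1L] / sum(theta)),
                 loglik = pc$ll, iterations = iter, converged = converged),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "<variance_components> sigma2_u %.4g, sigma2_e %.4g (h2 %.3f), loglik %.4f, %d iter%s\n",
    x$sigma2_u, x$sigma2_e, x$h2, x$loglik, x$iterations,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}
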