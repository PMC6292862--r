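`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global random state so simulator calls never leak
#' randomness into (or depend on) the caller's stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# 31-polynomial rolling hash (mod 2^31 - 1) over the deparsed object; used
# to stamp outputs with a config hash without a hashing dependency.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# population (denominator n) variance / sd
var_n <- function(x) mean((x - mean(x))^2)
sd_n <- function(x) sqrt(var_n(x))

stop_if_not_scalar_prob <- function(x, name, lo = 0, hi = 1,
                                    open_lo = FALSE, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lo) x > lo else x >= lo) &&
    (if (open_hi) x < hi else x <= hi)
  if (!ok) stop(sprintf("`%s` must be a single value in %s%g, %g%s",
                        name, if (open_lo) "(" else "[", lo, hi,
                        if (open_hi) ")" else "]"), call. = FALSE)
  invisible(x)
}
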