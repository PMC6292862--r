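# Small in-code fixtures shared across test files.

# hand-built 4-sample, 1-chromosome phased genotype set
toy_geno <- function() {
  map <- data.frame(
    id = paste0("M", 1:9), chrom = "1", pos = seq(1000L, 9000L, 1000L),
    allele_a = rep("A", 9), allele_b = rep("C", 9),
    call_rate = 1, maf = 0.25, gentrain = 0.9,
    stringsAsFactors = FALSE)
  # 8 haplotypes over 9 markers
  H <- rbind(
    c(1, 1, 1, 0, 0, 0, 1, 1, 1),  # s1 hap1
    c(1, 1, 1, 0, 0, 0, 1, 1, 1),  # s1 hap2 (homozygous)
    c(0, 0, 0, 0, 0, 0, 0, 0, 0),  # s2 hap1
    c(1, 1, 1, 0, 0, 0, 1, 1, 1),  # s2 hap2
    c(0, 0, 0, 1, 1, 1, 0, 0, 0),  # s3 hap1
    c(0, 0, 0, 0, 0, 0, 0, 0, 0),  # s3 hap2
    c(1, 0, 1, 0, 1, 0, 1, 0, 1),  # s4 hap1
    c(0, 1, 0, 1, 0, 1, 0, 1, 0))  # s4 hap2
  storage.mode(H) <- "integer"
  new_phased_geno(paste0("s", 1:4), map, H)
}

# small random GRM-like PSD matrix
toy_grm <- function(n, m = 4L * n, seed = 1L) {
  with_seed <- get("with_seed", asNamespace("haplocnv"))
  with_seed(seed, {
    Z <- matrix(stats::rbinom(n * m, 2L, 0.4), n)
    p <- colMeans(Z) / 2
    Zc <- sweep(Z, 2L, 2 * p)
    tcrossprod(Zc) / (2 * sum(p * (1 - p)))
  })
}

# dense-matrix REML log-likelihood (independent oracle)
dense_reml_ll <- function(su, se, y, K) {
  n <- length(y)
  V <- su * K + diag(se, n)
  X <- matrix(1, n)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  as.numeric(-0.5 * (determinant(V)$modulus + log(XVX) + t(y) %*% P %*% y))
}

# dense GLS oracle for [1 x] under V = su*K + se*I
dense_gls <- function(y, x, su, se, K) {
  n <- length(y)
  xs <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  X <- cbind(1, xs)
  Vi <- solve(su * K + diag(se, n))
  A <- solve(t(X) %*% Vi %*% X)
  b <- A %*% t(X) %*% Vi %*% y
  list(b = b[2L], se = sqrt(A[2L, 2L]))
}
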