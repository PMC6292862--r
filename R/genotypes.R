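#' Construct a phased genotype matrix
#'
#' @param samples Character vector of sample ids (length n).
#' @param map Marker map data frame with at least id, chrom, pos, allele_a,
#'   allele_b; optionally call_rate, maf, gentrain QC metrics.
#' @param H Integer haplotype matrix, `2n x m`, coded 0 (allele A) / 1
#'   (allele B); sample `i` occupies rows `2i-1` and `2i`. Input is assumed
#'   post-phasing: missing calls are a hard error.
#' @return A `phased_geno` object.
#' @export
new_phased_geno <- function(samples, map, H) {
  n <- length(samples)
  stopifnot(is.matrix(H), nrow(H) == 2L * n, ncol(H) == nrow(map))
  if (anyNA(H)) stop("phased genotypes must be complete (no missing calls)",
                     call. = FALSE)
  if (!all(H %in% c(0L, 1L))) stop("haplotype calls must be 0/1", call. = FALSE)
  req <- c("id", "chrom", "pos", "allele_a", "allele_b")
  if (!all(req %in% names(map))) {
    stop("map must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("marker positions must be strictly increasing within chromosome ",
           ch, call. = FALSE)
    }
  }
  structure(list(samples = samples, map = map, H = H), class = "phased_geno")
}

#' @export
print.phased_geno <- function(x, ...) {
  cat("<phased_geno>", length(x$samples), "samples x", nrow(x$map),
      "markers on", length(unique(x$map$chrom)), "chromosomes\n")
  invisible(x)
}

#' Diploid dosage matrix (count of allele B per sample per marker)
#'
#' @param geno A `phased_geno`.
#' @return An `n x m` integer matrix.
#' @export
dosages <- function(geno) {
  stopifnot(inherits(geno, "phased_geno"))
  n2 <- nrow(geno$H)
  D <- geno$H[seq(1L, n2, 2L), , drop = FALSE] +
    geno$H[seq(2L, n2, 2L), , drop = FALSE]
  rownames(D) <- geno$samples
  D
}

#' Subset a phased genotype matrix to a set of markers
#'
#' @param geno A `phased_geno`.
#' @param keep Integer or logical index into the marker map.
#' @return A `phased_geno` restricted to the kept markers, order preserved.
#' @export
subset_markers <- function(geno, keep) {
  new_phased_geno(geno$samples, geno$map[keep, , drop = FALSE],
                  geno$H[, keep, drop = FALSE])
}

#' Marker quality-control filter
#'
#' Retains autosomal markers with unique genomic coordinates that meet
#' minimum call rate, GenTrain score and minor allele frequency thresholds
#' (all boundaries inclusive). Markers sharing a (chrom, pos) coordinate are
#' all removed.
#'
#' @param markers Marker map data frame with call_rate, gentrain, maf columns.
#' @param min_call_rate,min_gentrain,min_maf Inclusive lower bounds
#'   (defaults 0.95, 0.70, 0.02).
#' @param autosomes Optional character vector of autosomal chromosome labels;
#'   by default every label except X, Y, XY, MT/M (case-insensitive) counts
#'   as autosomal.
#' @return The retained rows of `markers`, original order preserved. May be
#'   empty.
#' @export
qc_filter_markers <- function(markers, min_call_rate = 0.95,
                              min_gentrain = 0.70, min_maf = 0.02,
                              autosomes = NULL) {
  stopifnot(all(c("chrom", "pos", "call_rate", "gentrain", "maf") %in%
                  names(markers)))
  coord <- paste(markers$chrom, markers$pos, sep = ":")
  unique_coord <- !(duplicated(coord) | duplicated(coord, fromLast = TRUE))
  auto <- if (is.null(autosomes)) {
    !toupper(markers$chrom) %in% c("X", "Y", "XY", "MT", "M")
  } else {
    markers$chrom %in% autosomes
  }
  keep <- markers$call_rate >= min_call_rate &
    markers$gentrain >= min_gentrain &
    markers$maf >= min_maf &
    unique_coord & auto
  markers[keep, , drop = FALSE]
}

#' Apply marker QC to a phased genotype matrix
#'
#' @inheritParams qc_filter_markers
#' @param geno A `phased_geno` whose map carries QC metric columns.
#' @return The QC-filtered `phased_geno`.
#' @export
apply_marker_qc <- function(geno, min_call_rate = 0.95, min_gentrain = 0.70,
                            min_maf = 0.02, autosomes = NULL) {
  kept <- qc_filter_markers(geno$map, min_call_rate, min_gentrain, min_maf,
                            autosomes)
  subset_markers(geno, match(kept$id, geno$map$id))
}

# window haplotype codes for one chromosome: 2n x (m - L + 1) integer matrix,
# marker j of the window contributing bit 2^(j-1)
window_codes <- function(Hc, L) {
  mc <- ncol(Hc)
  nw <- mc - L + 1L
  stopifnot(nw >= 1L)
  codes <- matrix(0L, nrow = nrow(Hc), ncol = nw)
  w2 <- as.integer(2^(0:(L - 1L)))
  codes[, 1L] <- as.integer(Hc[, 1:L, drop = FALSE] %*% w2)
  if (nw > 1L) {
    for (w in 2:nw) {
      codes[, w] <- (codes[, w - 1L] - Hc[, w - 1L]) %/% 2L +
        Hc[, w + L - 1L] * w2[L]
    }
  }
  codes
}

decode_allele <- function(code, alleles_a, alleles_b) {
  L <- length(alleles_a)
  bits <- (code %/% 2^(0:(L - 1L))) %% 2
  paste(ifelse(bits == 1, alleles_b, alleles_a), collapse = "")
}

#' Enumerate sliding haplotype windows
#'
#' Builds overlapping windows of `L` consecutive markers (step 1), never
#' spanning a chromosome boundary, and enumerates the haplotype alleles
#' observed in each window with their population frequencies (computed over
#' all `2n` phased haplotypes).
#'
#' @param geno A `phased_geno` (post QC).
#' @param L Window size in markers; `L = 1` reduces to single-SNP analysis.
#' @return A `hap_window_set`: list with `windows` (win_id, chrom, start_idx,
#'   start_bp, end_bp, n_alleles), `alleles` (win_id, allele string, code,
#'   freq) and the window size `L`.
#' @export
build_windows <- function(geno, L = 6L) {
  stopifnot(inherits(geno, "phased_geno"), L >= 1L, L <= 25L)
  map <- geno$map
  win_rows <- list(); al_rows <- list()
  for (ch in unique(map$chrom)) {
    cols <- which(map$chrom == ch)
    if (length(cols) < L) {
      warning("chromosome ", ch, " has fewer than ", L,
              " markers; no windows built there")
      next
    }
    codes <- window_codes(geno$H[, cols, drop = FALSE], L)
    nw <- ncol(codes)
    starts <- cols[seq_len(nw)]
    aa <- map$allele_a[cols]; ab <- map$allele_b[cols]
    counts_by_win <- lapply(seq_len(nw), function(w) {
      tb <- tabulate(codes[, w] + 1L, nbins = 2L^L)
      nz <- which(tb > 0L)
      list(code = nz - 1L, count = tb[nz])
    })
    n_alleles <- vapply(counts_by_win, function(z) length(z$code), 0L)
    win_rows[[ch]] <- data.frame(
      chrom = ch, start_idx = starts,
      start_bp = map$pos[starts], end_bp = map$pos[starts + L - 1L],
      n_alleles = n_alleles, stringsAsFactors = FALSE
    )
    al_rows[[ch]] <- do.call(rbind, lapply(seq_len(nw), function(w) {
      z <- counts_by_win[[w]]
      loc <- seq_len(L) + (w - 1L)
      data.frame(
        chrom = ch, start_idx = starts[w],
        allele = vapply(z$code, decode_allele, "", aa[loc], ab[loc]),
        code = z$code, freq = z$count / nrow(codes),
        stringsAsFactors = FALSE
      )
    }))
  }
  windows <- do.call(rbind, win_rows)
  if (is.null(windows) || nrow(windows) == 0L) {
    stop("no windows could be built", call. = FALSE)
  }
  rownames(windows) <- NULL
  windows$win_id <- paste0(windows$chrom, ":", windows$start_idx)
  alleles <- do.call(rbind, al_rows)
  rownames(alleles) <- NULL
  alleles$win_id <- paste0(alleles$chrom, ":", alleles$start_idx)
  structure(list(windows = windows, alleles = alleles, L = as.integer(L)),
            class = "hap_window_set")
}

#' @export
print.hap_window_set <- function(x, ...) {
  cat("<hap_window_set>", nrow(x$windows), "windows of", x$L, "markers,",
      nrow(x$alleles), "haplotype alleles\n")
  invisible(x)
}

#' Code haplotype alleles as biallelic pseudo-markers
#'
#' Every (window, allele) pair whose frequency lies inside
#' `[freq_min, freq_max]` becomes a pseudo-marker whose genotype is the
#' number of copies (0, 1 or 2) of that haplotype allele carried by each
#' sample.
#'
#' @param geno A `phased_geno` (the one used in [build_windows()]).
#' @param windows A `hap_window_set`.
#' @param freq_min,freq_max Inclusive haplotype frequency bounds
#'   (defaults 0.05, 0.95).
#' @return A `pseudo_markers` object: `info` data frame (pm_id, win_id,
#'   chrom, start_idx, start_bp, end_bp, allele, freq) aligned with the
#'   columns of the `n x K` integer `counts` matrix.
#' @export
code_pseudo_markers <- function(geno, windows, freq_min = 0.05,
                                freq_max = 0.95) {
  stopifnot(inherits(windows, "hap_window_set"),
            freq_min > 0, freq_max < 1, freq_min < freq_max)
  L <- windows$L
  keep <- windows$alleles[windows$alleles$freq >= freq_min &
                            windows$alleles$freq <= freq_max, , drop = FALSE]
  n <- length(geno$samples)
  odd <- seq(1L, 2L * n, 2L); even <- odd + 1L
  info_list <- list(); count_cols <- list()
  for (ch in unique(windows$windows$chrom)) {
    cols <- which(geno$map$chrom == ch)
    kc <- keep[keep$chrom == ch, , drop = FALSE]
    if (nrow(kc) == 0L) next
    codes <- window_codes(geno$H[, cols, drop = FALSE], L)
    starts <- cols[seq_len(ncol(codes))]
    wloc <- match(kc$start_idx, starts)
    cnt <- matrix(0L, nrow = n, ncol = nrow(kc))
    for (j in seq_len(nrow(kc))) {
      is_al <- codes[, wloc[j]] == kc$code[j]
      cnt[, j] <- is_al[odd] + is_al[even]
    }
    winfo <- windows$windows[match(kc$win_id, windows$windows$win_id), ]
    info_list[[ch]] <- data.frame(
      win_id = kc$win_id, chrom = ch, start_idx = kc$start_idx,
      start_bp = winfo$start_bp, end_bp = winfo$end_bp,
      allele = kc$allele, freq = kc$freq, stringsAsFactors = FALSE
    )
    count_cols[[ch]] <- cnt
  }
  if (length(info_list) == 0L) {
    stop("no pseudo-markers survive the frequency filter", call. = FALSE)
  }
  info <- do.call(rbind, info_list)
  rownames(info) <- NULL
  # deterministic ordering: chrom appearance order, then start, then allele
  ord <- order(match(info$chrom, unique(geno$map$chrom)), info$start_idx,
               info$allele)
  counts <- do.call(cbind, count_cols)[, ord, drop = FALSE]
  info <- info[ord, , drop = FALSE]
  info$pm_id <- paste0(info$win_id, ":", info$allele)
  rownames(info) <- NULL
  colnames(counts) <- info$pm_id
  structure(list(info = info, counts = counts, samples = geno$samples,
                 L = L), class = "pseudo_markers")
}

#' @export
print.pseudo_markers <- function(x, ...) {
  cat("<pseudo_markers>", ncol(x$counts), "pseudo-markers x",
      nrow(x$counts), "samples (window size", x$L, ")\n")
  invisible(x)
}

#' Merge tied overlapping window alleles into a consensus allele
#'
#' Windows tied as most significant at consecutive start positions are merged
#' into a single consensus haplotype allele of length `L + k - 1`: each
#' successive allele must agree with its predecessor over the shared `L - 1`
#' markers and contributes its final character.
#'
#' @param alleles Character vector of k window allele strings (equal length L).
#' @param start_idx Integer start indices of the windows; must be step-1
#'   consecutive after sorting.
#' @param map Optional marker map used to report the bp span of the consensus.
#' @return A list: `consensus` (string), `length`, and, when `map` is given,
#'   `span_bp` (position of first and last underlying marker) and `chrom`.
#' @export
merge_tied_windows <- function(alleles, start_idx, map = NULL) {
  stopifnot(length(alleles) == length(start_idx), length(alleles) >= 1L)
  o <- order(start_idx)
  alleles <- alleles[o]; start_idx <- start_idx[o]
  L <- nchar(alleles[1L])
  stopifnot(all(nchar(alleles) == L))
  k <- length(alleles)
  if (k > 1L && any(diff(start_idx) != 1L)) {
    stop("window start indices must be consecutive (step 1)", call. = FALSE)
  }
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      if (substr(alleles[i], 2L, L) != substr(alleles[i + 1L], 1L, L - 1L)) {
        stop(sprintf(
          "inconsistent overlap between windows at starts %d ('%s') and %d ('%s')",
          start_idx[i], alleles[i], start_idx[i + 1L], alleles[i + 1L]),
          call. = FALSE)
      }
    }
  }
  consensus <- paste0(alleles[1L],
                      paste(substring(alleles[-1L], L, L), collapse = ""))
  out <- list(consensus = consensus, length = L + k - 1L)
  if (!is.null(map)) {
    first <- start_idx[1L]; last <- start_idx[k] + L - 1L
    stopifnot(last <= nrow(map))
    out$span_bp <- c(map$pos[first], map$pos[last])
    out$chrom <- map$chrom[first]
  }
  out
}
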