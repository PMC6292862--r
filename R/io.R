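# Format adapters. Coordinates are 1-based inclusive in every TSV; BED is
# written 0-based half-open with the conversion confined to these two
# functions. PLINK-1 binary and SAM are parsed directly: both are simple,
# fully specified layouts and only a minimal field subset is needed.

#' Write a phased genotype matrix as a PLINK-1 binary triplet
#'
#' SNP-major .bed (magic `6c 1b 01`, two bits per genotype: 00 = hom A1,
#' 10 = het, 11 = hom A2) with A1 = allele_a, A2 = allele_b, plus .bim and
#' .fam sidecars. Phase is not representable in this format; use the Oxford
#' writer to preserve it.
#'
#' @param geno A `phased_geno`.
#' @param prefix Output path prefix (writes `<prefix>.bed/.bim/.fam`).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(geno, prefix) {
  D <- dosages(geno)
  write_plink_dosage(D, geno$map, geno$samples, prefix)
}

#' Write a dosage matrix as a PLINK-1 binary triplet
#'
#' Used both for SNPs and for pseudo-markers recoded as biallelic markers
#' (dosage = copies of the haplotype allele, A1 = "A" absence, A2 = "P"
#' presence).
#'
#' @param D `n x m` dosage matrix in 0/1/2.
#' @param map Data frame with id, chrom, pos and optionally allele_a,
#'   allele_b.
#' @param samples Sample ids.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink_dosage <- function(D, map, samples, prefix) {
  stopifnot(nrow(D) == length(samples), ncol(D) == nrow(map))
  a1 <- map$allele_a %||% rep("A", nrow(map))
  a2 <- map$allele_b %||% rep("P", nrow(map))
  bim <- data.frame(map$chrom, map$id, 0L, map$pos, a1, a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(samples, samples, 0L, 0L, 0L, -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  n <- length(samples)
  codes <- c(0x00, 0x02, 0x03)  # dosage 0/1/2 of A2
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  bytes_per_snp <- ceiling(n / 4)
  for (j in seq_len(ncol(D))) {
    g <- codes[D[, j] + 1L]
    g <- c(g, rep(0x00, bytes_per_snp * 4L - n))
    gm <- matrix(g, nrow = 4L)
    byte <- gm[1L, ] + gm[2L, ] * 4L + gm[3L, ] * 16L + gm[4L, ] * 64L
    writeBin(as.raw(byte), con)
  }
  invisible(prefix)
}

#' Write pseudo-markers as a PLINK-1 binary triplet with a sidecar TSV
#'
#' Each haplotype pseudo-marker becomes a biallelic marker whose genotype
#' is the count of the haplotype allele (A1 = "A" absence, A2 = "P"
#' presence); the marker id is the pseudo-marker id and its position the
#' window start. The sidecar TSV records window id, chromosome, start/end
#' bp, allele string and frequency.
#'
#' @param pm A `pseudo_markers` object.
#' @param prefix Output path prefix (writes `.bed/.bim/.fam` and
#'   `<prefix>_windows.tsv`).
#' @return `prefix`, invisibly.
#' @export
write_pseudo_markers <- function(pm, prefix) {
  stopifnot(inherits(pm, "pseudo_markers"))
  map <- data.frame(id = pm$info$pm_id, chrom = pm$info$chrom,
                    pos = pm$info$start_bp, stringsAsFactors = FALSE)
  write_plink_dosage(pm$counts, map, pm$samples, prefix)
  side <- pm$info[, c("win_id", "chrom", "start_bp", "end_bp", "allele",
                      "freq")]
  utils::write.table(side, paste0(prefix, "_windows.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read a PLINK-1 binary triplet into a dosage matrix
#'
#' @param prefix Path prefix of the `.bed/.bim/.fam` triplet.
#' @return List: `dosage` (`n x m`), `map` (chrom, id, pos, allele_a,
#'   allele_b), `samples`.
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), sep = "\t",
                           colClasses = c("character", "character",
                                          "integer", "integer",
                                          "character", "character"))
  names(bim) <- c("chrom", "id", "cm", "pos", "allele_a", "allele_b")
  fam <- utils::read.table(paste0(prefix, ".fam"), sep = "\t",
                           colClasses = "character")
  samples <- fam[[2L]]
  n <- length(samples); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3L + ceiling(n / 4) * m)
  if (length(raw) < 3L || !identical(as.integer(raw[1:3]),
                                     c(0x6cL, 0x1bL, 0x01L))) {
    stop("not a SNP-major PLINK .bed file (bad magic at byte offset 0)",
         call. = FALSE)
  }
  body <- as.integer(raw[-(1:3)])
  bytes_per_snp <- ceiling(n / 4)
  if (length(body) != bytes_per_snp * m) {
    stop(sprintf("truncated .bed: expected %d body bytes, found %d",
                 bytes_per_snp * m, length(body)), call. = FALSE)
  }
  two_bits <- function(b, k) (b %/% as.integer(4^k)) %% 4L
  lut <- c(`0` = 0L, `2` = 1L, `3` = 2L, `1` = NA_integer_)
  D <- matrix(NA_integer_, nrow = n, ncol = m)
  for (j in seq_len(m)) {
    bytes <- body[((j - 1L) * bytes_per_snp + 1L):(j * bytes_per_snp)]
    g <- c(vapply(0:3, function(k) two_bits(bytes, k),
                  integer(bytes_per_snp)))
    g <- as.vector(t(matrix(g, ncol = 4L)))[seq_len(n)]
    D[, j] <- lut[as.character(g)]
  }
  rownames(D) <- samples
  colnames(D) <- bim$id
  list(dosage = D, map = bim[, c("chrom", "id", "pos", "allele_a",
                                 "allele_b")], samples = samples)
}

#' Write phased haplotypes in Oxford haps/sample format
#'
#' @param geno A `phased_geno`.
#' @param prefix Output path prefix (writes `<prefix>.haps` and
#'   `<prefix>.sample`).
#' @return `prefix`, invisibly.
#' @export
write_haps_sample <- function(geno, prefix) {
  hap <- cbind(geno$map$chrom, geno$map$id, geno$map$pos,
               geno$map$allele_a, geno$map$allele_b, t(geno$H))
  utils::write.table(hap, paste0(prefix, ".haps"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  smp <- rbind(c("ID_1", "ID_2", "missing"), c("0", "0", "0"),
               cbind(geno$samples, geno$samples, "0"))
  utils::write.table(smp, paste0(prefix, ".sample"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read Oxford haps/sample files into a phased genotype matrix
#'
#' @param prefix Path prefix of the `.haps`/`.sample` pair.
#' @return A `phased_geno`.
#' @export
read_haps_sample <- function(prefix) {
  hap <- utils::read.table(paste0(prefix, ".haps"), sep = "",
                           colClasses = "character")
  smp <- utils::read.table(paste0(prefix, ".sample"), sep = "",
                           colClasses = "character", skip = 2L)
  samples <- smp[[2L]]
  map <- data.frame(id = hap[[2L]], chrom = hap[[1L]],
                    pos = as.integer(hap[[3L]]),
                    allele_a = hap[[4L]], allele_b = hap[[5L]],
                    stringsAsFactors = FALSE)
  H <- t(vapply(seq_len(nrow(hap)), function(i) {
    as.integer(hap[i, -(1:5)])
  }, integer(2L * length(samples))))
  if (anyNA(H)) stop("malformed haps record", call. = FALSE)
  new_phased_geno(samples, map, t(H))
}

#' Write a per-base depth matrix as a 4-column TSV
#'
#' Columns: sample, chrom, pos (1-based), reads.
#'
#' @param depth `bases x samples` matrix (row 1 = `region_start`).
#' @param chrom Chromosome label.
#' @param region_start 1-based position of the first row.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_depth_tsv <- function(depth, chrom, region_start, file) {
  pos <- region_start + seq_len(nrow(depth)) - 1L
  long <- data.frame(
    sample = rep(colnames(depth), each = nrow(depth)),
    chrom = chrom, pos = pos, reads = as.vector(depth))
  utils::write.table(long, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read a per-base depth TSV into a matrix
#'
#' @param file Path to a TSV with columns sample, chrom, pos, reads.
#' @return List: `depth` matrix (`bases x samples`), `chrom`,
#'   `region_start`.
#' @export
read_depth_tsv <- function(file) {
  long <- utils::read.table(file, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "chrom", "pos", "reads") %in% names(long)))
  long$chrom <- as.character(long$chrom)
  long$sample <- as.character(long$sample)
  samples <- unique(long$sample)
  pos <- sort(unique(long$pos))
  depth <- matrix(NA_integer_, nrow = length(pos), ncol = length(samples),
                  dimnames = list(NULL, samples))
  idx <- cbind(match(long$pos, pos), match(long$sample, samples))
  depth[idx] <- long$reads
  if (anyNA(depth)) stop("depth TSV does not tile the region completely",
                         call. = FALSE)
  list(depth = depth, chrom = long$chrom[1L], region_start = pos[1L])
}

#' Write read pairs as SAM text
#'
#' Two records per pair; FLAG bits encode read pairing (0x1), strand (0x10)
#' and mate strand (0x20); TLEN carries the signed inferred insert. SEQ is
#' omitted (`*`) since only geometry is simulated.
#'
#' @param pairs Read-pair data frame (sample, chrom, left_pos, right_pos,
#'   left_strand, right_strand, inferred_insert).
#' @param file Output path.
#' @param read_len Read length used for the CIGAR.
#' @param chrom_len Declared reference length for the @SQ header.
#' @return `file`, invisibly.
#' @export
write_sam_pairs <- function(pairs, file, read_len = 100L,
                            chrom_len = 250000000) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (ch in unique(pairs$chrom)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ch, as.integer(chrom_len)), con)
  }
  flag <- function(strand, mate_strand, first) {
    1L + 64L * first + 128L * (1L - first) +
      16L * (strand == "-") + 32L * (mate_strand == "-")
  }
  cigar <- sprintf("%dM", read_len)
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    qn <- sprintf("%s_pair%06d", p$sample, i)
    writeLines(c(
      paste(qn, flag(p$left_strand, p$right_strand, 1L), p$chrom,
            p$left_pos, 60L, cigar, "=", p$right_pos, p$inferred_insert,
            "*", "*", sep = "\t"),
      paste(qn, flag(p$right_strand, p$left_strand, 0L), p$chrom,
            p$right_pos, 60L, cigar, "=", p$left_pos, -p$inferred_insert,
            "*", "*", sep = "\t")), con)
  }
  invisible(file)
}

#' Read pairs from SAM text
#'
#' Pairs records by QNAME; the leftmost-aligned mate defines the pair's
#' left side and its FLAG 0x10 bit the left strand.
#'
#' @param file Path to a SAM file.
#' @return Read-pair data frame (sample taken from the QNAME prefix).
#' @export
read_sam_pairs <- function(file) {
  lines <- readLines(file)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) stop("SAM file has no alignment records",
                                call. = FALSE)
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 11L)
  if (length(bad) > 0L) {
    stop("malformed SAM record at line ", bad[1L], call. = FALSE)
  }
  qname <- vapply(f, `[[`, "", 1L)
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  chrom <- vapply(f, `[[`, "", 3L)
  pos <- as.integer(vapply(f, `[[`, "", 4L))
  strand <- ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")
  rows <- lapply(split(seq_along(qname), qname), function(ii) {
    if (length(ii) != 2L) return(NULL)
    o <- ii[order(pos[ii])]
    data.frame(sample = sub("_pair[0-9]+$", "", qname[o[1L]]),
               chrom = chrom[o[1L]],
               left_pos = pos[o[1L]], right_pos = pos[o[2L]],
               left_strand = strand[o[1L]], right_strand = strand[o[2L]],
               inferred_insert = abs(as.integer(f[[o[1L]]][[9L]])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Convert 1-based inclusive calls to BED and write them
#'
#' BED is 0-based half-open: a 1-based inclusive interval `[start, end]`
#' becomes the BED line `chrom  start-1  end`.
#'
#' @param calls Data frame with chrom, start_bp, end_bp (1-based inclusive).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_bed <- function(calls, file) {
  bed <- data.frame(calls$chrom, calls$start_bp - 1L, calls$end_bp)
  utils::write.table(bed, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a BED file into 1-based inclusive intervals
#'
#' @param file Path to a 3+ column BED file.
#' @return Data frame: chrom, start_bp, end_bp (1-based inclusive).
#' @export
read_bed <- function(file) {
  bed <- utils::read.table(file, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = as.character(bed[[1L]]), start_bp = bed[[2L]] + 1L,
             end_bp = bed[[3L]], stringsAsFactors = FALSE)
}
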