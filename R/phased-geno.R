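#' Construct a marker map
#'
#' A marker map records, for each SNP, its identifier, chromosome and
#' physical position in base pairs. Positions must be strictly increasing
#' within each chromosome and SNP identifiers unique; both are enforced
#' here because downstream window construction, LD-decay binning and
#' panel merging all assume sorted per-chromosome coordinates.
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param chrom integer chromosome index (1-based).
#' @param pos_bp integer physical position in base pairs (>= 0).
#' @return A `data.frame` of class `marker_map` with columns
#'   `snp_id`, `chrom`, `pos_bp`, ordered by chromosome then position.
#' @export
marker_map <- function(snp_id, chrom, pos_bp) {
  if (anyDuplicated(snp_id)) stop("duplicate snp_id in marker map")
  map <- data.frame(snp_id = as.character(snp_id),
                    chrom = as.integer(chrom),
                    pos_bp = as.integer(pos_bp),
                    stringsAsFactors = FALSE)
  if (any(map$pos_bp < 0)) stop("pos_bp must be >= 0")
  map <- map[order(map$chrom, map$pos_bp), , drop = FALSE]
  rownames(map) <- NULL
  for (ch in unique(map$chrom)) {
    p <- map$pos_bp[map$chrom == ch]
    if (any(diff(p) <= 0))
      stop("duplicate or non-increasing positions on chromosome ", ch)
  }
  class(map) <- c("marker_map", "data.frame")
  map
}

#' Construct a phased genotype object
#'
#' Phased diploid genotypes are stored as two haplotype allele matrices
#' (individuals x SNPs, codes 0/1, `NA` allowed for missing calls) plus a
#' marker map. The dosage view in \{0,1,2\} is derived, never stored, so
#' the two can not drift apart.
#'
#' @param h1,h2 integer matrices (n x m) of haplotype allele codes in
#'   \{0,1\}; `NA` marks a missing call (both haplotypes of a missing
#'   genotype should be `NA`).
#' @param map a [marker_map()] with one row per column of `h1`.
#' @param ids character vector of individual identifiers (rownames used
#'   when `NULL`).
#' @return An object of class `phased_geno`.
#' @export
phased_geno <- function(h1, h2, map, ids = NULL) {
  h1 <- as.matrix(h1); h2 <- as.matrix(h2)
  stopifnot(identical(dim(h1), dim(h2)), ncol(h1) == nrow(map))
  if (!all(h1 %in% c(0L, 1L, NA)) || !all(h2 %in% c(0L, 1L, NA)))
    stop("haplotype allele codes must be 0, 1 or NA")
  if (is.null(ids)) ids <- rownames(h1)
  if (is.null(ids)) ids <- sprintf("acc%03d", seq_len(nrow(h1)))
  if (anyDuplicated(ids)) stop("duplicate individual ids")
  storage.mode(h1) <- "integer"; storage.mode(h2) <- "integer"
  dimnames(h1) <- dimnames(h2) <- list(ids, map$snp_id)
  structure(list(h1 = h1, h2 = h2, map = map, ids = ids),
            class = "phased_geno")
}

#' Genotype dosage matrix
#'
#' @param geno a `phased_geno` object.
#' @return Integer n x m matrix of minor/alternate allele counts in
#'   \{0,1,2\} (`NA` where either haplotype call is missing).
#' @export
dosage <- function(geno) {
  stopifnot(inherits(geno, "phased_geno"))
  geno$h1 + geno$h2
}

#' @export
print.phased_geno <- function(x, ...) {
  cat(sprintf("phased_geno: %d individuals x %d SNPs on %d chromosome(s)\n",
              nrow(x$h1), ncol(x$h1), length(unique(x$map$chrom))))
  nmiss <- sum(is.na(x$h1))
  if (nmiss > 0) cat(sprintf("  missing haplotype calls: %d\n", nmiss))
  invisible(x)
}

#' Subset a phased genotype object by SNP
#'
#' @param geno a `phased_geno`.
#' @param snp_idx integer or logical index into the SNP dimension.
#' @return A `phased_geno` restricted to the selected SNPs.
#' @export
subset_snps <- function(geno, snp_idx) {
  stopifnot(inherits(geno, "phased_geno"))
  map <- geno$map[snp_idx, , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- c("marker_map", "data.frame")
  phased_geno(geno$h1[, snp_idx, drop = FALSE],
              geno$h2[, snp_idx, drop = FALSE],
              map, ids = geno$ids)
}

# Allele frequency of the 1-coded allele, per SNP (missing calls ignored).
allele_freq <- function(geno) {
  d <- dosage(geno)
  colMeans(d, na.rm = TRUE) / 2
}

#' Minor allele frequency per SNP
#'
#' @param geno a `phased_geno`.
#' @return Numeric vector of per-SNP minor allele frequencies.
#' @export
maf <- function(geno) {
  p <- allele_freq(geno)
  pmin(p, 1 - p)
}
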