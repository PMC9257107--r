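#' Marker quality control
#'
#' Filters SNPs in three ordered steps: (1) minor allele frequency,
#' (2) call rate, (3) greedy left-to-right LD pruning. Pruning slides a
#' window of `ld_window` SNPs in steps of `ld_step` along each
#' chromosome; within a window, for every pair exceeding `ld_r2_max` the
#' later SNP (higher map index) is dropped, so ties always retain the
#' lower map index.
#'
#' The shipped defaults mirror the study protocol: `maf_min = 0.05`
#' (the study's stated MAF threshold of 0.5 would remove
#' every SNP and is treated as a typo for 0.05) and `ld_r2_max = 0.01`,
#' an unusually aggressive pruning level that survives here as the
#' documented default precisely because it is what the protocol states —
#' most users will want something like 0.5-0.9.
#'
#' @param geno a [phased_geno()]; haplotype calls may contain `NA`.
#' @param maf_min minimum minor allele frequency.
#' @param call_rate_min minimum fraction of non-missing genotype calls.
#' @param ld_r2_max maximum pairwise r2 retained by pruning; `1` (or
#'   anything >= 1) disables the pruning step.
#' @param ld_window,ld_step pruning window size and step, in SNPs.
#' @return The surviving `phased_geno` subset, with attribute
#'   `filter_log` (SNPs removed per step).
#' @export
filter_markers <- function(geno, maf_min = 0.05, call_rate_min = 0.9,
                           ld_r2_max = 0.01, ld_window = 50, ld_step = 5) {
  stopifnot(inherits(geno, "phased_geno"))
  for (v in c(maf_min, call_rate_min))
    if (v < 0 || v > 1) stop("thresholds must lie in [0, 1]")
  d <- dosage(geno)
  m <- ncol(d)
  keep <- maf(geno) >= maf_min
  n_maf <- sum(!keep)
  if (!any(keep)) stop("MAF filter removed all markers")
  cr <- colMeans(!is.na(d))
  keep2 <- keep & cr >= call_rate_min
  n_cr <- sum(keep) - sum(keep2)
  if (!any(keep2)) stop("call-rate filter removed all markers")
  g2 <- subset_snps(geno, which(keep2))
  n_ld <- 0L
  if (ld_r2_max < 1) {
    pruned <- .ld_prune(.mean_impute(dosage(g2)), g2$map,
                        ld_r2_max, ld_window, ld_step)
    n_ld <- sum(!pruned)
    if (!any(pruned)) stop("LD pruning removed all markers")
    g2 <- subset_snps(g2, which(pruned))
  }
  attr(g2, "filter_log") <- c(input = m, removed_maf = n_maf,
                              removed_call_rate = n_cr,
                              removed_ld = n_ld,
                              output = nrow(g2$map))
  g2
}

# Greedy windowed LD pruning; returns logical keep vector.
.ld_prune <- function(d, map, r2_max, window, step) {
  keep <- rep(TRUE, ncol(d))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    start <- 1L
    repeat {
      win <- idx[seq(start, min(start + window - 1L, length(idx)))]
      act <- win[keep[win]]
      if (length(act) > 1) {
        r2 <- suppressWarnings(stats::cor(d[, act, drop = FALSE]))^2
        for (a in seq_along(act)) {
          if (!keep[act[a]]) next
          for (b in seq_len(a - 1L)) {
            if (keep[act[b]] && is.finite(r2[a, b]) && r2[a, b] > r2_max) {
              keep[act[a]] <- FALSE  # drop the later SNP of the pair
              break
            }
          }
        }
      }
      if (start + window - 1L >= length(idx)) break
      start <- start + step
    }
  }
  keep
}

#' Pairwise within-chromosome linkage disequilibrium
#'
#' r2 is the squared Pearson correlation of dosage vectors, computed for
#' all within-chromosome SNP pairs separated by at most `max_dist_bp`.
#' Pairs involving a zero-variance SNP are skipped; their count is kept
#' as attribute `n_skipped`.
#'
#' @param geno a [phased_geno()] with a sorted map.
#' @param max_dist_bp maximum pair distance in bp.
#' @return A data.frame (`ld_table`) with columns `snp_i`, `snp_j`,
#'   `dist_bp`, `r2`.
#' @export
pairwise_ld <- function(geno, max_dist_bp = 500000) {
  stopifnot(inherits(geno, "phased_geno"))
  d <- .mean_impute(dosage(geno))
  map <- geno$map
  out <- vector("list", length(unique(map$chrom)))
  n_skipped <- 0L
  for (k in seq_along(unique(map$chrom))) {
    ch <- unique(map$chrom)[k]
    idx <- which(map$chrom == ch)
    if (length(idx) < 2) next
    pos <- map$pos_bp[idx]
    sds <- apply(d[, idx, drop = FALSE], 2, stats::sd)
    C2 <- suppressWarnings(stats::cor(d[, idx, drop = FALSE]))^2
    pr <- which(upper.tri(C2), arr.ind = TRUE)
    dist <- pos[pr[, 2]] - pos[pr[, 1]]
    ok_dist <- dist <= max_dist_bp
    pr <- pr[ok_dist, , drop = FALSE]; dist <- dist[ok_dist]
    var_ok <- sds[pr[, 1]] > 0 & sds[pr[, 2]] > 0
    n_skipped <- n_skipped + sum(!var_ok)
    pr <- pr[var_ok, , drop = FALSE]; dist <- dist[var_ok]
    out[[k]] <- data.frame(snp_i = map$snp_id[idx[pr[, 1]]],
                           snp_j = map$snp_id[idx[pr[, 2]]],
                           dist_bp = dist,
                           r2 = C2[pr],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0)
    res <- data.frame(snp_i = character(0), snp_j = character(0),
                      dist_bp = integer(0), r2 = numeric(0))
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  class(res) <- c("ld_table", "data.frame")
  res
}

#' LD decay distance at an r2 cutoff
#'
#' Bins pair distances (bins anchored at 0), averages r2 per bin,
#' smooths the bin means with a running mean of three, and returns the
#' midpoint of the first bin whose smoothed mean falls below
#' `r2_cutoff` without any later bin rising back above it. Returns `Inf`
#' (with attribute `beyond_max_dist = TRUE`) if mean r2 never decays
#' below the cutoff within the table's distance range.
#'
#' @param ld an `ld_table` from [pairwise_ld()].
#' @param r2_cutoff decay threshold (the study convention is 0.1).
#' @param bin_bp distance bin width in bp.
#' @return Decay distance in bp (a bin midpoint), or `Inf`.
#' @export
ld_decay_distance <- function(ld, r2_cutoff = 0.1, bin_bp = 25000) {
  if (nrow(ld) == 0) stop("empty LD table")
  bin <- floor(ld$dist_bp / bin_bp)
  means <- tapply(ld$r2, bin, mean)
  bins <- as.integer(names(means))
  ord <- order(bins)
  bins <- bins[ord]; means <- as.numeric(means)[ord]
  sm <- .runmean3(means)
  below <- sm < r2_cutoff
  hit <- NA_integer_
  for (i in seq_along(below)) {
    if (below[i] && all(below[i:length(below)])) { hit <- i; break }
  }
  if (is.na(hit)) {
    out <- Inf
    attr(out, "beyond_max_dist") <- TRUE
    return(out)
  }
  (bins[hit] + 0.5) * bin_bp
}

.runmean3 <- function(x) {
  n <- length(x)
  if (n <= 2) return(x)
  out <- x
  out[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  out[1] <- mean(x[1:2]); out[n] <- mean(x[(n - 1):n])
  out
}

#' Fixed-length haplotype windows
#'
#' Partitions each chromosome's SNPs, left to right, into non-overlapping
#' consecutive windows of exactly `L` SNPs; a chromosome-end remainder of
#' fewer than `L` SNPs forms one shorter window. Every SNP belongs to
#' exactly one window.
#'
#' @param map a [marker_map()].
#' @param L window length in SNPs (the study uses 2-5; `L = 1` gives
#'   singleton windows and reproduces the additive model).
#' @return A list of windows, each `list(chrom, snp_idx, snp_ids)` with
#'   `snp_idx` global row indices into `map`.
#' @export
make_haplotype_windows <- function(map, L) {
  if (L < 1) stop("L must be >= 1")
  out <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    starts <- seq(1L, length(idx), by = L)
    for (s in starts) {
      w <- idx[s:min(s + L - 1L, length(idx))]
      out[[length(out) + 1L]] <- list(chrom = ch, snp_idx = w,
                                      snp_ids = map$snp_id[w])
    }
  }
  out
}

#' Haplotype profile matrix
#'
#' For each window, enumerates the distinct haplotype alleles observed in
#' the panel and counts, for every individual, how many of its two
#' phased haplotypes match each allele. Within a window each
#' individual's counts sum to 2. Column names are
#' `win<w>:<allele string>`; window membership is kept in attribute
#' `window_of` and haplotype-allele frequencies in attribute `freq`.
#'
#' @param geno a [phased_geno()] with no missing haplotype calls.
#' @param windows window list from [make_haplotype_windows()].
#' @return Integer n x (total distinct alleles) matrix.
#' @export
haplotype_profiles <- function(geno, windows) {
  stopifnot(inherits(geno, "phased_geno"))
  if (anyNA(geno$h1) || anyNA(geno$h2))
    stop("haplotype profiles need complete phased calls; ",
         "use dosage-based kernels for panels with missing genotypes")
  n <- length(geno$ids)
  cols <- list(); colnm <- character(0); winof <- integer(0)
  for (w in seq_along(windows)) {
    idx <- windows[[w]]$snp_idx
    s1 <- apply(geno$h1[, idx, drop = FALSE], 1, paste0, collapse = "")
    s2 <- apply(geno$h2[, idx, drop = FALSE], 1, paste0, collapse = "")
    lev <- sort(unique(c(s1, s2)))
    cnt <- matrix(0L, n, length(lev))
    cnt[cbind(seq_len(n), match(s1, lev))] <-
      cnt[cbind(seq_len(n), match(s1, lev))] + 1L
    cnt[cbind(seq_len(n), match(s2, lev))] <-
      cnt[cbind(seq_len(n), match(s2, lev))] + 1L
    cols[[w]] <- cnt
    colnm <- c(colnm, paste0("win", w, ":", lev))
    winof <- c(winof, rep(w, length(lev)))
  }
  P <- do.call(cbind, cols)
  dimnames(P) <- list(geno$ids, colnm)
  attr(P, "window_of") <- winof
  attr(P, "freq") <- colMeans(P) / 2
  P
}

#' Genetic diversity summary
#'
#' Pairwise Euclidean distances on dosage rows, normalized to [0, 1] by
#' the maximum pairwise distance; a histogram of normalized distances in
#' bins of width 0.2; and the leaf order of an average-linkage
#' hierarchical clustering of the distance matrix.
#'
#' @param geno a [phased_geno()] with >= 2 individuals.
#' @return A list with `dist` (n x n matrix of normalized distances),
#'   `hist` (named proportions over the five bins), `order` (dendrogram
#'   leaf order), and `hclust` (the clustering object).
#' @export
diversity_summary <- function(geno) {
  d <- .mean_impute(dosage(geno))
  if (nrow(d) < 2) stop("need at least 2 individuals")
  D <- stats::dist(d)
  mx <- max(D)
  Dn <- if (mx > 0) D / mx else D
  breaks <- seq(0, 1, by = 0.2)
  h <- hist(as.numeric(Dn), breaks = breaks, plot = FALSE,
            include.lowest = TRUE, right = FALSE)
  props <- h$counts / sum(h$counts)
  names(props) <- sprintf("[%.1f,%.1f)", breaks[-6], breaks[-1])
  hc <- stats::hclust(Dn, method = "average")
  list(dist = as.matrix(Dn), hist = props, order = hc$order, hclust = hc)
}
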