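# Shared fixtures (memoized: built once per test run) and brute-force
# oracles kept deliberately independent of the package implementations.

.fixture_cache <- new.env(parent = emptyenv())

get_tiny <- function() {
  if (is.null(.fixture_cache$tiny))
    .fixture_cache$tiny <- make_fixture("tiny", seed = 42)
  .fixture_cache$tiny
}

get_rice <- function() {
  if (is.null(.fixture_cache$rice))
    .fixture_cache$rice <- make_fixture("rice250", seed = 1)
  .fixture_cache$rice
}

# build a phased_geno straight from a dosage matrix (0 -> 0|0, 1 -> 1|0,
# 2 -> 1|1), one chromosome, evenly spaced
geno_from_dosage <- function(d, pos = NULL, chrom = NULL) {
  d <- as.matrix(d)
  if (is.null(colnames(d))) colnames(d) <- paste0("s", seq_len(ncol(d)))
  if (is.null(rownames(d))) rownames(d) <- paste0("i", seq_len(nrow(d)))
  if (is.null(pos)) pos <- seq_len(ncol(d)) * 1000L
  if (is.null(chrom)) chrom <- rep(1L, ncol(d))
  h1 <- ifelse(is.na(d), NA_integer_, as.integer(d >= 1))
  h2 <- ifelse(is.na(d), NA_integer_, as.integer(d == 2))
  dimnames(h1) <- dimnames(h2) <- dimnames(d)
  phased_geno(h1, h2, marker_map(colnames(d), chrom, pos))
}

# exhaustive-pair greedy LD pruning (keep lower index on violation)
bf_ld_prune <- function(d, r2_max) {
  keep <- rep(TRUE, ncol(d))
  for (j in seq_len(ncol(d))) {
    if (!keep[j]) next
    for (i in seq_len(j - 1)) {
      if (!keep[i]) next
      r2 <- suppressWarnings(stats::cor(d[, i], d[, j]))^2
      if (is.finite(r2) && r2 > r2_max) { keep[j] <- FALSE; break }
    }
  }
  keep
}

# all-pairs LD table by direct looping
bf_ld_table <- function(d, map, max_dist) {
  out <- NULL
  for (i in seq_len(ncol(d) - 1)) for (j in (i + 1):ncol(d)) {
    if (map$chrom[i] != map$chrom[j]) next
    dist <- abs(map$pos_bp[j] - map$pos_bp[i])
    if (dist > max_dist) next
    if (stats::sd(d[, i]) == 0 || stats::sd(d[, j]) == 0) next
    out <- rbind(out, data.frame(snp_i = map$snp_id[i],
                                 snp_j = map$snp_id[j],
                                 dist_bp = dist,
                                 r2 = stats::cor(d[, i], d[, j])^2))
  }
  out
}

# haplotype profile counting by explicit string matching
bf_profiles <- function(geno, windows) {
  n <- length(geno$ids)
  cols <- list()
  for (w in seq_along(windows)) {
    idx <- windows[[w]]$snp_idx
    s1 <- apply(geno$h1[, idx, drop = FALSE], 1, paste0, collapse = "")
    s2 <- apply(geno$h2[, idx, drop = FALSE], 1, paste0, collapse = "")
    for (al in sort(unique(c(s1, s2))))
      cols[[paste0("win", w, ":", al)]] <- (s1 == al) + (s2 == al)
  }
  do.call(cbind, cols)
}

# TA-SNP selection rules (a) union (b) by direct enumeration
bf_select <- function(gwas, p_thresh, bin_bp) {
  sel <- gwas$snp_id[!is.na(gwas$p) & gwas$p < p_thresh]
  for (ch in unique(gwas$chrom)) {
    sub <- gwas[gwas$chrom == ch & !is.na(gwas$p), ]
    for (b in unique(floor(sub$pos_bp / bin_bp))) {
      inbin <- sub[floor(sub$pos_bp / bin_bp) == b, ]
      sel <- c(sel, inbin$snp_id[which.min(inbin$p)])
    }
  }
  ord <- order(gwas$chrom, gwas$pos_bp)
  intersect(gwas$snp_id[ord], sel)
}

# transitive gap-chaining by direct scan
bf_merge <- function(chosen, map, merge_bp) {
  idx <- sort(match(chosen, map$snp_id))
  groups <- list(idx[1])
  for (i in idx[-1]) {
    last <- groups[[length(groups)]]
    prev <- last[length(last)]
    same <- map$chrom[i] == map$chrom[prev] &&
      (map$pos_bp[i] - map$pos_bp[prev]) <= merge_bp
    if (same) groups[[length(groups)]] <- c(last, i)
    else groups[[length(groups) + 1]] <- i
  }
  lapply(groups, function(g) map$snp_id[g])
}

# strip kernel metadata, keep the numeric matrix
kmat <- function(K) {
  a <- unclass(K)
  attributes(a) <- list(dim = dim(a), dimnames = dimnames(a))
  a
}
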