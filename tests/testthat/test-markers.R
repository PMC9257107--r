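test_that("marker QC removes monomorphic, low-call-rate and duplicated SNPs", {
  d <- cbind(s1 = c(0, 1, 2, 1, 0, 2), s2 = rep(2, 6),
             s3 = c(2, 1, 0, 1, 2, 0), s4 = c(0, 0, 1, 2, 2, 1),
             s5 = c(1, 2, 0, 0, 1, 2), s6 = c(2, 0, 1, 1, 0, 2))
  g <- geno_from_dosage(d)
  out <- filter_markers(g, maf_min = 0.05, call_rate_min = 0, ld_r2_max = 1)
  expect_identical(out$map$snp_id, c("s1", "s3", "s4", "s5", "s6"))

  # duplicated pair: exactly one survives, the lower map index
  dup <- geno_from_dosage(cbind(a = c(0, 1, 2, 0, 1), b = c(0, 1, 2, 0, 1),
                                c = c(2, 0, 1, 1, 0)))
  out2 <- filter_markers(dup, maf_min = 0, call_rate_min = 0,
                         ld_r2_max = 0.99)
  expect_identical(out2$map$snp_id, c("a", "c"))

  # missingness: call rate below threshold drops the SNP
  dm <- cbind(x = c(NA, NA, NA, 1, 2, 0), y = c(0, 1, 2, 0, 1, 2))
  gm <- geno_from_dosage(dm)
  out3 <- filter_markers(gm, maf_min = 0, call_rate_min = 0.9, ld_r2_max = 1)
  expect_identical(out3$map$snp_id, "y")

  expect_error(filter_markers(g, maf_min = 0.6), "removed all")
})

test_that("windowed LD pruning matches the exhaustive greedy oracle", {
  fx <- get_tiny()
  g20 <- subset_snps(fx$geno, 1:20)
  out <- filter_markers(g20, maf_min = 0.05, call_rate_min = 0.9,
                        ld_r2_max = 0.5)
  d <- dosage(g20)
  keep_bf <- bf_ld_prune(d, 0.5) &
    apply(d, 2, function(x) min(mean(x) / 2, 1 - mean(x) / 2) >= 0.05)
  expect_identical(out$map$snp_id, g20$map$snp_id[keep_bf])

  # idempotence
  again <- filter_markers(out, maf_min = 0.05, call_rate_min = 0.9,
                          ld_r2_max = 0.5)
  expect_identical(again$map$snp_id, out$map$snp_id)
})

test_that("pairwise r2 matches brute force and is label-flip invariant", {
  dup <- geno_from_dosage(cbind(a = c(0, 1, 2, 0), b = c(0, 1, 2, 0),
                                c = c(2, 1, 0, 2)))
  ld <- pairwise_ld(dup, max_dist_bp = 1e6)
  expect_equal(ld$r2[ld$snp_i == "a" & ld$snp_j == "b"], 1)
  # perfect negative correlation also gives r2 = 1
  expect_equal(ld$r2[ld$snp_i == "a" & ld$snp_j == "c"], 1)

  fx <- get_tiny()
  g50 <- subset_snps(fx$geno, 1:50)
  ld50 <- pairwise_ld(g50, max_dist_bp = 1e6)
  bf <- bf_ld_table(dosage(g50), g50$map, 1e6)
  merged <- merge(ld50, bf, by = c("snp_i", "snp_j"))
  expect_equal(nrow(merged), nrow(ld50))
  expect_equal(merged$r2.x, merged$r2.y, tolerance = 1e-10)

  flip <- g50
  flip$h1[, 7] <- 1L - flip$h1[, 7]; flip$h2[, 7] <- 1L - flip$h2[, 7]
  expect_equal(pairwise_ld(flip, 1e6)$r2, ld50$r2, tolerance = 1e-10)
})

test_that("LD decay distance inverts a known exponential decay", {
  dists <- seq(1000, 600000, by = 1000)
  synth <- data.frame(snp_i = "a", snp_j = "b", dist_bp = dists,
                      r2 = exp(-dists / 1e5))
  dd <- ld_decay_distance(synth, r2_cutoff = 0.1, bin_bp = 10000)
  expect_equal(dd, -1e5 * log(0.1), tolerance = 10000)

  # already below the cutoff: first bin midpoint
  flat <- data.frame(snp_i = "a", snp_j = "b", dist_bp = dists,
                     r2 = 0.01)
  expect_equal(ld_decay_distance(flat, 0.1, 10000), 5000)

  # never decays: sentinel
  high <- data.frame(snp_i = "a", snp_j = "b", dist_bp = dists, r2 = 0.8)
  out <- ld_decay_distance(high, 0.1, 10000)
  expect_true(is.infinite(out))
  expect_true(attr(out, "beyond_max_dist"))
})

test_that("haplotype windows partition each chromosome with a remainder rule", {
  map7 <- marker_map(paste0("s", 1:7), rep(1, 7), (1:7) * 100)
  w <- make_haplotype_windows(map7, 3)
  expect_equal(lengths(lapply(w, `[[`, "snp_idx")), c(3, 3, 1))

  expect_length(make_haplotype_windows(map7, 1), 7)
  expect_error(make_haplotype_windows(map7, 0), "L")

  map2 <- marker_map(paste0("s", 1:10), rep(1:2, each = 5), rep((1:5) * 100, 2))
  w2 <- make_haplotype_windows(map2, 2)
  expect_length(w2, 6)
  for (win in w2)
    expect_length(unique(map2$chrom[win$snp_idx]), 1)

  fx <- get_tiny()
  for (L in 2:5) {
    wL <- make_haplotype_windows(fx$geno$map, L)
    idx <- sort(unlist(lapply(wL, `[[`, "snp_idx")))
    expect_identical(idx, seq_len(nrow(fx$geno$map)))  # exact partition
  }
})

test_that("haplotype profiles count phased alleles, two per individual per window", {
  hom <- phased_geno(matrix(0L, 1, 2), matrix(0L, 1, 2),
                     marker_map(c("a", "b"), 1, c(100, 200)))
  p <- haplotype_profiles(hom, make_haplotype_windows(hom$map, 2))
  expect_equal(as.numeric(p), 2)
  expect_identical(colnames(p), "win1:00")

  fx <- get_tiny()
  g <- subset_snps(fx$geno, 1:30)
  for (L in c(2, 3)) {
    w <- make_haplotype_windows(g$map, L)
    prof <- haplotype_profiles(g, w)
    winof <- attr(prof, "window_of")
    for (wi in unique(winof))
      expect_true(all(rowSums(prof[, winof == wi, drop = FALSE]) == 2))
    if (L == 2)
      expect_true(all(table(winof) <= 4))  # at most 2^2 biallelic alleles
  }
  # string-matching oracle
  w3 <- make_haplotype_windows(g$map, 3)
  prof3 <- haplotype_profiles(g, w3)
  bf <- bf_profiles(g, w3)
  expect_equal(unname(prof3[, colnames(bf)]), unname(bf))

  gna <- g; gna$h1[1, 1] <- NA
  expect_error(haplotype_profiles(gna, w3), "phased")
})

test_that("diversity summary matches a hand-computed distance matrix", {
  d <- rbind(i1 = c(0, 1, 2), i2 = c(0, 1, 2), i3 = c(2, 1, 0),
             i4 = c(1, 1, 1))
  g <- geno_from_dosage(d)
  ds <- diversity_summary(g)
  raw <- as.matrix(dist(d))
  expect_equal(ds$dist, raw / max(raw), tolerance = 1e-12)
  expect_equal(ds$dist["i1", "i2"], 0)

  rice <- get_rice()
  dr <- diversity_summary(rice$geno)
  expect_lt(dr$hist[1], 0.15)  # near-clone pairs are rare in a diverse panel
})
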