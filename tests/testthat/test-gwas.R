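test_that("with an identity kernel the mixed-model scan is simple regression", {
  set.seed(4)
  n <- 10
  X <- matrix(rbinom(n * 6, 2, 0.4), n, 6,
              dimnames = list(paste0("i", 1:n), paste0("s", 1:6)))
  y <- X[, 2] * 0.8 + rnorm(n); names(y) <- rownames(X)
  gw <- mlm_gwas(y, X, diag(n))
  p_lm <- vapply(1:6, function(j)
    summary(lm(y ~ X[, j]))$coefficients[2, 4], numeric(1))
  expect_equal(gw$p, p_lm, tolerance = 1e-6)
})

test_that("a large-effect QTL is ranked first in most replicates", {
  hits <- vapply(1:6, function(s) {
    geno <- simulate_phased_genotypes(n = 100, n_chrom = 2, n_snps = 60,
                                      chrom_length_bp = 2e6,
                                      ld_decay_halflen = 5e4,
                                      n_families = 0, seed = 20 + s)
    d <- dosage(geno)
    qtl <- 17
    set.seed(40 + s)
    y <- d[, qtl] * 1.2 + rnorm(100, 0, 0.6); names(y) <- geno$ids
    gw <- mlm_gwas(y, geno, additive_grm(geno))
    # count a hit if the QTL (or an immediate neighbour in LD) wins
    which.min(gw$p) %in% (qtl + (-1:1))
  }, logical(1))
  expect_gte(sum(hits), 5)
})

test_that("TA-SNP selection implements p-threshold union per-bin minima", {
  gw <- data.frame(snp_id = paste0("s", 1:6), chrom = 1,
                   pos_bp = c(1e5, 2.5e5, 7e5, 9e5, 9.9e5, 1.9e6),
                   beta = 0, se = 1,
                   p = c(0.001, 0.5, 0.5, 0.005, 0.5, 0.5))
  expect_identical(select_ta_snps(gw, 0.01, 3e5), c("s1", "s3", "s4", "s6"))
  # stricter variant: only bins that already contain a signal SNP
  expect_identical(select_ta_snps(gw, 0.01, 3e5,
                                  only_bins_with_signal = TRUE),
                   c("s1", "s4"))
  # saturation: everything significant selects everything
  gw$p <- 0.001
  expect_identical(select_ta_snps(gw, 0.01, 3e5), gw$snp_id)

  # brute-force oracle on random instances
  for (s in 1:5) {
    set.seed(s)
    g2 <- data.frame(snp_id = sprintf("m%02d", 1:50),
                     chrom = sample(1:3, 50, replace = TRUE),
                     pos_bp = sample.int(2e6, 50),
                     beta = 0, se = 1, p = runif(50)^2)
    g2 <- g2[order(g2$chrom, g2$pos_bp), ]
    expect_identical(select_ta_snps(g2, 0.01, 3e5),
                     bf_select(g2, 0.01, 3e5))
  }
})

test_that("panel assembly chain-merges neighbours within the gap limit", {
  map <- marker_map(paste0("s", 1:5), rep(1, 5),
                    c(1e5, 2.5e5, 7e5, 2.0e6, 2.29e6))
  pan <- assemble_panel(c("s1", "s2", "s3"), map, merge_bp = 3e5)
  expect_equal(pan$blocks, list(c("s1", "s2")))
  expect_identical(pan$singletons, "s3")

  # transitive chaining: 0, 290, 580 kb joins one block of three
  map3 <- marker_map(c("a", "b", "c"), rep(1, 3), c(1, 290001, 580001))
  pan3 <- assemble_panel(c("a", "b", "c"), map3, merge_bp = 3e5)
  expect_equal(pan3$blocks, list(c("a", "b", "c")))
  expect_length(pan3$singletons, 0)

  for (s in 1:5) {
    set.seed(100 + s)
    mapr <- marker_map(sprintf("r%02d", 1:20),
                       sample(1:2, 20, replace = TRUE),
                       sample.int(3e6, 20))
    chosen <- sample(mapr$snp_id, 12)
    pan_r <- assemble_panel(chosen, mapr, 3e5)
    groups <- c(pan_r$blocks, as.list(pan_r$singletons))
    ord <- order(vapply(groups, function(g)
      match(g[1], mapr$snp_id), integer(1)))
    expect_equal(groups[ord], bf_merge(chosen, mapr, 3e5))
  }
  expect_error(assemble_panel(character(0), map), "empty")
})

test_that("panel selection never sees test-fold phenotypes", {
  fx <- get_tiny()
  geno <- fx$geno
  K <- additive_grm(geno)
  y <- fx$pheno[, 1]; names(y) <- rownames(fx$pheno)
  test <- seq_len(8)
  y_mask <- y; y_mask[test] <- NA
  chosen1 <- select_ta_snps(mlm_gwas(y_mask, geno, K), 0.05, 2e5)
  y_shuf <- y; y_shuf[test] <- sample(y[test]); y_shuf[test] <- NA
  chosen2 <- select_ta_snps(mlm_gwas(y_shuf, geno, K), 0.05, 2e5)
  expect_identical(chosen1, chosen2)
})

test_that("the panel CV protocol runs end to end and reports panel sizes", {
  fx <- get_tiny()
  plan <- make_cv_plan(nrow(fx$pheno), 3, 1, seed = 5,
                       ids = rownames(fx$pheno))
  spec <- mask_spec("MT-CV2", "T1", "T2")
  res <- panel_cv_evaluate(fx$pheno, fx$geno, plan, spec,
                           model = list(type = "mt", structure = "un",
                                        n_iter = 400, burnin = 150),
                           p_thresh = 0.05, kernel_kind = "mixed",
                           seed = 5)
  sizes <- attr(res, "panel_sizes")
  expect_equal(dim(sizes), c(1, 3))
  expect_true(all(sizes > 0))
  expect_true(is.finite(attr(res, "panel_size_cv")))
  expect_true(all(abs(res$accuracy) <= 1))
})
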