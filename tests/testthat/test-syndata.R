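test_that("simulation is deterministic and structurally sound", {
  a <- make_fixture("tiny", seed = 42)
  b <- make_fixture("tiny", seed = 42)
  expect_identical(a$geno$h1, b$geno$h1)
  expect_identical(a$geno$h2, b$geno$h2)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$truth$true_genetic_values, b$truth$true_genetic_values)

  g <- a$geno
  expect_false(anyNA(g$h1))
  expect_identical(dosage(g), g$h1 + g$h2)
  expect_true(all(maf(g) >= 0.05))
  for (ch in unique(g$map$chrom))
    expect_true(all(diff(g$map$pos_bp[g$map$chrom == ch]) > 0))
  expect_false(anyDuplicated(g$map$snp_id) > 0)

  c_seed <- make_fixture("tiny", seed = 43)
  expect_false(identical(a$geno$h1, c_seed$geno$h1))
  expect_error(make_fixture("nope"), "arg")
})

test_that("LD vanishes in the no-LD limit and a single founder collapses the panel", {
  # halflen near zero + flat founder usage: adjacent SNPs ~ independent
  free <- simulate_phased_genotypes(n = 100, n_chrom = 2, n_snps = 120,
                                    chrom_length_bp = 1e6,
                                    ld_decay_halflen = 1, founder_conc = 50,
                                    n_families = 0, seed = 5)
  ld_free <- pairwise_ld(free, max_dist_bp = 5e4)
  ld_def <- pairwise_ld(simulate_phased_genotypes(
    n = 100, n_chrom = 2, n_snps = 120, chrom_length_bp = 1e6,
    n_families = 0, seed = 5), max_dist_bp = 5e4)
  expect_lt(mean(ld_free$r2), 0.08)
  expect_lt(mean(ld_free$r2), mean(ld_def$r2) / 3)

  clone <- simulate_phased_genotypes(n = 10, n_chrom = 1, n_snps = 20,
                                     chrom_length_bp = 1e5, n_founders = 1,
                                     n_families = 0, maf_min = 0,
                                     seed = 2)
  ds <- diversity_summary(clone)
  expect_true(all(ds$dist == 0))
})

test_that("phenotype simulation honours the trait model", {
  fx <- get_tiny()
  noiseless <- trait_model(c("T1", "T2"), fx$model$genetic_cov,
                           residual_cov = c(0, 0), n_qtl = 20,
                           mode = "qtl")
  sim <- simulate_multitrait_phenotypes(fx$geno, noiseless, seed = 3)
  expect_equal(sim$pheno, sim$truth$true_genetic_values)
  # per-trait variance of g matches the target (QTL mode rescales)
  expect_equal(unname(apply(sim$truth$true_genetic_values, 2, var)),
               unname(diag(noiseless$genetic_cov)), tolerance = 1e-8)

  bad <- matrix(c(1, 2, 2, 1), 2)  # eigenvalue -1
  expect_error(trait_model(c("a", "b"), bad, c(1, 1)),
               "positive semidefinite.*-1", ignore.case = TRUE)
})

test_that("uncorrelated trait models produce null cross-trait genetic correlations", {
  psi <- diag(c(0.5, 0.5))
  tm <- trait_model(c("A", "B"), psi, residual_cov = c(0.5, 0.5),
                    n_qtl = 40, pleiotropy_frac = 0.5, mode = "qtl")
  geno <- simulate_phased_genotypes(n = 100, n_chrom = 2, n_snps = 200,
                                    chrom_length_bp = 1e6, seed = 8)
  cors <- vapply(1:30, function(r) {
    s <- simulate_multitrait_phenotypes(geno, tm, seed = 100 + r)
    cor(s$truth$true_genetic_values)[1, 2]
  }, numeric(1))
  # centered on zero within the Monte-Carlo band of the simulator itself
  expect_lt(abs(mean(cors)), 3 * sd(cors) / sqrt(length(cors)) + 0.02)
})

test_that("the rice250 preset reproduces the study panel's headline structure", {
  fx <- get_rice()
  expect_identical(colnames(fx$pheno), c("Cd", "Fe", "Mn", "Cu", "Zn"))
  expect_equal(nrow(fx$pheno), 250)
  # simulated true genetic Fe-Cd correlation near the calibrated 0.95
  gcor <- cor(fx$truth$true_genetic_values)
  expect_gte(gcor["Fe", "Cd"], 0.85)
  expect_lte(gcor["Fe", "Cd"], 1.0)
})

test_that("REML heritability estimates track the simulated trait ordering", {
  # Cd > Fe > Mn > Cu > Zn in the trait model; rank agreement across seeds
  truth_rank <- c(Cd = 5, Fe = 4, Mn = 3, Cu = 2, Zn = 1)
  rhos <- vapply(1:5, function(s) {
    fx <- if (s == 1) get_rice() else make_fixture("rice250", seed = s)
    G <- additive_grm(fx$geno)
    h2 <- vapply(colnames(fx$pheno), function(tr)
      fit_st_gblup(fx$pheno[, tr], G, engine = "reml")$h2, numeric(1))
    cor(h2[names(truth_rank)], truth_rank, method = "spearman")
  }, numeric(1))
  expect_gte(mean(rhos), 0.6)
  expect_gte(sum(rhos >= 0.6), 4)
})
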