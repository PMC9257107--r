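test_that("REML matches a direct grid search of the restricted likelihood", {
  set.seed(11)
  n <- 8
  fx <- get_tiny()
  K <- unclass(additive_grm(fx$geno))[1:n, 1:n]
  y <- fx$pheno[1:n, 1]; names(y) <- rownames(K)
  fit <- fit_st_gblup(y, K, engine = "reml")
  # independent oracle: generic-matrix restricted likelihood on a
  # two-dimensional (sigma_g^2, sigma_e^2) grid
  X <- matrix(1, n, 1)
  reml_ll <- function(sg, se) {
    V <- sg * (K + 1e-6 * diag(n)) + se * diag(n)
    Vi <- solve(V)
    P <- Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi
    -0.5 * as.numeric(determinant(V)$modulus + log(t(X) %*% Vi %*% X) +
                        t(y) %*% P %*% y)
  }
  sv <- var(y) * exp(seq(-4, 2, length.out = 80))
  grid <- expand.grid(sg = sv, se = sv)
  ll <- mapply(reml_ll, grid$sg, grid$se)
  best <- grid[which.max(ll), ]
  expect_equal(fit$h2, best$sg / (best$sg + best$se), tolerance = 0.05)
})

test_that("a noiseless genetic signal drives the heritability to the boundary", {
  fx <- get_tiny()
  K <- unclass(additive_grm(fx$geno))
  y <- eigen(K, symmetric = TRUE)$vectors[, 1] * 3
  names(y) <- rownames(K)
  fit <- fit_st_gblup(y, K, engine = "reml")
  expect_gt(fit$h2, 0.98)
})

test_that("heritability follows the variance-component ratio in both engines", {
  fx <- get_tiny()
  G <- additive_grm(fx$geno)
  fr <- fit_st_gblup(fx$pheno[, 1], G, engine = "reml")
  expect_equal(estimate_heritability(fr)[[1]],
               fr$psi_u[1, 1] / (fr$psi_u[1, 1] + fr$psi_e))

  fg <- fit_st_gblup(fx$pheno[, 1], G, engine = "gibbs",
                     n_iter = 1500, burnin = 500, seed = 4)
  h2 <- estimate_heritability(fg)
  # mean-of-ratios vs ratio-of-means agree within Monte Carlo error
  expect_equal(unname(h2[1]), unname(attr(h2, "ratio_of_means")[1]),
               tolerance = 0.1)
  # reproducibility of seeded chains
  fg2 <- fit_st_gblup(fx$pheno[, 1], G, engine = "gibbs",
                      n_iter = 1500, burnin = 500, seed = 4)
  expect_identical(fg$draws$psi_u, fg2$draws$psi_u)
  expect_identical(fg$u, fg2$u)
})

test_that("with fixed variance components the Gibbs mean equals closed-form BLUP", {
  fx <- get_tiny()
  n <- 12
  K <- unclass(additive_grm(fx$geno))[1:n, 1:n]
  Y <- fx$pheno[1:n, ]
  psi_u <- matrix(c(0.5, 0.3, 0.3, 0.6), 2)
  psi_e <- c(0.5, 0.4)
  fit <- fit_mt(Y, K, "un", n_iter = 6000, burnin = 1000, seed = 9,
                fix_vc = list(psi_u = psi_u, psi_e = psi_e))
  Kr <- K + 1e-6 * diag(n)
  V <- kronecker(psi_u, Kr) + kronecker(diag(psi_e), diag(n))
  X <- kronecker(diag(2), matrix(1, n, 1))
  yv <- c(Y[, 1], Y[, 2])
  Vi <- solve(V)
  mu <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% yv)
  u_blup <- kronecker(psi_u, Kr) %*% Vi %*% (yv - X %*% mu)
  expect_lt(max(abs(c(fit$u) - u_blup)), 0.06)   # ~2 MC standard errors
})

test_that("predictions are equivariant, anchored at the prior mean, and id-checked", {
  fx <- get_tiny()
  G <- unclass(additive_grm(fx$geno))
  y <- fx$pheno[, 1]; names(y) <- rownames(G)
  fit <- fit_st_gblup(y, G, engine = "reml")
  perm <- sample(seq_along(y))
  fit_p <- fit_st_gblup(y[perm], G[perm, perm], engine = "reml")
  expect_equal(fit_p$u[names(y), 1], fit$u[, 1], tolerance = 1e-6)
  expect_error(predict_genetic_values(fit, 1, "ghost"), "unknown")

  # an unrelated individual with no phenotype reverts to the prior mean 0
  n <- 20
  K <- unclass(additive_grm(fx$geno))[1:n, 1:n]
  K[n, ] <- K[, n] <- 0; K[n, n] <- 1
  Y <- fx$pheno[1:n, ]; Y[n, ] <- NA
  fit_iso <- fit_mt(Y, K, "un", n_iter = 2000, burnin = 500, seed = 3)
  expect_lt(max(abs(fit_iso$u[n, ])), 0.2)
})

test_that("genetic correlations follow the fitted covariance structure", {
  mkfit <- function(psi) {
    structure(list(psi_u = psi, u = matrix(0, 2, ncol(psi),
                                           dimnames = list(NULL, colnames(psi))),
                   structure = "un", traits = colnames(psi)),
              class = "gblup_fit")
  }
  I2 <- diag(2); dimnames(I2) <- list(c("a", "b"), c("a", "b"))
  expect_equal(unclass(genetic_correlation(mkfit(I2))), I2,
               ignore_attr = TRUE)
  hi <- matrix(c(1, 0.95, 0.95, 1), 2, dimnames = dimnames(I2))
  expect_equal(genetic_correlation(mkfit(hi))["a", "b"], 0.95)
  # rank-1 factor structure with zero uniqueness: correlation exactly +/-1
  lam <- c(0.7, -1.3)
  fa1 <- tcrossprod(lam); dimnames(fa1) <- dimnames(I2)
  expect_equal(genetic_correlation(mkfit(fa1))["a", "b"], -1)

  fx <- get_tiny()
  dfit <- fit_mt(fx$pheno, additive_grm(fx$geno), "diag",
                 n_iter = 600, burnin = 200, seed = 2)
  expect_warning(cg <- genetic_correlation(dfit), "diagonal")
  expect_equal(unclass(cg), diag(2), ignore_attr = TRUE)
})

test_that("the factor-analytic sampler keeps the genetic covariance PSD", {
  set.seed(6)
  geno <- simulate_phased_genotypes(n = 40, n_chrom = 2, n_snps = 120,
                                    chrom_length_bp = 1e6, seed = 6)
  psi <- 0.5 * (diag(3) * 0.5 + 0.5)
  tm <- trait_model(c("A", "B", "C"), psi, residual_cov = rep(0.5, 3),
                    mode = "infinitesimal")
  sim <- simulate_multitrait_phenotypes(geno, tm, seed = 7)
  fit <- fit_mt(sim$pheno, additive_grm(geno), "fa", k = 1,
                n_iter = 800, burnin = 300, seed = 8)
  expect_true(all(is.finite(fit$u)))
  lt <- fit$draws$lower_tri_index
  for (i in c(1, nrow(fit$draws$psi_u))) {
    P <- matrix(0, 3, 3); P[lt] <- fit$draws$psi_u[i, ]
    P <- P + t(P) - diag(diag(P))
    expect_gte(min(eigen(P, only.values = TRUE)$values), -1e-8)
  }
  expect_error(fit_mt(sim$pheno[, 1:2], additive_grm(geno), "fa"),
               "three traits")
})

test_that("BMORS stacks stage-1 predictions linearly with safe fallbacks", {
  fx <- get_tiny()
  G <- additive_grm(fx$geno)
  Y <- fx$pheno; Y[1:6, "T1"] <- NA
  bm <- fit_bmors(Y, G, seed = 2)
  cf <- bm$coefficients$T1
  manual <- cf[1] + as.numeric(bm$stage1 %*% cf[-1])
  expect_equal(unname(bm$predictions[, "T1"]), manual, tolerance = 1e-10)
  # stage-2 weights of (0, 1, 0) reproduce stage 1 exactly by construction
  expect_equal(unname(0 + bm$stage1 %*% c(1, 0))[, 1],
               unname(bm$stage1[, 1]))

  Yc <- Y; Yc[, "T2"] <- 1  # constant trait: degenerate stage-1
  warns <- testthat::capture_warnings(bc <- fit_bmors(Yc, G, seed = 2))
  expect_true(any(grepl("degenerate", warns)))
  expect_equal(unname(bc$predictions[, "T2"]), unname(bc$stage1[, "T2"]))
})

test_that("model preconditions are enforced", {
  fx <- get_tiny()
  G <- additive_grm(fx$geno)
  Yna <- fx$pheno; Yna[, 2] <- NA
  expect_error(fit_mt(Yna, G, "un"), "no observed")
  expect_error(fit_mt(fx$pheno[, 1, drop = FALSE], G), "two traits")
  expect_error(fit_mt(fx$pheno, G, "un", n_iter = 100, burnin = 200),
               "burnin")
  Kbad <- unclass(G); Kbad[1, 2] <- Kbad[1, 2] + 1
  expect_error(fit_st_gblup(fx$pheno[, 1], Kbad), "symmetric")
})
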