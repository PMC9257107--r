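#' Single-trait GBLUP
#'
#' Fits `y = 1 mu + u + e` with `u ~ N(0, sigma_g^2 K)` and
#' `e ~ N(0, sigma_e^2 I)`. The REML engine profiles the restricted
#' likelihood down to a one-dimensional optimization in the variance
#' ratio `lambda = sigma_e^2 / sigma_g^2` via the eigendecomposition of
#' `K` on the observed individuals; genetic values for unobserved
#' individuals are the BLUP conditional means through `K`. The Gibbs
#' engine runs the multi-trait sampler with a single trait (scaled
#' inverse chi-squared priors, missing phenotypes imputed each sweep).
#'
#' @param y named numeric vector (length n, names = individual ids);
#'   `NA` marks masked/missing phenotypes.
#' @param K a `rel_matrix` (or plain symmetric matrix) over the same
#'   individuals; a 1e-6 ridge is added internally before factorization.
#' @param engine `"reml"` or `"gibbs"`.
#' @param n_iter,burnin,seed Gibbs chain controls (ignored for REML).
#' @param fix_vc optional `list(psi_u = , psi_e = )` fixing the variance
#'   components (Gibbs engine only; used for closed-form cross-checks).
#' @return A `gblup_fit` with elements `mu`, `u` (n x 1 matrix of
#'   genetic values, posterior/BLUP means), `psi_u`, `psi_e`, `h2`,
#'   `model`, `engine` and (Gibbs) chain summaries.
#' @export
fit_st_gblup <- function(y, K, engine = c("reml", "gibbs"),
                         n_iter = 20000, burnin = 12000, seed = 1,
                         fix_vc = NULL) {
  engine <- match.arg(engine)
  K <- .check_kernel(K, length(y))
  if (is.null(names(y))) names(y) <- rownames(K)
  if (engine == "gibbs") {
    Y <- matrix(y, ncol = 1, dimnames = list(names(y), "trait"))
    fit <- .mt_gibbs(Y, K, structure = "diag", k = 0,
                     n_iter = n_iter, burnin = burnin, seed = seed,
                     fix_vc = fix_vc)
    fit$model <- "ST"
    return(fit)
  }
  obs <- which(!is.na(y))
  if (length(obs) < 3) stop("too few observed phenotypes")
  if (stats::var(y[obs]) < 1e-12) {
    # constant phenotype: no variance to partition
    u0 <- matrix(0, nrow(K), 1, dimnames = list(rownames(K), "trait"))
    return(structure(list(mu = mean(y[obs]), u = u0,
                          psi_u = matrix(0, 1, 1), psi_e = 0, h2 = 0,
                          model = "ST", engine = "reml",
                          structure = "diag", converged = FALSE,
                          ids = rownames(K), traits = "trait"),
                     class = "gblup_fit"))
  }
  n <- length(obs)
  eig <- eigen(K[obs, obs] + 1e-6 * diag(n), symmetric = TRUE)
  U <- eig$vectors; d <- pmax(eig$values, 1e-10)
  ys <- crossprod(U, y[obs])
  xs <- crossprod(U, rep(1, n))
  # restricted log-likelihood profiled over sigma_g^2, X = intercept
  negll <- function(loglam) {
    lam <- exp(loglam)
    w <- 1 / (d + lam)
    xtx <- sum(xs^2 * w)
    beta <- sum(xs * ys * w) / xtx
    r <- ys - xs * beta
    s2 <- sum(r^2 * w) / (n - 1)
    0.5 * ((n - 1) * log(s2) + sum(log(d + lam)) + log(xtx) + (n - 1))
  }
  opt <- stats::optimize(negll, interval = c(-12, 12), tol = 1e-8)
  loglam <- opt$minimum
  boundary <- loglam < -11.5 || loglam > 11.5
  lam <- exp(loglam)
  w <- 1 / (d + lam)
  xtx <- sum(xs^2 * w)
  beta <- sum(xs * ys * w) / xtx
  r <- ys - xs * beta
  sg2 <- sum(r^2 * w) / (n - 1)
  se2 <- lam * sg2
  # BLUP of u for all individuals: u_hat = sg2 K[,obs] V^{-1} (y - mu)
  vinv_r <- U %*% (w * r / sg2)
  u <- as.numeric(K[, obs, drop = FALSE] %*% vinv_r * sg2)
  names(u) <- rownames(K)
  structure(list(mu = beta,
                 u = matrix(u, ncol = 1, dimnames = list(rownames(K), "trait")),
                 psi_u = matrix(sg2, 1, 1), psi_e = se2,
                 h2 = sg2 / (sg2 + se2),
                 model = "ST", engine = "reml",
                 structure = "diag",
                 converged = !boundary,
                 ids = rownames(K), traits = "trait"),
            class = "gblup_fit")
}

#' Multi-trait GBLUP by Gibbs sampling
#'
#' Fits the stacked model `y = mu + u + eps` with
#' `u ~ N(0, Psi_u (x) K)` and `eps ~ N(0, Psi_e (x) I)`, `Psi_e`
#' diagonal. The structure of the genetic covariance `Psi_u` governs its
#' update: `"diag"` draws independent scaled inverse chi-squared
#' variances (traits genetically uncorrelated), `"un"` draws the full
#' matrix from its inverse-Wishart full conditional, and `"fa"` uses a
#' factor-analytic decomposition `Psi_u = Lambda Lambda' + Pi` with
#' normal updates for the loadings and scaled inverse chi-squared updates
#' for the uniquenesses (`Psi_u` is then positive semidefinite in every
#' sweep by construction). Missing cells of `Y` are sampled from their
#' full conditionals each sweep, which is what lets observed
#' auxiliary-trait phenotypes of test-set individuals inform their
#' predictions under the CV2/CV3 designs.
#'
#' Priors (weakly informative, proper): scaled inverse chi-squared with
#' 4 degrees of freedom and scale equal to half the observed phenotypic
#' variance for every scalar variance; inverse-Wishart with `t + 1`
#' degrees of freedom (the smallest giving a near-flat implied marginal
#' on genetic correlations, so strong correlations are not shrunk) and
#' scale half the observed phenotypic covariance for the unstructured
#' `Psi_u`, the empirical-Bayes convention of Bayesian GBLUP software;
#' standard-normal prior on factor loadings.
#'
#' @param Y n x t numeric matrix (rownames = ids, colnames = traits);
#'   `NA` marks masked cells.
#' @param K relationship matrix over the same individuals.
#' @param structure `"un"`, `"diag"` or `"fa"`.
#' @param k number of latent factors for `"fa"` (default 1; must be < t,
#'   and `"fa"` needs at least three traits).
#' @param n_iter,burnin total sweeps and discarded burn-in (study
#'   protocol: 20,000 / 12,000; reduce for exploration).
#' @param seed integer seed; chains are reproducible bit-for-bit.
#' @param fix_vc optional `list(psi_u = , psi_e = )` to hold variance
#'   components fixed (for closed-form BLUP cross-checks).
#' @return A `gblup_fit`: posterior means `mu`, `u` (n x t), `psi_u`,
#'   `psi_e`, per-trait `h2` (posterior mean of the per-sweep ratio),
#'   `cor_g` (posterior mean genetic correlation), post-burn-in draws of
#'   the variance components in `draws`, and chain metadata.
#' @export
fit_mt <- function(Y, K, structure = c("un", "diag", "fa"), k = 1,
                   n_iter = 20000, burnin = 12000, seed = 1,
                   fix_vc = NULL) {
  structure <- match.arg(structure)
  Y <- as.matrix(Y)
  t <- ncol(Y)
  if (t < 2) stop("fit_mt needs at least two traits")
  if (structure == "fa") {
    if (t < 3) stop("the factor-analytic model requires at least three traits")
    if (k >= t) stop("k must be < number of traits")
  }
  K <- .check_kernel(K, nrow(Y))
  fit <- .mt_gibbs(Y, K, structure = structure, k = k, n_iter = n_iter,
                   burnin = burnin, seed = seed, fix_vc = fix_vc)
  fit$model <- switch(structure, un = "MT-UN", diag = "MT-diag", fa = "MT-FA")
  fit
}

.check_kernel <- function(K, n) {
  K <- unclass(as.matrix(K))
  if (nrow(K) != n) stop("kernel dimension does not match the data")
  if (max(abs(K - t(K))) > 1e-6) stop("kernel must be symmetric")
  K
}

# Core Gibbs sampler. Works in the eigenbasis of K: with K = U D U' the
# rotated genetic values decouple across eigen-indices, and simultaneous
# diagonalization of Psi_u^{-1} and Psi_e^{-1} turns the per-index t x t
# conditional into elementwise operations, so a sweep costs a few dense
# n x t products.
.mt_gibbs <- function(Y, K, structure, k, n_iter, burnin, seed, fix_vc) {
  n <- nrow(Y); t <- ncol(Y)
  ids <- rownames(Y); if (is.null(ids)) ids <- rownames(K)
  traits <- colnames(Y); if (is.null(traits)) traits <- paste0("trait", 1:t)
  obs_mask <- !is.na(Y)
  if (any(colSums(obs_mask) == 0)) stop("a trait has no observed phenotypes")
  if (burnin >= n_iter) stop("burnin must be < n_iter")
  eig <- eigen(K + 1e-6 * diag(n), symmetric = TRUE)
  U <- eig$vectors; d <- pmax(eig$values, 1e-8)
  ones_t <- as.numeric(crossprod(U, rep(1, n)))

  vp <- apply(Y, 2, stats::var, na.rm = TRUE)
  vp[!is.finite(vp) | vp <= 0] <- 1
  nu_e <- 4; Se <- vp / 2
  nu_u <- 4; Su <- vp / 2
  # unstructured prior scale centered on half the phenotypic covariance
  # (pairwise complete), the convention of the Bayesian GBLUP lineage;
  # falls back to the diagonal when a pair has no joint observations
  Sy <- stats::cov(Y, use = "pairwise.complete.obs")
  Sy[!is.finite(Sy)] <- 0
  diag(Sy) <- vp
  if (min(eigen(Sy, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    Sy <- diag(vp, t)
  nu0 <- t + 1; S0 <- 0.5 * Sy
  nu_pi <- 4; Spi <- vp / 4

  withr::with_seed(seed, {
    mu <- colMeans(Y, na.rm = TRUE)
    miss <- lapply(seq_len(t), function(j) which(!obs_mask[, j]))
    ymiss <- lapply(seq_len(t), function(j) rep(mu[j], length(miss[[j]])))
    # fixed part of the rotated data (observed cells only)
    ytil_fix <- vapply(seq_len(t), function(j) {
      yj <- Y[, j]; yj[miss[[j]]] <- 0
      as.numeric(crossprod(U, yj))
    }, numeric(n))
    Umiss <- lapply(miss, function(m) U[m, , drop = FALSE])

    if (!is.null(fix_vc)) {
      psi_u <- as.matrix(fix_vc$psi_u)
      psi_e <- rep_len(as.numeric(fix_vc$psi_e), t)
    } else {
      psi_u <- diag(vp / 2, t)
      psi_e <- vp / 2
    }
    if (structure == "fa") {
      Lambda <- matrix(0.5 * sqrt(vp / 2), t, k)
      Pi <- vp / 4
      psi_u <- tcrossprod(Lambda) + diag(Pi, t)
    }
    Ut <- matrix(0, n, t)
    n_keep <- n_iter - burnin
    ut_sum <- matrix(0, n, t); mu_sum <- numeric(t)
    psi_u_sum <- matrix(0, t, t); psi_e_sum <- numeric(t)
    h2_sum <- numeric(t); cor_sum <- matrix(0, t, t)
    lt <- which(lower.tri(diag(t), diag = TRUE))
    psi_u_draws <- matrix(NA_real_, n_keep, length(lt))
    psi_e_draws <- matrix(NA_real_, n_keep, t)
    h2_draws <- matrix(NA_real_, n_keep, t)
    n_jitter <- 0L

    for (it in seq_len(n_iter)) {
      # rotated phenotypes (observed part fixed, imputed part updated)
      Yt <- ytil_fix
      for (j in seq_len(t)) if (length(miss[[j]]) > 0)
        Yt[, j] <- Yt[, j] + as.numeric(crossprod(Umiss[[j]], ymiss[[j]]))

      # genetic values in the rotated basis
      psi_u_inv <- .safe_solve(psi_u)
      se_half <- sqrt(psi_e)
      M <- (se_half %o% se_half) * psi_u_inv
      em <- eigen(M, symmetric = TRUE)
      Q <- em$vectors * se_half           # rows scaled: diag(se_half) %*% V
      delta <- pmax(em$values, 0)
      W <- outer(d, delta, function(di, dj) di / (di + dj))
      Resid <- Yt - ones_t %o% mu
      A <- Resid %*% (Q / psi_e)
      Ut <- (A * W) %*% t(Q) +
        (matrix(stats::rnorm(n * t), n, t) * sqrt(W)) %*% t(Q)

      # intercepts (flat prior)
      mu <- as.numeric(crossprod(ones_t, Yt - Ut)) / n +
        stats::rnorm(t, 0, sqrt(psi_e / n))

      # impute missing phenotypes from their full conditionals
      for (j in seq_len(t)) if (length(miss[[j]]) > 0) {
        um <- as.numeric(Umiss[[j]] %*% Ut[, j])
        ymiss[[j]] <- mu[j] + um +
          stats::rnorm(length(um), 0, sqrt(psi_e[j]))
        Yt[, j] <- ytil_fix[, j] + as.numeric(crossprod(Umiss[[j]], ymiss[[j]]))
      }

      if (is.null(fix_vc)) {
        # residual variances (diagonal)
        E <- Yt - Ut - ones_t %o% mu
        sse <- colSums(E^2)
        psi_e <- (sse + nu_e * Se) / stats::rchisq(t, n + nu_e)

        # genetic covariance, by structure
        if (structure == "diag") {
          ssg <- colSums(Ut^2 / d)
          psi_u <- diag((ssg + nu_u * Su) / stats::rchisq(t, n + nu_u),
                        t)
        } else if (structure == "un") {
          S <- crossprod(Ut, Ut / d) + S0
          repeat {
            psi_u_try <- tryCatch(
              chol2inv(chol(stats::rWishart(1, n + nu0, .safe_solve(S))[, , 1])),
              error = function(e) NULL)
            if (!is.null(psi_u_try)) { psi_u <- psi_u_try; break }
            n_jitter <- n_jitter + 1L
            S <- S + 1e-6 * mean(diag(S)) * diag(t)
          }
        } else { # fa
          LPi <- Lambda / Pi
          B <- .safe_solve(crossprod(Lambda, LPi) + diag(k))
          MF <- (Ut %*% LPi) %*% B
          Ft <- MF + (matrix(stats::rnorm(n * k), n, k) %*% chol(B)) * sqrt(d)
          Fw <- Ft / d
          G0 <- crossprod(Ft, Fw)
          for (j in seq_len(t)) {
            Cj <- .safe_solve(G0 / Pi[j] + diag(k))
            mj <- Cj %*% (crossprod(Fw, Ut[, j]) / Pi[j])
            Lambda[j, ] <- mj + as.numeric(t(chol(Cj)) %*% stats::rnorm(k))
          }
          Rt <- Ut - tcrossprod(Ft, Lambda)
          ss <- colSums(Rt^2 / d)
          Pi <- (ss + nu_pi * Spi) / stats::rchisq(t, n + nu_pi)
          psi_u <- tcrossprod(Lambda) + diag(Pi, t)
        }
      }

      if (it > burnin) {
        i <- it - burnin
        ut_sum <- ut_sum + Ut
        mu_sum <- mu_sum + mu
        psi_u_sum <- psi_u_sum + psi_u
        psi_e_sum <- psi_e_sum + psi_e
        sg <- diag(psi_u)
        h2_it <- sg / (sg + psi_e)
        h2_sum <- h2_sum + h2_it
        cor_sum <- cor_sum + .cov_to_cor(psi_u)
        psi_u_draws[i, ] <- psi_u[lt]
        psi_e_draws[i, ] <- psi_e
        h2_draws[i, ] <- h2_it
      }
    }

    u_mean <- U %*% (ut_sum / n_keep)
    dimnames(u_mean) <- list(ids, traits)
    psi_u_mean <- psi_u_sum / n_keep
    psi_e_mean <- psi_e_sum / n_keep
    dimnames(psi_u_mean) <- list(traits, traits)
    names(psi_e_mean) <- traits
    h2 <- h2_sum / n_keep
    names(h2) <- traits
    h2_rom <- diag(psi_u_mean) / (diag(psi_u_mean) + psi_e_mean)
    cor_g <- cor_sum / n_keep
    dimnames(cor_g) <- list(traits, traits)
    structure(list(mu = mu_sum / n_keep,
                   u = u_mean,
                   psi_u = psi_u_mean, psi_e = psi_e_mean,
                   h2 = h2, h2_ratio_of_means = h2_rom,
                   cor_g = cor_g,
                   model = "MT", engine = "gibbs", structure = structure,
                   k = if (structure == "fa") k else NULL,
                   n_iter = n_iter, burnin = burnin, seed = seed,
                   n_jitter_redraws = n_jitter,
                   draws = list(psi_u = psi_u_draws, psi_e = psi_e_draws,
                                h2 = h2_draws, lower_tri_index = lt),
                   ess = apply(h2_draws, 2, .ess),
                   ids = ids, traits = traits,
                   obs_mask = obs_mask),
              class = "gblup_fit")
  })
}

.safe_solve <- function(S) {
  out <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(out))
    out <- solve(S + 1e-8 * mean(diag(S)) * diag(nrow(S)))
  (out + t(out)) / 2
}

# crude effective sample size from lag-1 autocorrelation
.ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(n)
  r1 <- stats::cor(x[-1], x[-n])
  max(1, n * (1 - r1) / (1 + r1))
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf("gblup_fit [%s, %s]: %d individuals x %d trait(s)\n",
              x$model, x$engine, nrow(x$u), ncol(x$u)))
  cat("  h2:", paste(sprintf("%s=%.3f", colnames(x$u), x$h2),
                     collapse = ", "), "\n")
  invisible(x)
}

#' Genomic heritability from a fitted model
#'
#' `h2_j = sigma_gj^2 / (sigma_gj^2 + sigma_ej^2)`. For Gibbs fits the
#' default is the posterior mean of the per-sweep ratio; the
#' ratio-of-posterior-means variant is attached as attribute
#' `ratio_of_means` (the two agree within Monte Carlo error on
#' well-mixed chains).
#'
#' @param fit a `gblup_fit`.
#' @return Named per-trait heritabilities.
#' @export
estimate_heritability <- function(fit) {
  stopifnot(inherits(fit, "gblup_fit"))
  out <- fit$h2
  if (!is.null(fit$h2_ratio_of_means))
    attr(out, "ratio_of_means") <- fit$h2_ratio_of_means
  out
}

#' Genetic correlation matrix from a fitted multi-trait model
#'
#' `cor_ij = cov_ij / (sigma_i sigma_j)` computed from the posterior-mean
#' genetic covariance; the posterior mean of the per-sweep correlation is
#' attached as attribute `posterior_mean`. For the diagonal structure the
#' correlations are identically zero off the diagonal (a warning
#' reminds the caller that the model assumed them away).
#'
#' @param fit a `gblup_fit` from [fit_mt()].
#' @return t x t correlation matrix.
#' @export
genetic_correlation <- function(fit) {
  stopifnot(inherits(fit, "gblup_fit"))
  if (identical(fit$structure, "diag")) {
    warning("diagonal genetic covariance: off-diagonal correlations are 0 by assumption")
    out <- diag(ncol(fit$u))
    dimnames(out) <- list(fit$traits, fit$traits)
    return(out)
  }
  out <- .cov_to_cor(fit$psi_u)
  if (!is.null(fit$cor_g)) attr(out, "posterior_mean") <- fit$cor_g
  out
}

#' Predicted genetic values for selected individuals
#'
#' Returns the posterior-mean (Gibbs) or BLUP (REML) genetic value of the
#' target trait. Because masked phenotype cells are augmented inside the
#' sampler, predictions for test individuals reflect any observed
#' auxiliary phenotypes those individuals carry.
#'
#' @param fit a `gblup_fit`.
#' @param trait trait name (or index).
#' @param ids individual ids (default: all fitted individuals).
#' @return Named numeric vector of predictions.
#' @export
predict_genetic_values <- function(fit, trait = 1, ids = NULL) {
  stopifnot(inherits(fit, "gblup_fit"))
  if (is.null(ids)) ids <- rownames(fit$u)
  idx <- match(ids, rownames(fit$u))
  if (anyNA(idx)) stop("unknown individual id(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  out <- fit$u[idx, trait]
  names(out) <- ids
  out
}

#' Two-stage multi-output regressor stacking (BMORS)
#'
#' Stage 1 fits a per-trait single-trait GBLUP; predicted values for
#' individuals with observed phenotypes are obtained out-of-sample by an
#' internal 5-fold cross-validation within the training portion (so
#' stage 2 never sees leaked fits), while individuals with missing
#' phenotypes are predicted from the full stage-1 fit. Stage 2 then, for
#' each target trait, ridge-regresses the observed target phenotype on
#' all t stage-1 predictions (GCV-selected ridge penalty) and predicts
#' the masked cells. If a target's stage-1 predictions are degenerate
#' (zero variance), the stage-1 output is returned for that trait with a
#' warning.
#'
#' @param Y n x t phenotype matrix with `NA` masked cells.
#' @param K relationship matrix.
#' @param engine stage-1 engine (`"reml"` default, or `"gibbs"`).
#' @param n_folds_stage1 internal folds for out-of-sample stage-1 values.
#' @param lambda_grid ridge penalties searched by generalized
#'   cross-validation in stage 2.
#' @param n_iter,burnin,seed chain controls (Gibbs stage 1) and fold seed.
#' @return A list with `predictions` (n x t matrix; rows with observed
#'   target phenotypes carry fitted values, masked rows carry the final
#'   BMORS predictions), `stage1` (n x t stage-1 predictions),
#'   `coefficients` and `lambda` per target.
#' @export
fit_bmors <- function(Y, K, engine = c("reml", "gibbs"),
                      n_folds_stage1 = 5,
                      lambda_grid = 10^seq(-3, 3, length.out = 25),
                      n_iter = 4000, burnin = 2000, seed = 1) {
  engine <- match.arg(engine)
  Y <- as.matrix(Y)
  t <- ncol(Y)
  if (t < 2) stop("BMORS needs at least two traits")
  K <- .check_kernel(K, nrow(Y))
  n <- nrow(Y)
  ids <- rownames(Y); if (is.null(ids)) ids <- rownames(K)
  traits <- colnames(Y); if (is.null(traits)) traits <- paste0("trait", 1:t)
  st_fit <- function(yv) {
    if (engine == "reml")
      fit_st_gblup(yv, K, engine = "reml")
    else
      fit_st_gblup(yv, K, engine = "gibbs", n_iter = n_iter,
                   burnin = burnin, seed = seed)
  }
  Z <- matrix(NA_real_, n, t, dimnames = list(ids, traits))
  withr::with_seed(seed, {
    for (j in seq_len(t)) {
      yj <- Y[, j]; names(yj) <- ids
      obs <- which(!is.na(yj))
      full <- st_fit(yj)
      Z[-obs, j] <- full$u[-obs, 1]
      folds <- sample(rep_len(seq_len(n_folds_stage1), length(obs)))
      for (f in seq_len(n_folds_stage1)) {
        hold <- obs[folds == f]
        ycv <- yj; ycv[hold] <- NA
        Z[hold, j] <- st_fit(ycv)$u[hold, 1]
      }
    }
  })
  preds <- Z
  coefs <- vector("list", t); names(coefs) <- traits
  lam <- numeric(t)
  for (j in seq_len(t)) {
    obs <- which(!is.na(Y[, j]))
    Zobs <- Z[obs, , drop = FALSE]
    sdz <- c(stats::sd(Z[, j]), apply(Zobs, 2, stats::sd))
    if (any(!is.finite(sdz)) || sdz[1] < 1e-10 || any(sdz[-1] < 1e-12)) {
      warning("degenerate stage-1 predictions for trait ", traits[j],
              "; returning stage-1 output")
      next
    }
    df <- data.frame(y = Y[obs, j], Zobs)
    rr <- MASS::lm.ridge(y ~ ., data = df, lambda = lambda_grid)
    sel <- which.min(rr$GCV)
    cf <- stats::coef(rr)[sel, ]
    coefs[[j]] <- cf
    lam[j] <- lambda_grid[sel]
    preds[, j] <- cf[1] + as.numeric(Z %*% cf[-1])
  }
  list(predictions = preds, stage1 = Z, coefficients = coefs,
       lambda = lam)
}
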