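#' Simulate phased genotypes with tunable LD and family structure
#'
#' Generates phased diploid genotypes by a founder-haplotype copying
#' (mosaic) process: each haplotype copies segments from a pool of
#' `n_founders` founder haplotypes, switching founders between adjacent
#' SNPs with probability `1 - exp(-d / ld_decay_halflen)` where `d` is
#' the base-pair gap. The founder haplotypes themselves carry
#' distance-decaying LD (a thresholded latent Gaussian AR(1) on the same
#' bp scale), so population LD decays approximately exponentially with a
#' scale set by the single `ld_decay_halflen` parameter. Each individual
#' draws founders according to its own Dirichlet-distributed usage
#' weights, producing a continuous gradient of pairwise relatedness like
#' that of a diverse germplasm panel; weak family structure is added by
#' making `n_families` clusters of `family_size` individuals whose
#' haplotypes are single-crossover recombinants of four cluster-specific
#' parental haplotypes.
#'
#' Founder alleles are thresholded at a per-SNP uniform(0.1, 0.9) target
#' frequency; columns whose realized minor allele frequency falls below
#' `maf_min` get their threshold redrawn (latents and paths kept fixed)
#' up to `max_redraw` times, so the realized MAF spectrum is bounded
#' away from 0 whenever the founder pool permits it.
#'
#' @param n number of diploid individuals (>= 2).
#' @param n_chrom number of chromosomes.
#' @param n_snps total SNP count, split evenly across chromosomes.
#' @param chrom_length_bp chromosome length in bp; SNP positions are
#'   drawn uniformly without replacement.
#' @param ld_decay_halflen LD scale parameter in bp (> 0); smaller values
#'   give faster decay. The default is calibrated so that a 250-line
#'   panel's mean r2 falls below 0.1 between 250 and 300 kb.
#' @param n_founders founder haplotype pool size.
#' @param founder_conc Dirichlet concentration of each individual's
#'   founder-usage weights; small values give individuals concentrated
#'   (distinct) ancestry and hence a wide spread of pairwise
#'   relatedness, large values a flat exchangeable background.
#' @param n_families,family_size number and size of sibling clusters
#'   (set `n_families = 0` for a fully unrelated panel).
#' @param maf_min minimum realized minor allele frequency enforced by
#'   column redraws.
#' @param max_redraw redraw attempts per violating SNP column.
#' @param seed integer seed; identical seeds give identical output.
#' @return A [phased_geno()] object with no missing calls.
#' @export
simulate_phased_genotypes <- function(n,
                                      n_chrom = 12,
                                      n_snps = 5040,
                                      chrom_length_bp = 4e6,
                                      ld_decay_halflen = 725000,
                                      n_founders = 40,
                                      founder_conc = 0.3,
                                      n_families = 10,
                                      family_size = 4,
                                      maf_min = 0.05,
                                      max_redraw = 100,
                                      seed = 1) {
  if (n < 2) stop("n must be >= 2")
  if (ld_decay_halflen <= 0) stop("ld_decay_halflen must be > 0")
  if (n_snps < 2 * n_chrom) stop("need at least 2 SNPs per chromosome")
  if (n_families * family_size > n) {
    n_families <- floor(n / family_size)
  }
  withr::with_seed(seed, {
    m_per <- rep(n_snps %/% n_chrom, n_chrom)
    extra <- n_snps %% n_chrom
    if (extra > 0) m_per[seq_len(extra)] <- m_per[seq_len(extra)] + 1L
    pos <- lapply(m_per, function(mc) sort(sample.int(chrom_length_bp, mc)))
    map <- marker_map(snp_id = sprintf("snp%05d", seq_len(n_snps)),
                      chrom = rep(seq_len(n_chrom), m_per),
                      pos_bp = unlist(pos))
    m <- nrow(map)
    n_fam_ind <- n_families * family_size
    n_unrel <- n - n_fam_ind

    # founder-switch paths for all base haplotypes:
    # 2 per unrelated individual + 4 parental per family.
    # Each individual (and each family) has its own Dirichlet-distributed
    # founder-usage weights, giving the panel a continuous gradient of
    # relatedness rather than a flat exchangeable background.
    n_base <- 2L * n_unrel + 4L * n_families
    rdir <- function(k) {
      w <- matrix(stats::rgamma(k * n_founders, founder_conc),
                  nrow = k, ncol = n_founders)
      w / rowSums(w)
    }
    w_ind <- rdir(n_unrel)
    w_fam <- rdir(n_families)
    wts <- rbind(w_ind[rep(seq_len(n_unrel), each = 2L), , drop = FALSE],
                 w_fam[rep(seq_len(n_families), each = 4L), , drop = FALSE])
    paths <- .mosaic_paths(n_base, map, ld_decay_halflen, n_founders, wts)

    P <- matrix(0L, nrow = 2L * n, ncol = m)
    if (n_unrel > 0)
      P[seq_len(2L * n_unrel), ] <- paths[seq_len(2L * n_unrel), , drop = FALSE]
    row0 <- 2L * n_unrel
    for (f in seq_len(n_families)) {
      par <- paths[row0 + (4L * (f - 1L)) + 1:4, , drop = FALSE]
      for (s in seq_len(family_size)) {
        ind <- n_unrel + (f - 1L) * family_size + s
        P[2L * ind - 1L, ] <- .recombine_path(par[1L, ], par[2L, ], map)
        P[2L * ind, ]      <- .recombine_path(par[3L, ], par[4L, ], map)
      }
    }

    # Founder haplotypes carry their own distance-decaying LD: a latent
    # Gaussian AR(1) along each chromosome (site correlation
    # exp(-gap / halflen)) thresholded at a per-SNP target frequency.
    # Population LD is then the founder LD attenuated by founder
    # switching, so both components decay on the same bp scale.
    L <- matrix(stats::rnorm(n_founders * m), n_founders, m)
    col0 <- 0L
    for (ch in unique(map$chrom)) {
      idx <- which(map$chrom == ch)
      phi <- exp(-diff(map$pos_bp[idx]) / ld_decay_halflen)
      for (kk in seq_along(phi)) {
        j <- col0 + kk
        L[, j + 1L] <- phi[kk] * L[, j] + sqrt(1 - phi[kk]^2) * L[, j + 1L]
      }
      col0 <- col0 + length(idx)
    }
    pfreq <- stats::runif(m, 0.1, 0.9)
    A <- matrix(0L, n_founders, m)
    A[L < rep(stats::qnorm(pfreq), each = n_founders)] <- 1L
    colbase <- matrix(rep((seq_len(m) - 1L) * n_founders, each = 2L * n),
                      nrow = 2L * n)
    H <- matrix(A[as.vector(P) + as.vector(colbase)], nrow = 2L * n)
    # rejection redraws: resample the frequency threshold (latents kept,
    # preserving the LD structure) for columns violating the MAF floor
    for (attempt in seq_len(max_redraw)) {
      frq <- colMeans(H)
      bad <- which(pmin(frq, 1 - frq) < maf_min)
      if (length(bad) == 0) break
      # a column whose path entries are all identical can never pass
      fixable <- bad[vapply(bad, function(k) length(unique(P[, k])) > 1L,
                            logical(1))]
      if (length(fixable) == 0) break
      pfreq[fixable] <- stats::runif(length(fixable), 0.25, 0.75)
      for (k in fixable)
        A[, k] <- as.integer(L[, k] < stats::qnorm(pfreq[k]))
      idx <- as.vector(P[, fixable, drop = FALSE]) +
        as.vector(colbase[, fixable, drop = FALSE])
      H[, fixable] <- matrix(A[idx], nrow = 2L * n)
    }
    odd <- seq(1L, 2L * n, by = 2L)
    phased_geno(H[odd, , drop = FALSE], H[odd + 1L, , drop = FALSE], map)
  })
}

# Founder-index paths for n_hap haplotypes along the map. Switching
# probability between adjacent SNPs is 1 - exp(-gap / halflen); after a
# switch the founder is drawn from the haplotype's own founder-usage
# weights (rows of `wts`), which produces a continuum of relatedness
# across the panel when the weights differ between individuals.
.mosaic_paths <- function(n_hap, map, halflen, n_founders, wts) {
  m <- nrow(map)
  P <- matrix(0L, nrow = n_hap, ncol = m)
  col0 <- 0L
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    mc <- length(idx)
    q <- 1 - exp(-diff(map$pos_bp[idx]) / halflen)
    for (h in seq_len(n_hap)) {
      sw <- c(TRUE, stats::runif(mc - 1L) < q)
      seg <- cumsum(sw)
      draws <- sample.int(n_founders, seg[mc], replace = TRUE,
                          prob = wts[h, ])
      P[h, col0 + seq_len(mc)] <- draws[seg]
    }
    col0 <- col0 + mc
  }
  P
}

# Single-crossover recombinant of two parental founder paths, one
# crossover per chromosome at a uniform inter-SNP boundary.
.recombine_path <- function(pa, pb, map) {
  out <- integer(length(pa))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    mc <- length(idx)
    first_a <- stats::runif(1) < 0.5
    cx <- if (mc > 1L) sample.int(mc - 1L, 1L) else 1L
    take_a <- c(rep(first_a, cx), rep(!first_a, mc - cx))
    out[idx] <- ifelse(take_a, pa[idx], pb[idx])
  }
  out
}

#' Specify a multi-trait genetic architecture
#'
#' @param trait_names character vector of trait names (length t).
#' @param genetic_cov t x t positive semidefinite genetic covariance
#'   matrix (the simulation target for the genetic covariance of breeding
#'   values).
#' @param residual_cov residual variances: a length-t non-negative vector
#'   or a diagonal matrix (residuals are independent across traits).
#' @param n_qtl number of causal loci per trait (scalar or length t);
#'   ignored in infinitesimal mode.
#' @param pleiotropy_frac fraction of each trait's QTLs drawn from a
#'   shared pleiotropic set whose effects carry the target cross-trait
#'   correlation.
#' @param mode `"qtl"` for a sparse architecture with a configurable
#'   shared-QTL fraction (gives GWAS true positives), or
#'   `"infinitesimal"` for exact model-matched draws
#'   g ~ N(0, genetic_cov (x) G).
#' @return A `trait_model` list.
#' @export
trait_model <- function(trait_names, genetic_cov, residual_cov,
                        n_qtl = 100, pleiotropy_frac = 1,
                        mode = c("qtl", "infinitesimal")) {
  mode <- match.arg(mode)
  t <- length(trait_names)
  genetic_cov <- as.matrix(genetic_cov)
  stopifnot(nrow(genetic_cov) == t, ncol(genetic_cov) == t)
  if (max(abs(genetic_cov - t(genetic_cov))) > 1e-8)
    stop("genetic_cov must be symmetric")
  ev <- eigen(genetic_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop(sprintf("genetic_cov is not positive semidefinite (smallest eigenvalue %.4g)",
                 min(ev)))
  if (is.matrix(residual_cov)) residual_cov <- diag(residual_cov)
  residual_cov <- rep_len(as.numeric(residual_cov), t)
  if (any(residual_cov < 0)) stop("residual variances must be >= 0")
  if (pleiotropy_frac < 0 || pleiotropy_frac > 1)
    stop("pleiotropy_frac must be in [0, 1]")
  structure(list(trait_names = as.character(trait_names),
                 genetic_cov = genetic_cov,
                 residual_cov = residual_cov,
                 n_qtl = rep_len(as.integer(n_qtl), t),
                 pleiotropy_frac = pleiotropy_frac,
                 mode = mode),
            class = "trait_model")
}

#' Trait model calibrated to the five rice grain trace elements
#'
#' Genomic heritabilities (Cd 0.62, Fe 0.50, Mn 0.35, Cu 0.21, Zn 0.14)
#' and genetic correlations (e.g. Fe-Cd and Cu-Zn both 0.95, Mn-Cd 0.39)
#' of the study panel, on a standardized scale with unit phenotypic
#' variance per trait, so sigma_g^2 = h^2 and sigma_e^2 = 1 - h^2.
#'
#' @param mode architecture mode passed to [trait_model()].
#' @param n_qtl causal loci per trait in QTL mode.
#' @return A `trait_model` for traits Cd, Fe, Mn, Cu, Zn.
#' @export
rice_trait_model <- function(mode = "qtl", n_qtl = 150) {
  tn <- c("Cd", "Fe", "Mn", "Cu", "Zn")
  h2 <- c(Cd = 0.62, Fe = 0.50, Mn = 0.35, Cu = 0.21, Zn = 0.14)
  R <- diag(5)
  dimnames(R) <- list(tn, tn)
  R["Cd", "Fe"] <- 0.95; R["Cd", "Mn"] <- 0.39
  R["Cd", "Cu"] <- 0.71; R["Cd", "Zn"] <- 0.67
  R["Fe", "Mn"] <- 0.44; R["Fe", "Cu"] <- 0.79; R["Fe", "Zn"] <- 0.76
  R["Mn", "Cu"] <- 0.59; R["Mn", "Zn"] <- 0.70
  R["Cu", "Zn"] <- 0.95
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  psi_u <- diag(sqrt(h2)) %*% R %*% diag(sqrt(h2))
  dimnames(psi_u) <- list(tn, tn)
  trait_model(tn, psi_u, residual_cov = 1 - h2,
              n_qtl = n_qtl, pleiotropy_frac = 1, mode = mode)
}

#' Simulate multi-trait phenotypes with specified genetic covariance
#'
#' Draws genetic values and independent residuals under the model
#' `y = g + e` with `e ~ N(0, diag(residual_cov))` per individual. In QTL
#' mode, effects at shared causal loci are drawn with the target
#' cross-trait correlation and each trait's genetic values are rescaled
#' to its target genetic variance; in infinitesimal mode genetic values
#' are drawn exactly as `g ~ N(0, genetic_cov (x) G)` with `G` the
#' additive relationship matrix of the supplied panel (no rescaling, so
#' variance-component estimators can be tested for unbiasedness).
#'
#' @param geno a [phased_geno()] panel.
#' @param model a [trait_model()].
#' @param seed integer seed.
#' @return A list with elements `pheno` (n x t matrix, rownames = ids)
#'   and `truth` (a `truth_record`: true genetic values, QTL ids and
#'   effects per trait, target and realized covariance components).
#' @export
simulate_multitrait_phenotypes <- function(geno, model, seed = 1) {
  stopifnot(inherits(geno, "phased_geno"), inherits(model, "trait_model"))
  n <- length(geno$ids)
  t <- length(model$trait_names)
  m <- nrow(geno$map)
  if (model$mode == "qtl" && any(model$n_qtl > m))
    stop("n_qtl exceeds the number of available markers")
  withr::with_seed(seed, {
    if (model$mode == "infinitesimal") {
      G <- additive_grm(geno)
      eg <- eigen(unclass(G), symmetric = TRUE)
      Lg <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), n)
      Bu <- .mat_sqrt(model$genetic_cov)
      g <- Lg %*% matrix(stats::rnorm(n * t), n, t) %*% t(Bu)
      qtl <- NULL
    } else {
      X <- scale(dosage(geno), center = TRUE, scale = FALSE)
      R <- .cov_to_cor(model$genetic_cov)
      q_shared <- round(model$pleiotropy_frac * min(model$n_qtl))
      shared <- if (q_shared > 0) sample.int(m, q_shared) else integer(0)
      beta_s <- matrix(stats::rnorm(q_shared * t), q_shared, t) %*%
        t(.mat_sqrt(R))
      g <- matrix(0, n, t)
      qtl <- vector("list", t)
      names(qtl) <- model$trait_names
      for (j in seq_len(t)) {
        n_priv <- model$n_qtl[j] - q_shared
        priv <- if (n_priv > 0)
          sample(setdiff(seq_len(m), shared), n_priv) else integer(0)
        eff_idx <- c(shared, priv)
        eff <- c(if (q_shared > 0) beta_s[, j] else numeric(0),
                 stats::rnorm(n_priv))
        gj <- as.numeric(X[, eff_idx, drop = FALSE] %*% eff)
        target_var <- model$genetic_cov[j, j]
        s <- if (stats::var(gj) > 0 && target_var > 0)
          sqrt(target_var / stats::var(gj)) else 0
        g[, j] <- gj * s
        qtl[[j]] <- data.frame(snp_id = geno$map$snp_id[eff_idx],
                               effect = eff * s,
                               shared = seq_along(eff_idx) <= q_shared,
                               stringsAsFactors = FALSE)
      }
    }
    e <- matrix(stats::rnorm(n * t), n, t) %*%
      diag(sqrt(model$residual_cov), t)
    y <- g + e
    dimnames(y) <- dimnames(g) <- list(geno$ids, model$trait_names)
    truth <- structure(list(true_genetic_values = g,
                            qtl = qtl,
                            psi_u_target = model$genetic_cov,
                            psi_e_target = model$residual_cov,
                            psi_u_realized = stats::cov(g),
                            psi_e_realized = apply(e, 2, stats::var),
                            mode = model$mode),
                       class = "truth_record")
    list(pheno = y, truth = truth)
  })
}

# symmetric PSD matrix square root
.mat_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S)) %*% t(e$vectors)
}

.cov_to_cor <- function(S) {
  d <- sqrt(diag(S))
  d[d == 0] <- 1
  S / tcrossprod(d)
}

#' Packaged simulation presets
#'
#' `rice250` emulates the study panel: 250 accessions, ~5,000 SNPs on 12
#' chromosomes with LD decaying to r2 ~ 0.1 by 250-300 kb, weak family
#' structure, and five traits (Cd, Fe, Mn, Cu, Zn) with the panel's
#' heritabilities and genetic correlations ([rice_trait_model()]).
#' `tiny` is a 30-individual, 200-SNP, 2-trait dataset for fast tests.
#'
#' @param preset `"rice250"` or `"tiny"`.
#' @param seed integer seed (all randomness derives from it).
#' @param mode trait-architecture mode, see [trait_model()].
#' @return A list with `geno`, `pheno`, `truth`, `model`, `preset`.
#' @export
make_fixture <- function(preset = c("rice250", "tiny"), seed = 1,
                         mode = "qtl") {
  preset <- match.arg(preset)
  if (preset == "rice250") {
    model <- rice_trait_model(mode = mode)
    geno <- simulate_phased_genotypes(n = 250, n_chrom = 12, n_snps = 5040,
                                      chrom_length_bp = 4e6,
                                      n_founders = 40, n_families = 10,
                                      seed = seed)
  } else {
    cors <- matrix(c(0.50, 0.8 * sqrt(0.50 * 0.62),
                     0.8 * sqrt(0.50 * 0.62), 0.62), 2, 2)
    dimnames(cors) <- list(c("T1", "T2"), c("T1", "T2"))
    model <- trait_model(c("T1", "T2"), cors,
                         residual_cov = c(0.50, 0.38),
                         n_qtl = 20, pleiotropy_frac = 1, mode = mode)
    geno <- simulate_phased_genotypes(n = 30, n_chrom = 2, n_snps = 200,
                                      chrom_length_bp = 1e6,
                                      n_founders = 12, n_families = 2,
                                      family_size = 4, seed = seed)
  }
  sim <- simulate_multitrait_phenotypes(geno, model, seed = seed + 1L)
  list(geno = geno, pheno = sim$pheno, truth = sim$truth,
       model = model, preset = preset)
}
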