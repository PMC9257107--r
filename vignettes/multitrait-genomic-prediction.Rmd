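---
title: "Multi-trait genomic prediction with additive and haplotype kernels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait genomic prediction with additive and haplotype kernels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtgblup)
```

## The problem

Breeding programs that screen germplasm collections for expensive traits
(here the motivating case: grain concentrations of Zn, Fe, Cu, Mn and Cd
in a diverse rice panel, measured by ICP-MS) face a phenotyping budget
problem: genotyping 250 accessions is cheap, measuring five trace
elements on all of them is not. Multi-trait (MT) genomic prediction
addresses this by borrowing information from genetically correlated
auxiliary traits. Whether that helps depends on *where* the auxiliary
phenotypes are available, which this package encodes as three
cross-validation designs:

* **CV1** — the test set has no phenotypes at all (pure genomic
  prediction);
* **CV2** — auxiliary traits are phenotyped on everything, the target
  trait only on the training set;
* **CV3** — auxiliary traits are phenotyped only on the test set (the
  cheap design: ~20% of the panel).

## Models

All predictions come from GBLUP-type mixed models. The single-trait
model is

$$ y = 1\mu + g + e, \qquad g \sim N(0, \sigma_g^2 K), \quad
   e \sim N(0, \sigma_e^2 I), $$

with $K$ a marker-derived relationship matrix, and genomic heritability
$h_g^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)$. The multi-trait model
stacks $t$ traits with $u \sim N(0, \Psi_u \otimes K)$ and
$\varepsilon \sim N(0, \Psi_\varepsilon \otimes I)$,
$\Psi_\varepsilon$ diagonal. The genetic covariance $\Psi_u$ may be
diagonal (`MT-diag`), unstructured (`MT-UN`), or factor-analytic
$\Psi_u = \Lambda\Lambda' + \Pi$ with $k$ latent factors (`MT-FA`,
needs at least three traits). `BMORS` is a two-stage alternative:
per-trait GBLUP, then a per-target ridge regression on the stacked
stage-1 predictions. Genetic correlations are
$\mathrm{cor}_{ij} = \mathrm{cov}_{ij} / (\sigma_i \sigma_j)$ from
$\Psi_u$.

Two kernels are built from the same phased genotypes:

* `additive_grm()` — VanRaden method 1,
  $G = ZZ' / (2\sum_k p_k(1-p_k))$ on centered dosages;
* `haplotype_hrm()` — the same Gram construction on counts (0/1/2) of
  fixed-length haplotype alleles in consecutive windows of 2–5 SNPs.
  Because a haplotype allele tags a specific local allele combination,
  this kernel absorbs *local epistasis* — interactions among tightly
  linked SNPs that persist across generations. With single-SNP windows
  the two kernels coincide exactly, which the test suite asserts to
  1e-8; this nesting is why variance components from $G$ and $H$ are
  comparable under the shared VanRaden-style normalization. A
  trace-scaling normalization (mean diagonal 1) is available as an
  alternative when cross-software comparability matters more than
  nesting.

## Estimation

Single-trait variance components are estimated by REML, profiled to a
one-dimensional optimization in $\lambda = \sigma_e^2/\sigma_g^2$ via
the eigendecomposition of $K$ (the suite checks the optimum against a
brute-force two-dimensional likelihood grid). All multi-trait models use
a Gibbs sampler. Two implementation choices matter:

* **Eigenbasis sampling.** With $K = UDU'$ the rotated genetic values
  decouple across eigencomponents; simultaneously diagonalizing
  $\Psi_u^{-1}$ and $\Psi_\varepsilon^{-1}$ reduces the $t \times t$
  per-component conditional to elementwise operations, so one sweep is
  a handful of dense $n \times t$ products. The protocol-faithful
  20,000-sweep chains are therefore cheap even at $n = 250$.
* **Missing-data augmentation.** Masked phenotype cells are drawn from
  their full conditionals each sweep. This is what makes CV2/CV3 work:
  an observed auxiliary phenotype of a *test* individual influences the
  posterior of its genetic values through the imputation loop, with no
  separate conditional-prediction formula. With variance components
  fixed and no missing data, the posterior mean of $u$ equals the
  closed-form mixed-model solution (asserted on small instances).

**Priors.** Scalar variances get scaled inverse-chi-squared priors with
4 degrees of freedom and scale half the phenotypic variance. For the
unstructured $\Psi_u$ we use an inverse-Wishart with $t+1$ degrees of
freedom and scale half the observed phenotypic *covariance*. Two
deliberate choices: $t+1$ is the smallest integer df for which the
implied marginal on each genetic correlation is essentially flat (at
$t+2$ it carries a $(1-r^2)^{1/2}$ factor that measurably attenuates
strong correlations — we verified against the exact marginal likelihood,
computable in the eigenbasis, that the attenuation came from the prior
and not the sampler); and centering the scale on the phenotypic
covariance rather than its diagonal follows the empirical-Bayes
convention of the Bayesian GBLUP software lineage. Factor loadings get
standard-normal priors; `MT-FA`'s $\Psi_u$ is positive semidefinite in
every sweep by construction.

## The synthetic panel

No genotypes or phenotypes are redistributed; everything downstream is
exercised on a seeded simulator whose defaults emulate the study
panel's published diagnostics. `simulate_phased_genotypes()` is a
founder-mosaic process: each haplotype copies segments from a pool of
founder haplotypes, switching founders between adjacent SNPs with
probability $1 - e^{-d/h}$. Founder haplotypes themselves carry
distance-decaying LD (thresholded latent AR(1) on the same scale) —
with linkage-equilibrium founders a mosaic's population LD would
plateau at roughly $1/F$ with no distance decay, which is why the
founder pool is structured. Each individual draws founders through its
own Dirichlet-distributed usage weights, creating a continuum of
relatedness, plus a few sibling families.

Defaults were calibrated once against the motivating study's reported diagnostics
and then frozen: `ld_decay_halflen = 725` kb puts the distance at which
mean $r^2$ drops below 0.1 at ~262 kb (reported: 250–300 kb);
`founder_conc = 0.3` with 40 founders puts ~19% of normalized pairwise
Euclidean distances in $[0.6, 0.8)$ (reported most-frequent bin:
12–23%) and essentially none below 0.2 (reported: <5%). The number of
families is not stated in the motivating study, which detected several
without counting them; the default of 10 families of 4 is a
configuration choice, exposed as arguments.
Phenotypes are simulated on a standardized scale ($\mu = 0$, unit
phenotypic variance), so $\sigma_g^2 = h^2$; the `rice250` preset uses
the reported heritabilities (Cd 0.62 … Zn 0.14) and genetic
correlations (Fe–Cd and Cu–Zn 0.95) as targets. Two architectures are
available: a sparse QTL mode (shared pleiotropic QTLs with correlated
effects, rescaled to the target variances — needed so GWAS-based panel
selection has true positives to find) and an infinitesimal mode with
exact model-matched draws $g \sim N(0, \Psi_u \otimes G)$ used for
unbiasedness checks.

What the simulator does *not* reproduce: real allele-frequency spectra,
mutation/recombination hotspots, genuine population-structure
confounding between QTLs and ancestry, non-Gaussian phenotype skew, and
multi-environment effects. Passing tests therefore demonstrate the
correctness and calibration of the estimators under the study's
statistical structure, not performance guarantees on any real panel.

```{r fixture, eval = FALSE}
fx <- make_fixture("rice250", seed = 1)
G  <- additive_grm(fx$geno)
fit_st_gblup(fx$pheno[, "Cd"], G, engine = "reml")$h2
```

## Cross-validation and reporting

`make_cv_plan()` draws 5 equal folds × 20 repeats (the study protocol;
both are arguments). `evaluate()` fits per fold, pools the five test
folds of a repeat, and records one Pearson correlation between
predicted genetic values and observed phenotypes per repeat — the
pooled-per-repeat convention (20 values) rather than per-fold (100
values), matching the protocol's wording; fold-level accuracies are
retained for the alternative analysis. `compare_models()` applies a
paired t-test on per-repeat accuracies by default (models compared
within one run share fold partitions); Welch's unpaired test is the
fallback when plans differ. `relative_gain()` reports
$100(\text{improved}-\text{base})/\text{base}$; `format_gain()` offers
both rounding and truncation because published tables mix the two.

## Selective marker panels

`mlm_gwas()` scores each SNP by generalized least squares with the null
mixed model's covariance held fixed (the standard
population-parameters-previously-determined approximation; with
$K = I$ it reduces exactly to simple regression, which is tested).
TA-SNP selection takes the union of (a) all SNPs with $p < 0.01$ and
(b) the minimum-p SNP of every 300-kb bin anchored at position 0 — rule
(b) deliberately fires in every non-empty bin, as specified by the
source protocol, with a stricter `only_bins_with_signal` variant.
Selected SNPs within 300 kb of each other are chain-merged into
haplotype blocks (transitive merging, so a block may span more than
300 kb end-to-end while every adjacent gap is within it); blocks
contribute haplotype-count columns and the remaining singletons dosage
columns to a jointly normalized mixed kernel. `panel_cv_evaluate()`
re-runs GWAS, selection, and kernel construction inside every training
fold, with test-fold phenotypes excluded from the scan — the suite
asserts that shuffling test-fold phenotypes leaves the selected panel
identical.

## Numerical choices and degenerate inputs

* All kernels get a 1e-6 ridge before factorization (wide-panel Gram
  matrices at $n = 250$ are numerically rank-deficient); eigenvalues
  are floored at 1e-8.
* LD pruning is greedy left-to-right in a 50-SNP window with step 5;
  ties drop the later SNP. The shipped thresholds reproduce the
  motivating study's QC (MAF 0.05 — its stated "0.5" is treated as a typo — and the
  stated, unusually aggressive, $r^2 > 0.01$ prune), all configurable.
* The LD-decay estimator smooths per-bin means with a running mean of
  three and requires the curve to stay below the cutoff, returning a
  sentinel `Inf` when it never decays.
* Constant phenotypes short-circuit REML to a zero-heritability fit;
  constant stage-1 BMORS predictions fall back to stage-1 output with a
  warning; monomorphic SNPs are excluded from kernels and skipped in
  GWAS with counts logged as attributes.
* Non-PSD genetic covariance draws in the UN sampler are redrawn with
  jitter and counted (`n_jitter_redraws`); the inverse-Wishart scale
  falls back to a diagonal if the pairwise-complete phenotypic
  covariance is not positive definite.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run reduced but honest
versions of the study design, chosen to keep a full check of the
pipeline in the minutes range: parameter-recovery experiments use 250
individuals with ~2,000 markers (20 replicates for heritability, 10
for genetic correlation, with 4,000/2,000-sweep chains); the
scheme-ordering experiment uses the full `rice250` fixture with one
5-fold repeat and 800-sweep chains across 10 seeds. The
protocol-faithful 20,000/12,000 × 20-repeat profile is a parameter
change away (`n_iter`, `burnin`, `n_repeats`).

## Known limitations

* Residual covariance is diagonal by design (as in the motivating
  study); genuinely correlated residuals would be absorbed into
  $\Psi_u$.
* The REML engine is single-trait only; multi-trait inference is
  MCMC-only, matching the software lineage it mirrors.
* BMORS stage-1 out-of-sample values use an internal 5-fold split (the
  source is silent on this; in-sample stage-1 values would leak).
* The mosaic simulator produces exchangeable-ish ancestry, not the
  confounded substructure of real germplasm; GWAS calibration on real
  panels is a harder problem than the simulated null suggests.
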