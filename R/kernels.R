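#' Relationship matrices
#'
#' All kernels in the package are n x n symmetric Gram matrices of
#' centered count columns with a VanRaden-style heterozygosity
#' normalization, tagged with their `kind` (`additive`, `haplotype`,
#' `mixed`). They are stored un-ridged; fitting functions add a small
#' stabilizing ridge (1e-6 on the diagonal) before any factorization.
#'
#' @param values n x n numeric matrix.
#' @param kind one of `"additive"`, `"haplotype"`, `"mixed"`.
#' @param source free-form descriptor of the marker set used.
#' @return The matrix with class `rel_matrix` and attributes `kind`,
#'   `source`.
#' @export
rel_matrix <- function(values, kind = c("additive", "haplotype", "mixed"),
                       source = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values))
  if (!all(is.finite(values))) stop("relationship matrix has non-finite entries")
  values <- (values + t(values)) / 2
  structure(values, kind = kind, source = source,
            class = c("rel_matrix", "matrix", "array"))
}

#' @export
print.rel_matrix <- function(x, ...) {
  cat(sprintf("rel_matrix (%s): %d x %d, mean diagonal %.3f\n",
              attr(x, "kind"), nrow(x), ncol(x), mean(diag(x))))
  invisible(x)
}

#' Additive genomic relationship matrix (VanRaden method 1)
#'
#' G = Z Z' / (2 sum p_k (1 - p_k)) with Z the dosage matrix centered at
#' twice the panel allele frequency. Under Hardy-Weinberg proportions the
#' mean diagonal is close to 1. Monomorphic SNPs carry no information and
#' are excluded (their count is available as attribute
#' `n_monomorphic`). Sporadic missing dosages are mean-imputed before
#' centering.
#'
#' @param geno a [phased_geno()] object or an n x m dosage matrix in
#'   \{0,1,2\}.
#' @return A `rel_matrix` of kind `additive`.
#' @export
additive_grm <- function(geno) {
  d <- if (inherits(geno, "phased_geno")) dosage(geno) else as.matrix(geno)
  if (ncol(d) < 1) stop("need at least one marker")
  d <- .mean_impute(d)
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  n_mono <- sum(!poly)
  if (!any(poly)) stop("all markers are monomorphic")
  Z <- sweep(d[, poly, drop = FALSE], 2, 2 * p[poly])
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(d), rownames(d))
  out <- rel_matrix(G, "additive",
                    source = sprintf("%d SNPs (VanRaden method 1)", sum(poly)))
  attr(out, "n_monomorphic") <- n_mono
  out
}

#' Haplotype-based relationship matrix
#'
#' Builds H from a haplotype profile matrix (columns = distinct haplotype
#' alleles per window, entries = copies carried in \{0,1,2\}; see
#' [haplotype_profiles()]). The default normalization is the VanRaden
#' analogue on allele-count columns, H = W W' / (2 sum q_a (1 - q_a))
#' with W the column-centered profile and q_a the haplotype-allele
#' frequencies, which puts genetic variances estimated with H on a scale
#' comparable to those from [additive_grm()]; with single-SNP windows the
#' two constructions coincide. `normalize = "trace"` rescales instead to
#' a unit mean diagonal. All-constant profile columns are dropped.
#'
#' @param profiles haplotype profile matrix from [haplotype_profiles()].
#' @param normalize `"vanraden"` (default) or `"trace"`.
#' @return A `rel_matrix` of kind `haplotype`.
#' @export
haplotype_hrm <- function(profiles, normalize = c("vanraden", "trace")) {
  normalize <- match.arg(normalize)
  W0 <- as.matrix(profiles)
  q <- colMeans(W0) / 2
  keep <- apply(W0, 2, function(x) any(x != x[1]))
  if (!any(keep)) stop("all haplotype profile columns are constant")
  W <- scale(W0[, keep, drop = FALSE], center = TRUE, scale = FALSE)
  H <- tcrossprod(W)
  if (normalize == "vanraden") {
    H <- H / (2 * sum(q[keep] * (1 - q[keep])))
  } else {
    H <- H * nrow(W) / sum(diag(H))
  }
  dimnames(H) <- list(rownames(W0), rownames(W0))
  rel_matrix(H, "haplotype",
             source = sprintf("%d haplotype alleles (%s normalization)",
                              sum(keep), normalize))
}

#' Mixed genotype + haplotype kernel for selective panels
#'
#' Concatenates centered dosage columns of singleton SNPs with centered
#' haplotype-count columns of merged blocks and applies a single joint
#' VanRaden-style normalization `2 * sum q (1 - q)` over all count
#' columns (each column is a count out of two copies, so SNP dosage
#' columns contribute p(1-p) exactly as in [additive_grm()]). With no
#' blocks this reduces to the additive GRM on the selected SNPs; with no
#' singleton SNPs it reduces to [haplotype_hrm()] on the blocks.
#'
#' @param snp_dosage n x s dosage matrix of singleton SNPs (or NULL).
#' @param block_profiles n x a haplotype profile matrix of merged blocks
#'   (or NULL).
#' @return A `rel_matrix` of kind `mixed`.
#' @export
mixed_panel_kernel <- function(snp_dosage = NULL, block_profiles = NULL) {
  cols <- list()
  if (!is.null(snp_dosage) && ncol(as.matrix(snp_dosage)) > 0)
    cols$snp <- .mean_impute(as.matrix(snp_dosage))
  if (!is.null(block_profiles) && ncol(as.matrix(block_profiles)) > 0)
    cols$hap <- as.matrix(block_profiles)
  if (length(cols) == 0) stop("empty panel: no SNPs and no blocks")
  M <- do.call(cbind, cols)
  q <- colMeans(M) / 2
  keep <- q > 0 & q < 1
  if (!any(keep)) stop("all panel columns are constant")
  W <- scale(M[, keep, drop = FALSE], center = TRUE, scale = FALSE)
  K <- tcrossprod(W) / (2 * sum(q[keep] * (1 - q[keep])))
  dimnames(K) <- list(rownames(M), rownames(M))
  rel_matrix(K, "mixed",
             source = sprintf("%d singleton SNPs + %d haplotype alleles",
                              if (is.null(cols$snp)) 0L else ncol(cols$snp),
                              if (is.null(cols$hap)) 0L else ncol(cols$hap)))
}

# column mean imputation for sporadic missing dosages
.mean_impute <- function(d) {
  if (!anyNA(d)) return(d)
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2]]
  d
}

#' Export / import a relationship matrix as TSV
#'
#' Square layout with individual ids as header row and first column.
#'
#' @param K a `rel_matrix`.
#' @param path output file.
#' @export
write_rel_matrix <- function(K, path) {
  df <- data.frame(id = rownames(K), as.data.frame(unclass(K)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rel_matrix
#' @param kind kernel kind tag to attach on read.
#' @export
read_rel_matrix <- function(path, kind = "additive") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df[[1]]
  rel_matrix(K, kind)
}
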