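#' Write phased genotypes as VCF 4.2
#'
#' Minimal sites-only body with phased `GT` calls (`0|1` style), one
#' contig line per chromosome. REF/ALT are placeholder alleles (the
#' simulator works on 0/1 codes, not nucleotides).
#'
#' @param geno a [phased_geno()].
#' @param path output file (plain text).
#' @export
write_phased_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "phased_geno"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=mtgblup",
               sprintf("##contig=<ID=%d>", unique(geno$map$chrom)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", geno$ids),
                     collapse = "\t")), con)
  gt <- matrix(paste0(t(geno$h1), "|", t(geno$h2)),
               nrow = ncol(geno$h1))         # variants x samples
  gt[is.na(t(geno$h1)) | is.na(t(geno$h2))] <- ".|."
  body <- cbind(geno$map$chrom, geno$map$pos_bp, geno$map$snp_id,
                "A", "T", ".", "PASS", ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write a phenotype table as TSV
#'
#' One header row (`id` then trait names); missing values written as
#' `NA`.
#'
#' @param Y n x t phenotype matrix with individual rownames.
#' @param path output file.
#' @export
write_phenotypes <- function(Y, path) {
  df <- data.frame(id = rownames(Y), as.data.frame(Y), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  Y <- as.matrix(df[, -1, drop = FALSE])
  rownames(Y) <- as.character(df[[1]])
  Y
}

#' Write a marker map as TSV
#'
#' @param map a [marker_map()].
#' @param path output file.
#' @export
write_marker_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load a dataset from VCF + phenotype TSV
#'
#' Parses the VCF with `vcfR`, reconstructs phased haplotypes from the
#' `GT` field, reads the phenotype table, and inner-joins the two on
#' individual id (the number of dropped ids is reported as attribute
#' `n_dropped`). Unphased (`/`-separated) calls are accepted only with
#' `require_phased = FALSE`; such genotypes still provide dosages for
#' additive kernels but are rejected by [haplotype_profiles()].
#'
#' @param vcf_path phased VCF file.
#' @param pheno_path phenotype TSV (`id` column + one column per trait,
#'   `NA` for missing).
#' @param require_phased error on unphased GT calls (default TRUE).
#' @return `list(geno = phased_geno, pheno = matrix)` with aligned,
#'   identically ordered individuals.
#' @export
load_dataset <- function(vcf_path, pheno_path, require_phased = TRUE) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  phased <- grepl("|", gt, fixed = TRUE) | gt %in% c(".", ".|.", "./.")
  if (require_phased && !all(phased, na.rm = TRUE))
    stop("unphased GT calls found; haplotype models need phased data ",
         "(set require_phased = FALSE to load dosages only)")
  a1 <- suppressWarnings(as.integer(substr(gt, 1, 1)))
  a2 <- suppressWarnings(as.integer(substr(gt, 3, 3)))
  map <- marker_map(snp_id = fix[, "ID"],
                    chrom = as.integer(fix[, "CHROM"]),
                    pos_bp = as.integer(fix[, "POS"]))
  ord <- match(map$snp_id, fix[, "ID"])
  h1 <- t(matrix(a1, nrow = nrow(gt)))[, ord, drop = FALSE]
  h2 <- t(matrix(a2, nrow = nrow(gt)))[, ord, drop = FALSE]
  rownames(h1) <- rownames(h2) <- colnames(gt)
  geno <- phased_geno(h1, h2, map)
  if (!all(phased, na.rm = TRUE)) attr(geno, "unphased") <- TRUE
  Y <- read_phenotypes(pheno_path)
  common <- intersect(geno$ids, rownames(Y))
  if (length(common) == 0) stop("no individual ids shared between VCF and phenotypes")
  n_dropped <- (length(geno$ids) - length(common)) +
    (nrow(Y) - length(common))
  keep <- match(common, geno$ids)
  geno <- structure(list(h1 = geno$h1[keep, , drop = FALSE],
                         h2 = geno$h2[keep, , drop = FALSE],
                         map = geno$map, ids = common),
                    class = "phased_geno")
  out <- list(geno = geno, pheno = Y[common, , drop = FALSE])
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Run a full cross-validation experiment
#'
#' Config-driven orchestration of the study design: load or simulate a
#' dataset, build the requested kernels, evaluate every (model x scheme
#' x target) cell, and assemble tidy per-repeat and summary tables with
#' relative gains against the ST-CV1 additive baseline and paired
#' t-tests. Cells that error are recorded in `failures` and the run
#' continues.
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{dataset}{`list(preset = , seed = )` for [make_fixture()],
#'       or `list(vcf = , pheno = )` file paths.}
#'     \item{targets}{character vector of target traits (auxiliaries
#'       default to all remaining traits; override with `auxiliaries`).}
#'     \item{schemes}{subset of `c("ST-CV1","MT-CV1","MT-CV2","MT-CV3")`.}
#'     \item{models}{list of model specs: `list(type =, structure =,
#'       kernel = "additive"|"haplotype", L = )`.}
#'     \item{cv}{`list(k_folds = 5, n_repeats = 20, seed = 1)`.}
#'     \item{mcmc}{`list(n_iter = 2000, burnin = 1000)` applied to every
#'       Gibbs fit (raise to the protocol's 20,000/12,000 for final
#'       runs).}
#'     \item{out_dir}{optional directory for TSV artifacts.}
#'   }
#' @return A list with `results` (per-repeat tidy data.frame), `summary`
#'   (per-cell means, gains, p-values), `failures`, and the `config`.
#' @export
run_experiment <- function(config) {
  ds <- config$dataset
  if (!is.null(ds$preset)) {
    fx <- make_fixture(ds$preset, seed = if (is.null(ds$seed)) 1 else ds$seed)
    geno <- fx$geno; Y <- fx$pheno
  } else {
    loaded <- load_dataset(ds$vcf, ds$pheno)
    geno <- loaded$geno; Y <- loaded$pheno
  }
  cv <- utils::modifyList(list(k_folds = 5, n_repeats = 20, seed = 1),
                          if (is.null(config$cv)) list() else config$cv)
  mcmc <- utils::modifyList(list(n_iter = 2000, burnin = 1000),
                            if (is.null(config$mcmc)) list() else config$mcmc)
  schemes <- if (is.null(config$schemes)) "ST-CV1" else config$schemes
  targets <- if (is.null(config$targets)) colnames(Y)[1] else config$targets
  models <- if (is.null(config$models)) list(list(type = "st")) else config$models

  plan <- make_cv_plan(nrow(Y), cv$k_folds, cv$n_repeats, cv$seed,
                       ids = rownames(Y))
  kernels <- list(additive = additive_grm(geno))
  need_L <- unique(unlist(lapply(models, function(m)
    if (identical(m$kernel, "haplotype")) m$L else NULL)))
  for (L in need_L) {
    prof <- haplotype_profiles(geno, make_haplotype_windows(geno$map, L))
    kernels[[paste0("haplotype_L", L)]] <- haplotype_hrm(prof)
  }

  rows <- list(); failures <- list()
  for (target in targets) {
    aux <- if (!is.null(config$auxiliaries)) config$auxiliaries else
      setdiff(colnames(Y), target)
    for (scheme in schemes) {
      for (mod in models) {
        mod$n_iter <- mcmc$n_iter; mod$burnin <- mcmc$burnin
        is_st <- scheme == "ST-CV1"
        if (is_st) mod$type <- "st"
        if (!is_st && identical(mod$type, "st")) next
        kname <- if (identical(mod$kernel, "haplotype"))
          paste0("haplotype_L", mod$L) else "additive"
        spec <- mask_spec(scheme, target,
                          if (is_st) character(0) else aux)
        label <- paste0(.fill_model(mod, spec)$label, "/", kname)
        res <- tryCatch(
          evaluate(Y, kernels[[kname]], plan, spec, mod, seed = cv$seed),
          error = function(e) e)
        if (inherits(res, "error")) {
          failures[[length(failures) + 1L]] <-
            data.frame(target = target, scheme = scheme, model = label,
                       error = conditionMessage(res))
          next
        }
        rows[[length(rows) + 1L]] <-
          data.frame(target = target, scheme = scheme, model = label,
                     kernel = kname, repeat_idx = seq_along(res$accuracy),
                     accuracy = res$accuracy, stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  summary <- NULL
  if (!is.null(results)) {
    cells <- unique(results[c("target", "scheme", "model", "kernel")])
    summary <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      cell <- merge(results, cells[i, ])
      base <- results[results$target == cells$target[i] &
                        results$scheme == "ST-CV1", ]
      gain <- p <- NA_real_
      if (nrow(base) > 0 && cells$scheme[i] != "ST-CV1") {
        bacc <- base$accuracy[order(base$repeat_idx)][seq_len(max(cell$repeat_idx))]
        gain <- relative_gain(mean(bacc), mean(cell$accuracy))
        cmp <- compare_models(cell$accuracy[order(cell$repeat_idx)], bacc)
        p <- cmp$p_value
      }
      data.frame(cells[i, ], mean_accuracy = mean(cell$accuracy),
                 gain_vs_st_cv1 = gain, p_vs_st_cv1 = p,
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(results, file.path(config$out_dir, "results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summary, file.path(config$out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(results = results, summary = summary, failures = failures,
       config = config)
}
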