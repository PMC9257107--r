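#' Cross-validation plan
#'
#' Random, stratification-free partition of `n` individuals into
#' `k_folds` folds of equal size (within one), independently re-drawn
#' for each of `n_repeats` repeats. The study protocol is 5 folds x 20
#' repeats, i.e. one hundred calibration/prediction rounds.
#'
#' @param n number of individuals.
#' @param k_folds folds per repeat.
#' @param n_repeats independent repeats.
#' @param seed integer seed; the plan is reproducible.
#' @param ids optional individual ids (default `1:n` as character).
#' @return A `cv_plan`: integer n x n_repeats matrix of fold labels plus
#'   metadata.
#' @export
make_cv_plan <- function(n, k_folds = 5, n_repeats = 20, seed = 1,
                         ids = NULL) {
  if (n < k_folds) stop("n must be >= k_folds")
  if (is.null(ids)) ids <- as.character(seq_len(n))
  folds <- withr::with_seed(seed, {
    vapply(seq_len(n_repeats),
           function(r) sample(rep_len(seq_len(k_folds), n)),
           integer(n))
  })
  rownames(folds) <- ids
  structure(list(folds = folds, n = n, k_folds = k_folds,
                 n_repeats = n_repeats, seed = seed, ids = ids),
            class = "cv_plan")
}

#' Phenotype-visibility specification for a CV scheme
#'
#' The four designs differ in where auxiliary-trait phenotypes are
#' visible: `ST-CV1` uses the target trait alone; `MT-CV1` adds
#' auxiliary phenotypes in the training set only; `MT-CV2` has them in
#' both training and test sets; `MT-CV3` has them only in the test set
#' (the budget-friendly design: auxiliaries are phenotyped on just the
#' prediction candidates). The target trait is always hidden in the test
#' set — it is what is being predicted.
#'
#' @param scheme one of `"ST-CV1"`, `"MT-CV1"`, `"MT-CV2"`, `"MT-CV3"`.
#' @param target target trait name.
#' @param auxiliaries character vector of auxiliary trait names (empty
#'   for `ST-CV1`).
#' @return A `mask_spec`.
#' @export
mask_spec <- function(scheme = c("ST-CV1", "MT-CV1", "MT-CV2", "MT-CV3"),
                      target, auxiliaries = character(0)) {
  scheme <- match.arg(scheme)
  if (target %in% auxiliaries)
    stop("target trait cannot also be an auxiliary trait")
  if (scheme != "ST-CV1" && length(auxiliaries) == 0)
    stop("MT schemes need at least one auxiliary trait")
  structure(list(scheme = scheme, target = target,
                 auxiliaries = as.character(auxiliaries)),
            class = "mask_spec")
}

#' Apply a CV masking scheme to a phenotype table
#'
#' Returns the phenotype matrix restricted to the traits the scheme
#' involves (target first), with cells hidden (`NA`) according to the
#' scheme's visibility pattern for the given repeat and fold.
#'
#' @param Y n x t phenotype matrix with individual rownames.
#' @param plan a [make_cv_plan()].
#' @param rep_idx,fold repeat and fold selecting the test set.
#' @param spec a [mask_spec()].
#' @return Masked phenotype matrix with attribute `test_ids`.
#' @export
apply_mask <- function(Y, plan, rep_idx, fold, spec) {
  stopifnot(inherits(plan, "cv_plan"), inherits(spec, "mask_spec"))
  Y <- as.matrix(Y)
  want <- c(spec$target, spec$auxiliaries)
  if (!all(want %in% colnames(Y)))
    stop("traits not present in phenotype table: ",
         paste(setdiff(want, colnames(Y)), collapse = ", "))
  test <- plan$folds[, rep_idx] == fold
  out <- Y[, want, drop = FALSE]
  out[test, spec$target] <- NA          # the target is always predicted
  if (spec$scheme %in% c("ST-CV1", "MT-CV1")) {
    out[test, spec$auxiliaries] <- NA   # no phenotypes in the test set
  } else if (spec$scheme == "MT-CV3") {
    out[!test, spec$auxiliaries] <- NA  # auxiliaries only in the test set
  }                                     # MT-CV2: auxiliaries everywhere
  attr(out, "test_ids") <- rownames(Y)[test]
  out
}

#' Evaluate a prediction model under a CV scheme
#'
#' For each repeat: fit the model once per fold on the masked phenotype
#' table, predict the test fold's target-trait genetic values, pool the
#' (prediction, observed phenotype) pairs of all folds, and record one
#' Pearson correlation. The result carries `n_repeats` accuracies and
#' their mean (per-fold accuracies are also retained for the
#' fold-level comparison variant). Constant predictions in a repeat are
#' recorded as accuracy 0 with a warning flag.
#'
#' @param Y full (unmasked) phenotype matrix.
#' @param K relationship matrix used by the model.
#' @param plan a [make_cv_plan()] over the rows of `Y`.
#' @param spec a [mask_spec()].
#' @param model model specification:
#'   `list(type = "st"|"mt"|"bmors", structure =, k =, engine =,
#'   n_iter =, burnin =)`; sensible defaults are filled in.
#' @param seed base seed; each (repeat, fold) fit gets a distinct
#'   derived seed.
#' @return An `accuracy_result`.
#' @export
evaluate <- function(Y, K, plan, spec, model = list(type = "st"),
                     seed = 1) {
  stopifnot(inherits(plan, "cv_plan"), inherits(spec, "mask_spec"))
  Y <- as.matrix(Y)
  model <- .fill_model(model, spec)
  acc <- numeric(plan$n_repeats)
  fold_acc <- matrix(NA_real_, plan$n_repeats, plan$k_folds)
  flagged <- logical(plan$n_repeats)
  for (r in seq_len(plan$n_repeats)) {
    pred <- obs <- numeric(0)
    for (f in seq_len(plan$k_folds)) {
      Ym <- apply_mask(Y, plan, r, f, spec)
      test <- attr(Ym, "test_ids")
      p <- .fit_and_predict(Ym, K, model, test, spec$target,
                            seed = seed + 1000L * r + f)
      o <- Y[test, spec$target]
      fold_acc[r, f] <- if (stats::sd(p) > 0 && stats::sd(o) > 0)
        stats::cor(p, o) else NA_real_
      pred <- c(pred, p); obs <- c(obs, o)
    }
    if (stats::sd(pred) == 0) {
      warning("constant predictions in repeat ", r, "; accuracy set to 0")
      acc[r] <- 0; flagged[r] <- TRUE
    } else {
      acc[r] <- stats::cor(pred, obs)
    }
  }
  structure(list(accuracy = acc, mean = mean(acc),
                 fold_accuracy = fold_acc,
                 scheme = spec$scheme, target = spec$target,
                 auxiliaries = spec$auxiliaries,
                 model = model$label, flagged = flagged,
                 n_repeats = plan$n_repeats),
            class = "accuracy_result")
}

.fill_model <- function(model, spec) {
  model$type <- match.arg(model$type, c("st", "mt", "bmors"))
  if (model$type != "st" && spec$scheme == "ST-CV1")
    stop("only the single-trait model is valid under ST-CV1")
  if (model$type == "st" && spec$scheme %in% c("MT-CV2", "MT-CV3"))
    stop("the single-trait model cannot use auxiliary phenotypes (CV2/CV3)")
  if (is.null(model$engine)) model$engine <- "reml"
  if (is.null(model$structure)) model$structure <- "un"
  if (is.null(model$k)) model$k <- 1
  if (is.null(model$n_iter)) model$n_iter <- 2000
  if (is.null(model$burnin)) model$burnin <- 1000
  if (is.null(model$label))
    model$label <- switch(model$type,
                          st = paste0("ST-GBLUP(", model$engine, ")"),
                          mt = paste0("MT-", toupper(model$structure)),
                          bmors = "BMORS")
  model
}

.fit_and_predict <- function(Ym, K, model, test_ids, target, seed) {
  if (model$type == "st") {
    yv <- Ym[, target]; names(yv) <- rownames(Ym)
    fit <- fit_st_gblup(yv, K, engine = model$engine,
                        n_iter = model$n_iter, burnin = model$burnin,
                        seed = seed)
    return(predict_genetic_values(fit, 1, test_ids))
  }
  if (model$type == "mt") {
    fit <- fit_mt(Ym, K, structure = model$structure, k = model$k,
                  n_iter = model$n_iter, burnin = model$burnin,
                  seed = seed)
    return(predict_genetic_values(fit, target, test_ids))
  }
  bm <- fit_bmors(Ym, K, engine = model$engine,
                  n_iter = model$n_iter, burnin = model$burnin,
                  seed = seed)
  p <- bm$predictions[test_ids, target]
  names(p) <- test_ids
  p
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("accuracy [%s, %s, target %s]: mean %.3f over %d repeats\n",
              x$model, x$scheme, x$target, x$mean, x$n_repeats))
  invisible(x)
}

#' Relative gain in prediction accuracy
#'
#' `100 * (improved - base) / base`, the convention used throughout the
#' study's gain statements (e.g. base 0.23 to 0.42 is +82.6%).
#'
#' @param base baseline accuracy (non-zero).
#' @param improved accuracy of the improved model.
#' @return Gain in percent (full precision; see [format_gain()]).
#' @export
relative_gain <- function(base, improved) {
  if (any(base == 0)) stop("relative gain undefined for a zero baseline")
  100 * (improved - base) / base
}

#' Format a percent gain for reporting
#'
#' @param gain percent gain from [relative_gain()].
#' @param digits decimal places.
#' @param mode `"round"` (default) or `"truncate"` (toward zero); some
#'   published tables truncate rather than round.
#' @return Character vector like `"82.6"`.
#' @export
format_gain <- function(gain, digits = 1, mode = c("round", "truncate")) {
  mode <- match.arg(mode)
  f <- 10^digits
  # pre-round far below the displayed precision so that values that are
  # exact in decimal (e.g. 12.5) are not truncated down by binary
  # floating-point representation error
  v <- if (mode == "round") round(gain * f) / f else
    trunc(round(gain * f, 6)) / f
  formatC(v, format = "f", digits = digits)
}

#' Compare two cross-validated models
#'
#' Student t-test on per-repeat accuracies: paired by default (the two
#' results must share a plan, so the 20 per-repeat differences are the
#' test units), or two-sample Welch. Identical accuracy vectors (zero
#' variance of differences) are reported as p = 1 with a warning.
#'
#' @param a,b `accuracy_result` objects (or plain numeric accuracy
#'   vectors).
#' @param paired use the paired test (default).
#' @return A list with `statistic`, `p_value`, `mean_diff`, `method`.
#' @export
compare_models <- function(a, b, paired = TRUE) {
  av <- if (inherits(a, "accuracy_result")) a$accuracy else as.numeric(a)
  bv <- if (inherits(b, "accuracy_result")) b$accuracy else as.numeric(b)
  if (paired && length(av) != length(bv))
    stop("paired comparison needs equal repeat counts")
  if (paired && stats::sd(av - bv) == 0) {
    warning("zero variance of paired differences; p set to 1")
    return(list(statistic = 0, p_value = 1, mean_diff = mean(av - bv),
                method = "paired t-test (degenerate)"))
  }
  tt <- stats::t.test(av, bv, paired = paired)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_diff = mean(av) - mean(bv),
       method = if (paired) "paired t-test" else "Welch two-sample t-test")
}
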