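#' @name expression_modeling
#' @title Modeling gene expression from promoter-bin enrichments
#'
#' @description
#' Expression is read out CAGE-style: for each gene the tag density of the
#' middle two bins (the +/- 100 bp window around the TSS in the 40-bin
#' layout) is summed over the plus- and minus-strand tracks,
#' `GEx = bin20p + bin21p + bin20m + bin21m`. The `gex` transform takes
#' `ln(GEx + eps)` for a pseudocount `eps` and quantile-scales it into
#' `[0, 1]` exactly like a mark column. Expression is then modeled from the
#' mark enrichments around the TSS at three input resolutions (1 bin, all 40
#' bins, or only the middle two bins), with either a linear or an additive
#' MARS model, and the pseudocount is chosen by scanning
#' `eps in {0.001, 0.01, 0.1, 1}` for the best cross-validated Pearson r.
NULL

EPS_GRID <- c(0.001, 0.01, 0.1, 1)

#' CAGE-style expression readout from strand tracks
#'
#' @param plus,minus `signal_track` objects for the two strands. Minus-strand
#'   values are taken as magnitudes (CAGE minus coverage is sometimes
#'   signed).
#' @param tss_regions a 40-bin `tss_flank` `region_set`.
#' @return named numeric vector of raw `GEx` values (one per gene).
#' @export
compute_cage_gex <- function(plus, minus, tss_regions) {
  stopifnot(tss_regions$region_type == "tss_flank",
            tss_regions$n_bins == 40L)
  if (is.null(plus) || is.null(minus)) {
    stop("both strand tracks are required", call. = FALSE)
  }
  minus$runs$value <- abs(minus$runs$value)
  cp <- count_region_bins(plus, tss_regions)
  cm <- count_region_bins(minus, tss_regions)
  gex <- cp[, 20L] + cp[, 21L] + cm[, 20L] + cm[, 21L]
  setNames(as.numeric(gex), rownames(cp))
}

#' The gex transform: log, clip, scale
#'
#' `gex = quantile_scale(ln(GEx + eps), q)`. Natural log; the base only
#' shifts the pre-scaling values affinely and is absorbed by the scaling.
#'
#' @param raw named vector of raw GEx values.
#' @param eps pseudocount, `> 0`.
#' @param q clip fraction, default 0.01.
#' @return numeric vector in `[0, 1]`, names preserved.
#' @export
transform_gex <- function(raw, eps, q = 0.01) {
  stopifnot(eps > 0)
  quantile_scale(log(raw + eps), q = q)
}

EXPRESSION_VARIANTS <- c("one_bin", "forty_bin", "middle_two")

#' Build the expression feature matrix at a chosen resolution
#'
#' `one_bin` uses the 1-bin TSS matrix (one column per mark); `forty_bin` all
#' 40 columns per mark; `middle_two` only bins 20 and 21 (1-based, the
#' +/- 100 bp window). Only the absolute (not the CpG-normalized) DNA
#' methylation columns enter.
#'
#' @param em a `tss_flank` `enrichment_matrix` with 40 bins (or 1 bin for
#'   `variant = "one_bin"`).
#' @param variant one of `"one_bin"`, `"forty_bin"`, `"middle_two"`.
#' @return numeric feature matrix (genes x columns).
#' @export
build_expression_features <- function(em, variant = EXPRESSION_VARIANTS) {
  variant <- match.arg(variant)
  need_bins <- if (variant == "one_bin") 1L else 40L
  if (em$n_bins != need_bins) {
    stop("variant '", variant, "' needs a ", need_bins, "-bin matrix",
         call. = FALSE)
  }
  keys <- em$marks$key[em$marks$methylation_flavor != "cpg_normalized"]
  cols <- unlist(lapply(keys, function(k) {
    idx <- mark_col_idx(em, k)
    if (variant == "middle_two") idx[c(20L, 21L)] else idx
  }))
  em$values[, cols, drop = FALSE]
}

#' Cross-validated expression model
#'
#' @param features feature matrix from [build_expression_features()].
#' @param gex transformed expression vector, aligned with the feature rows.
#' @param model_type `"linear"` or `"mars"`.
#' @param k,seed,folds cross-validation controls (see [kfold_cv()]).
#' @param ... passed to [fit_mars()] for MARS models.
#' @return a `cv_result`.
#' @export
fit_expression_cv <- function(features, gex,
                              model_type = c("linear", "mars"),
                              k = 10L, seed = 1L, folds = NULL, ...) {
  model_type <- match.arg(model_type)
  stopifnot(nrow(features) == length(gex))
  kfold_cv(features, gex, k = k,
           model = if (model_type == "linear") "ols" else "mars",
           seed = seed, folds = folds, ...)
}

#' Scan pseudocounts for the best-performing gex transform
#'
#' Runs the cross-validated model for each pseudocount in the grid and
#' returns the argmax of Pearson r (ties resolved toward the smaller
#' pseudocount).
#'
#' @param features feature matrix.
#' @param raw_gex raw GEx vector.
#' @param model_type `"linear"` or `"mars"`.
#' @param eps_grid pseudocount grid, default `c(0.001, 0.01, 0.1, 1)`.
#' @param k,seed cross-validation controls.
#' @param ... passed to [fit_mars()].
#' @return list with `table` (data.frame `eps`, `r`, `p`), `best_eps`,
#'   `best_r`.
#' @export
scan_pseudocounts <- function(features, raw_gex,
                              model_type = c("linear", "mars"),
                              eps_grid = EPS_GRID, k = 10L, seed = 1L, ...) {
  model_type <- match.arg(model_type)
  stopifnot(length(eps_grid) > 0)
  eps_grid <- sort(eps_grid)
  folds <- make_folds(length(raw_gex), k, seed)
  rows <- lapply(eps_grid, function(eps) {
    gex <- transform_gex(raw_gex, eps)
    cv <- fit_expression_cv(features, gex, model_type, k = k, seed = seed,
                            folds = folds, ...)
    data.frame(eps = eps, r = cv$pearson_r, p = cv$p_value)
  })
  tab <- do.call(rbind, rows)
  i <- which.max(tab$r)  # grid sorted ascending: ties go to the smaller eps
  list(table = tab, best_eps = tab$eps[i], best_r = tab$r[i])
}

#' Cross-cell-line expression transfer
#'
#' Fits the expression model on 100% of the source cell line's genes and
#' evaluates it on the target cell line. The pseudocount is the source cell
#' line's optimum and is used for the gex transform on both sides. The caller
#' supplies features built on the common marks of the two cell lines.
#'
#' @param features_a,raw_gex_a source-cell-line features and raw GEx.
#' @param features_b,raw_gex_b target-cell-line features and raw GEx
#'   (identical column sets).
#' @param eps pseudocount (the source optimum).
#' @param model_type `"linear"` or `"mars"`.
#' @param ... passed to [fit_mars()].
#' @return list with `r`, `p`, `eps`, `model_type`.
#' @export
transfer_expression <- function(features_a, raw_gex_a, features_b, raw_gex_b,
                                eps, model_type = c("linear", "mars"), ...) {
  model_type <- match.arg(model_type)
  stopifnot(identical(colnames(features_a), colnames(features_b)))
  gex_a <- transform_gex(raw_gex_a, eps)
  gex_b <- transform_gex(raw_gex_b, eps)
  fit <- if (model_type == "linear") {
    fit_ols(features_a, gex_a)
  } else {
    fit_mars(features_a, gex_a, ...)
  }
  pred <- predict(fit, features_b)
  ct <- pearson_with_pvalue(pred, gex_b)
  list(r = ct$r, p = ct$p, eps = eps, model_type = model_type)
}
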