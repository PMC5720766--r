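#' @name mark_imputation
#' @title Predicting each mark from all other marks
#'
#' @description
#' Within one constellation every mark is regressed on all remaining marks
#' under 10-fold cross-validation; full-data (100%) models expose the weight
#' structure. DNA methylation is special-cased throughout: when methylation is
#' the target, the CpG-normalized column is predicted and the absolute column
#' is removed from the predictors; for any other target, the normalized
#' methylation column is removed (only the total presence of methylation is
#' informative) while the absolute column stays.
NULL

# The response column key for a target mark under the methylation rules.
target_y_key <- function(em, target) {
  rows <- em$marks[em$marks$mark_name == target, , drop = FALSE]
  if (nrow(rows) == 0L) stop("mark '", target, "' not in matrix",
                             call. = FALSE)
  if (any(rows$methylation_flavor != "none")) {
    rows$key[rows$methylation_flavor == "cpg_normalized"]
  } else {
    rows$key[1L]
  }
}

#' Split an enrichment matrix into predictors and a response
#'
#' Applies the DNA methylation rules (see the module description) and removes
#' the target itself from the predictor set.
#'
#' @param em an `enrichment_matrix` (1-bin resolution).
#' @param target a mark name present in the matrix.
#' @return list with `X` (predictor matrix), `y` (response vector), `y_key`,
#'   `x_keys`.
#' @export
select_predictor_columns <- function(em, target) {
  stopifnot(em$n_bins == 1L)
  marks <- em$marks
  if (!target %in% marks$mark_name) {
    stop("mark '", target, "' not in matrix", call. = FALSE)
  }
  y_key <- target_y_key(em, target)
  target_is_meth <- any(marks$methylation_flavor[marks$mark_name == target] !=
                          "none")
  drop_keys <- if (target_is_meth) {
    marks$key[marks$mark_name == target]  # both methylation columns
  } else {
    c(marks$key[marks$mark_name == target],
      marks$key[marks$methylation_flavor == "cpg_normalized"])
  }
  x_keys <- setdiff(marks$key, drop_keys)
  list(
    X = em$values[, x_keys, drop = FALSE],
    y = as.numeric(em$values[, y_key]),
    y_key = y_key,
    x_keys = x_keys
  )
}

#' Cross-validated imputation of every mark from all others
#'
#' @param em an `enrichment_matrix` (1-bin).
#' @param k folds, default 10.
#' @param seed seed for the shared fold assignment (folds are drawn once per
#'   matrix and shared across targets for comparability).
#' @param predictors optional restriction of the predictor set to a subset of
#'   mark names (used by the reduced-panel analyses); targets are then all
#'   marks outside the panel.
#' @return an `imputation_report`: list with `constellation`, `table`
#'   (data.frame `mark`, `r`, `p`, `n`), `median_r`, `failures`, `seed`.
#' @export
impute_all_marks_cv <- function(em, k = 10L, seed = 1L, predictors = NULL) {
  stopifnot(em$n_bins == 1L)
  mark_names <- unique(em$marks$mark_name)
  if (is.null(predictors)) {
    if (length(mark_names) < 3L) stop("need at least 3 marks", call. = FALSE)
    targets <- mark_names
  } else {
    stopifnot(all(predictors %in% mark_names))
    targets <- setdiff(mark_names, predictors)
    if (length(targets) == 0L) stop("no target marks outside the panel",
                                    call. = FALSE)
  }
  folds <- make_folds(nrow(em$values), k, seed)
  res <- lapply(targets, function(tg) {
    sel <- select_predictor_columns(em, tg)
    if (!is.null(predictors)) {
      panel_keys <- panel_predictor_keys(em, predictors)
      sel$X <- em$values[, panel_keys, drop = FALSE]
    }
    tryCatch({
      cv <- kfold_cv(sel$X, sel$y, k = k, model = "ols", seed = seed,
                     folds = folds)
      list(mark = tg, r = cv$pearson_r, p = cv$p_value, ok = TRUE)
    },
    epicompress_constant_input = function(e) {
      list(mark = tg, r = NA_real_, p = NA_real_, ok = FALSE)
    })
  })
  tab <- data.frame(
    mark = vapply(res, `[[`, character(1), "mark"),
    r = vapply(res, `[[`, numeric(1), "r"),
    p = vapply(res, `[[`, numeric(1), "p"),
    n = nrow(em$values),
    stringsAsFactors = FALSE
  )
  failures <- tab$mark[!vapply(res, `[[`, logical(1), "ok")]
  if (length(failures) > 0L) {
    warning("per-mark failures excluded from the median: ",
            paste(failures, collapse = ", "))
  }
  structure(
    list(constellation = em$constellation, table = tab,
         median_r = median(tab$r, na.rm = TRUE), failures = failures,
         seed = seed, predictors = predictors),
    class = "imputation_report"
  )
}

#' @export
print.imputation_report <- function(x, ...) {
  cat("imputation_report:", nrow(x$table), "targets, median r =",
      fmt_num(x$median_r), "\n")
  invisible(x)
}

# Predictor column keys of a mark panel under the methylation rules (only the
# absolute flavor enters a predictor set).
panel_predictor_keys <- function(em, panel) {
  marks <- em$marks
  rows <- marks[marks$mark_name %in% panel &
                  marks$methylation_flavor != "cpg_normalized", , drop = FALSE]
  rows$key
}

#' Full-data (100%) linear models for every mark
#'
#' @param em an `enrichment_matrix` (1-bin).
#' @return a `weight_table`: named list of `linear_fit` objects (one per
#'   target mark) with the matrix's mark metadata attached.
#' @export
fit_full_models <- function(em) {
  stopifnot(em$n_bins == 1L)
  targets <- unique(em$marks$mark_name)
  fits <- lapply(targets, function(tg) {
    sel <- select_predictor_columns(em, tg)
    fit <- fit_ols(sel$X, sel$y)
    fit$target <- tg
    fit
  })
  names(fits) <- targets
  structure(list(fits = fits, marks = em$marks,
                 constellation = em$constellation),
            class = "weight_table")
}

#' @export
print.weight_table <- function(x, ...) {
  cat("weight_table:", length(x$fits), "full-data models\n")
  invisible(x)
}

REGULATORY_TYPES <- c("chromatin_remodeler", "coregulator", "epigenetic_mark",
                      "transcription_factor")

#' Overrepresentation of mark types among strong model weights
#'
#' Pools the absolute weights of all full-data models, restricted to the four
#' regulatory mark types (marks with unknown / non-regulatory function are
#' dropped), takes the `q` quantile of the pooled absolute weights as cutoff,
#' and reports, per target mark type, the relative frequency of each input
#' type among the above-cutoff weights — next to the baseline frequency of
#' each type among the predictor columns.
#'
#' @param weights a `weight_table` from [fit_full_models()].
#' @param q quantile cutoff over pooled absolute weights, default 0.95.
#' @return data.frame with `target_type`, `input_type`, `freq`,
#'   `baseline_freq`, `n_above`.
#' @export
mark_type_overrepresentation <- function(weights, q = 0.95) {
  marks <- weights$marks
  type_of_key <- setNames(marks$mark_type, marks$key)
  type_of_mark <- setNames(marks$mark_type, marks$mark_name)
  pool <- list()
  for (tg in names(weights$fits)) {
    t_type <- unname(type_of_mark[tg])
    if (!t_type %in% REGULATORY_TYPES) next
    w <- weights$fits[[tg]]$weights
    in_type <- unname(type_of_key[names(w)])
    keep <- in_type %in% REGULATORY_TYPES
    if (!any(keep)) next
    pool[[tg]] <- data.frame(target_type = t_type, input_type = in_type[keep],
                             w = abs(unname(w[keep])),
                             stringsAsFactors = FALSE)
  }
  if (length(pool) == 0L) stop("need at least 2 regulatory mark types",
                               call. = FALSE)
  pool <- do.call(rbind, pool)
  if (length(unique(c(pool$target_type, pool$input_type))) < 2L) {
    # single-type worlds are legal: frequencies are trivially 1
  }
  cutoff <- quantile(pool$w, q, type = 7, names = FALSE)
  # baseline: predictor-column counts per regulatory type
  pred_rows <- marks[marks$mark_type %in% REGULATORY_TYPES &
                       marks$methylation_flavor != "cpg_normalized", ,
                     drop = FALSE]
  base <- table(factor(pred_rows$mark_type, levels = REGULATORY_TYPES))
  base_freq <- as.numeric(base) / sum(base)
  names(base_freq) <- REGULATORY_TYPES
  out <- list()
  for (tt in intersect(REGULATORY_TYPES, unique(pool$target_type))) {
    sub <- pool[pool$target_type == tt & pool$w >= cutoff, , drop = FALSE]
    if (nrow(sub) == 0L) {
      out[[tt]] <- data.frame(target_type = tt, input_type = NA_character_,
                              freq = NA_real_, baseline_freq = NA_real_,
                              n_above = 0L, stringsAsFactors = FALSE)
      next
    }
    f <- table(factor(sub$input_type, levels = REGULATORY_TYPES))
    present <- names(f)[as.numeric(base) > 0 | f > 0]
    out[[tt]] <- data.frame(
      target_type = tt,
      input_type = present,
      freq = as.numeric(f[present]) / nrow(sub),
      baseline_freq = unname(base_freq[present]),
      n_above = nrow(sub),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Best-correlated single-mark baseline
#'
#' The strongest competitor to a model: the predictor column with the maximum
#' signed Pearson correlation with the target (signed, matching "best
#' correlated mark" — anti-correlated predictors are captured by the model,
#' not by this baseline).
#'
#' @param em an `enrichment_matrix` (1-bin).
#' @param target a mark name.
#' @return list with `best_mark` (predictor key) and `r`.
#' @export
best_correlated_baseline <- function(em, target) {
  sel <- select_predictor_columns(em, target)
  if (length(sel$x_keys) < 1L) stop("need at least 2 marks", call. = FALSE)
  rs <- suppressWarnings(as.numeric(cor(sel$X, sel$y)))
  rs[is.na(rs)] <- -Inf
  i <- which.max(rs)
  list(best_mark = sel$x_keys[i], r = rs[i])
}

#' Same-mark-other-cell-line baseline
#'
#' Pearson correlation of one mark's enrichments between two cell lines over
#' their shared genes — the "take the measurement from another cell line"
#' reference prediction.
#'
#' @param em_a,em_b `enrichment_matrix` objects of the same locus
#'   constellation for two cell lines.
#' @param mark a mark name present in both.
#' @return Pearson r over the shared genes.
#' @export
same_mark_other_cell_baseline <- function(em_a, em_b, mark) {
  shared <- intersect(rownames(em_a$values), rownames(em_b$values))
  if (length(shared) == 0L) stop("no shared genes between matrices",
                                 call. = FALSE)
  ka <- target_y_key(em_a, mark)
  kb <- target_y_key(em_b, mark)
  cor(em_a$values[shared, ka], em_b$values[shared, kb])
}
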