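#' @name mark_selection
#' @title Reduced panels and greedy information-content selection
#'
#' @description
#' Two ways of compressing a mark panel: (i) fix a reference panel — such as
#' the six IHEC histone modifications — and predict every other mark from it;
#' (ii) build a panel greedily, selecting in each round the mark that
#' maximizes the median cross-validated Pearson r over all not-yet-selected
#' target marks when added to the already selected predictors. The
#' information content of a mark set is exactly that median.
NULL

#' The six IHEC reference histone modifications
#' @export
IHEC_MARKS <- c("H3K4me1", "H3K4me3", "H3K9me3", "H3K27ac", "H3K27me3",
                "H3K36me3")

#' Predict all non-panel marks from a fixed predictor panel
#'
#' @param em a 1-bin `enrichment_matrix`.
#' @param predictors character vector of panel mark names (subset of the
#'   matrix marks).
#' @param k,seed cross-validation controls.
#' @return an `imputation_report` over all non-panel target marks.
#' @export
subset_impute_cv <- function(em, predictors, k = 10L, seed = 1L) {
  impute_all_marks_cv(em, k = k, seed = seed, predictors = predictors)
}

#' Cross-cell-line transfer with a restricted predictor panel
#'
#' @param em_a,em_b source and target `enrichment_matrix` objects.
#' @param predictors panel mark names (must be common to both cell lines).
#' @return data.frame of transfer results for every common non-panel mark.
#' @export
subset_transfer <- function(em_a, em_b, predictors) {
  transfer_all_marks(em_a, em_b, predictors = predictors)
}

#' Rank marks by single-predictor information content
#'
#' For each candidate mark, fits 10-fold-CV linear models with solely that
#' mark as input (plus intercept) for every other target mark and takes the
#' median Pearson r. Identical to the first round of [greedy_select()] when
#' the same seed is used.
#'
#' @param em a 1-bin `enrichment_matrix`.
#' @param k,seed cross-validation controls.
#' @return data.frame `mark`, `median_r`, sorted descending (ties broken by
#'   mark name).
#' @export
single_mark_ranking <- function(em, k = 10L, seed = 1L) {
  stopifnot(length(unique(em$marks$mark_name)) >= 2L)
  trace1 <- greedy_select(em, n_rounds = 1L, k = k, seed = seed)
  v <- trace1$rounds[[1L]]
  v <- v[order(-v$median_r, v$candidate), , drop = FALSE]
  rownames(v) <- NULL
  data.frame(mark = v$candidate, median_r = v$median_r,
             stringsAsFactors = FALSE)
}

#' Greedy forward selection of marks by information content
#'
#' Implements the selection recursion literally: starting from an empty set
#' `S`, each round evaluates every unselected candidate by the median
#' cross-validated Pearson r over all remaining target marks (excluding the
#' candidate itself) when the models use `S` plus the candidate as
#' predictors; the argmax joins `S` (ties resolved toward the lowest mark
#' index). DNA methylation follows the usual predictor/response rules. One
#' fold assignment, drawn from `seed`, is shared by every model for fairness
#' and determinism.
#'
#' @param em a 1-bin `enrichment_matrix`.
#' @param n_rounds number of selection rounds (`<=` number of marks; default
#'   all).
#' @param k,seed cross-validation controls.
#' @return a `selection_trace`: list with `selected` (ordered mark names),
#'   `ordervec` (their indices in the matrix's mark order), `median_r`
#'   (winner's score per round), `rounds` (per-round candidate score
#'   data.frames), `seed`.
#' @export
greedy_select <- function(em, n_rounds = NULL, k = 10L, seed = 1L) {
  stopifnot(em$n_bins == 1L)
  mark_names <- unique(em$marks$mark_name)
  n_marks <- length(mark_names)
  if (is.null(n_rounds)) n_rounds <- n_marks
  stopifnot(n_rounds >= 1L, n_rounds <= n_marks)
  folds <- make_folds(nrow(em$values), k, seed)
  selected <- character(0)
  rounds <- list()
  winner_r <- numeric(0)
  for (i in seq_len(n_rounds)) {
    candidates <- setdiff(mark_names, selected)
    if (length(candidates) == 1L) {
      # a single remaining mark terminates trivially: no targets to score
      selected <- c(selected, candidates)
      rounds[[i]] <- data.frame(candidate = candidates,
                                median_r = NA_real_,
                                stringsAsFactors = FALSE)
      winner_r <- c(winner_r, NA_real_)
      break
    }
    v <- vapply(candidates, function(cand) {
      s_j <- c(selected, cand)
      targets <- setdiff(mark_names, s_j)
      x_keys <- panel_predictor_keys(em, s_j)
      rs <- vapply(targets, function(tg) {
        y <- as.numeric(em$values[, target_y_key(em, tg)])
        tryCatch(
          pearson_with_pvalue(
            cv_predict_ols(em$values[, x_keys, drop = FALSE], y, folds),
            y)$r,
          epicompress_constant_input = function(e) NA_real_
        )
      }, numeric(1))
      median(rs, na.rm = TRUE)
    }, numeric(1))
    rounds[[i]] <- data.frame(candidate = candidates, median_r = unname(v),
                              stringsAsFactors = FALSE)
    # argmax with ties resolved toward the lowest mark index
    cand_idx <- match(candidates, mark_names)
    best <- candidates[order(-v, cand_idx)][1L]
    selected <- c(selected, best)
    winner_r <- c(winner_r, unname(v[best]))
  }
  structure(
    list(selected = selected,
         ordervec = match(selected, mark_names),
         median_r = winner_r,
         rounds = rounds,
         marks = mark_names,
         seed = seed, k = k),
    class = "selection_trace"
  )
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("selection_trace:", paste(x$selected, collapse = " > "), "\n")
  cat("  median r per round:", paste(fmt_num(x$median_r, 3), collapse = " "),
      "\n")
  invisible(x)
}

#' Marks needed to exceed median-r thresholds
#'
#' Runs the greedy selection once and reports, for each threshold, the first
#' round whose selected-set median r (over the remaining targets) exceeds it;
#' `NA` marks an unreachable threshold.
#'
#' @param em a 1-bin `enrichment_matrix`.
#' @param thresholds numeric vector in `(0, 1)`.
#' @param n_rounds,k,seed passed to [greedy_select()].
#' @return data.frame `threshold`, `n_marks` (NA when unreachable), plus the
#'   trace as attribute `"trace"`.
#' @export
threshold_curve <- function(em, thresholds, n_rounds = NULL, k = 10L,
                            seed = 1L) {
  stopifnot(all(thresholds > 0), all(thresholds < 1))
  trace <- greedy_select(em, n_rounds = n_rounds, k = k, seed = seed)
  n_marks <- vapply(thresholds, function(th) {
    hit <- which(!is.na(trace$median_r) & trace$median_r > th)
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }, integer(1))
  out <- data.frame(threshold = thresholds, n_marks = n_marks)
  attr(out, "trace") <- trace
  out
}
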