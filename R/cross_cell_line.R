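#' @name cross_cell_line
#' @title Transferring mark models across cell lines
#'
#' @description
#' Models are fitted on 100% of the loci in one cell line and evaluated on the
#' measured values of another, over the marks available in both. Comparing
#' each mark's median transfer performance with its median intra-cell-line
#' cross-validated performance separates generally applicable association
#' rules from cell-line-specific ones (a drop of at least 0.3 flags a mark as
#' transfer-fragile). The full source-by-target grid of median transfer r
#' doubles as a similarity matrix for clustering cell lines by how well one
#' predicts another.
NULL

#' Restrict two enrichment matrices to their common marks
#'
#' Both matrices are reduced to the marks present in both, in identical
#' order; methylation flavors are matched pairwise, so a methylation mark
#' present in only one cell line is dropped from both.
#'
#' @param em_a,em_b `enrichment_matrix` objects (same locus constellation,
#'   different cell lines).
#' @return list with elements `a` and `b`, the projected matrices.
#' @export
shared_mark_projection <- function(em_a, em_b) {
  common <- intersect(unique(em_a$marks$mark_name),
                      unique(em_b$marks$mark_name))
  # methylation must carry both flavors on both sides to survive
  common <- Filter(function(m) {
    fa <- sort(em_a$marks$methylation_flavor[em_a$marks$mark_name == m])
    fb <- sort(em_b$marks$methylation_flavor[em_b$marks$mark_name == m])
    identical(fa, fb)
  }, common)
  if (length(common) < 2L) stop("fewer than 2 common marks", call. = FALSE)
  project <- function(em) {
    rows <- which(em$marks$mark_name %in% common)
    meta <- em$marks[rows, , drop = FALSE]
    meta <- meta[order(match(meta$mark_name, common),
                       meta$methylation_flavor), , drop = FALSE]
    cols <- unlist(lapply(meta$key, function(k) mark_col_idx(em, k)))
    em$values <- em$values[, cols, drop = FALSE]
    em$marks <- meta
    rownames(em$marks) <- NULL
    em
  }
  list(a = project(em_a), b = project(em_b))
}

#' Predict a mark in one cell line from a model fitted in another
#'
#' Projects both matrices onto their common marks, fits the full-data (100%)
#' linear model for `target` in the source cell line under the methylation
#' predictor rules (optionally restricted to a predictor panel), and
#' evaluates Pearson r / p against the measured values in the target cell
#' line.
#'
#' @param em_a source-cell-line `enrichment_matrix` (1-bin).
#' @param em_b target-cell-line `enrichment_matrix` (1-bin).
#' @param target mark name present in both.
#' @param predictors optional mark-name panel restricting the model input.
#' @return a `transfer_result`: list with `source_cell`, `target_cell`,
#'   `mark`, `r`, `p`, `n`.
#' @export
transfer_predict <- function(em_a, em_b, target, predictors = NULL) {
  pr <- shared_mark_projection(em_a, em_b)
  sel_a <- select_predictor_columns(pr$a, target)
  x_keys <- sel_a$x_keys
  if (!is.null(predictors)) {
    x_keys <- intersect(panel_predictor_keys(pr$a, predictors), x_keys)
    if (length(x_keys) == 0L) stop("no panel predictors left", call. = FALSE)
  }
  fit <- fit_ols(pr$a$values[, x_keys, drop = FALSE], sel_a$y)
  y_key_b <- target_y_key(pr$b, target)
  pred <- predict(fit, pr$b$values[, x_keys, drop = FALSE])
  ct <- pearson_with_pvalue(pred, as.numeric(pr$b$values[, y_key_b]))
  structure(
    list(source_cell = em_a$constellation$cell_line,
         target_cell = em_b$constellation$cell_line,
         mark = target, r = ct$r, p = ct$p, n = nrow(pr$b$values)),
    class = "transfer_result"
  )
}

#' All-mark transfer between two cell lines
#'
#' Runs [transfer_predict()] for every common mark and returns a tidy table.
#'
#' @inheritParams transfer_predict
#' @return data.frame with `source_cell`, `target_cell`, `mark`, `r`, `p`.
#' @export
transfer_all_marks <- function(em_a, em_b, predictors = NULL) {
  pr <- shared_mark_projection(em_a, em_b)
  targets <- unique(pr$a$marks$mark_name)
  if (!is.null(predictors)) targets <- setdiff(targets, predictors)
  rows <- lapply(targets, function(tg) {
    tr <- transfer_predict(pr$a, pr$b, tg, predictors = predictors)
    data.frame(source_cell = tr$source_cell, target_cell = tr$target_cell,
               mark = tg, r = tr$r, p = tr$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Transfer-drop analysis: which marks lose accuracy across cell lines?
#'
#' For each mark present in the transfer table, computes the median transfer
#' r (pooled over all ordered cell-line pairs and locus constellations), the
#' median intra-cell-line CV r (pooled over the supplied imputation reports),
#' and flags marks whose drop (intra minus transfer) reaches `threshold`.
#' Marks observed in fewer than two cell lines never enter the transfer table
#' and are therefore excluded. Optionally compares the drop distributions of
#' two user-supplied mark groups with a two-sample Kolmogorov-Smirnov test.
#'
#' @param intra_reports list of `imputation_report` objects (one per
#'   constellation/cell line).
#' @param transfers data.frame from [transfer_all_marks()] calls, row-bound.
#' @param threshold flagging threshold on the drop, default 0.3.
#' @param groups optional named list of two character vectors of mark names;
#'   their drop distributions are compared with `ks.test`.
#' @return a `drop_report`: list with `table` (data.frame `mark`, `intra_r`,
#'   `transfer_r`, `drop`, `flagged`), `threshold`, and `ks` (or `NULL`).
#' @export
drop_analysis <- function(intra_reports, transfers, threshold = 0.3,
                          groups = NULL) {
  if (inherits(intra_reports, "imputation_report")) {
    intra_reports <- list(intra_reports)
  }
  intra <- do.call(rbind, lapply(intra_reports, `[[`, "table"))
  marks <- intersect(unique(transfers$mark), unique(intra$mark))
  tab <- data.frame(
    mark = marks,
    intra_r = vapply(marks, function(m)
      median(intra$r[intra$mark == m], na.rm = TRUE), numeric(1)),
    transfer_r = vapply(marks, function(m)
      median(transfers$r[transfers$mark == m], na.rm = TRUE), numeric(1)),
    stringsAsFactors = FALSE
  )
  tab$drop <- tab$intra_r - tab$transfer_r
  tab$flagged <- tab$drop >= threshold
  rownames(tab) <- NULL
  ks <- NULL
  if (!is.null(groups)) {
    stopifnot(length(groups) == 2L)
    d1 <- tab$drop[tab$mark %in% groups[[1L]]]
    d2 <- tab$drop[tab$mark %in% groups[[2L]]]
    ks <- suppressWarnings(ks.test(d1, d2))
  }
  structure(list(table = tab, threshold = threshold, ks = ks),
            class = "drop_report")
}

#' @export
print.drop_report <- function(x, ...) {
  cat("drop_report:", sum(x$table$flagged), "of", nrow(x$table),
      "marks flagged at threshold", x$threshold, "\n")
  invisible(x)
}

#' Predictive-strength similarity matrix between cell lines
#'
#' Square matrix of median Pearson r: rows are target cell lines, columns are
#' source cell lines. Off-diagonal entries are the median transfer r over the
#' pair's common marks; the diagonal holds each cell line's median intra
#' 10-fold-CV r.
#'
#' @param matrices named list of 1-bin `enrichment_matrix` objects, one per
#'   cell line.
#' @param k,seed cross-validation parameters for the diagonal.
#' @param predictors optional mark panel restriction (applied to both intra
#'   and transfer models).
#' @return numeric matrix with cell-line dimnames.
#' @export
predictive_similarity_matrix <- function(matrices, k = 10L, seed = 1L,
                                         predictors = NULL) {
  cells <- names(matrices)
  stopifnot(length(cells) >= 2L)
  sim <- matrix(NA_real_, length(cells), length(cells),
                dimnames = list(target = cells, source = cells))
  for (src in cells) {
    for (tgt in cells) {
      if (src == tgt) {
        rep <- impute_all_marks_cv(matrices[[tgt]], k = k, seed = seed,
                                   predictors = predictors)
        sim[tgt, src] <- rep$median_r
      } else {
        tr <- transfer_all_marks(matrices[[src]], matrices[[tgt]],
                                 predictors = predictors)
        sim[tgt, src] <- median(tr$r, na.rm = TRUE)
      }
    }
  }
  sim
}

#' Cluster cell lines by mutual predictive strength
#'
#' Average-linkage hierarchical clustering on the symmetrized distance
#' `d_ij = 1 - (r_ij + r_ji) / 2`.
#'
#' @param similarity square matrix from [predictive_similarity_matrix()].
#' @return list with `hclust` (the tree) and `leaf_order` (cell-line names in
#'   dendrogram order); a single cell line yields a trivial tree (`NULL`
#'   hclust, one leaf).
#' @export
cluster_cell_lines <- function(similarity) {
  stopifnot(nrow(similarity) == ncol(similarity))
  cells <- rownames(similarity)
  if (nrow(similarity) < 2L) {
    return(list(hclust = NULL, leaf_order = cells))
  }
  d <- 1 - (similarity + t(similarity)) / 2
  d <- pmax(d, 0)
  hc <- hclust(as.dist(d), method = "average")
  list(hclust = hc, leaf_order = cells[hc$order])
}
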