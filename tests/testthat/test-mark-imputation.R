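test_that("methylation predictor/response rules are enforced", {
  set.seed(31)
  vals <- matrix(runif(80), 20, 4)
  colnames(vals) <- c("meth.absolute", "meth.cpg_normalized", "H3K4me3",
                      "CTCF")
  em <- make_em(vals, mark_types = rep("epigenetic_mark", 4),
                meth_mark = "meth")
  # target = methylation: response is the normalized column, absolute dropped
  sel <- select_predictor_columns(em, "meth")
  expect_equal(sel$y_key, "meth.cpg_normalized")
  expect_setequal(sel$x_keys, c("H3K4me3", "CTCF"))
  # other target: normalized column dropped, absolute kept
  sel2 <- select_predictor_columns(em, "H3K4me3")
  expect_equal(sel2$y_key, "H3K4me3")
  expect_setequal(sel2$x_keys, c("meth.absolute", "CTCF"))
  # no methylation: everything else is a predictor
  em2 <- make_em(matrix(runif(60), 20, 3))
  sel3 <- select_predictor_columns(em2, colnames(em2$values)[1])
  expect_setequal(sel3$x_keys, colnames(em2$values)[-1])
  expect_error(select_predictor_columns(em2, "nope"), "not in matrix")
})

test_that("full-data models recover planted weights and reproduce predictions", {
  set.seed(32)
  n <- 1500
  b <- runif(n)
  a <- 0.8 * b + rnorm(n, sd = 0.05)
  c1 <- runif(n)
  em <- make_em(cbind(A = a, B = b, C = c1))
  wt <- fit_full_models(em)
  expect_equal(unname(wt$fits$A$weights["B"]), 0.8, tolerance = 0.03)
  expect_lt(abs(wt$fits$A$weights["C"]), 0.05)
  # weights reproduce in-sample predictions
  sel <- select_predictor_columns(em, "A")
  expect_equal(predict(wt$fits$A, sel$X), wt$fits$A$fitted, tolerance = 1e-12)
})

test_that("independent marks yield weights concentrated near zero", {
  set.seed(33)
  em <- make_em(matrix(runif(1000 * 6), 1000, 6))
  wt <- fit_full_models(em)
  ws <- unlist(lapply(wt$fits, `[[`, "weights"))
  expect_true(mean(abs(ws) < 0.1) > 0.9)
})

test_that("imputation report: planted-structure recovery and failure isolation", {
  w <- generate_world(world_config(n_genes = 800, marks = default_marks(8),
                                   seed = 31))
  em <- world_matrices(w)
  rep <- impute_all_marks_cv(em, seed = 31)
  expect_equal(nrow(rep$table), 8)
  expect_true(all(rep$table$p < 1e-10))
  expect_true(rep$median_r > 0.8)
  # a constant column becomes a per-mark failure, excluded from the median
  em_bad <- em
  em_bad$values[, 3] <- 0.5
  expect_warning(rep_bad <- impute_all_marks_cv(em_bad, seed = 31),
                 "failures")
  expect_equal(rep_bad$failures, em$marks$mark_name[3])
  expect_true(is.na(rep_bad$table$r[3]))
  expect_false(is.na(rep_bad$median_r))
})

test_that("pure-noise world has near-zero imputation medians", {
  set.seed(34)
  em <- make_em(matrix(runif(2000 * 5), 2000, 5))
  rep <- impute_all_marks_cv(em, seed = 34)
  expect_true(abs(rep$median_r) < 0.08)
})

test_that("model beats the best-correlated single mark; baseline is signed", {
  set.seed(35)
  n <- 1200
  z <- rnorm(n)
  vals <- cbind(A = z + rnorm(n, sd = 0.4),
                B = z + rnorm(n, sd = 0.4),
                C = -z + rnorm(n, sd = 0.4),
                D = rnorm(n))
  em <- make_em(vals)
  # baseline picks the max *signed* r: for target C that is D-ish/none of the
  # anti-correlated ones
  bl_a <- best_correlated_baseline(em, "A")
  expect_equal(bl_a$best_mark, "B")
  bl_c <- best_correlated_baseline(em, "C")
  expect_false(bl_c$best_mark %in% c("A", "B") && bl_c$r > 0.5)
  # exact copy: baseline r = 1
  em_dup <- make_em(cbind(A = z, B = z, C = rnorm(n)))
  expect_equal(best_correlated_baseline(em_dup, "A")$r, 1)
  # full model CV r dominates the baseline for every target
  rep <- impute_all_marks_cv(em, seed = 35)
  for (tg in c("A", "B", "C")) {
    expect_true(rep$table$r[rep$table$mark == tg] >=
                  best_correlated_baseline(em, tg)$r - 0.01)
  }
})

test_that("same-mark-other-cell baseline uses shared genes and errors on none", {
  w <- generate_world(transfer_world_config(seed = 33, n_genes = 400))
  ems <- lapply(setNames(w$cell_lines, w$cell_lines),
                function(cl) world_matrices(w, cl))
  expect_equal(same_mark_other_cell_baseline(ems[[1]], ems[[1]], "mark01"), 1)
  # shared-rule mark correlates across cell lines; cell-specific less
  r_shared <- same_mark_other_cell_baseline(ems[[1]], ems[[2]], "mark01")
  r_spec <- same_mark_other_cell_baseline(ems[[1]], ems[[2]], "mark15")
  expect_true(r_shared > r_spec)
  em_dis <- ems[[2]]
  rownames(em_dis$values) <- paste0("x", rownames(em_dis$values))
  expect_error(same_mark_other_cell_baseline(ems[[1]], em_dis, "mark01"),
               "shared genes")
})

test_that("mark-type overrepresentation: pooling, cutoff, frequencies", {
  set.seed(36)
  n <- 800
  # epigenetic marks share a factor; TFs are independent
  z <- rnorm(n)
  vals <- cbind(e1 = z + rnorm(n, 0.3), e2 = z + rnorm(n, sd = 0.3),
                e3 = z + rnorm(n, sd = 0.3),
                t1 = rnorm(n), t2 = rnorm(n), t3 = rnorm(n))
  em <- make_em(vals, mark_types = c(rep("epigenetic_mark", 3),
                                     rep("transcription_factor", 3)))
  wt <- fit_full_models(em)
  ov <- mark_type_overrepresentation(wt, q = 0.95)
  row_e <- ov[ov$target_type == "epigenetic_mark" &
                ov$input_type == "epigenetic_mark", ]
  expect_true(nrow(row_e) == 1 && row_e$freq > row_e$baseline_freq)
  # per-target-type frequencies sum to one (types with any weight above
  # the cutoff; empty types are flagged with an NA row)
  for (tt in unique(ov$target_type[ov$n_above > 0])) {
    expect_equal(sum(ov$freq[ov$target_type == tt]), 1, tolerance = 1e-12)
  }
  # quantile cutoff keeps ~5% of pooled weights
  n_above <- sum(unique(ov$n_above))
  n_pool <- 6 * 5
  expect_true(n_above <= ceiling(0.05 * n_pool) + 2)
  # single-type world: frequency 1 for that type
  em1 <- make_em(vals[, 1:3], mark_types = rep("coregulator", 3))
  ov1 <- mark_type_overrepresentation(fit_full_models(em1), q = 0.9)
  expect_true(all(ov1$input_type == "coregulator"))
  expect_true(all(ov1$freq == 1))
})
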