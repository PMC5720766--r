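test_that("the planted hub wins round one and the ranking agrees with truth", {
  w <- cached("hub_world_61", function()
    generate_world(hub_world_config(seed = 61, n_genes = 600, n_marks = 8)))
  em <- world_matrices(w)
  rk <- single_mark_ranking(em, seed = 61)
  expect_equal(rk$mark[1], "mark01")
  expect_equal(world_report(w)$expected_first_selection[["cellA"]], "mark01")
  # descending order
  expect_true(all(diff(rk$median_r) <= 0))
})

test_that("round one of greedy selection is identical to the single-mark ranking", {
  w <- cached("hub_world_61", function()
    generate_world(hub_world_config(seed = 61, n_genes = 600, n_marks = 8)))
  em <- world_matrices(w)
  rk <- single_mark_ranking(em, seed = 61)
  tr <- greedy_select(em, n_rounds = 1, k = 10, seed = 61)
  v1 <- tr$rounds[[1]]
  expect_equal(tr$selected[1], rk$mark[1])
  expect_equal(sort(v1$median_r), sort(rk$median_r))
  expect_identical(v1$median_r[match(rk$mark, v1$candidate)], rk$median_r)
})

test_that("greedy agrees with an exhaustive lm()-based oracle for two rounds", {
  # oracle: same folds, same scoring rule, but all models via lm() and an
  # explicit loop over candidates
  oracle_two_rounds <- function(em, seed) {
    vals <- em$values
    marks <- colnames(vals)
    folds <- make_folds(nrow(vals), 10, seed)
    cv_r <- function(x_cols, tg) {
      pred <- numeric(nrow(vals))
      df <- data.frame(y = vals[, tg], vals[, x_cols, drop = FALSE])
      for (f in unique(folds)) {
        fit <- lm(y ~ ., data = df[folds != f, , drop = FALSE])
        pred[folds == f] <- predict(fit, df[folds == f, , drop = FALSE])
      }
      cor(pred, vals[, tg])
    }
    score <- function(sel, cand) {
      targets <- setdiff(marks, c(sel, cand))
      median(vapply(targets, function(tg) cv_r(c(sel, cand), tg),
                    numeric(1)))
    }
    pick <- function(sel) {
      cands <- setdiff(marks, sel)
      v <- vapply(cands, function(cd) score(sel, cd), numeric(1))
      cands[order(-v, match(cands, marks))][1]
    }
    first <- pick(character(0))
    c(first, pick(first))
  }
  for (s in c(71, 72, 73)) {
    w <- generate_world(world_config(n_genes = 250,
                                     marks = default_marks(5),
                                     genes_per_chrom = 250, seed = s))
    em <- world_matrices(w)
    tr <- greedy_select(em, n_rounds = 2, k = 10, seed = s)
    expect_equal(tr$selected[1:2], oracle_two_rounds(em, s))
  }
})

test_that("one of two perfectly correlated informative twins is selected early, not both", {
  set.seed(62)
  n <- 800
  z1 <- rnorm(n); z2 <- rnorm(n)
  twin <- z1 + rnorm(n, sd = 0.15) # the dominant axis, measured twice
  vals <- cbind(
    twinA = twin, twinB = twin,      # identical information
    other = z2 + rnorm(n, sd = 0.2), # the secondary axis
    t1 = z1 + rnorm(n, sd = 0.6), t2 = z1 + rnorm(n, sd = 0.6),
    t3 = z1 + rnorm(n, sd = 0.6),
    t4 = z1 + 0.7 * z2 + rnorm(n, sd = 0.6)
  )
  em <- make_em(vals)
  tr <- suppressWarnings(greedy_select(em, n_rounds = 4, k = 10, seed = 62))
  # one twin is worth selecting immediately...
  expect_true(tr$selected[1] %in% c("twinA", "twinB"))
  # ...and its copy adds nothing, so it is not picked in the following rounds
  unpicked_twin <- setdiff(c("twinA", "twinB"), tr$selected[1])
  expect_false(unpicked_twin %in% tr$selected[2:4])
})

test_that("full selection yields a permutation; threshold curve is monotone", {
  w <- cached("hub_world_61", function()
    generate_world(hub_world_config(seed = 61, n_genes = 600, n_marks = 8)))
  em <- world_matrices(w)
  tr <- greedy_select(em, k = 10, seed = 61)
  expect_equal(sort(tr$ordervec), 1:8)
  expect_equal(sort(tr$selected), sort(unique(em$marks$mark_name)))
  # selected-set information content is essentially non-decreasing
  mr <- tr$median_r[!is.na(tr$median_r)]
  expect_true(all(diff(mr) > -0.02))
  curve <- threshold_curve(em, thresholds = c(0.05, 0.5, 0.8, 0.99),
                           k = 10, seed = 61)
  n_marks <- curve$n_marks
  expect_equal(n_marks[1], 1) # any informative mark clears a tiny threshold
  expect_true(all(diff(ifelse(is.na(n_marks), Inf, n_marks)) >= 0))
  expect_true(is.na(n_marks[4])) # unreachable beyond the noise ceiling
})

test_that("panel imputation: spanning panels recapture, orthogonal panels fail", {
  w <- cached("panel_world", function()
    generate_world(world_config(n_genes = 1000,
                                marks = default_marks(12, n_cell_specific = 4),
                                seed = 63)))
  em <- world_matrices(w)
  # shared marks 1..8 span the shared block; specific marks 9..12 live on an
  # orthogonal block
  panel_span <- paste0("mark0", 1:6)
  rep_all <- impute_all_marks_cv(em, seed = 63)
  rep_span <- subset_impute_cv(em, panel_span, seed = 63)
  shared_targets <- c("mark07", "mark08")
  r_span <- rep_span$table$r[rep_span$table$mark %in% shared_targets]
  r_all <- rep_all$table$r[rep_all$table$mark %in% shared_targets]
  expect_true(all(abs(r_span - r_all) < 0.05))
  # orthogonal targets are not predictable from the panel
  r_orth <- rep_span$table$r[grepl("mark09|mark1", rep_span$table$mark)]
  expect_true(median(r_orth) < 0.2)
  # predictors = all-but-one is exactly the all-mark imputation of that one
  one <- setdiff(unique(em$marks$mark_name), "mark03")
  rep_one <- subset_impute_cv(em, one, seed = 63)
  expect_equal(rep_one$table$r[rep_one$table$mark == "mark03"],
               rep_all$table$r[rep_all$table$mark == "mark03"],
               tolerance = 1e-12)
  expect_error(subset_impute_cv(em, unique(em$marks$mark_name), seed = 1),
               "no target")
})

test_that("panel transfer mirrors full transfer behavior on shared rules", {
  fx <- cached("transfer_world_ems", function() {
    w <- generate_world(transfer_world_config(seed = 41, n_genes = 800))
    list(world = w,
         ems = lapply(setNames(w$cell_lines, w$cell_lines),
                      function(cl) world_matrices(w, cl)))
  })
  ems <- fx$ems
  panel <- paste0("mark0", 1:6)
  tr_ab <- subset_transfer(ems$cellA, ems$cellB, panel)
  tr_aa <- subset_transfer(ems$cellA, ems$cellA, panel)
  intra <- subset_impute_cv(ems$cellA, panel, seed = 41)
  shared_t <- c("mark07", "mark08", "mark09", "mark10")
  m <- function(tab, mk) median(tab$r[tab$mark %in% mk])
  # same matrix on both sides: in-sample panel performance, slightly above CV
  expect_true(m(tr_aa, shared_t) >= m(intra$table, shared_t) - 0.01)
  # shared-rule targets transfer with little loss
  expect_true(m(intra$table, shared_t) - m(tr_ab, shared_t) < 0.05)
  # cell-specific targets do not transfer even from a shared panel
  spec_t <- paste0("mark1", 1:5)
  expect_true(m(intra$table, spec_t) - m(tr_ab, spec_t) > 0.2 ||
                m(tr_ab, spec_t) < 0.3)
})
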