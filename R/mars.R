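#' @name mars
#' @title Additive hinge-spline (MARS) regression
#'
#' @description
#' Additive multivariate adaptive regression splines: the model is an
#' intercept plus a sum of univariate hinge terms `max(0, x - c)` and
#' `max(0, c - x)` — degree 1, no interactions. The forward pass greedily adds
#' reflected hinge pairs at candidate knots (observed predictor values)
#' maximizing the residual-sum-of-squares reduction; the backward pass prunes
#' terms by generalized cross-validation,
#' `GCV = (RSS / n) / (1 - C(m) / n)^2` with
#' `C(m) = m + penalty * (m - 1) / 2` and `m` the number of terms including
#' the intercept. Coefficients are refit by OLS on the surviving basis.
NULL

# Candidate knots for one column: all distinct observed values, thinned to a
# quantile-spaced subset of at most max_knots when there are more (keeps the
# forward pass O(n * max_knots) per column).
candidate_knots <- function(x, max_knots) {
  ux <- sort(unique(x))
  if (length(ux) > max_knots) {
    ux <- ux[unique(round(seq(1, length(ux), length.out = max_knots)))]
  }
  ux
}

mars_cost <- function(m, penalty) m + penalty * (m - 1) / 2

mars_gcv <- function(rss, n, m, penalty) {
  c_m <- mars_cost(m, penalty)
  if (c_m >= n) return(Inf)
  (rss / n) / (1 - c_m / n)^2
}

# Evaluate the hinge basis of a term table on X (matched by column name).
mars_basis <- function(terms, X) {
  if (nrow(terms) == 0L) {
    return(matrix(numeric(0), nrow = nrow(X), ncol = 0L))
  }
  miss <- setdiff(unique(terms$col), colnames(X))
  if (length(miss) > 0L) {
    stop("prediction columns missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  B <- matrix(0, nrow = nrow(X), ncol = nrow(terms))
  for (i in seq_len(nrow(terms))) {
    x <- X[, terms$col[i]]
    B[, i] <- if (terms$dir[i] > 0) pmax(0, x - terms$knot[i]) else
      pmax(0, terms$knot[i] - x)
  }
  B
}

#' Fit an additive MARS model
#'
#' @param X predictor matrix (column names are kept in the term table; unnamed
#'   columns are labeled `x1..xp`).
#' @param y response vector.
#' @param max_terms maximum number of hinge terms added by the forward pass;
#'   default `min(200, max(20, 2 * ncol(X)))`.
#' @param gcv_penalty per-term GCV penalty, default 2 (the additive-model
#'   convention).
#' @param max_knots per-column cap on candidate knots, default 256; columns
#'   with fewer distinct values use all of them.
#' @param thresh forward-pass stop threshold on the relative R-squared
#'   improvement of the best candidate pair, default 0.001.
#' @return a `mars_fit`: list with `intercept`, `terms` (data.frame `col`,
#'   `dir`, `knot`, `coef`), `gcv`, `n_obs`, `rss`.
#' @export
fit_mars <- function(X, y, max_terms = NULL, gcv_penalty = 2,
                     max_knots = 256L, thresh = 0.001) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(max_terms)) max_terms <- min(200L, max(20L, 2L * ncol(X)))
  stopifnot(max_terms >= 1)
  empty_terms <- data.frame(col = character(), dir = integer(),
                            knot = numeric(), coef = numeric(),
                            stringsAsFactors = FALSE)
  intercept_fit <- function() {
    rss0 <- sum((y - mean(y))^2)
    structure(list(intercept = mean(y), terms = empty_terms,
                   gcv = mars_gcv(rss0, n, 1L, gcv_penalty),
                   n_obs = n, rss = rss0),
              class = "mars_fit")
  }
  if (n < 4L || ncol(X) == 0L || sd(y) == 0) return(intercept_fit())

  sst <- sum((y - mean(y))^2)
  # ---- forward pass ---------------------------------------------------
  # Q: orthonormal basis of the current design (starts at the intercept).
  Q <- matrix(1 / sqrt(n), n, 1L)
  r <- y - mean(y)
  terms <- list()       # list of c(col_index, dir, knot)
  knots_by_col <- lapply(seq_len(ncol(X)),
                         function(j) candidate_knots(X[, j], max_knots))
  eps <- .Machine$double.eps
  while (length(terms) < max_terms) {
    best <- list(red = 0, j = NA_integer_, knot = NA_real_)
    for (j in seq_len(ncol(X))) {
      kn <- knots_by_col[[j]]
      if (length(kn) == 0L) next
      D <- outer(X[, j], kn, "-")
      Hp <- pmax(D, 0)
      Hm <- pmax(-D, 0)
      # project out the current basis
      Hp <- Hp - Q %*% crossprod(Q, Hp)
      Hm <- Hm - Q %*% crossprod(Q, Hm)
      aa <- colSums(Hp * Hp); bb <- colSums(Hm * Hm)
      ab <- colSums(Hp * Hm)
      ar <- colSums(Hp * r);  br <- colSums(Hm * r)
      det <- aa * bb - ab * ab
      ok2 <- det > eps * pmax(aa * bb, 1e-300)
      red2 <- ifelse(ok2,
                     (bb * ar^2 - 2 * ab * ar * br + aa * br^2) / det, -Inf)
      red1 <- pmax(ifelse(aa > eps * n, ar^2 / aa, -Inf),
                   ifelse(bb > eps * n, br^2 / bb, -Inf))
      red <- pmax(red2, red1)
      i_best <- which.max(red)  # ties: lowest knot value (kn is sorted)
      if (length(i_best) == 1L && red[i_best] > best$red) {
        best <- list(red = red[i_best], j = j, knot = kn[i_best])
      }
    }
    if (is.na(best$j) || best$red / sst < thresh) break
    # add the reflected pair, dropping directions that are (numerically)
    # inside the current span
    for (dir in c(1L, -1L)) {
      x <- X[, best$j]
      h <- if (dir > 0) pmax(0, x - best$knot) else pmax(0, best$knot - x)
      ho <- as.numeric(h - Q %*% crossprod(Q, h))
      nrm <- sqrt(sum(ho^2))
      if (nrm > sqrt(eps) * max(sqrt(sum(h^2)), 1)) {
        qnew <- ho / nrm
        Q <- cbind(Q, qnew)
        r <- r - qnew * sum(qnew * r)
        terms[[length(terms) + 1L]] <- list(j = best$j, dir = dir,
                                            knot = best$knot)
        if (length(terms) >= max_terms) break
      }
    }
  }
  if (length(terms) == 0L) return(intercept_fit())
  term_tab <- data.frame(
    col = colnames(X)[vapply(terms, `[[`, 1L, "j")],
    dir = vapply(terms, `[[`, 1L, "dir"),
    knot = vapply(terms, function(t) t$knot, numeric(1)),
    stringsAsFactors = FALSE
  )

  # ---- backward pass: greedy GCV pruning ------------------------------
  B <- mars_basis(term_tab, X)
  rss_of <- function(keep) {
    Bk <- cbind(1, B[, keep, drop = FALSE])
    z <- .lm.fit(Bk, y)
    sum(z$residuals^2)
  }
  keep <- seq_len(nrow(term_tab))
  best_keep <- keep
  best_gcv <- mars_gcv(rss_of(keep), n, length(keep) + 1L, gcv_penalty)
  while (length(keep) > 0L) {
    rss_drop <- vapply(seq_along(keep),
                       function(i) rss_of(keep[-i]), numeric(1))
    i_drop <- which.min(rss_drop)
    keep <- keep[-i_drop]
    g <- mars_gcv(rss_drop[i_drop], n, length(keep) + 1L, gcv_penalty)
    if (g < best_gcv) {
      best_gcv <- g
      best_keep <- keep
    }
  }
  term_tab <- term_tab[best_keep, , drop = FALSE]
  rownames(term_tab) <- NULL

  # ---- final OLS refit ------------------------------------------------
  B <- mars_basis(term_tab, X)
  z <- .lm.fit(cbind(1, B), y)
  beta <- z$coefficients
  rss <- sum(z$residuals^2)
  term_tab$coef <- if (nrow(term_tab) > 0L) beta[-1L] else numeric(0)
  structure(
    list(intercept = beta[1L], terms = term_tab,
         gcv = mars_gcv(rss, n, nrow(term_tab) + 1L, gcv_penalty),
         n_obs = n, rss = rss),
    class = "mars_fit"
  )
}

#' @export
print.mars_fit <- function(x, ...) {
  cat("mars_fit:", nrow(x$terms), "hinge terms, gcv =", fmt_num(x$gcv),
      ", rss =", fmt_num(x$rss), "\n")
  invisible(x)
}

#' Predict from a fitted MARS model
#'
#' @param object a `mars_fit`.
#' @param X matrix containing (at least) the columns named in the term table.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.mars_fit <- function(object, X, ...) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  B <- mars_basis(object$terms, X)
  as.numeric(object$intercept +
               if (ncol(B) > 0L) B %*% object$terms$coef else 0)
}
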