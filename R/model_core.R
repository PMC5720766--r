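#' @name model_core
#' @title Least squares, cross-validation, correlation testing, BIC
#'
#' @description
#' The numeric engine shared by every analysis stage: ordinary least squares
#' with an intercept (QR, with a minimum-norm SVD fallback for rank-deficient
#' designs), k-fold cross-validation with seeded, shareable fold assignments,
#' the Pearson correlation t-test, and the Gaussian-likelihood BIC.
NULL

#' Fit ordinary least squares with intercept
#'
#' Minimizes `sum((y - b - X a)^2)` via QR. Rank-deficient designs (e.g. more
#' predictor columns than genes, or duplicated columns) are solved with the
#' minimum-norm pseudoinverse solution and a warning; predictions are
#' unchanged within the column span.
#'
#' @param X numeric matrix of predictors (may have zero columns).
#' @param y numeric response vector, `length(y) == nrow(X)`.
#' @return a `linear_fit`: list with `intercept`, `weights` (named by
#'   predictor column), `n_obs`, `rss`, `fitted`, `rank_deficient`.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  n <- length(y)
  if (n == 0L || nrow(X) != n) stop("empty or mismatched input", call. = FALSE)
  if (is.null(colnames(X)) && ncol(X) > 0L) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  Xa <- cbind(`(Intercept)` = 1, X)
  qr_d <- qr(Xa)
  deficient <- qr_d$rank < ncol(Xa)
  if (!deficient) {
    beta <- qr.coef(qr_d, y)
    fitted <- as.numeric(Xa %*% beta)
  } else {
    warning("rank-deficient design: minimum-norm least-squares solution used")
    sv <- svd(Xa)
    tol <- max(dim(Xa)) * .Machine$double.eps * sv$d[1L]
    pos <- sv$d > tol
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    beta <- setNames(as.numeric(beta), colnames(Xa))
    fitted <- as.numeric(Xa %*% beta)
  }
  structure(
    list(intercept = unname(beta[1L]),
         weights = beta[-1L],
         n_obs = n,
         rss = sum((y - fitted)^2),
         fitted = fitted,
         rank_deficient = deficient),
    class = "linear_fit"
  )
}

#' @export
print.linear_fit <- function(x, ...) {
  cat("linear_fit:", length(x$weights), "weights, n =", x$n_obs,
      ", rss =", fmt_num(x$rss), "\n")
  invisible(x)
}

#' Predict from a fitted linear model
#'
#' @param object a `linear_fit`.
#' @param X matrix whose columns match the fitted predictors (matched by
#'   name when both are named).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.linear_fit <- function(object, X, ...) {
  X <- as.matrix(X)
  w <- object$weights
  if (length(w) == 0L) return(rep(object$intercept, nrow(X)))
  if (!is.null(colnames(X)) && !is.null(names(w))) {
    if (!all(names(w) %in% colnames(X))) {
      stop("prediction columns do not match fitted predictors", call. = FALSE)
    }
    X <- X[, names(w), drop = FALSE]
  } else if (ncol(X) != length(w)) {
    stop("prediction columns do not match fitted predictors", call. = FALSE)
  }
  as.numeric(object$intercept + X %*% w)
}

#' Pearson correlation with t-test p-value
#'
#' `r` is the sample Pearson correlation; the two-sided p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` against Student's t with `n - 2`
#' degrees of freedom. A constant input vector raises a condition of class
#' `epicompress_constant_input`, distinct from numeric failures.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @return list with elements `r` and `p`.
#' @export
pearson_with_pvalue <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 3L) stop("need equal-length vectors, n >= 3",
                                     call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop(structure(
      class = c("epicompress_constant_input", "error", "condition"),
      list(message = "correlation undefined for constant input",
           call = sys.call(-1))
    ))
  }
  r <- cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t_stat), df = n - 2)
  }
  list(r = r, p = p)
}

#' Seeded fold assignment for k-fold cross-validation
#'
#' Shuffles observation indices under `seed` and splits the permutation into
#' `k` contiguous, near-equal blocks. Shared across targets of one matrix so
#' per-mark performances are comparable.
#'
#' @param n number of observations.
#' @param k number of folds (`k <= n`).
#' @param seed integer seed.
#' @return integer vector of fold labels in `1..k`, one per observation.
#' @export
make_folds <- function(n, k = 10L, seed = 1L) {
  if (k > n) stop("k must not exceed the number of observations",
                  call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  sizes <- diff(floor(seq(0, n, length.out = k + 1)))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), times = sizes)
  fold
}

# Fast per-fold OLS cross-validated predictions. Xa must include whatever
# columns the model uses (no intercept column; added here). Falls back to the
# pseudoinverse path only when the training design is rank deficient.
cv_predict_ols <- function(X, y, fold) {
  X <- as.matrix(X)
  n <- length(y)
  pred <- numeric(n)
  Xa <- cbind(1, X)
  for (f in sort(unique(fold))) {
    test <- fold == f
    fit <- tryCatch(
      {
        z <- .lm.fit(Xa[!test, , drop = FALSE], y[!test])
        if (z$rank < ncol(Xa)) stop("deficient") else z
      },
      error = function(e) NULL
    )
    if (is.null(fit)) {
      lf <- suppressWarnings(fit_ols(X[!test, , drop = FALSE], y[!test]))
      pred[test] <- predict(lf, X[test, , drop = FALSE])
    } else {
      pred[test] <- as.numeric(Xa[test, , drop = FALSE] %*% fit$coefficients)
    }
  }
  pred
}

#' k-fold cross-validation for linear or MARS models
#'
#' Observations are partitioned into `k` near-equal folds (seeded shuffle, or
#' a caller-supplied shared assignment); each fold is predicted by a model fit
#' on the remaining folds; Pearson r and p are computed on the concatenated
#' out-of-fold predictions against the measured values.
#'
#' @param X predictor matrix.
#' @param y response vector.
#' @param k number of folds, default 10.
#' @param model `"ols"` or `"mars"`.
#' @param seed integer seed for the fold shuffle (ignored when `folds` given).
#' @param folds optional precomputed fold assignment from [make_folds()].
#' @param ... further arguments to [fit_mars()] when `model = "mars"`.
#' @return a `cv_result`: list with `predictions` (input order), `pearson_r`,
#'   `p_value`, `fold_assignment`, `seed`, `model`.
#' @export
kfold_cv <- function(X, y, k = 10L, model = c("ols", "mars"), seed = 1L,
                     folds = NULL, ...) {
  model <- match.arg(model)
  X <- as.matrix(X)
  n <- length(y)
  if (is.null(folds)) folds <- make_folds(n, k, seed)
  stopifnot(length(folds) == n)
  if (model == "ols") {
    pred <- cv_predict_ols(X, y, folds)
  } else {
    pred <- numeric(n)
    for (f in sort(unique(folds))) {
      test <- folds == f
      fit <- fit_mars(X[!test, , drop = FALSE], y[!test], ...)
      pred[test] <- predict(fit, X[test, , drop = FALSE])
    }
  }
  ct <- pearson_with_pvalue(pred, y)
  structure(
    list(predictions = pred, pearson_r = ct$r, p_value = ct$p,
         fold_assignment = folds, seed = seed, model = model),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result (", x$model, "): r =", fmt_num(x$pearson_r),
      ", p =", fmt_num(x$p_value), "\n")
  invisible(x)
}

#' Bayesian information criterion of a linear fit
#'
#' Gaussian-likelihood convention: `BIC = n * ln(rss / n) + (p + 2) * ln(n)`
#' where `p` is the number of weights and the `+2` counts the intercept and
#' the noise variance.
#'
#' @param fit a `linear_fit`.
#' @return BIC value; `-Inf` with a warning when `rss == 0`.
#' @export
bic_linear <- function(fit) {
  n <- fit$n_obs
  if (fit$rss <= 0) {
    warning("zero residual sum of squares: BIC is -Inf")
    return(-Inf)
  }
  p <- length(fit$weights)
  n * log(fit$rss / n) + (p + 2) * log(n)
}
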