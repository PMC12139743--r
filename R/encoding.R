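#' Regularization grid
#'
#' Twenty ridge penalties log-spaced between 10 and 10000.
#'
#' @param n number of grid values.
#' @param range grid endpoints.
#' @return Ascending numeric vector.
#' @export
ridge_lambda_grid <- function(n = 20, range = c(10, 10000)) {
  if (n < 1) stop_invalid("grid must be non-empty")
  10^seq(log10(range[1]), log10(range[2]), length.out = n)
}

#' Closed-form ridge regression
#'
#' Solves `argmin ||y - Xw||^2 + lambda ||w||^2` via the normal equations
#' `(X'X + lambda I) w = X'y`, factorized by Cholesky. The intercept is
#' handled by centering the columns of `X` and `y`; the returned weights
#' exclude it.
#'
#' @param X design matrix.
#' @param y response vector.
#' @param lambda ridge penalty (> 0; `lambda = 0` gives OLS and is allowed
#'   when `X'X` is invertible).
#' @param center center `X` columns and `y` before solving (default `TRUE`).
#' @return List of class `ridge_fit`: `weights`, `x_center`, `y_center`,
#'   `lambda`.
#' @export
ridge_fit <- function(X, y, lambda, center = TRUE) {
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop_invalid("X and y must be finite")
  if (lambda < 0) stop_invalid("lambda must be >= 0")
  if (nrow(X) != length(y)) stop_invalid("X rows must match length(y)")
  xc <- if (center) colMeans(X) else rep(0, ncol(X))
  yc <- if (center) mean(y) else 0
  Xc <- sweep(X, 2L, xc)
  A <- crossprod(Xc)
  diag(A) <- diag(A) + lambda
  b <- crossprod(Xc, y - yc)
  R <- chol(A)
  w <- backsolve(R, backsolve(R, b, transpose = TRUE))
  out <- list(weights = as.numeric(w), x_center = xc, y_center = yc,
              lambda = lambda)
  class(out) <- "ridge_fit"
  out
}

#' Predict from a ridge fit
#' @param object a `ridge_fit`.
#' @param newdata design matrix.
#' @param ... unused.
#' @return Predicted response vector.
#' @export
predict.ridge_fit <- function(object, newdata, ...) {
  as.numeric(sweep(newdata, 2L, object$x_center) %*% object$weights) +
    object$y_center
}

# Round-robin assignment of blocks (in schedule order) to k contiguous
# cross-validation folds; all rows of a block — across all concatenated
# contacts — share its fold.
fold_of_row <- function(block_of_row, k_folds) {
  blocks <- unique(block_of_row)
  if (length(blocks) < k_folds)
    stop_invalid("need at least ", k_folds, " blocks for ", k_folds,
                 "-fold cross-validation, got ", length(blocks))
  fold_of_block <- rep_len(seq_len(k_folds), length(blocks))
  fold_of_block[match(block_of_row, blocks)]
}

# Per-fold sufficient statistics via per-block Gram matrices: fold training
# statistics are totals minus the held-out blocks', and centering enters
# through the rank-one correction A - n mu mu', b - n mu ybar.
fold_sufficient_stats <- function(X, y, fold, k_folds) {
  p <- ncol(X)
  tot_XtX <- crossprod(X)
  tot_Xty <- crossprod(X, y)
  tot_xs <- colSums(X)
  tot_ys <- sum(y)
  tot_n <- nrow(X)
  lapply(seq_len(k_folds), function(f) {
    te <- fold == f
    Xte <- X[te, , drop = FALSE]
    yte <- y[te]
    n <- tot_n - nrow(Xte)
    xs <- tot_xs - colSums(Xte)
    ys <- tot_ys - sum(yte)
    mu <- xs / n
    ybar <- ys / n
    A <- (tot_XtX - crossprod(Xte)) - n * tcrossprod(mu)
    b <- as.numeric(tot_Xty - crossprod(Xte, yte)) - n * mu * ybar
    list(A = A, b = b, mu = mu, ybar = ybar, Xte = Xte, yte = yte)
  })
}

fold_r <- function(yte, pred) {
  if (stats::sd(yte) == 0 || stats::sd(pred) == 0) {
    warning("zero-variance held-out data; fold r recorded as 0")
    return(0)
  }
  stats::cor(yte, pred)
}

#' Cross-validated ridge evaluation
#'
#' Fits the ridge model with 5-fold cross-validation at a fixed penalty.
#' Folds are contiguous block groups (blocks round-robined into folds), so
#' temporally autocorrelated samples never straddle a train/test split. Each
#' fold's accuracy is the Pearson correlation between the measured and
#' predicted held-out response; the model's prediction accuracy is the
#' arithmetic mean over folds.
#'
#' @param X lagged design matrix (or output of [concatenate_contacts()], in
#'   which case `y` and `block_of_row` are taken from it).
#' @param y response vector.
#' @param lambda ridge penalty.
#' @param block_of_row block id per row (defaults to `attr(X, "block_of_row")`).
#' @param k_folds number of folds (default 5).
#' @param keep_weights retain per-fold weight vectors (default `TRUE`).
#' @return List of class `encoding_result`: `fold_r`, `mean_r`,
#'   `lambda_used`, `fold_weights` (`[k x p]`), `column_labels`.
#' @export
cv_evaluate <- function(X, y = NULL, lambda, block_of_row = NULL, k_folds = 5,
                        keep_weights = TRUE) {
  if (is.list(X) && !is.null(X$X)) {
    if (is.null(y)) y <- X$y
    if (is.null(block_of_row)) block_of_row <- X$block_of_row
    X <- X$X
  }
  if (is.null(block_of_row)) block_of_row <- attr(X, "block_of_row")
  if (is.null(block_of_row)) stop_invalid("block_of_row is required")
  labels <- attr(X, "column_labels")
  fold <- fold_of_row(block_of_row, k_folds)
  stats_f <- fold_sufficient_stats(X, y, fold, k_folds)
  p <- ncol(X)
  r <- numeric(k_folds)
  W <- if (keep_weights) matrix(NA_real_, k_folds, p) else NULL
  for (f in seq_len(k_folds)) {
    s <- stats_f[[f]]
    A <- s$A
    diag(A) <- diag(A) + lambda
    R <- chol(A)
    w <- backsolve(R, backsolve(R, s$b, transpose = TRUE))
    pred <- as.numeric(sweep(s$Xte, 2L, s$mu) %*% w) + s$ybar
    r[f] <- fold_r(s$yte, pred)
    if (keep_weights) W[f, ] <- w
  }
  out <- list(fold_r = r, mean_r = mean(r), lambda_used = lambda,
              fold_weights = W, column_labels = labels, k_folds = k_folds)
  class(out) <- "encoding_result"
  out
}

#' Cross-validated accuracy over a penalty grid
#'
#' Same fold scheme as [cv_evaluate()], but solves all grid penalties from
#' one eigendecomposition of each fold's centered Gram matrix, making grid
#' searches cheap.
#'
#' @inheritParams cv_evaluate
#' @param lambdas penalty grid.
#' @return Numeric vector of mean cross-validated r, one per penalty.
#' @export
cv_grid <- function(X, y = NULL, lambdas, block_of_row = NULL, k_folds = 5) {
  if (is.list(X) && !is.null(X$X)) {
    if (is.null(y)) y <- X$y
    if (is.null(block_of_row)) block_of_row <- X$block_of_row
    X <- X$X
  }
  if (is.null(block_of_row)) block_of_row <- attr(X, "block_of_row")
  fold <- fold_of_row(block_of_row, k_folds)
  stats_f <- fold_sufficient_stats(X, y, fold, k_folds)
  acc <- matrix(NA_real_, k_folds, length(lambdas))
  for (f in seq_len(k_folds)) {
    s <- stats_f[[f]]
    eg <- eigen(s$A, symmetric = TRUE)
    d <- pmax(eg$values, 0)
    Ub <- crossprod(eg$vectors, s$b)
    XteV <- sweep(s$Xte, 2L, s$mu) %*% eg$vectors
    for (j in seq_along(lambdas)) {
      pred <- as.numeric(XteV %*% (Ub / (d + lambdas[j]))) + s$ybar
      acc[f, j] <- suppressWarnings(fold_r(s$yte, pred))
    }
  }
  colMeans(acc)
}

#' Select a single global ridge penalty across datasets
#'
#' To keep weight scales comparable across participants, areas and
#' conditions, one penalty is used everywhere: for each grid value the mean
#' cross-validated accuracy is averaged (unweighted) over all datasets, and
#' the maximizing penalty is returned (ties broken toward the smaller
#' penalty).
#'
#' @param datasets list of datasets, each a list with `X`, `y` and
#'   `block_of_row` (e.g. outputs of [concatenate_contacts()]).
#' @param lambdas penalty grid (default [ridge_lambda_grid()]).
#' @param k_folds folds (default 5).
#' @return List: `lambda` (selected value), `grid`, `mean_r_by_lambda`.
#' @export
select_global_lambda <- function(datasets, lambdas = ridge_lambda_grid(),
                                 k_folds = 5) {
  if (length(datasets) < 1L) stop_invalid("need at least one dataset")
  if (length(lambdas) < 1L) stop_invalid("penalty grid must be non-empty")
  acc <- vapply(datasets, function(d)
    cv_grid(d$X, d$y, lambdas, block_of_row = d$block_of_row,
            k_folds = k_folds),
    numeric(length(lambdas)))
  mean_acc <- if (is.matrix(acc)) rowMeans(acc) else acc
  list(lambda = lambdas[which.max(mean_acc)], grid = lambdas,
       mean_r_by_lambda = mean_acc)
}
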