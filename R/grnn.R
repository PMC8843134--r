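#' Fit a generalized regression neural network
#'
#' A GRNN is a memory-based kernel regressor: the stored training
#' exemplars plus a single isotropic width parameter sigma. Its prediction
#' at a query x is the Gaussian-kernel weighted mean of the training
#' targets,
#'
#'   yhat(x) = sum_i y_i exp(-D_i^2 / (2 sigma^2)) /
#'             sum_i   exp(-D_i^2 / (2 sigma^2)),
#'
#' with D_i^2 the squared Euclidean distance from x to exemplar x_i. Since
#' the weights are a convex combination, predictions always lie within
#' `[min(y), max(y)]`; sigma -> 0 interpolates the exemplars and
#' sigma -> Inf predicts their mean.
#'
#' @param x numeric matrix of training inputs (rows = exemplars), on a
#'   common scale (see [fit_minmax()]).
#' @param y numeric vector of training targets.
#' @param sigma kernel width (> 0) in input-scale units.
#' @return an object of class `grnn`.
#' @export
grnn_fit <- function(x, y, sigma) {
  x <- as.matrix(x)
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) ||
      sigma <= 0) {
    stop("sigma must be a single positive number", call. = FALSE)
  }
  if (nrow(x) != length(y) || nrow(x) < 1) {
    stop("need equally many inputs and targets (>= 1)", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("training data must be finite", call. = FALSE)
  structure(list(x = x, y = as.numeric(y), sigma = sigma), class = "grnn")
}

#' @export
print.grnn <- function(x, ...) {
  cat("GRNN:", nrow(x$x), "exemplars,", ncol(x$x), "features, sigma =",
      signif(x$sigma, 4), "\n")
  invisible(x)
}

#' Predict from a fitted GRNN
#'
#' Evaluation is numerically stabilized by subtracting the largest exponent
#' before exponentiation, so the nearest exemplar always carries weight
#' `exp(0) = 1` and the weight sum can never underflow to zero.
#'
#' @param model a `grnn` from [grnn_fit()].
#' @param newdata numeric matrix of query rows (or a single row vector).
#' @return numeric vector of predictions, one per query row.
#' @export
grnn_predict <- function(model, newdata) {
  q <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(q) != ncol(model$x)) stop("feature dimension mismatch", call. = FALSE)
  if (anyNA(q) || any(!is.finite(q))) stop("queries must be finite", call. = FALSE)
  # squared distances: ||q||^2 + ||x||^2 - 2 q x'
  d2 <- outer(rowSums(q^2), rowSums(model$x^2), "+") - 2 * tcrossprod(q, model$x)
  d2[d2 < 0] <- 0
  e <- -d2 / (2 * model$sigma^2)
  e <- e - apply(e, 1, max)
  w <- exp(e)
  drop(w %*% model$y) / rowSums(w)
}

#' Select the GRNN width by cross-validated RMSE
#'
#' Evaluates each candidate sigma by k-fold cross-validation on a shared
#' fold assignment and returns the candidate with the lowest held-out
#' RMSE; ties (within `1e-12`) are broken toward the largest sigma, i.e.
#' the smoother model.
#'
#' @param x,y training inputs and targets.
#' @param folds integer fold assignment from [kfold_split()].
#' @param grid candidate sigmas (> 0); default 20 log-spaced values in
#'   `[0.01, 2]`, spanning interpolation to heavy smoothing on unit-scaled
#'   features.
#' @return list with `sigma` (the selected value) and `profile`
#'   (data frame of sigma vs cross-validated RMSE).
#' @export
select_sigma <- function(x, y, folds, grid = default_sigma_grid()) {
  if (length(grid) == 0) stop("sigma grid is empty", call. = FALSE)
  if (any(grid <= 0)) stop("sigma candidates must be > 0", call. = FALSE)
  x <- as.matrix(x)
  rmse <- vapply(grid, function(s) {
    err <- numeric(0)
    for (f in sort(unique(folds))) {
      tr <- folds != f
      m <- grnn_fit(x[tr, , drop = FALSE], y[tr], s)
      err <- c(err, grnn_predict(m, x[!tr, , drop = FALSE]) - y[!tr])
    }
    sqrt(mean(err^2))
  }, numeric(1))
  best <- max(which(rmse <= min(rmse) + 1e-12))
  list(sigma = grid[best],
       profile = data.frame(sigma = grid, cv_rmse = rmse))
}

#' @rdname select_sigma
#' @export
default_sigma_grid <- function() exp(seq(log(0.01), log(2), length.out = 20))
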