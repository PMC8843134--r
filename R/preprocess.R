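#' Box-Cox power transform fitted by maximum likelihood
#'
#' Fits the transform lambda by profiling the normal log-likelihood over
#' lambda in `[-5, 5]`: the transformed values are `(y^l - 1)/l` for
#' `l != 0` and `log(y)` at `l = 0`, with the Jacobian term
#' `(l - 1) * sum(log y)` included in the likelihood. Values must be
#' strictly positive; a non-positive input is shifted up front by
#' `1 - min(y)` and the shift is returned so the transform can be inverted.
#'
#' @param y numeric vector of responses.
#' @param lambda optional fixed lambda; when `NULL` (default) the MLE is
#'   searched on `interval`.
#' @param interval search interval for lambda.
#' @return list with `transformed`, `lambda`, `shift`.
#' @export
boxcox_fit_transform <- function(y, lambda = NULL, interval = c(-5, 5)) {
  if (length(y) == 0 || any(!is.finite(y))) {
    stop("Box-Cox input must be non-empty and finite", call. = FALSE)
  }
  shift <- if (min(y) <= 0) 1 - min(y) else 0
  ys <- y + shift
  if (min(ys) <= 0) stop("values not positive after shift", call. = FALSE)
  if (is.null(lambda)) {
    slog <- sum(log(ys))
    n <- length(ys)
    prof <- function(l) {
      z <- boxcox_apply(ys, l)
      v <- stats::var(z) * (n - 1) / n
      if (!is.finite(v) || v <= 0) return(-Inf)
      -n / 2 * log(v) + (l - 1) * slog
    }
    lambda <- stats::optimize(prof, interval = interval, maximum = TRUE,
                              tol = 1e-6)$maximum
  }
  list(transformed = boxcox_apply(ys, lambda), lambda = lambda, shift = shift)
}

boxcox_apply <- function(y, lambda) {
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

#' @rdname boxcox_fit_transform
#' @param z transformed values to map back to the original scale.
#' @export
boxcox_inverse <- function(z, lambda, shift = 0) {
  y <- if (abs(lambda) < 1e-12) exp(z) else {
    base <- lambda * z + 1
    # clamp: inverse only defined where lambda*z + 1 > 0; predictions that
    # stray below are pinned to the transform's domain edge
    base[base < 0] <- 0
    base^(1 / lambda)
  }
  y - shift
}

#' Flag multivariate outliers by PCA score distance
#'
#' Projects rows onto the principal components explaining at least
#' `var_explained` of the variance and computes each row's score distance
#' (Mahalanobis distance in that score space,
#' `sqrt(sum((score_j / sdev_j)^2))`). The squared score distance of a
#' Gaussian row follows a chi-squared distribution with as many degrees of
#' freedom as retained components, so the `threshold_sd` argument (in
#' familiar one-dimensional standard-deviation units) is calibrated through
#' that distribution: a row is flagged when its distance exceeds the
#' chi-squared quantile whose tail probability matches `|Z| > threshold_sd`
#' for a standard normal. Flagging is report-only; removal is the caller's
#' decision.
#'
#' @param x numeric matrix or data frame (>= 3 rows, no missing values).
#' @param threshold_sd flag threshold in score-space standard deviations.
#' @param var_explained minimum cumulative variance of the retained
#'   component space.
#' @return integer vector of flagged row indices (possibly empty).
#' @export
pca_outlier_flags <- function(x, threshold_sd = 3, var_explained = 0.95) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 rows", call. = FALSE)
  if (anyNA(x)) stop("missing values not supported", call. = FALSE)
  keep <- apply(x, 2, stats::sd) > 0
  x <- x[, keep, drop = FALSE]
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  usable <- p$sdev > 1e-10
  if (sum(usable) < 2) {
    warning("fewer than 2 usable principal components; no outliers flagged")
    return(integer(0))
  }
  cum <- cumsum(p$sdev[usable]^2) / sum(p$sdev[usable]^2)
  q <- max(2L, which(cum >= var_explained)[1])
  scores <- p$x[, seq_len(q), drop = FALSE]
  d2 <- rowSums(sweep(scores, 2, p$sdev[seq_len(q)], "/")^2)
  cutoff <- stats::qchisq(1 - 2 * stats::pnorm(-threshold_sd), df = q)
  which(d2 > cutoff)
}

#' Assign records to k cross-validation folds
#'
#' Random permutation split into `k` folds whose sizes differ by at most
#' one; deterministic given `seed`.
#'
#' @param n number of records.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return integer vector of length `n` with fold ids in `1..k`.
#' @export
kfold_split <- function(n, k = 5, seed) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 2 || n < k) stop("need n >= k >= 2", call. = FALSE)
  old <- local_rng_seed(seed)
  on.exit(restore_rng(old))
  folds <- rep(seq_len(k), length.out = n)
  folds[sample.int(n)]
}

#' Min-max feature scaling fitted on training rows
#'
#' @param x numeric matrix of features (training rows).
#' @return a `minmax_scaler` storing per-column extrema.
#' @export
fit_minmax <- function(x) {
  x <- as.matrix(x)
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  degenerate <- hi <= lo
  if (any(degenerate)) {
    warning("degenerate feature(s) with max == min mapped to 0: ",
            paste(colnames(x)[degenerate], collapse = ", "))
  }
  structure(list(lo = lo, hi = hi, degenerate = degenerate),
            class = "minmax_scaler")
}

#' @rdname fit_minmax
#' @param scaler a fitted `minmax_scaler`.
#' @param newdata matrix to scale; values outside the training extrema map
#'   outside `[0, 1]` and are deliberately not clipped.
#' @export
apply_minmax <- function(scaler, newdata) {
  x <- as.matrix(newdata)
  rng <- scaler$hi - scaler$lo
  rng[scaler$degenerate] <- 1
  out <- sweep(sweep(x, 2, scaler$lo, "-"), 2, rng, "/")
  out[, scaler$degenerate] <- 0
  out
}

#' @rdname fit_minmax
#' @param scaled matrix on the scaled scale to invert.
#' @export
invert_minmax <- function(scaler, scaled) {
  x <- as.matrix(scaled)
  rng <- scaler$hi - scaler$lo
  rng[scaler$degenerate] <- 0
  sweep(sweep(x, 2, rng, "*"), 2, scaler$lo, "+")
}
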