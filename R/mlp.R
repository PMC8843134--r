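#' Single-hidden-layer perceptron with tanh hidden units
#'
#' The network computes
#'
#'   yhat = w0 + sum_j w_j * tanh(b_j + sum_i W_ji x_i),
#'
#' i.e. a tanh ("tansig") hidden layer of size `p` feeding a linear
#' ("purelin") output unit. `mlp_model()` packs weights into a model
#' object; [mlp_forward()] evaluates it; [train_lm()] fits it by
#' Levenberg-Marquardt least squares.
#'
#' @param W1 `p x d` input-to-hidden weight matrix.
#' @param b1 hidden bias vector of length `p`.
#' @param w2 hidden-to-output weight vector of length `p`.
#' @param b2 output bias (scalar).
#' @param log optional training log.
#' @return object of class `mlp`.
#' @export
mlp_model <- function(W1, b1, w2, b2, log = NULL) {
  W1 <- as.matrix(W1)
  p <- nrow(W1)
  if (length(b1) != p || length(w2) != p || length(b2) != 1) {
    stop("inconsistent weight dimensions", call. = FALSE)
  }
  if (any(!is.finite(W1)) || any(!is.finite(b1)) || any(!is.finite(w2)) ||
      !is.finite(b2)) {
    stop("weights must be finite", call. = FALSE)
  }
  structure(list(W1 = W1, b1 = as.numeric(b1), w2 = as.numeric(w2),
                 b2 = as.numeric(b2), log = log),
            class = "mlp")
}

#' @export
print.mlp <- function(x, ...) {
  cat("MLP:", ncol(x$W1), "inputs ->", nrow(x$W1),
      "tanh hidden units -> linear output\n")
  invisible(x)
}

#' @rdname mlp_model
#' @param model an `mlp`.
#' @param x numeric matrix of inputs (rows = cases) or a single row vector.
#' @return numeric vector of network outputs.
#' @export
mlp_forward <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != ncol(model$W1)) stop("input dimension mismatch", call. = FALSE)
  h <- tanh(sweep(x %*% t(model$W1), 2, model$b1, "+"))
  drop(h %*% model$w2) + model$b2
}

#' Mean squared error
#'
#' The training criterion: `mean((y - yhat)^2)`.
#'
#' @param y,yhat equal-length numeric vectors.
#' @return scalar error.
#' @export
sse_error <- function(y, yhat) {
  if (length(y) == 0 || length(y) != length(yhat)) {
    stop("need equal-length non-empty vectors", call. = FALSE)
  }
  mean((y - yhat)^2)
}

# pack/unpack weights <-> flat parameter vector (order: W1, b1, w2, b2)
mlp_pack <- function(model) c(as.vector(model$W1), model$b1, model$w2, model$b2)

mlp_unpack <- function(theta, p, d) {
  W1 <- matrix(theta[seq_len(p * d)], nrow = p)
  b1 <- theta[p * d + seq_len(p)]
  w2 <- theta[p * d + p + seq_len(p)]
  b2 <- theta[p * d + 2 * p + 1]
  mlp_model(W1, b1, w2, b2)
}

# residuals yhat - y and their analytic Jacobian wrt the packed parameters
mlp_residual_jacobian <- function(theta, x, y, p) {
  d <- ncol(x)
  m <- mlp_unpack(theta, p, d)
  a <- sweep(x %*% t(m$W1), 2, m$b1, "+")  # n x p pre-activations
  h <- tanh(a)
  yhat <- drop(h %*% m$w2) + m$b2
  g <- 1 - h^2                              # tanh'
  n <- nrow(x)
  J <- matrix(0, n, length(theta))
  # dyhat/dW1[j,i] = w2_j * g_j * x_i  (column-major over W1)
  for (i in seq_len(d)) {
    J[, (i - 1) * p + seq_len(p)] <- g * rep(m$w2, each = n) * x[, i]
  }
  J[, p * d + seq_len(p)] <- g * rep(m$w2, each = n)  # d/db1
  J[, p * d + p + seq_len(p)] <- h                    # d/dw2
  J[, p * d + 2 * p + 1] <- 1                         # d/db2
  list(r = yhat - y, J = J)
}

#' Train the perceptron by Levenberg-Marquardt
#'
#' Full-batch damped Gauss-Newton on the residual sum of squares with an
#' analytic Jacobian. The damping factor `mu` starts at `1e-3`, is divided
#' by 10 after an accepted step and multiplied by 10 after a rejected one;
#' iteration stops at `max_iter`, when the gradient max-norm drops below
#' `tol`, or when `mu` exceeds `1e10`. Weights are initialized uniformly in
#' `[-0.5, 0.5]` from `seed`, and the best weights seen (lowest SSE) are
#' returned, so training is reproducible.
#'
#' @param x numeric matrix of scaled inputs.
#' @param y numeric vector of (transformed) targets.
#' @param p hidden-layer size (>= 1).
#' @param seed integer seed for the weight initialization.
#' @param max_iter,tol stopping controls.
#' @return an `mlp` whose `$log` records iterations, accepted steps and
#'   final SSE.
#' @export
train_lm <- function(x, y, p, seed, max_iter = 1000, tol = 1e-8) {
  x <- as.matrix(x)
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    stop("training data must be finite", call. = FALSE)
  }
  p <- as.integer(p)
  if (p < 1) stop("hidden size must be >= 1", call. = FALSE)
  n <- nrow(x); d <- ncol(x)
  if (n < 5 * p) {
    warning("fewer than 5 rows per hidden unit (n = ", n, ", p = ", p,
            "); fit may be unstable")
  }
  n_par <- p * d + 2 * p + 1
  old <- local_rng_seed(seed)
  on.exit(restore_rng(old))
  theta <- stats::runif(n_par, -0.5, 0.5)
  rj <- mlp_residual_jacobian(theta, x, y, p)
  sse <- sum(rj$r^2)
  best_theta <- theta; best_sse <- sse
  mu <- 1e-3
  iter <- 0L; accepted <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    g <- crossprod(rj$J, rj$r)
    if (max(abs(g)) < tol) break
    A <- crossprod(rj$J)
    step <- tryCatch(
      solve(A + mu * diag(n_par), -g),
      error = function(e) NULL
    )
    ok <- FALSE
    if (!is.null(step)) {
      cand <- theta + drop(step)
      rj_new <- mlp_residual_jacobian(cand, x, y, p)
      new_sse <- sum(rj_new$r^2)
      if (is.finite(new_sse) && new_sse < sse) ok <- TRUE
    }
    if (ok) {
      theta <- cand; rj <- rj_new; sse <- new_sse
      accepted <- accepted + 1L
      if (sse < best_sse) { best_sse <- sse; best_theta <- theta }
      mu <- mu / 10
    } else {
      mu <- mu * 10
      if (mu > 1e10) break
    }
  }
  m <- mlp_unpack(best_theta, p, d)
  m$log <- list(iterations = iter, accepted = accepted, sse = best_sse,
                mse = best_sse / n, mu = mu, seed = seed, p = p)
  m
}

#' Choose the hidden-layer size by cross-validated trial and error
#'
#' For each candidate size, runs `restarts` seeded trainings per fold of a
#' shared fold assignment and scores the size by the median held-out RMSE
#' across restarts (the median guards against the occasional bad
#' Levenberg-Marquardt initialization). Ties are broken toward the
#' smallest network.
#'
#' @param x,y training inputs and targets.
#' @param folds fold assignment from [kfold_split()].
#' @param candidates hidden sizes to try (default `1:10`).
#' @param restarts seeded restarts per size (default 5).
#' @param seed base seed; restart r of size p trains with
#'   `seed + 1000 * p + r`.
#' @param max_iter passed to [train_lm()].
#' @return list with `p` (selected size) and `profile` (size vs median
#'   cross-validated RMSE).
#' @export
select_hidden_size <- function(x, y, folds, candidates = 1:10, restarts = 5,
                               seed = 1L, max_iter = 200) {
  if (length(candidates) == 0) stop("no candidate sizes", call. = FALSE)
  x <- as.matrix(x)
  med <- vapply(candidates, function(p) {
    per_restart <- vapply(seq_len(restarts), function(r) {
      err <- numeric(0)
      for (f in sort(unique(folds))) {
        tr <- folds != f
        m <- suppressWarnings(train_lm(x[tr, , drop = FALSE], y[tr], p,
                                       seed = seed + 1000L * p + r,
                                       max_iter = max_iter))
        err <- c(err, mlp_forward(m, x[!tr, , drop = FALSE]) - y[!tr])
      }
      sqrt(mean(err^2))
    }, numeric(1))
    stats::median(per_restart)
  }, numeric(1))
  best <- which.min(med)  # which.min takes the first, i.e. smallest p, on ties
  list(p = candidates[best],
       profile = data.frame(p = candidates, cv_rmse = med))
}
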