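test_that("mlp_forward implements the printed feed-forward equation", {
  zero <- mlp_model(matrix(0, 2, 3), c(0, 0), c(0, 0), 0)
  expect_equal(mlp_forward(zero, c(1, 2, 3)), 0)
  bias <- mlp_model(matrix(0, 2, 3), c(0, 0), c(0, 0), 5.5)
  expect_equal(mlp_forward(bias, c(1, 2, 3)), 5.5)

  # p = 1, w11 = 1, w2 = 1: yhat = tanh(x1)
  m <- mlp_model(matrix(c(1, 0, 0), 1, 3), 0, 1, 0)
  expect_equal(mlp_forward(m, c(0.5, 0, 0)), tanh(0.5))
  expect_equal(mlp_forward(m, c(0.5, 9, -9)), 0.46211716, tolerance = 1e-7)

  expect_error(mlp_forward(m, c(1, 2)), "dimension")
  expect_error(mlp_model(matrix(0, 2, 3), c(0, 0), 0, 0), "dimensions")
  expect_error(mlp_model(matrix(Inf, 1, 1), 0, 0, 0), "finite")
})

test_that("vectorized forward pass equals the brute-force loop", {
  withr::local_seed(12)
  for (p in c(1, 3, 7)) {
    W1 <- matrix(rnorm(p * 3), p, 3)
    m <- mlp_model(W1, rnorm(p), rnorm(p), rnorm(1))
    x <- matrix(rnorm(15), 5, 3)
    expect_equal(mlp_forward(m, x),
                 apply(x, 1, function(r) naive_mlp(m, r)),
                 tolerance = 1e-12)
    # hidden contribution of each unit is bounded by |w2_j|
    h <- tanh(sweep(x %*% t(m$W1), 2, m$b1, "+"))
    expect_true(all(abs(sweep(h, 2, m$w2, "*")) <= rep(abs(m$w2), each = 5)))
  }
})

test_that("sse_error is the mean squared residual", {
  expect_equal(sse_error(c(1, 2), c(1, 2)), 0)
  expect_equal(sse_error(c(1, 2), c(1, 0)), 2)
  y <- c(0.5, 1, 2); yhat <- c(1, 0, 4)
  expect_equal(sse_error(y, y + 3 * (yhat - y)), 9 * sse_error(y, yhat))
  expect_error(sse_error(numeric(0), numeric(0)), "non-empty")
})

test_that("analytic Jacobian matches central finite differences", {
  withr::local_seed(13)
  x <- matrix(runif(30), 10, 3)
  y <- rnorm(10)
  p <- 4
  theta <- rnorm(p * 3 + 2 * p + 1, sd = 0.5)
  rj <- grnnga:::mlp_residual_jacobian(theta, x, y, p)
  h <- 1e-6
  for (j in seq_along(theta)) {
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    fd <- (grnnga:::mlp_residual_jacobian(tp, x, y, p)$r -
           grnnga:::mlp_residual_jacobian(tm, x, y, p)$r) / (2 * h)
    denom <- pmax(abs(fd), 1e-8)
    expect_lt(max(abs(rj$J[, j] - fd) / denom), 1e-4)
  }
})

test_that("Levenberg-Marquardt recovers a noiseless teacher network", {
  withr::local_seed(14)
  x <- matrix(runif(120), 40, 3)
  teacher <- mlp_model(matrix(rnorm(6), 2, 3), rnorm(2), rnorm(2), rnorm(1))
  y <- mlp_forward(teacher, x)
  fit <- train_lm(x, y, p = 2, seed = 21, max_iter = 500)
  rmse <- sqrt(mean((mlp_forward(fit, x) - y)^2))
  expect_lt(rmse, 1e-3 * sd(y))
  # reproducibility and improvement over the initial weights
  fit2 <- train_lm(x, y, p = 2, seed = 21, max_iter = 500)
  expect_identical(grnnga:::mlp_pack(fit), grnnga:::mlp_pack(fit2))
  expect_lte(fit$log$sse, sum((mlp_forward(fit, x) - y)^2) + 1e-9)
  expect_error(train_lm(x, c(y[-1], NA), 2, seed = 1), "finite")
  expect_warning(train_lm(x[1:4, ], y[1:4], p = 2, seed = 1, max_iter = 5),
                 "per hidden unit")
})

test_that("a small-weight tanh unit reproduces a linear law", {
  x <- matrix(seq(0, 0.1, length.out = 30), ncol = 1)
  y <- 2 * x[, 1] + 1
  fit <- train_lm(x, y, p = 1, seed = 3, max_iter = 500)
  pred <- mlp_forward(fit, x)
  expect_gt(compute_metrics(y, pred)$r2, 0.999)
})

test_that("hidden-size selection is deterministic and prefers adequacy", {
  withr::local_seed(15)
  x <- matrix(runif(90), 30, 3)
  y <- 1 + x %*% c(1, -2, 0.5) + rnorm(30, sd = 0.01)
  folds <- kfold_split(30, 5, seed = 6)
  sel <- select_hidden_size(x, drop(y), folds, candidates = c(1, 4),
                            restarts = 2, seed = 9, max_iter = 100)
  expect_true(sel$p %in% c(1, 4))
  # linear ground truth: the small net does not lose to the big one
  expect_lte(sel$profile$cv_rmse[sel$profile$p == sel$p],
             sel$profile$cv_rmse[sel$profile$p == 4] + 1e-12)
  again <- select_hidden_size(x, drop(y), folds, candidates = c(1, 4),
                              restarts = 2, seed = 9, max_iter = 100)
  expect_identical(sel$p, again$p)
  expect_equal(select_hidden_size(x, drop(y), folds, candidates = 3,
                                  restarts = 1, seed = 1,
                                  max_iter = 30)$p, 3)
  expect_error(select_hidden_size(x, drop(y), folds, candidates = integer(0)),
               "candidate")
})
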