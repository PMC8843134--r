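test_that("init_population respects bounds, seeds and degenerate boxes", {
  cfg <- ga_config(seed = 3)
  pop <- init_population(cfg)
  expect_equal(dim(pop), c(200, 3))
  expect_true(all(pop[, 1] >= 0 & pop[, 1] <= 200))
  expect_true(all(pop[, 2] >= 0 & pop[, 2] <= 300))
  expect_true(all(pop[, 3] >= 0 & pop[, 3] <= 100))
  expect_identical(pop, init_population(ga_config(seed = 3)))
  expect_false(identical(pop, init_population(ga_config(seed = 4))))

  squeezed <- init_population(ga_config(bounds = list(n = c(5, 5 + 1e-9),
                                                      k = c(1, 2),
                                                      mg = c(0, 1)),
                                        seed = 1))
  expect_true(all(abs(squeezed[, 1] - 5) <= 1e-9))
  expect_error(ga_config(pop_size = 1), "at least 2")
  expect_error(ga_config(p_crossover = 1.2), "rates")
  expect_error(ga_config(bounds = list(n = c(1, 1), k = c(0, 1),
                                       mg = c(0, 1))), "low < high")
})

test_that("roulette selection weights are proportional to shifted fitness", {
  # shifted weights for fitness (0, 2): (eps*range, 2 + eps*range)
  w <- grnnga:::roulette_weights(c(0, 2))
  expect_equal(w, c(0.02, 2.02))
  # equal fitness selects uniformly
  expect_equal(grnnga:::roulette_weights(c(3, 3, 3)), c(1, 1, 1))
  withr::local_seed(31)
  draws <- replicate(20000, roulette_select(c(5, 5)))
  p1 <- mean(draws == 1)
  expect_lt(abs(p1 - 0.5), 3 * sqrt(0.25 / 20000))
  # negative fitness handled by the shift
  draws2 <- replicate(20000, roulette_select(c(-3, -1)))
  p2 <- 2.02 / (0.02 + 2.02)
  expect_lt(abs(mean(draws2 == 2) - p2), 3 * sqrt(p2 * (1 - p2) / 20000))
  expect_equal(roulette_select(7), 1)
  expect_error(roulette_select(numeric(0)), "empty")
  expect_error(roulette_select(c(1, Inf)), "finite")
})

test_that("2-point crossover exchanges exactly one interior segment", {
  withr::local_seed(32)
  a <- c(1, 2, 3); b <- c(10, 20, 30)
  # the 3 admissible cut pairs give children from a known set
  allowed <- list(c(1, 20, 3), c(1, 20, 30), c(1, 2, 30))
  for (i in 1:50) {
    kids <- two_point_crossover(a, b, p_c = 1)
    expect_true(any(vapply(allowed, identical, logical(1), kids[[1]])))
    # every child gene comes from one of the parents at that locus
    expect_true(all(kids[[1]] == a | kids[[1]] == b))
    expect_true(all(kids[[2]] == a | kids[[2]] == b))
    # the two children exchange complementary segments
    expect_equal(kids[[1]] + kids[[2]], a + b)
  }
  same <- two_point_crossover(c(4, 4, 4), c(4, 4, 4), p_c = 1)
  expect_equal(same[[1]], c(4, 4, 4))
  none <- two_point_crossover(a, b, p_c = 0)
  expect_identical(none, list(a, b))
  expect_error(two_point_crossover(1, 2, 0.5), "length >= 2")
})

test_that("uniform mutation redraws genes at the nominal rate within bounds", {
  lo <- c(0, 0, 0); hi <- c(200, 300, 100)
  x <- c(50, 60, 70)
  expect_identical(uniform_mutation(x, 0, lo, hi), x)
  withr::local_seed(33)
  full <- uniform_mutation(x, 1, lo, hi)
  expect_true(all(full >= lo & full <= hi))
  expect_false(any(full == x))
  # mutated fraction over 1e5 genes ~ Binomial(1e5, 0.04)
  n_genes <- 1e5
  big <- rep(-1, n_genes)  # sentinel outside [0, 1] bounds
  mut <- uniform_mutation(big, 0.04, rep(0, n_genes), rep(1, n_genes))
  frac <- mean(mut != -1)
  expect_lt(abs(frac - 0.04), 3 * sqrt(0.04 * 0.96 / n_genes))
})

test_that("ga_optimize maximizes analytic objectives inside the box", {
  seen <- new.env(); seen$bad <- FALSE
  bounds_ok <- function(p) {
    seen$bad <- seen$bad || any(p[, 1] < 0 | p[, 1] > 200 |
                                p[, 2] < 0 | p[, 2] > 300 |
                                p[, 3] < 0 | p[, 3] > 100)
    p[, 1] + p[, 2] + p[, 3]
  }
  res <- ga_optimize(bounds_ok, ga_config(seed = 2, generations = 200))
  expect_false(seen$bad)
  # monotone objective drives all doses to the upper corner within 1%
  expect_gt(res$value, 0.99 * 600)
  expect_equal(as.numeric(res$levels), c(200, 300, 100), tolerance = 0.01)
  # elitism makes the best-fitness history non-decreasing
  expect_true(all(diff(res$history$best) >= 0))
  expect_equal(max(res$history$best), res$value)
  # reproducible
  res2 <- ga_optimize(function(p) p[, 1] + p[, 2] + p[, 3],
                      ga_config(seed = 2, generations = 200))
  expect_identical(as.numeric(res$levels), as.numeric(res2$levels))
})

test_that("ga_optimize survives non-finite objective values with a warning", {
  spiky <- function(p) {
    f <- -(p[, 1] - 100)^2
    f[p[, 2] > 250] <- NaN
    f
  }
  warns <- testthat::capture_warnings(
    res <- ga_optimize(spiky, ga_config(seed = 5, generations = 30,
                                        pop_size = 40)))
  expect_true(any(grepl("non-finite", warns)))
  expect_true(is.finite(res$value))
})

test_that("the GA pinpoints a concave analytic optimum on every seed", {
  target <- c(100, 150, 50)
  obj <- function(p) {
    -(p[, 1] - 100)^2 - (p[, 2] - 150)^2 - (p[, 3] - 50)^2
  }
  for (s in 1:5) {
    res <- ga_optimize(obj, ga_config(seed = s, generations = 300))
    expect_lt(max(abs(as.numeric(res$levels) - target)), 2)
  }
})
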