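test_that("true_surface evaluates the polynomial exactly", {
  flat <- surface_spec(intercept = 7, linear = c(0, 0, 0),
                       quadratic = c(0, 0, 0), interaction_nk = 0)
  expect_equal(true_surface(flat, c(0, 100, 200), c(0, 150, 300), c(0, 50, 100)),
               rep(7, 3))

  lin <- surface_spec(intercept = 1, linear = c(n = 0.1, k = 0.2, mg = 0.3),
                      quadratic = c(0, 0, 0), interaction_nk = 0)
  # 1 + 0.1*100 + 0.2*100 + 0.3*50 = 46
  expect_equal(true_surface(lin, 100, 100, 50), 46)

  sym <- surface_spec(linear = c(n = 0.1, k = 0.1, mg = 0),
                      quadratic = c(n = -1e-4, k = -1e-4, mg = 0),
                      interaction_nk = 2e-4,
                      bounds = list(n = c(0, 200), k = c(0, 200),
                                    mg = c(0, 100)))
  expect_equal(true_surface(sym, 30, 170, 50), true_surface(sym, 170, 30, 50))
  expect_error(true_surface(lin, 500, 0, 0), "bounds")
})

test_that("generate_experiment has the factorial shape and noiseless limit", {
  noiseless <- generate_experiment(surface_spec(noise_sd = 0, seed = 1))
  expect_equal(nrow(noiseless$records), 36)
  expect_equal(nrow(noiseless$replicates), 108)
  truth <- true_surface(surface_spec(), noiseless$replicates$n_g,
                        noiseless$replicates$k_g, noiseless$replicates$mg_g)
  expect_equal(noiseless$replicates$fy, truth, tolerance = 1e-12)
  expect_equal(noiseless$records$fy_sem, rep(0, 36), tolerance = 1e-12)
  expect_error(generate_experiment(surface_spec(), design = data.frame()),
               "empty")
  # determinism by seed
  a <- generate_experiment(surface_spec(seed = 9))
  b <- generate_experiment(surface_spec(seed = 9))
  expect_identical(a$records, b$records)
})

test_that("cell means concentrate around the surface at the CLT rate", {
  spec0 <- surface_spec()
  truth <- true_surface(spec0, default_design()$n_g, default_design()$k_g,
                        default_design()$mg_g)
  bound <- 4 * spec0$noise_sd / sqrt(spec0$n_reps)
  clean_runs <- 0L
  for (s in 1:200) {
    tab <- generate_experiment(surface_spec(seed = s))
    if (all(abs(tab$records$fy_mean - truth) <= bound)) {
      clean_runs <- clean_runs + 1L
    }
  }
  expect_gte(clean_runs, 198L)
})

test_that("generated SEMs estimate the replicate-mean noise scale", {
  # With r = 3 a single cell's SEM is chi-distributed with 2 df and spreads
  # widely; unbiasedness holds in quadrature, so pool cells and compare the
  # root-mean-square SEM to noise_sd / sqrt(r).
  target <- surface_spec()$noise_sd / sqrt(3)
  pooled <- unlist(lapply(1:10, function(s) {
    generate_experiment(surface_spec(seed = s))$records$fy_sem
  }))
  expect_lt(abs(sqrt(mean(pooled^2)) / target - 1), 0.10)
  # and per-cell concentration appears as replication grows
  big <- generate_experiment(surface_spec(n_reps = 30, seed = 3))
  tgt <- surface_spec()$noise_sd / sqrt(30)
  expect_lt(max(abs(big$records$fy_sem / tgt - 1)), 0.5)
  expect_lt(abs(mean(big$records$fy_sem) / tgt - 1), 0.10)
})

test_that("true_optimum agrees with closed forms and breaks ties low", {
  # concave quadratic with interior vertex at -b/2a per axis
  conc <- surface_spec(intercept = 0,
                       linear = c(n = 0.2, k = 0.3, mg = 0.4),
                       quadratic = c(n = -1e-3, k = -1e-3, mg = -4e-3),
                       interaction_nk = 0, noise_sd = 0)
  opt <- true_optimum(conc)
  expect_equal(as.numeric(opt$levels), c(100, 150, 50), tolerance = 1e-2)
  expect_equal(opt$value, true_surface(conc, 100, 150, 50), tolerance = 1e-6)

  mono <- surface_spec(intercept = 0, linear = c(n = 1, k = 1, mg = 1),
                       quadratic = c(0, 0, 0), interaction_nk = 0)
  expect_equal(as.numeric(true_optimum(mono)$levels), c(200, 300, 100),
               tolerance = 1e-6)

  flat <- surface_spec(intercept = 5, linear = c(0, 0, 0),
                       quadratic = c(0, 0, 0), interaction_nk = 0)
  expect_equal(as.numeric(true_optimum(flat)$levels), c(0, 0, 0))

  # default calibration peaks at high N and K with interior Mg
  expect_equal(as.numeric(true_optimum(surface_spec())$levels),
               c(200, 300, 50), tolerance = 1e-2)
})

test_that("surface reconstruction: GRNN fitted to a low-noise experiment
           tracks the true surface on a dense held-out grid", {
  spec <- surface_spec(noise_sd = 1, seed = 5)
  tab <- generate_experiment(spec)
  x <- as.matrix(tab$records[, c("n_g", "k_g", "mg_g")])
  scaler <- fit_minmax(x)
  xs <- apply_minmax(scaler, x)
  y <- tab$records$fy_mean
  # sigma picked for cross-treatment generalization (folds over cells)
  sig <- select_sigma(xs, y, kfold_split(36, 5, seed = 2))$sigma
  model <- grnn_fit(xs, y, sig)
  grid <- expand.grid(n_g = seq(0, 200, 10), k_g = seq(0, 300, 10),
                      mg_g = seq(0, 100, 10))
  truth <- true_surface(spec, grid$n_g, grid$k_g, grid$mg_g)
  pred <- grnn_predict(model, apply_minmax(scaler, as.matrix(grid)))
  expect_gte(compute_metrics(truth, pred)$r2, 0.95)
})
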