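#' Specify a ground-truth dose-response surface
#'
#' Defines a quadratic-with-interaction response surface over the dose box,
#'
#'   f(N, K, Mg) = b0 + sum_f b_f x_f + sum_f q_f x_f^2 + b_nk * N * K,
#'
#' the shape family that captures the phenomenology of factorial fertilizer
#' trials: strong positive N and K main effects with an N x K synergy,
#' curvature giving plateaus (or toxicity) at high doses, and a weak
#' magnesium effect with an interior optimum. Defaults are calibrated so
#' that surface values, effect sizes and replicate noise resemble the
#' fruit-yield column of the packaged banana trial: values span roughly
#' 42--134 kg/plant, the Mg response rises ~8 kg to an interior optimum at
#' 50 g and falls back (the order of the Mg differences seen in the real
#' data), and replicate-level noise SD is 6 (the trial's SEM * sqrt(3)
#' averages ~8.5 with most cells between 2 and 11).
#'
#' @param intercept surface value at zero dose (trait units).
#' @param linear named numeric `c(n, k, mg)`: linear coefficients per gram.
#' @param quadratic named numeric `c(n, k, mg)`: quadratic coefficients.
#' @param interaction_nk coefficient on N*K.
#' @param noise_sd replicate-level Gaussian noise SD (trait units), >= 0.
#' @param n_reps replicates per cell, >= 1.
#' @param bounds list of `c(low, high)` per factor (grams per plant).
#' @param seed integer seed used by [generate_experiment()].
#' @return A `surface_spec` list.
#' @export
surface_spec <- function(intercept = 42,
                         linear = c(n = 0.18, k = 0.10, mg = 0.32),
                         quadratic = c(n = -4e-4, k = -1.5e-4, mg = -3.2e-3),
                         interaction_nk = 8e-4,
                         noise_sd = 6,
                         n_reps = 3L,
                         bounds = list(n = c(0, 200), k = c(0, 300),
                                       mg = c(0, 100)),
                         seed = 1L) {
  stopifnot(length(linear) == 3, length(quadratic) == 3, length(bounds) == 3)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  if (any(lo >= hi)) stop("each bound must satisfy low < high", call. = FALSE)
  structure(list(intercept = intercept,
                 linear = stats::setNames(as.numeric(linear), c("n", "k", "mg")),
                 quadratic = stats::setNames(as.numeric(quadratic), c("n", "k", "mg")),
                 interaction_nk = as.numeric(interaction_nk),
                 noise_sd = noise_sd, n_reps = as.integer(n_reps),
                 bounds = stats::setNames(bounds, c("n", "k", "mg")),
                 seed = as.integer(seed)),
            class = "surface_spec")
}

in_bounds <- function(spec, n, k, mg, tol = 1e-9) {
  b <- spec$bounds
  all(n >= b$n[1] - tol & n <= b$n[2] + tol &
      k >= b$k[1] - tol & k <= b$k[2] + tol &
      mg >= b$mg[1] - tol & mg <= b$mg[2] + tol)
}

#' Evaluate the noiseless ground-truth surface
#'
#' @param spec a [surface_spec()]
#' @param n,k,mg numeric vectors of doses (recycled to common length); must
#'   lie within the spec's bounds.
#' @return numeric vector of trait values.
#' @export
true_surface <- function(spec, n, k, mg) {
  m <- max(length(n), length(k), length(mg))
  n <- rep_len(as.numeric(n), m)
  k <- rep_len(as.numeric(k), m)
  mg <- rep_len(as.numeric(mg), m)
  if (!in_bounds(spec, n, k, mg)) {
    stop("doses outside the surface bounds", call. = FALSE)
  }
  unname(
    spec$intercept +
      spec$linear["n"] * n + spec$linear["k"] * k + spec$linear["mg"] * mg +
      spec$quadratic["n"] * n^2 + spec$quadratic["k"] * k^2 +
      spec$quadratic["mg"] * mg^2 +
      spec$interaction_nk * n * k)
}

#' Simulate a full-factorial dose-response experiment
#'
#' For every cell of the design grid, draws `n_reps` replicate observations
#' `true_surface + N(0, noise_sd^2)` and assembles a [trait_table] carrying
#' both the replicates and the derived means and SEMs. All three trait
#' columns are simulated from the same surface (the generator emulates one
#' trait; downstream code selects columns by trait name), so tests exercise
#' the full table schema.
#'
#' @param spec a [surface_spec()]
#' @param design data frame with columns `n_g,k_g,mg_g`, a full factorial
#'   grid within bounds; default the packaged trial's 3 x 4 x 3 design.
#' @return a `trait_table` with `$replicates` filled and
#'   `$provenance$surface_spec` set.
#' @export
generate_experiment <- function(spec, design = default_design(spec)) {
  if (is.null(design) || nrow(design) == 0) {
    stop("design grid is empty", call. = FALSE)
  }
  n_t <- nrow(design)
  r <- spec$n_reps
  truth <- true_surface(spec, design$n_g, design$k_g, design$mg_g)
  old <- local_rng_seed(spec$seed)
  on.exit(restore_rng(old))
  eps <- matrix(stats::rnorm(n_t * r, sd = spec$noise_sd), nrow = n_t)
  vals <- truth + eps                      # n_t x r replicate matrix
  means <- rowMeans(vals)
  sems <- apply(vals, 1, stats::sd) / sqrt(r)
  if (r == 1) sems <- rep(0, n_t)
  rec <- data.frame(n_g = design$n_g, k_g = design$k_g, mg_g = design$mg_g)
  for (tr in TRAITS) {
    rec[[paste0(tr, "_mean")]] <- means
    rec[[paste0(tr, "_sem")]] <- sems
  }
  rec$n_reps <- r
  reps <- data.frame(
    treatment = rep(seq_len(n_t), times = r),
    n_g = rep(design$n_g, r), k_g = rep(design$k_g, r),
    mg_g = rep(design$mg_g, r),
    rep = rep(seq_len(r), each = n_t)
  )
  v <- as.vector(vals)
  for (tr in TRAITS) reps[[tr]] <- v
  ord <- order(reps$treatment, reps$rep)
  reps <- reps[ord, ]
  rownames(reps) <- NULL
  tab <- new_trait_table(rec, replicates = reps,
                         provenance = list(surface_spec = spec,
                                           seed = spec$seed))
  validate_trait_table(tab)
  tab
}

#' @rdname generate_experiment
#' @export
default_design <- function(spec = surface_spec()) {
  b <- spec$bounds
  expand.grid(n_g = seq(b$n[1], b$n[2], length.out = 3),
              k_g = seq(b$k[1], b$k[2], length.out = 4),
              mg_g = seq(b$mg[1], b$mg[2], length.out = 3))
}

#' Locate the ground-truth optimum by brute force
#'
#' Dense-grid search (`grid_points` per axis, default 201) over the bound
#' box followed by local refinement with `optim(method = "L-BFGS-B")`. Grid
#' ties are broken toward the lexicographically smallest (N, K, Mg) point.
#' This is the independent oracle that optimizer results are compared
#' against in parameter-recovery tests.
#'
#' @param spec a [surface_spec()]
#' @param grid_points grid resolution per axis (>= 2).
#' @return list with `levels` ([fertilizer_levels()]) and `value`.
#' @export
true_optimum <- function(spec, grid_points = 201L) {
  b <- spec$bounds
  ng <- seq(b$n[1], b$n[2], length.out = grid_points)
  kg <- seq(b$k[1], b$k[2], length.out = grid_points)
  mgg <- seq(b$mg[1], b$mg[2], length.out = grid_points)
  best <- c(val = -Inf, n = NA, k = NA, mg = NA)
  nk_grid <- expand.grid(n = ng, k = kg)
  # slice over Mg to keep memory bounded
  for (mg in mgg) {
    v <- true_surface(spec, nk_grid$n, nk_grid$k, rep(mg, nrow(nk_grid)))
    i <- which(v > best["val"] + 1e-12)
    if (length(i) > 0) {
      # among strictly-better points take the lexicographically smallest
      cand <- i[order(v[i], decreasing = TRUE)]
      top_val <- v[cand[1]]
      tied <- i[v[i] >= top_val - 1e-12]
      tied <- tied[order(nk_grid$n[tied], nk_grid$k[tied])]
      j <- tied[1]
      best <- c(val = v[j], n = nk_grid$n[j], k = nk_grid$k[j], mg = mg)
    }
  }
  ref <- stats::optim(
    par = best[c("n", "k", "mg")],
    fn = function(p) -true_surface(spec, p[1], p[2], p[3]),
    method = "L-BFGS-B",
    lower = c(b$n[1], b$k[1], b$mg[1]),
    upper = c(b$n[2], b$k[2], b$mg[2])
  )
  val <- -ref$value
  par <- ref$par
  if (val < best["val"] + 1e-12) {  # keep the grid tie-break on flat surfaces
    par <- best[c("n", "k", "mg")]
    val <- best[["val"]]
  }
  list(levels = fertilizer_levels(par[[1]], par[[2]], par[[3]]),
       value = unname(val))
}
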