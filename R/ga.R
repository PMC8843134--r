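#' Genetic-algorithm configuration
#'
#' Defaults follow the dose-optimization protocol: population 200,
#' 1000 generations, crossover rate 0.7, mutation rate 0.04, roulette-wheel
#' selection, 2-point crossover, uniform mutation, and box constraints on
#' the three doses. One elite individual is carried over per generation so
#' the best-so-far fitness is non-decreasing; set `elitism = 0` to disable.
#'
#' @param bounds list of `c(low, high)` per gene; default the trial's dose
#'   box N in \[0, 200\], K in \[0, 300\], Mg in \[0, 100\] grams.
#' @param pop_size,generations,p_crossover,p_mutation,elitism GA controls.
#' @param seed integer seed; the whole run is deterministic given it.
#' @return a `ga_config` list.
#' @export
ga_config <- function(bounds = list(n = c(0, 200), k = c(0, 300),
                                    mg = c(0, 100)),
                      pop_size = 200L, generations = 1000L,
                      p_crossover = 0.7, p_mutation = 0.04,
                      elitism = 1L, seed = 1L) {
  if (p_crossover < 0 || p_crossover > 1 || p_mutation < 0 || p_mutation > 1) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (pop_size < 2) stop("population must hold at least 2 individuals", call. = FALSE)
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  if (any(lo >= hi)) stop("each bound must satisfy low < high", call. = FALSE)
  structure(list(bounds = bounds, lo = lo, hi = hi,
                 pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 elitism = as.integer(elitism), seed = as.integer(seed)),
            class = "ga_config")
}

#' Initialize a real-coded population
#'
#' Chromosomes are real dose triples sampled uniformly within the bound
#' box; deterministic given the config seed.
#'
#' @param config a [ga_config()].
#' @return `pop_size x n_genes` numeric matrix.
#' @export
init_population <- function(config) {
  old <- local_rng_seed(config$seed)
  on.exit(restore_rng(old))
  ng <- length(config$lo)
  matrix(stats::runif(config$pop_size * ng,
                      rep(config$lo, each = config$pop_size),
                      rep(config$hi, each = config$pop_size)),
         ncol = ng, dimnames = list(NULL, names(config$bounds)))
}

# Selection weights: fitness shifted to be strictly positive so roulette is
# defined for negative or tied fitness; epsilon keeps the worst individual
# selectable.
roulette_weights <- function(fitness, eps = 0.01) {
  if (length(fitness) == 0) stop("empty population", call. = FALSE)
  if (any(!is.finite(fitness))) stop("fitness must be finite", call. = FALSE)
  rng <- max(fitness) - min(fitness)
  if (rng == 0) return(rep(1, length(fitness)))
  fitness - min(fitness) + eps * rng
}

#' Roulette-wheel parent selection
#'
#' Draws one parent index with probability proportional to the shifted
#' fitness `f - min(f) + 0.01 * range(f)`; when all fitness values are
#' equal the draw is uniform.
#'
#' @param fitness numeric vector of fitness values (maximization).
#' @return a single parent index.
#' @export
roulette_select <- function(fitness) {
  w <- roulette_weights(fitness)
  sample.int(length(w), 1L, prob = w)
}

#' 2-point crossover on gene boundaries
#'
#' With probability `p_c` two distinct cut points are drawn uniformly from
#' the gene boundaries `1..L` and the genes strictly between them (the
#' segment `(c1, c2]`) are exchanged between the parents; otherwise the
#' children are exact copies. For the 3-gene dose chromosome the possible
#' cut pairs are (1,2), (1,3) and (2,3).
#'
#' @param a,b equal-length parent chromosomes (length >= 2).
#' @param p_c crossover probability.
#' @return list of two children.
#' @export
two_point_crossover <- function(a, b, p_c) {
  L <- length(a)
  if (L < 2 || length(b) != L) {
    stop("2-point crossover needs equal-length chromosomes of length >= 2",
         call. = FALSE)
  }
  if (stats::runif(1) < p_c) {
    cuts <- sort(sample.int(L, 2L))
    seg <- (cuts[1] + 1L):cuts[2]
    tmp <- a[seg]; a[seg] <- b[seg]; b[seg] <- tmp
  }
  list(a, b)
}

#' Uniform mutation under box constraints
#'
#' Each gene is independently replaced, with probability `p_m`, by a fresh
#' uniform draw from its bound interval.
#'
#' @param x chromosome (within bounds).
#' @param p_m per-gene mutation probability.
#' @param lo,hi per-gene bounds.
#' @return mutated chromosome.
#' @export
uniform_mutation <- function(x, p_m, lo, hi) {
  hit <- stats::runif(length(x)) < p_m
  if (any(hit)) x[hit] <- stats::runif(sum(hit), lo[hit], hi[hit])
  x
}

#' Maximize an objective over the dose box with the genetic algorithm
#'
#' Generational loop: the `elitism` fittest individuals are copied
#' unchanged; the remaining slots are filled by roulette-selected parents
#' recombined by 2-point crossover and perturbed by uniform mutation.
#' Returns the best individual over all evaluations. Candidates mapping to
#' a non-finite objective value are assigned the worst fitness of their
#' generation (with a warning) so the search continues.
#'
#' @param objective function taking an `n x n_genes` matrix of candidates
#'   and returning a numeric vector of objective values (maximized).
#' @param config a [ga_config()].
#' @return an `optimization_result`: `levels`, `value`, per-generation
#'   `history` (best/mean fitness), `evaluations`, and the config echo.
#' @export
ga_optimize <- function(objective, config = ga_config()) {
  old <- local_rng_seed(config$seed)
  on.exit(restore_rng(old))
  ng <- length(config$lo)
  pop <- matrix(stats::runif(config$pop_size * ng,
                             rep(config$lo, each = config$pop_size),
                             rep(config$hi, each = config$pop_size)),
                ncol = ng)
  evals <- 0L
  eval_fitness <- function(p) {
    f <- objective(p)
    evals <<- evals + nrow(p)
    if (any(!is.finite(f))) {
      warning("non-finite objective value(s); assigned worst-in-generation fitness")
      worst <- if (any(is.finite(f))) min(f[is.finite(f)]) else 0
      f[!is.finite(f)] <- worst
    }
    f
  }
  fit <- eval_fitness(pop)
  best_i <- which.max(fit)
  best_x <- pop[best_i, ]; best_f <- fit[best_i]
  hist_best <- hist_mean <- numeric(config$generations)
  for (gen in seq_len(config$generations)) {
    elite_idx <- order(fit, decreasing = TRUE)[seq_len(config$elitism)]
    n_child <- config$pop_size - config$elitism
    w <- roulette_weights(fit)
    parents <- sample.int(config$pop_size, 2L * ceiling(n_child / 2),
                          replace = TRUE, prob = w)
    children <- matrix(0, ceiling(n_child / 2) * 2, ng)
    for (i in seq_len(ceiling(n_child / 2))) {
      pair <- two_point_crossover(pop[parents[2 * i - 1], ],
                                  pop[parents[2 * i], ],
                                  config$p_crossover)
      children[2 * i - 1, ] <- uniform_mutation(pair[[1]], config$p_mutation,
                                                config$lo, config$hi)
      children[2 * i, ] <- uniform_mutation(pair[[2]], config$p_mutation,
                                            config$lo, config$hi)
    }
    children <- children[seq_len(n_child), , drop = FALSE]
    new_pop <- rbind(pop[elite_idx, , drop = FALSE], children)
    new_fit <- c(fit[elite_idx],
                 if (n_child > 0) eval_fitness(children[, , drop = FALSE]))
    pop <- new_pop; fit <- new_fit
    gi <- which.max(fit)
    if (fit[gi] > best_f) { best_f <- fit[gi]; best_x <- pop[gi, ] }
    hist_best[gen] <- best_f
    hist_mean[gen] <- mean(fit)
  }
  structure(list(levels = fertilizer_levels(best_x[1], best_x[2], best_x[3]),
                 value = best_f,
                 history = data.frame(generation = seq_len(config$generations),
                                      best = hist_best, mean = hist_mean),
                 evaluations = evals,
                 config = config, seed = config$seed),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  lv <- x$levels
  cat(sprintf("GA optimum: N = %.2f g, K = %.2f g, Mg = %.2f g -> %.4f\n",
              lv["n_g"], lv["k_g"], lv["mg_g"], x$value))
  cat("  ", x$evaluations, "objective evaluations over",
      x$config$generations, "generations\n")
  invisible(x)
}
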