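#' Default pipeline configuration
#'
#' One list drives the whole analysis. Per-stage seeds are derived from the
#' single global seed by fixed offsets (replicate reconstruction +1, fold
#' assignment +2, model refits +3, GA for trait t +10 t) so every random
#' draw traces back to `seed`.
#'
#' @param seed global integer seed.
#' @param cv_folds folds for the shared cross-validation split (default 5).
#' @param boxcox apply a Box-Cox transform to the targets (default `TRUE`);
#'   inputs are designed doses and are min-max scaled, not transformed.
#' @param outlier_threshold_sd score-distance threshold for
#'   [pca_outlier_flags()].
#' @param outlier_action `"flag"` (report only, default) or `"remove"`.
#' @param sigma_grid GRNN width candidates.
#' @param mlp_sizes,mlp_restarts,mlp_max_iter hidden-size search controls.
#' @param ga a [ga_config()]; its seed is overridden per trait.
#' @param reference dose triple the reduction summary compares against;
#'   default the best-yield treatment of the packaged trial
#'   (N 200, K 300, Mg 50 g).
#' @return a `run_config` list.
#' @export
default_config <- function(seed = 42L,
                           cv_folds = 5L,
                           boxcox = TRUE,
                           outlier_threshold_sd = 3,
                           outlier_action = c("flag", "remove"),
                           sigma_grid = default_sigma_grid(),
                           mlp_sizes = 1:10,
                           mlp_restarts = 5L,
                           mlp_max_iter = 200L,
                           ga = ga_config(),
                           reference = fertilizer_levels(200, 300, 50)) {
  structure(list(seed = as.integer(seed), cv_folds = as.integer(cv_folds),
                 boxcox = isTRUE(boxcox),
                 outlier_threshold_sd = outlier_threshold_sd,
                 outlier_action = match.arg(outlier_action),
                 sigma_grid = sigma_grid,
                 mlp_sizes = mlp_sizes,
                 mlp_restarts = as.integer(mlp_restarts),
                 mlp_max_iter = as.integer(mlp_max_iter),
                 ga = ga, reference = reference),
            class = "run_config")
}

#' Per-factor dose reduction relative to a reference treatment
#'
#' `100 * (1 - optimal / reference)` per factor: the percentage by which
#' the optimized dose undercuts the reference (negative when it exceeds
#' it). Factors with a zero reference dose are undefined and returned as
#' `NA`.
#'
#' @param optimal,reference dose triples ([fertilizer_levels()] or numeric
#'   length-3 vectors ordered N, K, Mg).
#' @return named numeric vector of three percentages.
#' @export
compute_reduction <- function(optimal, reference) {
  o <- as.numeric(optimal); r <- as.numeric(reference)
  out <- ifelse(r > 0, 100 * (1 - o / r), NA_real_)
  names(out) <- c("n", "k", "mg")
  out
}

#' Run the full surrogate-modelling and optimization analysis
#'
#' End-to-end protocol on a factorial fertilizer trial:
#' \enumerate{
#'   \item load the data (packaged trial by default) and reconstruct
#'     replicate-level observations from means and SEMs;
#'   \item screen for multivariate outliers by PCA score distance
#'     (flag-only by default);
#'   \item assign the shared treatment-level cross-validation folds;
#'   \item for each trait, evaluate GRNN and MLP under the shared folds
#'     ([cv_evaluate()]) and collect R2/RMSE/MBE for pooled training and
#'     testing predictions;
#'   \item per trait, refit the family with the higher testing R2 on the
#'     full data (cross-validation-selected hyper-parameter) and maximize
#'     its prediction over the dose box with the genetic algorithm;
#'   \item summarize each optimum as percent dose reductions against the
#'     reference treatment.
#' }
#'
#' @param config a [default_config()].
#' @param table optional pre-loaded `trait_table`; defaults to the packaged
#'   trial.
#' @param traits traits to model and optimize.
#' @param families surrogate families to compare.
#' @param output_dir optional directory; when given, the metrics table,
#'   optimization summaries and convergence traces are written there as
#'   CSV/JSON.
#' @return a `run_report`: `metrics` (data frame, one row per family x
#'   trait x split), `selection` (family chosen per trait),
#'   `optimization` (per-trait `optimization_result`), `reduction`
#'   (per-trait percentages), `outliers`, `folds`, and the config echo.
#' @export
run_full_analysis <- function(config = default_config(), table = NULL,
                              traits = trait_names(),
                              families = c("grnn", "mlp"),
                              output_dir = NULL) {
  if (is.null(table)) table <- load_table1()
  if (is.null(table$replicates)) {
    table <- reconstruct_replicates(table, seed = config$seed + 1L)
  }
  rec <- table$records
  flags <- pca_outlier_flags(rec[c("n_g", "k_g", "mg_g",
                                   paste0(TRAITS, "_mean"))],
                             threshold_sd = config$outlier_threshold_sd)
  if (config$outlier_action == "remove" && length(flags) > 0) {
    keep <- setdiff(seq_len(nrow(rec)), flags)
    table$records <- rec[keep, ]
    table$replicates <- table$replicates[table$replicates$treatment %in% keep, ]
    table$replicates$treatment <- match(table$replicates$treatment, keep)
    validate_trait_table(table, factorial = FALSE)
  }
  n_records <- nrow(modelling_frame(table, traits[1]))
  folds <- kfold_split(n_records, config$cv_folds, seed = config$seed + 2L)
  metrics <- list(); cv_fits <- list()
  for (trait in traits) {
    for (family in families) {
      cv <- cv_evaluate(family, table, trait, folds, config,
                        seed = config$seed + 3L)
      cv_fits[[paste(family, trait, sep = ".")]] <- cv
      for (split in c("training", "testing")) {
        m <- cv[[split]]
        metrics[[length(metrics) + 1L]] <- data.frame(
          model = toupper(family), trait = toupper(trait), split = split,
          r2 = m$r2, rmse = m$rmse, mbe = m$mbe,
          hyper = cv$hyper, stringsAsFactors = FALSE)
      }
    }
  }
  metrics <- do.call(rbind, metrics)
  selection <- list(); optimization <- list(); reduction <- list()
  for (ti in seq_along(traits)) {
    trait <- traits[ti]
    test_r2 <- vapply(families, function(fam) {
      cv_fits[[paste(fam, trait, sep = ".")]]$testing$r2
    }, numeric(1))
    fam <- families[which.max(test_r2)]
    selection[[trait]] <- fam
    dat <- modelling_frame(table, trait)
    surrogate <- fit_trait_model(
      fam, as.matrix(dat[, c("n_g", "k_g", "mg_g")]), dat$y, config,
      seed = config$seed + 3L,
      hyper = cv_fits[[paste(fam, trait, sep = ".")]]$hyper)
    ga_cfg <- config$ga
    ga_cfg$seed <- config$seed + 10L * ti
    optimization[[trait]] <- ga_optimize(surrogate$predict, ga_cfg)
    reduction[[trait]] <- compute_reduction(optimization[[trait]]$levels,
                                            config$reference)
  }
  report <- structure(list(metrics = metrics, selection = selection,
                           optimization = optimization, reduction = reduction,
                           outliers = flags, folds = folds, config = config,
                           table = table),
                      class = "run_report")
  if (!is.null(output_dir)) write_run_report(report, output_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Surrogate model comparison (pooled 5-fold CV metrics):\n")
  print(format(x$metrics, digits = 4), row.names = FALSE)
  cat("\nGA dose optima (objective: family with higher testing R2):\n")
  for (trait in names(x$optimization)) {
    o <- x$optimization[[trait]]
    red <- x$reduction[[trait]]
    cat(sprintf(
      "  %-4s [%s]: N %6.2f g, K %6.2f g, Mg %6.2f g -> %8.3f  (reduction %0.f/%0.f/%0.f%%)\n",
      toupper(trait), toupper(x$selection[[trait]]),
      o$levels["n_g"], o$levels["k_g"], o$levels["mg_g"], o$value,
      red["n"], red["k"], red["mg"]))
  }
  if (length(x$outliers) > 0) {
    cat("\nFlagged treatments (PCA score distance):",
        paste(x$outliers, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a run report to disk
#'
#' Emits `metrics.csv`, `optima.json` (doses, predicted values,
#' reductions, configuration echo) and one `convergence_<trait>.csv` per
#' optimized trait.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  optima <- lapply(names(report$optimization), function(trait) {
    o <- report$optimization[[trait]]
    list(trait = toupper(trait), model = toupper(report$selection[[trait]]),
         n_g = unname(o$levels["n_g"]), k_g = unname(o$levels["k_g"]),
         mg_g = unname(o$levels["mg_g"]), predicted = o$value,
         reduction_pct = as.list(report$reduction[[trait]]))
  })
  jsonlite::write_json(
    list(optima = optima,
         seed = report$config$seed,
         folds = as.list(tabulate(report$folds)),
         outliers = report$outliers),
    file.path(dir, "optima.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (trait in names(report$optimization)) {
    utils::write.csv(report$optimization[[trait]]$history,
                     file.path(dir, paste0("convergence_", trait, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
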