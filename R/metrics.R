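#' Regression comparison criteria
#'
#' Computes the three criteria used to compare the surrogate models:
#' the coefficient of determination `R2 = 1 - SS_res / SS_tot` (sums of
#' squares about the observed mean), the root mean square error
#' `RMSE = sqrt(mean((obs - pred)^2))`, and the mean bias error
#' `MBE = mean(pred - obs)` (positive = over-prediction). By construction
#' `RMSE >= |MBE|` and `R2 = 1` exactly when `RMSE = 0`.
#'
#' @param observed,predicted equal-length finite numeric vectors.
#' @return named list `r2`, `rmse`, `mbe`. When the observed values have
#'   zero variance `r2` is `NA` with a warning.
#' @export
compute_metrics <- function(observed, predicted) {
  if (length(observed) == 0 || length(observed) != length(predicted)) {
    stop("need equal-length non-empty vectors", call. = FALSE)
  }
  if (any(!is.finite(observed)) || any(!is.finite(predicted))) {
    stop("metrics require finite values", call. = FALSE)
  }
  res <- observed - predicted
  rmse <- sqrt(mean(res^2))
  mbe <- mean(predicted - observed)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot <= 0) {
    warning("observed values have zero variance; R2 undefined")
    r2 <- NA_real_
  } else {
    r2 <- 1 - sum(res^2) / ss_tot
  }
  list(r2 = r2, rmse = rmse, mbe = mbe)
}

# Fit one model family on a training split and return a predict closure on
# the raw dose scale. Preprocessing (min-max input scaling, Box-Cox on the
# target) is fitted on the training rows only; predictions are returned in
# original trait units.
fit_trait_model <- function(family, x_raw, y_raw, config, seed,
                            inner_folds = NULL, hyper = NULL) {
  scaler <- fit_minmax(x_raw)
  xs <- apply_minmax(scaler, x_raw)
  if (isTRUE(config$boxcox)) {
    bc <- boxcox_fit_transform(y_raw)
    yt <- bc$transformed
  } else {
    bc <- list(lambda = 1, shift = -1)  # identity: (y^1 - 1)/1 shifted back
    yt <- y_raw
  }
  inv <- function(z) {
    if (isTRUE(config$boxcox)) boxcox_inverse(z, bc$lambda, bc$shift) else z
  }
  if (family == "grnn") {
    if (is.null(hyper)) {
      if (is.null(inner_folds)) inner_folds <- kfold_split(length(yt), config$cv_folds, seed)
      hyper <- select_sigma(xs, yt, inner_folds, grid = config$sigma_grid)$sigma
    }
    fit <- grnn_fit(xs, yt, hyper)
    predict_raw <- function(xq) inv(grnn_predict(fit, apply_minmax(scaler, xq)))
  } else if (family == "mlp") {
    if (is.null(hyper)) {
      if (is.null(inner_folds)) inner_folds <- kfold_split(length(yt), config$cv_folds, seed)
      hyper <- select_hidden_size(xs, yt, inner_folds,
                                  candidates = config$mlp_sizes,
                                  restarts = config$mlp_restarts,
                                  seed = seed,
                                  max_iter = config$mlp_max_iter)$p
    }
    fit <- suppressWarnings(train_lm(xs, yt, hyper, seed = seed,
                                     max_iter = config$mlp_max_iter))
    predict_raw <- function(xq) inv(mlp_forward(fit, apply_minmax(scaler, xq)))
  } else {
    stop("unknown model family '", family, "'", call. = FALSE)
  }
  list(family = family, fit = fit, predict = predict_raw,
       scaler = scaler, boxcox = bc, hyper = hyper)
}

#' Cross-validated evaluation of a surrogate family on one trait
#'
#' Runs the shared-fold protocol: for every fold, the model (with the
#' hyper-parameter fixed across folds) is refitted on the remaining folds
#' and predicts both splits. "Training" metrics pool the in-fold fitted
#' predictions across folds and "testing" metrics pool the held-out
#' predictions, both computed in original trait units after inverting the
#' target transform. Folds are assigned over the modelling records
#' (replicates when present), so a held-out replicate may share its
#' treatment with training replicates; testing metrics therefore measure
#' prediction at noise level within the design region, not extrapolation
#' to unseen treatments.
#'
#' @param family `"grnn"` or `"mlp"`.
#' @param table a `trait_table` with replicates (see
#'   [reconstruct_replicates()]); means are used when replicates are absent.
#' @param trait trait code.
#' @param folds integer fold assignment over the modelling records from
#'   [kfold_split()] (length `nrow(table$replicates)`, or
#'   `nrow(table$records)` when fitting to means).
#' @param config pipeline configuration, see [default_config()].
#' @param seed seed for fold-level refits.
#' @param hyper optional fixed hyper-parameter (sigma or hidden size);
#'   selected on the full data with the shared folds when `NULL`.
#' @return list with `training` and `testing` metric lists, `hyper`, and
#'   the pooled prediction tables.
#' @export
cv_evaluate <- function(family, table, trait, folds, config = default_config(),
                        seed = 1L, hyper = NULL) {
  trait <- match_trait(trait)
  dat <- modelling_frame(table, trait)
  if (length(folds) != nrow(dat)) {
    stop("folds must assign one fold per modelling record", call. = FALSE)
  }
  if (min(tabulate(folds)) < 2) stop("every fold needs >= 2 records", call. = FALSE)
  row_fold <- folds
  x <- as.matrix(dat[, c("n_g", "k_g", "mg_g")])
  y <- dat$y
  if (is.null(hyper)) {
    hyper <- fit_trait_model(family, x, y, config, seed,
                             inner_folds = row_fold)$hyper
  }
  train_obs <- train_pred <- test_obs <- test_pred <- numeric(0)
  for (f in sort(unique(row_fold))) {
    tr <- row_fold != f
    m <- fit_trait_model(family, x[tr, , drop = FALSE], y[tr], config,
                         seed = seed + f, hyper = hyper)
    train_obs <- c(train_obs, y[tr])
    train_pred <- c(train_pred, m$predict(x[tr, , drop = FALSE]))
    test_obs <- c(test_obs, y[!tr])
    test_pred <- c(test_pred, m$predict(x[!tr, , drop = FALSE]))
  }
  list(family = family, trait = trait, hyper = hyper,
       training = compute_metrics(train_obs, train_pred),
       testing = compute_metrics(test_obs, test_pred),
       pooled = list(training = data.frame(observed = train_obs,
                                           predicted = train_pred),
                     testing = data.frame(observed = test_obs,
                                          predicted = test_pred)))
}

# Replicate-level modelling frame (falls back to treatment means), with the
# treatment index retained for group-aware fold assignment.
modelling_frame <- function(table, trait) {
  trait <- match_trait(trait)
  if (!is.null(table$replicates)) {
    d <- table$replicates[, c("treatment", "n_g", "k_g", "mg_g")]
    d$y <- table$replicates[[trait]]
  } else {
    d <- table$records[, c("n_g", "k_g", "mg_g")]
    d$treatment <- seq_len(nrow(d))
    d$y <- table$records[[paste0(trait, "_mean")]]
  }
  d
}
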