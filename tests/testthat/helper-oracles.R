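# Independent brute-force oracles and small-table builders used across the
# suite. These deliberately re-derive each quantity from its definition,
# element by element, so they share no code with the implementation.

# GRNN prediction by direct evaluation of the kernel-weighted-mean formula
# (no numerical stabilization).
naive_grnn <- function(x_train, y_train, sigma, query) {
  w <- numeric(nrow(x_train))
  for (i in seq_len(nrow(x_train))) {
    d2 <- sum((query - x_train[i, ])^2)
    w[i] <- exp(-d2 / (2 * sigma^2))
  }
  sum(y_train * w) / sum(w)
}

# MLP forward pass as an explicit double loop over hidden units and inputs.
naive_mlp <- function(model, x_row) {
  acc <- model$b2
  for (j in seq_len(nrow(model$W1))) {
    a <- model$b1[j]
    for (i in seq_len(ncol(model$W1))) a <- a + model$W1[j, i] * x_row[i]
    acc <- acc + model$w2[j] * tanh(a)
  }
  acc
}

# Elementwise metric definitions.
naive_metrics <- function(obs, pred) {
  n <- length(obs)
  se <- 0; bias <- 0
  for (i in seq_len(n)) {
    se <- se + (obs[i] - pred[i])^2
    bias <- bias + (pred[i] - obs[i])
  }
  mu <- sum(obs) / n
  ss_tot <- sum((obs - mu)^2)
  list(r2 = 1 - se / ss_tot, rmse = sqrt(se / n), mbe = bias / n)
}

# UPGMA merge heights by direct agglomeration: at every step merge the two
# groups with the smallest average pairwise distance.
naive_upgma_heights <- function(z) {
  d <- as.matrix(dist(z))
  groups <- as.list(seq_len(nrow(z)))
  heights <- numeric(0)
  while (length(groups) > 1) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(groups)) {
      for (b in seq_along(groups)) {
        if (a >= b) next
        avg <- mean(d[groups[[a]], groups[[b]]])
        if (avg < best[1]) best <- c(avg, a, b)
      }
    }
    heights <- c(heights, best[1])
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
  }
  heights
}

# Minimal trait table from explicit level/mean columns (SEMs default 0).
make_table <- function(levels_df, fy, fl = fy, nrps = fy,
                       fy_sem = 0, fl_sem = 0, nrps_sem = 0,
                       factorial = FALSE) {
  rec <- data.frame(levels_df,
                    fy_mean = fy, fy_sem = fy_sem,
                    fl_mean = fl, fl_sem = fl_sem,
                    nrps_mean = nrps, nrps_sem = nrps_sem)
  tab <- grnnga:::new_trait_table(rec)
  grnnga:::validate_trait_table(tab, factorial = factorial)
  tab
}
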