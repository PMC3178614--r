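# shared fixtures, all built in code

# deterministic single-gradient stack: layer value = scaled column index
tiny_gradient_stack <- function(n_rows = 10L, n_cols = 10L) {
  g <- build_grid(c(west = 0, east = 1, south = 0, north = 1),
                  1 / n_cols)
  g$n_rows <- n_rows
  g$south <- g$north - n_rows * g$cell_size
  col <- rep(seq_len(n_cols), times = n_rows)
  layer_stack(g, list(layer("grad1", (col - 1) / (n_cols - 1),
                            "continuous")))
}

# occurrence_set straight from a data.frame
occ_from_df <- function(df) {
  defaults <- list(uncertainty_m = 100, year = 2000L, vouchered = TRUE,
                   source_id = NA_character_)
  for (nm in names(defaults))
    if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  sdmbaseline:::new_occurrence_set(df)
}

# record content of an occurrence set, provenance attributes stripped
records_of <- function(occ) {
  df <- data.frame(occ)
  rownames(df) <- NULL
  df
}

# hand-built suitability surface over an n-cell background
surface_from_scores <- function(logistic, raw = NULL, grid = NULL) {
  n <- length(logistic)
  if (is.null(raw)) raw <- logistic / sum(logistic)
  H <- -sum(raw * log(raw))
  structure(list(grid = grid, raw = raw, logistic = logistic,
                 background_cells = seq_len(n), H = H),
            class = "suitability_surface")
}

# validation_report with chosen summary quantities (omission p constant)
report_with <- function(train_auc, test_auc, p = 1e-4, n_rep = 5) {
  omission <- data.frame(replicate = rep(seq_len(n_rep), each = 2),
                         threshold = "fixed", value = 0.5,
                         partition = rep(c("train", "test"), n_rep),
                         omission = 0, area = 0.1, p = p)
  structure(list(species_id = "x",
                 mean_train_auc = mean(train_auc),
                 mean_test_auc = mean(test_auc),
                 auc_gap = abs(mean(train_auc) - mean(test_auc)) /
                   mean(train_auc),
                 train_auc = train_auc, test_auc = test_auc,
                 omission = omission, n_rep = n_rep),
            class = "validation_report")
}

# independent objective for the maxent oracle: same convex objective,
# evaluated directly (no shared code with fit_maxent)
oracle_objective <- function(lambda, Fp, Fb, beta) {
  eta <- as.numeric(Fb %*% lambda)
  -mean(as.numeric(Fp %*% lambda)) + log(sum(exp(eta))) +
    sum(beta * abs(lambda))
}

# dense coarse-to-fine grid search minimizing oracle_objective
oracle_grid_search <- function(Fp, Fb, beta, lower = -10, upper = 10,
                               rounds = 8, pts = 11) {
  p <- ncol(Fb)
  lo <- rep(lower, p); hi <- rep(upper, p)
  best <- rep(0, p)
  for (r in seq_len(rounds)) {
    grids <- lapply(seq_len(p), function(j) seq(lo[j], hi[j],
                                                length.out = pts))
    cand <- as.matrix(expand.grid(grids))
    vals <- apply(cand, 1, oracle_objective, Fp = Fp, Fb = Fb, beta = beta)
    best <- cand[which.min(vals), ]
    step <- (hi - lo) / (pts - 1)
    lo <- best - step; hi <- best + step
  }
  as.numeric(best)
}
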