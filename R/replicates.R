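#' Fit a replicated ensemble of maxent models for one species
#'
#' Runs the replicated split-sample scheme: in each replicate a random
#' `test_frac` share of the species' presence cells (rounded, minimum one
#' cell) is withheld as test records and the model is fitted on the
#' remaining training cells only. Each replicate stores its train/test
#' split, fitted model, suitability surface, train and test AUC, and the
#' binomial omission tests at the standard eleven thresholds for both
#' partitions. The whole ensemble is reproducible from `seed`.
#'
#' @param cells integer grid cell ids of the species' unique presence cells
#'   (modelling eligibility requires at least 10), or one row of a
#'   [snap_and_deduplicate()] result.
#' @param stack a `layer_stack`.
#' @param n_rep number of replicates (default 100).
#' @param test_frac share of cells withheld for testing (default 0.4).
#' @param seed integer RNG seed.
#' @param reg_multiplier,tol,max_iter passed to [fit_maxent()].
#' @param background_max background size cap: all valid cells are used when
#'   there are at most this many, otherwise a seeded uniform sample of this
#'   size (default 10000).
#' @param classes,n_hinge,n_threshold passed to [expand_features()].
#' @param min_cells eligibility floor on unique presence cells (default 10).
#' @param species_id provenance label.
#' @return a `replicate_ensemble`: per-replicate results, the mean logistic
#'   surface over replicates, and configuration.
#' @export
run_replicates <- function(cells, stack, n_rep = 100L, test_frac = 0.4,
                           seed = 1L, reg_multiplier = 1.0, tol = 1e-5,
                           max_iter = 500L, background_max = 10000L,
                           classes = "auto", n_hinge = 8L, n_threshold = 8L,
                           min_cells = 10L, species_id = NA_character_) {
  if (is.data.frame(cells)) {
    species_id <- cells$species_id[1]
    cells <- cells$cell_ids[[1]]
  }
  cells <- sort(unique(as.integer(cells)))
  n <- length(cells)
  if (n < min_cells)
    stop("species ", species_id, ": only ", n, " unique cells; at least ",
         min_cells, " required for modelling")
  if (test_frac <= 0 || test_frac >= 1) stop("test_frac must be in (0,1)")
  n_test <- max(1L, round(test_frac * n))
  n_train <- n - n_test
  set.seed(seed)
  valid_cells <- which(stack$valid)
  bg <- if (length(valid_cells) <= background_max) valid_cells
        else sort(sample(valid_cells, background_max))
  features <- expand_features(stack, n_presence = n_train, classes = classes,
                              n_hinge = n_hinge, n_threshold = n_threshold)
  ib <- feature_rows(features, bg)
  replicates <- vector("list", n_rep)
  sum_logistic <- 0
  for (r in seq_len(n_rep)) {
    test <- sort(sample(cells, n_test))
    train <- setdiff(cells, test)
    model <- fit_maxent(train, bg, features, reg_multiplier = reg_multiplier,
                        tol = tol, max_iter = max_iter)
    surf <- predict(model, features)
    bg_scores <- surf$logistic[bg]
    train_auc <- compute_auc(surf$logistic[train], bg_scores)
    test_auc <- compute_auc(surf$logistic[test], bg_scores)
    omis <- binomial_omission_tests(surf, train, test)
    replicates[[r]] <- list(train = train, test = test, model = model,
                            surface = surf, train_auc = train_auc,
                            test_auc = test_auc, omission = omis)
    sum_logistic <- sum_logistic + surf$logistic
  }
  structure(list(species_id = species_id, cells = cells,
                 replicates = replicates, n_rep = n_rep,
                 test_frac = test_frac, n_train = n_train, n_test = n_test,
                 seed = seed, background_cells = bg,
                 mean_logistic = sum_logistic / n_rep,
                 grid = stack$grid, set_id = stack$set_id),
            class = "replicate_ensemble")
}

#' @export
print.replicate_ensemble <- function(x, ...) {
  cat(sprintf(
    "replicate_ensemble: %s, %d cells (%d train / %d test), %d replicates\n",
    x$species_id, length(x$cells), x$n_train, x$n_test, x$n_rep))
  cat(sprintf("  mean train AUC %.4f, mean test AUC %.4f\n",
              mean(vapply(x$replicates, `[[`, numeric(1), "train_auc")),
              mean(vapply(x$replicates, `[[`, numeric(1), "test_auc"))))
  invisible(x)
}

#' Ensemble summary table
#'
#' @param ensemble a `replicate_ensemble`.
#' @return data.frame with one row per replicate: train and test AUC and the
#'   worst (largest) omission p-value.
#' @export
ensemble_summary <- function(ensemble) {
  data.frame(
    replicate = seq_len(ensemble$n_rep),
    train_auc = vapply(ensemble$replicates, `[[`, numeric(1), "train_auc"),
    test_auc = vapply(ensemble$replicates, `[[`, numeric(1), "test_auc"),
    max_omission_p = vapply(ensemble$replicates,
                            function(r) max(r$omission$p), numeric(1)))
}
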