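#' Configuration for the synthetic landscape and virtual-species simulator
#'
#' The simulator emulates the kind of data the pipeline consumes in the
#' field: smooth continuous environmental gradients plus categorical region
#' layers on a regular grid, virtual species with known logistic niches,
#' museum-style occurrence records carrying a georeferencing-error radius,
#' collection year and voucher flag, and site-by-species survey abundance
#' matrices. All outputs are deterministic under `seed`.
#'
#' @param n_rows,n_cols grid dimensions (default 50 x 50).
#' @param bounds lon/lat bounding box (default a 1-degree square, giving
#'   roughly 2 km cells at 50 x 50 — the order of magnitude of a 30
#'   arc-second analysis grid).
#' @param n_continuous number of continuous gradient layers (default 2).
#' @param n_categorical number of categorical region layers (default 1).
#' @param n_categories categories per categorical layer (default 4).
#' @param n_species number of virtual species (default 5).
#' @param n_records occurrence records sampled per species (default 60).
#' @param error_model georeference-error mixture: probability and radius
#'   ranges (meters) of "small" (passes a 1 km filter) and "large" (fails)
#'   errors. Default plants 20 percent large errors so the precision filter
#'   is always exercised.
#' @param year_model collection-year distribution spanning both sides of
#'   1950 (default uniform 1930-2010) so the temporal filter is exercised.
#' @param p_vouchered probability a record is vouchered (default 0.85).
#' @param seed RNG seed (default 1).
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(n_rows = 50L, n_cols = 50L,
                              bounds = c(west = -98, east = -97,
                                         south = 30, north = 31),
                              n_continuous = 2L, n_categorical = 1L,
                              n_categories = 4L, n_species = 5L,
                              n_records = 60L,
                              error_model = list(p_large = 0.2,
                                                 small = c(0, 1000),
                                                 large = c(1500, 5000)),
                              year_model = list(min = 1930L, max = 2010L),
                              p_vouchered = 0.85, seed = 1L) {
  cfg <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              bounds = bounds, n_continuous = as.integer(n_continuous),
              n_categorical = as.integer(n_categorical),
              n_categories = as.integer(n_categories),
              n_species = as.integer(n_species),
              n_records = as.integer(n_records),
              error_model = error_model, year_model = year_model,
              p_vouchered = p_vouchered, seed = as.integer(seed))
  with(cfg, stopifnot(n_rows >= 1, n_cols >= 1, n_continuous >= 0,
                      n_categorical >= 0, n_categories >= 1,
                      n_species >= 1, n_records >= 1,
                      p_vouchered > 0, p_vouchered <= 1))
  if (!is.null(error_model$p_large))
    stopifnot(error_model$p_large >= 0, error_model$p_large <= 1)
  structure(cfg, class = "simulation_config")
}

# smooth a grid-shaped matrix with a separable moving-average kernel
smooth_matrix <- function(m, passes = 3L, span = 5L) {
  k <- rep(1 / span, span)
  pad <- span %/% 2
  for (i in seq_len(passes)) {
    m <- t(apply(m, 1, function(r)
      stats::filter(c(rep(r[1], pad), r, rep(r[length(r)], pad)), k)[
        (pad + 1):(pad + length(r))]))
    m <- apply(m, 2, function(r)
      stats::filter(c(rep(r[1], pad), r, rep(r[length(r)], pad)), k)[
        (pad + 1):(pad + length(r))])
  }
  m
}

#' Generate a synthetic environmental layer stack
#'
#' Continuous layers are a random low-order polynomial trend plus smoothed
#' Gaussian noise (so niches along them are spatially coherent, as real
#' climatic gradients are); categorical layers are contiguous regions built
#' as the nearest-seed (Voronoi) partition of random seed points. The stack
#' has full validity.
#'
#' @param cfg a [simulation_config()].
#' @return a `layer_stack` on the configured grid.
#' @export
generate_layers <- function(cfg) {
  set.seed(cfg$seed)
  grid <- build_grid(cfg$bounds,
                     (cfg$bounds[["east"]] - cfg$bounds[["west"]]) / cfg$n_cols)
  # bounds may not give square cells for arbitrary n_rows; rebuild exactly
  grid$n_rows <- cfg$n_rows
  grid$south <- grid$north - grid$n_rows * grid$cell_size
  rows <- matrix(seq_len(cfg$n_rows), cfg$n_rows, cfg$n_cols)
  cols <- matrix(seq_len(cfg$n_cols), cfg$n_rows, cfg$n_cols, byrow = TRUE)
  u <- (rows - 1) / max(1, cfg$n_rows - 1)
  v <- (cols - 1) / max(1, cfg$n_cols - 1)
  lyrs <- list()
  for (i in seq_len(cfg$n_continuous)) {
    cf <- stats::rnorm(5)
    trend <- cf[1] * u + cf[2] * v + cf[3] * u * v + cf[4] * u^2 + cf[5] * v^2
    noise <- smooth_matrix(matrix(stats::rnorm(cfg$n_rows * cfg$n_cols),
                                  cfg$n_rows, cfg$n_cols))
    m <- trend + 0.5 * noise / max(stats::sd(noise), 1e-9)
    m <- (m - mean(m)) / stats::sd(m)
    lyrs[[paste0("grad", i)]] <- layer(paste0("grad", i),
                                       as.numeric(t(m)), "continuous")
  }
  for (i in seq_len(cfg$n_categorical)) {
    seeds_r <- stats::runif(cfg$n_categories, 1, cfg$n_rows)
    seeds_c <- stats::runif(cfg$n_categories, 1, cfg$n_cols)
    d <- sapply(seq_len(cfg$n_categories), function(k)
      (as.numeric(t(rows)) - seeds_r[k])^2 + (as.numeric(t(cols)) - seeds_c[k])^2)
    lab <- max.col(-d)
    lyrs[[paste0("region", i)]] <- layer(paste0("region", i), lab,
                                         "categorical",
                                         categories = seq_len(cfg$n_categories))
  }
  layer_stack(grid, lyrs, set_id = "synthetic")
}

#' Define a virtual species with a known logistic niche
#'
#' True suitability is logistic-linear in the continuous layers with an
#' optional additive bonus inside preferred categories:
#' \eqn{s(x) = logit^{-1}(\alpha + \sum_l \beta_l \, env_l(x) + bonus)}.
#'
#' @param species_id name.
#' @param alpha intercept (controls overall prevalence).
#' @param beta named numeric vector of slopes per continuous layer.
#' @param cat_pref optional named list: categorical layer name -> numeric
#'   vector of per-category bonuses.
#' @param native native flag (default TRUE).
#' @param detectability sampling detectability in (0, 1\] (default 1).
#' @return a `virtual_species`.
#' @export
virtual_species <- function(species_id, alpha = 0, beta = c(grad1 = 2),
                            cat_pref = NULL, native = TRUE,
                            detectability = 1.0) {
  stopifnot(is.finite(alpha), all(is.finite(beta)),
            detectability > 0, detectability <= 1)
  structure(list(species_id = species_id, alpha = alpha, beta = beta,
                 cat_pref = cat_pref, native = native,
                 detectability = detectability),
            class = "virtual_species")
}

#' True suitability of a virtual species over a stack
#'
#' @param sp a `virtual_species`.
#' @param stack a `layer_stack` containing the layers named in the niche.
#' @return numeric vector over grid cells (`NA` outside validity).
#' @export
true_suitability <- function(sp, stack) {
  eta <- rep(sp$alpha, n_cells(stack$grid))
  for (nm in names(sp$beta)) {
    if (is.null(stack$layers[[nm]]))
      stop("niche references unknown layer '", nm, "'")
    eta <- eta + sp$beta[[nm]] * stack$layers[[nm]]$values
  }
  for (nm in names(sp$cat_pref)) {
    codes <- stack$layers[[nm]]$values
    eta <- eta + sp$cat_pref[[nm]][codes]
  }
  s <- 1 / (1 + exp(-eta))
  s[!stack$valid] <- NA
  s
}

#' Sample museum-style occurrence records for a virtual species
#'
#' Cells are drawn (with replacement) with probability proportional to
#' true suitability times detectability; each record gets a uniform point
#' within its cell, a reported georeferencing-error radius from the
#' small/large error mixture, a collection year from the year model, and a
#' voucher flag. Passing `exclude_mask` suppresses sampling inside a region
#' (used to emulate a species never collected in the focal watershed).
#'
#' @param sp a `virtual_species`.
#' @param stack a `layer_stack`.
#' @param n number of records.
#' @param cfg a [simulation_config()] supplying error/year/voucher models.
#' @param seed RNG seed (default: cfg's seed).
#' @param exclude_mask optional [region_mask()]; no records are drawn from
#'   cells inside it.
#' @return an `occurrence_set`.
#' @export
sample_occurrences <- function(sp, stack, n, cfg = simulation_config(),
                               seed = cfg$seed, exclude_mask = NULL) {
  stopifnot(n >= 1)
  set.seed(seed)
  s <- true_suitability(sp, stack)
  w <- s * sp$detectability
  w[is.na(w)] <- 0
  if (!is.null(exclude_mask)) w[as.logical(exclude_mask)] <- 0
  if (sum(w) <= 0) stop("species has zero sampling weight everywhere")
  cells <- sample(seq_along(w), n, replace = TRUE, prob = w)
  ctr <- cell_center(stack$grid, cells)
  half <- stack$grid$cell_size / 2
  lon <- ctr$lon + stats::runif(n, -half, half)
  lat <- ctr$lat + stats::runif(n, -half, half)
  em <- cfg$error_model
  large <- stats::runif(n) < em$p_large
  unc <- ifelse(large,
                stats::runif(n, em$large[1], em$large[2]),
                stats::runif(n, em$small[1], em$small[2]))
  yr <- as.integer(round(stats::runif(n, cfg$year_model$min,
                                      cfg$year_model$max)))
  rec <- data.frame(species_id = sp$species_id, lon = lon, lat = lat,
                    uncertainty_m = unc, year = yr,
                    vouchered = stats::runif(n) < cfg$p_vouchered,
                    source_id = sprintf("sim-%s-%04d", sp$species_id,
                                        seq_len(n)),
                    stringsAsFactors = FALSE)
  new_occurrence_set(rec, sprintf(
    "simulated %d records for %s (seed %d)", n, sp$species_id, seed))
}

#' Synthesize an occurrence table with planted quality violations
#'
#' Writes a CSV with known, disjoint counts of records violating each
#' quality rule — a large (> 1 km) georeferencing-error radius, a pre-1950
#' collection year, or a missing voucher — alongside fully compliant
#' records, so a downstream filter report can be checked against the
#' planted truth exactly. Each planted violator breaks exactly one rule.
#'
#' @param path output CSV path.
#' @param n_clean number of compliant records.
#' @param n_large_error records with uncertainty radius > 1 km.
#' @param n_old records collected before 1950.
#' @param n_unvouchered records lacking a voucher.
#' @param species_id species name used throughout.
#' @param seed RNG seed.
#' @return (invisibly) the planted counts as a named list.
#' @export
synthesize_occurrence_table <- function(path, n_clean = 20L,
                                        n_large_error = 5L, n_old = 3L,
                                        n_unvouchered = 4L,
                                        species_id = "Virtualis cleanus",
                                        seed = 1L) {
  set.seed(seed)
  n_clean <- as.integer(n_clean); n_large_error <- as.integer(n_large_error)
  n_old <- as.integer(n_old); n_unvouchered <- as.integer(n_unvouchered)
  n <- n_clean + n_large_error + n_old + n_unvouchered
  grp <- rep(c("clean", "error", "old", "unvouchered"),
             c(n_clean, n_large_error, n_old, n_unvouchered))
  rec <- data.frame(
    species = species_id,
    decimalLongitude = stats::runif(n, -98, -97),
    decimalLatitude = stats::runif(n, 30, 31),
    coordinateUncertaintyInMeters = ifelse(grp == "error",
                                           stats::runif(n, 1500, 5000),
                                           stats::runif(n, 10, 900)),
    year = ifelse(grp == "old", sample(1900:1949, n, replace = TRUE),
                  sample(1960:2005, n, replace = TRUE)),
    vouchered = grp != "unvouchered",
    stringsAsFactors = FALSE)
  utils::write.csv(rec, path, row.names = FALSE)
  invisible(list(n_clean = n_clean, n_large_error = n_large_error,
                 n_old = n_old, n_unvouchered = n_unvouchered, n_total = n))
}

#' Sample a site-by-species survey abundance matrix
#'
#' Per-site, per-species abundance is Poisson with mean
#' `effort * s(site) * detectability` — a thinned count proportional to
#' local true suitability. The expected composition is stored alongside the
#' realized counts for ground-truth checks.
#'
#' @param community list of `virtual_species`.
#' @param stack a `layer_stack`.
#' @param sites integer cell ids of the survey sites.
#' @param effort expected count per site for a species at suitability 1
#'   (default 30).
#' @param seed RNG seed.
#' @return sites x species integer matrix (class `assemblage_matrix`) with
#'   attribute `expected` (the Poisson means) and `sites` (cell ids).
#' @export
sample_survey <- function(community, stack, sites, effort = 30, seed = 1L) {
  bad <- sites < 1 | sites > n_cells(stack$grid)
  if (any(bad)) stop("survey sites outside grid")
  set.seed(seed)
  S <- sapply(community, function(sp)
    true_suitability(sp, stack)[sites] * sp$detectability)
  S <- matrix(S, nrow = length(sites))
  expected <- effort * S
  counts <- matrix(stats::rpois(length(expected), expected),
                   nrow = length(sites))
  dimnames(counts) <- list(paste0("site_", sites),
                           vapply(community, `[[`, character(1),
                                  "species_id"))
  dimnames(expected) <- dimnames(counts)
  structure(counts, class = c("assemblage_matrix", class(counts)),
            expected = expected, sites = sites, effort = effort,
            seed = seed)
}
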