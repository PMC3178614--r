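#' Pipeline configuration with field-standard defaults
#'
#' Defaults follow the study-design values used throughout the package:
#' records filtered at a 1 km georeferencing-error radius, a 1950 earliest
#' collection year and vouchered records only; 100 model replicates
#' withholding 40 percent of cells as test records; acceptance at mean test
#' AUC > 0.9, all omission p-values < 0.05 and a < 5 percent train/test AUC
#' gap; and a 0.5 suitability threshold for the modeled-but-undocumented
#' classification.
#'
#' @param filter list: `max_uncertainty_km`, `min_year`, `vouchered_only`.
#' @param model list: `n_rep`, `test_frac`, `reg_multiplier`,
#'   `background_max`, `min_cells`.
#' @param acceptance list: `auc_min`, `p_max`, `gap_max`, `gap_relative`.
#' @param community list: `threshold`, `aggregate`.
#' @param seed integer master seed.
#' @param out_dir optional directory for artifact output.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(filter = list(), model = list(),
                            acceptance = list(), community = list(),
                            seed = 1L, out_dir = NULL) {
  merge <- function(defaults, user) utils::modifyList(defaults, user)
  cfg <- list(
    filter = merge(list(max_uncertainty_km = 1, min_year = 1950L,
                        vouchered_only = TRUE), filter),
    model = merge(list(n_rep = 100L, test_frac = 0.4, reg_multiplier = 1.0,
                       background_max = 10000L, min_cells = 10L), model),
    acceptance = merge(list(auc_min = 0.9, p_max = 0.05, gap_max = 0.05,
                            gap_relative = TRUE), acceptance),
    community = merge(list(threshold = 0.5, aggregate = "mean_surface"),
                      community),
    seed = as.integer(seed), out_dir = out_dir)
  with(cfg$model, {
    if (test_frac <= 0 || test_frac >= 1)
      stop("config error: test_frac must be in (0,1)")
    if (n_rep < 1) stop("config error: n_rep must be >= 1")
  })
  with(cfg$filter, {
    if (max_uncertainty_km <= 0) stop("config error: max_uncertainty_km <= 0")
    if (min_year <= 0) stop("config error: min_year <= 0")
  })
  with(cfg$acceptance, {
    if (auc_min <= 0 || auc_min >= 1) stop("config error: auc_min not in (0,1)")
    if (p_max <= 0 || p_max >= 1) stop("config error: p_max not in (0,1)")
  })
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Values present in the file override the defaults of [pipeline_config()].
#'
#' @param path YAML file with any of the sections `filter`, `model`,
#'   `acceptance`, `community`, plus optional `seed` and `out_dir`.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(filter = y$filter %||% list(),
                  model = y$model %||% list(),
                  acceptance = y$acceptance %||% list(),
                  community = y$community %||% list(),
                  seed = y$seed %||% 1L, out_dir = y$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full reconstruction pipeline
#'
#' Executes filter -> snap -> model -> validate -> community (-> survey
#' comparison) and returns an artifact bundle. Each stage failure aborts
#' with an error naming the stage.
#'
#' @param cfg a [pipeline_config()].
#' @param occurrences an `occurrence_set` (or CSV path readable by
#'   [load_occurrences()]).
#' @param stack a `layer_stack` of environmental variables.
#' @param watershed a [region_mask()] for the focal watershed.
#' @param detections data.frame of per-species collection-event counts
#'   (`species_id`, `survey_A`, `survey_B`, `historical`); may be empty.
#' @param native named logical vector: species id -> native flag. Species
#'   missing from it are treated as native.
#' @param surveys optional named list of two or more site x species
#'   abundance matrices for the assemblage comparison.
#' @return a `pipeline_result` bundle: filtered records and filter report,
#'   per-species ensembles, validation reports and acceptance decisions,
#'   the modeled community table, the survey comparison (Bray-Curtis +
#'   Mantel) when surveys were given, and a run manifest.
#' @export
run_pipeline <- function(cfg, occurrences, stack, watershed,
                         detections = NULL, native = NULL, surveys = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  if (is.character(occurrences))
    occurrences <- stage("load", load_occurrences(occurrences))
  filtered <- stage("filter", filter_records(
    occurrences, cfg$filter$max_uncertainty_km, cfg$filter$min_year,
    cfg$filter$vouchered_only))
  cells <- stage("snap", snap_and_deduplicate(filtered, stack$grid))
  eligible <- cells[cells$n_cells >= cfg$model$min_cells, , drop = FALSE]
  if (nrow(eligible) == 0)
    stop("pipeline stage 'model' failed: no species meets the ",
         cfg$model$min_cells, "-cell eligibility rule", call. = FALSE)
  ensembles <- list(); reports <- list(); decisions <- list()
  for (i in seq_len(nrow(eligible))) {
    sp <- eligible$species_id[i]
    ens <- stage("model", run_replicates(
      eligible$cell_ids[[i]], stack, n_rep = cfg$model$n_rep,
      test_frac = cfg$model$test_frac, seed = cfg$seed + i,
      reg_multiplier = cfg$model$reg_multiplier,
      background_max = cfg$model$background_max,
      min_cells = cfg$model$min_cells, species_id = sp))
    rep <- stage("validate", validation_report(ens))
    dec <- stage("validate", evaluate_acceptance(
      rep, cfg$acceptance$auc_min, cfg$acceptance$p_max,
      cfg$acceptance$gap_max, cfg$acceptance$gap_relative))
    ensembles[[sp]] <- ens; reports[[sp]] <- rep; decisions[[sp]] <- dec
  }
  accepted <- ensembles[vapply(decisions, `[[`, logical(1), "accepted")]
  if (is.null(detections))
    detections <- data.frame(species_id = character(0), survey_A = integer(0),
                             survey_B = integer(0), historical = integer(0))
  if (is.null(native)) {
    native <- rep(TRUE, length(ensembles))
    names(native) <- names(ensembles)
  }
  community <- NULL
  if (length(accepted)) {
    extra <- data.frame(
      species_id = names(accepted),
      mean_test_auc = vapply(names(accepted), function(s)
        reports[[s]]$mean_test_auc, numeric(1)),
      variable_set = if (is.null(stack$set_id)) NA_character_ else stack$set_id,
      n_records = vapply(names(accepted), function(s)
        length(ensembles[[s]]$cells), numeric(1)),
      stringsAsFactors = FALSE)
    community <- stage("community", build_modeled_community(
      accepted, watershed, detections, native,
      threshold = cfg$community$threshold,
      aggregate = cfg$community$aggregate, extra = extra))
  }
  comparison <- NULL
  if (!is.null(surveys) && length(surveys) >= 2) {
    comparison <- stage("compare", {
      d <- lapply(surveys, bray_curtis)
      list(distances = d,
           mantel = mantel_test(d[[1]], d[[2]], seed = cfg$seed))
    })
  }
  manifest <- list(
    seed = cfg$seed,
    config = unclass(cfg),
    n_records_in = nrow(occurrences), n_records_filtered = nrow(filtered),
    n_species_eligible = nrow(eligible),
    n_species_accepted = length(accepted),
    package_version = as.character(utils::packageVersion("sdmbaseline")))
  result <- structure(list(
    filtered = filtered, filter_report = attr(filtered, "filter_report"),
    cells = cells, ensembles = ensembles, reports = reports,
    decisions = decisions, community = community, comparison = comparison,
    manifest = manifest), class = "pipeline_result")
  if (!is.null(cfg$out_dir)) write_pipeline_bundle(result, cfg$out_dir)
  result
}

write_pipeline_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_occurrences(result$filtered, file.path(out_dir, "filtered.csv"),
                    file.path(out_dir, "filter_report.json"))
  if (!is.null(result$community))
    utils::write.csv(as.data.frame(result$community),
                     file.path(out_dir, "modeled_community.csv"),
                     row.names = FALSE)
  val <- do.call(rbind, lapply(result$reports, function(r)
    data.frame(species_id = r$species_id, mean_train_auc = r$mean_train_auc,
               mean_test_auc = r$mean_test_auc, auc_gap = r$auc_gap)))
  if (!is.null(val))
    utils::write.csv(val, file.path(out_dir, "validation.csv"),
                     row.names = FALSE)
  dec <- do.call(rbind, lapply(result$decisions, function(d)
    data.frame(species_id = d$species_id, accepted = d$accepted,
               criterion_i = d$criterion_i, criterion_ii = d$criterion_ii,
               criterion_iii = d$criterion_iii)))
  if (!is.null(dec))
    utils::write.csv(dec, file.path(out_dir, "acceptance.csv"),
                     row.names = FALSE)
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "pipeline_result: %d -> %d records, %d eligible species, %d accepted\n",
    m$n_records_in, m$n_records_filtered, m$n_species_eligible,
    m$n_species_accepted))
  if (!is.null(x$comparison))
    print(x$comparison$mantel)
  invisible(x)
}
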