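#' Maximum modeled suitability inside a watershed
#'
#' Extracts, for one species' accepted ensemble, the maximum logistic
#' suitability over the watershed's cells — a coarse-scale proxy for the
#' species' potential to establish there. By default the per-species surface
#' is the cell-wise mean of the replicate logistic surfaces (stable against
#' replicate noise); `aggregate = "per_replicate_max"` instead takes the
#' maximum within the watershed per replicate and averages those maxima.
#'
#' @param ensemble a `replicate_ensemble`.
#' @param watershed a [region_mask()] on the ensemble's grid.
#' @param aggregate `"mean_surface"` (default) or `"per_replicate_max"`.
#' @return maximum watershed probability in \[0,1\].
#' @export
extract_watershed_max <- function(ensemble, watershed,
                                  aggregate = c("mean_surface",
                                                "per_replicate_max")) {
  aggregate <- match.arg(aggregate)
  w <- as.logical(watershed)
  if (aggregate == "mean_surface") {
    vals <- ensemble$mean_logistic[w]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0)
      stop("watershed mask '", attr(watershed, "mask_id"),
           "' overlaps no valid cells")
    max(vals)
  } else {
    maxima <- vapply(ensemble$replicates, function(r) {
      vals <- r$surface$logistic[w]
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0)
        stop("watershed mask '", attr(watershed, "mask_id"),
             "' overlaps no valid cells")
      max(vals)
    }, numeric(1))
    mean(maxima)
  }
}

#' Build the modeled historical community table
#'
#' Joins per-species maximum watershed suitability (from accepted ensembles
#' only) with detection-event counts from the two surveys and the historical
#' record, and classifies each species: `documented` when any source
#' recorded it; `modeled-but-undocumented` when a native species with zero
#' detections anywhere has maximum watershed probability above `threshold`
#' (the signal that the species plausibly belonged to the historical
#' community); `low-suitability` otherwise. Undetected non-native species
#' with high suitability are never labelled modeled-but-undocumented; they
#' carry a `potential-invader` note instead.
#'
#' @param accepted_models named list (species id -> `replicate_ensemble`) of
#'   models that passed [evaluate_acceptance()].
#' @param watershed a [region_mask()] for the focal watershed.
#' @param detections data.frame with columns `species_id`, `survey_A`,
#'   `survey_B`, `historical` (collection-event counts); species absent from
#'   it count zero everywhere.
#' @param native named logical vector: species id -> native flag.
#' @param threshold suitability cut for the undocumented classification
#'   (default 0.5).
#' @param aggregate passed to [extract_watershed_max()].
#' @param extra optional data.frame keyed by `species_id` with columns
#'   `mean_test_auc`, `variable_set`, `n_records` to carry into the table.
#' @return a `modeled_community` data.frame sorted by
#'   `max_watershed_probability` descending (species id breaks ties), with
#'   per-source counts, `total`, `status`, and `note` columns.
#' @export
build_modeled_community <- function(accepted_models, watershed, detections,
                                    native, threshold = 0.5,
                                    aggregate = "mean_surface",
                                    extra = NULL) {
  stopifnot(length(accepted_models) >= 1)
  sp <- names(accepted_models)
  get_count <- function(s, col) {
    i <- match(s, detections$species_id)
    if (is.na(i) || is.null(detections[[col]])) 0L
    else as.integer(detections[[col]][i])
  }
  rows <- lapply(sp, function(s) {
    mx <- extract_watershed_max(accepted_models[[s]], watershed,
                                aggregate = aggregate)
    a <- get_count(s, "survey_A"); b <- get_count(s, "survey_B")
    h <- get_count(s, "historical")
    tot <- a + b + h
    nat <- isTRUE(unname(native[s]))
    status <- if (tot > 0) "documented"
    else if (nat && mx > threshold) "modeled-but-undocumented"
    else "low-suitability"
    note <- if (!nat && tot == 0 && mx > threshold) "potential-invader" else ""
    data.frame(species_id = s, native = nat,
               max_watershed_probability = mx,
               survey_A = a, survey_B = b, historical = h, total = tot,
               status = status, note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(extra)) {
    i <- match(out$species_id, extra$species_id)
    for (col in intersect(c("mean_test_auc", "variable_set", "n_records"),
                          names(extra)))
      out[[col]] <- extra[[col]][i]
  }
  out <- out[order(-out$max_watershed_probability, out$species_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "watershed_id") <- attr(watershed, "mask_id")
  attr(out, "threshold") <- threshold
  class(out) <- c("modeled_community", "data.frame")
  out
}

#' @export
print.modeled_community <- function(x, ...) {
  cat(sprintf("modeled_community: %d species in watershed '%s' (threshold %g)\n",
              nrow(x), attr(x, "watershed_id"), attr(x, "threshold")))
  print.data.frame(x, digits = 3)
  invisible(x)
}
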