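#' Default column mapping for occurrence tables
#'
#' Darwin-Core-flavoured defaults used by [load_occurrences()].
#' @export
default_occurrence_schema <- function() {
  list(species_id = "species",
       lat = "decimalLatitude",
       lon = "decimalLongitude",
       uncertainty_m = "coordinateUncertaintyInMeters",
       year = "year",
       vouchered = "vouchered",
       source_id = "source_id")
}

new_occurrence_set <- function(records, log = character(0)) {
  structure(records, class = c("occurrence_set", "data.frame"),
            filter_log = log)
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set: %d records, %d species\n",
              nrow(x), length(unique(x$species_id))))
  for (l in attr(x, "filter_log")) cat(" ", l, "\n")
  invisible(x)
}

append_log <- function(occ, msg) {
  attr(occ, "filter_log") <- c(attr(occ, "filter_log"), msg)
  occ
}

#' Load presence-only occurrence records from a delimited table
#'
#' Every parseable row becomes a record; rows with unparseable or
#' out-of-range coordinates are dropped and counted in the provenance log.
#' `source_id` and `uncertainty_m` may be absent from the file (filled with
#' `NA`); the coordinate, species, year and voucher columns are mandatory.
#'
#' @param path CSV/TSV file.
#' @param schema named list mapping record fields to column names; see
#'   [default_occurrence_schema()].
#' @param sep field separator (default `","`).
#' @return an `occurrence_set` (data.frame of records with a filter log).
#' @export
load_occurrences <- function(path, schema = default_occurrence_schema(),
                             sep = ",") {
  if (!file.exists(path)) stop("occurrence file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0) {
    warning("empty occurrence file: ", path)
    return(new_occurrence_set(
      data.frame(species_id = character(0), lon = numeric(0),
                 lat = numeric(0), uncertainty_m = numeric(0),
                 year = integer(0), vouchered = logical(0),
                 source_id = character(0)),
      sprintf("loaded 0 records from %s", basename(path))))
  }
  optional <- c("uncertainty_m", "source_id")
  for (f in setdiff(names(schema), optional))
    if (!schema[[f]] %in% names(raw))
      stop("mandatory column '", schema[[f]], "' (", f, ") missing from ", path)
  get <- function(f) if (schema[[f]] %in% names(raw)) raw[[schema[[f]]]] else NA
  rec <- data.frame(
    species_id = normalize_species(as.character(get("species_id"))),
    lon = suppressWarnings(as.numeric(get("lon"))),
    lat = suppressWarnings(as.numeric(get("lat"))),
    uncertainty_m = suppressWarnings(as.numeric(get("uncertainty_m"))),
    year = suppressWarnings(as.integer(get("year"))),
    vouchered = as.logical(get("vouchered")),
    source_id = as.character(get("source_id")),
    stringsAsFactors = FALSE)
  bad_coord <- is.na(rec$lon) | is.na(rec$lat) |
    rec$lon < -180 | rec$lon > 180 | rec$lat < -90 | rec$lat > 90
  bad_unc <- !is.na(rec$uncertainty_m) & rec$uncertainty_m < 0
  drop <- bad_coord | bad_unc
  rec <- rec[!drop, , drop = FALSE]
  rownames(rec) <- NULL
  new_occurrence_set(rec, c(
    sprintf("loaded %d records from %s", nrow(raw), basename(path)),
    sprintf("dropped %d rows with unparseable/out-of-range coordinates",
            sum(drop))))
}

normalize_species <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  paste0(toupper(substring(x, 1, 1)), tolower(substring(x, 2)))
}

#' Quality-filter occurrence records
#'
#' Applies the three record-quality rules: georeferencing-error radius at
#' most `max_uncertainty_km` (records whose reported error radius exceeds it
#' are excluded, as are records with no reported radius, which cannot
#' certify their precision), collection year at least `min_year` (unknown
#' years are excluded), and — when `vouchered_only` — museum-vouchered
#' records only. The rules commute, so the attached report counts, for each
#' rule, every record that fails it regardless of the other rules.
#'
#' @param occ an `occurrence_set`.
#' @param max_uncertainty_km maximum permissible georeference error radius,
#'   km (default 1, matching a ~1 km grid resolution).
#' @param min_year earliest permissible collection year (default 1950, the
#'   start of the climate-layer averaging era).
#' @param vouchered_only keep only vouchered records (default TRUE).
#' @return filtered `occurrence_set`; `attr(, "filter_report")` holds counts
#'   removed per rule (`n_uncertainty`, `n_year`, `n_unvouchered`,
#'   `n_removed`, `n_in`, `n_out`).
#' @export
filter_records <- function(occ, max_uncertainty_km = 1, min_year = 1950L,
                           vouchered_only = TRUE) {
  stopifnot(max_uncertainty_km > 0, min_year > 0)
  fail_unc <- is.na(occ$uncertainty_m) |
    occ$uncertainty_m > max_uncertainty_km * 1000
  fail_year <- is.na(occ$year) | occ$year < min_year
  fail_vouch <- if (vouchered_only) is.na(occ$vouchered) | !occ$vouchered
  else rep(FALSE, nrow(occ))
  drop <- fail_unc | fail_year | fail_vouch
  report <- list(n_in = nrow(occ),
                 n_uncertainty = sum(fail_unc),
                 n_year = sum(fail_year),
                 n_unvouchered = sum(fail_vouch),
                 n_removed = sum(drop),
                 n_out = sum(!drop))
  out <- occ[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out <- new_occurrence_set(out, attr(occ, "filter_log"))
  out <- append_log(out, sprintf(
    "filter: uncertainty<=%gkm removed %d; year>=%d removed %d; voucher rule removed %d; %d -> %d records",
    max_uncertainty_km, report$n_uncertainty, min_year, report$n_year,
    report$n_unvouchered, report$n_in, report$n_out))
  attr(out, "filter_report") <- report
  out
}

#' Snap records to grid cells and deduplicate per species
#'
#' Each record maps to exactly one cell (half-open cell membership, see
#' [cell_of()]); duplicate records within a cell collapse to a single cell
#' id. Records outside the grid are dropped with a warning, never silently.
#'
#' @param occ an `occurrence_set`.
#' @param grid a `grid_spec`.
#' @return a data.frame of class `cell_occurrences` with one row per
#'   species: `species_id`, `cell_ids` (list column of unique cell ids),
#'   `n_cells`, `n_records_raw`.
#' @export
snap_and_deduplicate <- function(occ, grid) {
  ids <- cell_of(grid, occ$lon, occ$lat)
  outside <- is.na(ids)
  if (any(outside))
    warning(sum(outside), " record(s) outside the grid were dropped")
  sp <- occ$species_id[!outside]
  ids <- ids[!outside]
  by_sp <- split(ids, sp)
  res <- data.frame(species_id = names(by_sp),
                    n_records_raw = vapply(by_sp, length, integer(1)),
                    stringsAsFactors = FALSE)
  res$cell_ids <- lapply(by_sp, function(v) sort(unique(v)))
  res$n_cells <- vapply(res$cell_ids, length, integer(1))
  rownames(res) <- NULL
  class(res) <- c("cell_occurrences", "data.frame")
  res
}

#' Assemble the candidate species pool for modelling
#'
#' Pool membership requires at least one record inside the basin mask and an
#' eligible habitat class (freshwater or freshwater-estuarine; marine and
#' strictly estuarine species are excluded). Non-native species are kept and
#' flagged, since suitability estimates for them inform invasion potential
#' rather than historical composition. Species absent from the habitat table
#' are flagged unknown and excluded with a warning.
#'
#' @param occ an `occurrence_set`.
#' @param basin_mask a [region_mask()] defining the basin.
#' @param habitat_table named character vector: species ->
#'   `{"freshwater", "freshwater-estuarine", ...}`.
#' @param native_table named logical vector: species -> native flag.
#' @return data.frame `species_pool` with `species_id`, `native`,
#'   `habitat_class`, `in_basin`.
#' @export
assemble_species_pool <- function(occ, basin_mask, habitat_table,
                                  native_table) {
  grid <- attr(basin_mask, "grid")
  species <- sort(unique(occ$species_id))
  unknown <- setdiff(species, names(habitat_table))
  if (length(unknown)) {
    warning("species with unknown habitat class excluded: ",
            paste(unknown, collapse = ", "))
    species <- setdiff(species, unknown)
  }
  cell_ids <- cell_of(grid, occ$lon, occ$lat)
  in_basin_rec <- !is.na(cell_ids) & as.logical(basin_mask)[cell_ids]
  pool <- data.frame(
    species_id = species,
    habitat_class = unname(habitat_table[species]),
    native = unname(native_table[species]),
    in_basin = vapply(species, function(s)
      any(in_basin_rec[occ$species_id == s]), logical(1)),
    stringsAsFactors = FALSE)
  eligible <- pool$in_basin &
    pool$habitat_class %in% c("freshwater", "freshwater-estuarine")
  pool <- pool[eligible, , drop = FALSE]
  rownames(pool) <- NULL
  class(pool) <- c("species_pool", "data.frame")
  pool
}

#' Write an occurrence set and its machine-readable filter report
#'
#' @param occ a filtered `occurrence_set`.
#' @param csv_path output CSV for the records.
#' @param report_path optional JSON output for the filter report.
#' @export
write_occurrences <- function(occ, csv_path, report_path = NULL) {
  utils::write.csv(as.data.frame(occ), csv_path, row.names = FALSE)
  if (!is.null(report_path)) {
    rep <- attr(occ, "filter_report")
    if (is.null(rep)) rep <- list(n_in = nrow(occ), n_out = nrow(occ))
    jsonlite::write_json(rep, report_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
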