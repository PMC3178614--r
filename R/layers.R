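#' Create an environmental layer
#'
#' @param name layer name.
#' @param values numeric vector of per-cell values (row-major from NW),
#'   `NA` for nodata. Categorical layers store integer category codes.
#' @param kind `"continuous"` or `"categorical"`.
#' @param categories for categorical layers, the declared code table
#'   (integer codes). Values outside it are an error.
#' @return a `layer` object.
#' @export
layer <- function(name, values, kind = c("continuous", "categorical"),
                  categories = NULL) {
  kind <- match.arg(kind)
  if (kind == "categorical") {
    if (is.null(categories)) categories <- sort(unique(values[!is.na(values)]))
    categories <- as.integer(categories)
    bad <- !is.na(values) & !(values %in% categories)
    if (any(bad)) stop("layer '", name, "': values outside declared categories")
    values <- as.integer(values)
  } else {
    if (any(is.infinite(values))) stop("layer '", name, "': non-finite values")
    values <- as.numeric(values)
  }
  structure(list(name = name, kind = kind, values = values,
                 categories = categories),
            class = "layer")
}

#' Bundle co-registered layers into a stack
#'
#' All layers must share the grid's cell count. The stack's validity mask is
#' the intersection of per-layer data masks: a cell is valid only when every
#' layer has data there.
#'
#' @param grid a `grid_spec`.
#' @param layers list of [layer()] objects.
#' @param set_id optional label recording which variable-set/extent
#'   combination this stack instantiates.
#' @return a `layer_stack`.
#' @export
layer_stack <- function(grid, layers, set_id = NULL) {
  stopifnot(length(layers) >= 1)
  nms <- vapply(layers, function(l) l$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate layer names")
  n <- n_cells(grid)
  for (l in layers)
    if (length(l$values) != n)
      stop("layer '", l$name, "' has ", length(l$values),
           " cells; grid has ", n, " (alignment error)")
  valid <- Reduce(`&`, lapply(layers, function(l) !is.na(l$values)))
  names(layers) <- nms
  structure(list(grid = grid, layers = layers, valid = valid,
                 set_id = set_id),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("layer_stack: %d layers on %d x %d grid, %d valid cells%s\n",
              length(x$layers), x$grid$n_rows, x$grid$n_cols, sum(x$valid),
              if (is.null(x$set_id)) "" else paste0(" [set ", x$set_id, "]")))
  for (l in x$layers) cat(sprintf("  %-20s %s\n", l$name, l$kind))
  invisible(x)
}

#' Assemble a variable-set layer stack, optionally clipped to an extent
#'
#' Retains only the layers named in `variable_set`, in the declared order,
#' and sets cells outside `extent_mask` to nodata. Used to instantiate the
#' candidate variable-set/extent combinations compared during variable-set
#' selection.
#'
#' @param rasters named list of [layer()] objects, or paths to ESRI ASCII
#'   grids (read as continuous unless named in `categorical`).
#' @param grid a `grid_spec` all layers must align to.
#' @param variable_set character vector of layer names to keep, in order.
#' @param extent_mask optional [region_mask()]; cells outside become nodata.
#' @param set_id optional label for the combination instantiated.
#' @param categorical names of raster paths to read as categorical.
#' @return a `layer_stack`.
#' @export
assemble_layer_stack <- function(rasters, grid, variable_set = NULL,
                                 extent_mask = NULL, set_id = NULL,
                                 categorical = character(0)) {
  lyrs <- lapply(names(rasters), function(nm) {
    r <- rasters[[nm]]
    if (is.character(r))
      r <- read_ascii_grid(r, name = nm,
                           kind = if (nm %in% categorical) "categorical" else "continuous")
    r
  })
  names(lyrs) <- names(rasters)
  if (!is.null(variable_set)) {
    missing <- setdiff(variable_set, names(lyrs))
    if (length(missing))
      stop("unknown layer name(s) in variable set: ",
           paste(missing, collapse = ", "))
    lyrs <- lyrs[variable_set]
  }
  if (!is.null(extent_mask)) {
    stopifnot(inherits(extent_mask, "region_mask"))
    drop <- !as.logical(extent_mask)
    lyrs <- lapply(lyrs, function(l) { l$values[drop] <- NA; l })
  }
  layer_stack(grid, lyrs, set_id = set_id)
}

#' Read an ESRI ASCII grid into a layer
#'
#' Plain-text raster format with a 6-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by
#' row-major values from the NW corner.
#'
#' @param path file path.
#' @param name layer name (default: file stem).
#' @param kind `"continuous"` or `"categorical"`.
#' @return a list with the `layer` and its implied `grid_spec`.
#' @export
read_ascii_grid <- function(path, name = NULL,
                            kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("raster not found: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("raster ", path, ": value count does not match header")
  nodata <- hdr[["nodata_value"]]
  if (!is.null(nodata)) vals[vals == nodata] <- NA
  if (is.null(name)) name <- sub("\\.[^.]+$", "", basename(path))
  grid <- build_grid(c(west = hdr$xllcorner,
                       east = hdr$xllcorner + hdr$ncols * hdr$cellsize,
                       south = hdr$yllcorner,
                       north = hdr$yllcorner + hdr$nrows * hdr$cellsize),
                     hdr$cellsize)
  l <- layer(name, vals, kind)
  attr(l, "grid") <- grid
  l
}

#' Write a per-cell surface as an ESRI ASCII grid
#'
#' @param values numeric vector over cells (row-major from NW).
#' @param grid a `grid_spec`.
#' @param path output file.
#' @param nodata value written for `NA` cells.
#' @export
write_ascii_grid <- function(values, grid, path, nodata = -9999) {
  stopifnot(length(values) == n_cells(grid))
  v <- values
  v[is.na(v)] <- nodata
  hdr <- c(paste("ncols", grid$n_cols), paste("nrows", grid$n_rows),
           paste("xllcorner", grid$west), paste("yllcorner", grid$south),
           paste("cellsize", grid$cell_size), paste("NODATA_value", nodata))
  m <- matrix(v, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Stack manifest
#'
#' Structured-text description of a stack: layer names, kinds, category
#' codes, and the variable-set id it instantiates.
#' @param stack a `layer_stack`.
#' @return character vector of manifest lines.
#' @export
stack_manifest <- function(stack) {
  c(sprintf("set_id: %s", if (is.null(stack$set_id)) "NA" else stack$set_id),
    sprintf("grid: %d x %d @ %g deg", stack$grid$n_rows, stack$grid$n_cols,
            stack$grid$cell_size),
    sprintf("valid_cells: %d", sum(stack$valid)),
    vapply(stack$layers, function(l)
      sprintf("layer: %s kind: %s%s", l$name, l$kind,
              if (l$kind == "categorical")
                paste0(" categories: ", paste(l$categories, collapse = ","))
              else ""),
      character(1), USE.NAMES = FALSE))
}
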