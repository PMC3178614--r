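#' Build a regular geographic analysis grid
#'
#' Defines a regular lon/lat grid (WGS84 geographic coordinates) covering a
#' bounding box at a fixed cell size. When the cell size does not divide the
#' box exactly the grid is expanded eastward/southward (ceiling rule) so the
#' box is always fully covered. Cells are indexed row-major from the
#' north-west corner; `cell_id = (row - 1) * n_cols + col`.
#'
#' @param bounds named numeric vector or list with `west`, `east`, `south`,
#'   `north` in decimal degrees.
#' @param cell_size_deg cell edge length in decimal degrees (e.g. 30
#'   arc-seconds = 1/120 degree).
#' @return an object of class `grid_spec` with fields `n_rows`, `n_cols`,
#'   `cell_size`, `west`, `north` (NW origin) and derived `east`, `south`.
#' @examples
#' g <- build_grid(c(west = 0, east = 1, south = 0, north = 1), 0.25)
#' g$n_rows * g$n_cols  # 16
#' @export
build_grid <- function(bounds, cell_size_deg) {
  b <- as.list(bounds)
  stopifnot(is.numeric(cell_size_deg), cell_size_deg > 0)
  for (k in c("west", "east", "south", "north"))
    if (is.null(b[[k]])) stop("bounds must supply '", k, "'")
  if (b$east <= b$west || b$north <= b$south)
    stop("degenerate bounds: need east > west and north > south")
  # ceiling with tolerance so exactly-divisible boxes do not gain a row/col
  n_cols <- ceiling((b$east - b$west) / cell_size_deg - 1e-9)
  n_rows <- ceiling((b$north - b$south) / cell_size_deg - 1e-9)
  g <- structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    cell_size = cell_size_deg,
    west = b$west, north = b$north,
    east = b$west + n_cols * cell_size_deg,
    south = b$north - n_rows * cell_size_deg
  ), class = "grid_spec")
  g
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g deg, lon [%g, %g], lat [%g, %g]\n",
              x$n_rows, x$n_cols, x$cell_size, x$west, x$east, x$south, x$north))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Map points to grid cells
#'
#' Cell membership uses half-open intervals: `[west, east)` in longitude and
#' `(south, north]` in latitude, so every point inside the grid maps to
#' exactly one cell and a point on an interior boundary belongs to the cell
#' whose west (or north) edge it touches. The grid's own outer east and
#' south edges are included in the last column/row so bounding-box edge
#' records are not lost.
#'
#' @param grid a `grid_spec`.
#' @param lon,lat numeric vectors of equal length, decimal degrees.
#' @return integer cell ids (row-major from NW); `NA` for points outside the
#'   grid.
#' @export
cell_of <- function(grid, lon, lat) {
  # snap within ~1e-9 of a cell edge onto it so the half-open ownership
  # rule is stable under floating-point representation of boundary points
  tol <- 1e-9
  u <- (lon - grid$west) / grid$cell_size
  v <- (grid$north - lat) / grid$cell_size
  col <- floor(u + tol) + 1L
  row <- floor(v + tol) + 1L
  # the grid's own outer east/south edges are included in the last col/row
  col[col == grid$n_cols + 1L & lon <= grid$east] <- grid$n_cols
  row[row == grid$n_rows + 1L & lat >= grid$south] <- grid$n_rows
  out <- (row - 1L) * grid$n_cols + col
  bad <- col < 1L | col > grid$n_cols | row < 1L | row > grid$n_rows
  out[bad] <- NA_integer_
  as.integer(out)
}

#' Cell-center coordinates of grid cells
#'
#' Inverse companion of [cell_of()]: `cell_of(grid, cell_center(grid, id))`
#' returns `id`, and centers are within half a cell of any point in the cell.
#'
#' @param grid a `grid_spec`.
#' @param cell_id integer cell ids.
#' @return data.frame with columns `lon`, `lat`.
#' @export
cell_center <- function(grid, cell_id) {
  row <- (cell_id - 1L) %/% grid$n_cols + 1L
  col <- (cell_id - 1L) %% grid$n_cols + 1L
  data.frame(
    lon = grid$west + (col - 0.5) * grid$cell_size,
    lat = grid$north - (row - 0.5) * grid$cell_size
  )
}

#' Create a grid-aligned region mask
#'
#' @param grid a `grid_spec`.
#' @param cells integer cell ids inside the region, or a logical vector of
#'   length `n_rows * n_cols`.
#' @param id optional label (e.g. `"watershed"`).
#' @return a `region_mask`: logical vector over cells with attributes.
#' @export
region_mask <- function(grid, cells, id = "mask") {
  n <- n_cells(grid)
  if (is.logical(cells)) {
    stopifnot(length(cells) == n)
    m <- cells
  } else {
    cells <- as.integer(cells)
    if (any(cells < 1L | cells > n)) stop("mask cells outside grid")
    m <- rep(FALSE, n)
    m[cells] <- TRUE
  }
  structure(m, class = "region_mask", grid = grid, mask_id = id)
}

#' Rasterize a polygon onto a grid
#'
#' Uses cell-center-in-polygon membership. Polygons come as two-column
#' lon/lat matrices (closed or open rings) or GeoJSON files containing one
#' Polygon geometry.
#'
#' @param grid a `grid_spec`.
#' @param polygon two-column numeric matrix of vertex lon/lat, or a path to
#'   a GeoJSON file with a Polygon.
#' @param id mask label.
#' @return a `region_mask`.
#' @export
rasterize_polygon <- function(grid, polygon, id = "polygon") {
  if (is.character(polygon)) polygon <- read_geojson_polygon(polygon)
  poly <- as.matrix(polygon)
  stopifnot(ncol(poly) == 2)
  # close the ring; mgcv::in.out expects a closed boundary loop
  if (any(poly[1, ] != poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  ctr <- cell_center(grid, seq_len(n_cells(grid)))
  inside <- mgcv::in.out(poly, cbind(ctr$lon, ctr$lat))
  region_mask(grid, as.logical(inside), id = id)
}

read_geojson_polygon <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- if (!is.null(gj$type) && identical(gj$type, "Polygon")) gj
  else if (!is.null(gj$geometry)) gj$geometry
  else if (!is.null(gj$features)) gj$features$geometry[1, , drop = TRUE]
  else stop("no Polygon geometry found in ", path)
  ring <- geom$coordinates
  while (is.list(ring)) ring <- ring[[1]]
  if (length(dim(ring)) == 3) ring <- ring[1, , ]
  matrix(as.numeric(ring), ncol = 2)
}
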