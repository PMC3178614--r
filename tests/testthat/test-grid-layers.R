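test_that("grid construction counts cells exactly and by the ceiling rule", {
  g <- build_grid(c(west = 0, east = 1, south = 0, north = 1), 0.25)
  expect_equal(c(g$n_rows, g$n_cols), c(4L, 4L))
  g2 <- build_grid(c(west = 0, east = 1, south = 0, north = 1), 0.3)
  expect_equal(c(g2$n_rows, g2$n_cols), c(4L, 4L))  # expanded to cover
  expect_gte(g2$east, 1); expect_lte(g2$south, 0)
  expect_error(build_grid(c(west = 0, east = 0, south = 0, north = 1), 0.1),
               "degenerate")
})

test_that("cell_of and cell_center are mutually consistent for random points", {
  g <- build_grid(c(west = -98, east = -97, south = 30, north = 31), 1 / 120)
  set.seed(3)
  lon <- runif(500, -98, -97 - 1e-9)
  lat <- runif(500, 30 + 1e-9, 31)
  ids <- cell_of(g, lon, lat)
  expect_false(anyNA(ids))
  ctr <- cell_center(g, ids)
  half <- g$cell_size / 2 + 1e-12
  expect_true(all(abs(ctr$lon - lon) <= half))
  expect_true(all(abs(ctr$lat - lat) <= half))
  expect_equal(cell_of(g, ctr$lon, ctr$lat), ids)
})

test_that("ESRI ASCII grids round-trip through write and read", {
  g <- build_grid(c(west = 0, east = 1, south = 0, north = 1), 0.2)
  vals <- c(seq_len(24) / 10, NA)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(vals, g, path)
  l <- read_ascii_grid(path, name = "v")
  expect_equal(l$values, vals)
  rg <- attr(l, "grid")
  expect_equal(rg$n_rows, g$n_rows)
  expect_equal(rg$cell_size, g$cell_size)
})

test_that("layer stacks enforce alignment and validity intersection", {
  g <- build_grid(c(west = 0, east = 1, south = 0, north = 1), 0.5)
  a <- layer("a", c(1, NA, 3, 4), "continuous")
  b <- layer("b", c(1, 2, NA, 4), "continuous")
  st <- layer_stack(g, list(a, b))
  expect_equal(st$valid, c(TRUE, FALSE, FALSE, TRUE))
  expect_error(layer_stack(g, list(layer("c", 1:5, "continuous"))),
               "alignment")
  expect_error(layer("cat", c(1, 2, 9), "categorical", categories = 1:2),
               "categories")
})

test_that("variable-set subsetting keeps order and rejects unknown names", {
  g <- build_grid(c(west = 0, east = 1, south = 0, north = 1), 0.5)
  rasters <- list(x = layer("x", 1:4, "continuous"),
                  y = layer("y", 4:1, "continuous"),
                  z = layer("z", c(1, 1, 2, 2), "categorical"))
  st <- assemble_layer_stack(rasters, g, variable_set = c("z", "x"),
                             set_id = "9")
  expect_equal(names(st$layers), c("z", "x"))
  expect_equal(st$set_id, "9")
  expect_error(assemble_layer_stack(rasters, g, variable_set = "bogus"),
               "unknown layer")
})

test_that("subsetting then masking equals masking then subsetting", {
  g <- build_grid(c(west = 0, east = 1, south = 0, north = 1), 0.25)
  set.seed(1)
  rasters <- list(x = layer("x", rnorm(16), "continuous"),
                  y = layer("y", rnorm(16), "continuous"))
  m <- region_mask(g, 1:8)
  a <- assemble_layer_stack(rasters, g, variable_set = "y", extent_mask = m)
  b <- assemble_layer_stack(
    list(y = assemble_layer_stack(rasters, g, extent_mask = m)$layers$y),
    g, variable_set = "y")
  expect_equal(a$layers$y$values, b$layers$y$values)
  expect_equal(a$valid, b$valid)
})

test_that("adding layers never grows the validity mask", {
  g <- build_grid(c(west = 0, east = 1, south = 0, north = 1), 0.25)
  set.seed(2)
  v1 <- rnorm(16); v1[sample(16, 3)] <- NA
  v2 <- rnorm(16); v2[sample(16, 3)] <- NA
  st1 <- layer_stack(g, list(layer("a", v1, "continuous")))
  st2 <- layer_stack(g, list(layer("a", v1, "continuous"),
                             layer("b", v2, "continuous")))
  expect_true(all(st1$valid | !st2$valid))
  expect_true(all(!st2$valid[!st1$valid]))
})

test_that("an empty extent mask gives an all-nodata stack that refuses to fit", {
  g <- build_grid(c(west = 0, east = 1, south = 0, north = 1), 0.25)
  rasters <- list(x = layer("x", rnorm(16), "continuous"))
  empty <- region_mask(g, integer(0))
  st <- assemble_layer_stack(rasters, g, extent_mask = empty)
  expect_equal(sum(st$valid), 0)
  expect_error(expand_features(st, n_presence = 10), "no valid cells")
})

test_that("polygon rasterization uses cell-center membership", {
  g <- build_grid(c(west = 0, east = 1, south = 0, north = 1), 0.25)
  # square covering the NW 2x2 block of cell centers
  sq <- matrix(c(0, 0.5, 0.5, 0.5, 0.5, 1, 0, 1), ncol = 2, byrow = TRUE)
  m <- rasterize_polygon(g, sq, id = "sq")
  expect_equal(which(as.logical(m)), c(1L, 2L, 5L, 6L))
  expect_equal(attr(m, "mask_id"), "sq")
})

test_that("GeoJSON polygon masks load and rasterize", {
  path <- withr::local_tempfile(fileext = ".geojson")
  writeLines(jsonlite::toJSON(list(
    type = "Feature",
    geometry = list(type = "Polygon",
                    coordinates = list(list(c(0, 0.5), c(0.5, 0.5),
                                            c(0.5, 1), c(0, 1), c(0, 0.5)))),
    properties = list(name = "ws")), auto_unbox = TRUE), path)
  g <- build_grid(c(west = 0, east = 1, south = 0, north = 1), 0.25)
  m <- rasterize_polygon(g, path)
  expect_equal(which(as.logical(m)), c(1L, 2L, 5L, 6L))
})

test_that("variable-set specs assemble stacks of the documented sizes", {
  # full complement: 15 bioclim + 4 topo + 13 supplemental layers
  g <- build_grid(c(west = 0, east = 1, south = 0, north = 1), 0.5)
  nms <- c(paste0("bio", 1:15), c("altitude", "slope", "aspect", "cti"),
           paste0("supp", 1:13))
  set.seed(4)
  rasters <- setNames(lapply(nms, function(nm)
    layer(nm, rnorm(4), "continuous")), nms)
  set3 <- assemble_layer_stack(rasters, g, variable_set = nms, set_id = "3")
  expect_length(set3$layers, 32)
  set9_names <- c(paste0("bio", 1:7), c("altitude", "slope", "aspect", "cti"),
                  paste0("supp", 1:13))
  set9 <- assemble_layer_stack(rasters, g, variable_set = set9_names,
                               set_id = "9")
  expect_length(set9$layers, 24)
  expect_equal(set9$set_id, "9")
})

test_that("stack manifest lists set id, layer names and kinds", {
  g <- build_grid(c(west = 0, east = 1, south = 0, north = 1), 0.5)
  st <- layer_stack(g, list(layer("x", 1:4, "continuous"),
                            layer("z", c(1, 1, 2, 2), "categorical")),
                    set_id = "3")
  man <- stack_manifest(st)
  expect_match(man[1], "set_id: 3")
  expect_true(any(grepl("layer: z kind: categorical categories: 1,2", man)))
})
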