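test_that("load_occurrences parses valid rows, drops bad coordinates, enforces schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(
    species = c("A a", "B b", "C c"),
    decimalLatitude = c(30.2, 30.5, 30.9),
    decimalLongitude = c(-97.1, -97.5, -97.9),
    coordinateUncertaintyInMeters = 100,
    year = 2000, vouchered = TRUE), path, row.names = FALSE)
  occ <- load_occurrences(path)
  expect_s3_class(occ, "occurrence_set")
  expect_equal(nrow(occ), 3)

  write.csv(data.frame(
    species = c("A a", "B b"), decimalLatitude = c(95, 30),
    decimalLongitude = c(-97, -97),
    coordinateUncertaintyInMeters = 100, year = 2000, vouchered = TRUE),
    path, row.names = FALSE)
  occ <- load_occurrences(path)
  expect_equal(nrow(occ), 1)
  expect_match(paste(attr(occ, "filter_log"), collapse = " "),
               "dropped 1 rows")

  # schema maps year to a column that does not exist
  expect_error(
    load_occurrences(path, schema = modifyList(default_occurrence_schema(),
                                               list(year = "collYear"))),
    "missing")
})

test_that("empty occurrence file yields an empty set with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("species,decimalLatitude,decimalLongitude,year,vouchered", path)
  expect_warning(occ <- load_occurrences(path), "empty")
  expect_equal(nrow(occ), 0)
})

test_that("filter thresholds sit exactly at the stated boundaries", {
  occ <- occ_from_df(data.frame(
    species_id = "A a", lon = -97, lat = 30,
    uncertainty_m = c(1500, 1000, 500, 500, 500),
    year = c(2000L, 2000L, 1949L, 1950L, 2000L),
    vouchered = c(TRUE, TRUE, TRUE, TRUE, FALSE)))
  out <- filter_records(occ, max_uncertainty_km = 1, min_year = 1950)
  rep <- attr(out, "filter_report")
  # 1500 m excluded, 1000 m (== 1 km) retained; 1949 excluded, 1950 kept
  expect_equal(rep$n_uncertainty, 1)
  expect_equal(rep$n_year, 1)
  expect_equal(rep$n_unvouchered, 1)
  expect_equal(nrow(out), 2)
  expect_equal(out$uncertainty_m, c(1000, 500))
})

test_that("missing year or uncertainty fails the respective rule", {
  occ <- occ_from_df(data.frame(
    species_id = "A a", lon = -97, lat = 30,
    uncertainty_m = c(NA, 100), year = c(2000L, NA), vouchered = TRUE))
  out <- filter_records(occ)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "filter_report")$n_uncertainty, 1)
  expect_equal(attr(out, "filter_report")$n_year, 1)
})

test_that("filtering compliant records is the identity with an all-zero report", {
  occ <- occ_from_df(data.frame(
    species_id = c("A a", "B b"), lon = c(-97, -97.5), lat = c(30, 30.5),
    uncertainty_m = c(100, 900), year = c(1980L, 2010L),
    vouchered = TRUE))
  out <- filter_records(occ)
  expect_equal(records_of(out), records_of(occ))
  rep <- attr(out, "filter_report")
  expect_equal(rep$n_removed, 0)
  expect_equal(rep$n_uncertainty + rep$n_year + rep$n_unvouchered, 0)
})

test_that("filtering is idempotent and order-invariant", {
  set.seed(5)
  n <- 60
  occ <- occ_from_df(data.frame(
    species_id = "A a", lon = runif(n, -98, -97), lat = runif(n, 30, 31),
    uncertainty_m = runif(n, 0, 3000),
    year = sample(1930:2010, n, replace = TRUE),
    vouchered = runif(n) < 0.7))
  once <- filter_records(occ)
  twice <- filter_records(once)
  expect_equal(records_of(twice), records_of(once))

  # single-rule passes composed in different orders give the same set
  r1 <- filter_records(occ, max_uncertainty_km = 1, min_year = 1,
                       vouchered_only = FALSE)           # uncertainty only
  r1 <- filter_records(r1, max_uncertainty_km = 1e6, min_year = 1950,
                       vouchered_only = FALSE)           # year only
  r1 <- filter_records(r1, max_uncertainty_km = 1e6, min_year = 1,
                       vouchered_only = TRUE)            # voucher only
  r2 <- filter_records(occ, max_uncertainty_km = 1e6, min_year = 1,
                       vouchered_only = TRUE)
  r2 <- filter_records(r2, max_uncertainty_km = 1e6, min_year = 1950,
                       vouchered_only = FALSE)
  r2 <- filter_records(r2, max_uncertainty_km = 1, min_year = 1,
                       vouchered_only = FALSE)
  joint <- filter_records(occ)
  expect_equal(records_of(r1), records_of(joint))
  expect_equal(records_of(r2), records_of(joint))
})

test_that("snap collapses duplicate cells and keeps distinct ones", {
  g <- build_grid(c(west = 0, east = 1, south = 0, north = 1), 0.1)
  # 12 records jittered inside one cell
  one <- occ_from_df(data.frame(
    species_id = "A a", lon = 0.55 + runif(12, -0.04, 0.04),
    lat = 0.55 + runif(12, -0.04, 0.04)))
  res <- snap_and_deduplicate(one, g)
  expect_equal(res$n_cells, 1)
  expect_equal(res$n_records_raw, 12)

  ctr <- cell_center(g, 1:12)
  twelve <- occ_from_df(data.frame(species_id = "A a", lon = ctr$lon,
                                   lat = ctr$lat))
  expect_equal(snap_and_deduplicate(twelve, g)$n_cells, 12)
})

test_that("a point on an interior boundary joins the cell whose west/north edge it touches", {
  g <- build_grid(c(west = 0, east = 1, south = 0, north = 1), 0.1)
  eps <- 1e-9
  # vertical interior edge at lon = 0.3: same cell as a point just east
  expect_equal(cell_of(g, 0.3, 0.55), cell_of(g, 0.3 + eps, 0.55))
  expect_false(cell_of(g, 0.3, 0.55) == cell_of(g, 0.3 - eps, 0.55))
  # horizontal interior edge at lat = 0.7: same cell as a point just south
  expect_equal(cell_of(g, 0.55, 0.7), cell_of(g, 0.55, 0.7 - eps))
  expect_false(cell_of(g, 0.55, 0.7) == cell_of(g, 0.55, 0.7 + eps))
})

test_that("records outside the grid are dropped with a warning", {
  g <- build_grid(c(west = 0, east = 1, south = 0, north = 1), 0.1)
  occ <- occ_from_df(data.frame(species_id = "A a", lon = c(0.5, 2),
                                lat = c(0.5, 0.5)))
  expect_warning(res <- snap_and_deduplicate(occ, g), "outside")
  expect_equal(res$n_records_raw, 1)
})

test_that("unique-cell count is monotone in the record set", {
  g <- build_grid(c(west = 0, east = 1, south = 0, north = 1), 0.1)
  set.seed(9)
  lon <- runif(40); lat <- runif(40)
  for (k in c(5, 15, 30)) {
    small <- occ_from_df(data.frame(species_id = "A a", lon = lon[1:k],
                                    lat = lat[1:k]))
    big <- occ_from_df(data.frame(species_id = "A a", lon = lon[1:(k + 10)],
                                  lat = lat[1:(k + 10)]))
    expect_lte(snap_and_deduplicate(small, g)$n_cells,
               snap_and_deduplicate(big, g)$n_cells)
  }
})

test_that("species pool applies basin and habitat rules (brute-force oracle)", {
  g <- build_grid(c(west = 0, east = 1, south = 0, north = 1), 0.1)
  basin <- region_mask(g, cell_of(g, rep(0.25, 25), rep(seq(0.55, 0.95,
    length.out = 25), 1)), id = "basin")  # western-north strip
  sp <- c("In one", "In two", "In three", "Out range", "Marine sp")
  occ <- occ_from_df(data.frame(
    species_id = rep(sp, each = 2),
    lon = c(0.25, 0.25, 0.25, 0.25, 0.25, 0.25, 0.85, 0.85, 0.25, 0.25),
    lat = c(0.6, 0.7, 0.8, 0.9, 0.6, 0.9, 0.2, 0.3, 0.6, 0.7)))
  habitat <- c("In one" = "freshwater", "In two" = "freshwater-estuarine",
               "In three" = "freshwater", "Out range" = "freshwater",
               "Marine sp" = "marine")
  native <- setNames(c(TRUE, TRUE, FALSE, TRUE, TRUE), sp)
  pool <- assemble_species_pool(occ, basin, habitat, native)
  # oracle: enumerate records, check basin membership and habitat by hand
  in_basin <- as.logical(basin)[cell_of(g, occ$lon, occ$lat)]
  expected <- sort(unique(occ$species_id[in_basin]))
  expected <- expected[habitat[expected] %in%
                         c("freshwater", "freshwater-estuarine")]
  expect_setequal(pool$species_id, expected)
  expect_equal(nrow(pool), 3)
  expect_false("Marine sp" %in% pool$species_id)
  expect_false("Out range" %in% pool$species_id)
  expect_false(pool$native[pool$species_id == "In three"])
})

test_that("species with unknown habitat class are excluded with a warning", {
  g <- build_grid(c(west = 0, east = 1, south = 0, north = 1), 0.5)
  basin <- region_mask(g, 1:4, id = "basin")
  occ <- occ_from_df(data.frame(species_id = c("Known sp", "Mystery sp"),
                                lon = 0.25, lat = 0.75))
  expect_warning(
    pool <- assemble_species_pool(occ, basin,
                                  c("Known sp" = "freshwater"),
                                  c("Known sp" = TRUE, "Mystery sp" = TRUE)),
    "unknown habitat")
  expect_equal(pool$species_id, "Known sp")
})
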