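test_that("reading drops malformed rows, imputes counts and maps Darwin Core headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "scientificName,decimalLatitude,decimalLongitude,eventDate,individualCount,datasetKey",
    "Anas platyrhynchos,43.1,10.2,2020-05-01,3,DS1",
    "Anas platyrhynchos,43.2,10.3,2020-05-02,,DS1",
    "Ardea cinerea,,10.4,2020-05-03,2,DS2",
    "Ardea cinerea,43.4,10.5,2021-06-01,1,DS2"), path)
  rs <- read_occurrences(path)
  expect_equal(nrow(rs), 3)
  expect_named(rs[1:6], c("species", "lon", "lat", "date", "count", "dataset"))
  expect_equal(attr(rs, "provenance")$dropped_invalid, 1)
  # blank individualCount imputed as 1
  expect_equal(rs$count[rs$date == as.Date("2020-05-02")], 1)
  expect_equal(rs$lon[1], 10.2)
  expect_error(read_occurrences(tempfile()), "not found")
})

test_that("reading a file with zero valid rows errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,lon,lat,date,count,dataset",
               "x,,43,2020-01-01,1,D"), path)
  expect_error(read_occurrences(path), "no valid occurrence rows")
})

test_that("deduplication keeps the max-count record and is idempotent", {
  df <- data.frame(
    species = c("a", "a", "a", "b"),
    lon = c(1, 1, 1, 1), lat = c(2, 2, 2, 2),
    date = as.Date(c("2020-01-01", "2020-01-01", "2020-02-01", "2020-01-01")),
    count = c(1, 5, 2, 3),
    dataset = "D1", stringsAsFactors = FALSE)
  rs <- make_rs(df)
  dd <- deduplicate(rs)
  # duplicate pair collapses to the count-5 record
  expect_equal(nrow(dd), 3)
  expect_equal(dd$count[dd$species == "a" & dd$date == as.Date("2020-01-01")], 5)
  # same coordinates, different dates: both kept
  expect_equal(sum(dd$species == "a"), 2)
  # species key: same coords/date but different species are not duplicates
  expect_true("b" %in% dd$species)
  expect_equal(as.data.frame(deduplicate(dd))[1:6],
               as.data.frame(dd)[1:6])
})

test_that("context assignment filters by polygon and time and indexes cells", {
  polys <- list(P1 = cbind(c(10, 10.1, 10.1, 10), c(43, 43, 43.1, 43.1)))
  cfg <- study_config(time_start = as.Date("2016-01-01"),
                      time_end = as.Date("2025-12-31"),
                      cell_resolution = 0.01, datasets = polys)
  df <- data.frame(
    species = "s",
    lon = c(10.005, 10.005, 50),
    lat = c(43.005, 43.005, 0),
    date = as.Date(c("2020-06-01", "2010-06-01", "2020-06-01")),
    count = 1, dataset = NA_character_, stringsAsFactors = FALSE)
  rs <- assign_context(make_rs(df), cfg)
  expect_equal(nrow(rs), 1)  # one too old, one outside all polygons
  expect_equal(rs$dataset, "P1")
  expect_equal(rs$cell_x, 1000L)
  expect_equal(rs$cell_y, 4300L)
  expect_equal(rs$time_unit, 4L)  # 2020 in a 2016-start frame
})

test_that("overlapping polygons resolve to the first dataset, with a warning", {
  polys <- list(A = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
                B = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  cfg <- study_config(datasets = polys)
  df <- data.frame(species = "s", lon = 0.5, lat = 0.5,
                   date = as.Date("2020-01-01"), count = 1,
                   dataset = NA_character_, stringsAsFactors = FALSE)
  expect_warning(rs <- assign_context(make_rs(df), cfg), "overlapping")
  expect_equal(rs$dataset, "A")
})

test_that("record sets round-trip through CSV bit-exactly", {
  fx <- tiny_fx()
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(fx$records, path)
  back <- read_occurrences(path)
  expect_equal(as.data.frame(back)[c("species", "lon", "lat", "date",
                                     "count", "dataset")],
               as.data.frame(fx$records)[c("species", "lon", "lat", "date",
                                           "count", "dataset")])
})

test_that("area polygons load from GeoJSON and WKT", {
  polys <- list(D1 = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
                D2 = cbind(c(2, 3, 3, 2), c(0, 0, 1, 1)))
  gj <- withr::local_tempfile(fileext = ".geojson")
  prevcommon:::write_areas_geojson(polys, gj)
  got <- read_areas(gj)
  expect_named(got, c("D1", "D2"))
  expect_true(prevcommon:::points_in_polygon(0.5, 0.5, got$D1))
  expect_false(prevcommon:::points_in_polygon(0.5, 0.5, got$D2))

  wkt <- withr::local_tempfile(fileext = ".wkt")
  writeLines(c("D1;POLYGON ((0 0, 1 0, 1 1, 0 1, 0 0))",
               "D2;POLYGON ((2 0, 3 0, 3 1, 2 1, 2 0))"), wkt)
  got2 <- read_areas(wkt)
  expect_named(got2, c("D1", "D2"))
  expect_equal(unname(got2$D1[1:4, ]), unname(got$D1[1:4, ]))
})

test_that("cell indexing is a pure floor and order-invariant", {
  lon <- c(10.005, -0.005, 0.01)
  lat <- c(43.005, 0.015, -0.02)
  ci <- cell_index(lon, lat, 0.01)
  expect_equal(ci[, "cell_x"], c(1000L, -1L, 1L))
  expect_equal(ci[, "cell_y"], c(4300L, 1L, -2L))
  perm <- c(3, 1, 2)
  expect_equal(cell_index(lon[perm], lat[perm], 0.01), ci[perm, ])
})
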