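test_that("grid round-trips exactly through both on-disk formats", {
  vals <- matrix(c(1.5, -2.25, 720.125, 840.5, NA, 3), 2, 3)
  g <- grid(vals, 10, origin = c(1000, 2000), nodata = -9999)
  for (ext in c(".tif", ".asc")) {
    path <- withr::local_tempfile(fileext = ext)
    write_grid(g, path)
    g2 <- read_grid(path)
    expect_identical(g2$values, g$values)
    expect_true(is_aligned(g, g2))
    expect_identical(g2$nodata, g$nodata)
  }
})

test_that("ASCII nodata header is preserved and categorical codes enforced", {
  path <- withr::local_tempfile(fileext = ".asc")
  g <- grid(matrix(c(1, 2, NA, 3), 2, 2), 5, origin = c(0, 10),
            nodata = -9999, kind = "categorical")
  write_grid(g, path)
  g2 <- read_grid(path, kind = "categorical")
  expect_identical(g2$nodata, -9999)
  expect_identical(g2$values, g$values)

  bad <- withr::local_tempfile(fileext = ".asc")
  write_grid(grid(matrix(c(1, 2, 2.5, 3), 2, 2), 5, origin = c(0, 10)), bad)
  expect_error(read_grid(bad, kind = "categorical"), "non-integer")
})

test_that("multi-band or unreadable rasters are rejected", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines("not a raster at all", path)
  expect_error(read_grid(path), "ASCII grid")
  expect_error(read_grid(tempfile(fileext = ".tif")), "does not exist")
})

test_that("resampling: identity, constant preservation and hand bilinear", {
  g <- grid(matrix(rnorm(16), 4, 4), 10, origin = c(0, 40))
  expect_identical(resample_to(g, g, "bilinear")$values, g$values)

  const <- grid(matrix(7, 3, 3), 30, origin = c(0, 90))
  fine <- grid(matrix(0, 9, 9), 10, origin = c(0, 90))
  expect_true(all(resample_to(const, fine, "bilinear")$values == 7))

  checker <- grid(matrix(c(0, 10, 10, 0), 2, 2), 1, origin = c(0, 2))
  centre <- grid(matrix(0, 1, 1), 1, origin = c(0.5, 1.5))
  expect_equal(resample_to(checker, centre, "bilinear")$values[1, 1], 5)

  cat_g <- grid(matrix(c(1, 2, 2, 1), 2, 2), 1, kind = "categorical")
  expect_error(resample_to(cat_g, centre, "bilinear"), "invalid")
  expect_silent(resample_to(cat_g, cat_g, "nearest"))
})

test_that("bilinear output stays within the contributing neighbourhood range", {
  set.seed(11)
  src <- grid(matrix(runif(100, -5, 5), 10, 10), 10, origin = c(0, 100))
  tmpl <- grid(matrix(0, 23, 23), 4.3, origin = c(1, 99))
  out <- resample_to(src, tmpl, "bilinear")
  expect_true(all(out$values >= min(src$values) - 1e-12))
  expect_true(all(out$values <= max(src$values) + 1e-12))
})

test_that("slope and aspect match closed forms on analytic planes", {
  flat <- grid(matrix(800, 6, 6), 10)
  expect_true(all(derive_slope(flat)$values == 0))
  expect_true(all(derive_aspect(flat)$values == -1))

  # z = x: rises east at 45 degrees for 10 m pixels; downslope is due west
  z <- outer(rep(1, 8), seq(0, 70, 10))
  plane <- grid(z, 10, origin = c(0, 80))
  expect_equal(max(abs(derive_slope(plane)$values[2:7, 2:7] - 45)), 0,
               tolerance = 1e-6)
  expect_equal(max(abs(derive_aspect(plane)$values[2:7, 2:7] - 270)), 0,
               tolerance = 1e-6)

  # plane dipping due east: aspect 90
  east_dip <- grid(-z, 10, origin = c(0, 80))
  expect_equal(max(abs(derive_aspect(east_dip)$values[2:7, 2:7] - 90)), 0,
               tolerance = 1e-6)

  expect_error(derive_slope(grid(matrix(NA_real_, 3, 3), 10)), "no valid")
})

test_that("TWI: monotone down a uniform slope, epsilon guard, hand D8 pit", {
  # single-column inclined plane: flow accumulates strictly downslope
  dem <- grid(matrix(seq(100, 10, length.out = 10), 10, 1), 10)
  twi <- derive_twi(dem)$values
  expect_true(all(diff(twi[, 1]) > 0))

  flat <- grid(matrix(500, 4, 4), 10)
  tf <- derive_twi(flat, eps = 1e-6)$values
  expect_true(all(is.finite(tf)))
  expect_equal(max(tf) - min(tf), 0, tolerance = 1e-9)

  # 3x3 bowl: all 8 border cells drain into the centre pit
  z <- matrix(10, 3, 3); z[2, 2] <- 5
  pit <- derive_twi(grid(z, 10), eps = 1e-6)
  expect_equal(pit$values[2, 2], log((9 * 100 / 10) / 1e-6), tolerance = 1e-9)
})

test_that("TWI is invariant to a constant DEM offset", {
  set.seed(4)
  z <- matrix(cumsum(rnorm(64)), 8, 8)
  t1 <- derive_twi(grid(z, 10))$values
  t2 <- derive_twi(grid(z + 500, 10))$values
  expect_equal(t1, t2, tolerance = 1e-9)
})

test_that("distance transform matches analytic and brute-force oracles", {
  tmpl <- grid(matrix(0, 5, 5), 10, origin = c(0, 50))
  # vertical line through x = 25 (column 3 centres)
  vert <- distance_from_lines(tmpl, list(cbind(c(25, 25), c(-100, 100))))
  expect_equal(vert$values[3, ], abs((1:5 - 3)) * 10, tolerance = 1e-9)
  expect_equal(vert$values[1, 3], 0)

  # degenerate point segment at the grid centre
  pt <- distance_from_lines(tmpl, list(cbind(25, 25)))
  expect_equal(pt$values[1, 1], sqrt(20^2 + 20^2), tolerance = 1e-9)

  expect_error(distance_from_lines(tmpl, list()), "non-empty")

  # brute force: minimum over densely sampled points along the polyline
  set.seed(9)
  line <- cbind(c(-5, 120, 333), c(40, 260, 90))
  tm50 <- grid(matrix(0, 37, 41), 9, origin = c(0, 333))
  fast <- distance_from_lines(tm50, list(line))
  ts <- seq(0, 1, length.out = 4000)
  pts <- rbind(
    cbind(line[1, 1] + ts * (line[2, 1] - line[1, 1]),
          line[1, 2] + ts * (line[2, 2] - line[1, 2])),
    cbind(line[2, 1] + ts * (line[3, 1] - line[2, 1]),
          line[2, 2] + ts * (line[3, 2] - line[2, 2])))
  ctr <- cell_centers(tm50)
  px <- rep(ctr$x, each = 37); py <- rep(ctr$y, times = 41)
  brute <- sqrt(matrix(
    vapply(seq_along(px), function(i) min((pts[, 1] - px[i])^2 +
                                            (pts[, 2] - py[i])^2),
           numeric(1)), 37, 41))
  expect_equal(fast$values, brute, tolerance = 1e-3)
})

test_that("GeoJSON polylines are parsed from all common wrappers", {
  path <- withr::local_tempfile(fileext = ".geojson")
  writeLines('{"type":"FeatureCollection","features":[
    {"type":"Feature","geometry":{"type":"LineString",
      "coordinates":[[0,0],[10,10]]}},
    {"type":"Feature","geometry":{"type":"MultiLineString",
      "coordinates":[[[1,1],[2,2]],[[3,3],[4,4],[5,5]]]}}]}', path)
  lines <- read_lines_geojson(path)
  expect_length(lines, 3L)
  expect_equal(lines[[1]], rbind(c(0, 0), c(10, 10)))
  expect_equal(nrow(lines[[3]]), 3L)
})
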