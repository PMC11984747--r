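test_that("ASCII grid write/read round-trips values, NoData and georeferencing", {
  set.seed(21)
  v <- matrix(rnorm(60), 6, 10)
  v[2, 3] <- NA
  g <- raster_grid(v, xll = 68.1, yll = 6.74, cellsize = 0.25,
                   band_name = "tmin_01")
  path <- withr::local_tempfile(fileext = ".asc")
  write_asc(g, path)
  g2 <- read_asc(path)
  expect_identical(g2$values, v)             # bit-exact, incl. NA mask
  expect_identical(g2$xll, g$xll)
  expect_identical(g2$yll, g$yll)
  expect_identical(g2$cellsize, g$cellsize)
  expect_equal(g2$band_name, sub("\\.asc$", "", basename(path)))
})

test_that("raster stacks are verified mutually aligned", {
  dir <- withr::local_tempdir()
  g1 <- raster_grid(matrix(1:12, 3, 4), 70, 10, 0.5, band_name = "a")
  g2 <- raster_grid(matrix(13:24, 3, 4), 70, 10, 0.5, band_name = "b")
  write_asc(g1, file.path(dir, "a.asc"))
  write_asc(g2, file.path(dir, "b.asc"))
  stk <- read_raster_stack(file.path(dir, c("a.asc", "b.asc")))
  expect_named(stk, c("a", "b"))
  expect_identical(stk$b$values, matrix(as.numeric(13:24), 3, 4))

  bad <- raster_grid(matrix(0, 3, 4), 70, 10, 0.25, band_name = "c")
  write_asc(bad, file.path(dir, "c.asc"))
  expect_error(read_raster_stack(file.path(dir, c("a.asc", "c.asc"))),
               "misaligned.*c\\.asc")
})

test_that("clipping to the grid's own extent is the identity", {
  g <- raster_grid(matrix(rnorm(100), 10, 10), 70, 10, 0.5)
  cl <- clip_to_bbox(g, bbox(70, 75, 10, 15))
  expect_identical(cl$values, g$values)
  expect_identical(c(cl$xll, cl$yll), c(g$xll, g$yll))
})

test_that("clip windows match hand-computed pixel indices", {
  # 100x100 grid of 0.1 deg pixels, origin (60 E, 40 N at the top):
  # yll = 30 N; clip to the subcontinental box
  g <- raster_grid(matrix(seq_len(10000), 100, 100), xll = 60, yll = 30,
                   cellsize = 0.1)
  cl <- clip_to_bbox(g, india_bbox())
  # lon 68.1..70 E -> cols 82..100 (floor((68.1-60)/.1)=81 -> col 82)
  # lat 6.74..35.7 N meets the 30..40 N grid in rows 44..100
  # (row0 = floor((40-35.7)/0.1) = 43), clipped top edge at 35.7 N
  expect_equal(ncol(cl$values), 19)
  expect_equal(nrow(cl$values), 57)
  expect_equal(cl$xll, 68.1)
  expect_equal(cl$yll, 30)
  expect_identical(cl$values, g$values[44:100, 82:100])
  expect_error(clip_to_bbox(g, bbox(0, 5, 0, 5)), "does not intersect")
})

test_that("point extraction follows the half-open pixel convention", {
  v <- matrix(as.numeric(1:16), 4, 4, byrow = TRUE)  # row 1 = north
  g <- raster_grid(v, xll = 0, yll = 0, cellsize = 1)
  # pixel centres
  expect_equal(extract_at_points(g, 0.5, 3.5), 1)
  expect_equal(extract_at_points(g, 3.5, 0.5), 16)
  # west edge of a pixel belongs to it; shared vertical edge goes east-ward
  expect_equal(extract_at_points(g, 1, 3.5), 2)
  # shared horizontal edge: (top, bottom] assigns to the pixel above
  expect_equal(extract_at_points(g, 0.5, 3), 1)
  # grid corners: top edge exclusive, bottom edge inclusive
  expect_error(extract_at_points(g, 0.5, 4), "outside")
  expect_equal(extract_at_points(g, 0.5, 0), 13)
  expect_error(extract_at_points(g, 4.5, 1), "outside")
})

test_that("clip then extract equals extract on the unclipped grid", {
  sc <- basic_scenario()
  g <- sc$bio$amt
  box <- bbox(72, 78, 10, 16)
  cl <- clip_to_bbox(g, box)
  set.seed(3)
  lon <- runif(50, 72.1, 77.9)
  lat <- runif(50, 10.1, 15.9)
  expect_identical(extract_at_points(cl, lon, lat),
                   extract_at_points(g, lon, lat))
})

test_that("NoData extraction warns and propagates NA, never 0", {
  v <- matrix(1, 2, 2); v[1, 1] <- NA
  g <- raster_grid(v, 0, 0, 1)
  expect_warning(out <- extract_at_points(g, c(0.5, 1.5), c(1.5, 1.5)),
                 "NoData")
  expect_identical(out, c(NA, 1))
})

test_that("non-WGS84 rasters and degenerate boxes are rejected", {
  expect_error(raster_grid(matrix(0, 2, 2), 0, 0, 1, crs = "EPSG:32643"),
               "unsupported CRS")
  expect_error(bbox(10, 5, 0, 1), "degenerate")
})
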