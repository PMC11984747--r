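test_that("constant climate collapses the indices to their trivial values", {
  mc <- monthly_climate(tmin = rep(20, 12), tmax = rep(30, 12),
                        ppt = rep(100, 12), tavg = rep(25, 12))
  b <- compute_bioclim(mc)
  expect_equal(unname(b[["amt"]]), 25)
  expect_equal(unname(b[["tar"]]), 10)
  expect_equal(unname(b[["amdtr"]]), 10)
  expect_equal(unname(b[["iso"]]), 100)
  expect_equal(unname(b[["apn"]]), 1200)
  expect_equal(unname(b[["ts"]]), 0)
  expect_equal(unname(b[["ps"]]), 0)
})

test_that("alternating-climate indices match hand arithmetic", {
  tavg <- rep(c(20, 30), 6)
  mc <- monthly_climate(tmin = tavg - 5, tmax = tavg + 5,
                        ppt = rep(50, 12), tavg = tavg)
  b <- compute_bioclim(mc)
  expect_equal(unname(b[["tar"]]), 20)    # 35 - 15
  expect_equal(unname(b[["amdtr"]]), 10)
  expect_equal(unname(b[["iso"]]), 50)
  # sample SD = sqrt(300/11); ts = 100 * SD / (25 + 273.15)
  expect_equal(unname(b[["ts"]]), 100 * sqrt(300 / 11) / 298.15,
               tolerance = 1e-12)
  expect_equal(round(unname(b[["ts"]]), 4), 1.7516)
})

test_that("precipitation seasonality matches the one-wet-month hand value", {
  ppt <- c(rep(0, 11), 120)
  # APN = 120, SD = sqrt(13200/11), ps = 100*SD/11
  expect_equal(precipitation_seasonality(ppt),
               100 * sqrt(13200 / 11) / 11, tolerance = 1e-12)
  expect_equal(round(precipitation_seasonality(ppt), 2), 314.92)
  expect_error(precipitation_seasonality(c(rep(1, 11), -1)), "nonnegative")
})

test_that("seasonality formulas respond correctly to shifts and scalings", {
  set.seed(11)
  for (i in 1:20) {
    tavg <- runif(12, 5, 35)
    c0 <- runif(1, -5, 5)
    sd0 <- sd(tavg)
    # translation leaves the SD untouched, only the kelvin denominator moves
    expect_equal(temperature_seasonality(tavg + c0),
                 100 * sd0 / (mean(tavg) + c0 + 273.15), tolerance = 1e-12)
    ppt <- runif(12, 0, 300)
    k <- runif(1, 0.2, 5)
    expect_equal(precipitation_seasonality(k * ppt),
                 100 * k * sd(ppt) / (1 + k * sum(ppt) / 12),
                 tolerance = 1e-12)
  }
})

test_that("indices agree with an independent re-implementation on random climates", {
  set.seed(42)
  for (i in 1:1000) {
    mc <- random_monthly()
    expect_equal(unclass(compute_bioclim(mc)), bioclim_reference(mc),
                 tolerance = 1e-9)
  }
})

test_that("isothermality stays in (0, 100] and is NA for zero annual range", {
  set.seed(7)
  for (i in 1:200) {
    mc <- random_monthly()
    b <- compute_bioclim(mc)
    if (b[["tar"]] > 0 && b[["amdtr"]] > 0) {
      expect_gt(b[["iso"]], 0)
      expect_lte(b[["iso"]], 100 + 1e-12)
    }
  }
  flat <- monthly_climate(tmin = rep(10, 12), tmax = rep(10, 12),
                          ppt = rep(1, 12))
  expect_true(is.na(compute_bioclim(flat)[["iso"]]))
})

test_that("non-finite monthly values are rejected with a missing-data error", {
  expect_error(monthly_climate(tmin = c(NA, rep(0, 11)), tmax = rep(10, 12),
                               ppt = rep(1, 12)), "missing or non-finite")
  expect_error(temperature_seasonality(c(rep(10, 11), Inf)),
               "missing or non-finite")
  expect_error(monthly_climate(tmin = rep(10, 12), tmax = rep(5, 12),
                               ppt = rep(1, 12)), "tmax < tmin")
})

test_that("SD denominator and WorldClim compatibility switches work", {
  tavg <- rep(c(20, 30), 6)
  expect_equal(temperature_seasonality(tavg, sd_denominator = "n"),
               100 * 5 / 298.15, tolerance = 1e-12)
  expect_equal(temperature_seasonality(tavg, mode = "worldclim"),
               100 * sqrt(300 / 11), tolerance = 1e-12)
})

test_that("per-pixel raster application equals per-site application", {
  sc <- basic_scenario()
  cl <- sc$climate
  bio <- sc$bio
  set.seed(13)
  ij <- cbind(sample(nrow(bio$amt$values), 25, replace = TRUE),
              sample(ncol(bio$amt$values), 25, replace = TRUE))
  for (r in seq_len(nrow(ij))) {
    i <- ij[r, 1]; j <- ij[r, 2]
    mc <- monthly_climate(
      tmin = vapply(cl$tmin, function(g) g$values[i, j], 0),
      tmax = vapply(cl$tmax, function(g) g$values[i, j], 0),
      ppt = vapply(cl$ppt, function(g) g$values[i, j], 0),
      tavg = vapply(cl$tavg, function(g) g$values[i, j], 0))
    b <- compute_bioclim(mc)
    for (nm in bioclim_names())
      expect_equal(bio[[nm]]$values[i, j], unname(b[[nm]]),
                   tolerance = 1e-12)
  }
})

test_that("NoData in any month propagates to every index layer", {
  sc <- basic_scenario()
  cl <- sc$climate
  cl$ppt[[3]]$values[5, 7] <- NA
  bio <- bioclim_stack(cl$tmin, cl$tmax, cl$ppt, tavg = cl$tavg)
  for (nm in bioclim_names())
    expect_true(is.na(bio[[nm]]$values[5, 7]))
  expect_false(anyNA(bio$amt$values[-5, ]))
})
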