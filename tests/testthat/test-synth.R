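test_that("the generator is bit-reproducible from (config, seed)", {
  cfg <- scenario_preset("basic", 91)
  a <- venom_scenario(cfg)
  b <- venom_scenario(cfg)
  expect_identical(a$climate$tavg[[7]]$values, b$climate$tavg[[7]]$values)
  expect_identical(a$sites, b$sites)
  expect_identical(a$table$activity, b$table$activity)
  c2 <- venom_scenario(scenario_preset("basic", 92))
  expect_false(identical(a$table$activity, c2$table$activity))
})

test_that("zero seasonal amplitude yields TS = 0 and PS = 0 at every pixel", {
  cfg <- scenario_config(seed = 93, nrow = 10, ncol = 10,
                         seasonal_amp_t = 0, seasonal_amp_p = 0)
  cl <- simulate_monthly_climate(cfg)
  bio <- bioclim_stack(cl$tmin, cl$tmax, cl$ppt, tavg = cl$tavg)
  expect_true(all(abs(bio$ts$values) < 1e-12))
  expect_true(all(abs(bio$ps$values) < 1e-12))
})

test_that("a monotone west-east trend without bumps makes AMT increase along columns", {
  cfg <- scenario_config(seed = 94, nrow = 8, ncol = 12, n_bumps = 0,
                         trend_t = c(lon = 0.5, lat = 0))
  cl <- simulate_monthly_climate(cfg)
  bio <- bioclim_stack(cl$tmin, cl$tmax, cl$ppt, tavg = cl$tavg)
  expect_true(all(diff(t(bio$amt$values)) > 0))
  # physical ordering holds everywhere
  for (m in c(1, 6, 12)) {
    expect_true(all(cl$tmax[[m]]$values >= cl$tavg[[m]]$values))
    expect_true(all(cl$tavg[[m]]$values >= cl$tmin[[m]]$values))
    expect_true(all(cl$ppt[[m]]$values >= 0))
  }
})

test_that("site replication matches the pooled-sampling design", {
  cfg <- scenario_preset("basic", 95)
  sites <- sample_sites(cfg)
  expect_equal(nrow(sites), 115)
  expect_equal(nrow(unique(sites[, c("longitude", "latitude")])), 34)

  all_unique <- scenario_config(seed = 95, n_locations = 20, n_samples = 20)
  s2 <- sample_sites(all_unique)
  expect_equal(nrow(unique(s2[, c("longitude", "latitude")])), 20)

  jit <- scenario_config(seed = 95, jitter = 0.5)
  s3 <- sample_sites(jit)
  expect_equal(nrow(unique(s3[, c("longitude", "latitude")])), 115)
  # jitter stays below one pixel
  expect_true(max(abs(s3$longitude - sites$longitude)) < jit$cellsize)
})

test_that("noiseless activities are recovered exactly by the regression", {
  cfg <- scenario_preset("basic", 96, sigma = 0)
  sc <- venom_scenario(cfg)
  f <- ols_fit(as.matrix(sc$table[, names(cfg$beta)]), sc$table$activity)
  expect_equal(f$r2, 1, tolerance = 1e-10)
  expect_equal(setNames(f$coefficients[names(cfg$beta), "estimate"],
                        names(cfg$beta)),
               cfg$beta, tolerance = 1e-8)
})

test_that("the heteroscedastic preset scales the error SD with its covariate", {
  cfg <- scenario_preset("hetero", 97)
  sc <- venom_scenario(cfg)
  expect_equal(sc$truth$sd_site,
               cfg$sigma * sc$bio_at_sites$apn / mean(sc$bio_at_sites$apn),
               tolerance = 1e-12)
})

test_that("spatially correlated errors carry the imposed correlation structure", {
  cfg <- scenario_preset("spatial", 98, n_locations = 80, n_samples = 80,
                         sigma = 5)
  cl <- simulate_monthly_climate(cfg)
  bio <- bioclim_stack(cl$tmin, cl$tmax, cl$ppt, tavg = cl$tavg)
  sites <- sample_sites(cfg)
  ba <- bioclim_at_points(bio, sites$longitude, sites$latitude)
  # average over replicate draws: nearby errors correlate, distant do not
  d <- as.matrix(dist(cbind(sites$longitude, sites$latitude)))
  near <- d > 0 & d < 1; far <- d > 6
  cors_near <- numeric(30); cors_far <- numeric(30)
  for (r in 1:30) {
    act <- simulate_activities(sites, ba, cfg, seed = 5000 + r)
    eps <- apply_transform(act$table$activity, cfg$transform) -
      act$truth$linpred
    ee <- tcrossprod(eps)
    cors_near[r] <- mean(ee[near]); cors_far[r] <- mean(ee[far])
  }
  expect_gt(mean(cors_near), 2 * abs(mean(cors_far)))
})

test_that("scenario misconfiguration is rejected up front", {
  expect_error(scenario_config(), "seed is mandatory")
  expect_error(scenario_config(seed = 1, sigma = -1), "sigma")
  expect_error(scenario_config(seed = 1, beta = c(foo = 1)),
               "beta names")
  expect_error(scenario_config(seed = 1, n_locations = 10, n_samples = 5),
               "n_locations")
})

test_that("an inconsistent transform/noise pairing warns about redraws", {
  cfg <- scenario_preset("basic", 99, intercept = 2,
                         beta = c(amt = 0.05), sigma = 30)
  cl <- simulate_monthly_climate(cfg)
  bio <- bioclim_stack(cl$tmin, cl$tmax, cl$ppt, tavg = cl$tavg)
  sites <- sample_sites(cfg)
  ba <- bioclim_at_points(bio, sites$longitude, sites$latitude)
  expect_warning(simulate_activities(sites, ba, cfg), "redrew")
})
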