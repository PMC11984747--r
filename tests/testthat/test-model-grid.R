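test_that("data generated on the log scale downselects the ln cell with the true support", {
  cfg <- scenario_preset("lognormal", 61)
  sc <- venom_scenario(cfg)
  # selection of a noisy winner is itself stochastic: require the modal
  # choice over replicate noise draws to be the generating transform
  sel <- character(7)
  ln_card <- NULL
  for (r in 1:7) {
    act <- simulate_activities(sc$sites, sc$bio_at_sites, cfg,
                               seed = 7000 + r)
    card <- build_model_grid(act$table, "activity", names(cfg$beta))
    sel[r] <- card$selected
    if (is.null(ln_card) && identical(card$selected, "ln")) ln_card <- card
  }
  expect_gte(sum(sel == "ln", na.rm = TRUE), 5)
  expect_true(ln_card$grid$downselected[ln_card$grid$transform == "ln"])
  expect_setequal(ln_card$fits$ln$predictors, names(cfg$beta))
  # recovered coefficients near the generating ones
  est <- ln_card$fits$ln$coefficients[names(cfg$beta), "estimate"]
  se <- ln_card$fits$ln$coefficients[names(cfg$beta), "se"]
  expect_true(all(abs(est - cfg$beta) < 4 * se))
})

test_that("a pure-noise response yields no downselected model", {
  sc <- basic_scenario()
  dat <- sc$table
  set.seed(62)
  hits <- 0
  for (r in 1:10) {
    dat$activity <- runif(nrow(dat), 50, 150)
    card <- build_model_grid(dat, "activity", c("amt", "ps"))
    if (!is.na(card$selected) &&
        card$grid$f_p[card$grid$transform == card$selected] <= 0.05)
      hits <- hits + 1
  }
  # F-test significance gates selection; false selections are rare
  expect_lte(hits, 2)
})

test_that("a single-predictor grid cell reduces exactly to the simple regression", {
  sc <- basic_scenario()
  card <- build_model_grid(sc$table, "activity", "ps",
                           transforms = "identity")
  direct <- ols_fit(as.matrix(sc$table[, "ps", drop = FALSE]),
                    sc$table$activity)
  expect_equal(card$fits$identity$coefficients, direct$coefficients,
               tolerance = 1e-12)
  expect_equal(card$fits$identity$adj_r2, direct$adj_r2)
})

test_that("multicollinearity reports but never vetoes downselection", {
  cfg <- scenario_preset("collinear", 63)
  sc <- venom_scenario(cfg)
  # the shared-latent-factor construction inflates VIF in the full model
  full <- ols_fit(as.matrix(sc$table[, c("amt", "tar", "amdtr", "ps")]),
                  sc$table$activity)
  expect_gt(max(run_diagnostics(full)$vif), 10)

  card <- build_model_grid(sc$table, "activity",
                           c("amt", "tar", "amdtr", "ps"))
  g <- card$grid
  if (!is.na(card$selected)) {
    sel <- g[g$transform == card$selected, ]
    expect_true(sel$N && sel$H && sel$L)   # only N/H/L gate selection
  }
})

test_that("transforms whose domain excludes the data yield unavailable cells, not errors", {
  sc <- basic_scenario()
  dat <- sc$table
  dat$activity[1] <- 0                     # kills ln and inverse
  card <- build_model_grid(dat, "activity", c("amt", "ps"))
  g <- card$grid
  expect_false(g$available[g$transform == "ln"])
  expect_false(g$available[g$transform == "inverse"])
  expect_true(g$available[g$transform == "identity"])
})

test_that("model cards serialize to JSON and rebuild the prediction equation", {
  cfg <- scenario_preset("lognormal", 61)
  sc <- venom_scenario(cfg)
  card <- build_model_grid(sc$table, "activity", names(cfg$beta))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_card(card, path)
  mod <- read_model_json(path, transform = "ln")
  f <- card$fits[["ln"]]
  expect_equal(mod$transform, "ln")
  expect_equal(mod$intercept, f$coefficients["(Intercept)", "estimate"])
  expect_equal(mod$beta[f$predictors],
               setNames(f$coefficients[f$predictors, "estimate"],
                        f$predictors))
})
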