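# shared synthetic objects, built once per test run

# small basic scenario: full chain with default study-condition sizes
basic_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- venom_scenario("basic", seed = 101)
    cache
  }
})

# random monthly climate for oracle sweeps
random_monthly <- function() {
  tmin <- runif(12, -5, 20)
  tmax <- tmin + runif(12, 0.5, 15)
  monthly_climate(tmin = tmin, tmax = tmax,
                  ppt = runif(12, 0, 400),
                  tavg = tmin + runif(12, 0, 1) * (tmax - tmin))
}

# straight-line re-implementation of the seven index formulas,
# independent of compute_bioclim's code path
bioclim_reference <- function(mc) {
  amt <- sum(mc$tavg) / 12
  tar <- max(mc$tmax) - min(mc$tmin)
  amdtr <- sum(mc$tmax - mc$tmin) / 12
  sdt <- sqrt(sum((mc$tavg - amt)^2) / 11)
  apn <- sum(mc$ppt)
  pbar <- apn / 12
  sdp <- sqrt(sum((mc$ppt - pbar)^2) / 11)
  c(amt = amt, tar = tar, amdtr = amdtr,
    iso = if (tar > 0) amdtr / tar * 100 else NA_real_,
    ts = 100 * sdt / (amt + 273.15),
    apn = apn,
    ps = 100 * sdp / (1 + pbar))
}

# closed-form normal-equations OLS, independent of ols_fit's lm route
ols_reference <- function(X, y) {
  A <- cbind(1, as.matrix(X))
  beta <- solve(t(A) %*% A, t(A) %*% y)
  fitted <- drop(A %*% beta)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  n <- nrow(A); p <- ncol(A)
  sigma2 <- rss / (n - p)
  se <- sqrt(diag(solve(t(A) %*% A)) * sigma2)
  r2 <- 1 - rss / tss
  list(beta = drop(beta), se = se, r2 = r2,
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p))
}
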