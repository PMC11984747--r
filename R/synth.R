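#' Scenario configuration for the synthetic generator
#'
#' Describes one fully seeded synthetic study: a gridded climate over a
#' rectangular extent, a set of sampling locations with within-location
#' replication (mirroring a field design of ~115 venom samples pooled over
#' ~34 point locations), and activities generated from a known linear model
#' of the bioclimatic predictors on a chosen transform scale.
#'
#' @param seed Integer random seed (mandatory; every draw derives from it).
#' @param nrow,ncol Grid shape in pixels.
#' @param cellsize Pixel size in degrees.
#' @param xll,yll Lower-left corner of the grid (decimal degrees).
#' @param n_locations Number of distinct sampling locations (default 34).
#' @param n_samples Number of venom samples (default 115); locations are
#'   reused for the surplus samples.
#' @param jitter Replicate coordinate jitter as a fraction of a pixel
#'   (default 0: replicates share their location's coordinates exactly;
#'   values in (0, 1) mimic pooled nearby samples).
#' @param transform True response transform ("identity", "ln", "sqrt",
#'   "inverse").
#' @param intercept,beta True intercept and named coefficient vector on the
#'   transform scale; `beta` names must be bioclim indices
#'   (see [bioclim_names()]).
#' @param sigma Error SD on the transform scale (>= 0).
#' @param hetero_covariate Optional bioclim index name; when set, the error
#'   SD at a site is `sigma * x / mean(x)` for that covariate
#'   (heteroscedastic errors).
#' @param spatial_range Exponential correlation range of the errors in
#'   degrees (0 = independent errors).
#' @param beta_east Optional named increments added to `beta` for sites in
#'   the eastern half of the extent (a spatially non-stationary truth for
#'   exercising GWR).
#' @param seasonal_amp_t Seasonal half-amplitude of monthly mean
#'   temperature (degrees C).
#' @param seasonal_amp_p Relative seasonal amplitude of monthly
#'   precipitation (0..1).
#' @param trend_t Named vector `c(lon = , lat = )`: linear temperature trend
#'   (degrees C per degree of longitude/latitude).
#' @param n_bumps Number of Gaussian bumps per smooth spatial field (0 =
#'   pure trend fields).
#' @param collinear If `TRUE`, the diurnal-range field is tied to the
#'   annual-temperature field, making AMT, TAR and AMDTR near-collinear
#'   (high VIF) by construction.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(seed,
                            nrow = 40, ncol = 40, cellsize = 0.25,
                            xll = 70, yll = 8,
                            n_locations = 34, n_samples = 115,
                            jitter = 0,
                            transform = "identity",
                            intercept = 10,
                            beta = c(amt = 3, ps = 0.8),
                            sigma = 8,
                            hetero_covariate = NULL,
                            spatial_range = 0,
                            beta_east = NULL,
                            seasonal_amp_t = 6,
                            seasonal_amp_p = 0.8,
                            trend_t = c(lon = 0.3, lat = -0.5),
                            n_bumps = 8,
                            collinear = FALSE) {
  if (missing(seed) || !is.numeric(seed))
    stop("seed is mandatory", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (!all(names(beta) %in% bioclim_names()))
    stop("beta names must be bioclim indices: ",
         paste(bioclim_names(), collapse = ", "), call. = FALSE)
  if (n_locations > n_samples)
    stop("n_locations cannot exceed n_samples", call. = FALSE)
  transform <- match.arg(transform, c("identity", "ln", "sqrt", "inverse"))
  structure(as.list(environment()), class = "scenario_config")
}

# sum of seeded Gaussian bumps over the grid, rescaled to [0, 1]
smooth_field <- function(lon, lat, cfg, n_bumps = cfg$n_bumps) {
  if (n_bumps == 0) return(matrix(0, nrow(lon), ncol(lon)))
  ex <- cfg$ncol * cfg$cellsize
  ey <- cfg$nrow * cfg$cellsize
  cx <- stats::runif(n_bumps, cfg$xll, cfg$xll + ex)
  cy <- stats::runif(n_bumps, cfg$yll, cfg$yll + ey)
  w <- stats::runif(n_bumps, 0.15, 0.4) * max(ex, ey)
  a <- stats::runif(n_bumps, -1, 1)
  f <- matrix(0, nrow(lon), ncol(lon))
  for (i in seq_len(n_bumps))
    f <- f + a[i] * exp(-((lon - cx[i])^2 + (lat - cy[i])^2) / (2 * w[i]^2))
  rng <- range(f)
  if (diff(rng) == 0) return(matrix(0, nrow(lon), ncol(lon)))
  (f - rng[1]) / diff(rng)
}

#' Simulate monthly climate grids
#'
#' Builds 12-month stacks of tmin, tmax, tavg and precipitation over the
#' scenario grid. Each field is a low-order spatial trend plus a seeded sum
#' of Gaussian bumps; seasonal cycles have spatially varying amplitude so
#' the seasonality indices (TS, PS) span a range across the extent. The
#' construction enforces `tmax >= tavg >= tmin` (symmetric diurnal range)
#' and `ppt >= 0` everywhere; the same `(config, seed)` always yields
#' bit-identical grids.
#'
#' @param cfg A [scenario_config()].
#' @return List with elements `tmin`, `tmax`, `tavg`, `ppt`, each a list of
#'   12 aligned [raster_grid()] layers.
#' @export
simulate_monthly_climate <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed + 1L)
  # pixel-centre coordinates; row 1 = north
  lon_c <- cfg$xll + (seq_len(cfg$ncol) - 0.5) * cfg$cellsize
  lat_c <- cfg$yll + (cfg$nrow - seq_len(cfg$nrow) + 0.5) * cfg$cellsize
  lon <- matrix(lon_c, cfg$nrow, cfg$ncol, byrow = TRUE)
  lat <- matrix(lat_c, cfg$nrow, cfg$ncol)

  base_t <- 25 + cfg$trend_t[["lon"]] * (lon - cfg$xll) +
    cfg$trend_t[["lat"]] * (lat - cfg$yll) +
    3 * smooth_field(lon, lat, cfg)
  amp_t <- cfg$seasonal_amp_t * (0.5 + 0.5 * smooth_field(lon, lat, cfg))
  dr <- if (cfg$collinear) {
    # diurnal range tied to annual temperature: AMT/TAR/AMDTR collinear
    rngt <- range(base_t)
    span <- if (diff(rngt) > 0) diff(rngt) else 1
    6 + 6 * (base_t - rngt[1]) / span +
      0.3 * smooth_field(lon, lat, cfg)
  } else {
    6 + 6 * smooth_field(lon, lat, cfg)
  }
  base_p <- 40 + 120 * smooth_field(lon, lat, cfg)
  amp_p <- pmin(cfg$seasonal_amp_p * (0.4 + 0.6 *
                                        smooth_field(lon, lat, cfg)), 1)

  mk <- function(values, name) {
    raster_grid(values, xll = cfg$xll, yll = cfg$yll,
                cellsize = cfg$cellsize, band_name = name)
  }
  months <- seq_len(12)
  tavg <- lapply(months, function(m)
    mk(base_t + amp_t * cospi(2 * (m - 5) / 12), sprintf("tavg_%02d", m)))
  tmin <- lapply(months, function(m)
    mk(tavg[[m]]$values - dr / 2, sprintf("tmin_%02d", m)))
  tmax <- lapply(months, function(m)
    mk(tavg[[m]]$values + dr / 2, sprintf("tmax_%02d", m)))
  ppt <- lapply(months, function(m)
    mk(pmax(base_p * (1 + amp_p * cospi(2 * (m - 7) / 12)), 0),
       sprintf("ppt_%02d", m)))
  list(tmin = tmin, tmax = tmax, tavg = tavg, ppt = ppt)
}

#' Draw sampling locations and replicate them into a sample skeleton
#'
#' Draws `n_locations` points uniformly inside the grid extent (one pixel
#' margin) and assigns the `n_samples` samples round-robin to locations.
#' With the default `jitter = 0` replicates share coordinates exactly, so
#' the number of unique coordinate pairs equals `n_locations`; positive
#' jitter displaces replicates by less than `jitter` pixels to mimic pooled
#' nearby samples.
#'
#' @param cfg A [scenario_config()].
#' @return Data frame: `sample_id`, `location_id`, `longitude`, `latitude`.
#' @export
sample_sites <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed + 2L)
  cs <- cfg$cellsize
  loc_lon <- stats::runif(cfg$n_locations, cfg$xll + cs,
                          cfg$xll + (cfg$ncol - 1) * cs)
  loc_lat <- stats::runif(cfg$n_locations, cfg$yll + cs,
                          cfg$yll + (cfg$nrow - 1) * cs)
  loc <- rep_len(seq_len(cfg$n_locations), cfg$n_samples)
  lon <- loc_lon[loc]
  lat <- loc_lat[loc]
  if (cfg$jitter > 0) {
    extra <- duplicated(loc)
    lon[extra] <- lon[extra] +
      stats::runif(sum(extra), -1, 1) * cfg$jitter * cs / 2
    lat[extra] <- lat[extra] +
      stats::runif(sum(extra), -1, 1) * cfg$jitter * cs / 2
  }
  data.frame(sample_id = sprintf("S%03d", seq_len(cfg$n_samples)),
             location_id = sprintf("L%02d", loc),
             longitude = lon, latitude = lat)
}

#' Simulate venom activities from bioclimatic covariates
#'
#' Generates `transform(activity) = intercept + X beta + eps` at every
#' sample, with Gaussian errors that are optionally heteroscedastic (SD
#' proportional to a covariate) and/or spatially correlated (exponential
#' covariance over inter-site distance). Activities are recovered by
#' [back_transform()]; draws whose transform-scale value falls outside the
#' transform's domain (e.g. a negative activity under `identity`) are
#' redrawn per sample, and a redraw total above 10% of the samples triggers
#' a warning that the scenario is inconsistent with the transform.
#'
#' @param sites Data frame from [sample_sites()].
#' @param bio Data frame of bioclim covariates at the samples (one row per
#'   sample, columns named as [bioclim_names()]).
#' @param cfg A [scenario_config()].
#' @param seed Seed for the error draws (default `cfg$seed + 3`); vary it to
#'   replicate the same scenario with fresh noise.
#' @return List: `table` (validated sample table with an `activity` column)
#'   and `truth` (`beta`, `beta_site` matrix when `beta_east` is set,
#'   `intercept`, `transform`, `sigma`, `sd_site`, `linpred` (noise-free
#'   transform scale), `activity_true` (noise-free activity units),
#'   `n_redraws`).
#' @export
simulate_activities <- function(sites, bio, cfg, seed = cfg$seed + 3L) {
  stopifnot(inherits(cfg, "scenario_config"))
  n <- nrow(sites)
  vars <- names(cfg$beta)
  if (!all(vars %in% names(bio)))
    stop("bio lacks covariate(s): ",
         paste(setdiff(vars, names(bio)), collapse = ", "), call. = FALSE)
  X <- as.matrix(bio[, vars, drop = FALSE])
  if (any(!is.finite(X)))
    stop("non-finite bioclim covariates at the sites", call. = FALSE)
  set.seed(seed)

  beta_site <- matrix(cfg$beta, n, length(vars), byrow = TRUE,
                      dimnames = list(NULL, vars))
  if (!is.null(cfg$beta_east)) {
    east <- sites$longitude > cfg$xll + cfg$ncol * cfg$cellsize / 2
    for (v in names(cfg$beta_east))
      beta_site[east, v] <- beta_site[east, v] + cfg$beta_east[[v]]
  }
  linpred <- cfg$intercept + rowSums(X * beta_site)

  sd_site <- rep(cfg$sigma, n)
  if (!is.null(cfg$hetero_covariate)) {
    h <- bio[[cfg$hetero_covariate]]
    if (is.null(h)) stop("unknown hetero covariate", call. = FALSE)
    sd_site <- cfg$sigma * h / mean(h)
  }

  draw_eps <- function() {
    if (cfg$spatial_range > 0) {
      d <- as.matrix(stats::dist(cbind(sites$longitude, sites$latitude)))
      S <- exp(-d / cfg$spatial_range)
      z <- drop(t(chol(S + diag(1e-10, n))) %*% stats::rnorm(n))
      z * sd_site
    } else {
      stats::rnorm(n, 0, sd_site)
    }
  }
  domain_ok <- function(yt) {
    switch(cfg$transform,
           identity = yt > 0, ln = rep(TRUE, length(yt)),
           sqrt = yt >= 0, inverse = yt > 0)
  }
  yt <- linpred + draw_eps()
  n_redraws <- 0L
  bad <- which(!domain_ok(yt))
  tries <- 0L
  while (length(bad) > 0 && tries < 100L) {
    n_redraws <- n_redraws + length(bad)
    yt[bad] <- linpred[bad] + stats::rnorm(length(bad), 0, sd_site[bad])
    bad <- bad[!domain_ok(yt[bad])]
    tries <- tries + 1L
  }
  if (length(bad) > 0)
    stop("could not draw domain-valid activities for sample(s) ",
         paste(bad, collapse = ", "),
         "; the scenario is inconsistent with transform '",
         cfg$transform, "'", call. = FALSE)
  if (n_redraws > 0.1 * n)
    warning("redrew ", n_redraws, " error draws (> 10% of samples): ",
            "the scenario is barely consistent with transform '",
            cfg$transform, "'", call. = FALSE)

  tab <- cbind(sites, bio[, setdiff(names(bio), c("lon", "lat")),
                          drop = FALSE])
  tab$activity <- back_transform(yt, cfg$transform)
  tab <- validate_sample_table(tab, activity_cols = "activity")
  truth <- list(beta = cfg$beta,
                beta_site = if (is.null(cfg$beta_east)) NULL else beta_site,
                intercept = cfg$intercept, transform = cfg$transform,
                sigma = cfg$sigma, sd_site = sd_site,
                linpred = linpred,
                activity_true = back_transform(linpred, cfg$transform),
                n_redraws = n_redraws)
  list(table = tab, truth = truth)
}

#' Run a complete synthetic scenario
#'
#' Convenience chain: [simulate_monthly_climate()] -> [bioclim_stack()] ->
#' [sample_sites()] -> [bioclim_at_points()] -> [simulate_activities()].
#'
#' @param cfg A [scenario_config()], or a preset name (see
#'   [scenario_preset()]) combined with `seed`.
#' @param seed Seed when `cfg` is a preset name.
#' @param activity_seed Seed for the error draws only (defaults to
#'   `seed + 3`).
#' @return List: `cfg`, `climate` (monthly stacks), `bio` (bioclim index
#'   rasters), `sites`, `bio_at_sites`, `table`, `truth`.
#' @export
venom_scenario <- function(cfg, seed = NULL, activity_seed = NULL) {
  if (is.character(cfg)) cfg <- scenario_preset(cfg, seed)
  stopifnot(inherits(cfg, "scenario_config"))
  climate <- simulate_monthly_climate(cfg)
  bio <- bioclim_stack(climate$tmin, climate$tmax, climate$ppt,
                       tavg = climate$tavg)
  sites <- sample_sites(cfg)
  bio_at <- bioclim_at_points(bio, sites$longitude, sites$latitude)
  act <- simulate_activities(
    sites, bio_at, cfg,
    seed = if (is.null(activity_seed)) cfg$seed + 3L else activity_seed)
  list(cfg = cfg, climate = climate, bio = bio, sites = sites,
       bio_at_sites = bio_at, table = act$table, truth = act$truth)
}

#' Preset synthetic scenarios
#'
#' Named variants that between them exercise every diagnostic gate:
#' \describe{
#'   \item{basic}{identity transform, Gaussian homoscedastic errors; the
#'     well-specified baseline.}
#'   \item{lognormal}{truth on the log scale (multiplicative errors); the
#'     identity-scale fit violates normality/homoscedasticity while the
#'     `ln` cell is well specified.}
#'   \item{hetero}{error SD proportional to annual precipitation; trips the
#'     Breusch-Pagan gate.}
#'   \item{collinear}{temperature indices generated from a shared latent
#'     field; trips the VIF gate.}
#'   \item{spatial}{spatially correlated errors (exponential range 2
#'     degrees); the GWR check is informative here.}
#' }
#'
#' @param preset One of `"basic"`, `"lognormal"`, `"hetero"`,
#'   `"collinear"`, `"spatial"`.
#' @param seed Integer seed.
#' @param ... Overrides passed to [scenario_config()].
#' @return A [scenario_config()].
#' @export
scenario_preset <- function(preset = c("basic", "lognormal", "hetero",
                                       "collinear", "spatial"),
                            seed, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    basic = list(),
    lognormal = list(transform = "ln", intercept = -4,
                     beta = c(amt = 0.35, ps = 0.07), sigma = 0.35),
    hetero = list(n_locations = 200, n_samples = 200,
                  beta = c(amt = 3, apn = 0.02),
                  hetero_covariate = "apn"),
    collinear = list(collinear = TRUE,
                     beta = c(amt = 3, amdtr = 2, ps = 0.8)),
    spatial = list(spatial_range = 2))
  over <- list(...)
  args[names(over)] <- over
  do.call(scenario_config, c(list(seed = seed), args))
}
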