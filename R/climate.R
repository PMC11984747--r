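#' Monthly climate record for one site or pixel
#'
#' Bundles the twelve monthly minimum, maximum and mean temperatures (degrees
#' Celsius) and monthly precipitation totals (mm) that the bioclimatic indices
#' are computed from. When `tavg` is not supplied it is taken as
#' `(tmax + tmin) / 2`.
#'
#' @param tmin,tmax Numeric vectors of length 12, monthly minimum and maximum
#'   temperature (degrees C). `tmax` must be >= `tmin` in every month.
#' @param ppt Numeric vector of length 12, monthly precipitation totals (mm),
#'   nonnegative.
#' @param tavg Optional numeric vector of length 12, monthly mean temperature
#'   (degrees C). Defaults to the midpoint of `tmin` and `tmax`.
#' @return An object of class `monthly_climate`: a list with elements `tmin`,
#'   `tmax`, `tavg`, `ppt`.
#' @examples
#' mc <- monthly_climate(tmin = rep(20, 12), tmax = rep(30, 12),
#'                       ppt = rep(100, 12))
#' compute_bioclim(mc)
#' @export
monthly_climate <- function(tmin, tmax, ppt, tavg = NULL) {
  check_month_vec(tmin, "tmin")
  check_month_vec(tmax, "tmax")
  check_month_vec(ppt, "ppt")
  if (any(ppt < 0))
    stop("ppt must be nonnegative (months ",
         paste(which(ppt < 0), collapse = ", "), ")", call. = FALSE)
  if (any(tmax < tmin))
    stop("tmax < tmin in months ",
         paste(which(tmax < tmin), collapse = ", "), call. = FALSE)
  if (is.null(tavg)) {
    tavg <- (tmax + tmin) / 2
  } else {
    check_month_vec(tavg, "tavg")
  }
  structure(list(tmin = as.numeric(tmin), tmax = as.numeric(tmax),
                 tavg = as.numeric(tavg), ppt = as.numeric(ppt)),
            class = "monthly_climate")
}

check_month_vec <- function(x, name) {
  if (!is.numeric(x) || length(x) != 12L)
    stop(name, " must be a numeric vector of length 12", call. = FALSE)
  if (any(!is.finite(x)))
    stop("missing or non-finite monthly value in ", name,
         " (months ", paste(which(!is.finite(x)), collapse = ", "), ")",
         call. = FALSE)
  invisible(x)
}

#' Names of the seven bioclimatic indices
#'
#' @return Character vector: `amt`, `tar`, `amdtr`, `iso`, `ts`, `apn`, `ps`.
#' @export
bioclim_names <- function() c("amt", "tar", "amdtr", "iso", "ts", "apn", "ps")

month_sd <- function(x, sd_denominator) {
  if (sd_denominator == "n-1") stats::sd(x)
  else sqrt(sum((x - mean(x))^2) / length(x))
}

#' Temperature seasonality (coefficient of variation x 100)
#'
#' `100 * SD(tavg) / (AMT + 273.15)`: the dispersion of the twelve monthly
#' mean temperatures relative to the annual mean expressed in kelvin. A
#' `worldclim` compatibility mode returns the plain `SD(tavg) * 100`
#' convention (no kelvin denominator) used by the WorldClim BIO4 rasters.
#'
#' @param tavg Numeric vector of 12 monthly mean temperatures (degrees C).
#' @param sd_denominator `"n-1"` (sample SD, default) or `"n"` (population
#'   SD, the WorldClim convention).
#' @param mode `"cv"` (default) or `"worldclim"`.
#' @return Scalar seasonality index (dimensionless, CV x 100).
#' @export
temperature_seasonality <- function(tavg, sd_denominator = c("n-1", "n"),
                                    mode = c("cv", "worldclim")) {
  sd_denominator <- match.arg(sd_denominator)
  mode <- match.arg(mode)
  check_month_vec(tavg, "tavg")
  s <- month_sd(tavg, sd_denominator)
  if (mode == "worldclim") return(100 * s)
  100 * s / (mean(tavg) + 273.15)
}

#' Precipitation seasonality (coefficient of variation x 100)
#'
#' `100 * SD(ppt) / (1 + APN / 12)`: the dispersion of monthly precipitation
#' relative to (one plus) the mean monthly total. The `+1` keeps the index
#' defined in fully arid pixels.
#'
#' @param ppt Numeric vector of 12 monthly precipitation totals (mm),
#'   nonnegative.
#' @inheritParams temperature_seasonality
#' @return Scalar seasonality index (dimensionless, CV x 100).
#' @export
precipitation_seasonality <- function(ppt, sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  check_month_vec(ppt, "ppt")
  if (any(ppt < 0))
    stop("ppt must be nonnegative (months ",
         paste(which(ppt < 0), collapse = ", "), ")", call. = FALSE)
  100 * month_sd(ppt, sd_denominator) / (1 + sum(ppt) / 12)
}

#' Compute the seven bioclimatic indices from monthly climate
#'
#' Reduces one site's (or pixel's) twelve-month climatology to the seven
#' predictors used throughout the package:
#' \describe{
#'   \item{amt}{annual mean temperature, `mean(tavg)` (degrees C)}
#'   \item{tar}{temperature annual range, `max(tmax) - min(tmin)` (degrees C)}
#'   \item{amdtr}{annual mean diurnal temperature range,
#'     `mean(tmax - tmin)` (degrees C)}
#'   \item{iso}{isothermality, `amdtr / tar * 100` (percent); `NA` when
#'     `tar == 0`}
#'   \item{ts}{temperature seasonality, see [temperature_seasonality()]}
#'   \item{apn}{annual precipitation, `sum(ppt)` (mm)}
#'   \item{ps}{precipitation seasonality, see [precipitation_seasonality()]}
#' }
#'
#' @param mc A [monthly_climate()] object.
#' @inheritParams temperature_seasonality
#' @param ts_mode Seasonality convention for `ts`, passed to
#'   [temperature_seasonality()] as `mode`.
#' @return Named numeric vector of class `bioclim` with the seven indices.
#' @export
compute_bioclim <- function(mc, sd_denominator = c("n-1", "n"),
                            ts_mode = c("cv", "worldclim")) {
  sd_denominator <- match.arg(sd_denominator)
  ts_mode <- match.arg(ts_mode)
  stopifnot(inherits(mc, "monthly_climate"))
  amt <- mean(mc$tavg)
  tar <- max(mc$tmax) - min(mc$tmin)
  amdtr <- mean(mc$tmax - mc$tmin)
  iso <- if (tar > 0) amdtr / tar * 100 else NA_real_
  out <- c(
    amt = amt,
    tar = tar,
    amdtr = amdtr,
    iso = iso,
    ts = temperature_seasonality(mc$tavg, sd_denominator, ts_mode),
    apn = sum(mc$ppt),
    ps = precipitation_seasonality(mc$ppt, sd_denominator)
  )
  class(out) <- c("bioclim", "numeric")
  out
}

#' @export
print.bioclim <- function(x, ...) {
  cat("Bioclimatic indices:\n")
  print(round(unclass(x), 4), ...)
  invisible(x)
}

#' Compute bioclimatic index rasters from monthly climate stacks
#'
#' Per-pixel application of [compute_bioclim()] over aligned 12-layer raster
#' stacks. A pixel that is NoData in any input layer is NoData in every
#' output layer. Per-pixel results are identical to calling
#' [compute_bioclim()] on the monthly vector extracted at that pixel.
#'
#' @param tmin,tmax,ppt Lists of 12 aligned [raster_grid()] layers (months
#'   January to December).
#' @param tavg Optional list of 12 aligned layers; defaults to the per-pixel
#'   midpoint of `tmin` and `tmax`.
#' @inheritParams compute_bioclim
#' @return Named list of seven [raster_grid()] layers (`amt`, `tar`, `amdtr`,
#'   `iso`, `ts`, `apn`, `ps`).
#' @export
bioclim_stack <- function(tmin, tmax, ppt, tavg = NULL,
                          sd_denominator = c("n-1", "n"),
                          ts_mode = c("cv", "worldclim")) {
  sd_denominator <- match.arg(sd_denominator)
  ts_mode <- match.arg(ts_mode)
  for (nm in c("tmin", "tmax", "ppt")) {
    stk <- get(nm)
    if (!is.list(stk) || length(stk) != 12L)
      stop(nm, " must be a list of 12 raster_grid layers", call. = FALSE)
  }
  ref <- tmin[[1]]
  all_layers <- c(tmin, tmax, ppt, tavg)
  for (g in all_layers) check_aligned(ref, g)

  as_cube <- function(stk) {
    # pixels x 12 matrix, NA = NoData
    do.call(cbind, lapply(stk, function(g) as.vector(g$values)))
  }
  tn <- as_cube(tmin); tx <- as_cube(tmax); pp <- as_cube(ppt)
  ta <- if (is.null(tavg)) (tn + tx) / 2 else as_cube(tavg)

  valid <- stats::complete.cases(cbind(tn, tx, pp, ta))
  n <- nrow(tn)
  out <- matrix(NA_real_, n, 7, dimnames = list(NULL, bioclim_names()))

  if (any(valid)) {
    tnv <- tn[valid, , drop = FALSE]; txv <- tx[valid, , drop = FALSE]
    ppv <- pp[valid, , drop = FALSE]; tav <- ta[valid, , drop = FALSE]
    row_sd <- function(m) {
      mu <- rowMeans(m)
      ss <- rowSums((m - mu)^2)
      if (sd_denominator == "n-1") sqrt(ss / (ncol(m) - 1))
      else sqrt(ss / ncol(m))
    }
    amt <- rowMeans(tav)
    tar <- apply(txv, 1, max) - apply(tnv, 1, min)
    amdtr <- rowMeans(txv - tnv)
    iso <- ifelse(tar > 0, amdtr / tar * 100, NA_real_)
    sdt <- row_sd(tav)
    ts <- if (ts_mode == "worldclim") 100 * sdt else
      100 * sdt / (amt + 273.15)
    apn <- rowSums(ppv)
    ps <- 100 * row_sd(ppv) / (1 + apn / 12)
    out[valid, ] <- cbind(amt, tar, amdtr, iso, ts, apn, ps)
  }

  stats::setNames(lapply(bioclim_names(), function(nm) {
    raster_grid(matrix(out[, nm], nrow = nrow(ref$values)),
                xll = ref$xll, yll = ref$yll, cellsize = ref$cellsize,
                band_name = nm)
  }), bioclim_names())
}

#' Extract bioclimatic predictors at sampling points
#'
#' Convenience wrapper: samples each index raster of a [bioclim_stack()]
#' result at the given coordinates (nearest-pixel rule) and returns a
#' data frame with one column per index.
#'
#' @param bio Named list of [raster_grid()] layers, as from [bioclim_stack()].
#' @param lon,lat Numeric vectors of point coordinates (decimal degrees).
#' @return Data frame with columns `lon`, `lat` and one column per layer.
#' @export
bioclim_at_points <- function(bio, lon, lat) {
  vals <- lapply(bio, extract_at_points, lon = lon, lat = lat)
  out <- data.frame(lon = lon, lat = lat)
  for (nm in names(bio)) out[[nm]] <- vals[[nm]]
  out
}
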