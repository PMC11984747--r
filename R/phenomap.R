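#' Project a fitted model pixel-wise into a venom phenotype map
#'
#' Evaluates `intercept + sum(beta_j * x_j)` at every pixel of an aligned
#' bioclimatic raster stack, back-transforms to activity units, and returns
#' the predicted-activity raster with summary statistics and marginal
#' profiles (per-row and per-column mean activity over valid pixels, the
#' strips drawn along the map axes). A pixel that is NoData in any covariate
#' is NoData in the map. Pixels whose covariates fall outside the model's
#' training range are still predicted but marked in an extrapolation mask —
#' a nationwide projection from a few dozen sampling locations extrapolates
#' over much of its extent, and the mask makes that visible.
#'
#' @param fit A `venom_fit` (or a list with elements `intercept`, `beta`
#'   named by predictor, `transform`, optionally `xrange`, as from
#'   [read_model_json()]).
#' @param stack Named list of aligned [raster_grid()] covariate layers
#'   containing every model predictor.
#' @return Object of class `prediction_map`: `grid` (predicted activity
#'   [raster_grid()]), `linear` (transform-scale raster), `extrapolated`
#'   (0/1 mask raster or `NULL`), `summary` (min/max/mean over valid
#'   pixels, pixel counts), `profile_row`, `profile_col`, `transform`,
#'   `model_id`.
#' @export
predict_surface <- function(fit, stack) {
  mod <- as_prediction_model(fit)
  miss <- setdiff(names(mod$beta), names(stack))
  if (length(miss) > 0)
    stop("covariate layer(s) missing from stack: ",
         paste(miss, collapse = ", "), call. = FALSE)
  layers <- stack[names(mod$beta)]
  ref <- layers[[1]]
  for (g in layers) check_aligned(ref, g)

  Xp <- do.call(cbind, lapply(layers, function(g) as.vector(g$values)))
  colnames(Xp) <- names(mod$beta)
  valid <- stats::complete.cases(Xp)
  lin <- rep(NA_real_, nrow(Xp))
  lin[valid] <- mod$intercept +
    drop(Xp[valid, , drop = FALSE] %*% mod$beta)
  pred <- rep(NA_real_, length(lin))
  pred[valid] <- back_transform(lin[valid], mod$transform)

  extrap <- NULL
  if (!is.null(mod$xrange)) {
    em <- rep(NA_real_, nrow(Xp))
    out_of_range <- rep(FALSE, sum(valid))
    for (j in names(mod$beta)) {
      r <- mod$xrange[, j]
      out_of_range <- out_of_range |
        Xp[valid, j] < r[1] | Xp[valid, j] > r[2]
    }
    em[valid] <- as.numeric(out_of_range)
    extrap <- raster_grid(matrix(em, nrow = nrow(ref$values)),
                          xll = ref$xll, yll = ref$yll,
                          cellsize = ref$cellsize,
                          band_name = "extrapolation_mask")
  }

  pm <- matrix(pred, nrow = nrow(ref$values))
  grid <- raster_grid(pm, xll = ref$xll, yll = ref$yll,
                      cellsize = ref$cellsize, band_name = "predicted")
  ok <- is.finite(pred)
  summary <- list(
    min = if (any(ok)) min(pred[ok]) else NA_real_,
    max = if (any(ok)) max(pred[ok]) else NA_real_,
    mean = if (any(ok)) mean(pred[ok]) else NA_real_,
    n_valid = sum(ok), n_pixels = length(pred),
    empty = !any(ok)
  )
  structure(list(
    grid = grid,
    linear = raster_grid(matrix(lin, nrow = nrow(ref$values)),
                         xll = ref$xll, yll = ref$yll,
                         cellsize = ref$cellsize, band_name = "linear"),
    extrapolated = extrap,
    summary = summary,
    profile_row = rowMeans(pm, na.rm = TRUE),
    profile_col = colMeans(pm, na.rm = TRUE),
    transform = mod$transform,
    model_id = mod$model_id
  ), class = "prediction_map")
}

as_prediction_model <- function(fit) {
  if (inherits(fit, "venom_fit")) {
    if (fit$k == 0)
      stop("cannot map an intercept-only model", call. = FALSE)
    beta <- stats::setNames(fit$coefficients[fit$predictors, "estimate"],
                            fit$predictors)
    list(intercept = fit$coefficients["(Intercept)", "estimate"],
         beta = beta, transform = fit$transform, xrange = fit$xrange,
         model_id = paste0(fit$transform, ":",
                           paste(fit$predictors, collapse = "+")))
  } else if (is.list(fit) && all(c("intercept", "beta", "transform") %in%
                                 names(fit))) {
    list(intercept = fit$intercept, beta = fit$beta,
         transform = fit$transform, xrange = fit$xrange,
         model_id = paste0(fit$transform, ":",
                           paste(names(fit$beta), collapse = "+")))
  } else {
    stop("fit must be a venom_fit or a model list (intercept, beta, ",
         "transform)", call. = FALSE)
  }
}

#' @export
print.prediction_map <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Prediction map (%s back-transform): %d x %d pixels\n",
              x$transform, nrow(x$grid$values), ncol(x$grid$values)))
  if (s$empty) cat("  empty domain: no valid pixels\n")
  else cat(sprintf("  activity min/mean/max = %.4g / %.4g / %.4g (%d of %d pixels valid)\n",
                   s$min, s$mean, s$max, s$n_valid, s$n_pixels))
  invisible(x)
}

#' Export a prediction map to disk
#'
#' Writes the predicted-activity raster as an ESRI ASCII grid, a JSON
#' sidecar with the summary statistics and marginal profiles, the
#' extrapolation mask (if present), and optionally a rendered PNG with a
#' blue-to-red activity gradient.
#'
#' @param map A `prediction_map`.
#' @param path Output raster path (e.g. `"pla2_map.asc"`); the sidecars take
#'   the same stem.
#' @param render Also write a PNG rendering (default `FALSE`).
#' @return Named character vector of the files written, invisibly.
#' @export
export_prediction <- function(map, path, render = FALSE) {
  stopifnot(inherits(map, "prediction_map"))
  stem <- sub("\\.[^.]*$", "", path)
  files <- c(raster = path)
  write_asc(map$grid, path)
  if (!is.null(map$extrapolated)) {
    files["extrapolation_mask"] <- paste0(stem, "_extrapolation.asc")
    write_asc(map$extrapolated, files["extrapolation_mask"])
  }
  files["summary"] <- paste0(stem, "_summary.json")
  jsonlite::write_json(
    list(model_id = map$model_id, transform = map$transform,
         summary = map$summary,
         profile_row = map$profile_row, profile_col = map$profile_col),
    files["summary"], auto_unbox = TRUE, digits = NA, na = "null",
    pretty = TRUE)
  if (render) {
    files["png"] <- paste0(stem, ".png")
    render_map_png(map, files["png"])
  }
  invisible(files)
}

# blue -> red gradient rendering with marginal profile strips
render_map_png <- function(map, path) {
  v <- map$grid$values
  grDevices::png(path, width = 800, height = 800)
  on.exit(grDevices::dev.off())
  graphics::layout(matrix(c(2, 4, 1, 3), 2, 2, byrow = TRUE),
                   widths = c(4, 1), heights = c(1, 4))
  pal <- grDevices::colorRampPalette(c("blue", "cyan", "yellow", "red"))(64)
  e <- grid_extent(map$grid)
  graphics::par(mar = c(4, 4, 0.5, 0.5))
  graphics::image(
    x = seq(e["lon_min"], e["lon_max"], length.out = ncol(v) + 1),
    y = seq(e["lat_min"], e["lat_max"], length.out = nrow(v) + 1),
    z = t(v[rev(seq_len(nrow(v))), , drop = FALSE]),
    col = pal, xlab = "longitude (E)", ylab = "latitude (N)",
    useRaster = TRUE)
  graphics::par(mar = c(0.5, 4, 0.5, 0.5))
  graphics::plot(map$profile_col, type = "l", axes = FALSE, xlab = "",
                 ylab = "activity")
  graphics::par(mar = c(4, 0.5, 0.5, 0.5))
  graphics::plot(rev(map$profile_row), seq_along(map$profile_row),
                 type = "l", axes = FALSE, xlab = "activity", ylab = "")
  invisible(path)
}
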