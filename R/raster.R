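#' Georeferenced raster grid
#'
#' Minimal north-up raster container: a numeric matrix (row 1 = northernmost
#' row) with square pixels on a geographic (WGS84 lon/lat) grid. NoData is
#' represented as `NA` in memory and as a sentinel value on disk; it is never
#' silently converted to 0.
#'
#' @param values Numeric matrix; `NA` marks NoData pixels.
#' @param xll,yll Coordinates of the lower-left corner of the grid (decimal
#'   degrees).
#' @param cellsize Pixel size in degrees (> 0, square pixels).
#' @param crs Coordinate reference identifier; only `"WGS84"` is supported.
#' @param band_name Label for the layer.
#' @return Object of class `raster_grid`.
#' @export
raster_grid <- function(values, xll, yll, cellsize, crs = "WGS84",
                        band_name = "band") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix", call. = FALSE)
  if (!identical(crs, "WGS84"))
    stop("unsupported CRS '", crs, "': only geographic WGS84 is handled",
         call. = FALSE)
  if (!is.finite(cellsize) || cellsize <= 0)
    stop("cellsize must be a positive number", call. = FALSE)
  structure(list(values = values, xll = as.numeric(xll),
                 yll = as.numeric(yll), cellsize = as.numeric(cellsize),
                 crs = crs, band_name = as.character(band_name)),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  e <- grid_extent(x)
  cat(sprintf("raster_grid '%s': %d rows x %d cols, %.6g deg pixels\n",
              x$band_name, nrow(x$values), ncol(x$values), x$cellsize))
  cat(sprintf("  extent: %.4f..%.4f E, %.4f..%.4f N (%s)\n",
              e["lon_min"], e["lon_max"], e["lat_min"], e["lat_max"], x$crs))
  cat(sprintf("  valid pixels: %d / %d\n",
              sum(!is.na(x$values)), length(x$values)))
  invisible(x)
}

#' Grid extent
#'
#' @param grid A [raster_grid()].
#' @return Named vector `lon_min`, `lon_max`, `lat_min`, `lat_max`.
#' @export
grid_extent <- function(grid) {
  c(lon_min = grid$xll,
    lon_max = grid$xll + ncol(grid$values) * grid$cellsize,
    lat_min = grid$yll,
    lat_max = grid$yll + nrow(grid$values) * grid$cellsize)
}

check_aligned <- function(ref, g, name = g$band_name) {
  ok <- identical(dim(ref$values), dim(g$values)) &&
    isTRUE(all.equal(c(ref$xll, ref$yll, ref$cellsize),
                     c(g$xll, g$yll, g$cellsize), tolerance = 1e-12)) &&
    identical(ref$crs, g$crs)
  if (!ok)
    stop("raster layer '", name, "' is not aligned with '", ref$band_name,
         "' (transform, shape or CRS differs)", call. = FALSE)
  invisible(TRUE)
}

#' Bounding box in decimal degrees
#'
#' @param lon_min,lon_max,lat_min,lat_max Box edges, `lon_min < lon_max`,
#'   `lat_min < lat_max`.
#' @return Object of class `bbox`.
#' @export
bbox <- function(lon_min, lon_max, lat_min, lat_max) {
  if (!(lon_min < lon_max && lat_min < lat_max))
    stop("degenerate bounding box: need lon_min < lon_max, lat_min < lat_max",
         call. = FALSE)
  structure(list(lon_min = lon_min, lon_max = lon_max,
                 lat_min = lat_min, lat_max = lat_max), class = "bbox")
}

#' Clip extent covering the Indian subcontinent
#'
#' The longitude/latitude window (68.1 E to 97.4 E, 6.74 N to 35.7 N) used
#' when cropping national prediction maps.
#'
#' @return A [bbox()].
#' @export
india_bbox <- function() bbox(68.1, 97.4, 6.74, 35.7)

#' Write a raster grid as an ESRI ASCII grid (.asc)
#'
#' Plain-text raster format: six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by rows north to south.
#' Values are written with 17 significant digits so that doubles round-trip
#' bit-exactly.
#'
#' @param grid A [raster_grid()].
#' @param path Output file path.
#' @param nodata Sentinel written for `NA` pixels (default -9999).
#' @return `path`, invisibly.
#' @export
write_asc <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "raster_grid"))
  v <- grid$values
  if (any(v == nodata, na.rm = TRUE))
    stop("grid contains the NoData sentinel ", nodata,
         " as a real value; choose another sentinel", call. = FALSE)
  hdr <- c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", format(grid$xll, digits = 17)),
    paste("yllcorner", format(grid$yll, digits = 17)),
    paste("cellsize", format(grid$cellsize, digits = 17)),
    paste("NODATA_value", format(nodata, digits = 17))
  )
  v[is.na(v)] <- nodata
  rows <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid (.asc)
#'
#' @param path File path.
#' @param band_name Layer label; defaults to the file stem.
#' @return A [raster_grid()]; sentinel pixels become `NA`.
#' @export
read_asc <- function(path, band_name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid ", path, ": expected ", hdr$ncols * hdr$nrows,
         " values, found ", length(vals), call. = FALSE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  if (is.null(band_name))
    band_name <- sub("\\.[^.]*$", "", basename(path))
  raster_grid(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
              cellsize = hdr$cellsize, band_name = band_name)
}

#' Read a stack of mutually aligned raster layers
#'
#' Reads each file with [read_asc()] and verifies that every layer shares the
#' first layer's transform, shape and CRS; band names are taken from the file
#' stems.
#'
#' @param paths Character vector of file paths.
#' @return Named list of [raster_grid()] layers.
#' @export
read_raster_stack <- function(paths) {
  if (length(paths) == 0) stop("empty path list", call. = FALSE)
  grids <- lapply(paths, read_asc)
  for (j in seq_along(grids)[-1]) {
    tryCatch(check_aligned(grids[[1]], grids[[j]]),
             error = function(e) stop("misaligned raster '", paths[j],
                                      "': ", conditionMessage(e),
                                      call. = FALSE))
  }
  stats::setNames(grids, vapply(grids, `[[`, "", "band_name"))
}

#' Clip a raster to a bounding box
#'
#' Returns the smallest pixel-aligned window of `grid` containing the part of
#' `box` that intersects the grid: edges snap outward to pixel boundaries and
#' values are never resampled.
#'
#' @param grid A [raster_grid()].
#' @param box A [bbox()].
#' @return A [raster_grid()] over the clipped window.
#' @export
clip_to_bbox <- function(grid, box) {
  stopifnot(inherits(grid, "raster_grid"), inherits(box, "bbox"))
  e <- grid_extent(grid)
  if (box$lon_max <= e["lon_min"] || box$lon_min >= e["lon_max"] ||
      box$lat_max <= e["lat_min"] || box$lat_min >= e["lat_max"])
    stop("bounding box does not intersect the grid extent", call. = FALSE)
  cs <- grid$cellsize
  nc <- ncol(grid$values); nr <- nrow(grid$values)
  # pixel columns 1..nc run west->east, rows 1..nr north->south
  col0 <- max(0L, as.integer(floor((box$lon_min - grid$xll) / cs + 1e-9)))
  col1 <- min(nc, as.integer(ceiling((box$lon_max - grid$xll) / cs - 1e-9)))
  ytop <- grid$yll + nr * cs
  row0 <- max(0L, as.integer(floor((ytop - box$lat_max) / cs + 1e-9)))
  row1 <- min(nr, as.integer(ceiling((ytop - box$lat_min) / cs - 1e-9)))
  vals <- grid$values[(row0 + 1L):row1, (col0 + 1L):col1, drop = FALSE]
  raster_grid(vals,
              xll = grid$xll + col0 * cs,
              yll = ytop - row1 * cs,
              cellsize = cs, crs = grid$crs, band_name = grid$band_name)
}

#' Extract raster values at point locations
#'
#' Nearest-pixel (containing-pixel) sampling, no interpolation. The pixel
#' footprint is half-open: `[left, right)` in longitude and `(top, bottom]`
#' in latitude, so a point on a shared edge belongs to exactly one pixel.
#' Points on NoData pixels yield `NA` (with a warning naming them).
#'
#' @param grid A [raster_grid()].
#' @param lon,lat Numeric vectors of point coordinates (decimal degrees).
#' @return Numeric vector of pixel values.
#' @export
extract_at_points <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "raster_grid"), length(lon) == length(lat))
  cs <- grid$cellsize
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  ytop <- grid$yll + nr * cs
  col <- floor((lon - grid$xll) / cs) + 1
  row <- ceiling((ytop - lat) / cs)
  bad <- col < 1 | col > nc | row < 1 | row > nr
  if (any(bad))
    stop("point(s) outside grid extent: ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  out <- grid$values[cbind(row, col)]
  if (anyNA(out))
    warning("point(s) fall on NoData pixels of '", grid$band_name, "': ",
            paste(which(is.na(out)), collapse = ", "), call. = FALSE)
  out
}
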