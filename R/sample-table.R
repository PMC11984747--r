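#' Read and validate a venom sample table
#'
#' CSV with one row per venom sample: `sample_id`, optional `state_code`,
#' `latitude` (degrees N), `longitude` (degrees E), one column per enzyme
#' activity (any further numeric columns), optional logical `pooled`.
#' Duplicate coordinates are allowed — nearby or pooled samples share a
#' location — but sample ids must be unique.
#'
#' @param path CSV file path.
#' @param activity_cols Character vector naming the activity columns; by
#'   default every numeric column other than the coordinates.
#' @param strict_extent If `TRUE`, reject coordinates outside `extent`.
#' @param extent A [bbox()]; defaults to [india_bbox()].
#' @return A `data.frame` of class `sample_table` with attribute
#'   `activity_cols`.
#' @export
read_sample_table <- function(path, activity_cols = NULL,
                              strict_extent = FALSE, extent = india_bbox()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_table(df, activity_cols = activity_cols,
                        strict_extent = strict_extent, extent = extent)
}

#' Validate an in-memory sample table
#'
#' @param df Data frame with the columns described in [read_sample_table()].
#' @inheritParams read_sample_table
#' @return `df`, classed as `sample_table`, with attribute `activity_cols`.
#' @export
validate_sample_table <- function(df, activity_cols = NULL,
                                  strict_extent = FALSE,
                                  extent = india_bbox()) {
  required <- c("sample_id", "latitude", "longitude")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("sample table missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  problems <- character()
  bad_coord <- which(!is.finite(suppressWarnings(as.numeric(df$latitude))) |
                     !is.finite(suppressWarnings(as.numeric(df$longitude))))
  if (length(bad_coord) > 0)
    problems <- c(problems, paste0("non-numeric coordinate in row(s) ",
                                   paste(bad_coord, collapse = ", ")))
  df$latitude <- as.numeric(df$latitude)
  df$longitude <- as.numeric(df$longitude)

  if (anyDuplicated(df$sample_id))
    problems <- c(problems, paste0("duplicate sample_id in row(s) ",
                                   paste(which(duplicated(df$sample_id)),
                                         collapse = ", ")))
  if (strict_extent) {
    out <- which(df$longitude < extent$lon_min | df$longitude > extent$lon_max |
                 df$latitude < extent$lat_min | df$latitude > extent$lat_max)
    if (length(out) > 0)
      problems <- c(problems, paste0("coordinates outside extent in row(s) ",
                                     paste(out, collapse = ", ")))
  }

  if (is.null(activity_cols)) {
    numeric_cols <- names(df)[vapply(df, is.numeric, TRUE)]
    activity_cols <- setdiff(numeric_cols, c("latitude", "longitude"))
  } else {
    miss <- setdiff(activity_cols, names(df))
    if (length(miss) > 0)
      stop("activity column(s) not found: ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  for (ac in activity_cols) {
    neg <- which(is.finite(df[[ac]]) & df[[ac]] < 0)
    if (length(neg) > 0)
      problems <- c(problems, paste0("negative ", ac, " in row(s) ",
                                     paste(neg, collapse = ", ")))
  }
  if (length(problems) > 0)
    stop("invalid sample table:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)

  attr(df, "activity_cols") <- activity_cols
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Count unique sampling locations
#'
#' Pooled or replicated samples share coordinates; this counts the distinct
#' (longitude, latitude) pairs in a sample table.
#'
#' @param df A sample table (data frame with `longitude`, `latitude`).
#' @return Integer count of unique coordinate pairs.
#' @export
n_unique_locations <- function(df) {
  nrow(unique(df[, c("longitude", "latitude")]))
}
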