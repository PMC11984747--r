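#' Transformation-gridded model selection with diagnostic gating
#'
#' For each response transform (`identity`, `ln`, `sqrt`, `inverse`): fit
#' the full multiple regression on the candidate predictors, refine it by
#' [backward_stepwise()], and gate the refined model with
#' [run_diagnostics()]. One cell is then downselected: among the cells whose
#' refined model passes the normality (N), homoscedasticity (H) and
#' linearity (L) gates, retains at least one predictor, and is significant
#' by the overall F-test at `alpha`, the cell with the largest adjusted
#' R-squared wins. Multicollinearity (M) is reported but never vetoes
#' downselection — a model can be retained on predictive grounds despite
#' inflated VIFs. If no cell qualifies, the card is still emitted with no
#' downselection.
#'
#' A transform whose domain excludes some observed activities (e.g. `ln`
#' with zero activities) yields an unavailable cell rather than an error, so
#' one degenerate response cannot abort the grid.
#'
#' @param data Data frame holding the response and predictor columns.
#' @param response Name of the activity column.
#' @param predictors Character vector of candidate predictor columns.
#' @param transforms Transforms to grid over (default all four).
#' @param alpha Significance level for stepwise t-tests, gates and the
#'   F-test (default 0.05).
#' @param protect_adj_r2 Passed to [backward_stepwise()].
#' @param ... Further arguments to [run_diagnostics()].
#' @return Object of class `model_card`: list with `response`, `grid` (one
#'   row per transform: predictor-inclusion flags, fit statistics, gate
#'   flags, `downselected`), `fits` (named list of `venom_fit`),
#'   `diagnostics` (named list), `selected` (winning transform name or
#'   `NA`).
#' @export
build_model_grid <- function(data, response, predictors,
                             transforms = c("identity", "ln", "sqrt",
                                            "inverse"),
                             alpha = 0.05, protect_adj_r2 = FALSE, ...) {
  stopifnot(response %in% names(data), all(predictors %in% names(data)))
  cc <- stats::complete.cases(data[, c(response, predictors)])
  if (!all(cc))
    stop("incomplete rows in data: ", paste(which(!cc), collapse = ", "),
         call. = FALSE)
  y_raw <- data[[response]]
  X <- as.matrix(data[, predictors, drop = FALSE])

  fits <- list(); diags <- list()
  rows <- lapply(transforms, function(tr) {
    yt <- tryCatch(apply_transform(y_raw, tr), error = function(e) NULL)
    if (is.null(yt)) {
      return(data.frame(transform = tr, available = FALSE, k = NA_integer_,
                        r2 = NA_real_, adj_r2 = NA_real_, f_p = NA_real_,
                        aic = NA_real_, N = NA, H = NA, L = NA, M = NA,
                        downselected = FALSE))
    }
    fit <- backward_stepwise(X, yt, transform = tr, alpha = alpha,
                             protect_adj_r2 = protect_adj_r2)
    fits[[tr]] <<- fit
    if (fit$k == 0) {
      return(data.frame(transform = tr, available = TRUE, k = 0L,
                        r2 = 0, adj_r2 = 0, f_p = NA_real_, aic = fit$aic,
                        N = NA, H = NA, L = NA, M = NA,
                        downselected = FALSE))
    }
    dg <- run_diagnostics(fit, alpha = alpha, ...)
    diags[[tr]] <<- dg
    data.frame(transform = tr, available = TRUE, k = fit$k,
               r2 = fit$r2, adj_r2 = fit$adj_r2, f_p = fit$f_p,
               aic = fit$aic, N = dg$N, H = dg$H, L = dg$L, M = dg$M,
               downselected = FALSE)
  })
  grid <- do.call(rbind, rows)

  incl <- matrix(FALSE, nrow(grid), length(predictors),
                 dimnames = list(NULL, predictors))
  for (tr in names(fits)) {
    i <- match(tr, grid$transform)
    incl[i, fits[[tr]]$predictors] <- TRUE
  }
  grid <- cbind(grid, as.data.frame(incl))

  eligible <- grid$available & !is.na(grid$N) & grid$N & grid$H & grid$L &
    grid$k > 0 & !is.na(grid$f_p) & grid$f_p <= alpha
  selected <- NA_character_
  if (any(eligible)) {
    win <- which(eligible)[which.max(grid$adj_r2[eligible])]
    grid$downselected[win] <- TRUE
    selected <- grid$transform[win]
  }
  structure(list(response = response, predictors = predictors,
                 grid = grid, fits = fits, diagnostics = diags,
                 selected = selected, alpha = alpha),
            class = "model_card")
}

#' @export
print.model_card <- function(x, ...) {
  cat("Model card for response '", x$response, "'\n", sep = "")
  show <- x$grid[, c("transform", "k", "adj_r2", "f_p", "N", "H", "L", "M",
                     "downselected")]
  show$adj_r2 <- round(show$adj_r2, 4)
  show$f_p <- signif(show$f_p, 3)
  print(show, row.names = FALSE)
  if (is.na(x$selected))
    cat("no model downselected (no cell passed the N/H/L + F-test gates)\n")
  else
    cat("downselected: transform '", x$selected, "' with predictors ",
        paste(x$fits[[x$selected]]$predictors, collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Serialize a model card (or one fitted model) to JSON
#'
#' The JSON carries the pass/fail grid and, per transform cell, the fitted
#' coefficients — enough for [predict_surface()] to rebuild the prediction
#' equation.
#'
#' @param card A `model_card`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_card <- function(card, path) {
  stopifnot(inherits(card, "model_card"))
  cells <- lapply(names(card$fits), function(tr) {
    f <- card$fits[[tr]]
    list(transform = tr,
         coefficients = as.list(stats::setNames(f$coefficients$estimate,
                                                rownames(f$coefficients))),
         predictors = f$predictors,
         r2 = f$r2, adj_r2 = f$adj_r2, f_p = f$f_p, aic = f$aic,
         n = f$n, k = f$k,
         xrange = if (is.null(f$xrange)) NULL else
           as.list(as.data.frame(f$xrange)))
  })
  obj <- list(response = card$response,
              selected = card$selected,
              grid = card$grid,
              cells = stats::setNames(cells, names(card$fits)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a serialized model card cell for prediction
#'
#' @param path JSON written by [write_model_card()].
#' @param transform Which cell to load; default the downselected one.
#' @return List with `intercept`, `beta` (named), `transform`, `xrange`.
#' @export
read_model_json <- function(path, transform = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(transform)) transform <- obj$selected
  if (is.null(transform) || is.na(transform) ||
      !transform %in% names(obj$cells))
    stop("no downselected cell in ", path,
         "; pass `transform` explicitly", call. = FALSE)
  cell <- obj$cells[[transform]]
  beta <- unlist(cell$coefficients)
  list(intercept = unname(beta[["(Intercept)"]]),
       beta = beta[setdiff(names(beta), "(Intercept)")],
       transform = cell$transform,
       xrange = if (is.null(cell$xrange)) NULL else
         vapply(cell$xrange, as.numeric, numeric(2)),
       response = obj$response)
}
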