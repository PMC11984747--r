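#' Ordinary least-squares fit of activity on bioclimatic predictors
#'
#' Fits `y ~ 1 + X` by least squares and assembles the quantities the model
#' grid and diagnostics consume: coefficient table with classical standard
#' errors, t statistics and p-values, R-squared and adjusted R-squared, the
#' overall F-test p-value, and AIC under the Gaussian profile-likelihood
#' convention `n * log(RSS/n) + 2 * (k + 2)` (intercept and error variance
#' counted as parameters; comparable across models of the same response on
#' the same transform scale only).
#'
#' @param X Numeric matrix or data frame of predictors (no intercept
#'   column), `n` rows, `k` columns, named.
#' @param y Numeric response vector (already on the transform scale).
#' @param transform Transform label carried for provenance (does not modify
#'   `y`).
#' @return Object of class `venom_fit`: list with `coefficients` (data frame
#'   with `estimate`, `se`, `t`, `p` rows incl. intercept), `residuals`,
#'   `fitted`, `r2`, `adj_r2`, `f_p`, `aic`, `n`, `k`, `sigma`, `predictors`,
#'   `transform`, `xrange` (training range per predictor) and the underlying
#'   `lm` object.
#' @export
ols_fit <- function(X, y, transform = "identity") {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n) stop("X and y differ in length", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite values in X or y", call. = FALSE)
  if (n <= k + 1)
    stop("need n > k + 1 observations (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  design <- cbind(`(Intercept)` = 1, X)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("rank-deficient design: collinear column(s) ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  dat <- data.frame(.y = y, X, check.names = FALSE)
  fml <- stats::as.formula(paste("`.y` ~",
                                 paste0("`", colnames(X), "`",
                                        collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  # perfect fits are legitimate (noise-free scenarios); silence summary.lm
  sm <- suppressWarnings(summary(fit))
  ct <- sm$coefficients
  rownames(ct) <- sub("^`(.*)`$", "\\1", rownames(ct))
  rss <- sum(stats::residuals(fit)^2)
  fstat <- sm$fstatistic
  f_p <- if (is.null(fstat)) NA_real_ else
    unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  structure(list(
    coefficients = data.frame(estimate = ct[, 1], se = ct[, 2],
                              t = ct[, 3], p = ct[, 4],
                              row.names = rownames(ct)),
    residuals = unname(stats::residuals(fit)),
    fitted = unname(stats::fitted(fit)),
    r2 = sm$r.squared,
    adj_r2 = sm$adj.r.squared,
    f_p = f_p,
    aic = n * log(rss / n) + 2 * (k + 2),
    rss = rss,
    n = n, k = k,
    sigma = sm$sigma,
    predictors = colnames(X),
    transform = transform,
    xrange = apply(X, 2, range),
    lm = fit
  ), class = "venom_fit")
}

#' Intercept-only fit (all predictors eliminated)
#'
#' @param y Response vector.
#' @param transform Transform label.
#' @return A `venom_fit` with `k = 0`, `r2 = 0`, flagged
#'   `intercept_only = TRUE`.
#' @keywords internal
intercept_only_fit <- function(y, transform = "identity") {
  n <- length(y)
  fit <- stats::lm(y ~ 1)
  rss <- sum(stats::residuals(fit)^2)
  sm <- summary(fit)
  out <- structure(list(
    coefficients = data.frame(estimate = mean(y),
                              se = sm$coefficients[1, 2],
                              t = sm$coefficients[1, 3],
                              p = sm$coefficients[1, 4],
                              row.names = "(Intercept)"),
    residuals = unname(stats::residuals(fit)),
    fitted = unname(stats::fitted(fit)),
    r2 = 0, adj_r2 = 0, f_p = NA_real_,
    aic = n * log(rss / n) + 2 * 2,
    rss = rss, n = n, k = 0L,
    sigma = sm$sigma,
    predictors = character(0),
    transform = transform,
    xrange = NULL, lm = fit
  ), class = "venom_fit")
  out$intercept_only <- TRUE
  out
}

#' @export
print.venom_fit <- function(x, ...) {
  cat(sprintf("Linear model (transform = %s): n = %d, k = %d\n",
              x$transform, x$n, x$k))
  print(round(x$coefficients, 5))
  cat(sprintf("R2 = %.4f, adj. R2 = %.4f, F-test p = %s, AIC = %.2f\n",
              x$r2, x$adj_r2, format.pval(x$f_p, digits = 4), x$aic))
  invisible(x)
}

#' Predict from a fitted model at new predictor values
#'
#' Evaluates the linear predictor `intercept + sum(beta_j * x_j)` on the
#' model's transform scale. Back-transformation is left to the caller (see
#' [back_transform()] and [predict_surface()]).
#'
#' @param object A `venom_fit`.
#' @param newdata Data frame or matrix containing the model's predictors.
#' @param ... Unused.
#' @return Numeric vector of transform-scale predictions.
#' @export
predict.venom_fit <- function(object, newdata, ...) {
  beta <- object$coefficients$estimate
  names(beta) <- rownames(object$coefficients)
  if (object$k == 0) return(rep(beta[["(Intercept)"]], nrow(newdata)))
  miss <- setdiff(object$predictors, colnames(newdata))
  if (length(miss) > 0)
    stop("newdata lacks predictor(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  Xn <- as.matrix(as.data.frame(newdata)[, object$predictors, drop = FALSE])
  drop(beta[["(Intercept)"]] + Xn %*% beta[object$predictors])
}
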