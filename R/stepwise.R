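#' Backward stepwise elimination of non-significant predictors
#'
#' Starting from the full model, repeatedly refits after removing the
#' predictor with the largest coefficient p-value exceeding `alpha`,
#' stopping when every remaining predictor is significant. Ties in p-value
#' are broken deterministically by predictor order in `X`. If every
#' predictor is eliminated the intercept-only model is returned with
#' `intercept_only = TRUE`.
#'
#' With `protect_adj_r2 = TRUE` a removal that would lower the adjusted
#' R-squared is not performed and elimination stops there; in that mode the
#' final adjusted R-squared is never below the full model's. The default is
#' `FALSE`: elimination is driven purely by the t-test significance of the
#' coefficients, which is what lets a pure-noise predictor be discarded even
#' when its |t| lies between 1 and the critical value (such a removal lowers
#' adjusted R-squared slightly but yields a model whose terms are all
#' significant).
#'
#' @inheritParams ols_fit
#' @param alpha Significance level for the coefficient t-tests (default
#'   0.05).
#' @param protect_adj_r2 If `TRUE`, stop before any drop that would decrease
#'   adjusted R-squared.
#' @return A `venom_fit` for the reduced model, with attribute `path`: a
#'   character vector of predictors in the order they were dropped.
#' @export
backward_stepwise <- function(X, y, transform = "identity", alpha = 0.05,
                              protect_adj_r2 = FALSE) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- colnames(X)
  fit <- ols_fit(X, y, transform)
  dropped <- character(0)
  repeat {
    pv <- fit$coefficients[fit$predictors, "p"]
    over <- which(pv > alpha)
    if (length(over) == 0) break
    # largest p; ties broken by original column order (match on keep order)
    worst <- over[which.max(pv[over])]
    cand <- setdiff(fit$predictors, fit$predictors[worst])
    new_fit <- if (length(cand) == 0) intercept_only_fit(y, transform)
               else ols_fit(X[, cand, drop = FALSE], y, transform)
    if (protect_adj_r2 && new_fit$adj_r2 < fit$adj_r2) break
    dropped <- c(dropped, fit$predictors[worst])
    fit <- new_fit
    if (fit$k == 0) break
  }
  attr(fit, "path") <- dropped
  fit
}
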