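#' Diagnostic gate battery for a fitted model
#'
#' Runs the four reliability checks applied to every candidate model and
#' reports pass/fail flags at level `alpha`:
#' \describe{
#'   \item{N (normality)}{Shapiro-Wilk test on the residuals.}
#'   \item{H (homoscedasticity)}{Breusch-Pagan test; the studentized
#'     (Koenker) variant by default, the classic chi-squared form with
#'     `studentize = FALSE`.}
#'   \item{L (linearity)}{Rainbow test: F comparison of the full-sample fit
#'     against the fit on the central `fraction` of observations ordered by
#'     fitted values.}
#'   \item{M (multicollinearity)}{Variance inflation factors; the gate
#'     passes when every VIF is below `vif_threshold`. A single-predictor
#'     model has VIF 1 by definition.}
#' }
#' A perfect fit (RSS numerically zero) leaves the Rainbow and Shapiro-Wilk
#' statistics undefined; those gates are reported as passes with
#' `degenerate = TRUE`.
#'
#' @param fit A `venom_fit` (needs >= 8 residuals for Shapiro-Wilk).
#' @param alpha Gate significance level (default 0.05).
#' @param vif_threshold VIF pass threshold (default 10).
#' @param studentize Use the studentized (Koenker) Breusch-Pagan variant
#'   (default `TRUE`).
#' @param fraction Central fraction of observations for the Rainbow subfit
#'   (default 0.5).
#' @return List of class `diagnostics_report`: statistics and p-values per
#'   test, `vif` per predictor, logical flags `N`, `H`, `L`, `M`, and
#'   `degenerate`.
#' @export
run_diagnostics <- function(fit, alpha = 0.05, vif_threshold = 10,
                            studentize = TRUE, fraction = 0.5) {
  stopifnot(inherits(fit, "venom_fit"))
  if (fit$n < 8)
    stop("diagnostics need >= 8 residuals (Shapiro-Wilk minimum)",
         call. = FALSE)
  if (fit$k == 0)
    stop("diagnostics are undefined for an intercept-only model",
         call. = FALSE)
  degenerate <- fit$rss < 1e-12 * max(1, sum(fit$fitted^2)) ||
    stats::sd(fit$residuals) == 0

  if (degenerate) {
    sw_w <- NA_real_; sw_p <- NA_real_
    bp_stat <- NA_real_; bp_p <- NA_real_
    rb_stat <- NA_real_; rb_p <- NA_real_
    N <- TRUE; H <- TRUE; L <- TRUE
  } else {
    sw <- stats::shapiro.test(fit$residuals)
    sw_w <- unname(sw$statistic); sw_p <- unname(sw$p.value)

    bp <- lmtest::bptest(fit$lm, studentize = studentize)
    bp_stat <- unname(bp$statistic); bp_p <- unname(bp$p.value)

    # rainbow with observations ordered by fitted values: refit on the
    # sorted model frame so lmtest's default (as-ordered) split applies
    ord <- order(fit$fitted)
    mf <- stats::model.frame(fit$lm)[ord, , drop = FALSE]
    lm_ord <- stats::lm(stats::formula(fit$lm), data = mf)
    rb <- lmtest::raintest(lm_ord, fraction = fraction)
    rb_stat <- unname(rb$statistic); rb_p <- unname(rb$p.value)

    N <- sw_p > alpha; H <- bp_p > alpha; L <- rb_p > alpha
  }

  vif <- if (fit$k == 1) stats::setNames(1, fit$predictors)
         else car::vif(fit$lm)
  names(vif) <- sub("^`(.*)`$", "\\1", names(vif))
  M <- all(vif < vif_threshold)

  structure(list(shapiro_w = sw_w, shapiro_p = sw_p,
                 bp_stat = bp_stat, bp_p = bp_p,
                 rainbow_stat = rb_stat, rainbow_p = rb_p,
                 vif = vif,
                 N = N, H = H, L = L, M = M,
                 alpha = alpha, vif_threshold = vif_threshold,
                 degenerate = degenerate),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  flag <- function(ok) if (isTRUE(ok)) "pass" else "FAIL"
  cat(sprintf("Shapiro-Wilk  W = %.4f  p = %.4g  [N %s]\n",
              x$shapiro_w, x$shapiro_p, flag(x$N)))
  cat(sprintf("Breusch-Pagan LM = %.4f  p = %.4g  [H %s]\n",
              x$bp_stat, x$bp_p, flag(x$H)))
  cat(sprintf("Rainbow       F = %.4f  p = %.4g  [L %s]\n",
              x$rainbow_stat, x$rainbow_p, flag(x$L)))
  cat(sprintf("max VIF = %.3f (threshold %g)  [M %s]\n",
              max(x$vif), x$vif_threshold, flag(x$M)))
  if (x$degenerate) cat("note: perfect fit; N/H/L gates degenerate\n")
  invisible(x)
}
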