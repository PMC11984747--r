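#' Fit an assay standard curve
#'
#' Ordinary least-squares line through known analyte amounts and their
#' absorbance responses (e.g. NOB substrate concentrations read at 425 nm, or
#' an H2O2 dilution series). The slope, in absorbance units per nmol, is the
#' conversion factor used by [specific_activity()].
#'
#' @param levels Known analyte amounts (nmol); at least two distinct values.
#' @param responses Absorbances (AU), same length as `levels`.
#' @return List of class `standard_curve`: `slope` (AU/nmol), `intercept`
#'   (AU), `r2`, `levels`, `responses`.
#' @export
fit_standard_curve <- function(levels, responses) {
  stopifnot(length(levels) == length(responses))
  if (length(unique(levels)) < 2)
    stop("degenerate standard curve: need >= 2 distinct levels",
         call. = FALSE)
  fit <- stats::lm(responses ~ levels)
  r2 <- suppressWarnings(summary(fit))$r.squared
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2, levels = levels, responses = responses),
            class = "standard_curve")
}

#' Specific enzymatic activity from reaction kinetics
#'
#' Converts a monitored absorbance time course into a specific activity in
#' nmol of substrate turned over per minute per mg of venom protein: the
#' kinetic rate (OLS slope of absorbance against time, AU/min) is divided by
#' the standard-curve slope (AU/nmol) and the venom protein mass (mg). A
#' negative fitted rate is clipped to zero and flagged.
#'
#' @param times Time points (minutes), strictly increasing, >= 2 points.
#' @param absorbances Absorbance readings (AU) at `times`.
#' @param venom_mass Venom protein in the reaction (mg), > 0.
#' @param curve A [fit_standard_curve()] result with positive slope.
#' @return List of class `activity_record`: `value` (nmol/min/mg), `rate`
#'   (AU/min), `clipped` flag.
#' @export
specific_activity <- function(times, absorbances, venom_mass, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (length(times) < 2 || any(diff(times) <= 0))
    stop("times must be strictly increasing with >= 2 points", call. = FALSE)
  if (length(absorbances) != length(times))
    stop("times and absorbances differ in length", call. = FALSE)
  if (!is.finite(venom_mass) || venom_mass <= 0)
    stop("venom_mass must be > 0 (mg)", call. = FALSE)
  if (!is.finite(curve$slope) || curve$slope <= 0)
    stop("degenerate standard curve: slope must be > 0 AU/nmol",
         call. = FALSE)
  rate <- unname(stats::coef(stats::lm(absorbances ~ times))[2])
  clipped <- rate < 0
  value <- max(rate, 0) / curve$slope / venom_mass
  structure(list(value = value, rate = rate, clipped = clipped,
                 units = "nmol/min/mg"),
            class = "activity_record")
}

#' Relative (percent-of-standard) activity
#'
#' Proteolytic readouts are expressed relative to a purified protease
#' standard run in the same assay: `100 * sample / standard`. Values above
#' 100 are allowed (sample exceeds the standard) and flagged.
#'
#' @param sample_abs Sample absorbance (AU).
#' @param standard_abs Standard absorbance (AU), > 0.
#' @return Percent relative activity (numeric), with attribute
#'   `exceeds_standard`.
#' @export
relative_activity <- function(sample_abs, standard_abs) {
  if (!is.finite(standard_abs) || standard_abs <= 0)
    stop("standard absorbance must be > 0", call. = FALSE)
  pct <- 100 * sample_abs / standard_abs
  attr(pct, "exceeds_standard") <- pct > 100
  pct
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA comparing group means (used to
#' compare intrapopulation replicate variability). With zero within-group
#' variance and unequal means the F statistic is reported as `Inf` with
#' p = 0 and `degenerate = TRUE`.
#'
#' @param groups List of numeric vectors, >= 2 groups with >= 2 values each.
#' @return List: `F`, `p`, `df_between`, `df_within`, `ss_between`,
#'   `ss_within`, `degenerate`.
#' @export
oneway_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs >= 2 values", call. = FALSE)
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  n <- length(y); k <- nlevels(g)
  gm <- tapply(y, g, mean)
  ssb <- sum(tapply(y, g, length) * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  df_b <- k - 1; df_w <- n - k
  if (ssw == 0 && ssb > 0) {
    return(list(F = Inf, p = 0, df_between = df_b, df_within = df_w,
                ss_between = ssb, ss_within = ssw, degenerate = TRUE))
  }
  if (ssw == 0 && ssb == 0) {
    return(list(F = 0, p = 1, df_between = df_b, df_within = df_w,
                ss_between = 0, ss_within = 0, degenerate = TRUE))
  }
  tab <- stats::anova(stats::lm(y ~ g))
  list(F = tab[["F value"]][1], p = tab[["Pr(>F)"]][1],
       df_between = df_b, df_within = df_w,
       ss_between = ssb, ss_within = ssw, degenerate = FALSE)
}

#' Average replicate activities per sample
#'
#' Triplicate assay values are averaged before regression; the replicate SD
#' is carried alongside for reporting only.
#'
#' @param values Numeric vector of replicate readouts.
#' @return List: `mean`, `sd`, `n`.
#' @export
summarise_replicates <- function(values) {
  values <- values[is.finite(values)]
  list(mean = mean(values), sd = stats::sd(values), n = length(values))
}
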