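#' Response transformations
#'
#' Activities are modelled on four response scales: untransformed
#' (`identity`), natural log (`ln`), square root (`sqrt`) and reciprocal
#' (`inverse`). Transforms are applied to the response only, never to the
#' bioclimatic predictors, and domain violations are errors naming the
#' offending samples — values are never silently offset.
#'
#' @param y Numeric vector of activities.
#' @param transform One of `"identity"`, `"ln"`, `"sqrt"`, `"inverse"`.
#' @return Transformed numeric vector.
#' @export
apply_transform <- function(y, transform = c("identity", "ln", "sqrt",
                                             "inverse")) {
  transform <- match.arg(transform)
  if (any(!is.finite(y)))
    stop("non-finite activity value(s) at position(s) ",
         paste(which(!is.finite(y)), collapse = ", "), call. = FALSE)
  bad <- switch(transform,
                identity = integer(0),
                ln = which(y <= 0),
                inverse = which(y <= 0),
                sqrt = which(y < 0))
  if (length(bad) > 0)
    stop("transform '", transform, "' undefined for sample(s) ",
         paste(bad, collapse = ", "),
         " (nonpositive activity); transforms never apply silent offsets",
         call. = FALSE)
  switch(transform,
         identity = y, ln = log(y), sqrt = sqrt(y), inverse = 1 / y)
}

#' Back-transform model-scale predictions to activity units
#'
#' Naive inversion of [apply_transform()]: `exp` for `ln`, squaring for
#' `sqrt`, reciprocal for `inverse`. No retransformation (smearing) bias
#' correction is applied. A reciprocal of zero is returned as `NA`
#' (propagated as NoData in maps).
#'
#' @param values Numeric vector on the transformed (model) scale.
#' @param transform One of `"identity"`, `"ln"`, `"sqrt"`, `"inverse"`.
#' @return Numeric vector in activity units.
#' @export
back_transform <- function(values, transform = c("identity", "ln", "sqrt",
                                                 "inverse")) {
  transform <- match.arg(transform)
  switch(transform,
         identity = values,
         ln = exp(values),
         sqrt = values^2,
         inverse = ifelse(values == 0, NA_real_, 1 / values))
}
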