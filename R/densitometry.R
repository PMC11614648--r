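#' Normalize band densitometry against a loading control
#'
#' Ratio of a target band's integrated intensity to the housekeeping
#' (reference) band's intensity from the same lane. Vectorized; the ratio
#' is invariant under common rescaling of both channels.
#'
#' @param target Target-band intensity (arbitrary units, >= 0).
#' @param reference Reference-band intensity (> 0).
#' @return `target / reference`.
#' @export
densitometry_normalize <- function(target, reference) {
  if (any(target < 0)) abort("target intensities must be non-negative")
  if (any(reference <= 0)) abort("reference intensities must be strictly positive")
  target / reference
}

#' Fold change between two measurements
#'
#' @param value_a Numerator value(s).
#' @param value_b Denominator value(s) (> 0).
#' @param decimals Decimals to round to (default 1, the usual reporting
#'   convention for assay fold changes).
#' @return `round(value_a / value_b, decimals)`.
#' @examples
#' fold_change(253, 158) # 1.6
#' @export
fold_change <- function(value_a, value_b, decimals = 1) {
  if (any(value_b <= 0)) abort("denominator must be strictly positive")
  round(value_a / value_b, decimals)
}
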