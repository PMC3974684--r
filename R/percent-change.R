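#' Signed percent change between two median/LD50 values
#'
#' The uniform effect-size report for survival comparisons: the signed
#' percent change of `comparison` relative to `reference`,
#' `100 * (comparison - reference) / reference`, rounded half away from
#' zero to `decimals` places (so a 21.95% reduction prints as -22.0 at
#' one decimal).
#'
#' @param reference Reference median or LD50 (must be > 0); vectorized.
#' @param comparison Comparison median or LD50; vectorized.
#' @param decimals Decimal places in the rounded result (default 1).
#' @return Signed percent change, rounded.
#' @section Errors: `replilife_zero_reference_error` when any reference
#'   is not strictly positive.
#' @examples
#' percent_change(13.6, 7.5, decimals = 0)  # -45
#' percent_change(12.3, 9.6, decimals = 1)  # -22.0
#' @export
percent_change <- function(reference, comparison, decimals = 1) {
  if (any(!is.finite(reference) | reference <= 0)) stop_zero_reference()
  round_half_away(100 * (comparison - reference) / reference, decimals)
}
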