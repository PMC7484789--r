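# Growth percentages, multiplicative independence expectation, rescue
# fold-change and the normalized cell-death index.

#' Percent growth relative to a matched control
#'
#' @param count_condition Cell count (or confluence) of the condition.
#' @param count_control Matching control count, `> 0`.
#' @return `100 * count_condition / count_control` (percent).
#' @export
percent_growth <- function(count_condition, count_control) {
  if (any(!is.finite(count_control)) || any(count_control <= 0))
    stop("control count must be positive")
  if (any(count_condition < 0)) stop("counts must be non-negative")
  100 * count_condition / count_control
}

#' Expected combined growth under multiplicative independence
#'
#' If two perturbations act independently, the expected growth of the
#' combined condition is the product of the single-condition growth
#' percentages: `V = pct_a * pct_b / 100` (percent scale). Symmetric in
#' its arguments; scaling both inputs by `k` scales `V` by `k^2`.
#'
#' @param pct_a,pct_b Single-perturbation growth, percent (`>= 0`).
#' @return Predicted combined growth `V`, percent.
#' @export
predicted_independent_growth <- function(pct_a, pct_b) {
  if (any(pct_a < 0) || any(pct_b < 0)) stop("percent growth must be >= 0")
  pct_a * pct_b / 100
}

#' Rescue fold-change relative to the independence expectation
#'
#' Observed combined growth divided by the predicted value `V`. Values
#' above 1 indicate rescue (positive epistasis), below 1 antagonism.
#'
#' @param observed_combined Observed combined-condition growth, percent.
#' @param v_predicted Predicted growth from
#'   [predicted_independent_growth()], `> 0`.
#' @return Dimensionless fold-change.
#' @export
rescue_fold <- function(observed_combined, v_predicted) {
  if (any(!is.finite(v_predicted)) || any(v_predicted <= 0))
    stop("predicted growth must be positive")
  observed_combined / v_predicted
}

#' Growth-normalized cell-death index
#'
#' Cytotoxicity fluorescence normalized to the relative cell growth of the
#' same condition, expressed as fold-change over the untreated control
#' (whose own index is exactly 1). Invariant to globally rescaling the raw
#' fluorescence units.
#'
#' @param cytotox Cytotoxicity fluorescence, a.u.
#' @param relative_growth Growth relative to the untreated control of the
#'   same knockdown, fraction `> 0`.
#' @param untreated_cytotox,untreated_growth Same quantities for the
#'   untreated control.
#' @return `data.frame` with `death_normalized` (a.u./fraction) and
#'   `fold_vs_untreated`.
#' @export
cell_death_index <- function(cytotox, relative_growth, untreated_cytotox,
                             untreated_growth) {
  gr <- c(relative_growth, untreated_growth)
  if (any(!is.finite(gr)) || any(gr <= 0))
    stop("growth fractions must be positive")
  death <- cytotox / relative_growth
  ref <- untreated_cytotox / untreated_growth
  data.frame(death_normalized = death, fold_vs_untreated = death / ref)
}
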