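# DNA fibre assay: fork speeds and sister-fork symmetry statistics.

#' Replication fork speed from a labelled tract length
#'
#' Converts a pulse-labelled fibre tract length (CldU or IdU segment, in
#' micrometres) into a synthesis speed in kb/min, using the standard
#' stretched-fibre conversion factor of 2.59 kb per micrometre:
#' `speed = length * kb_per_um / pulse`.
#'
#' @param length_um Tract length in micrometres (vectorised, `>= 0`).
#' @param pulse_min Pulse duration in minutes (`> 0`).
#' @param kb_per_um Length-to-kilobase conversion factor, kb per um.
#'   Default 2.59, the standard value for fibres spread on glass.
#' @return Numeric vector of speeds in kb/min.
#' @examples
#' fork_speed(20, 20)   # 2.59 kb/min
#' fork_speed(10, 20)   # 1.295 kb/min
#' @export
fork_speed <- function(length_um, pulse_min, kb_per_um = 2.59) {
  if (any(!is.finite(pulse_min)) || any(pulse_min <= 0))
    stop("pulse_min must be positive and finite")
  if (any(!is.finite(length_um)) || any(length_um < 0))
    stop("length_um must be non-negative and finite")
  if (!is.numeric(kb_per_um) || length(kb_per_um) != 1L || kb_per_um <= 0)
    stop("kb_per_um must be a single positive number")
  length_um * kb_per_um / pulse_min
}

#' Classify sister-fork pairs as symmetric or asymmetric
#'
#' A pair of sister forks (the two arms emanating bidirectionally from one
#' replication origin) is called symmetric when the relative length
#' difference `(longer - shorter) / longer` is below `threshold`
#' (default 25%). Equivalently, symmetric iff `shorter / longer > 1 - threshold`.
#' The classification is invariant under swapping the two arms.
#'
#' Pairs with both arms zero are undefined and returned as `NA`; callers
#' should exclude them from summaries.
#'
#' @param left_um,right_um Arm lengths in micrometres (vectorised).
#' @param threshold Relative length-difference cutoff (fraction of the
#'   longer arm). Default 0.25.
#' @return Character vector, `"symmetric"` or `"asymmetric"` (`NA` when both
#'   arms are zero).
#' @export
classify_symmetry <- function(left_um, right_um, threshold = 0.25) {
  stopifnot(length(left_um) == length(right_um),
            is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1)
  if (any(left_um < 0, na.rm = TRUE) || any(right_um < 0, na.rm = TRUE))
    stop("arm lengths must be non-negative")
  longer  <- pmax(left_um, right_um)
  shorter <- pmin(left_um, right_um)
  out <- ifelse((longer - shorter) / longer < threshold, "symmetric", "asymmetric")
  out[longer == 0] <- NA_character_
  out
}

#' Sister-fork asymmetry ratio (longer arm / shorter arm)
#'
#' Order of the arms is irrelevant; the ratio is always `>= 1`. Pairs whose
#' shorter arm is zero have an undefined (infinite) ratio and are returned
#' as `Inf`; summary functions exclude them with a logged count.
#'
#' @inheritParams classify_symmetry
#' @return Numeric vector of ratios `>= 1` (or `Inf`).
#' @export
asymmetry_ratio <- function(left_um, right_um) {
  stopifnot(length(left_um) == length(right_um))
  if (any(left_um < 0, na.rm = TRUE) || any(right_um < 0, na.rm = TRUE))
    stop("arm lengths must be non-negative")
  pmax(left_um, right_um) / pmin(left_um, right_um)
}

#' Fraction of sister-fork pairs exceeding a fold-asymmetry cutoff
#'
#' Fraction of pairs whose asymmetry ratio exceeds `fold` (default 2, the
#' conventional cutoff for calling a fork stalled). Pairs with an infinite
#' ratio (a zero-length arm) are excluded; the number excluded is attached
#' as attribute `n_excluded`.
#'
#' @inheritParams classify_symmetry
#' @param fold Fold-difference cutoff, dimensionless. Default 2.
#' @return Scalar fraction in `[0, 1]` with attribute `n_excluded`.
#' @export
fraction_fold_asymmetric <- function(left_um, right_um, fold = 2) {
  if (length(left_um) == 0L) stop("no sister-fork pairs supplied")
  r <- asymmetry_ratio(left_um, right_um)
  ok <- is.finite(r)
  if (!any(ok)) stop("all pairs have a zero-length arm; fraction undefined")
  structure(mean(r[ok] > fold), n_excluded = sum(!ok))
}

#' Tukey five-number summary of fork speeds
#'
#' Quartiles by linear interpolation between order statistics
#' (`stats::quantile` type 7); whiskers are the most extreme observations
#' within 1.5 interquartile ranges of the box, as in a Tukey boxplot.
#'
#' @param values Numeric vector (kb/min or any single unit), `n >= 1`.
#' @return A one-row `data.frame` with columns `q1`, `median`, `q3`,
#'   `whisker_low`, `whisker_high`, `n`.
#' @export
summarize_speeds <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values to summarize")
  qs  <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- qs[3] - qs[1]
  lo  <- min(values[values >= qs[1] - 1.5 * iqr])
  hi  <- max(values[values <= qs[3] + 1.5 * iqr])
  data.frame(q1 = qs[1], median = qs[2], q3 = qs[3],
             whisker_low = lo, whisker_high = hi, n = length(values))
}

#' Compare fork-speed (or ratio) distributions between groups
#'
#' Dispatches to the unpaired two-tailed Student's t-test, the
#' Kruskal-Wallis rank-sum test (which accepts more than two groups), or
#' the Mann-Whitney/Wilcoxon rank-sum test.
#'
#' @param a Numeric vector (first group), or for `"kruskal_wallis"` a list
#'   of numeric vectors when `b` is `NULL`.
#' @param b Numeric vector (second group), optional for Kruskal-Wallis.
#' @param test One of `"t_unpaired_twotailed"`, `"kruskal_wallis"`,
#'   `"mann_whitney"`.
#' @return List with `test`, `statistic`, `p_value`, and
#'   `degenerate` (`TRUE` when a t-test was requested on essentially
#'   constant data, in which case `statistic`/`p_value` are `NA`).
#' @export
compare_groups <- function(a, b = NULL,
                           test = c("t_unpaired_twotailed", "kruskal_wallis",
                                    "mann_whitney")) {
  test <- match.arg(test)
  if (test == "kruskal_wallis") {
    groups <- if (is.list(a)) a else list(a, b)
    if (any(vapply(groups, length, 1L) < 2L)) stop("each group needs n >= 2")
    kt <- stats::kruskal.test(groups)
    return(list(test = test, statistic = unname(kt$statistic),
                p_value = kt$p.value, degenerate = FALSE))
  }
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  if (test == "mann_whitney") {
    wt <- stats::wilcox.test(a, b, exact = FALSE)
    return(list(test = test, statistic = unname(wt$statistic),
                p_value = wt$p.value, degenerate = FALSE))
  }
  if (stats::sd(c(a - mean(a), b - mean(b))) == 0) {
    warning("degenerate variance: t-test undefined on constant groups")
    return(list(test = test, statistic = NA_real_, p_value = NA_real_,
                degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE, alternative = "two.sided")
  list(test = test, statistic = unname(tt$statistic), p_value = tt$p.value,
       degenerate = FALSE)
}
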