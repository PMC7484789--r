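# Independent brute-force oracles used across test files. These stay
# deliberately naive and separate from the package implementations.

# Symmetry call written directly from the definition, one pair at a time.
oracle_symmetry <- function(l, r, threshold = 0.25) {
  longer <- max(l, r); shorter <- min(l, r)
  if (longer == 0) return(NA_character_)
  if ((longer - shorter) / longer < threshold) "symmetric" else "asymmetric"
}

oracle_ratio <- function(l, r) max(l, r) / min(l, r)

# Percentile by explicit order-statistic interpolation (quantile type 7).
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Partial correlation as the correlation of lm() residuals.
oracle_partial_residual <- function(x, y, z) {
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  stats::cor(rx, ry)
}

# Per-base-pair overlap count on a toy genome: how many peaks touch the
# gene footprint (0-based half-open intervals on a single chromosome).
oracle_peak_count <- function(peak_start, peak_end, gene_start, gene_end) {
  sum(vapply(seq_along(peak_start), function(i) {
    bp <- seq(peak_start[i], peak_end[i] - 1L)
    any(bp >= gene_start & bp < gene_end)
  }, logical(1)))
}
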