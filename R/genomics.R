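# Genome-wide co-enrichment statistics: peak-per-gene counting, (partial)
# correlation over expression, chromatin-state fold enrichment and
# DRIP-qPCR normalization. Interval arithmetic goes through GenomicRanges;
# all tabular coordinates are BED-style 0-based half-open.

#' Convert a BED-style data frame to a GRanges
#'
#' @param df `data.frame` with `chrom`, `start`, `end` (0-based half-open)
#'   and optionally further columns kept as metadata.
#' @return `GRanges` (1-based closed, as GenomicRanges represents them).
#' @export
granges_from_bed <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (any(df$start >= df$end)) stop("malformed interval: start >= end at line ",
                                    which(df$start >= df$end)[1])
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  extra <- setdiff(names(df), c("chrom", "start", "end"))
  if (length(extra))
    S4Vectors::mcols(gr) <- df[extra]
  gr
}

#' Count peaks overlapping each gene body
#'
#' A peak counts for a gene iff they share at least 1 bp under half-open
#' BED semantics; a peak overlapping several genes counts for each.
#'
#' @param peaks,genes `GRanges` or BED-style data frames
#'   ([granges_from_bed()] is applied to data frames).
#' @return Integer vector of per-gene peak counts, in the order of `genes`.
#' @export
count_peaks_per_gene <- function(peaks, genes) {
  if (is.data.frame(peaks)) peaks <- granges_from_bed(peaks)
  if (is.data.frame(genes)) genes <- granges_from_bed(genes)
  GenomicRanges::countOverlaps(genes, peaks, minoverlap = 1L)
}

#' Pairwise correlation between two per-gene signals
#'
#' @param x,y Numeric vectors, `n >= 4`, finite, non-constant.
#' @param method `"spearman"` (default, robust to heavy-tailed counts) or
#'   `"pearson"`.
#' @return List with `r`, `p_value`, `n`, `method`.
#' @export
pairwise_correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  if (length(x) < 4L) stop("need n >= 4")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       method = method)
}

#' Partial correlation of two signals controlling for a covariate
#'
#' First-order partial correlation via the closed form
#' `r_xy.z = (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) (1 - r_yz^2))`,
#' with a two-sided p-value from `t = r sqrt((n - 3) / (1 - r^2))` on
#' `n - 3` degrees of freedom. The 95% confidence interval uses the
#' distribution-free asymptotic variance of a correlation (the influence-
#' function/moment estimator on the covariate-adjusted residuals) rather
#' than the Fisher z transform, because peak-count signals are
#' heteroskedastic and heavy-tailed, which makes normal-theory intervals
#' anticonservative. For `method = "spearman"` all three variables are
#' rank-transformed first. The estimate is numerically identical to
#' correlating the residuals of `x ~ z` and `y ~ z` (the package tests
#' hold the two routes to 1e-10 of each other).
#'
#' @param x,y Signals; `z` the covariate (e.g. gene expression). `n >= 5`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `r`, `p_value`, `ci_lower`, `ci_upper`, `n`, `method`.
#' @export
partial_correlation <- function(x, y, z, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n)
  if (n < 5L) stop("need n >= 5")
  if (method == "spearman") { x <- rank(x); y <- rank(y); z <- rank(z) }
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0)
    stop("zero variance")
  r_xy <- stats::cor(x, y); r_xz <- stats::cor(x, z); r_yz <- stats::cor(y, z)
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12)
    stop("degenerate: covariate collinear with a signal")
  r <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  r <- max(min(r, 1), -1)
  df <- n - 3L
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  # moment-based CI on the covariate-adjusted residuals
  rx <- x - mean(x) - stats::cov(x, z) / stats::var(z) * (z - mean(z))
  ry <- y - mean(y) - stats::cov(y, z) / stats::var(z) * (z - mean(z))
  xs <- rx / stats::sd(rx); ys <- ry / stats::sd(ry)
  xi <- xs * ys - (r / 2) * (xs^2 + ys^2)
  se_r <- stats::sd(xi) / sqrt(n)
  zq <- stats::qnorm(0.975)
  list(r = r, p_value = p,
       ci_lower = max(r - zq * se_r, -1),
       ci_upper = min(r + zq * se_r, 1),
       n = n, method = method)
}

#' Tile a genome into fixed-width bins
#'
#' @param seqlengths Named integer vector of chromosome lengths, bp.
#' @param bin_width Bin size, bp. Default 200.
#' @return `GRanges` of bins tiling each chromosome (last bin clipped).
#' @export
make_genome_bins <- function(seqlengths, bin_width = 200L) {
  stopifnot(!is.null(names(seqlengths)), all(seqlengths > 0), bin_width > 0)
  GenomicRanges::tileGenome(seqlengths, tilewidth = bin_width,
                            cut.last.tile.in.chrom = TRUE)
}

#' Classify genome bins by peak-class overlap
#'
#' Each bin is classified by which peak sets overlap it (>= 1 bp):
#' `"INO80+DRIP"`, `"DRIP"` (DRIP only), `"INO80"` (INO80 only) or
#' `"NoDRIP+NoINO80"`. The four classes partition the bins.
#'
#' @param ino80,drip Peak sets (`GRanges` or BED-style data frames).
#' @param bins `GRanges` of genome bins (see [make_genome_bins()]).
#' @return Factor of length `length(bins)` with the four class levels.
#' @export
classify_peak_overlap <- function(ino80, drip, bins) {
  if (is.data.frame(ino80)) ino80 <- granges_from_bed(ino80)
  if (is.data.frame(drip)) drip <- granges_from_bed(drip)
  has_i <- IRanges::overlapsAny(bins, ino80, minoverlap = 1L)
  has_d <- IRanges::overlapsAny(bins, drip, minoverlap = 1L)
  cls <- ifelse(has_i & has_d, "INO80+DRIP",
         ifelse(has_d, "DRIP",
         ifelse(has_i, "INO80", "NoDRIP+NoINO80")))
  factor(cls, levels = c("INO80+DRIP", "DRIP", "INO80", "NoDRIP+NoINO80"))
}

#' Fold enrichment of region classes across chromatin states
#'
#' For each chromatin state and region class,
#' `fold = (bp of class in state / total class bp within the segmentation)
#' / (state bp / genome bp)`, where the genome is the segmented territory.
#' By construction the genome-fraction-weighted mean fold per class is
#' exactly 1 (conservation identity), so folds express redistribution, not
#' abundance.
#'
#' @param seg Segmentation: `GRanges` with a `state` metadata column, or a
#'   4-column BED-style data frame (`chrom`, `start`, `end`, `state`).
#' @param class_regions Named list of region sets (`GRanges` or BED-style
#'   data frames), e.g. the bin classes from [classify_peak_overlap()].
#' @return `data.frame` with one row per state: `state`,
#'   `genome_fraction`, then one `fold_<class>` column per class (`NA` for
#'   a class with no bp inside the segmentation, flagged by a warning).
#' @export
state_enrichment <- function(seg, class_regions) {
  if (is.data.frame(seg)) seg <- granges_from_bed(seg)
  if (!"state" %in% names(S4Vectors::mcols(seg)))
    stop("segmentation needs a 'state' column")
  stopifnot(is.list(class_regions), !is.null(names(class_regions)))
  seg_states <- as.character(S4Vectors::mcols(seg)$state)
  states <- unique(seg_states)
  state_bp <- vapply(states, function(s)
    sum(GenomicRanges::width(GenomicRanges::reduce(seg[seg_states == s]))),
    numeric(1))
  genome_bp <- sum(state_bp)
  out <- data.frame(state = states, genome_fraction = state_bp / genome_bp)
  for (cl in names(class_regions)) {
    reg <- class_regions[[cl]]
    if (is.data.frame(reg)) reg <- granges_from_bed(reg)
    reg <- GenomicRanges::reduce(reg)
    # suppressed warning: disjoint seqlevels just mean zero overlap here,
    # reported below through the empty-class flag
    bp_in <- vapply(states, function(s)
      sum(GenomicRanges::width(suppressWarnings(GenomicRanges::intersect(
        reg, seg[seg_states == s], ignore.strand = TRUE)))), numeric(1))
    class_bp <- sum(bp_in)
    if (class_bp == 0) {
      warning("class '", cl, "' has no bp inside the segmentation")
      out[[paste0("fold_", cl)]] <- NA_real_
    } else {
      out[[paste0("fold_", cl)]] <-
        (bp_in / class_bp) / (state_bp / genome_bp)
    }
  }
  out
}

#' DRIP-qPCR fold enrichment over a control condition
#'
#' Input-corrected immunoprecipitation signal relative to the matched
#' control: `(ip_sample / input_sample) / (ip_control / input_control)`.
#' Quantities are linear (already converted from Ct if needed). A sample
#' IP far below its input-corrected control (`< background_frac` of it) is
#' flagged as background, as for a mock IP.
#'
#' @param ip_sample,input_sample,ip_control,input_control Positive linear
#'   DNA quantities (vectorised).
#' @param background_frac Flagging threshold for near-zero IPs.
#'   Default 0.05.
#' @return `data.frame` with `fold_enrichment` and logical `background`.
#' @export
drip_qpcr_enrichment <- function(ip_sample, input_sample, ip_control,
                                 input_control, background_frac = 0.05) {
  vals <- cbind(ip_sample, input_sample, ip_control, input_control)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all quantities must be positive and finite")
  fe <- (ip_sample / input_sample) / (ip_control / input_control)
  data.frame(fold_enrichment = fe, background = fe < background_frac)
}
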