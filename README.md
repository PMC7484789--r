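# rloopkit

Statistical toolkit for studies of R-loop homeostasis — the balance
between co-transcriptional RNA:DNA-hybrid formation and its resolution by
chromatin-associated machines — and its consequences for DNA replication
and cell growth.

A recurring experimental question in this field is whether a factor
*resolves* R-loops (removes them after they form) or *prevents* their
formation. Answering it takes several independent measurement domains,
each with its own quantitative conventions. rloopkit implements all of
them as tested, reusable R functions:

* **DNA-fibre analysis** — fork speed from pulse-labelled tract lengths,
  `speed = (length × 2.59)/time` (kb/min); sister-fork symmetry
  classification (< 25% relative length difference), asymmetry ratios
  (longer/shorter arm), and fold-asymmetry fractions; Tukey summaries
  and standard group tests.
* **3D colocalization** — threshold + 26-connectivity segmentation of
  two-channel nuclear puncta with the conventional 10-voxel background
  filter; object-based voxel-overlap colocalization percentages; the van
  Steensel cross-correlation function (CCF) with an explicit randomness
  criterion; population-median intensity normalization.
* **Locus turnover kinetics** — the per-interval fold-change-in-intensity
  statistic FC-I(log2) = log2(I_t2/I_t1) from reporter/normalizer
  time-lapse traces; its positive (net formation) vs negative (net
  resolution) sign decomposition; a decision table mapping
  total/positive/negative condition comparisons to a mechanistic
  verdict; and formation/resolution rate recovery under an
  immigration–death (M/M/∞) model.
* **Genomic co-enrichment** — peak counts per gene body (BED-convention
  half-open intervals via GenomicRanges), pairwise and partial
  correlation controlling for gene expression, chromatin-state fold
  enrichment with its exact conservation identity, and input-corrected
  DRIP-qPCR enrichment.
* **Growth epistasis** — percent growth, the multiplicative independence
  expectation `V = %growth_A × %growth_B / 100`, rescue fold-changes,
  and the growth-normalized cell-death index.

Every stage has a seeded synthetic-data generator
(`sim_fibre_population()`, `sim_two_channel_volume()`,
`sim_locus_trace()`, `sim_gene_peak_table()`, `sim_growth_plate()`) that
emulates the statistical structure the analysis assumes and records
ground truth, so the whole pipeline is testable end to end without any
external dataset. `run_demo()` executes every stage on synthetic data and
writes all tables plus a summary/manifest pair.

## Worked example

```r
library(rloopkit)

## Fibre stage: tracts of 20, 10 and 31 um over a 20 min pulse
fork_speed(c(20, 10, 31), pulse_min = 20)
#> [1] 2.5900 1.2950 4.0145

## A population where 60% of origins carry one stalled sister fork
fib <- sim_fibre_population(fibre_sim_config(
  n_tracks = 200, stall_prob = 0.6, stall_severity = 0.6, seed = 42))
table(classify_symmetry(fib$pairs$left_um, fib$pairs$right_um))
#> asymmetric  symmetric
#>        131         69
fraction_fold_asymmetric(fib$pairs$left_um, fib$pairs$right_um)
#> [1] 0.57
```

A stalled arm loses 60% of its length, so stalled pairs sit near ratio
2.5 and the > 2-fold fraction (0.57) tracks the simulated stall
probability; the residual speed noise moves a handful of borderline
pairs across the 25% symmetry line.

```r
## Turnover verdict: tethering halves the positive FC-I values
## (formation events shrink) while negatives are untouched
set.seed(7)
ctrl <- c(rnorm(350, 0.3, 0.25), rnorm(150, -0.25, 0.2))
teth <- ifelse(ctrl > 0, ctrl / 2, ctrl)
v <- compare_turnover(list(control = ctrl, tethered = teth))
v$verdict
#> [1] "net_formation_reduced_via_turnover"
```

Totals and positives test lower (Kruskal–Wallis p < 1e-4) while the
negative values are indistinguishable (p = 1): the pattern expected of a
factor that removes R-loops after they form rather than blocking their
formation.

```r
## Genomics stage: two signals confounded by expression only
g <- sim_gene_peak_table(genomics_sim_config(
  n_genes = 2000, direct_association = 0, seed = 7))
pairwise_correlation(g$genes$ino80_abundance, g$genes$drip_abundance)$r
#> [1] 0.5252
partial_correlation(g$genes$ino80_abundance, g$genes$drip_abundance,
                    g$genes$expression)[c("r", "ci_lower", "ci_upper")]
#> $r          [1] -0.0022
#> $ci_lower   [1] -0.0677
#> $ci_upper   [1] 0.0632
```

The raw correlation (Spearman rho = 0.53) is entirely explained by
expression: the partial correlation's confidence interval covers 0, as
constructed.

```r
## Growth epistasis: observed 40% growth vs 50% x 80% predicted
rescue_fold(40, predicted_independent_growth(50, 80))
#> [1] 1
```

## Documentation

The methods vignette (`vignettes/rloopkit-methods.Rmd`) describes the
models, estimator choices (including why the resolution rate uses an
ARMA(1,1) fit with a small-sample correction rather than the raw
regression slope), parameter defaults, and the limits of what synthetic
validation shows. All exported functions carry roxygen documentation.
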