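---
title: "rloopkit: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rloopkit: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rloopkit)
```

rloopkit packages the quantitative core of a common experimental programme
in R-loop biology: deciding whether a chromatin factor *resolves* RNA:DNA
hybrids (turns them over after they form) or *prevents* their formation,
and measuring the genomic and replicative consequences. The package covers
five measurement domains — DNA-fibre replication tracks, 3D two-channel
puncta imaging, live-cell locus intensity time series, genome-wide peak
co-enrichment, and proliferation/cytotoxicity plates — and ships a seeded
synthetic-data generator for each, so every estimator can be scored
against recorded ground truth without any external dataset.

This vignette explains the models behind each stage, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic tests do and do not establish about real data.

## DNA-fibre fork speed and sister-fork symmetry

A pulse-labelled fibre tract of length $L$ (µm) synthesized during a pulse
of $t$ minutes gives a fork speed

$$v = \frac{L \times 2.59}{t} \quad \text{kb/min},$$

with 2.59 kb/µm the standard stretched-fibre conversion (`fork_speed()`,
`kb_per_um` configurable). Sister forks — the two arms emanating from one
origin — are called *symmetric* when the relative length difference
$(\ell_{\max}-\ell_{\min})/\ell_{\max}$ is below 25%
(`classify_symmetry()`); the denominator choice (longer arm) makes the
criterion symmetric under arm swap and bounded in $[0,1)$. The
*asymmetry ratio* is $\ell_{\max}/\ell_{\min} \ge 1$, and
`fraction_fold_asymmetric()` reports the fraction of pairs above a fold
cutoff (default 2, the conventional stall call). Pairs with a zero-length
arm have an undefined ratio; they are excluded with a logged count rather
than propagating infinities into medians.

Speed distributions are summarized as Tukey boxplots (`summarize_speeds()`;
type-7 linear-interpolation quartiles, whiskers at the most extreme
observations within 1.5 IQR — the quartile convention is documented so
independent oracles can match it exactly). Group comparisons dispatch to
the unpaired two-tailed Student's *t*, Kruskal–Wallis, or Mann–Whitney
tests (`compare_groups()`).

The fibre generator (`sim_fibre_population()`) draws per-arm speeds
independently from $\mathcal N(\bar v, \sigma_v)$ and, with probability
`stall_prob`, shortens **one** uniformly chosen arm of a pair by the
factor $1-\text{severity}$. The single-arm convention is what makes a
stall produce asymmetry: shortening both arms equally would cancel out of
the ratio. With `speed_sd = 0` and severity $s$ every stalled pair has
ratio exactly $1/(1-s)$, which gives the tests closed-form expectations.

## 3D puncta segmentation and colocalization

`segment_objects()` thresholds a 3D volume (absolute value or percentile
of the in-mask intensities; no automatic threshold is silently applied)
and labels connected components, 26-connectivity by default
(6/18 configurable), matching the behaviour of common commercial 3D
analysis packages. Components below `min_voxels` (default 10) are
discarded as background. Per object it reports voxel count, intensity
sum, centroid, and a length defined as the extent of the voxel centres
projected on the object's first principal axis plus the projection of one
voxel — a definition chosen so a single voxel has a non-zero length equal
to the voxel size along that axis.

Colocalization is object-based: a channel-B object colocalizes iff it
shares at least one voxel with any channel-A object
(`coloc_by_voxel_overlap()`); the summary percentage is over all B
objects. Properties of colocalizing vs non-colocalizing objects are
compared with classical one-way ANOVA (`compare_object_properties()`).

Randomness of the overlap is assessed with the van Steensel
cross-correlation function (`ccf_van_steensel()`): the Pearson
correlation between channel A and channel B translated voxel-wise along
one lateral axis, $r(d) = \mathrm{cor}(A[x], B[x+d])$, so a genuine
colocalization signal peaks at $d = 0$ while a constructed displacement
peaks at the shift that realigns the channels. Because no standard
significance rule exists for the profile, the package uses an explicit,
documented criterion: verdict `"nonrandom"` iff $r(0)$ is the global
maximum and exceeds the mean + 3 SD of the baseline correlations at
$|d| > d_{\max}/2$. The criterion is intentionally conservative and
configurable study-side by choosing `max_shift`.

The volume generator places spherical, constant-intensity objects without
wrap-around. A fraction `coloc_fraction` of B objects is centred *inside*
a host A sphere (offset at most $r_{\min}-1$, which guarantees at least
one shared voxel); the rest are kept far enough from every A object that
no voxel can be shared. Same-channel objects are mutually separated so
segmentation recovers them one-to-one, which is what lets the tests score
estimated colocalization against ground truth object-for-object. Spheres
rather than irregular blobs are a deliberate choice: they give analytic
volume and length ground truth. Real nuclear puncta are neither spherical
nor constant-intensity, and real backgrounds are structured; passing
these tests therefore validates the *bookkeeping* (segmentation,
overlap, counting) and the statistical machinery, not robustness to
realistic optics.

## Locus R-loop turnover: FC-I(log2)

At a tagged locus imaged every `dt` = 6 min, the reporter intensity
(an RNA:DNA-hybrid-binding fluorophore) normalized by the locus-tag
channel gives $I_t$ (`relative_intensity()`; frames whose normalizer
falls below 1% of its own median are dropped and counted). The
fold-change in intensity between consecutive frames,

$$\mathrm{FCI}(t) = \log_2 \frac{I_t}{I_{t-dt}},$$

is positive when net formation exceeded resolution over the interval and
negative when resolution won (`fci_series()`, `decompose_fci()`).
Intervals spanning dropped frames are excluded rather than rescaled, so
every value sits on a common per-interval scale. Over a gap-free trace
the values telescope exactly to $\log_2(I_{\text{last}}/I_{\text{first}})$,
and scaling $I$ by any constant leaves them unchanged — both properties
are asserted in the tests. Zeros are excluded from the sign partition by
default and counted separately.

`compare_turnover()` pools values across cells within each condition
(pooling, not per-cell means, is the default because the per-interval
values are the unit of information here) and compares the total, positive
and negative value sets between treatment and reference with
Kruskal–Wallis tests at $\alpha = 0.05$ (configurable). The three
outcomes map through a pure decision table (`turnover_verdict()`,
unit-tested over all 27 combinations):

* total lower, positives lower, negatives unchanged → the treatment
  removes what is formed: `net_formation_reduced_via_turnover`;
* total lower, positives lower, negatives also more negative → a uniform
  downward shift: `formation_suppressed`;
* nothing significant → `no_effect`; anything else → `inconclusive`.

### Birth–death model and rate recovery

The generator (`sim_locus_trace()`) treats the latent R-loop count as an
immigration–death process: formation at rate $\lambda_f$ (events/min) and
per-R-loop resolution at rate $\mu$ (/min), observed every $dt$ minutes
through the chain's exact one-step transition

$$N_{t+dt} = \mathrm{Binomial}(N_t,\, e^{-\mu\, dt}) +
\mathrm{Poisson}\!\left(\tfrac{\lambda_f}{\mu}(1 - e^{-\mu\, dt})\right),$$

i.e. standing R-loops are thinned by their survival probability and
within-interval arrivals are already thinned for their partial exposure.
This exact transition (rather than an Euler step, or adding untinned
$\mathrm{Poisson}(\lambda_f\, dt)$ arrivals) is what makes the
closed-form checks available: the stationary mean is exactly
$\lambda_f/\mu$ (the M/M/$\infty$ law) and the autoregressive coefficient
of the observed level is exactly $e^{-\mu\, dt}$. The reporter reads
$\text{gain} \times N$ plus Gaussian noise (floored at $10^{-6}$ so
ratios stay defined); the normalizer is constant plus noise. No
experimental values exist for $\lambda_f$ and $\mu$ at a tethering
locus, so the defaults ($\lambda_f = 0.5$/min, $\mu = 0.01$/min,
stationary mean 50) are documented as illustrative regimes, not fitted
rates.

`estimate_rates()` recovers the rates from an observed trace.
The formation rate comes from the conditional-moment regression
$\Delta I_k = a - b\, I_{k-1} + \varepsilon$, whose conditional mean is
exact for this chain on transient as well as stationary traces, as
$\hat\lambda_f = a/(g\, dt)$. The resolution rate does **not** use the
raw OLS slope: at the default study size (250 frames,
$\mu\, dt = 0.06$) the slope carries both the Kendall small-sample bias
of autoregression estimates and an errors-in-variables attenuation from
measurement noise, which together inflate $\hat\mu$ by roughly half.
Instead, the observed series — AR(1) latent level plus white observation
noise — is exactly ARMA(1,1), so $\phi$ is taken from an ARMA(1,1)
maximum-likelihood fit, the first-order correction
$\phi_c = \phi + (1+3\phi)/n$ is applied, and
$\hat\mu = -\log(\phi_c)/dt$. The OLS route remains available
(`method = "ols"`) and is the automatic fallback; the raw coefficients
$a, b$ are always returned.

## Genome-wide co-enrichment

Peak/gene bookkeeping uses BED-convention 0-based half-open coordinates
throughout, with a 1 bp overlap sufficing; interval arithmetic is
delegated to GenomicRanges. `count_peaks_per_gene()` counts peaks per
gene body (a peak overlapping several genes counts for each). Abundance
correlations (`pairwise_correlation()`) default to Spearman, appropriate
for heavy-tailed counts; Pearson is available.

`partial_correlation()` implements the first-order closed form

$$r_{xy\cdot z} = \frac{r_{xy} - r_{xz} r_{yz}}
{\sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}},$$

with the two-sided p-value from $t = r\sqrt{(n-3)/(1-r^2)}$ on $n-3$
degrees of freedom; the tests hold it to $10^{-10}$ of an independent
residual-regression computation. The 95% confidence interval is *not*
the Fisher-z interval: peak-count signals are heteroskedastic and
heavy-tailed, which makes normal-theory intervals anticonservative
(empirically ~82% coverage at nominal 95% on the package's own
generator), so the interval uses the distribution-free
influence-function variance of the correlation computed on the
covariate-adjusted residuals (~92–94% coverage, improving with n).

`classify_peak_overlap()` classifies fixed-width genome bins by the
presence of each peak type; `state_enrichment()` computes, per chromatin
state and region class,

$$\text{fold}(c, s) = \frac{\text{bp of } c \text{ in } s / \text{bp of } c}
{\text{bp of } s / \text{bp of genome}},$$

where the genome is the segmented territory. The class bp total is
accumulated over states, so the genome-fraction-weighted mean fold per
class is exactly 1 — a conservation identity asserted for every class on
every random segmentation in the tests. `drip_qpcr_enrichment()` computes
input-corrected IP enrichment over a control,
$(\mathrm{IP_s/In_s})/(\mathrm{IP_c/In_c})$, with near-zero IPs flagged
as background; quantities are linear (a documented efficiency-2
conversion applies if Ct values are supplied upstream).

The gene/peak generator draws expression from a lognormal and produces
the two per-gene count signals as Poisson (optionally gamma-overdispersed)
around $\text{rate} = \max(\beta_e e + \beta_d u, 0)$ with a shared
latent $u$. Because the conditional mean is linear in expression and the
two signals are conditionally independent when $\beta_d = 0$, the
population partial correlation given expression is exactly zero in that
case while the pairwise correlation stays positive — the confounding
structure the partial-correlation analysis is designed to expose. An
additive-Gaussian-plus-rounding construction was rejected: rounding
imposes the same nonlinearity on both signals, which leaks into linear
residuals and makes the "no direct association" case test as associated.

## Growth-rescue epistasis

With single-perturbation growth percentages $p_a, p_b$ (relative to
control = 100), multiplicative independence predicts combined growth

$$V = \frac{p_a \times p_b}{100},$$

and `rescue_fold()` reports observed/expected — above 1, the second
perturbation rescues the first. The cell-death index normalizes
cytotoxicity fluorescence by the relative growth of the same condition
and expresses it as fold over the untreated control, whose own index is
exactly 1 by construction; the index is invariant to global rescaling of
fluorescence units. The plate generator applies noise only to the
combined condition, so the mean rescue fold converges to the simulated
interaction parameter without ratio-of-noisy-means bias.

## Problem sizes, determinism and limitations

All generators draw from one seeded RNG per call (`withr::with_seed`),
so identical config + seed reproduces output bitwise and callers' RNG
state is untouched. The test suite exercises: 10,000 random sister-fork
pairs against brute-force re-implementations; 64³ two-channel volumes
(50 objects/channel) over 50 seeds per colocalization fraction;
100-cell pooled FC-I ensembles and 100-trace rate-recovery ensembles at
250 frames; 400-gene tables over 100 seeds for the partial-correlation
logic; and 25 random segmentations for the enrichment identity. These
sizes keep the full suite within a few minutes while leaving
Monte-Carlo error well inside each assertion's tolerance.

What the synthetic validation does *not* establish: robustness to
fibre-tracing errors, optical blur/deconvolution artefacts, photobleaching
or locus-tracking drift, read-mapping or peak-calling noise, and
plate-position effects. The generators emulate the statistical structure
the estimators assume — they are ground-truth harnesses, not forward
models of the instruments. Dataset-dependent headline figures from any
particular study (percent asymmetric forks, percent colocalization,
positive-FC-I fractions, rescue folds) depend on biology and acquisition
settings; here they parameterize synthetic regimes only.
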