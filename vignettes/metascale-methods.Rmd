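---
title: "Hierarchical space-time scale analysis of metacommunity time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical space-time scale analysis of metacommunity time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Ecological theory holds that communities are organized at distinct
hierarchical scales: different sets of species fluctuate at different
temporal frequencies, and the spatial extent of the processes driving each
set should be commensurate with its temporal scale — decadal change should
carry broad-scale spatial imprints (biogeography, dispersal limitation),
while faster fluctuations should reflect finer, more local processes.
`metascale` implements a four-step statistical chain that makes this
space–time duality testable on ordinary long-term monitoring data: one
community table (taxa × years) per site, site coordinates, annual water
chemistry, and a genus-level dispersal-trait table.

The chain is:

1. **Temporal modeling per site.** The sampling-year vector is converted
   into PCNM/dbMEM eigenfunctions — sine-like waves of decreasing period,
   akin to a Fourier basis for the sampling design. A redundancy analysis
   (RDA) of the Hellinger-transformed community table on forward-selected
   eigenfunctions yields canonical axes; each *significant* axis is a
   species group with its own temporal scale, and its site ("lc") scores
   are the modeled group trend.
2. **Species matrices.** For each axis, the |Spearman| correlations of raw
   taxon abundances with the modeled trend, where significant, are compiled
   into a sites × taxa matrix — a time-explicit description of which taxa
   carry each scale of change, and how strongly.
3. **Environmental and spatial matrices.** The same construction for
   environmental variables (with collinearity pruning), and a spatial PCNM
   basis built from site coordinates, forward-selected against each species
   matrix.
4. **Variance partitioning.** Each species-group matrix is partitioned into
   pure environmental, pure spatial, shared and residual fractions
   (adjusted R², partial-RDA permutation tests). A dispersal-trait
   comparison of the group-contributing taxa separates dispersal limitation
   from mass effects as the interpretation of a spatial signal.

## The temporal eigenfunction basis

`build_eigenbasis()` constructs the classical truncated-distance PCNM
basis: Euclidean distances among sampling points are kept up to a
truncation threshold `t` (default: the longest minimum-spanning-tree edge,
i.e. 1 year for an unbroken annual series) and all larger distances are
replaced by `4t`; the matrix `-d²/2` is Gower double-centered and
eigen-decomposed; retained eigenvectors are scaled to unit norm, ordered by
descending eigenvalue, and sign-fixed (largest-magnitude element positive)
for reproducibility.

**Retention tolerance.** Eigenvectors are retained while their eigenvalue
exceeds `tol` × the largest eigenvalue, with `tol = 0.05` by default. The
choice deserves a note. For a 20-step annual series the spectrum of the
truncated-distance PCoA has 13 eigenvalues above numerical zero, but the
13th is an outlier in character: its relative size (2.2% of the dominant
eigenvalue) is five times smaller than the 12th (11.5%), and its
eigenvector oscillates at essentially the sampling interval (13 sign
changes in 20 points), i.e. at the Nyquist limit where a wave cannot be
distinguished from sampling noise. The 5% tolerance discards exactly such
trailing near-Nyquist eigenfunctions while keeping every interpretable
wave, and reproduces the canonical count of 12 eigenfunctions for a
20-year annual series that this style of temporal analysis reports. Setting
`tol` near zero recovers the strictly-positive-eigenvalue criterion (13
eigenfunctions at n = 20) if a user prefers it; all downstream machinery is
indifferent to the choice because forward selection decides which
eigenfunctions enter a model.

No Moran's-I filtering is applied: the basis is defined by the
positive-eigenvalue criterion of the classical procedure, and coordinates
are treated as planar Euclidean without geodesic correction.

## RDA, forward selection and axis tests

`rda_fit()` is a plain least-squares RDA: the centered response is
projected onto the centered predictors, the fitted matrix is decomposed by
SVD, canonical eigenvalues are fitted variances (SS/(n−1)), and lc scores
are the fitted values projected on the axes. R² is corrected with the
Ezekiel formula (`adjusted_r2()`), which may legitimately be negative for
uninformative predictors.

`forward_select()` implements double stopping: selection proceeds only if
the global model with all candidates is significant (permutation test at
`alpha`); candidates are then added in order of added variance, each gated
by a permutation test of its partial contribution, stopping when a
candidate is non-significant or when the cumulative adjusted R² would
exceed the global model's adjusted R². Ties in added variance break toward
the lower-ranked (broader-scale) eigenfunction, deterministically.

`permutation_axis_test()` tests canonical axes sequentially: for axis *k*,
response and predictors are residualized on the lc scores of axes < *k*,
and the pseudo-F of the leading canonical eigenvalue is compared with its
distribution under free row permutation. Two details matter:

* each permuted replicate is **re-residualized on the conditioning axes**
  before the statistic is computed, so observed and permuted data receive
  identical treatment — omitting this step leaves conditioning-aligned
  variance in the permuted denominators and makes the test anticonservative
  for axes beyond the first;
* rows are permuted freely. Freely permuting rows of a time series ignores
  temporal autocorrelation; this mirrors the automatic procedure this
  analysis style is built on and is a documented caveat, not a corrected
  one. Significance is counted from axis 1 up to the first non-significant
  axis, as is standard for sequential (conditional) tests.

Defaults are `alpha = 0.05` and `n_perm = 999`; p-values are
`(exceedances + 1)/(n_perm + 1)`.

## Correlation matrices and collinearity pruning

Step 2 correlates **raw** (untransformed) abundances with the modeled
trends, because the trend is already on the community scale and rank
correlation is invariant to monotone transformations of either series.
Significance is assessed per correlation at `alpha` with no
multiple-testing correction — a deliberate reproduction of the reporting
convention of monitoring studies; the matrices are descriptive inputs to
the partitioning stage, not inferential endpoints. Environmental series
with two seasonal samples per year are averaged to one annual value at read
time.

Collinearity pruning of the environmental matrix treats two variables as
redundant when either (a) their strength columns correlate (|Spearman| >
`collinearity_rho`, default 0.7) across sites, or (b) the median
within-site correlation of their annual series exceeds the same threshold.
Criterion (b) exists because strongly coupled drivers (sulfate and
conductivity in acidifying lakes, whose series track each other almost
perfectly) produce strength columns that are *near-constant* across sites,
and the rank correlation of near-constant columns is dominated by
estimation jitter — the series criterion recognizes the coupling that the
column criterion cannot resolve. The weaker trend-correlate of a redundant
pair is dropped, deterministically.

## Variance partitioning

`variance_partition()` Hellinger-transforms the species-group matrix (the
matrices are zero-rich, and the transformation removes the double-zero
artifact from Euclidean ordination) and computes three adjusted R² values —
environment alone, space alone, both — from which the six fractions follow
by arithmetic. Negative adjusted fractions are reported as computed;
clipping would break the additivity identity
`pure_env + pure_space + shared + residual = 1`, which holds to 1e-9 by
construction and is asserted in the tests. Marginal fractions are tested by
global RDA permutation; pure fractions by partial RDA with permutation of
reduced-model residuals (`scheme = "reduced"`, the standard for partial
ordination tests) or free permutation (`scheme = "direct"`) — the original
procedure does not specify which, so both are provided behind a switch. No
significance is defined for the shared and residual fractions.

## Dispersal traits

Group membership is read off the species matrix (nonzero columns per site);
taxon labels map to genera by their first token; genera absent from the
trait table or recorded as `unknown` are excluded from the denominators and
reported as excluded, never silently coerced. Percentages are per-site over
classified taxa (so each site contributes one observation per trait class),
and groups are compared by one-way ANOVA on arcsine-square-root-transformed
proportions.

## The synthetic generator

`generate_metacommunity()` draws datasets with the statistical structure
the analysis assumes, plus ground truth, so every stage is testable without
real monitoring data. The default design emulates a boreal-lake monitoring
program: 26 lakes × 20 annual samples, 12 slow-trend taxa, 8 taxa cycling
with a 5-year period, 10 stationary taxa, an east–west compositional
gradient confined to the slow group, and a declining sulfate-like driver
(conductivity tracking it) coupled to the slow trend at |ρ| ≈ 0.9.

Design choices that took genuine deliberation:

* **Balanced response pairs.** Within each planted group, taxa respond to
  the group signal in +/− pairs of log-linear coefficients (magnitudes
  0.5–0.75 for the slow group, 0.18–0.28 for the fast group). Group
  structure therefore lives in *composition* — exactly what
  Hellinger-based RDA detects — while plain community totals and plain
  group means stay signal-free. The signed coefficients are part of the
  returned truth, and recovery checks that need a group-level trajectory
  use the response-sign-aware mean.
* **Amplitudes are moderate by design.** A multiplicative (log-linear)
  response of amplitude *b* to a trend *s(t)* carries a deterministic
  quadratic harmonic (∝ *s²*) whose eigenvalue grows as *b⁴* against the
  signal's *b²*; large amplitudes would plant an unintended third temporal
  component. The chosen magnitudes keep that harmonic below the detection
  floor, which was verified by running the full temporal model on
  noise-free intensities.
* **The slow group dominates.** Its amplitudes are set so that its
  canonical eigenvalue exceeds the fast group's in every lake (even after
  spatial attenuation), keeping the axis identity — axis 1 decadal, axis 2
  cyclic — stable across lakes, as the empirical pattern this design
  emulates requires.
* **The spatial gradient selects responders.** Each slow taxon has a
  spatial preference in [−1, 1]; its response amplitude is scaled by a
  logistic in (gradient strength × preference × lake x-position), and its
  mean abundance by the corresponding exponential weight. Regionally
  distinct taxon sets therefore carry the *same* slow trend — the gradient
  moves which taxa respond, not the trend's shape — and the axis-1 species
  matrix inherits an east–west structure that does not depend on count
  noise. The fast group has no spatial structure, giving the planted
  contrast the partitioning stage must recover.
* **Count noise and the validation regime.** Counts are negative binomial
  around the intensity curves (variance μ + dispersion·μ²; dispersion → 0
  gives Poisson). Defaults are `mean_abundance = 400`, `dispersion =
  0.001` — an interannual CV of about 6%, deliberately *cleaner* than real
  kick-net counts. Two effects set this boundary: with heavy noise the
  fast axis loses power, and, more subtly, the expectation of the square
  root of a noisy count is biased by a term proportional to the squared CV,
  which is modulated by the trend and therefore becomes a weak but
  *detectable* pseudo-component of the Hellinger matrix at high
  dispersion. The default regime is a validation instrument: recovery
  failures indicate implementation errors rather than power limits. Passing
  tests in this regime demonstrate correctness of the chain, not that real
  monitoring data — with CVs an order of magnitude larger, taxonomic
  turnover, and missing years — would yield equally clean recovery; users
  exploring realistic power should raise `dispersion` deliberately.
* **Traits.** The trait table assigns about 85% weak flyers (AFS low) and
  60% high female dispersal, with a configurable share of entirely unknown
  genera to exercise the exclusion paths.

One generator invariant from the design brief was reinterpreted: for a
20-point series, "shuffled group means correlate ≈ 0 (|ρ| < 0.3) with the
planted signals" is unattainable, since the null sampling distribution of
Spearman's ρ at n = 20 alone exceeds 0.3 a fifth of the time, and in
low-noise regimes a shuffled subset inherits signal through binomial sign
imbalance. The tests instead assert the intended *relative* property: a
group-coherence score (mean per-taxon |ρ| with the assigned group's
signal) is high under true labels and collapses under label shuffling.

## Numerical conventions

* Hellinger transform maps all-zero rows to all-zero rows (legal
  downstream).
* Permutation p-values are `(exceedances + 1)/(n_perm + 1)`; with a fixed
  seed every result in the pipeline is bit-reproducible, and the report
  bundle written by `run_pipeline()` is byte-identical across runs.
* Eigenvector and canonical-axis orientation: the largest-magnitude element
  (of the eigenvector or lc-score column) is made positive. Axis
  orientation is arbitrary in RDA, which is why Step 2 stores |ρ|.
* Forward-selection ties break toward the lower eigenfunction rank; the
  cumulative-adjusted-R² stopping comparison carries a 1e-8 tolerance so
  that exact-fit models are not rejected by floating-point error.
* Years are calendar integers; the temporal basis uses `year − min(year)`.
  Reals are serialized at full precision; p-values at 4 digits in reports.

## Problem sizes used by the test suite

The suite validates the chain at sizes a laptop handles in minutes: the
two-group recovery check fits 10 lakes with 999 permutations; type-I error
calibration uses 500 null replicates at 199 permutations; the space-signal
contrast runs 50 end-to-end replicates of the full 26-lake pipeline at 199
permutations. These sizes were chosen to keep Monte-Carlo error well inside
the asserted bounds.

## Known limitations

* Free row permutation ignores temporal autocorrelation; p-values for
  strongly autocorrelated series are somewhat liberal. Restricted/block
  permutation is out of scope.
* The sequential axis test conditions on *estimated* axes; under strongly
  heteroscedastic count noise, axes beyond the first can inherit mild
  miscalibration even with correct re-residualization.
* Collinearity between the environmental and spatial predictor matrices is
  reported but not corrected; the design (dynamic correlations vs. static
  space) keeps their spans nearly orthogonal.
* The trait analysis is presence-based (each contributing taxon counts
  once, not abundance-weighted) and genus-level; finer trait resolution is
  out of scope.
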