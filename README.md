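# metascale

Hierarchical space–time scale analysis of metacommunity time series.

Long-term monitoring programs produce one community table (taxa × years)
per site, plus water chemistry and site coordinates. Ecological theory
predicts that such communities are organized at distinct hierarchical
scales — some species groups change slowly (decadal trends), others cycle
on 3–5-year time scales — and that the *spatial* extent of the processes
behind each group should match its *temporal* scale. `metascale` implements
a four-step analysis chain that identifies the temporal species groups and
tests whether each carries a commensurate spatial and environmental signal.
It is aimed at community ecologists working with lake or stream invertebrate
monitoring series, but the machinery is agnostic to the organism.

## The method

1. **Temporal modeling (per site).** The sampling-year vector is converted
   to PCNM/dbMEM eigenfunctions: principal coordinates of the truncated
   distance matrix (distances ≤ *t* kept, larger ones replaced by 4*t*),
   i.e. sine-like waves of decreasing period — a Fourier-like basis for the
   sampling design; 20 annual samples yield 12 eigenfunctions. A redundancy
   analysis (RDA) of the Hellinger-transformed community table
   (ŷᵢⱼ = √(yᵢⱼ/yᵢ·)) on forward-selected eigenfunctions (double-stopping:
   global-model gate, per-step permutation test, global adjusted-R² ceiling)
   yields canonical axes tested sequentially by permutation. Each
   significant axis is a species group with its own temporal scale; its
   "lc" site scores are the modeled group trend, and explained variance is
   reported as the Ezekiel-adjusted R²,
   R²adj = 1 − (1 − R²)(n − 1)/(n − m − 1).
2. **Species matrices.** For each axis, the |Spearman ρ| between each
   taxon's raw abundance and the modeled trend, where significant, enters a
   sites × taxa matrix (zero otherwise).
3. **Environmental and spatial matrices.** The same construction for the
   annual chemistry variables, pruned for collinearity; and a spatial PCNM
   basis built from site coordinates, forward-selected against each species
   matrix.
4. **Variance partitioning.** Each species-group matrix (Hellinger-
   transformed) is decomposed via partial RDA into six fractions — pure
   environment, pure space, the two uncorrected marginals, shared, and
   residual — with permutation p-values for the testable fractions. A
   dispersal-trait analysis (adult flying strength, female dispersal; one-way
   ANOVA on arcsine-square-root proportions) helps attribute a spatial
   signal to dispersal limitation rather than mass effects.

A synthetic-data generator with planted ground truth (slow trend + 5-year
cycle + noise taxa, east–west gradient confined to the slow group, declining
sulfate-like driver) makes the whole chain testable end to end; see the
methods vignette (`vignettes/metascale-methods.Rmd`) for the model,
parameter meanings and design rationale.

## A worked example

```r
library(metascale)

sim   <- generate_metacommunity(synthetic_config(n_lakes = 6, seed = 1))
basis <- temporal_eigenbasis(1988:2007)   # 12 PCNM eigenfunctions
model <- fit_temporal_model(sim$abundance[["L03"]], basis,
                            n_perm = 999, seed = 1)
print(model)
```

```
temporal model 'L03': 9 eigenfunctions selected (PCNM1, PCNM7, PCNM3, ...)
2 significant canonical axes at alpha = 0.05; adj R2 = 0.873
 axis eigenvalue p_value adj_var_share significant
    1  5.026e-03   0.001      0.628412        TRUE
    2  1.620e-03   0.001      0.202584        TRUE
    3  1.019e-04   0.410      0.012744       FALSE
    ...
```

Two species groups are recovered: a slow group on axis 1 (63% of the
adjusted variance — its lc scores track the planted decadal trend) and a
faster group on axis 2 (20% — the planted 5-year cycle). Axis 3 onward is
noise. Continuing through Steps 2–4 for the slow group on the full 26-lake
default dataset:

```r
sim    <- generate_metacommunity(synthetic_config(seed = 1))
set.seed(1)
models <- lapply(sim$abundance, fit_temporal_model, basis = basis, n_perm = 199)
tt <- lapply(names(models), function(l)
  taxa_trend_correlations(sim$abundance[[l]], models[[l]]))
et <- lapply(names(models), function(l)
  env_trend_correlations(sim$env[[l]], models[[l]]))
names(tt) <- names(et) <- names(models)

M1 <- assemble_species_matrix(tt, 1)            # lakes x taxa, |rho|
S1 <- spatial_predictors(M1, sim$coords, n_perm = 199)
E1 <- assemble_env_matrix(et, 1, env = sim$env) # collinearity-pruned
variance_partition(M1, E1, S1, n_perm = 999, seed = 1)
```

```
variance partitioning (adjusted R2):
  Pure environment                     0.0043  (P = 0.448)
  Pure space                           0.5287  (P = 0.001)
  Space uncorrected for environment    0.4989  (P = 0.001)
  Environment uncorrected for space   -0.0255  (P = 0.534)
  Shared variance                     -0.0298
  Residual                             0.4968
```

The planted east–west gradient shows up as a strongly significant pure-space
fraction for the slow group (the same analysis on the axis-2 matrix finds
none, since the fast group has no spatial structure). Negative adjusted
fractions are reported as computed; the four additive fractions sum to 1
exactly.

`run_pipeline()` executes all steps for a dataset (synthetic or read from
delimited files) and writes a deterministic report bundle — per-lake trend
models, correlation reports, per-axis matrices, the six-fraction partition
table, the trait summary, a manifest and a stage log:

```r
cfg <- pipeline_config(synthetic = list(n_lakes = 26, seed = 1),
                       n_perm = 999, seed = 42, out_dir = "results/run1")
run_pipeline(cfg)
```

A thin command-line front end over the same functions is installed at
`inst/cli/metascale.R` (subcommands `run`, `simulate`, `temporal`,
`partition`, `traits`).

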