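# beakrates

Heterogeneity in rates of phenotypic evolution — where on a phylogeny a
trait evolves fast, how fast, and what predicts it — is a central
question in comparative biology, classically studied with avian beak
shape. `beakrates` implements the full analysis chain for such a study
as a tested, reusable R package, aimed at researchers in phylogenetic
comparative methods and geometric morphometrics:

1. **Landmark QC and shape space** — quality control of multi-user 3D
   landmark markups (edge inversion, curve disorder, between-user
   Procrustes distance ≥ 0.2), user averaging, generalized Procrustes
   analysis with thin-plate-spline sliding of semi-landmarks, ordinary
   and phylogenetic PCA, and selection of the axes explaining 99% of
   shape variance.
2. **Variable-rates Brownian inference** — for tip traits
   `X ~ MVN(1 ⊗ α, Σ ⊗ C(r))`, where `C(r)` accumulates branch lengths
   scaled by multiplicative rate scalars `r` on single branches or on a
   branch plus all its descendants. A reversible-jump MCMC samples the
   shift configuration (Poisson prior on the shift count, log-uniform
   scalars), with the phylogenetic mean `α` and trait covariance `Σ`
   profiled out analytically in a C++ pruning pass. Branch rates are
   summarised as posterior medians; terminal branches give
   species-specific *tip rates*. Maximum-likelihood *relative clade
   rates* (background = 1, clades of ≥ 5 species) cover the deep-time
   scale, and Gelman–Rubin PSRF (< 1.1) / effective sample size (≥ 200)
   gate convergence.
3. **Correlates of rates** — species-level predictors (log age, log
   body mass, log generation length, temperature, UVB, log range size,
   island proportion, log competition index, measurement error) and
   clade-level predictors (log distinctiveness in morphospace, log
   richness, log crown age, range and competition summaries), fitted by
   PGLS with Pagel's λ estimated by profile ML:
   `V(λ) = λ·C + (1 − λ)·diag(C)`, with variance inflation factors for
   collinearity.
4. **Synthetic data with ground truth** — birth–death trees, planted
   rate shifts, exact multivariate-BM traits, corrupted multi-user
   markups of a beak template, predictor tables with known PGLS
   structure, and flood-fill range grids, so every estimator above is
   verified by parameter recovery.

## Worked example

```r
library(beakrates)

# 1. a 64-species tree with one clade evolving 20x faster
tree  <- simulate_tree(64, seed = 1)
shift <- rate_config(edge = 18, scope = "clade", scalar = 20)
traits <- simulate_traits(tree, mvbm_params(c(0, 0), diag(2)),
                          scalars = shift, seed = 2)

# 2. reversible-jump MCMC over branch/clade rate scalars
post  <- variable_rates_mcmc(tree, traits,
                             mcmc_settings(n_iter = 5e4, thin = 50, seed = 3))
rates <- summarize_rates(post)
inside <- effective_rates(tree, shift) > 1
median(rates$edges$median_rate[inside])   # rate inside the shifted clade
median(rates$edges$median_rate[!inside])  # background rate
mean(post$k)                              # posterior mean shift count

# 3. species-level PGLS with a planted age effect (-0.5 at lambda 0.6)
sim <- simulate_predictors(tree, betas = c(log_age = -0.5), lambda = 0.6,
                           seed = 4)
d <- sim$design; d$log_rate <- sim$response
pgls(log_rate ~ log_age, d, tree, lambda = "ML")
```

Output:

```
median branch rate inside the shifted clade: 35.1
median branch rate elsewhere:               1.00
posterior mean number of shifts:            2.4
PGLS fit: lambda = 0.635, d.f. = 1,62, adjusted R2 = 0.89
         term estimate     se       t        p
1 (Intercept)   0.0564 0.1181   0.478 6.34e-01
2     log_age  -0.5006 0.0224 -22.314 2.52e-31
```

The sampler concentrates posterior rate mass inside the planted clade
(median 35 vs 1 elsewhere — rates are relative to a background of 1,
with the global scale absorbed by the profiled `Σ`), keeps the shift
count near its Poisson(2) prior, and the PGLS recovers both the planted
slope (−0.5006 ± 0.022) and the error structure (λ̂ = 0.635 vs 0.6).

## The analysis workflow

The `analysis/` directory chains the package into the full study at
desk scale; each script is a thin driver that reads the previous
stage's tables from `results/` and reports what it found:

```sh
Rscript analysis/01_simulate.R     # tree, planted x50 clade shift, markups, grid
Rscript analysis/02_shapespace.R   # QC -> averaging -> GPA + sliding -> PCA/pPCA
Rscript analysis/03_rates.R        # 2 RJ-MCMC chains, diagnostics, clade rates
Rscript analysis/04_correlates.R   # species & clade PGLS, VIFs
```

`run_pipeline(run_config(seed = 1), "out/")` runs the same chain
in-process with one seed and writes a manifest.

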