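---
title: "Methods: estimating and explaining rate heterogeneity in beak-shape evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating and explaining rate heterogeneity in beak-shape evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, algorithms, and design choices behind
`beakrates`. The package implements a complete comparative pipeline for
multivariate trait-rate analysis — landmark quality control, Procrustes
shape space, variable-rates Brownian inference, and phylogenetic
regression of rates on ecological predictors — together with a
synthetic-data layer that makes every stage testable against known
ground truth.

## The scientific problem

Rates of phenotypic evolution vary enormously across lineages. For an
ecomorphological trait such as beak shape, the interesting questions are
where on the tree the rate shifts sit, how large they are, and what
species- or clade-level factors (age, range, environment, competition,
morphological distinctiveness, richness) predict them. Answering these
questions requires chaining several standard but delicate analyses, each
of which this package exposes as a tested function.

## Landmark data and quality control

Shapes enter as configurations of four fixed landmarks (beak tip,
posterior dorsal midline, posterior left and right tomial edges) and
three curves of sliding semi-landmarks (dorsal profile and the two
tomial edges; 25 points per curve by default, 75 in total). Multiple
independent users mark each specimen; `qc_markups()` screens each markup
for three failure modes:

1. **Edge inversion** (`EDGE_INVERSION`): left and right tomial curves
   swapped, or placed grossly asymmetrically. A swapped markup is close
   to a mirror image of an honest one, so a naive comparison of raw
   block distances after optimal rotation can be fooled — the proper
   rotation closest to a reflection partially "undoes" the swap. We
   instead test the *repair*: if relabelling the user's left and right
   blocks fits the reference clearly better (distance below 0.8 of the
   as-submitted distance), the markup is flagged. The asymmetry half of
   the rule has no published quantitative form; we flag when left and
   right mean deviations from the reference differ by more than 50%
   relative to the larger one, above an absolute floor of 0.05
   (unit-centroid-size units) so that near-perfect markups are never
   flagged on relative grounds. Both numbers are arguments.
2. **Curve disorder** (`CURVE_DISORDER`): semi-landmarks placed in the
   wrong order along their curve. Each point is projected onto the
   reference curve's polyline; the claimed order must be monotone in
   projected arc position. Honest noise can swap projections of
   adjacent points, so a violation counts only when the position jumps
   backwards by more than one mean inter-point spacing, with a Spearman
   rank-correlation guard (< 0.95 flags) for subtler scrambling.
3. **User discrepancy** (`USER_DISCREPANCY`): mean Procrustes distance
   to the other users at or above 0.2. The rules apply sequentially:
   the discrepancy pool contains only users that passed the geometric
   checks, because a single scrambled markup sits ~0.7 Procrustes units
   from everyone and would otherwise drag every honest user past the
   threshold.

The reference shape for the geometric checks is the *medoid* of the
other users (minimum summed Procrustes distance to everyone), not their
mean: a GPA consensus that includes a corrupted markup inherits its
scrambled curve, while the medoid stays honest as long as honest users
are the majority. With two other users the tie is broken by including
the checked user's distances, which again favours an honest reference.

The specimen's *measurement error* is the mean between-user Procrustes
distance over accepted users (over all users if fewer than two
survive), and is carried downstream as a species-level predictor.

## Procrustes alignment and sliding semi-landmarks

`gpa()` is a standard generalized Procrustes analysis: configurations
are centred, scaled to unit centroid size, and iteratively rotated to
the running consensus using the SVD-based optimal rotation with the
determinant forced to +1 — reflections are disallowed because beaks are
chiral, and a reflection could fake bilateral symmetry. The Procrustes
distance between two shapes is the root summed squared deviation after
superimposition; it is symmetric and zero exactly on similarity
equivalence classes.

Semi-landmarks are slid to reduce thin-plate-spline bending energy
against the consensus (`slide_semilandmarks()`). Each pass linearises
the curves at the current positions (tangents by central differences,
anchored at the curves' fixed endpoints) and solves the closed-form
joint minimiser of the TPS bending energy over all tangent
displacements. Three numerical choices matter:

* **Kernel sign.** For 3D data the TPS kernel is `U(r) = r`; depending
  on the sign convention the resulting bending-energy matrix can come
  out negative semi-definite. We normalise the sign numerically so the
  quadratic form is PSD (checked on its smallest eigenvalue).
* **Order-preserving cap.** Displacements are clamped at half the local
  inter-point spacing, which guarantees slid curves never trigger the
  curve-disorder rule. The capped joint solution is no longer the exact
  box-constrained optimum, but a capped coordinate-descent line search
  matches it to within a few percent (this is a test).
* **Monotonicity.** Tangent linearisation plus capping cannot guarantee
  descent by construction, so a backtracking halving step accepts a
  displacement only if the bending energy does not increase. The
  recorded per-pass energies are non-increasing by construction and
  asserted in tests.

Three passes are the default (the number is an argument; the published
treatments do not state one). GPA is re-run after every pass.

## Trait spaces: PCA and phylogenetic PCA

`shape_pca()` eigendecomposes the covariance of the vectorised aligned
coordinates about the consensus. `shape_ppca()` replaces the ordinary
mean and covariance with their phylogenetic GLS counterparts under a
pure Brownian-motion tip covariance `C`: the evolutionary covariance
`t(X - 1a) C^-1 (X - 1a) / (n - 1)` with `a` the GLS mean. We
deliberately do not estimate a signal parameter inside the pPCA,
matching the original formulation of the method. On a star phylogeny
with equal branch lengths, `C` is proportional to the identity and the
pPCA scores equal the PCA scores axis by axis up to sign — one of the
acceptance checks. Eigenvector signs are fixed by making each
eigenvector's largest-magnitude entry positive, so scores are
reproducible.

`select_axes()` keeps the smallest set of leading axes whose cumulative
variance fraction reaches 99% (the conventional near-total cut; an
argument). The pipeline additionally caps retained axes at 8 by
default: with noisy crowd-sourced markups, the variance tail is
measurement noise spread over many near-zero axes, and feeding dozens
of noise axes into a profile-likelihood rate model wastes degrees of
freedom on dimensions with no phylogenetic structure.

## The variable-rates model

Traits follow multivariate Brownian motion with an unrestricted
symmetric positive-definite per-unit-time covariance (traits may be
correlated) and branch-specific rate scalars: tip values are MVN with
covariance `kron(Sigma, C)` where `C` accumulates rate-scaled branch
lengths. A *shift* scales either a single branch or a branch plus all
its descendants (clade scope, stem included). The effective rate of an
edge is the product of every scalar covering it.

`mvbm_loglik()` computes the profile likelihood — phylogenetic mean by
GLS, `Sigma` at its conditional ML — in one postorder pruning pass
(Felsenstein contrasts), so no dense `n x n` or `np x np` matrix is
ever formed; the pass is implemented in C++ because the sampler calls
it every iteration. The pruning result is checked against a dense
Kronecker-MVN oracle to 1e-8 on random instances.

Profiling `Sigma` out at each evaluation (rather than sampling it)
keeps the reversible-jump state space down to the shift configuration
alone. The cost is a known identifiability convention: a global
rescaling of all effective rates is absorbed by `Sigma`, so reported
rates are meaningful *relative to a background of 1*, and all recovery
checks are framed as inside/outside ratios.

### Priors and moves

`variable_rates_mcmc()` samples shift configurations with:

* shift count: Poisson with mean 2 (argument `prior_shift_mean`);
* shift location: uniform over free (edge, scope) slots;
* scalar value: log-uniform on `exp(c(-7, 7))` — uninformative over
  plausible rate magnitudes, and the same law the synthetic generator
  uses to plant shifts, so recovery experiments are well-posed.

Moves are add-shift, delete-shift, resize (random walk on the log
scalar, reflected at the prior bounds), and move-to-adjacent-edge, with
Metropolis–Hastings acceptance including the exact proposal and
combinatorial terms. Running the sampler with the likelihood disabled
reproduces the Poisson prior on the shift count (a test). A guard
aborts with a diagnostic if nothing has been accepted after 10% of the
iterations.

Desk-scale defaults are 200 000 iterations, thinned every 100, 50%
burn-in. The burn-in fraction and thinning mirror standard practice for
this model family; the iteration count is chosen so that a 128-tip,
two-trait chain finishes in seconds while passing its convergence gates
(PSRF < 1.1 across chains, ESS at least 200), and all of these are
arguments. Branch rates are summarised as the per-edge posterior
median; terminal-edge medians are the *tip rates* used as
species-specific rates of evolution.

### ML clade rates

`ml_clade_rates()` fits one multiplicative rate per labelled
monophyletic clade (crown-group edges; optionally including the stem)
against a background of 1, maximising the same profile likelihood over
log rates with BFGS. Labels smaller than 5 species are dropped, the
conventional minimum for clade-level rate estimates. The fitted model
nests the single-rate model, so its likelihood can never be lower —
asserted on every fit.

## Correlates

Species-level predictors follow the standard design: species age (the
terminal branch length in the tree), body mass, generation length,
range size, proportion of range on islands, mean temperature and UVB
over the range, a competition index, and measurement error from QC.
The competition index counts, in every grid cell a species occupies,
the co-occurring species of the same family sharing diet and foraging
class, averaged over all the focal's occupied cells (cells with zero
competitors included — the natural reading of averaging "across grid
cells"). Mass, generation length, range size and age are
log-transformed; competitor counts can be zero, so they are transformed
as `log(x + 1)`. Tip rates enter the regression on the log scale by
default (`log_rate = TRUE`), since rates are positive and
right-skewed; the flag exposes the alternative.

`pgls()` is generalized least squares with the Pagel-lambda covariance:
off-diagonal entries of the Brownian covariance multiplied by `lambda`,
diagonal untouched. `lambda` is estimated by profile ML on a 0..1 grid
in steps of 0.01 refined by golden-section search — profile likelihoods
in `lambda` can be flat, and the grid-plus-polish is robust where
derivative methods stall. Coefficients get the usual GLS standard
errors, two-sided t-tests (no multiplicity correction, matching the
conventional presentation of such tables), and an adjusted R² measured
against the intercept-only GLS fit under the same covariance. At
`lambda = 0` the fit reduces to OLS exactly; at fixed `lambda = 1` it
matches a dense GLS oracle — both are tests, alongside an independent
cross-check against `nlme::gls` with a Pagel correlation structure.

Clade-level summaries are richness, crown age (MRCA height), mean range
size, the proportion of island species (species with more than half
their range area on islands — the table needs a per-species
dichotomy and this is the natural cut), mean competition, and
*distinctiveness*: the Euclidean distance from the clade's centroid to
the grand centroid over the retained score axes. Variance inflation
factors (`vif()`) diagnose predictor collinearity; exact collinearity
is reported as `Inf`, not an error.

## The synthetic-data generator

The generator exists to give every stage a ground truth; its defaults
describe the study conditions the tests and acceptance checks run
under:

* **Trees**: constant-rate birth-death conditioned on the tip count
  (via `ape::rphylo`), 128 tips for rate recovery, 200 for PGLS
  recovery.
* **Rate shifts**: planted at distinct random edges, scalars
  log-uniform — one 16-species clade at scalar 50 is the headline
  recovery experiment; scalar 10 for the ML clade fit.
* **Traits**: exact MVN increments edge by edge, so the simulated tip
  covariance is the model's `kron(Sigma, C)` by construction (verified
  empirically against the Kronecker form on small trees).
* **Markups**: template plus iid Gaussian displacement per user
  (noise 0.004 raw units puts honest users ~0.03 Procrustes units
  apart, comfortably inside the 0.2 gate), with constructed corruptions
  that mirror the QC failure modes exactly; outlier users are displaced
  to a *target* Procrustes distance (default 0.3 = 1.5 x the gate) by a
  fixed-point rescaling.
* **Predictors**: log-normal masses and ranges, beta island
  proportions, Poisson competitor counts; the response is
  `design %*% betas` plus MVN error with a Pagel-lambda tree covariance
  (default planted effect: -0.5 on log age at lambda 0.6).
* **Grids**: abstract equal-area cells (110 km squares by default), a
  smooth latitudinal temperature/UVB field, Bernoulli island flags, and
  ranges grown by seeded flood-fill so co-occurrence has realistic
  spatial autocorrelation. No map projection is implemented, and no
  claim is made that the 110 km resolution is optimal for the
  competition index — the cell size is an argument.

What the generator does *not* emulate: real scan/mesh artefacts,
allometry and size variation (shapes are unit-size by construction),
taxonomic error, range-map error, spatially structured guild
assignments, or tree uncertainty (every run conditions on one tree).
Passing recovery tests therefore demonstrates the estimators are
correct and calibrated under the model's own assumptions — not that
those assumptions hold for any particular empirical system.

## Degenerate inputs and numerical conventions

* Zero-length shared paths that collapse two tips make `C` singular;
  the likelihood raises an explicit error rather than returning noise.
* Profiled `Sigma` requires more contrasts than traits (`n - 1 > p`);
  non-PD profiles evaluate to `-Inf` and are rejected by the sampler
  and the ML optimiser (guarded to a large finite penalty for BFGS).
* Medians over even sample counts use the midpoint convention.
* The ESS estimator truncates the autocorrelation sum at Geyer's first
  non-positive pair and is clamped to at most `n` (and the implied
  autocorrelation time to at least 1), so iid traces report ESS = n.
* PSRF follows the classic two-estimator form
  `sqrt(((n-1)/n W + B/n) / W)`; exact-copy chains give
  `sqrt((n-1)/n)` by construction.
* GPA consensus initialisation uses the first configuration; the
  solution is unique only up to a global rotation, and tests compare
  rotation-invariant summaries.
* All simulations and samplers are pure functions of their seed; the
  pipeline derives per-stage seeds deterministically from one global
  seed (kept below 2^31).

## Problem sizes

The shipped analyses and checks use 128-tip trees with 200 000 MCMC
iterations for rate recovery (about ten seconds per chain), 100-tip
trees for ML clade rates, 200-tip trees with 100 replicates for PGLS
recovery, 50 specimens x 4 users for the QC study, and trees of 4-6
tips against dense-matrix oracles. These sizes give stable stochastic
checks at interactive runtimes; all of them are arguments, and nothing
in the implementation is specific to them.

## Known limitations

* Single fixed tree per run; no integration over tree distributions.
* Brownian motion only — no Ornstein-Uhlenbeck or early-burst variants,
  and no measurement-error term inside the likelihood (measurement
  error enters only as a regression covariate, as in the standard
  design).
* The clade-level PGLS in the analysis scripts uses a
  representative-tip tree (one tip per clade) for the among-clade
  covariance; with few clades this is a coarse approximation.
* `Sigma` is profiled, not sampled, so posterior rate uncertainty does
  not propagate uncertainty in the trait covariance.
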