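---
title: "Nestedness, modularity and environment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nestedness, modularity and environment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(econetclim)
```

This vignette is the package's account of its science: the metrics and
models it implements, the tunable parameters and their defaults, what the
synthetic-data generators emulate (and what they do not), and the numerical
and design choices made where the methodology left them open.

## Network representation

All networks are binary.  Mutualistic webs (pollination, seed dispersal)
are bipartite plant-by-animal incidence matrices: links only connect the
two parties.  Food webs are directed unipartite adjacency matrices —
resource → consumer — in which mutual links (both directions) are allowed
but self-links are not.  Weighted records are truncated to presence/absence
on read; the raw files are never modified.  Species with no links at all
are dropped with a warning rather than refused: nestedness and the
degree-based null model are undefined for degree-0 species, and dropping
them is the common practice for incidence matrices.  For nestedness, a food
web is recast as a resource–consumer bipartite matrix (rows = species with
out-degree ≥ 1, columns = species with in-degree ≥ 1; a species may occupy
both sides), which conserves the link count exactly.

## NODF

NODF averages a paired-overlap percentage over all row pairs and all column
pairs.  For a pair (u, v) with fill(u) > fill(v) the contribution is
100·|ones(v) ∩ ones(u)|/fill(v); pairs with *equal* marginal totals
contribute exactly zero (the decreasing-fill rule — this is what protects
NODF from the overestimation that affects earlier nestedness indices).  The
score is invariant under row/column permutation and under transposition,
and ranges over [0, 100].  The implementation is vectorised; the test suite
checks it cell-for-cell against a naive double-loop oracle and against
`vegan::nestednodf`.

## Modularity and its maximisation

Two standard null-term forms are used, chosen by network type:

* bipartite (Barber): $Q = \frac{1}{L}\sum_{ij}(B_{ij} - k_i d_j/L)\,
  \delta(g_i, g_j)$ over plant–animal pairs;
* directed (Leicht–Newman): $Q = \frac{1}{m}\sum_{ij}(A_{ij} -
  k_i^{out} k_j^{in}/m)\,\delta(g_i, g_j)$.

The directed form is a design choice: the original analysis names only the
software it used, and the Leicht–Newman in/out-degree null term is the
standard directed generalisation consistent with the modularity literature
it cites.

Maximisation is by simulated annealing (C++), which limits the resolution
bias of greedy agglomeration.  Moves are single-node reassignments (to any
existing module or a new one) plus collective merges and random-bisection
splits.  Defaults, chosen once to satisfy an exhaustive-search oracle on
small graphs and then left alone:

* initial temperature: auto-tuned from 200 sampled move magnitudes so that
  most early proposals are accepted (the 90th-percentile |ΔQ| with 80%
  acceptance), overridable via `annealing_schedule(t0 = ...)`;
* geometric cooling, factor 0.995, down to `t0 × 1e-4` (≈ 1,800
  temperature steps);
* chain length per temperature: n² single-node moves and n collective
  moves;
* 3 independent restarts, best partition kept.

The single-module partition (Q = 0 exactly) is always a candidate, so the
returned score is never negative.  On 8-node networks the annealer attains
the exhaustive optimum over all 4,140 partitions in ≥ 95 of 100 seeded runs
(verified in the test suite).  All stochastic entry points take an explicit
seed and restore the caller's RNG state; there is no hidden global
randomness anywhere in the package.

## Null models and Z-scores

Degree distributions strongly influence both NODF and M, so both metrics
are standardized as $Z = (X_{real} - X_{null})/SD_{null}$ against 500
degree-preserving nulls (the default `n_null`).

**Directed webs** use edge switching: two randomly chosen edges A→B, C→D
are rewired to A→D, C→B, with one-way and mutual edges switched in separate
pools (A↔B, C↔D → A↔D, C↔B), and a proposal applied only if it creates no
self-edges and no multiple edges — including no one-way edge that would
meet an existing opposite edge to form a new mutual pair.  This preserves
every node's (one-way in, one-way out, mutual) triple *exactly*, which the
tests assert over 10,000 accepted swaps.  The target is 10 × (edge count)
accepted swaps per replicate with a generous attempt budget; highly
constrained webs (e.g. a 3-cycle, where no proposal is legal) are returned
unchanged rather than erroring.

**Bipartite webs** use the degree-probability model: cell (i, j) is an
independent Bernoulli draw with $p_{ij} = \min(1, k_i d_j / L)$ — the
probability that a plant connects to an animal proportional to the product
of their degrees.  The classical averaged-fill variant
$p_{ij} = (k_i/C + d_j/R)/2$ of probabilistic null model II is available
via `variant = "average"`; the product form is the default because it is
the form the verbal description states, and the two differ.  Draws with an
all-zero row or column are resampled (capped at 1,000 attempts): the metric
domain requires it.  One consequence, quantified in the tests: conditioning
on no-empty-lines inflates expected degrees noticeably on sparse matrices,
so the Monte-Carlo expectation check uses a dense regular fixture where the
conditioning probability is ~10⁻⁵.

For metric M each null replicate is annealed with its own sub-seed under
the same schedule (per-replicate retuning would add cost without changing
the ensemble mean appreciably).  A zero-variance ensemble (all nulls
identical) raises an error naming the metric rather than returning an
infinite Z.

## Climate-change velocity

Velocity = temporal gradient / spatial gradient.  The temporal gradient is
|current − LGM| at the site's grid cell; the spatial gradient is the local
slope of the *current* climate surface there, from the four rook
neighbours: dz/dx = (east − west)/2Δx, dz/dy = (north − south)/2Δy, slope =
√((dz/dx)² + (dz/dy)²), with Δx, Δy great-circle cell spacings in km on a
spherical Earth of radius 6,371 km (Δx shrinks with cos(latitude)).  Slope
in km rather than map degrees is a deliberate choice — the sources do not
disambiguate, and only the regression's standardized coefficients matter
downstream, which are scale-free.

Zero-slope (locally flat) sites get an *undefined* velocity, not a floor
value; the design-table builder drops such rows with a logged count.
Velocities enter all regressions as log(v + ε) with ε defaulting to 10⁻⁶ of
the smallest positive value, so the transform is an ε-perturbation of the
plain log for strictly positive data while tolerating exact zeros.
Rasters are plain-text ESRI ASCII grids (header + rows north-first); no
reprojection is performed and coordinates are assumed WGS-84 decimal
degrees throughout.

## Regression: OLS, AICc multimodel inference, SEVM

The response (Z_NODF or Z_M) and all predictors — species richness,
elevation, mean annual temperature, temperature seasonality, annual
precipitation, precipitation seasonality, human footprint, log
temperature- and precipitation-change velocity — are centred and scaled to
unit variance, so every estimate is a standardized coefficient.

Species richness is forced into every candidate model (its importance is
1.00 by construction): associations are sought *beyond* richness, which
mechanically affects both metrics.  The remaining 8 predictors are
enumerated exhaustively (256 subsets).  AICc uses the Gaussian profile
likelihood with k = (mean parameters) + 1 for the error variance:
AICc = AIC + 2k(k+1)/(n−k−1).  Akaike weights
$w_i = e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}$ give variable importance
(the summed weight of models containing a term) and feed model averaging
over the smallest top-ranked set with cumulative weight ≥ 0.95.

Averaging is *conditional* (subset) by default — each coefficient is
averaged over retained models containing it, with weights renormalized —
with the full-model (shrinkage) average behind `method = "full"`; the
software convention behind the published tables is not documented, and the
conditional form matches the common default.  Averaged standard errors use
the revised unconditional-variance estimator
$\sqrt{\sum_i w_i (se_i^2 + (\beta_i - \bar\beta)^2)}$, and p-values come
from a normal approximation.  Conditional averaging is known to be
anticonservative for weak effects; the recovery simulations below quantify
this.

**Spatial structure.**  Spatial weights default to row-standardized
k-nearest-neighbour connectivity (k = 6) by great-circle distance — the
original neighbour rule is not recoverable from the sources, so it is
configurable and recorded in the run manifest.  The residual Moran's test
uses $I = (n/S_0)\,e'We/e'e$ with expectation and variance from the
Cliff–Ord regression-residual trace formulas in the annihilator matrix
M = I − X(X′X)⁻¹X′ and a two-sided normal p-value; a permutation p-value
(999 permutations) is available as a cross-check.  The moment approximation
holds its nominal size — empirical type-I error at α = 0.05 stays within
[0.03, 0.07] over 500 simulations in the acceptance checks.

**SEVM.**  Moran eigenvectors are the eigenvectors of the doubly centred
symmetrized connectivity matrix (I − 11′/n) W (I − 11′/n), ordered by
eigenvalue (equivalently Moran coefficient); only positive-eigenvalue
vectors — positively autocorrelated map patterns — are candidates, the
common filtering convention.  The filter is selected greedily: at each step
the candidate that most reduces the absolute standardized residual Moran
statistic of the *full* model is appended, stopping as soon as the residual
Moran p exceeds α = 0.05 or no candidate improves; the selected filter is
then held fixed while the whole subset-selection/averaging machinery is
rerun.  An empty filter is a valid outcome when residuals are already
independent.

## What the synthetic data emulate — and what they do not

`gen_site_table()` emulates the statistical structure the regression stage
assumes: sites uniform on a 10° × 10° window; each predictor a smooth
Gaussian-process field (exponential covariance, range half the window)
plus 30% white nugget, standardized to the sample; the response a linear
combination with *known standardized coefficients* (defaults 0.7 on
richness, 0.3 on mean temperature, 0 elsewhere) plus an error whose
variance tops the total up to 1 — that unit-variance calibration is what
makes the stated betas true standardized effects — split half/half
(configurable) between a spatially autocorrelated GP with range one
quarter of the window and white noise.  Latent fields are mapped into
plausible site-table units (0.1 °C, mm, a 0–100 footprint score clipped at
~4 sd, velocities via exp so the analysis-time log recovers the linear
field); the rounding and clipping this entails perturb the linear truth by
well under 1% at these scales.

Under these conditions (n = 100 sites, 100 replicates, in the acceptance
checks): SEVM-averaged estimates recover the nonzero effects with absolute
bias < 0.1 (observed ≈ 0.02); null predictors are flagged nonsignificant in
≥ 80% of runs (observed ≈ 0.85, versus ~95% when the error is purely
white) — the residual inflation comes from chance correlation between the
spatially smooth error and spatially smooth null predictors, which a
globally-targeted Moran filter cannot fully absorb, compounded by the
anticonservatism of conditional averaging; and the filter renders the
residual Moran test nonsignificant in ≥ 90% of spatially confounded data
sets (observed 0.96).

What the generators do **not** emulate: the taxonomic composition and
geographic clustering of real network compilations, sampling-effort
gradients, link weights, detection error in interaction records, and any
dependence of network structure on the covariates *through the network
generator* (the response is attached at the site level).  Passing tests
therefore certify the statistical machinery, not the ecology of any
particular data set.

Network generators: `gen_bipartite_nested()` uses a logistic threshold on
the sum of row and column ranks, with the threshold solved so the expected
fill equals the target connectance exactly — bias 0 is uniform fill and
the large-bias limit a deterministic staircase (NODF → 100).  This
rank-threshold form was chosen over sequential-swap approaches for
analytic control of the expected fill; note that a perfect staircase can
only keep all rows occupied when fill ≥ ~0.5.  `gen_bipartite_modular()`
plants a block partition (within/between link probabilities), returned
with the network for recovery checks.  `gen_foodweb()` draws each
unordered pair independently as mutual / one-way / absent with
probabilities set from the target connectance and mutual fraction.
`gen_raster_pair()` builds a planar northward gradient (in km, so central
differences are exact) minus a known offset, making velocity = offset /
gradient analytically at every interior cell.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run annealing oracles on
8-node graphs (exhaustive enumeration over all 4,140 partitions),
null-ensemble calibration at the full n_null = 500 on ~10-node fixtures,
and the regression simulations at n = 100 sites × 100 replicates —
problem sizes chosen so the full battery completes in minutes on one core
while leaving the statistical assertions well-powered.  Pipelines on
hundreds of networks with 500 nulls each are the intended production use;
the per-network null ensemble is the hot spot (the C++ annealer does ~500
maximisations per network), and `--n-null`/`n_null` supports desk-scale
runs.

Ties and degenerate inputs: equal-fill pairs contribute exactly 0 to NODF;
a constant null ensemble errors rather than dividing by zero; rank
deficiency and zero-variance columns are named errors; misaligned rasters
and out-of-grid sites are refused; empty-filter SEVM is valid; p-values
below 0.01 print as "<0.01" in the formatted grids.  Annealing resyncs Q by
full recomputation at every temperature step, so accumulated floating-point
drift cannot exceed one temperature's worth of increments.

## Known limitations

Weighted networks, overlapping communities, phylogenetic signal
corrections, spatial autoregressive (SAR/CAR) alternatives to SEVM, raster
reprojection and multi-model palaeoclimate ensembles are all out of scope.
The Moran test is the moment-based normal approximation, not the exact
ratio-of-quadratic-forms distribution; its calibration is verified by
simulation instead.  Conditional model averaging inflates the significance
of weak effects relative to the shrinkage average — where that matters,
compare both (`model_average(..., method = "full")`).
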