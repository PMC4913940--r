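# econetclim

Analysis of the architecture of binary ecological networks — food webs,
plant–pollinator and plant–seed-disperser webs — in relation to climate,
climate-change velocity and human impact.

Ecological networks tend to be *nested* (specialists interact with subsets
of the partners of generalists) and *modular* (groups of species interact
more within than between groups), and both properties covary with the
environment.  This package implements the complete analysis chain needed to
test such associations across a collection of georeferenced networks:

1. **Network structure.** NODF nestedness on binary incidence matrices
   (food webs are first recast as resource–consumer bipartite matrices),
   and modularity *M* — the Barber bipartite form
   *Q* = (1/L) Σᵢⱼ (Bᵢⱼ − kᵢdⱼ/L) δ(gᵢ, gⱼ) or the Leicht–Newman directed
   form *Q* = (1/m) Σᵢⱼ (Aᵢⱼ − kᵢᵒᵘᵗkⱼⁱⁿ/m) δ(gᵢ, gⱼ) — maximised by
   simulated annealing (compiled in C++).
2. **Null-model standardization.** Each metric is expressed as
   *Z* = (X_real − X_null)/SD_null over 500 degree-preserving null
   networks: an edge-switching algorithm for directed webs that exactly
   preserves every node's (one-way in, one-way out, mutual) degree triple,
   and a degree-probability model for bipartite webs with
   p(plant i, animal j) = min(1, kᵢdⱼ/L).
3. **Climate-change velocity.** The temporal climate difference (current
   minus Last Glacial Maximum) divided by the local spatial climate
   gradient (4-neighbour slope of the current surface, in km), with an
   offset log transform for the regressions.
4. **Spatial multimodel regression.** Standardized-coefficient OLS with
   all-subsets AICc selection, Akaike-weight variable importance,
   95%-confidence-set model averaging, a global Moran's test on the
   residuals, and a spatial-eigenvector (SEVM) pass in which Moran
   eigenvectors of the connectivity matrix are added until residual
   spatial autocorrelation disappears, the filter held fixed while the
   same model selection is repeated.
5. **Synthetic data.** Generators for nested/modular bipartite networks,
   random food webs, site tables with known standardized effects and
   spatially autocorrelated errors, and raster pairs with analytically
   known velocities — so every stage is testable with known ground truth.

## Worked example

```r
library(econetclim)

# a strongly nested 12 x 12 mutualistic web
net <- gen_bipartite_nested(12, 12, connectance = 0.35,
                            nestedness_bias = 8, seed = 42)
z <- standardize_metric(net, "NODF", n_null = 500, seed = 42)
z$x_real          # NODF = 82.0
z$z               # Z_NODF = 2.86  (null mean 63.4, null sd 6.5)
maximize_modularity(net, seed = 42)
# modularity fit: M = 0.265306 over 4 modules
```

Raw NODF (82 of 100) overstates the evidence for nestedness: much of it is
forced by the web's heterogeneous degrees, which the 500 degree-preserving
nulls reproduce (mean 63.4), leaving a standardized excess of 2.9 null
standard deviations.

The regression stage, on 100 synthetic sites whose `Z_NODF` was generated
with true standardized effects 0.7 (species richness) and 0.3 (mean
temperature) plus spatially autocorrelated noise:

```r
sim <- gen_site_table(100, seed = 1)
co <- attr(sim$design, "coords")
W <- knn_weights(co[, "lat"], co[, "lon"], k = 6)
suite <- run_regression_suite(sim$design, W, max_candidates = 25)
suite$table
```

```
 Variables      OLS_full      OLS_best  OLS_averaged OLS_imp     SEVM_full     SEVM_best SEVM_averaged SEVM_imp
 n_species 0.737 (<0.01) 0.732 (<0.01) 0.733 (<0.01)    1.00 0.760 (<0.01) 0.746 (<0.01) 0.749 (<0.01)    1.00
    T_mean 0.241 (<0.01) 0.235 (<0.01) 0.236 (<0.01)    1.00 0.271 (<0.01) 0.262 (<0.01) 0.263 (<0.01)    1.00
       ...
   Moran_I  0.069 (0.03)  0.098 (0.03)                        0.027 (0.15)  0.066 (0.09)
        R2          0.65          0.64                                0.68          0.66
```

Both true effects are recovered with standardized estimates near their
generating values and importance 1.00; the residual Moran's I, significant
under plain OLS (0.069, p = 0.03), becomes nonsignificant once the selected
spatial filter (here a single eigenvector) is added — the pattern that
motivates reading effect estimates from the SEVM columns.

`run_pipeline()` / `pipeline_config()` drive the whole chain (networks →
metrics → Z-scores → design table → OLS → Moran test → SEVM → CSV grids +
run manifest) from one seeded configuration;
`inst/scripts/econetclim-cli.R` is a thin command-line wrapper with
`simulate` and `run-all` verbs.

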