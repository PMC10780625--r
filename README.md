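# dendrostand

Dendroecological analysis of multi-aged, stem-mapped forest stands, built
around the study design used for Mediterranean *Pinus pinea* plots: a
circular mapped plot, increment cores from every adult tree, a nearby
monthly climate record, and the question of whether trees of different age
classes occupy space differently and respond to climate differently.

The package is aimed at forest ecologists and dendrochronologists who want
the complete computational chain — spatial pattern statistics, tree-ring
chronology construction, and climate response functions — as tested,
scriptable R functions rather than a patchwork of GUI programs, plus
simulators that generate stands, ring series and climate with known
structure so every stage can be validated end to end.

## What it computes

**Spatial patterns.** Ripley's K on a circular window of area *A*,

    K(d) = A * sum_{i != j} 1[d_ij <= d] / n^2,

with Besag's variance-stabilized transform `L(d) = sqrt(K(d)/pi) - d`,
pointwise Monte Carlo envelopes from complete spatial randomness (99
simulations, 95% level by default), and the bivariate cross-type
generalization

    K12(d) = (n2 * K12hat(d) + n1 * K21hat(d)) / (n1 + n2)

tested against a null that rotates one class rigidly about the plot
centre, preserving each class's internal structure. Classifications per
distance: clustered / random / regular (univariate) and attraction /
independence / repulsion (bivariate).

**Tree-ring chronologies.** Cross-dating screen (correlation with the
master below 0.40 discards a core), pith-offset estimation from
innermost-ring curvature (`r = L^2/(8h) + h/2`), regression correction
for years-to-coring-height, 5-year age structure, strict biometric
screening (2-of-3 parameters above group mean minus sd, more than 20
rings), and per-class detrending — cubic smoothing spline (old trees),
modified negative exponential `a*exp(-b*t) + k` (mature), and Regional
Curve Standardization (young) — with chronology statistics MRW, MSm, MSi,
CC, CM and first-order autocorrelation of raw and standardized masters.

**Climate response.** Bootstrap orthogonalized response functions of the
standardized master on 24 monthly regressors of the biological year
(October of the year before growth through September of the growth year;
12 precipitation plus 12 maximum *or* minimum temperature columns).
Regressors are standardized and orthogonalized by principal components
(components above the mean eigenvalue retained); in each of 1000
replicates the regression is refit on years resampled with replacement
and verified on the out-of-bag years. Significance: `|mean/sd| >= 1.96`
per regressor; overall `R_V` (mean verification correlation) and `r/s`
(its ratio to its standard deviation), banded at `<0.05`, `<0.1`, `ns`.

## Worked example

```r
library(dendrostand)

## a 111-tree stand: clustered young cohort, random mature and old trees
sc  <- spatial_scenario(n_per_class = c(Y = 56, M = 31, O = 24),
                        process_per_class = list(
                          Y = thomas_process(n_parents = 7, cluster_sd = 4)),
                        seed = 1)
pat <- generate_point_pattern(sc)
pat
#> Planar point pattern: 111 points in a radius-40.0 m circular window
#> marks:  M=31, O=24, Y=56

## univariate K with a 95% CSR envelope for the young cohort
csr_envelope(subset(pat, "Y"), seed = 2)   # see ?csr_envelope
#> Univariate K-function on 56 points, distances 1-40 m
#> envelope from 99 simulations; per-distance classification:
#> clustered    random
#>        33         7

## chronology of the mature class, negative-exponential detrending
climate <- generate_climate(climate_scenario(seed = 3))
rings   <- generate_ring_series(ring_scenario(seed = 4), climate)
trees   <- merge_cores(rings)
M       <- trees[substr(names(trees), 1, 1) == "M"]
chM     <- build_chronology(lapply(M, detrend, method = "negexp"),
                            raw = M, label = "M")
chM
#> Chronology M: 28 series, 1926-1997 (72 yr)
#>   MRW 1.888 mm | MSm 0.275 MSi 0.337 | CC 0.508 CM 0.723 | AC1 raw 0.507 std 0.072

## P-Tmax response function over the 1958-1997 common period
X  <- build_regressor_matrix(climate, 1958, 1997, temperature = "tmax")
y  <- setNames(chM$index, chM$years)[rownames(X)]
bootstrap_response_function(y, X, n_boot = 1000, seed = 5)
#> Bootstrap response function: 24 regressors, 10 components, 1000 replications
#>   R_V = 0.795, r/s = 8.31 (p <0.05)
#>   significant regressors (|mean/sd| >= 1.96):
#>     p_oct_prev   +0.070 (sd 0.009)
#>     p_nov_prev   +0.070 (sd 0.010)
#>     ...
```

Reading the output: the Y cohort is classified clustered over most
distances (its generating process was a Thomas cluster process); the
simulated mature chronology has a mean ring width of 1.89 mm, high mean
sensitivity and inter-series correlation, and standardization removed the
raw master's lag-1 persistence (0.51 raw, 0.07 standardized); the
response function recovers the simulated climate signal — wet previous
October/November favouring growth — with a strongly significant overall
relationship. The full pipeline (`run_pipeline(pipeline_config(...))`)
writes these results as CSV tables per class, and
`inst/scripts/dendrostand-cli.R` exposes it as `simulate`, `spatial`,
`chron`, `response` and `all` subcommands.

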