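---
title: "Spatial patterns, chronologies and climate response in multi-aged stands: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial patterns, chronologies and climate response in multi-aged stands: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrostand)
```

This vignette is the package's account of the science it implements: the
statistical models, the parameters that matter and their defaults, what
the synthetic-data generators do and do not emulate, and the numerical
and design choices made where the methodology left them open.

## The setting

A multi-aged stand of umbrella pine on a circular 5000 m² plot (radius
40 m). Every adult tree (DBH ≥ 3 cm) is mapped in polar coordinates and
assigned to a chronological class from its age at coring height: young
(Y, up to 40 years), mature (M, 41–80), old (O, over 80); plants below
the adult size threshold count as established regeneration (ER) from age
3. Two increment cores per adult tree provide ring-width series; a
monthly station record provides precipitation and temperature. Three
questions drive the analysis: how each cohort is arranged in space, how
its growth history reads after standardization, and which months of
climate control its year-to-year growth.

## Point-pattern statistics

### Estimator

Ripley's K counts, for each distance $d$ on the grid
$\{1, 2, \dots, 40\}$ m (1 m steps up to half the plot diameter, to
limit edge effects), the ordered pairs of trees within $d$:

$$K(d) = \frac{A}{n^2} \sum_{i \ne j} \mathbf{1}[d_{ij} \le d],$$

with ties at exactly $d$ counted inside (closed inequality). The Besag
transform $L(d) = \sqrt{K(d)/\pi} - d$ is zero in expectation under
complete spatial randomness (CSR) and stabilizes the variance.

The default estimator carries **no edge-correction weight**. This is a
deliberate choice, not an omission: envelope inference compares the
observed statistic with the same statistic on simulated null patterns in
the same window, so any edge bias cancels between data and null. The
estimator is therefore *biased* for the theoretical $\pi d^2$ under CSR
(increasingly so at large $d$) while the *test* retains its level. An
isotropic correction for the circular window is available
(`correction = "isotropic"`; the weight is the reciprocal fraction of
the circle of radius $d_{ij}$ centred on tree $i$ that lies inside the
plot) and is the estimator the package's CSR closed-form tests validate
against $\pi d^2$.

### Envelopes and classification

The CSR null simulates `n_sims = 99` patterns with the observed $n$
uniform on the disc. The envelope is the **pointwise empirical quantile**
band at $(1 \pm 0.95)/2$, not the simulation minimum/maximum: with 99
simulations, min/max would give a 2% pointwise test rather than the
nominal 5%. Observed $L(d)$ above the band is classified clustered,
below regular, inside random. These are pointwise statements; across the
40 grid distances some excursions are expected under the null, which is
why the recovery tests ask for a planted signal *somewhere in its
expected distance range* rather than everywhere.

### Bivariate association

The cross-type statistic uses the same estimator shape with denominator
$n_1 n_2$ and the symmetric combination
$K_{12} = (n_2 \hat K_{12} + n_1 \hat K_{21})/(n_1 + n_2)$. The
classical toroidal-shift null wraps one class across a rectangle's edges
and is undefined on a disc. The package's null instead applies a random
rigid rotation of class 2 about the plot centre plus an optional mirror
reflection: within-class structure and the window are preserved exactly,
only the relative placement randomizes — the same conditioning idea as
the toroidal shift, adapted to the circular window. This is a documented
deviation from the rectangular-window convention. Above/below/inside the
envelope reads attraction/repulsion/independence.

Degenerate patterns (0 or 1 point in a class) yield zero statistics with
a flag rather than an error, so batch runs over sparse classes proceed.

## Ring-width series and chronologies

### Screening

Two screens mirror field practice. The **cross-dating screen** builds a
leave-one-out mean master and discards cores correlating below 0.40 with
it, or with under 15 years of overlap ("undatable"). The correlation is
computed on first differences of logs, which isolates the
high-frequency, climate-synchronous signal the way cross-dating programs
do; overlap is counted in years before differencing. The **biometric
screen** works in 10-year age groups: a tree is kept only if at least
two of DBH, height and crown area exceed the group mean minus one
standard deviation, and only if its series has strictly more than 20
rings. Singleton groups have no sd; their trees pass by default and are
flagged. With an $r < 0.40$ rule on series as short as 15–25 rings, a
healthy core can fall below threshold by sampling accident with
probability of order $10^{-3}$–$10^{-2}$; the planted-defect validation
therefore plants its dating defects in long series (at least 70 rings),
where a shuffled series cannot reach 0.40 by chance, and recovery of the
planted set is exact at most seeds.

### Age estimation

Cores missing the pith get an offset from the pith-locator geometry: an
innermost-ring arc with chord $L$ and sagitta $h$ lies on a circle of
radius $\hat r = L^2/(8h) + h/2$; dividing by the mean width of the
innermost rings and rounding gives the missing ring count. Years to
reach coring height come from an OLS regression of ground-vs-breast
height ring-count differences on age at breast height, predictions
rounded and clamped at zero. Corrected ages feed the 5-year age
structure; chronological classes follow the age at coring height, which
is how the class bounds are defined.

### Detrending

Each class uses the method suited to its growth stage:

* **Spline (class O).** A discrete cubic smoothing spline obtained by
  penalized least squares with a second-difference penalty; the penalty
  weight is set from the filter's frequency response
  $H(f) = 1/(1 + \lambda\,(2\sin \pi f)^4)$ so that $H = 0.5$ at a
  wavelength of 67% of the series length — the conventional
  conservative dendro choice. Configurable via `stiffness`.
* **Negative exponential (class M).** $a e^{-bt} + k$ with $a, b > 0$,
  $k \ge 0$, fit by bounded Levenberg–Marquardt; if the fit fails or is
  not a decreasing positive curve, the fallback is the horizontal mean.
* **RCS (class Y).** All series are aligned by cambial age (pith offset
  plus ring number); the mean width per cambial age, smoothed by the
  same spline with a cutoff of 10% of the maximum cambial age, is the
  regional curve; every ring is divided by the curve at its cambial
  age. RCS preserves low-frequency signal that curve-by-curve fitting
  removes, which matters for young trees whose whole lifespan is one
  trend. Ages beyond the curve's support use its last supported value.

Indices are width divided by fitted curve, so a well-fit series has
index mean near 1; detrending never changes series length.

### Chronology statistics

Cores of a tree are averaged into a tree-level series before chronology
building (the between-core noise is within-tree, not between-tree
information). The master is the per-year arithmetic mean of indices
(Tukey's biweight optional). Statistics: MRW (mean ring width of the raw
series), MSm and MSi (mean sensitivity
$\mathrm{mean}_t\, 2|x_{t+1}-x_t|/(x_{t+1}+x_t)$ of the master and
averaged over series), CC (mean pairwise inter-series correlation over
overlaps of at least 20 years — the definition of the "cross-dating
coefficient" is not standardized, so this conventional choice is
documented rather than assumed), CM (mean correlation of each series
with the master), and AC1 on the raw-width master and the standardized
master. Effective standardization leaves AC1 of the indexed master near
zero while the raw master stays strongly positive.

## Climate response functions

The 24-regressor design spans the **biological year**: October of the
year before growth through September of the growth year, 12 monthly
precipitation columns plus 12 monthly maximum *or* minimum temperature
columns — two designs run separately, never a 36-column joint fit. The
dependent variable is the standardized (indexed) master: residual
(prewhitened) chronologies were considered and rejected because they
strip the persistence that is part of the growth signal here.

The estimator is a bootstrap orthogonalized regression:

1. standardize regressors; eigen-decompose their correlation matrix;
   retain components with eigenvalue above the mean (a Guttman-type
   rule; a fixed count is configurable);
2. per replicate, resample the years with replacement as the calibration
   set, regress calibration indices on the retained component scores,
   rotate coefficients back to regressor space, and compute the Pearson
   correlation between predictions and observations on the
   **out-of-bag** years (replicates with fewer than two such years are
   redrawn);
3. aggregate: per-regressor bootstrap mean and sd, significance
   $|\text{mean}/\text{sd}| \ge 1.96$; $R_V$ the mean verification
   correlation; $r/s = R_V / \mathrm{sd}(r)$; band `<0.05` at 1.96,
   `<0.1` at 1.645, else `ns`.

Standardization makes every result invariant to rescaling any regressor
by a positive constant.

Two properties of this estimator deserve honest statement. First,
**component truncation leaks signal**: the projection of a true
single-regressor effect onto the retained component subspace spreads
over all regressors, so regressors with no signal can acquire small but
stable coefficients and be flagged. With the default fixed
orthogonalization (components computed once from the climate matrix, the
classical design) a strong planted signal can induce spurious flags on
roughly a third of the null regressors; the `pca = "resample"` option
recomputes standardization, decomposition and retention inside every
replicate, which widens the coefficient spread honestly and keeps
spurious flags to roughly one in ten. Second, the **$r/s$ test is
conservative**: the bootstrap spread of the verification correlation
overestimates the sampling spread of its mean, so under a pure-noise
chronology $r/s$ is approximately normal with standard deviation near
0.7 rather than 1, and $|r/s| \ge 1.96$ occurs in well under 5% of null
datasets (about 0.8% in a 600-experiment measurement at the default
settings). A significant $r/s$ is therefore a strong signal; a
non-significant one is weak evidence of absence.

## The synthetic-data generators

The generators define the conditions under which the pipeline is
validated; their defaults mirror the study system.

* **Stem maps.** Exact per-class counts (rejection sampling) inside the
  40 m window: 56 Y, 31 M, 24 O by default, Y generated by a Thomas
  cluster process (parents may fall outside the window so edge intensity
  is unbiased; offspring clipped), M and O by CSR, plus a strongly
  clustered 50-plant ER cohort in the full pipeline. Cross-class rules:
  independence, hard minimum distance (repulsion), or shared cluster
  parents (attraction).
* **Climate.** Independent monthly Gaussians (precipitation truncated at
  zero) around a coastal-Tuscan profile: November precipitation maximum,
  July minimum, annual total 644.6 mm; warm-summer temperature cycles
  with Tmax ≥ Tmin enforced. Monthly independence is the simplest model
  sufficient for signal-recovery testing.
* **Ring series.** $w_t = g(\text{cambial age}) \times
  \exp(\beta' z_t + e_t + \text{core noise})$ with $g$ a per-class
  negative exponential, $z_t$ the standardized biological-year
  regressors, and $e_t$ AR(1). Defaults: $\phi = 0.5$,
  $\sigma = 0.20$, core sd 0.08, and $\beta$ on previous-October and
  previous-November precipitation, March precipitation and January
  maximum temperature — the autumn-recharge signal. These values were
  chosen once so that the simulated chronology statistics land in the
  reported ranges for this system (MRW near 1.3/1.85/1.2 mm for Y/M/O,
  inter-series correlations near 0.7, raw AC1 0.6–0.8), and the class
  age ranges (Y 21–40, M 41–74, O 108–140, coring year 1997) reproduce
  the two-generation age structure with its multi-decade establishment
  gap. Multiplicative log-normal noise guarantees positive widths.

What the generators do **not** emulate: spatial autocorrelation of
growth between neighbouring trees, competition or release events,
missing and false rings, measurement drift, month-to-month climate
correlation, and any feedback from stand structure to growth. Passing
the recovery suites therefore shows the *estimators* are correct and
calibrated under the stated model, not that real data meet that model.

Validation fixtures are sized by variance arguments, not convenience:
the RCS check uses a 50-tree shared-curve cohort with noise sd 0.05
because the mean index at sample depth 10 then has standard error
$0.05/\sqrt{10} \approx 0.016$, comfortably inside the ±0.05
normalization band being tested; the stunted-tree plant is stratified
over the screening age groups (at most 40% of any group, stunt factor
0.1) so the group thresholds provably stay above the stunted level and
exact recovery is well-posed; planted dating defects go into cores of at
least 70 rings for the same reason.

## Numerical choices and degenerate inputs

* Distances are evaluated on the closed grid; ties at exactly $d$ count
  as within.
* Pair counting sorts the $O(n^2)$ distance vector once and reads counts
  off by binary search; an independently coded naive double loop is the
  test oracle and must agree exactly.
* `n = 0` or 1 point: zero statistics plus a `degenerate` flag.
* Negative-exponential fits start from data-driven values and fall back
  to the horizontal mean rather than failing.
* The smoothing-spline linear system is solved densely; series are at
  most a few hundred years, so no banded solver is needed.
* All randomness flows from explicit seeds; `run_pipeline()` derives a
  deterministic substream per stage from one master seed, so changing
  one stage's simulation count never perturbs another stage, and a
  fixed seed reproduces the report bundle byte for byte.
* Problem sizes in the validation suites (200-trial calibration runs,
  100-cohort persistence runs, 1000-replicate bootstraps) were chosen to
  give 3-sigma binomial bands that are informative while keeping the
  whole suite runnable on a laptop in a few minutes.

## Known limitations

* The no-correction K estimator is not comparable across windows of
  different shape; use the isotropic correction for absolute values.
* The rotation null for bivariate association preserves each class's
  structure but, unlike a true toroidal shift, does not randomize
  orientation-specific alignment with the window boundary; anisotropic
  patterns could in principle leak.
* RCS assumes the cohort shares one growth law; applying it across
  classes with different laws biases the low-frequency signal.
* The cross-dating screen's 0.40 threshold is a hard rule; on very short
  series its false-flag probability is non-negligible (order 1% per
  core), which is visible in planted-defect runs as an occasional extra
  discard at some seeds.
* The response-function significance machinery is conservative (see
  above); month-level inference should read flagged months as reliable
  and unflagged months as undetermined.
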