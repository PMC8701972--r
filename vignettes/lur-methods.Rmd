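---
title: "Land-use regression modelling of annual NO2: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Land-use regression modelling of annual NO2: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(no2lur)
library(tibble)
```

## The model

`no2lur` implements the classical land-use regression (LUR) workflow for
annual nitrogen dioxide: at each of $n$ ground monitoring sites, the annual
mean concentration $y_i$ (ppb) is regressed on a small set of geographic
predictors extracted around the site,

$$y_i = \beta_0 + \sum_k \beta_k z_{ik} + \varepsilon_i,$$

where each $z_{ik}$ is a candidate predictor (a satellite NO2 column value
at the site, road length within a buffer, vegetation fraction within a
buffer, ...) centred and standardized with its across-site mean and sample
SD. Standardization makes the $\beta_k$ directly comparable (ppb per SD)
and makes the intercept the predicted concentration at the training means.
The fitted surface is then evaluated at arbitrary locations to map
exposure, and aggregated with gridded population weights to administrative
units for epidemiological use.

The scientific core is not the OLS fit but the *supervised,
direction-constrained forward selection* that chooses the predictors.
Candidates are screened (columns with more than 75% missing, identical, or
zero values across sites are dropped), each surviving candidate carries a
pre-defined expected coefficient direction (roads, impervious surface,
population: positive; vegetation, water: negative), and predictors are
added one at a time. A candidate enters only if

1. its fitted coefficient has the expected direction,
2. no coefficient already in the model flips direction, and
3. it raises adjusted $R^2$ by more than 1 percentage point
   (`gain_threshold = 0.01`, absolute).

Each round evaluates **all** remaining candidates and admits the best
admissible one by adjusted-$R^2$ gain. The phrase "starting with the most
correlated variable" is honoured through the round-one evaluation order
and the deterministic tie-break (larger absolute Pearson correlation with
$y$, then lexicographic name). An alternative reading — a single fixed
correlation-ordered pass — is auditable from the selection trace that
`forward_select()` attaches to every model. Coefficient direction is
judged on the point estimate alone; p-values are reported post hoc, not
used as a gate.

## Quality control of monitor series

Hourly series are aggregated to daily means, requiring at least 75% of the
24 hours for a valid day; annual means require at least 75% of the days in
the year (inclusive bound: 273/365 = 0.748 fails, 274/365 passes; leap
years use 366). The day-level 75% rule mirrors the year-level rule; the
hour-level threshold is a package choice (configurable) because the
convention is usually left unstated. Negative hourly concentrations are
physically impossible for NO2 and are treated as missing instrument noise
(logged). Coordinates supplied as geographic strings must carry at least
five decimal places, counted on the literal string — parsing first would
silently erase trailing zeros.

## Buffer extraction semantics

All geometry is Euclidean in a planar metric CRS; geographic inputs must
be projected upstream. The conventions are chosen to be exactly testable
against brute-force oracles:

* **Point value**: the containing cell, with half-open cell intervals
  `[x0, x0 + cell)`, so boundary points resolve deterministically.
* **Buffer average / buffer sum (rasters)**: cells whose *centres* lie in
  the closed disc (ties at exactly $r$ included). Cell-centre membership
  is the standard zonal-statistics convention and admits an exhaustive
  enumeration oracle; area-weighted clipping does not. No-data cells are
  excluded from numerator and denominator; an empty disc falls back to
  the containing cell.
* **Buffer road length**: each segment clipped to the closed disc by
  solving the quadratic $|P(t) - C|^2 = r^2$, lengths in km.
* **Distance to nearest**: minimum point-to-segment distance, km; an
  empty feature layer yields missing (never zero), logged.

The 22 canonical radii run from 100 m to 10 km (`lur_buffer_radii()`).
Buffer statistics are non-decreasing and nested in the radius, which the
test suite asserts as properties.

## Diagnostics

After selection the package reports variance inflation factors
($\mathrm{VIF}_k = 1/(1-R^2_k)$, flagged above 3), Cook's distance
(flagged above $4/n$) and standardized DFBETAS (flagged above
$2/\sqrt{n}$, any coefficient, intercept included — "df-beta values" in
the field's shorthand are taken to mean the standardized version), and
Moran's I of the residuals. Influence measures use the hat-matrix
identities of `stats` and are oracle-tested against explicit leave-one-out
refits.

Case-by-case manual review of suspect monitors is replaced by a
deterministic policy, `sequential_removal()`: repeatedly drop the site
with the largest Cook's distance among those flagged by *both* rules,
refit, and stop when no site is doubly flagged. Reproducibility is
preferred over judgement; the removal log carries the before/after fit so
a human can still audit each exclusion.

Moran's I uses inverse-distance weights (zero diagonal, unstandardized
rows) by default — k-nearest and adjacency schemes are available — with
the exact null expectation $-1/(n-1)$, a seeded 999-draw permutation
p-value, and the kurtosis-corrected analytic randomization approximation
for reference. The weight scheme in the field is often a GIS default left
undocumented; ours is explicit and configurable.

## Validation

Cross-validation evaluates the *final* model: selection runs once on the
full training set and the 5-fold CV (repeated, seeded) refits only the
coefficients. This matches the usual LUR reporting practice; re-running
selection inside every fold answers a different question (stability of
the selection path) and can be done by calling `forward_select()` on fold
subsets. Two $R^2$ conventions are reported throughout — squared Pearson
correlation between observed and predicted, and $1 - SSE/SST$ — because
published agreement metrics rarely say which was used. `%RMSE` divides by
the mean measured concentration over all sites.

Historical transfer (`external_evaluate()`) applies the frozen
coefficients *and* the frozen training column means/SDs to new sites and
periods; column statistics are never recomputed from evaluation data. The
mean bias $\mathrm{MB} = \overline{\hat y - y}$ is signed: negative means
underprediction.

## Mapping

`predict_grid()` evaluates every model term at each cell centroid with
exactly the monitor-site semantics (no precomputed convolution; a fast
path would have to match the direct path to 1e-9 to be admissible).
Negative predictions are not clamped by default — a linear model may
extrapolate below zero in remote cells, and silent clamping would bias
population-weighted summaries; `clamp_zero = TRUE` exists. Cells map to
polygons by cell-centre-in-polygon with an even-odd rule plus an explicit
boundary check, so over a polygon partition every centre lands in exactly
one polygon (first match in stable order). Township summaries report both
unweighted and population-weighted means, and cross-polygon percentiles
of both, because published township tables are often ambiguous about
which variant they show.

## The synthetic world

Because the real monitor-predictor dataset and rasters are not
redistributable, every stage is exercised on seeded synthetic worlds
(`generate_world()`):

* **Predictor fields**: seeded white noise smoothed with a separable
  Gaussian kernel (length scale = half the nominal correlation length),
  affinely rescaled to exact target mean/SD. The kernel construction was
  chosen over spectral synthesis for simplicity; the correlation length
  is approximate and only moment-level properties are asserted.
* **Roads**: random straight segments (uniform origin and bearing,
  exponential lengths, mean 15 km) clipped to the extent, classed
  major/minor.
* **Truth**: annual NO2 is a linear model in four standardized terms —
  satellite column (point, +6.03 ppb/SD), major-road length in 5 km
  (+3.02), vegetation in 1.8 km (−3.43), impervious surface in 7 km
  (+1.87) — around an intercept of 27.6 ppb, with Gaussian site noise
  *calibrated* so the generating model explains 63% of the variance of
  $y$ across the sampled sites. The default network has 105 sites in a
  120 km domain; resulting annual means have mean ≈ 27.6 ppb and
  SD ≈ 10 ppb, spanning roughly 7-49 ppb. The shape of the distribution
  beyond these moments is a modelling choice (approximately normal);
  only the moments are calibrated.
* **Hourly series**: annual mean × winter-peaking seasonal sinusoid
  (relative amplitude 0.4, mean-centred over the year) × 12-h-period
  diurnal sinusoid (amplitude 0.15), plus Gaussian noise (SD 20% of the
  annual mean), truncated at zero; multi-day outage blocks and
  independent hourly drops are then deleted. The seasonal form is a
  sinusoid because only the existence and rough strength of seasonality
  is established for this kind of network, not its shape.
* **Candidate set**: the four generative terms plus 45 decoys — five
  decoy buffer variables (population, water, trees, barren, minor roads)
  at eight well-spaced radii, and four decoy point variables (elevation,
  temperature, precipitation, distances to roads/point sources). Decoys
  are *other variables*, not the generative variables at other radii:
  adjacent-radius buffers of the same field correlate at ≈ 0.99, so
  including them turns set recovery into a radius-resolution question
  (see limitations) rather than a variable-identification one.

Synthetic worlds deliberately do not emulate retrieval physics, plume
chemistry, dispersion, terrain channelling, or the clustered placement of
real monitoring networks. Passing tests therefore demonstrate algorithmic
correctness and statistical behaviour under known truth — not that a
model fitted to real data would attain any particular accuracy.

## What the experiments show — including a negative result

Two package-level Monte-Carlo experiments probe the selection rule under
the default study conditions (105 sites, ≈ 0.63 generative $R^2$, 45
decoys):

* `recovery_experiment()`: across seeded worlds the four generative terms
  are almost always found (the satellite term always enters first, with
  by far the largest incremental adjusted $R^2$), and the generative
  $R^2$ realizes at 0.63 ± 0.05 as calibrated.
* `null_experiment()`: with the response replaced by pure noise, repeated
  5-fold CV correctly reports $R^2$ near zero.

They also expose a real property of the classical >1% gain rule that
users should know: with ~45 candidates and ~105 sites, the rule's
admission threshold corresponds to $|r| \gtrsim 0.14$, which pure noise
exceeds with non-trivial probability once the best of many candidates is
taken (and the sign constraint only halves the risk per candidate). In
our measured experiments a spurious extra term enters the null model in
roughly half the seeded worlds, and the *exact* selected set equals the
generative set in roughly 60% of worlds — the failures split between one
small spurious addition after the true terms and a miss of the smallest
(2%-contribution) term. Mean
recovered coefficients of the large terms are unbiased within Monte-Carlo
error; the smallest term shows a slight conditional-on-selection upward
bias, a well-known property of threshold-based selection. Parsimony in
the published workflow therefore rests on the direction constraints *and*
analyst supervision, not on the gain rule alone. These measured rates are
computed by the acceptance test suite itself; nothing here is asserted
beyond what the tests run.

## Numerical and degenerate-input choices

* Ties in selection gain (within 1e-12) break by |correlation|, then
  name: full determinism, candidate-order invariance.
* Rank-deficient candidate additions are skipped and logged, not fatal;
  rank deficiency in a requested final fit is an error naming the
  aliased columns.
* `standardize_predictors()` refuses zero-variance columns (screening
  should have removed them).
* Moran's I refuses constant residuals (zero variance) and n < 4.
* Sequential removal stops (with a warning) rather than refit with
  $n \le p + 2$.
* All generators derive per-layer sub-seeds from the master seed, so
  regenerating one layer never perturbs another, and every generator is
  bit-reproducible for a fixed seed.

## Problem sizes

The packaged experiments use the study-scale defaults: 105-site worlds on
a 120 × 120 km domain at 1 km predictor resolution, 50 seeded worlds per
Monte-Carlo experiment, 50 CV repeats, 999 Moran permutations, and small
(toy-sized) grids for the mapping worked examples. These sizes were
chosen so the full suite documents the method's behaviour at the scale
the method is actually used, while remaining comfortable to run on a
laptop.

## Known limitations

* Radius resolution: buffers of one variable at adjacent radii are
  nearly collinear, so the *radius* of a selected buffer is far less
  identifiable than the variable itself; the recovery experiment is
  designed around variable identity for this reason.
* The >1% absolute gain rule is not a false-discovery control (see
  above).
* Cell-centre membership differs from area-weighted zonal statistics for
  buffers comparable to the cell size; with 1 km cells the smallest
  canonical radii (100-400 m) degenerate to the containing cell value.
* No geodesy: all inputs must share one planar metric CRS.
* Population-weighted summaries inherit any no-data holes in the
  prediction grid (cells with missing terms are excluded, not imputed).
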