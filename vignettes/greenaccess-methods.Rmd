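---
title: "Methods: accessibility, equity and nonlinear effects of park green space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accessibility, equity and nonlinear effects of park green space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(greenaccess)
```

Urban park green space (PGS) is unevenly distributed, and the question of
who can actually reach it — on foot or by car, within a 15-minute living
circle — is a question of green justice. `greenaccess` implements the
three analytical layers of that question: *how accessible* is park green
space from every populated grid cell, *how equally* is that accessibility
shared within streets and districts, and *which street-level factors*
drive accessibility and equity, including nonlinear threshold effects
that a linear regression cannot see.

# Gaussian-weighted two-step floating catchment area

Accessibility is measured with the two-step floating catchment area
(2SFCA) family, using a normalised Gaussian impedance weight

$$G(t, t_0) = \frac{e^{-\frac12 (t/t_0)^2} - e^{-\frac12}}{1 - e^{-\frac12}},
\qquad 0 \le t \le t_0,$$

and $G = 0$ beyond the catchment threshold $t_0$. $G$ equals 1 at zero
travel time, decreases strictly, and reaches 0 continuously at $t_0$.
The default $t_0$ is 15 minutes for both walking and driving — the
"15-minute life circle" planning convention — and can be overridden per
mode.

**Step 0 — supply capacity.** A park's capacity is its area divided by
the per-capita area standard of its type (national park-design code):
comprehensive 60, theme 50, community 40, amusement 30 m² per person.
`park_capacity()` returns $S_j = S_j^A / pcpa_j$, the population the park
can serve; typed standards are what let a small community park and a
large comprehensive park compete on equal per-capita footing.

**Step 1 — supply–demand ratio.** For every park $j$,
$R_j = S_j / \sum_{k: t_{kj} \le t_0} G(t_{kj}, t_0) P_k$: capacity per
decay-weighted person inside the catchment (`supply_demand_ratios()`).
A park whose catchment holds no population cannot distribute its
capacity; its ratio is set to 0, the park is flagged `unreached`, and it
is excluded from conservation accounting rather than raising a division
error.

**Step 2 — accessibility.** For every cell $i$,
$A_i = \sum_{j: t_{ij} \le t_0} G(t_{ij}, t_0) R_j$
(`accessibility_scores()`). $A_i$ is dimensionless service capacity per
person. When every park is reached, the construction conserves mass:
$\sum_i P_i A_i = \sum_j S_j$ — total capacity is exactly distributed
over the population, which the test suite verifies on hundreds of random
instances alongside a brute-force double-loop oracle.

Travel time from a cell to a park is the minimum over the park's
entrances — entrances are the physical access points, so a large park
with gates on two sides is legitimately closer than its centroid
suggests. Zone (street/district) summaries default to the simple mean of
member-cell $A_i$; a population-weighted mean is available by
configuration.

# Lorenz curves and the Gini coefficient

Equity is summarised by the Gini coefficient of accessibility versus
population. Cells are the Lorenz units; each carries population $P_i$
and, by default, service mass $A_i P_i$, so that "perfect equality"
means *equal per-capita accessibility* — a cell with twice the people
needs twice the service mass to be equally served. (The alternative
convention, service mass $A_i$, is exposed as a configuration choice.)
Units are sorted ascending by per-capita service before cumulation —
the standard Lorenz construction, which guarantees the curve stays below
the diagonal — and zero-population cells are dropped because per-capita
service is undefined for them. The coefficient is the trapezoidal
approximation

$$G_1 = 1 - \sum_{k=1}^{n} (X_k - X_{k-1})(Y_k + Y_{k-1}),$$

with cumulative population share $X$ and service share $Y$. $G_1 = 0$
iff per-capita service is identical across units; a single unit holding
everything gives $1 - 1/n$. If total service is zero, every unit has
identical (zero) per-capita service and the curve is defined as the
equality diagonal, keeping $G_1 = 0$ without a special case. The
implementation is tested against the independent mean-absolute-difference
definition of the weighted Gini to $10^{-9}$, plus the scale-invariance,
replication-invariance and progressive-transfer axioms.

# The boosted-tree engine

The explanatory layer is a from-scratch gradient-boosted regression-tree
engine with squared-error loss. The model is the stagewise sum

$$f_0 = \bar y, \qquad f_m(x) = f_{m-1}(x) + \xi\, h_m(x),$$

where each $h_m$ is a CART regression tree fitted to the current
residuals $y - f_{m-1}(x)$ (the negative gradient of squared loss), its
leaf values are residual means (the closed-form line-search step for
squared loss), and $\xi$ is the learning rate. For $0 < \xi \le 1$ the
training MSE is non-increasing in $m$ — each leaf's update is a scaled
projection of the residual — and the suite asserts this trajectory on
every fitted model.

Splits are chosen greedily by squared-error reduction, with thresholds
at midpoints of consecutive distinct sorted values. Determinism is a
design requirement: ties break to the lowest feature index, then the
lowest threshold, so permuting rows or re-running a seed reproduces the
model bit for bit. Defaults follow common boosting practice where the
method itself does not dictate them: tree depth 3, minimum leaf size 5.
The headline schedule is $M = 5000$ trees at $\xi = 0.001$ with
quintuple (5-fold) cross-validation; because a desk-scale test suite
cannot afford 5000-tree refits per fold, the tests and the bundled
end-to-end checks run reduced but equivalent schedules (e.g. $M = 300$,
$\xi = 0.05$) — the engine is identical, only the schedule is shorter.
Cross-validation shuffles rows with a seeded permutation into contiguous
folds and reports $R^2 = 1 - SS_{res}/SS_{tot}$ about each validation
fold's mean (negative values are possible and meaningful for fits worse
than the mean). No stochastic row or column subsampling is used.

Correctness has two independent anchors in the tests: closed-form cases
(one unshrunk round must equal plain CART on the centred response;
unlimited depth at $\xi = 1$ must drive training error to zero) and a
cross-implementation check against xgboost at matched hyperparameters
(exact greedy splits, no regularisation), where predictions agree to
$R^2 > 0.99$ — in practice to about $10^{-6}$.

**Relative importance** attributes each split's squared-error
improvement to its feature, sums over all trees, and normalises to
percentages summing to 100. Key variables are those strictly above a 7%
contribution cutoff.

**Partial dependence** clamps one feature to each value of a grid
spanning its 1st–99th percentile (50 points by default) and averages
the model prediction over all rows. The quantile clipping, and the
down-weighting of sparse grid bins during smoothing, both serve the same
purpose: tails with few observations produce unreliable curve segments,
and planning-relevant thresholds should be read from the well-supported
interior. Smoothing is locally-weighted quadratic regression (loess,
span 0.5 by default, endpoints retained); the raw curve is kept
alongside the smooth.

**OLS baseline.** `ols_fit()` is a thin, validated wrapper over
`stats::lm` that reports coefficients and $R^2$ and refuses
rank-deficient designs by naming the collinear columns.
`compare_models()` reports OLS in-sample $R^2$ against the boosted
model's cross-validated $R^2$; on data with genuine threshold effects
the boosted model wins, on purely linear data the two agree closely —
both behaviours are asserted in the suite.

# Street scenarios

Streets are classified per mode by crossing accessibility and equity at
fixed cutoffs: high accessibility means mean $A$ strictly greater than
10 (walking) or 1 (driving); low equity means Gini strictly greater than
0.5. The four labels HA-HE, HA-LE, LA-HE, LA-LE partition the street
set; values exactly at a cutoff are classified low-accessibility /
high-equity because the definitions are strict inequalities. The labels
separate streets where planners should prioritise supply (LA-\*) from
streets where the distribution, not the amount, is the problem (\*-LE).

# The synthetic city

No administrative inputs ship with the package; a generator provides
city datasets with known structure so every stage is testable.

* **Grid.** A square grid of 500 m cells, 30 × 30 by default (225 km²)
  — the grid convention used for accessibility measurement, at a size a
  laptop handles comfortably.
* **Population.** 1.6 million residents by default (a dense central
  urban area at roughly 7,100/km²), apportioned by largest-remainder
  rounding so cell populations are integers summing *exactly* to the
  total. The spatial surface is a uniform floor plus a small number of
  Gaussian "city-core" kernels (3 by default, bandwidth 15% of the city
  side), emulating population concentration along river corridors and
  historic cores without real geography; the `clustering` parameter
  scales the concentration and 0 recovers a uniform city.
* **Parks.** Default counts 8/7/55/93 for comprehensive/theme/community/
  amusement — the type proportions of a large central-Chinese park
  inventory scaled to the default area. Areas are drawn log-uniformly
  from type-specific ranges (comprehensive largest, amusement smallest);
  1–4 entrances sit on the circle of the park's equivalent-area radius.
* **Travel.** Straight-line centroid-to-nearest-entrance distance times
  a detour factor (1.2) over mode speed: walking 5 km/h, driving
  30 km/h. No network routing is attempted; real travel-time matrices
  can be supplied in long-format CSV.
* **Streets/districts.** Regular tilings (5 × 5 cells per street, 3 × 3
  streets per district) stand in for administrative boundaries.

The street-level **feature table** draws the 15 predictors from
moment-matched marginals (lognormals for the skewed, positive
quantities; a clipped normal for land-use mix; a small discrete
distribution for the park-type count) so their scales resemble a real
street table. Responses are built from an `effects_spec()`: each
predictor contributes a known additive effect — linear, plateau
(saturating threshold), Gaussian peak, or null — plus Gaussian noise,
and the noiseless ground-truth function is returned with the table. This
is what makes effect recovery a *test* rather than a demonstration: the
suite asserts that a plateau effect planted on population density at
threshold 0.07 is found first in the importance ranking and that its
smoothed partial dependence is flat beyond the threshold (within 15% of
the curve's range, on a 529-street table with noise SD 0.3 and an
$M = 300$, $\xi = 0.05$ schedule).

What the generator does **not** emulate: real road networks and
congestion, building-level population apportionment (the kernel surface
replaces it, since no reproducible recipe exists for the original),
spatial autocorrelation between predictors and the geometry (predictors
are drawn independently of the map), and park quality. Passing tests
therefore demonstrate that the *methods* behave correctly on data with
known structure — not that any particular city looks like the synthetic
one.

# Pipeline, determinism and numerical choices

`run_pipeline()` executes generate → travel times → 2SFCA (both modes)
→ street means → street/overall Gini → feature assembly → four boosted
response models (mean accessibility and Gini × walking and driving) with
importance, key variables, partial dependence and OLS comparison →
scenario classification, writing every table as CSV, models as
documented JSON, and a manifest (config hash, seed, versions, file
list). One master seed is split into independent per-stage streams, so
changing the boosting settings does not perturb the generated city. Runs
are bit-reproducible: the suite md5-compares two complete runs. A
failing stage aborts with the stage name and leaves a `FAILED` marker
beside any partial outputs.

Remaining numerical conventions: split improvements below $10^{-12}$
count as no improvement (stops tree growth on constant responses);
Gini values are reported unclamped (floating-point can give $-10^{-16}$
for exact equality, which the $[0,1]$ invariant tolerates at $10^{-9}$);
empty zones are omitted with warnings rather than errors; and boundary
scenario values fall on the low-accessibility/high-equity side by the
strict-inequality definition.

# Known limitations

* Euclidean-with-detour travel times understate barriers (rivers,
  highways); supply measured travel times for realistic runs.
* The 2SFCA variant is the plain Gaussian form; no competing catchment
  sizes, kernel-density or multi-modal blends.
* Importance is reported from the full-data fit, with cross-validation
  reported separately; fold-averaged importance is not computed.
* OLS standard errors and significance are not reported (the baseline
  exists for the $R^2$ comparison).
* With the default 30 × 30 city the feature table has 36 streets —
  enough to exercise the pipeline end to end, but parameter-recovery
  claims in the tests use ~500-street tables.
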