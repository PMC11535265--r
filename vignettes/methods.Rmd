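---
title: "Exposure-zone regionalization of mortality risk: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exposure-zone regionalization of mortality risk: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(expozone)
```

# The problem

In regions with heavy industry, mortality from specific causes — ischemic
heart disease, mesothelioma, pneumoconiosis — clusters near pollution
sources: contaminated rivers, cement plants, refineries, zones of elevated
fine particulate matter (PM2.5). `expozone` implements a complete pipeline
for turning locality-level death registries and pollution-factor rasters into
a risk regionalization:

1. **Cause screening** — crude mortality rates and mortality-rate ratios
   (MRR) against a national reference series select causes that repeatedly
   exceed the reference.
2. **Exposure suitability** — a presence-background maximum-entropy model
   fitted on localities with cases, over a stack of pollution covariates
   (distance to rivers, distance to industries, PM2.5, elevation), yields a
   continuous suitability surface.
3. **Zonation** — Fisher-Jenks natural breaks classify the surface into
   three exposure zones (low / medium / very high).
4. **Association** — cases and population aggregate by zone into 2x2 tables;
   odds ratios with Woolf intervals, relative risks, and the attributable
   fraction in the exposed quantify the disease-exposure association.

Because real registry extracts and the satellite PM2.5 product are not
redistributable, the package ships a synthetic-region simulator with planted,
known exposure-disease effects. Every stage is tested against that truth.

# Models and formulas

## Rates and screening

The crude rate is $r = s \cdot c / p$ for $c$ cases, population $p$ and scale
$s$ (100,000 by default). Person-time is approximated by a single census
population times the window length; this mirrors common registry practice
(one census for a multi-year window) and slightly biases rates when the
population changes over the window — a deliberate fidelity choice,
documented rather than corrected. The MRR is the ratio of local to reference
rate; causes are ranked by the number of years with MRR strictly above 1,
restricted to the top-k causes by total deaths, with an exclusion list for
causes whose aetiology is not pollution-specific (e.g. diabetes). Years in
which the reference series records zero deaths give a *missing* MRR, not an
infinite one. Ties in the year count break by total deaths, then cause code,
so the ranking is permutation-stable.

## Maximum-entropy suitability

Let $f_j(x) \in [0,1]$ be features built from the scaled covariates (linear,
quadratic, optional pairwise products, and hinge features in both
orientations at equally spaced knots). The model is the Gibbs distribution
over background cells

$$q_\lambda(x) = \frac{\exp\big(\sum_j \lambda_j f_j(x)\big)}{Z_\lambda},$$

with $\lambda$ maximizing the $L_1$-regularized presence log-likelihood

$$\frac{1}{m}\sum_{i=1}^{m}\sum_j \lambda_j f_j(x_i) - \log Z_\lambda
  - \sum_j \beta_j |\lambda_j|, \qquad
  \beta_j = \beta_{\mathrm{mult}} \cdot s_j / \sqrt{m},$$

where $s_j$ is the background standard deviation of $f_j$ and $m$ the
presence count. The optimizer is cyclic coordinate ascent: each coordinate
takes a soft-thresholded Newton step (the exact minimizer of the local
quadratic model with the $L_1$ term), halved until the regularized gain does
not decrease, so the gain trace is non-decreasing by construction. Fitting
stops when a full cycle improves the gain by less than $10^{-6}$ (or after
500 cycles). Each accepted step's gain increment is credited to the updated
feature's source covariate — product features split credit equally — giving
the familiar *percent contribution* table after flooring negative
accumulations at zero and normalizing to 100%.

The *raw* output is $q_\lambda$, which sums to 1 over the background. The
*logistic* output is $e^{H} q / (1 + e^{H} q)$ with $H$ the entropy of $q$:
a strictly increasing transform into $(0,1)$ under which a uniform model
scores exactly 0.5 everywhere. Training quality is summarized by the
rank-based AUC (Mann-Whitney probability that a presence cell outscores a
background cell, ties counted one half).

Presence records default to *one point per locality with at least one case*;
a `presence_mode = "case"` option replicates each locality by its case count
instead. Both readings of "cases by location as occurrence data" are
defensible; the default treats the locality as the observational unit, while
case mode weights the presence means by burden.

## Natural-breaks zonation

Fisher-Jenks finds the contiguous partition of the sorted suitability values
into $k$ classes minimizing total within-class squared deviation, by exact
dynamic programming ($O(k n^2)$, implemented in C++). Among cost-ties the
partition with lexicographically smallest breaks is returned. For rasters
above 20,000 valid cells the DP runs on a seeded uniform subsample — still
the exact optimum for that sample, which matches how desktop GIS classifiers
behave on large rasters. Classification uses half-open intervals
$[b_c, b_{c+1})$ with the top class closed, so a value equal to an internal
break belongs to the *higher* class and every cell gets exactly one label.
Each internal break is reported as the smallest member of the upper class,
which makes classification reproduce the optimal partition exactly; we report
data-driven bounds rather than forcing any particular printed lower bound.

## Zone association

With zones fixed, localities aggregate into per-zone cases $c_z$ and
population $p_z$. For a contrast of exposed zones $E$ against unexposed $U$:

* $A = \sum_{z \in E} c_z$, $B = \sum_{z \in U} c_z$, $C = p_E - A$,
  $D = p_U - B$;
* odds ratio $\mathrm{OR} = AD/BC$; undefined when $B$ or $C$ is zero unless
  the Haldane-Anscombe correction (add 0.5 to all four cells) is requested —
  the refusal default mirrors how a cause with cases only in the top zone
  should be reported as "not comparable" rather than papered over;
* the default confidence interval is Woolf's,
  $\exp(\ln \mathrm{OR} \pm z_{1-\alpha/2}\sqrt{1/A + 1/B + 1/C + 1/D})$,
  the epidemiological standard; a `linear` option
  ($\mathrm{OR} \pm z \cdot \mathrm{OR} \cdot \sqrt{\sum 1/\text{cell}}$)
  is provided because some published tables print arithmetically symmetric
  intervals, and the result labels which method produced it;
* relative risk is the crude rate ratio between the two sides;
* the attributable fraction in the exposed is
  $100 \cdot (\mathrm{OR}-1)/\mathrm{OR}$ percent (the OR-based form; an
  RR-based variant is the same arithmetic applied to RR). Protective
  associations report 0 with a flag rather than a negative percentage.

# The synthetic region

`region_config()` describes a small industrial valley: by default a 64 x 64
grid at 250 m (16 x 16 km), two rivers, five industries, sixty localities.
The generator's defaults are the package's study conditions:

* **Elevation** — a sum of four low-frequency cosine bumps with random
  phases, rescaled to 1,700-2,100 m. Smooth by construction, so tests can
  reason about it; it does not emulate fractal terrain roughness.
* **Rivers** — monotone random-walk polylines spanning the grid west to
  east, reflected at the edges; this guarantees a nontrivial distance
  gradient across the whole region.
* **Industries** — uniform random points in the interior.
* **PM2.5** — background 8 ug/m3 plus an 18 ug/m3 plume decaying
  exponentially from the nearest industry (e-folding 1.5 km) plus Gaussian
  cell noise (sd 0.5), i.e. 20-26 ug/m3 near sources: the regime of a
  heavily polluted basin with clean-air surroundings.
* **Populations** — log-uniform between 500 and 5,000, matching the skewed
  size distribution of small municipal localities.
* **Mortality** — Poisson counts per locality-year with mean
  $p \cdot r_0 \cdot \exp(\gamma \cdot \text{score})$, where the score is a
  known deterministic exposure surface (a convex combination of exponential
  proximity to industries and rivers, rescaled to $[0,1]$). Poisson, not
  binomial, because these are rare events in a rate framework. The default
  $r_0 = 1.5\times10^{-5}$ per person-year and $\gamma = \ln 6$ put the
  region in the published regime of tens of cases per 100,000 over an
  8-year window with roughly an order-of-magnitude rate spread between the
  extreme zones.

One global seed fans out to deterministic per-component substreams
(elevation, rivers, industries, PM noise, localities, mortality), so adding
or regenerating one component never perturbs the draws of another, and the
same configuration is bit-identical across runs.

For association-recovery studies, `simulate_association_study()` plants an
*exact* odds ratio: the unexposed per-person probability $\mu_u$ is solved
from the realized populations so the expected total case count equals the
design value (200 by default), and the exposed probability is the
odds-transform $\mu_e = \mathrm{OR}\cdot\mathrm{odds}_u /
(1 + \mathrm{OR}\cdot\mathrm{odds}_u)$, making the population-level odds
ratio of the expected table exactly the target. Both the target OR and the
expected case yield are design parameters fixed before any data are drawn.

**What the simulator does not emulate:** spatial autocorrelation of
residual risk, migration and person-time censoring, age/sex structure (the
pipeline computes crude rates only), covariate measurement error, and the
real geography of any particular valley. Passing tests therefore demonstrate
that the *methods* are implemented correctly and recover planted effects
under realistic magnitudes — not that any particular real-world estimate is
reproduced.

# Numerical choices

* **Grids** are upper-left-origin, row-major-down (y decreases with row
  index), square cells in metres, planar coordinates throughout; distances
  are exact point-to-segment Euclidean distances to cell centers, with no
  geodesy — appropriate for study areas tens of kilometres across.
* **Resampling** is bilinear for continuous layers; distance layers are
  *recomputed* from their source vectors on the target grid rather than
  resampled, because resampling a distance surface blurs exactly where the
  gradient matters. Nodata propagates as the union of missingness. The
  common analysis resolution is a required user choice; the package does not
  guess between mixed input resolutions.
* **Collinearity screening** drops, while any pair of layers has
  $|r| \ge 0.85$, the member of the worst pair with the larger mean absolute
  correlation against the other retained layers (ties break on the later
  name). This keeps the most independent information and is deterministic
  and idempotent. Zero-variance layers have undefined correlation and are
  dropped first with a warning.
* **MaxEnt optimization** caps any single coordinate step at 10 on the
  natural-parameter scale to avoid overflow, uses a log-sum-exp normalizer,
  and bounds the per-coordinate curvature away from zero at $10^{-12}$.
  Background is all valid cells up to 10,000, then a seeded uniform sample.
  Features are clamped to the training $[0,1]$ range when projecting.
* **Fisher-Jenks** guards tiny negative within-class costs from floating
  cancellation at zero and compares cost ties at a $10^{-10}$ relative
  tolerance during reconstruction.
* **Rounding**: rates and fractions are stored at full precision; rounding
  is applied only at report time.

# Problem sizes

The test suite and the acceptance script run end-to-end studies on 32-64
cell grids with 40-64 localities and ~200 expected cases per study, and 100
replicate studies for coverage checks — sizes at which the exact DP, the
brute-force oracles, and 100-fold replication all complete in seconds on a
single CPU while leaving the statistical regime (rare events, hundreds of
cases) intact.

# Known limitations

* Crude rates only; no age/sex standardization or small-area smoothing.
* No covariate-adjusted (regression) odds ratios and no spatial
  autocorrelation correction in the association stage.
* One planar CRS is assumed; there is no reprojection machinery.
* The MaxEnt implementation follows the published training scheme
  (coordinate-wise updates with $L_1$ soft-thresholding, entropy-calibrated
  logistic output) but is not a bit-for-bit replica of any particular
  desktop release's clamping tables or default regularization schedules.

# A worked run

```{r, eval = FALSE}
library(expozone)

res <- run_pipeline(pipeline_config(seed = 3))
pc <- res$causes[[1]]

pc$contribution      # percent contribution per covariate
pc$auc               # training AUC
pc$breaks            # Jenks breaks of the logistic surface
pc$summary           # per-zone cases, population, rate, area
pc$associations[[1]] # OR, Woolf CI, RR, attributable fraction

autoplot(pc$zones)                       # exposure-zone map
plot_associations(pc$associations)       # forest plot
```
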