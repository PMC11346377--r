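---
title: "Spatial linear models on stream networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial linear models on stream networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(streamnet)
```

## The model

Data observed at sites on a dendritic stream network exhibit dependence that
ordinary geostatistics cannot express: correlation may follow the watercourse
(and only connect sites that actually share flow), follow the network in both
directions, or act through straight-line proximity. **streamnet** fits the
Gaussian spatial stream-network (SSN) linear model

$$
\mathbf{y} = \mathbf{X}\boldsymbol\beta + \boldsymbol\tau_{tu}
  + \boldsymbol\tau_{td} + \boldsymbol\tau_{e} + \boldsymbol\epsilon,
$$

where the three spatially dependent error components and the independent
nugget $\boldsymbol\epsilon$ are zero-mean Gaussian with

$$
\Sigma = \Sigma_{tu}(\sigma^2_{tu}, \alpha_{tu})
       + \Sigma_{td}(\sigma^2_{td}, \alpha_{td})
       + \Sigma_{e}(\sigma^2_{e}, \alpha_{e})
       + \sigma^2_0 I .
$$

Each spatial component has its own partial sill $\sigma^2$ (its contribution
to the variance at distance zero) and range $\alpha$ (its length scale).

* **Tail-up** errors arise from a moving average over the water flowing
  *from upstream*. They connect only *flow-connected* pairs (one site lies on
  the other's downstream path) and must be weighted to conserve variance at
  junctions.
* **Tail-down** errors average *downstream* and connect both flow-connected
  and flow-unconnected pairs (sites that share a junction but not flow); no
  weights are needed.
* **Euclidean** errors act through straight-line distance, capturing drivers
  not confined to the channel (e.g. climate, regional geology), and are the
  only spatial component that crosses disconnected networks.

### Pair geometry

Every pair of sites on one network is summarised by its stream distances to
the pair's closest common downstream point, $a \ge b \ge 0$, with total
stream distance $h = a + b$. The pair is flow-connected exactly when $b = 0$.
`hydro_dist()` produces the asymmetric downstream-distance matrix and this
$(h, a, b)$ decomposition from a single per-site quantity, the outlet
distance `up_dist`, plus the edge topology; an independent brute-force edge
walk in the test suite certifies the arithmetic. Pairs on different networks
(`netID`) are treated as infinitely far apart on the stream, so their
tail-up/tail-down covariance is exactly zero while the Euclidean component
still applies.

### Additive function values and tail-up weights

Junction weighting uses the *additive function value* (AFV). Given a
strictly positive additive attribute per edge (cumulative watershed area in
real data; the generator uses accumulated upstream channel length as a
proxy), the outlet edge has AFV 1 and each upstream edge at a junction
receives the downstream AFV times its attribute share, so segment weights sum
to one at every junction and AFVs never increase upstream. Confluences with
more than two upstream edges are allowed: the recursion does not assume
binary junctions. The tail-up weight of a flow-connected pair is

$$ w_{ij} = \sqrt{\mathrm{AFV}_{up} / \mathrm{AFV}_{down}}, $$

which equals the square root of the product of the segment weights passed
between the two sites; flow-unconnected pairs get weight exactly 0, never a
small number.

### Covariance functions

With $t = h/\alpha$ (flow-connected, used by tail-up and tail-down) and
$A = a/\alpha$, $B = b/\alpha$ (flow-unconnected tail-down):

| type | flow-connected | flow-unconnected |
|---|---|---|
| exponential | $e^{-t}$ | $e^{-(A+B)}$ |
| linear with sill | $(1-t)_+$ | $(1-A)_+$ |
| spherical | $1 - \tfrac32 t + \tfrac12 t^3$ on $[0,1]$ | $(1-A)^2(1 + \tfrac{A}{2} - \tfrac{3B}{2})$ for $A \le 1$ |

The Euclidean component offers exponential, gaussian
($e^{-(d/\alpha)^2}$) and spherical forms. Each closed form is the
normalised kernel-product integral
$\int_0^\infty g(x+a)\,g(x+b)\,dx \big/ \int_0^\infty g(x)^2\,dx$
of its moving-average kernel (exponential kernel, interval indicator, and
$(1-x/\alpha)_+$ respectively); `ma_cov_numeric()` evaluates that integral by
adaptive quadrature and the test suite verifies every closed form against it
to $10^{-6}$ over a grid of $(a, b, \alpha)$. With this kernel scaling no
remapping is needed: the kernel parameter *is* the reported range.

**Range convention.** $\alpha$ is the natural scale of each form — the
e-folding distance for exponential/gaussian and the exact support for
spherical/linear-with-sill. No effective-range factor (such as 3 for the
exponential) is applied anywhere; conventions differ across software, so
compare ranges accordingly.

## Estimation

`ssn_lm()` estimates $\boldsymbol\beta$ by generalized least squares through
the Cholesky factor of $\Sigma$ (never an explicit inverse) and the
covariance parameters by minimizing

$$
-2\ell(\theta) = \log|\Sigma| + \mathbf{r}'\Sigma^{-1}\mathbf{r} + n\log 2\pi,
\qquad \mathbf{r} = \mathbf{y} - \mathbf{X}\hat\beta(\theta),
$$

for ML, with REML (the default) adding $\log|X'\Sigma^{-1}X|$ and replacing
$n$ by $n - p$. Numerical choices, all overridable via `control`:

* **Optimizer.** Nelder–Mead on log-transformed partial sills, ranges and
  nugget; relative objective tolerance $10^{-6}$, iteration cap 2000, plus
  two short restarts from deterministically perturbed starts (fixed $\pm$
  shifts on the log scale, so fits are exactly reproducible). If a capped
  exploratory run wins it is continued with the full budget.
* **Profiling polish.** For a common factor $c$ on all variance components
  the objective is minimized analytically at
  $c = \mathbf{r}'\Sigma^{-1}\mathbf{r}/(n-p)$ (REML; $n$ for ML), so after
  the simplex the variance components are rescaled by that factor and
  re-polished. For models whose only parameter is the nugget this makes the
  fit exact: an all-`"none"` model reproduces OLS coefficients and the
  $n - p$ divisor variance to optimizer precision.
* **Initial values.** The OLS residual variance is split equally over the
  active variance components; each range starts at half the median nonzero
  pairwise distance of its metric (stream or Euclidean).
* **Cholesky jitter.** If the factorization fails, $10^{-10}\times$ the mean
  diagonal is added, escalating tenfold to at most $10^{-6}$, after which the
  objective reports $+\infty$ for that parameter vector.
* **AIC counting.** Under REML, AIC $= -2\ell + 2q$ with $q$ the number of
  estimated covariance parameters only; under ML the $p$ fixed effects are
  added. The convention is stated here because REML likelihoods of models
  with different fixed effects are not comparable.
* **Inference.** Coefficient tests and intervals use the asymptotic normal
  (z) reference without a degrees-of-freedom adjustment.

## Prediction

`predict()` / `augment()` perform universal kriging. For a prediction site
with covariates $x_p$ and cross-covariance vector $c_p$ (assembled from the
same components, but never including the nugget — cross blocks have no
measurement-error term),

$$
\hat y_p = x_p'\hat\beta + c_p'\Sigma^{-1}(\mathbf{y} - X\hat\beta), \qquad
\mathrm{se}^2 = \sigma^2_{tot} - c_p'\Sigma^{-1}c_p
  + m_p'(X'\Sigma^{-1}X)^{-1} m_p,
$$

with $m_p = x_p - X'\Sigma^{-1}c_p$ and $\sigma^2_{tot}$ the sum of all
partial sills *plus the nugget*: intervals are prediction intervals for a new
noisy observation, matching the `.lower`/`.upper` output convention, and the
fixed-effect uncertainty term is included. Consequences worth knowing:

* with a zero nugget, kriging interpolates: at an observed site the
  prediction equals the observation and the standard error is zero;
* with a positive nugget, a prediction co-located with an observation does
  *not* collapse onto it and keeps positive uncertainty;
* negative prediction variances can only arise from rounding; they are
  clamped at zero and warned about if beyond $10^{-10}$ relative noise.

The default interval level is 0.95 with the Gaussian quantile (1.959964).
`loocv()` re-predicts each site from the other $n-1$ with $\hat\theta$ held
fixed (a direct re-solve per site, not a refit), reporting bias, RMSPE and
empirical interval coverage.

## Simulation and the synthetic study

`ssn_simulate()` draws $\mathbf{y} = \mu + L\mathbf{z}$ with $L$ a square
root of $\Sigma$: the Cholesky factor when well conditioned, otherwise an
eigendecomposition square root with eigenvalues below numerical zero clamped,
so exactly singular cases (e.g. co-located sites without a nugget) yield
exactly identical values rather than Cholesky noise. Seeding follows the
`stats::simulate()` convention: the global RNG state is restored afterwards
and the seed is attached to the result.

The generator that stands in for real pre-processed data grows a random
dendritic tree from the outlet (new edges attach to a uniformly chosen edge
with probability 0.5, otherwise extend a headwater tip), draws log-normal
edge lengths (meanlog 0, sdlog 0.5), accumulates upstream length as the
additive attribute and embeds edges in the plane with jittered headings. The
embedding may self-intersect; only network distances and point-to-point
Euclidean distances enter the model, so this is accepted. Observed sites are
uniform over total channel length; prediction sites are systematic (every
`pred_spacing` units along each edge, plus one site at the outlet so the set
is never empty). Covariates are an elevation-like gradient that increases
with outlet distance plus independent Gaussian noise.

The default study conditions — 200 edges, 300 observed sites, exponential
tail-up ($\sigma^2 = 2$, $\alpha = 8$), spherical tail-down ($1$, $12$),
gaussian Euclidean ($1$, $3$), nugget $0.5$, and
$\beta = (10, -0.5, 0.5)$ — put all three ranges well inside the span of
observed pairwise distances (stream distances mostly below ~25 units,
Euclidean below ~15) with a signal-to-nugget ratio of 8:1, the regime in
which such a model is scientifically useful and its variance components are
identifiable. The acceptance suite redraws the response 50 times over one
fixed design and checks that the median of each estimated partial sill lands
within ±50% of truth and that Wald and leave-one-out intervals achieve
their nominal coverage; problem sizes were chosen so the whole study runs
in minutes on one CPU.

What the generator does **not** emulate: real watershed geometry and
delineated drainage areas, measurement networks that preferentially sample
mainstems, non-Gaussian responses, covariates with their own spatial
structure, and geodesic coordinates (all coordinates are planar/projected).
Passing tests therefore certify the estimator and its linear algebra under
the stated model, not robustness to the many ways field data depart from it.

## Data interfaces

The native format is a directory of CSV tables (`edges.csv`, `obs.csv`,
`preds-<name>.csv`, `meta.json`) with deterministic row and column order, so
writes are byte-stable and diffable; point site tables can also be exchanged
as GeoJSON FeatureCollections. A compatibility reader,
`read_ssn_folder()`, consumes the attribute tables of the classic `.ssn`
folder layout (`.dbf` or `.csv`) with the classic column names matched
case-insensitively (`rid`, `pid`, `ratio`, `afvArea`, `NEAR_X`/`NEAR_Y`,
`netID`) and the mapping logged. Because the classic layout keeps edge
topology in a binary database, this dialect requires an explicit
downstream-edge column (`todown`). Throughout the package, `ratio` is the
fractional position along an edge measured **from the downstream node**
(`ratio = 0` is the downstream end), consistent with
`up_dist(site) = up_dist(downstream node) + ratio * length`; sites placed
exactly at a junction stay on the edge stated in the input.

Edges with a nonpositive additive attribute are rejected outright rather
than given a guessed weight; distance matrices can be persisted and reloaded
as plain CSV via `write_distances()`/`read_distances()`.

## Known limitations

* Only Gaussian responses; no spatial GLMs, no nonspatial random effects and
  no Euclidean anisotropy.
* Covariance families are limited to those listed above (no Mariah, Cauchy
  or Matérn) and no standard errors are reported for covariance parameters.
* Dense linear algebra throughout: practical up to a few thousand observed
  sites.
* Prediction-by-prediction covariance (block kriging across a prediction
  set) is out of scope; prediction sites are treated one at a time.
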