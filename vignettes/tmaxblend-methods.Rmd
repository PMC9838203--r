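---
title: "Blending station temperature records with reanalysis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blending station temperature records with reanalysis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`tmaxblend` fits a single Bayesian hierarchical model that integrates
point-location daily maximum temperature (Tmax) records with a gridded
reanalysis field. This vignette is the package's account of the science: the
model and its assumptions, the tunable parameters and why their defaults are
what they are, the numerical choices inside the spline and sampling
machinery, what the synthetic-data generator does and does not emulate, and
the known limitations.

## The observation model

Station observations are noisy, occasionally *wrong* (digitisation slips,
instrument faults), and gappy. We therefore model each observation as a
two-component discrete mixture, conditional on a latent indicator
$z_{j,t}$:

$$
y_{s_j,t} \mid z_{j,t}=1 \sim N(\mu_{s_j,t}, \sigma_j^2), \qquad
y_{s_j,t} \mid z_{j,t}=0 \sim \mathrm{Unif}(U_{\min}, U_{\max}), \qquad
z_{j,t} \sim \mathrm{Bern}(\pi_j).
$$

The Uniform component represents an erroneous outlier about whose generating
mechanism we assume nothing beyond bounded support; $1-\pi_j$ is station
$j$'s outlier proportion. The bounds default to $\pm 80$ °C — far outside
anything physically plausible for 2 m air temperature — and detection is
insensitive to them as long as they comfortably exceed the data range.
Because the Uniform has bounded support, temperatures outside
$(U_{\min}, U_{\max})$ have zero density under *both* components; the
readers reject them at load rather than letting the likelihood silently
misbehave.

The mean links the station record to the reanalysis covariate $x_{s_j,t}$:

$$
\mu_{s_j,t} = \alpha_0 + f(s_j) + g(s_j)\, x_{s_j,t} + h_j(x_{s_j,t}).
$$

The first three terms are a *spatially varying linear* bias model — both the
intercept $\alpha_0 + f(s)$ and the slope $g(s)$ are smooth surfaces of
longitude and latitude, reflecting the empirical pattern that nearby
stations relate to the reanalysis similarly. The last term $h_j$ is a
station-specific, purely non-linear deviation in the covariate. The split
matters for extrapolation: a linear map is safe to interpolate spatially,
while unconstrained non-linear structure is not; $h_j$ is built so it can be
integrated out as a random effect when predicting at unseen locations.

### Priors and defaults

| parameter | prior | default reasoning |
|---|---|---|
| $\pi_j$ | Beta(5, 2) | mean 0.71, sd 0.16: most points are genuine, but substantial mass below 1 |
| $\alpha_0$ | N(0, 25) | the intercept when the covariate is 0 °C should be near 0 °C; sd 5 °C rules out absurd values only |
| $\sigma_j^2$ | InvGamma(2, $\beta_\sigma$) | conditionally conjugate; shape 2 fixes the scale family so $\beta_\sigma$ alone controls location |
| $\beta_\sigma$ | Exp(0.1) = Gamma(1, 0.1) | mean 10, variance 100 — a flat-ish hyperprior that still pools the station variances |
| all $\lambda$ | half-Cauchy(20) | heavy-tailed on the penalty scale: admits both near-linear and very wiggly smooths |

The Gamma$(c=1, d=0.1)$ form of the Exp(0.1) prior is what makes
$\beta_\sigma$ conjugate given the $\sigma_j^{-2}$. The half-Cauchy is
placed on $\lambda$ directly (not on a transformed scale); its scale 20 was
kept for every penalty parameter, null-space and wiggly alike.

## Spline construction

All three smooths use order-2 thin-plate regression splines: radial kernel
$r^2\log r$ in 2-D, $|r|^3$ in 1-D, polynomial null space of constants plus
linear terms. Construction is deterministic — no knot heuristics:

1. form the radial kernel on the distinct construction points;
2. eigen-decompose and keep the $k$ leading (largest-magnitude) eigenvectors;
3. absorb the side condition $T'\delta = 0$ (which restricts the radial part
   to the subspace where the thin-plate energy is non-negative) by a QR null
   space, giving the penalised ("wiggly") columns and the diagonal-derived
   penalty block;
4. rescale wiggly columns to unit root-mean-square over the construction
   points, adjusting the penalty inversely, so the half-Cauchy(20) prior
   means the same thing for every smooth.

The spatial bases take the stations themselves as construction points, with
total size $J-1$ — the most the $J$ locations can support once the intercept
is identified. The intercept surface $f$ absorbs a sum-to-zero constraint
(the constant column is dropped and the remaining columns centered over the
stations) so that $\alpha_0$ stays identifiable without post-hoc
adjustment.

The covariate smooth $h_j$ drops the polynomial null space entirely (8
penalised columns by default, shared basis across stations, one pooled
$\lambda_h$). Two further choices:

* **Knots.** The covariate has thousands of distinct values, so the kernel
  is built on a deterministic quantile-spaced subset (default 30 knots)
  before eigen-truncation. This caps the eigen problem at a trivial size
  while spanning the covariate range by construction.
* **Trend removal.** Truncated radial columns are not automatically
  orthogonal to $[1, x]$, so a raw "null-space-excluded" basis could still
  absorb linear signal and compete with $g(s)x$. `orthogonalize_basis()`
  residualises the columns against the polynomial functions over the
  training covariate values; afterwards any $h_j$ has exactly zero
  least-squares linear trend on the training design, and the same projection
  is applied at prediction time. The penalty is unchanged because polynomial
  components carry no roughness energy.

Numerical tolerances: symmetric-eigen truncation with sign-stable ordering;
penalty symmetry enforced by averaging; the capacity rule
`n_basis <= distinct points` is an error, as is an all-duplicate point set.
A consequence of the 2-D null space is that at least 4 stations are needed
(3 polynomial columns plus at least one free column for the $J-1$ slope
basis); leave-one-station-out cross-validation therefore needs 5.

## Change of support

Stations rarely coincide with grid-cell centers, and a single
"representative" cell is an arbitrary choice. Each station's covariate is a
fixed-in-time weighted average of its $k=10$ nearest non-missing cells
(Euclidean distance in decimal degrees, cells masked everywhere — e.g. sea
cells in a land-only product — excluded before the search). The weight
function is normalised inverse distance $w_i \propto 1/d_i^p$ with $p = 1$
by default and exposed as a configuration option, since only
"distance-weighted" is pinned down by the method; a station exactly on a
cell center takes that cell with weight 1, and ties at the $k$-th distance
break lexicographically by (lat index, lon index) for determinism.
Coordinates are treated as planar degrees: the intended domains are
country-scale, where the metric distortion is immaterial relative to a
10-cell average.

## Gibbs sampler

Every full conditional is conjugate except the penalty parameters:

* $z_{j,t}$: Bernoulli with odds
  $\pi_j N(y;\mu,\sigma_j^2) : (1-\pi_j)/(U_{\max}-U_{\min})$, computed on
  the log scale. The Gaussian kernel here is the standard
  $\exp\{-(y-\mu)^2/(2\sigma^2)\}$ with its normalising constant.
* $\pi_j$: Beta$(\alpha_\pi + \sum_t z, \beta_\pi + n_j - \sum_t z)$.
* $\sigma_j^2$: InvGamma with the count and residual sum restricted to
  $z=1$, non-missing points.
* $\alpha$, $\beta$, $\gamma_j$: canonical-form Gaussians
  $N_C(b, Q)$; draws solve the Cholesky-factorised precision system (mean
  $Q^{-1}b$, noise via the factor). Rows with $z=0$ are excluded, which is
  provably identical to deleting them from the dataset.
* $\beta_\sigma$: Gamma$(c + J\alpha_\sigma,\; d + \sum_j \sigma_j^{-2})$.
* $\lambda$'s: Gaussian random walk on $\log\lambda$ with the Jacobian in
  the acceptance ratio; the target is the coefficient block's Gaussian prior
  density including its $\tfrac12\log\det\Omega(\lambda)$ term, times the
  half-Cauchy prior.

The scan order is fixed (data augmentation first): $z \to \pi \to \sigma^2
\to \alpha \to \beta \to \gamma \to \beta_\sigma \to \lambda$. Any fixed
order yields a valid Gibbs sampler; fixing one makes runs reproducible.
Initialisation is data-driven and deterministic (zero smooths, overall-mean
intercept, per-station variances, $\pi = 0.95$, all $z = 1$, unit
penalties); when several chains run, the positive parameters are dispersed
by seed-controlled multiplicative U(0.5, 2) noise so that multivariate
$\hat R$ diagnostics are meaningful. Step sizes for the five Metropolis
updates adapt multiplicatively every 50 iterations during burn-in, steering
acceptance into [0.2, 0.5], and freeze afterwards to preserve detailed
balance.

Desk-scale defaults are 3 chains × 6000 iterations, 3000 burn-in, thinning
3 — the scale at which the package's own recovery and calibration checks
run, chosen so a 6-station, one-year fit takes well under a minute.
Reference-scale settings (3 × 100000 after 50000 burn-in) remain a
configuration choice.

Convergence is summarised by the Brooks–Gelman multivariate potential scale
reduction factor, reported on the usual square-root (shrink-factor) scale
with the $(m+1)/m$ chain factor. The monitored subset — $\alpha_0$, the
five $\lambda$'s, $\beta_\sigma$ and the mean of the $\sigma_j^2$ — spans
every level of the hierarchy while staying low-dimensional; it is
configurable. A near-singular within-chain covariance gets a $10^{-10}$
ridge and a warning.

## Outlier flagging and the injection experiment

Flagging uses the posterior mean of the indicator: a point is an outlier
when $p(z_{j,t}=1\mid y) < 0.5$. Stricter rules are a threshold choice; for
example, 0.1 implements "flag only if $1 - p(z=1\mid y) > 0.9$".

The sensitivity experiment corrupts randomly chosen clean points by adding
or subtracting (probability 0.5 each) a draw from
$\mathrm{Unif}(M-5, M+5)$, where $M = \max|y - \overline{y}|$ — large
enough to be an outlier, close enough to an extreme not to be trivial. $M$
is computed globally over stations by default (a per-station option
exists), and corrupted values are clipped into the mixture support, a clip
that is essentially never active with $\pm 80$ °C bounds. Experiments can
either refit the sampler per trial or rescore the contaminated data under
an existing posterior; both modes are provided because flagging stabilises
long before the smooth surfaces do. False positives are counted among
previously clean points only — neither injected nor already flagged by the
reference fit.

## Prediction

At a fitted station, the posterior predictive distribution simulates
$N(\mu, \sigma_j^2)$ per retained draw, for observed dates (checking) or
missing ones (imputation). At an unseen location only the linear part is
extrapolated: per posterior draw the surfaces $f$ and $g$ are evaluated at
the target, then a fresh $\gamma^* \sim N(0, (\lambda_h S_h)^{-1})$ builds a
new non-linear deviation and a fresh
$\sigma^{*2} \sim \mathrm{InvGamma}(\alpha_\sigma, \beta_\sigma)$ supplies
the noise — the station-specific terms are integrated out as random
effects. Drawing $\sigma^{*2}$ from its hierarchical prior (rather than any
station's full conditional) is the only coherent choice at a data-free
location. One fresh draw per posterior draw keeps the predictive sample the
same size as the posterior sample. Covariate values outside the training
range evaluate by the basis's natural extrapolation, with a warning.

Downscaling runs this prediction at every node of a regular grid (any
resolution; each node's covariate comes from the same change-of-support
rule). Aggregation to polygons approximates the integral of the predictive
random field: per draw, a region's value is the mean over the grid-cell
centers it contains (point-in-polygon on centers; a boundary cell joins the
first region in file order), so aggregation commutes with averaging by
construction, and region means converge as the grid is refined. The
uncertainty decomposition reports, per cell, the sd of the full predictive
draws, of the mean $\mu$ including $h^*$, and of the linear-only mean — the
third is computed by omitting $h^*$ from each draw's mean rather than by
refitting, which is the decomposition of the *fitted* model's uncertainty
rather than of a different model's.

## The synthetic-data generator

Every check in the package runs on data the generator produces, so its
defaults *are* the study conditions. The reanalysis emulator is a seasonal
sinusoid (mean 24 °C, amplitude 12 °C — an eastern-Mediterranean-like
annual Tmax range of roughly 5–40 °C) plus a smooth spatial gradient, a
shared AR(1) daily anomaly ($\phi = 0.8$, sd 2.5 °C) and small iid cell
noise, on a 0.1° grid. These values were chosen to reproduce the regime
that governs the injection experiment's difficulty: with station noise
around 2 °C, the maximum absolute deviation of a multi-year series from its
mean lands near 20–29 °C, so injected offsets of at least $M-5$ are many
noise standard deviations — the same regime as real Mediterranean Tmax
records, where $M$ is about 25 °C.

Stations are placed uniformly in the domain interior; observations follow
the model's own generative process — identity bias surfaces by default
($f = 0$, $g = 1$, $\alpha_0 = 1.5$ °C), a modest sinusoidal per-station
non-linearity (amplitude ≤ 0.5 °C), per-station noise sds around 2 °C,
$\pi_j = 0.99$, Uniform contamination drawn from the observed range ± 30 °C
(narrower than the mixture's ± 80 °C support, so some synthetic outliers
are genuinely hard), and block missingness (runs of 5–30 days, ~5% of
values). Every generated quantity is recorded so recovery is assessable
without external data.

What the generator does **not** emulate: orography and coastal effects
(real bias fields vary with elevation and land–sea contrast), seasonally
varying noise, reanalysis error structure that correlates with the state,
and non-sinusoidal seasonality. Passing the package's recovery and
calibration checks therefore demonstrates the *inference machinery* is
correct under the model's own assumptions — not that the model is adequate
for any particular real network, which is what the posterior predictive
checks and leave-one-station-out tools are for on real data.

## Problem sizes and test design

The suite runs entirely at desk scale, sizes chosen as the smallest that
make each check sharp: miniature 4-station designs for the
full-conditional oracles (moment agreement within Monte-Carlo error at
$10^4$–$10^5$ draws), a 6 × 500-day dataset for ten scaled injection
trials of 50 points each, one 6 × 2000-day full trial with 500 injections,
ten 6 × 300-day replicates for parameter recovery, and a 3-chain reference
fit on 6 × 300 days for calibration and convergence. The injection-trial
refits use short single chains (1200 iterations) because the indicator
posteriors stabilise within a few hundred scans — verified against the
full-length fit.

## Decisions where the design was genuinely open

* Thin-plate order: order 2 (the conventional choice; nothing in the
  method's description constrains it).
* Half-Cauchy placed on $\lambda$ itself; same scale for null-space and
  wiggly penalties.
* The hyperprior constants $(c, d)$ of the $\beta_\sigma$ update are the
  Gamma(1, 0.1) representation of the Exp(0.1) prior.
* Inverse-distance power $p = 1$ (only "distance-weighted" is specified);
  exposed as config.
* Cross-validation tail summaries default to the 5% / 95% quantiles of the
  per-day predictive means, with the quantile pair configurable (2.5/97.5
  also in use for interval construction).
* Reanalysis is read from long-format CSV; the container in this build has
  no NetCDF R library, and the CSV schema (`time, lon, lat, value`) is
  lossless for regular grids.

## Known limitations

Elevation and other local covariates are not in the mean (the spatial
surfaces must absorb orographic bias); there is no temporal autocorrelation
in the residuals, so multi-day predictive trajectories are too rough even
when daily marginals are calibrated; the outlier component cannot localise
errors smaller than a few noise sds; and the spatial bases, with capacity
$J-1$, cannot represent bias structure finer than the station network
resolves — the uncertainty surfaces, not the point predictions, are the
honest summary far from stations.
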