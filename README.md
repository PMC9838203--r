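# tmaxblend

Bayesian integration of daily maximum temperature station records with
gridded reanalysis output.

Weather-station series are the closest thing to ground truth for daily Tmax,
but they are spatially sparse and plagued by missing stretches and erroneous
outliers (manual records, digitisation slips). Reanalysis products cover the
whole domain on a regular grid but are biased model output. `tmaxblend` fits
one hierarchical model that uses each source to fix the other's weakness: it
flags non-physical outliers, learns the station–reanalysis bias, imputes
missing values, and predicts Tmax — with full uncertainty — at any location,
grid resolution or polygon region. The intended users are climate and
environmental-epidemiology researchers who need temperature exposure
estimates at spatial configurations no station network matches.

## The model

For station *j* at location *s_j* on day *t*, with `x` the reanalysis
covariate (a 10-nearest-cell inverse-distance weighted average at the
station's coordinates):

```
y_{s_j,t} | z_{j,t} = 1  ~  N(mu_{s_j,t}, sigma_j^2)
y_{s_j,t} | z_{j,t} = 0  ~  Uniform(-80, 80)            # erroneous outlier
z_{j,t}                  ~  Bernoulli(pi_j),   pi_j ~ Beta(5, 2)

mu_{s_j,t} = alpha_0 + f(s_j) + g(s_j) x_{s_j,t} + h_j(x_{s_j,t})
```

`f` and `g` are thin-plate regression spline surfaces of longitude/latitude:
a spatially varying *linear* bias model. `h_j` is a station-specific
penalised spline of the covariate with its polynomial null space removed — a
purely non-linear "random-effect" deviation. Station variances are pooled
through `sigma_j^2 ~ InvGamma(2, beta_sigma)`, `beta_sigma ~ Exp(0.1)`, and
every penalty parameter gets a half-Cauchy(20) prior. All unknowns are
sampled by a Gibbs scan (conditional conjugacy throughout) with random-walk
Metropolis steps on the log penalty parameters, tuned to a 0.2–0.5
acceptance rate during burn-in.

A data point is declared an outlier when its posterior non-outlier
probability `p(z = 1 | y)` falls below 0.5. Prediction at unseen locations
extrapolates only the linear part; `h` and `sigma^2` are integrated out by
drawing fresh `gamma* ~ N(0, (lambda_h S_h)^{-1})` and
`sigma*^2 ~ InvGamma(2, beta_sigma)` per posterior draw.

## Worked example

```r
library(tmaxblend)

field <- simulate_reanalysis(n_days = 300, seed = 11)           # gridded covariate
sim   <- simulate_stations(field, J = 6, truth = truth_spec(), seed = 11)

cfg <- blend_config(chains = 3, iterations = 6000, burnin = 3000, thin = 3, seed = 5)
fit <- tmax_blend(sim$stations, field, cfg)
summary(fit)
```

```
Posterior summary
  alpha_0: 1.340   beta_sigma: 9.063
  per-station sigma_j: 2.36 2.36 2.18 2.13 2.04 1.80
  per-station outlier proportion (1 - pi_j): 0.011 0.011 0.012 0.020 0.016 0.015
  penalty acceptance rates: f_null=0.38 f_wiggly=0.33 g_null=0.32 g_wiggly=0.35 h=0.34
  deviance 7645.7 (sd 7.9); MPSRF 1.051; flagged outliers 10
```

The generator's truth here was `alpha_0 = 1.5`, `g = 1`, `sigma_j ~ 2` and
1% contamination: the intercept's posterior mean is 1.34 (its 95% interval
covers 1.5), the recovered noise sds sit around 2 °C, the estimated outlier
proportions around 0.01, and all ten flagged points are true contaminated
points. MPSRF 1.051 indicates the three chains agree.

```r
report <- flag_outliers(fit)                    # station, date, y, p_z1, flagged
pr     <- ppd_station(fit, "S01", seed = 1)     # imputation / checking intervals
head(data.frame(date = pr$dates, mean = pr$mean, lower = pr$lower, upper = pr$upper), 4)
```

```
        date  mean lower upper
1 2010-01-01  9.90  4.90 14.74
2 2010-01-02 10.63  6.05 15.36
3 2010-01-03  8.95  4.20 13.66
4 2010-01-04  7.69  3.16 12.21
```

Downscaling and uncertainty decomposition:

```r
grid <- downscale(fit, field, resolution = 0.05, dates = field$times[100], seed = 2)
ud   <- uncertainty_decomposition(grid)
colMeans(ud[, c("sd_ppd", "sd_mu", "sd_mu_linear")])
#  sd_ppd   sd_mu   sd_mu_linear
#    3.01    0.19           0.13
```

The full predictive sd (3.0 °C) is dominated by the integrated-out
station-level variance; the mean surface itself is pinned down to ~0.2 °C.
`aggregate_regions()` averages the draw-level grid over GeoJSON polygons,
and `loso_cv()` runs the leave-one-station-out check. A thin command-line
front end (`inst/scripts/tmaxblend.R`) exposes `simulate`, `fit`,
`flag-outliers`, `inject`, `predict`, `downscale`, `aggregate`, `cv` and
`diagnose` subcommands over the same functions and writes a reproducibility
manifest per run.

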