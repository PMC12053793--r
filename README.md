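# metarange

Metapopulation colonisation–extinction dynamics at species range limits.

## The problem

Why does a species' geographic range stop where it does, even when
suitable habitat continues beyond the boundary? One long-standing
hypothesis treats the range edge as a metapopulation phenomenon: each
habitat patch flickers between occupied and vacant through recurrent
local extinction and recolonisation, and the range limit falls where
the balance of those two rates can no longer sustain occupancy. Under
the Levins patch-occupancy model, with per-interval colonisation
probability *c* (vacant, suitable patches becoming occupied) and
extinction probability *e* (occupied patches emptying), the
steady-state fraction of occupied patches is

&nbsp;&nbsp;&nbsp;&nbsp; *n*\* = *c* / (*c* + *e*),

so geographic gradients in *c* and *e* alone predict a geographic
gradient in occupancy. The decisive test is whether *n*\*(*d*),
predicted purely from observed colonisation and extinction events,
reproduces the observed occupancy decline *n*_obs(*d*) toward the
limit (*d* = along-coast distance to the range limit, 0 at the limit).

`metarange` implements that test end to end for two-snapshot
plot-occupancy resurveys (the motivating system is a short-lived
coastal dune plant surveyed twice, three years apart, along ~938 km of
coastline):

* **survey handling** — CSV I/O for plot surveys, pairing of the two
  snapshots, exclusion of non-dune plots, classification of
  colonisation candidates (vacant then, suitable now) and extinction
  candidates (occupied then, regardless of later suitability), and the
  local-abundance covariate (mean count over all other plots within
  500 m);
* **inference** — binomial and Gaussian GLMs fitted by IRLS written in
  the package (with likelihood traces, separation and collinearity
  diagnostics), type II analysis-of-deviance tests, AICc, and a
  binomial GLMM with a spatially correlated random effect
  (cov = σ² exp(−h/ρ)) fitted by Laplace approximation;
* **equilibrium** — the *n*\*(*d*) curve from the fitted *c* and *e*
  models, a plot-level bootstrap confidence envelope, and the
  containment comparison against the Wald band of the
  observed-occupancy model;
* **simulation** — a spatially explicit stochastic patch-occupancy
  model (SPOM) that generates two-survey datasets with known ground
  truth: habitat gradients declining toward the limit, cause-specific
  habitat turnover (succession, wind, driftwood, water), colonisation
  increasing with suitable area and local abundance, extinction
  decreasing with initial abundance and area.

## Worked example

Simulate a 2000-plot two-survey dataset from the built-in SPOM and run
the full analysis (500 bootstrap replicates):

```r
library(metarange)
cfg <- sim_config(n_plots = 2000L, seed = 42L)
sim <- simulate_survey_pair(cfg)
fit <- metarange(sim$t1, sim$t2, B = 500, seed = 42L)
print(fit)
```

```
Metapopulation range-limit analysis
Paired dune plots: 2000 (t1-only 0, t2-only 0, non-dune 0 dropped)
Colonisation: 126/639 suitable-but-vacant plots (c = 0.197)
Extinction:   106/366 occupied plots (e = 0.290)
Occupancy (all plots):      t1 0.183, t2 0.193
Occupancy (suitable plots): t1 0.383, t2 0.398
Colonisation ~ distance: b = 0.0006628 log-odds/km (p = 0.069, n = 639)
Extinction   ~ distance: b = -0.0007571 log-odds/km (p = 0.0773, n = 366)
Observed occupancy (t2):   0.262 at the limit -> 0.545 at the core
Equilibrium prediction n*: 0.290 at the limit -> 0.524 at the core
Containment of n* in the observed band: 1.000
```

Reading the output: 19.7% of the suitable-but-vacant plots were
colonised over the interval and 29.0% of the occupied plots went
extinct; colonisation rises away from the limit (positive log-odds
slope per km toward the range core) while extinction falls, and the
equilibrium prediction built only from those two event models
(0.290 at the limit rising to 0.524 at the core) tracks the
independently fitted observed-occupancy curve (0.262 → 0.545), lying
inside its 95% band at every grid distance.

The fitted object carries the usual surface:

```r
coef(fit)                                  # c and e model coefficients
predict(fit, dist_km = c(0, 469, 938))     # c, e, n* at chosen distances
summary(fit)                               # covariate models, trends, causes
plot(fit)                                  # curves, reversed distance axis
write_report(fit, "out/")                  # report.json + tidy CSVs
```

`summary(fit)` additionally reports the covariate models (colonisation
~ suitable area × log10 local abundance; extinction ~ log10 initial
abundance × log10 local abundance + area) with type II tests and the
AICc comparison against their spatially correlated versions, the
Gaussian covariate trends over distance, and the split of extinctions
into demographic (habitat still suitable) versus environmental, with
cause proportions.

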