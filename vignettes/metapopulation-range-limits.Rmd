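---
title: "Methods: metapopulation dynamics at a range limit"
author: "metarange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metapopulation dynamics at a range limit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metarange)
```

## The model and its assumptions

`metarange` asks whether a species' range limit is consistent with
metapopulation dynamics: patches (here 5 × 5 m survey plots) are
treated as a two-state Markov chain, vacant or occupied, with
per-interval colonisation probability $c$ for vacant suitable patches
and extinction probability $e$ for occupied patches. The stationary
occupied fraction of that chain is the Levins equilibrium

$$n^* = \frac{c}{c + e},$$

which holds for the one-generation chain and equally for any
compounding of generations into a census interval (the $k$-step chain
has the same stationary distribution). The analysis estimates $c(d)$
and $e(d)$ as functions of distance $d$ to the range limit (km, 0 at
the limit, increasing toward the range core) from observed transitions
between two survey snapshots, predicts $n^*(d)$, and compares it to
the occupancy gradient $n_{obs}(d)$ fitted independently to
second-survey occupancy of suitable plots.

Assumptions worth keeping in view:

* **Event definitions.** A *colonisation candidate* is a plot
  unoccupied at the first survey and containing suitable habitat at
  the second; suitability at the first survey is not required. An
  *extinction candidate* is any plot occupied at the first survey,
  regardless of later suitability. Candidacy is decided by
  first-survey occupancy alone, so no plot is both, and every paired
  dune plot is a colonisation candidate, an extinction candidate, or
  vacant-and-unsuitable.
* **Quasi-stationarity.** $n^*$ describes a steady state; the
  comparison against $n_{obs}$ is meaningful only if the system is
  near equilibrium over the census interval.
* **Rates are pool averages.** The distance-only models estimate the
  mean rate among candidates at each distance. Where plot quality
  (habitat area, neighbourhood abundance) varies within a distance
  band, the vacant pool is a non-random sample of plots (the best
  plots are already occupied), which flattens $n^*(d)$ slightly
  relative to the occupancy of an average plot; see "Known
  limitations".

## Data model and derived covariates

Surveys are CSV tables with one row per plot: `plot_id`, `dist_km`,
projected planar coordinates `x_m`, `y_m`, `suitable_area_m2` (0–25;
"suitable" means the area is positive, with no minimum-area
threshold), `abundance`, optional semicolon-separated `causes` of
unsuitability (`succession`, `wind`, `driftwood`, `water`; several may
apply to one plot), and optional `is_dune`. Plots lacking coastal dune
habitat in either year are excluded at pairing.

The local-abundance covariate $L$ of a focal plot is the mean count
over all *other* plots within 500 m (planar Euclidean distance;
neighbourhoods are local, so projection error and the along-coast vs
straight-line distinction are negligible at this radius). Two
decisions the data model does not make for us:

* vacant neighbours count as zeros in the mean — $L$ is the average
  over all neighbouring plots, occupied or not, which is the natural
  reading of a propagule-pressure proxy;
* plots with no neighbour within the radius get a missing $L$ and drop
  from covariate models by complete-case filtering (this is why
  covariate-model $n$ is slightly smaller than the candidate pool).

Abundance covariates enter models as $\log_{10}(x + 1)$, defined at
zero.

## Inference machinery

Binomial (logit) and Gaussian (identity) GLMs are fitted by IRLS
written in the package, with step-halving so the log-likelihood trace
is non-decreasing; convergence is a relative log-likelihood change
below $10^{-10}$ (at most 100 iterations). Standard errors come from
the observed information. Coefficients beyond ±30 on the logit scale,
or fitted probabilities collapsing to 0/1, are flagged as separation;
rank-deficient designs are an error naming the collinear columns. The
test suite cross-checks coefficients, standard errors, likelihoods and
AIC against `stats::glm` and the type II tests against `car::Anova`.

Term tests are type II: each term is tested against the model
containing all other terms that respect marginality, so a main effect
is never tested in the presence of its own interaction (in
`y ~ A + B + A:B`, `A` is tested as `A + B` versus `B`).
Likelihood-ratio statistics are used for plain GLMs; Wald statistics
for spatial fits, where refitting per term would repeat the outer
covariance optimisation.

The spatial extension adds one Gaussian random effect per plot with
exponential-decay covariance $\sigma^2 e^{-h/\rho}$ ($h$ in metres).
The marginal likelihood is approximated by Laplace: an inner Newton
optimisation of the joint log-density over (fixed effects, random
effects), block-eliminated so each step costs one dense Cholesky of an
$n \times n$ matrix, inside a Nelder–Mead search (with one restart)
over $(\log\sigma^2, \log\rho)$ bounded to $\log\sigma^2 \in [-12, 6]$
and $\rho \in [1, 10^7]$ m. A relative nugget of $10^{-6}$ keeps the
correlation matrix positive definite when $\rho$ is large. AICc counts
$\sigma^2$ and $\rho$ as two extra parameters (no dispersion parameter
for binomial). $\hat\sigma^2 < 10^{-4}$ is reported as a boundary fit
that reduces to the plain GLM. The dense solver is capped at
$n = 4000$ rows; sparse approximations for larger problems are out of
scope. Validation is by three routes: agreement with adaptive
Gauss–Hermite quadrature of the exact integral at $n = 4$ (within
0.05 log-likelihood units), collapse to the plain GLM when
$\sigma^2 = 0$, and agreement with `glmmTMB`'s Laplace objective on a
common model.

AICc uses the small-sample form
$\mathrm{AIC} + 2k(k+1)/(n-k-1)$, undefined (an error) for
$n \le k + 1$; inside the pipeline a fit too small for AICc carries
`NA` rather than failing.

## Equilibrium curve, bootstrap envelope, comparison

The distance-only $c$ and $e$ models that feed the equilibrium
prediction are plain GLMs: the spatial random effect is offered for
the covariate models, where residual autocorrelation is the concern,
and a population-level prediction from a spatial fit would use the
zero-mean random effect anyway. $n^*(d)$ is evaluated on 200 evenly
spaced distances from 0 to the largest observed distance.

The confidence envelope resamples the two candidate pools
independently with replacement at the plot level (the pools are
disjoint by construction, so this equals a joint plot-level
bootstrap), refits both models, recomputes $n^*(d)$, and takes
pointwise percentile bands (2.5/97.5% at the default level) over
replicates — percentile rather than basic or BCa, which is the
standard choice for curve envelopes and is validated directly by a
coverage simulation. Replicates whose refits fail (separation or
non-convergence) are dropped and counted; more than 5% failures is an
error rather than a silent degradation. The envelope is deterministic
given the seed.

The comparison lays $n^*(d)$ over the 95% band of the
observed-occupancy GLM (Wald on the linear predictor, transformed to
the probability scale, so bands respect [0, 1]) and reports the
*containment fraction*: the share of grid points where $n^*$ lies
inside the band. The band is pointwise, not simultaneous; a
simultaneous band would be wider and containment correspondingly
easier, so the pointwise choice is the conservative reading.

## What the simulator emulates

The synthetic-data generator is a spatially explicit stochastic
patch-occupancy model on a 938 km, 3500-plot coastline surveyed twice
with two generations between snapshots (a three-year interval for a
plant with a one-to-two-year generation time). Its defaults were
calibrated once so that simulated surveys land in the empirically
reported regime for this kind of system — roughly a fifth of suitable
vacant plots colonised and three tenths of occupied plots going
extinct per interval, about half the plots containing suitable
habitat, overall occupancy near 0.2, and occupancy of suitable plots
falling from roughly 0.5 at the core to 0.3 at the limit — and were
not adjusted afterwards.

Per generation, in a fixed order: (1) habitat transitions — each
suitable plot loses its habitat to cause $k$ with probability
$\mathrm{invlogit}(a_k + b_k d)$ (succession commoner toward the
limit, wind disturbance toward the core, driftwood and water rare and
flat; simultaneous hits give multi-cause records), and unsuitable
plots recover with probability 0.05, redrawing area from the habitat
gradient; (2) extinction trials,
$\mathrm{invlogit}(\alpha_e - 0.81 \log_{10}(N+1) - 0.047 A)$, forced
where habitat was just lost; (3) colonisation trials for vacant
suitable plots, $\mathrm{invlogit}(\alpha_c + 0.093 A + 0.73
\log_{10}(L+1))$, with $L$ computed from pre-step abundances; (4)
abundance redraw for occupied plots from a rounded lognormal whose
median declines toward the limit. The covariate coefficients are the
fitted magnitudes reported for the motivating system, so simulated
data exercise the models at realistic effect sizes. The within-
generation event order is a convention; nothing in a two-snapshot
survey identifies it. There is no seed bank and no within-generation
rescue.

Distance never enters the event logits directly: gradients in
colonisation and extinction *emerge* from the habitat-area gradient,
the abundance gradient and the local-abundance feedback, mirroring the
mediation structure in which a distance effect on colonisation
disappears once patch and population covariates are included.

Ground truth: the simulator records the exact per-plot event
probabilities used in each inter-survey generation. For
one-generation intervals these are the interval-level candidate-pool
probabilities, and `true_event_curves()` summarises them into the
generator's true $c(d)$, $e(d)$ and $n^*(d)$ by fitting logistic
curves in distance to the recorded probabilities (fractional-response
IRLS) — i.e. the estimand of the distance-only models. For
multi-generation intervals the interval probability of a plot depends
on the realised path of the whole landscape, so exact truth curves are
not defined and the function refuses rather than approximates.

What passing simulator-based tests do **not** show about real data:
the generator has no observation error, no GPS relocation error, no
plot-size misclassification, stationary parameters over time, and
covariate relationships exactly of the fitted form, so recovery and
coverage results are statements about the estimator under a correctly
specified model, not about field robustness.

## Validation design and problem sizes

The validation suite anchors exact arithmetic on the published event
counts of the motivating survey (232 colonisations among 1223
candidates, 195 extinctions among 638; 135 of 189 complete extinction
records still suitable), verifies the Levins identity against the
fixed point of the occupancy recursion to $10^{-12}$ over a
probability grid, and then tests properties on simulated data. The
problem sizes are chosen to keep the full suite within a desk-scale
run (about six minutes): a 300-plot, 2000-generation run for the
long-run equilibrium check (batch-means Monte-Carlo error); 100
datasets of 3000 plots for covariate-slope recovery within 2 standard
errors (one-generation intervals with habitat turnover disabled, so
the fitted covariate models nest the generator); 50 replicates of
$n = 400$ for the AICc preference of the spatial model under strong
correlation ($\sigma^2 = 1$, $\rho = 5$ km); 100 seeds of 3000 plots
for sign recovery of the toward-core colonisation slope under a
steepened habitat gradient; 200 datasets of 1200 plots with a
200-replicate bootstrap for envelope coverage at the mid-grid
distance; and 50 replicates of 3000 plots for the whole-curve
containment comparison.

## Known limitations

* **Whole-curve containment is a demanding summary.** $n^*(d)$ and
  $n_{obs}(d)$ are two estimates of comparable sampling variance
  (candidate pools of ~1000 and ~700 against an occupancy sample of
  ~1800). Even though both are computed from the same survey outcomes
  and are positively correlated, requiring the $n^*$ point curve to
  sit inside the 95% pointwise band of $n_{obs}$ at ≥95% of 200 grid
  points fails in roughly half of matched 3000-plot replicate
  simulations — partly pure sampling noise, partly a small systematic
  flattening of $n^*$ (about −0.02 at the core end) from
  candidate-pool conditioning: vacant plots at the core are
  poorer-than-average plots, so the fitted $c(d)$ under-states the
  colonisation rate of an average plot where occupancy is high.
  A single dataset in which containment is 1.0 is therefore genuine
  but favourable; across replicates the median containment is high
  while the ≥0.95 tail probability is near one half. The package
  reports the containment fraction honestly and leaves the
  interpretation to the analyst.
* The equilibrium comparison inherits the quasi-stationarity
  assumption; a system far from equilibrium (e.g. after a mass
  disturbance) can satisfy the event models yet show occupancy far
  from $n^*$.
* The spatial GLMM is dense ($O(n^3)$ per covariance evaluation) and
  capped at 4000 rows.
* Cause proportions condition on the complete-cause subset; if
  missingness of cause records were informative, the
  demographic/environmental split would be biased accordingly.
* Distance units are kilometres throughout; coefficients are log-odds
  per km and are not directly comparable to analyses that measure
  distance in metres.
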