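---
title: "Density surface modelling of storm-petrel strip-transect surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density surface modelling of storm-petrel strip-transect surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

European storm-petrels are among the smallest seabirds; they breed in
burrows on offshore islands, return to colonies only at night, and forage
far out at sea. Colony censuses are laborious and infrequent, so at-sea
abundance estimated from aerial surveys is an attractive complement. The
survey design this package supports is the standard strip transect: an
aircraft flies straight parallel lines and observers record every
storm-petrel group within 200 m of the trackline on either side, together
with the group size. Two altitudes are typically mixed — broad-scale
coverage flown high, and fine-scale coastal blocks flown low — and the
detectability of a bird the size of a swallow plausibly depends on both
altitude and sea state. `stormdsm` implements the full analysis chain from
raw tracklines and sightings to a habitat model and a bootstrapped total
abundance, and ships a synthetic survey generator with known ground truth
so that every stage can be verified end to end.

## Pipeline overview

1. **Gridding** (`build_grid`, `effort_per_cell`, `aggregate_counts`).
   A planar 4 x 4 km analysis grid covers the study area. Each on-effort
   transect segment is buffered by the strip half-width (0.2 km, flat end
   caps), clipped to each cell, and the clipped areas accumulate into the
   per-(cell x pass) effort area `a_i`; off-effort segments contribute
   nothing, and overlapping on-effort intervals along one trackline are
   unioned first. Counts are sums of group sizes per (cell x pass). One
   pass is one transect flown on one day: repeated passes stay separate
   rows so that the offset keeps its meaning.
2. **Covariates** (`build_covariates`, `colony_proximity_score`,
   `auto_boxcox`). Distance to the coastline, distance to the 500 m
   isobath (shelf-edge proxy), depth (clamped non-positive), Horn-method
   gradient magnitudes of the dynamic fields, inverse-distance-weighted
   appending, 8-day temporal matching, and a colony proximity score
   `sum_c pairs_c / d_ic^2` where `d_ic` is the shortest over-sea path
   from the cell centre to colony `c`. Skewed covariates can be Box-Cox
   transformed; the fitted lambda is stored and re-applied (never
   re-estimated) on prediction tables.
3. **The count model** (`dsm_gam`). A negative-binomial log-link additive
   model with `log(a_i)` as offset, penalized thin-plate regression spline
   smooths with a second penalty on each penalty null space (shrinkage:
   a term can leave the model entirely), a bivariate spatial smooth,
   centred factor-smooth interactions (sea state by altitude), a
   parametric altitude term, and ridge random effects.
4. **Selection** (`concurvity_screen`, `select_by_aic`,
   `altitude_model`, `distribution_model`). Worst-case concurvity above
   0.8 groups covariates; every subset of a group is refitted and the
   lowest-AIC model kept regardless of which correlated terms survive. In
   the distribution model a non-significant year random effect (p >= 0.05)
   is dropped and the model refitted.
5. **Inference** (`build_prediction_grid`, `estimate_total`,
   `bootstrap_ci`, `validate_split`). Whole-area prediction at
   standardized conditions — median surveyed Julian day (195 for a
   May-September season), Beaufort 0, low altitude, full cell area
   (16 km^2) as offset — summed and rounded once; per-cell CV from the
   link-scale standard error; a winsorised percentile bootstrap CI; and an
   80/20 x 100 cross-validation harness.

## The model

For counts `y_i` (individuals in cell-pass `i`, effort area `a_i`):

```
y_i ~ NB(mu_i, theta),  Var(y_i) = mu_i + mu_i^2 / theta
log mu_i = log a_i + beta_0 + f_xy(x_i, y_i) + sum_k f_k(z_ik)
           + f_ss,alt(i)(ss_i) + delta * 1[altitude_i = high] + b_year(i)
```

Each `f_k` is a thin-plate regression spline, maximum five knots. In the
implementation every smooth block is rotated to the eigenbasis of its
wiggliness penalty, so both the wiggliness penalty and the null-space
shrinkage penalty are diagonal; the full penalty is then diagonal, which
makes the REML determinant terms exact and cheap. The centring constraint
(each smooth sums to zero over the data) is absorbed by column centring,
which is why the altitude factor must also appear as a parametric term:
the factor smooths carry no level means.

Smoothing parameters minimise the Laplace-approximate REML score with the
likelihood divided by `gamma = 1.2`, which behaves like shrinking the
sample size and yields smoother fits; updates are extended Fellner-Schall
steps, safeguarded by step-halving on the REML score itself (the raw
update can oscillate with period two on terms that want infinite
smoothing). `theta` is estimated by alternating profile maximisation of
the exact negative-binomial likelihood with the REML fit, which converges
in a handful of alternations. The Poisson limit is available either as
`family = "poisson"` or a very large fixed `theta`.

Reported per-term p-values are approximate Wald tests: z-tests on
parametric coefficients, and for a smooth block a chi-square statistic on
a rank-r pseudo-inverse of the coefficient covariance with r tied to the
rounded effective degrees of freedom. They are adequate for screening and
for the altitude detectability test, and are labelled approximate.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `cell_km` | 4 | km | grid resolution matching the coarsest covariate layers |
| `strip_half_width_km` | 0.2 | km | 200 m strip either side of the trackline |
| `k` (univariate smooths) | 5 | knots | simplest effective response curves |
| `k` (spatial smooth) | 30 | knots | enough flexibility for residual spatial trend |
| `gamma` | 1.2 | — | extra penalty per effective df; favours smooth fits |
| concurvity threshold | 0.8 | — | pairing level for the correlated-group screen |
| `winsor_percentile` | 97.5 | % | cap on extreme counts before bootstrapping |
| `B` | 1000 | replicates | percentile bootstrap size |
| prediction day | 195 | Julian day | median of a May-September survey season |

## The synthetic world

`world_config` + `gen_environment` simulate a coastal study area:
stationary Gaussian random fields (squared-exponential covariance,
circulant-embedding FFT synthesis) for SST, salinity, log-chlorophyll and
a bathymetry perturbation; a rasterised elliptical landmass whose
coastline shapes a smooth offshore-deepening depth profile (8 m/km by
default, putting the 500 m shelf proxy about 60 km out); and per-year
anomalies of the dynamic fields. `gen_truth` builds the expected density
surface from closed-form partial effects on the log scale and records the
true total. `gen_transects` lays out straight parallel lines — broad/high
over everything, fine/low (2-nautical-mile spacing) in a coastal block —
with per-leg Beaufort states drawn from a mixture putting at least 95% of
effort at sea state 3 or below, and per-transect years and Julian days.
`gen_sightings` places latent groups per cell-strip intersection with
negative-binomial counts (`theta = 2` in the standard conditions), group
sizes 80.5% singletons / 10.7% pairs / geometric tail, and thins each
group with probability `exp(delta_alt 1[high] + beta_ss(alt) ss)`,
complete detection at sea state 0 and low altitude.

Default calibration keeps the mean sea density near 0.3-0.5 birds per
km^2 — the scale implied by an abundance of roughly 150,000 birds over a
450,000 km^2 study area — and the standard simulation studies use worlds
of 24 x 24 to 40 x 40 cells with a few hundred to a few thousand surveyed
cell-passes, sizes chosen so the whole verification suite runs on a
laptop. What the generator deliberately omits: curved tracklines, spatial
clustering of groups beyond the negative binomial, availability bias
(birds resting on the water with hidden rumps), observer heterogeneity,
and real geography. Passing recovery tests therefore demonstrate that the
estimator chain is consistent under its own assumptions, not that those
assumptions hold for real surveys.

## Numerical choices

- PIRLS: Fisher weights `mu/(1 + mu/theta)`, relative penalized-deviance
  tolerance 1e-8, maximum 200 iterations, step-halving; divergence of the
  linear predictor beyond `exp(50)` raises a separation error.
- Smoothing parameters live in `[1e-9, 1e11]` with Fellner-Schall steps
  capped at `e^5` per iteration.
- Knots: quantiles of unique values (univariate); deterministic k-means
  started from evenly-indexed ordered locations (bivariate), so fits are
  reproducible without touching the RNG.
- Penalty eigenvalues below `1e-8` of the largest are reassigned to the
  shrinkage penalty, keeping the total penalty full-rank on every smooth
  coordinate.
- Half-open cell convention `[x, x+4)`: a point on an interior boundary
  belongs to the +x/+y cell, everywhere.
- Ties in AIC selection (difference < 1e-6) go to fewer effective df.
- Interpolated (type-7) quantiles throughout (winsorisation cap and
  bootstrap percentiles).
- All generators are pure functions of (arguments, seed); the caller's
  RNG state is saved and restored.

## Design decisions on genuinely open points

- **Smoothing criterion.** REML, implemented via extended Fellner-Schall
  updates; chosen for stability on shrinkage terms. No GCV mode is
  provided — one well-tested selector seemed better than two.
- **Bootstrap resampling unit.** Surveyed (cell x pass) rows, with the
  final model structure refitted per replicate (smoothing re-estimated,
  dispersion held at the point fit). A cheaper multivariate-normal
  coefficient-resampling mode (`method = "parametric"`) exists for
  exploration. Winsorisation is applied once to the observed counts before
  resampling; the point estimate itself uses raw counts.
- **Prediction offset.** The full cell area (16 km^2), making predictions
  density times area; rounding happens once, on the final total.
- **Per-cell CV.** Delta method on the log link: the CV of the response
  equals the standard error of the linear predictor.
- **Land-avoiding distances.** Dijkstra on the 8-connected sea-cell graph
  (orthogonal step = cell, diagonal = cell x sqrt 2); the octile metric
  overestimates Euclidean lengths by at most ~8%. The colony's own cell is
  clamped at half a cell so the score stays finite.
- **Which covariates get Box-Cox.** Configurable; by default variables
  with |skewness| > 1, since the set used in any given analysis is a
  data-dependent choice.

## Known limitations

- The altitude detectability coefficient is only identified by cells
  surveyed at both altitudes; designs with little dual coverage give
  noisy, occasionally sign-flipped estimates, and whole-area abundance
  standardized to "low altitude, sea state 0" inherits that noise.
- Winsorising counts at the 97.5th percentile before the bootstrap
  removes a few percent of total count mass when counts are sparse (mostly
  zeros with a thin right tail, the typical survey regime). The resampled
  totals then sit systematically below the point estimate, and the
  percentile interval can miss a true total on the high side more often
  than the nominal 5%. The coverage property test in the acceptance suite
  measures exactly this; disabling the cap (`winsor_percentile = 100`)
  restores nominal coverage in the same experiment. For real analyses the
  cap should be seen as a variance-stabilising tradeoff, not a free lunch.
- Double-penalty shrinkage is not a hard variable selector: in a modest
  fraction of pure-noise replicates REML's optimum keeps a sub-1-edf
  remnant of an idle term rather than removing it entirely. Side-by-side
  fits with mgcv's equivalent formulation (`select = TRUE`, REML, same
  `gamma`) reproduce the same interior optima on the same datasets, so
  this is a property of the method, not of this implementation; the
  shrinkage property test in the acceptance suite quantifies it.
- Geometry is planar: transects are straight lines and strip unions are
  exact only along a common carrier line; curved tracklines would need a
  general polygon-union backend.
- Approximate Wald p-values on smooths are anti-conservative in small
  samples; the altitude test (a single parametric coefficient) is the
  only p-value given inferential weight in the pipeline.
- Availability bias is not modelled; estimates standardized to optimal
  detection conditions remain minimum estimates.

## A complete run

```{r}
library(stormdsm)

world  <- gen_environment(world_config(), seed = 1)
truth  <- gen_truth(world,
  effects = list(depth = function(d) 1.2 * exp(pmax(d, -1500) / 300)),
  intercept = -1.2, theta = 2,
  detect = list(delta_alt = log(0.5), beta_ss = c(high = -0.05, low = -0.05)))
design <- gen_transects(world, broad_spacing_km = 4,
                        fine_region = c(0, 120, 0, 120), seed = 2)
sightings <- gen_sightings(truth, design, seed = 3)
records <- append_covariates(
  aggregate_counts(world$grid, sightings,
                   effort_per_cell(world$grid, design)),
  build_covariates(world))

dual <- dual_altitude_subset(records)
am <- altitude_model(dual, env_covariates = c("depth", "sst"))
am$altitude_coef          # log detectability penalty of flying high

dm <- distribution_model(records,
  env_covariates = c("depth", "dist_coast", "chl_a", "sst", "grad_sst"))
est <- estimate_total(dm$fit, build_prediction_grid(world))
est$total; truth$total_N_true

ci <- bootstrap_ci(dm$fit, records, build_prediction_grid(world),
                   B = 1000, seed = 4)
validate_split(dm$fit, records, n_iter = 100, seed = 5)
```
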