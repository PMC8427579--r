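---
title: "Modeling tree recruitment from repeated forest inventories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling tree recruitment from repeated forest inventories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Tree recruitment (in-growth) is the arrival of stems above an inventory's
calipering threshold: a tree is a recruit in a census period when its DBH
is at or above the threshold at the second census and was below it (or the
tree was absent) at the first. Recruitment counts per plot, period and
species are extremely zero-heavy and right-skewed: most species produce no
recruits on most plots in most periods, while occasional plot-species
combinations produce dozens.

`ingrowth` implements a complete analysis pipeline for such data:

1. **Covariates.** Stand structure (basal area, stem density, and the
   basal-area-weighted shade-casting ability of the overstory, recruits
   excluded) and site environment (seasonal degree-day sum above 5.5 °C
   for April–October, seasonal climatic water balance from monthly
   precipitation minus slope/aspect-corrected Thornthwaite potential
   evapotranspiration, and the soil water "bucket size"
   `BS = SDR × AWC × (1 − CFV)` with soil depth capped at 2 m).
2. **Trait groups.** Species are clustered into six groups in the
   two-dimensional (drought tolerance, shade tolerance) space with seeded
   k-means, labeled `D<d>S<s>` by the rounded group means.
3. **Model.** A hierarchical negative-binomial regression with
   trait-group coefficients, plot and species random intercepts, species
   random slopes, and a `log(area × period length)` exposure offset,
   sampled by a built-in MCMC sampler.
4. **Presentation.** Mean-over-groups + deviation effect estimates,
   effect curves over each group's 1st–99th covariate percentile, and
   basal-area × stem-density interaction surfaces.
5. **Synthetic data.** A generator that emulates the inventory structure
   so the full pipeline can be exercised and validated without access to
   the (restricted) source inventories.

# The count model

For plot $i$, period $t$ and species $j$ in trait group $g$:

$$Y_{i,t,j} \sim \mathrm{NB}(\mu_{i,t,j}, \phi), \qquad
\mathrm{Var}(Y) = \mu + \mu^2/\phi$$

$$\log \mu_{i,t,j} = \log(A_{i,t}\,\Delta t_{i,t}) + \beta_{0,g} + u_{0,i}
+ u_{0,j} + \sum_m \big(\beta_g^{(m)} + u_j^{(m)}\big)\, x_{i,t}^{(m)}$$

with all random effects normal, $u \sim N(0, \sigma^2)$. The covariates
$x^{(m)}$ are the six mains (basal area, stem density, SCA, degree-day
sum, water balance, bucket size), z-standardized per data set, plus the
two products of standardized mains: basal area × stem density (available
growing space) and water balance × bucket size (available water). A
drop-water-balance mode handles data sets where water balance is
collinear with the degree-day sum; dropping a main drops its interaction.
Collinearity is screened by variance inflation factors with the usual
critical value of 10.

## Priors

The reference analysis used package-default priors without reporting
them, so the defaults here are weakly informative, proper and
configurable: $N(0, 5^2)$ on $\beta_{0,g}$ and $\beta_g^{(m)}$,
half-normal$(0, 2)$ on every random-effect scale, and Gamma(2, rate 0.1)
on $\phi$. One scale is estimated per random-slope variable (plus one for
plot and one for species intercepts); whether the source analysis shared
scales across variables is not stated, and per-variable scales are the
more general choice.

## The sampler

The model is fit with an in-package adaptive Metropolis-within-Gibbs
sampler rather than an external probabilistic-programming dependency. The
update scheme exploits the model's conditional-independence structure:

* **Vectorized block updates.** Group coefficients partition the rows by
  trait group, random effects by plot or species, so all units of a block
  are proposed and accepted/rejected simultaneously with one likelihood
  sweep (compiled in C++; the NB log-pmf is evaluated with per-iteration
  precomputed `lgamma` tables, so a sweep costs one `exp` and one `log`
  per row).
* **Joint adaptive proposals.** Per-group coefficient vectors
  $(\beta_{0,g}, \beta_g^{(\cdot)})$ and per-species effect vectors are
  also updated jointly with multivariate normal proposals whose
  covariances are estimated during warmup (Haario-style), which handles
  the posterior correlation induced by correlated covariates.
* **Exact translation Gibbs moves.** Shifting a group's coefficient
  against the matching random effects of the species nested in that group
  leaves every linear predictor unchanged; the conditional distribution
  of such a shift is Gaussian and is drawn exactly. The same applies to
  the global intercept against the plot effects, and — because the site
  covariates are constant within a plot — to each plot-level covariate's
  coefficients against an `x`-weighted pattern in the plot effects (the
  partial confounding of plot-level covariates with plot intercepts is
  the classic slow direction of such models). These moves eliminate the
  slow "coefficient vs. random effects" directions.
* **Collapsed scale updates.** With few species per trait group, a group
  coefficient and its species effects are separated only by their priors,
  and the species-effect scale controls that split; sampling the scale
  conditional on the split mixes slowly no matter how often it is
  updated. Each species-effect scale is therefore also sampled from its
  marginal with the likelihood-null translation direction integrated out
  analytically (a one-dimensional Gaussian integral per group), followed
  by an exact redraw of the translation. This costs no likelihood
  evaluations and removes the dominant autocorrelation of the scales.
* **Interweaved scale updates.** Each random-effect scale $\sigma$ is
  updated both in centered form (given the effects) and in non-centered
  form (rescaling the effects with $z = u/\sigma$ held fixed), the
  ancillarity–sufficiency interweaving strategy that mixes through the
  funnel geometry. Both updates use slice sampling, which adapts its
  bracket automatically and avoids the step-size ceiling of random-walk
  proposals. $\log\phi$ is also slice-sampled.
* **Adaptation discipline.** Proposal scales and covariances adapt in
  batches during warmup only and are frozen afterwards, so the retained
  draws come from a fixed transition kernel. Given a seed, draws are
  bit-identical.

Convergence is assessed with the rank-normalized split-chain
Gelman–Rubin diagnostic (threshold 1.01) and a Geyer
initial-monotone-sequence effective sample size, both computed from first
principles in the package. The reference configuration is 4 chains ×
5,000 iterations with 2,000 warmup, optionally thinned to 3,000 retained
draws; the acceptance gate runs a reduced 2,000/1,000 configuration.

## Model criticism

Randomized quantile ("scaled") residuals are computed DHARMa-style: each
observation's randomized rank among posterior-predictive simulations,
uniform on [0, 1] under a correct model, tested with a Kolmogorov–Smirnov
test and complemented by a zero-count calibration (observed zeros against
the simulated 95% band). `compare_families()` screens Poisson, NB,
zero-inflated Poisson/NB and hurdle-NB. The screen fits each family by
MAP with trait-group intercepts, pooled slopes and the family shape
parameters, without random effects: residual uniformity and zero
calibration are driven by the conditional distribution family, for which
this approximation suffices, and it keeps the operation within seconds.
The full hierarchical fit uses the NB family, which the reference
analysis selected by the same kind of screen.

# Covariate conventions and numerical choices

* **Aspect.** Only the north (−1) and south (+1) multipliers of the
  slope-exposure score are stated in the source method; the default here
  interpolates continuously with $-\cos(\mathrm{aspect})$, reproducing
  both endpoints without a discontinuity at east/west, and a `binary`
  mode classifies aspects into north/south half-planes instead.
* **Thornthwaite PET.** The canonical 1948 monthly formulation: heat
  index $I = \sum (T_i/5)^{1.514}$ over months above 0 °C, cubic exponent
  $a(I)$, daylength and month-length correction from latitude, the
  Willmott high-temperature branch above 26.5 °C, and zero PET at or
  below 0 °C. The heat index is computed per calendar year from the
  months present in that year; missing winter months contribute zero,
  exactly as sub-zero winter means would.
* **Latitude** is required by the daylength correction but is not part of
  the terrain table contract; an optional `latitude` column (default 47°,
  central Europe) supplies it.
* **Water balance** uses calendar-month sums of daily inputs; partial
  months are an error, never imputed. The averaging window is
  configurable (reference window 1971–2017; synthetic fixtures use 3–5
  seasons).
* **Degree-day seasons** are April 1 – October 31 (214 days,
  leap-independent); any missing day is an error.
* **Trait scaling** uses the population (divide-by-*n*) standard
  deviation so each tolerance column has mean 0 and sd exactly 2, which
  makes the symmetric two-point case land exactly on ±2.
* **k-means** is plain Lloyd iteration seeded at the configured
  centroids, ties to the lowest index, empty clusters retained with a
  warning — deterministic given inputs. The six default centroids
  approximate the published figure (four along the
  drought-tolerant/shade-tolerant diagonal, two drought-intolerant at low
  and medium shade tolerance); the exact coordinates are not tabulated in
  the source, so these are documented approximations.
* **Recruit exclusion.** Stand covariates are computed over the second
  census excluding the current period's recruits (they are the trees
  first observed above threshold in that census). Trees are never
  un-recruited if a later measurement shrinks below threshold.
* **Effect curves** set all non-focal standardized covariates to 0 (their
  mean), random effects to 0 (the population-median plot and species) and
  the exposure to 1 ha·yr, so predictions read as recruits per ha per
  year; integrating over random effects is available as an option. The
  display transform used by the source figures (log-modulus) is a
  plotting concern and is not applied to stored numbers.

# The synthetic world

The generator's defaults state a world resembling the published
inventory summaries:

* Four design presets (`CH_FR`, `GER_FR`, `FLAN_NFI`, `CH_NFI`) fix the
  calipering threshold (4 / 7 / 7 / 12 cm), the plot-size distribution
  (log-normal 0.03–3.47 ha; 0.05/0.10 ha; 0.02/0.03 ha; 0.02 ha) and the
  period-length distribution (means 12.2 / 14.8 / 14.7 / 9.7 yr).
* Plot covariates are multivariate normal with means/sds spanning the
  published ranges (basal area 35 ± 12 m²/ha, stem density 900 ± 500/ha,
  SCA 3.5 ± 0.9, degree-days 2500 ± 500 °C·d, water balance 120 ± 280 mm,
  bucket size 32 ± 6 cm), clipped to the observed extremes, with a
  correlation that couples basal area to stem density (0.5) and SCA
  (0.3) and degree-days negatively to water balance (−0.4) — warm sites
  are dry sites.
* Species tolerance traits scatter around the six archetypal profiles so
  every trait group is populated; species shade-casting ability tracks
  shade tolerance.
* True effects mirror the qualitative published findings (negative basal
  area and SCA for light-demanding groups, positive SCA for very
  shade-tolerant groups, positive stem density and degree-days, small
  water effects, positive basal-area × density interaction), with
  $\beta_0 = -2.5$, $\sigma_{plot} = 0.5$, $\sigma_{species} = 0.3$,
  $\sigma_{slope} = 0.1$ and $\phi = 1$. This intercept places the
  response in the zero-dominated regime of the published summaries
  (median 0, ~70% zeros, long right tail). These values are illustrative
  calibrations of the stated world, not estimates.
* Tree lists are constructed to match the covariate targets: census-1
  stems hit the plot's density and (rescaled) basal-area targets, grow by
  gamma increments (default 0.2 cm/yr), suffer light mortality (1%/yr),
  and new trees appear at 2/ha/yr, 70% crossing the threshold.

The parameter-recovery experiment fixes one design (covariates, species
pool, trait groups) and redraws random effects and counts per replicate,
so the same coefficients are scored across replicates. Its desk scale is
120 plots × 18 species — three species per trait group — because with
one or two species per group the group coefficient and its species
effects are separated only by the priors and the posterior means carry a
genuine small-sample allocation bias; at three per group the 95%
intervals are calibrated and per-coefficient biases sit well inside half
a Monte-Carlo standard deviation.

What a green test on this world does establish: the pipeline's
covariate arithmetic, the likelihood, the sampler's correctness and
convergence behavior, interval calibration, and the residual/family
diagnostics. What it does not establish: anything about real inventories
— spatial autocorrelation, measurement error, browsing and disturbance,
non-stationary climate, and observer effects are all absent from the
generator, and the published real-data coefficient estimates are not
reproducible without the four restricted data sets.

# Known limitations

* The sampler is tuned for the desk-scale problems of the test world
  (hundreds of plots); very large inventories would warrant a gradient
  sampler.
* `fit_posterior` supports the NB and Poisson families; zero-inflated and
  hurdle variants are available in the MAP-based family screen only,
  following the source analysis's conclusion that plain NB is the best
  compromise.
* Per-capita recruitment rates are deliberately out of scope (the source
  analysis rejected them for data-coverage reasons), as are quadratic
  SCA terms (tested and rejected there) and any additional interactions.
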