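# ingrowth

Hierarchical negative-binomial modeling of tree recruitment (in-growth)
from repeated forest-inventory tree lists.

## The problem

Forest inventories caliper every stem above a diameter threshold (DBH 4,
7 or 12 cm depending on the design). A *recruit* is a tree that exceeds
that threshold for the first time between two consecutive censuses.
Recruitment counts per plot × period × species are zero-dominated and
overdispersed, and the drivers of recruitment — stand structure, the
shade cast by the overstory, summer warmth, water availability — act
differently on species with different shade and drought tolerance.

`ingrowth` is for forest ecologists and biometricians who want to fit
this kind of model to repeated tree lists, or to study its behavior on
synthetic inventories. It provides:

- **Covariate derivation** — basal area, stem density and
  basal-area-weighted shade-casting ability (SCA) from tree lists
  (recruits excluded); seasonal degree-day sum (Σ max(T − 5.5 °C, 0),
  April–October), seasonal water balance (monthly precipitation minus
  slope/aspect-corrected Thornthwaite PET) and soil bucket size
  (BS = SDR × AWC × (1 − CFV), depth capped at 2 m).
- **Trait groups** — seeded k-means on (drought, shade) tolerance scaled
  to mean 0 / sd 2, labels `D<d>S<s>`, genus fallback for species without
  trait values.
- **The count model** — for plot *i*, period *t*, species *j* in trait
  group *g*:

  ```
  Y_{i,t,j} ~ NB(mu_{i,t,j}, phi),   Var = mu + mu^2/phi
  log mu = log(A Δt) + beta0_g + u0_i + u0_j + Σ_m (beta_g^(m) + u_j^(m)) x^(m)
  ```

  with six z-standardized mains plus the basal-area × stem-density and
  water-balance × bucket-size interactions, VIF screening (< 10), and a
  built-in adaptive MCMC sampler (vectorized Metropolis blocks, joint
  adaptive proposals, exact translation Gibbs moves, interweaved slice
  updates for the variance scales; C++ likelihood kernels). Convergence
  is judged by rank-normalized split R-hat < 1.01.
- **Diagnostics** — DHARMa-style randomized quantile residuals,
  zero-count calibration, and a Poisson / NB / zero-inflated / hurdle
  family screen.
- **Presentation** — effect estimates as mean-over-groups + group
  deviations with 95% credible intervals, effect curves over each
  group's 1st–99th covariate percentile, and interaction surfaces at the
  10/30/50/70/90th stem-density percentiles.
- **Synthetic inventories** — a generator with per-design presets
  (plot sizes, period lengths, thresholds), correlated covariates,
  trait-structured species pools, tree lists and NB counts from known
  parameters, plus a parameter-recovery harness.

## Worked example

```r
library(ingrowth)

cfg <- generator_config(n_plots = 80, n_species = 10, seed = 1)
syn <- synth_recruitment_data(cfg)

mean(syn$design$y == 0)   # 0.659  -- zero-dominated response
round(vif(syn$design), 2)
#> basal_area stem_density    sca   dds    wb    bs
#>       1.30         1.34   1.11  1.44  1.47  1.27

fit <- fit_posterior(syn$design, chains = 4, iter = 2000, warmup = 1000,
                     seed = 2)
attr(convergence(fit), "max_rhat")                 # 1.0067 -- converged

est <- effect_estimates(fit)
est[est$variable == "sca", c("group", "overall_mean", "deviation",
                             "dev_lo", "dev_hi")]
#>   group overall_mean deviation dev_lo   dev_hi
#>    D2S1        -0.58    -0.389  -1.04  0.27434
#>    D2S3        -0.58    -0.158  -0.79  0.48784
#>    D2S5        -0.58     0.907   0.10  1.69071
#>    D4S3        -0.58     0.383  -0.23  1.04245
#>    D4S4        -0.58    -0.067  -0.93  0.80291
#>    D5S1        -0.58    -0.676  -1.34 -0.00064

res <- scaled_residuals(fit, n_sim = 200, seed = 3)
ks.test(res$residuals, "punif")$p.value            # 0.13 -- uniform
res$zero_calibration
#> observed_zeros simulated_mean simulated_lo simulated_hi
#>            527        537.245          510       571.05
```

Read it as the model recovering the world the generator stated: shade
casting depresses recruitment overall (mean effect −0.58 on the
standardized log scale), the very shade-tolerant group `D2S5` deviates
upward (+0.91, interval excluding 0) and the light-demanding `D5S1`
deviates downward (−0.68) — and the fitted model reproduces the observed
number of zeros (527 observed, simulated band 510–571).

Real tree lists enter through the same interfaces:
`read_trees()`/`read_plots()` → `inventory_data()` →
`tabulate_recruitment()` (or `harmonize_threshold()` to re-caliper at an
artificially raised threshold), `read_climate()`/`read_terrain()` →
`site_environment()`, `read_traits()` → `build_trait_groups()`, then
`build_design()` → `fit_posterior()`.

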