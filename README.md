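# plethodem

Demography and space-use analysis for terrestrial plethodontid
salamanders sampled on cover-board arrays — built around the Eastern
Red-backed Salamander (*Plethodon cinereus*), whose populations can
differ demographically over distances of tens of meters.

The package implements, as a tested and reusable pipeline:

* **Robust-design spatial capture–recapture (SCR).** Detections at a
  5 × 10 grid of cover boards follow a half-normal kernel
  $p = \lambda\,e^{-d^2/2\sigma^2}$ around a latent activity center;
  secondary occasions are closed, while between primary sessions
  individuals survive with $\Phi^{\Delta/365}$ and their activity centers
  take a bivariate normal step with per-axis SD $\tau$ (mean dispersal
  $\tau\sqrt{\pi/2}$). Abundance uses Bayesian data augmentation; the
  MCMC core is in C++ with dedicated interweaving moves for the
  $\sigma$– and $\tau$–path ridges.
* **Fabens von Bertalanffy growth.** Capture–recapture growth
  $SVL_t = SVL_{t-1} + (L_{sex} - SVL_{t-1})(1 - e^{-K I/365})$, with
  sex-specific asymptote and plot-by-sex growth coefficients
  $K = \beta_0 + \beta_1 POS + \beta_2 SEX\,(+\,\beta_3 POS \cdot SEX)$,
  fitted in state-space form with latent sizes at first capture.
* **Space use.** Probability-of-use surfaces, kernel utilization
  distributions, 50% core isopleths, probability of home-range overlap
  (PHR), core-overlap counts and nearest-neighbour distances.
* **Lifetime-fecundity projection.** Annual binomial survival with
  per-female truncated-normal survival probability, size-dependent
  gravidity, a clutch-size-on-SVL regression and 90% hatching success,
  projected over a 20-year horizon.
* **Synthetic data.** Generators that mirror the fitted models exactly,
  with ground truth attached, so every estimator is testable by
  parameter recovery without any field data.

All user-facing functions take and return tidy tables; fitted objects
have `tidy()`/`glance()` methods and `autoplot()` figures.

## A worked example

Simulate one season-structured plot, fit the SCR model, and summarize:

```r
library(plethodem)

design <- study_design()                       # 50 boards, 6 primaries
truth  <- scr_params(phi = 0.996, sigma = 3.496, lam = 0.019,
                     density = 0.613, tau = 0.99)
caps   <- simulate_scr_history(design, truth, seed = 1)
nrow(caps)                                     # 798 detections
length(unique(caps$individual_id))             # 204 individuals observed

fit <- fit_scr(caps, design, seed = 1)
tidy(fit)
#> # A tibble: 6 x 7
#>   term             mean      sd  lower  upper  rhat   ess
#> 1 phi            0.976  0.0165  0.940  0.999   1.02  64.3
#> 2 sigma          3.22   0.190   2.89   3.66    1.41  35.6
#> 3 lam            0.0202 0.00140 0.0175 0.0230  1.01  77.4
#> 4 tau            0.793  0.259   0.258  1.25    1.28  12.6
#> 5 density        0.706  0.0775  0.549  0.849   1.77  11.4
#> 6 mean_dispersal 0.994  0.324   0.324  1.56    1.28  12.6
```

`sigma` is the space-use scale in meters, `density` salamanders per m²,
and `tau` the per-axis SD of between-season activity-center shifts; the
95% intervals cover the generating values. The desk-scale default is
deliberately short — the fit warns when split-Rhat exceeds 1.05 (as
here for `density`), and longer chains via `mcmc_config()` tighten the
diagnostics.

Growth, maturity and fecundity:

```r
growth <- simulate_growth_series(growth_params(), 200,
                                 c(169, 196, 169, 196, 169), seed = 1) |>
  fit_growth(seed = 1)
contrast_k(growth, "successional_female", "mature_female")$significant
#> TRUE

clutch <- fit_clutch_model(make_clutch_table(seed = 1))
growth_group_draws(growth, "successional", "female") |>
  project_population(clutch, projection_config(), seed = 1)
#> # A tibble: 1 x 8  (lifespan, clutches and fecundity means +- SD)
```

The per-female lifespan statistic alone:

```r
project_lifespan(projection_config(), seed = 1)
#> # A tibble: 1 x 3
#>   lifespan_mean lifespan_sd n_sims
#> 1          5.84        6.12 100000
```

A command-line wrapper over the same functions ships in
`inst/cli/plethodem` (subcommands `simulate`, `fit-scr`, `fit-growth`,
`space-use`, `project`, `run-all`, `show-config`).

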