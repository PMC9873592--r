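---
title: "Models and methods in plethodem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in plethodem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plethodem)
```

`plethodem` implements a complete demographic analysis for terrestrial
plethodontid salamanders sampled on cover-board arrays: a robust-design
spatial capture-recapture (SCR) model, a Fabens-type von Bertalanffy
growth model, post-hoc space-use and overlap statistics, and a stochastic
lifetime-fecundity projection. This vignette explains each model, its
assumptions, the tunable parameters, and the numerical and design choices
made where the procedure admitted more than one defensible reading.

## Study design and state space

A `study_design()` describes the sampling geometry: by default a 5 x 10
grid of 50 cover boards at 1-m spacing, surveyed in spring and fall over
three years (6 primary sessions of 3 secondary occasions each). The
between-primary intervals are computed from date stamps, so annual rates
can be powered down to the actual season lengths (169-196 days by
default).

Latent activity centers (ACs) live on the board bounding box plus a
buffer. The buffer defaults to 10.5 m, i.e. 3x the space-use scale
reported for these populations (sigma of about 3.5 m); the simulator
refuses buffers below 2.5 sigma because edge truncation would then bias
density. Density is an intensive quantity, so buffer choice affects
computing cost far more than the estimate itself.

## The SCR model

The observation model is the standard half-normal SCR form: an individual
with AC $s$ is detected at a board at distance $d$ in one secondary
occasion with probability $\lambda \exp(-d^2/2\sigma^2)$, independently
across boards and occasions. Between primary sessions the population is
open: each individual survives an interval of $\Delta$ days with
probability $\Phi^{\Delta/365}$ and its AC takes a bivariate normal step
with per-axis SD $\tau$; the derived mean dispersal distance is
$\tau\sqrt{\pi/2}$ (the mean of a Rayleigh variate). Within primaries the
population is closed. Abundance uses Bayesian data augmentation: $M$
pseudo-individuals (default 4x the number observed) enter with
probability $\psi$; all included individuals are present from the first
primary (no recruitment — the model targets survival and movement, and
this is the simplest structure consistent with a single density per
plot). Density is reported per posterior draw as the included
superpopulation divided by the state-space area — the entry density,
which is the quantity the simulator's density parameter controls. An
alternative estimand, the alive count averaged over primaries, is kept
as the `density_avg_alive` draw column; it conflates abundance with
survival, and when the true annual survival sits near 1 under the
uniform prior (so the posterior mass for survival lies below truth) it
is systematically pulled low, which is why it is not the headline
density.

Priors: $\Phi, \lambda, \psi \sim U(0,1)$; $\sigma, \tau \sim U(0, 20)$ m;
ACs uniform at entry. Convergence is summarized by split-$\hat R$ per
parameter and flagged against a 1.05 threshold; non-convergence is warned
about, never silently dropped.

### Sampler

The sampler is Metropolis-within-Gibbs written in C++: conjugate Beta
updates for $\psi$; Gibbs updates of the inclusion indicators and of each
individual's death time (a categorical over the few allowed values);
Gaussian-prior Gibbs draws for all AC coordinates that carry no detection
information; random-walk Metropolis for everything else, with step sizes
adapted during burn-in (clamped so they cannot collapse). Latent
quantities of excluded individuals are refreshed from their priors each
sweep and are marginalized out of the survival update, so the augmented
block cannot throttle mixing of $\Phi$.

Data-augmentation SCR samplers mix slowly along two well-known ridges,
and two dedicated moves address them:

* a **non-centered rescale move for $\tau$**: propose $\tau' = c\tau$ and
  rescale every AC path around its entry point, $s'_p = s_1 + c(s_p -
  s_1)$. The random-walk prior terms cancel exactly against the Jacobian,
  leaving acceptance driven by the detection likelihood;
* an **interweaving move for $\sigma$**: propose $\sigma' = c\sigma$ and
  rescale each observed individual's path around its detection centroid.
  Here the prior terms do not cancel and are accounted for explicitly
  (Jacobian $2P\log c$ per individual plus the Gaussian step ratio).

Both are deterministic-transform Metropolis moves with symmetric
log-scale proposals. A rigid whole-path translation move per observed
individual decorrelates paths from the detection pattern. Inside the
sampler the detection kernel is truncated at $4\sigma$ and evaluated
through an 8192-point interpolation table (relative error about 1e-6);
the exported likelihood `scr_detect_loglik_cpp()` is exact, and the test
suite checks it against direct base-R binomial evaluation and a grid
marginalization.

### Scale of the recovery experiments

Simulation-recovery tests run one chain of 4,000 iterations (1,600
burn-in) per replicate at the field design and published parameter
values, a configuration chosen so a 20-replicate coverage experiment
completes on a laptop; `mcmc_config(scale = "full")` reproduces a
production-length run. At this scale effective sample sizes for
$\sigma$ and density are modest (tens), so interval endpoints carry some
Monte-Carlo noise; the coverage criterion (80% across replicates) absorbs
this.

## The growth model

Growth follows the Fabens capture-recapture form of the von Bertalanffy
curve,
$$SVL_t = SVL_{t-1} + (L_{sex} - SVL_{t-1})\,(1 - e^{-K I/365}),$$
with sex-specific asymptote $L$ and the growth coefficient modelled on
plot (POS = 1 for successional) and sex (SEX = 1 for male) indicators.
The published group-level coefficients for these populations are not
additive in POS and SEX (the successional-male estimate exceeds the sum
of the main effects by about 0.2 / yr), so the default linear predictor
includes the POS x SEX interaction — a saturated parameterization of the
four groups; `interaction = FALSE` restores the additive model. Derived
per-group K draws are emitted either way, and group contrasts use the
rule that a difference is significant when more than 97.5% of its
posterior mass lies on one side of zero.

The model is fitted in state-space form: each individual's size at first
capture is latent with a Uniform(10, 60) mm prior; true sizes then
propagate deterministically along the curve, and each recorded SVL is
true size plus Gaussian noise with estimated SD (Half-Normal(0, 5 mm)
prior; "precision 0.01" priors on $L$ and the $\beta$s are read as
inverse variance, i.e. SD 10). An earlier formulation that conditioned
on the *observed* previous SVL was rejected during development: with
0.5-mm measurement noise it produced a demonstrable errors-in-variables
bias (asymptote posteriors excluding truth, noise SD inflated by exactly
the predicted $\sqrt{1+e^{-2KI/365}}$ factor). The state-space form
recovers all generating parameters in simulation.

Individuals whose final SVL is below their first SVL are removed before
fitting (`filter_negative_growth()`), shrinkage being attributed to
measurement error; equality is retained and the removal count is
reported. Unsexed individuals are rejected with an error — the asymptote
is sex-specific, so they cannot enter the likelihood.

The simulator draws initial sizes uniformly on 18-40 mm by default: the
range spans juvenile-to-adult entry sizes while staying below the male
asymptote, so simulated increments are informative about K. Measurement
noise defaults to 0.5 mm so that recovery tests exercise the
observation-error pathway (set `sigma_obs = 0` in `growth_params()` for
noiseless series).

### Time to maturity

`time_to_length()` inverts the growth curve in closed form,
$t = -\ln((L - x_1)/(L - x_0))/K$, and `maturity_curve()` turns posterior
(L, K) draws into a cumulative proportion-mature-versus-age curve. Ages
include a `pre_growth_lag` (default 1.0 year) between the projection
clock's origin and the onset of post-hatching growth. The lag is a
reconstruction, not an estimate: published times to maturity for these
populations exceed the growth-only travel time from hatch size by about
one year, consistent with a clock that starts at oviposition (egg
development plus the first overwintering before surface growth). The
default reproduces the published medians to better than 0.1 year for all
four plot-by-sex groups; set the lag to 0 for a hatching-origin clock.

## Space use and overlap

From fitted parameters, each individual's probability-of-use surface is a
distance-decay kernel around its AC, normalized over a shared raster
(0.1-m cells by default). The published formula for this surface is
typographically ambiguous ("exp(-d sigma^2)" with the text saying
"negative exponential"); the kernel is therefore selectable —
half-normal $\exp(-d^2/2\sigma^2)$ by default, for consistency with the
detection model, or negative-exponential $\exp(-d/\sigma)$.

The full published procedure then scatters 1000 multinomial "use" points
over the surface (jittered within cells so bandwidth estimation is
non-degenerate), estimates a kernel-density utilization distribution
(bivariate Gaussian kernel; reference "href" bandwidth $h =
\sqrt{(s_x^2+s_y^2)/2}\; n^{-1/6}$, computed via `MASS::kde2d`), extracts
the 50% core isopleth (smallest cell prefix by density reaching half the
mass, ties broken by stable cell order), and computes the probability of
home-range overlap PHR$_{ij}$ = the mass of individual $j$'s UD inside
individual $i$'s core. `space_use_analysis(method = "surface")` provides
the deterministic large-sample limit (the normalized surface used
directly as the UD), which is exact for qualitative comparisons and far
cheaper at realistic densities; `method = "kde"` runs the full point
sampling.

"Overlap" counts individuals whose 50% core masks intersect (a binary
rule); nearest-neighbour distances use posterior-mean ACs. Coincident ACs
give a zero distance with a warning. Self-PHR at level $p$ equals $p$ up
to grid tolerance — one of several identities (including the analytic
Gaussian core area $2\pi\ln 2\,\sigma^2$ and a Monte-Carlo integration
oracle) checked by the test suite.

## Lifetime-fecundity projection

The projection composes published life-history constants: hatching at
13.5 mm SVL; maturity first possible at 34 mm; annual gravidity
probability 0.56 for 34-43 mm females and 0.94 above 43 mm; clutch size
from a Gaussian linear regression on SVL (fit any table of (SVL, clutch)
with `fit_clutch_model()`; the package ships a synthetic stand-in
generator, `make_clutch_table()`, because the source clutch data are
external); 90% hatching success; and annual survival drawn once per
female from Normal(0.836, 0.07) truncated to [0.4, 1.0], applied as an
annual Bernoulli trial up to a 20-year horizon.

Two conventions deserve note.

* **One survival draw per lifetime.** Drawing the survival probability
  once per individual (rather than annually) makes lifespan a mixture of
  capped geometric variables; the convexity of the geometric mean in the
  survival probability raises the expected lifespan by about one year
  relative to the homogeneous case, and is required to reproduce the
  published mean. The homogeneous expectation
  $\sum_{t=1}^{20}\Phi^t \approx 4.96$ at $\Phi = 0.836$ is checked
  against the simulator in the tests.
* **Truncation by clipping.** "Truncated to 0.4-1.0" admits two standard
  implementations: renormalized truncated-normal sampling, or clipping
  draws to the bounds (which leaves point mass at the endpoints). The two
  differ by about 0.13 year in mean lifespan (5.71 vs 5.84 at these
  settings), and only the clipping convention reproduces the published
  value; it is therefore the default, with
  `projection_config(survival_truncation = "renormalize")` available.

Reproduction is evaluated at the SVL attained at each whole year of age;
clutch draws are floored at zero, and expected hatchlings (clutch x 0.9)
accumulate without rounding. `project_population()` is an internally
vectorized equivalent of repeated `simulate_life()` calls (the tests
check their agreement), using one posterior (L, K) draw and one
clutch-coefficient draw per simulated female. The default 100,000
simulations give a Monte-Carlo standard error on mean lifespan of about
0.02 year.

## What the synthetic data do and do not emulate

The generators mirror the fitted models exactly — uniform ACs, Gaussian
dispersal, half-normal detection, Fabens growth with Gaussian measurement
error, and a linear clutch-size law. They deliberately omit features of
real cover-board data: recruitment and temporary emigration
(unavailability below the surface), behavioral interactions under boards,
weather-driven detection variation, and sex- or size-structured
detection. Passing recovery tests therefore demonstrates correctness of
the estimators under the stated model, not robustness to these
violations; the published analysis itself reported that weather
covariates on survival were not supported, which motivates keeping the
null structure here.

## Numerical choices

Truncated-normal draws use the inverse-CDF method. The SCR sampler's
kernel truncation (4 sigma) and interpolated exponential introduce
likelihood errors several orders of magnitude below one log unit.
Split-$\hat R$ uses half-chains, so single-chain runs still produce a
diagnostic; effective sample sizes use the initial-positive-sequence
autocorrelation estimator. Degenerate inputs fail loudly: no spatial
recaptures (sigma unidentifiable), unsexed growth records, constant-SVL
clutch tables, single individuals in overlap summaries, isopleth levels
outside (0, 1). All simulators and fitters are bit-reproducible given
`(seed, configuration)`.

## Known limitations

* No recruitment in either the SCR model or its simulator; density is
  the average alive count over the study, so it slightly understates
  first-primary abundance when survival is below one.
* Survival and dispersal are shared across sexes and sizes.
* The projection has no density dependence and no multi-generation
  dynamics; it is a per-female lifetime tally.
* The clutch-size stand-in is synthetic; users with the original
  published clutch data can supply them as a CSV of (svl, clutch).

## A minimal run

```{r example, eval = FALSE}
design <- study_design()
truth <- truth_params(scr = scr_params(), growth = growth_params())

captures <- simulate_scr_history(design, truth, seed = 1)
scr <- fit_scr(captures, design, seed = 1)
tidy(scr)

growth <- simulate_growth_series(truth, 200, c(169, 196, 169), seed = 1) |>
  fit_growth(seed = 1)
contrast_k(growth, "successional_female", "mature_female")

clutch <- fit_clutch_model(make_clutch_table(seed = 1))
growth_group_draws(growth, "successional", "female") |>
  project_population(clutch, projection_config(), seed = 1)
```
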