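---
title: "Modelling soybean seedling emergence seed by seed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling soybean seedling emergence seed by seed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emergesim)
```

## The problem

Crop establishment is the first yield-determining step of a soybean crop:
a sown seed must germinate, survive its first days, and push its hypocotyl
through the seedbed to the surface. Each of these steps can fail, and the
failures have distinct causes — seeds that never germinate, seedlings killed
by drought right after germination, and seedlings mechanically blocked under
soil aggregates or under a rain-induced surface crust. Field counts only
show the aggregate outcome; a seed-by-seed stochastic simulation makes the
causes visible and lets one ask what would change under another sowing date,
seedbed, or cultivar.

`emergesim` implements this chain in three parts: (i) estimation of cultivar
germination parameters from laboratory incubation time-courses, (ii) a
daily-time-step simulator of germination and emergence for every seed in a
virtual seedbed driven by daily weather, and (iii) evaluation statistics
comparing simulated with observed emergence courses. A synthetic-data
generator produces lab courses, weather scenarios and seedbed templates with
known ground truth so that every stage is testable without external data.

## Germination biology and its estimation

### Gompertz time-courses

Cumulative germination fractions over time at one incubation level are
described by the three-parameter Gompertz curve

$$g(t) = A \, e^{-e^{-k (t - t_m)}}$$

with asymptote $A \in [0,1]$ (the final germination fraction), rate $k$
(1/h) and inflection time $t_m$ (h). This parameterization has a closed-form
inverse, so the time $T_p$ to reach any percentile $p < 100A$ — and hence
the germination rate $1/T_p$ — follows analytically from a fit.
Replicate dishes are pooled by summing counts before fitting: with 25 seeds
per dish, per-replicate fits are too noisy to average meaningfully.
Fits use Levenberg–Marquardt least squares with data-driven starting values
and up to ten random restarts drawn from a private RNG stream (so fitting
never perturbs a caller's random sequence).

### Cardinal temperatures and base water potential

Below the optimum, germination rate rises linearly with temperature. For
each percentile $p \in \{20, 40, 50, 60, 80, 90\}$ the rate $1/T_p$ is
regressed on temperature and the x-intercept — the temperature at which the
rate extrapolates to zero — is that percentile's base temperature; the
cultivar's $T_b$ is their unweighted mean. The temperatures entering the
regression are chosen automatically: the longest contiguous run of
sub-optimal temperatures on which every percentile regression reaches
$R^2 \ge 0.95$ (configurable, and overridable by an explicit list). If no
window qualifies, the best window is used and flagged in the diagnostics
rather than failing: degraded data should degrade gracefully.

The base water potential $\Psi_b$ is estimated identically from incubations
over osmotic potentials at a fixed temperature, regressing rate on $\psi$.
Here the per-percentile x-intercepts are biologically meaningful on their
own: the fastest-germinating seeds of a lot tolerate the lowest potentials,
so the percentile spread estimates the within-lot distribution of $\Psi_b$.
Both the mean and the full set are reported.

The optimum temperature comes from a unimodal beta-type response
$$r(T) = r_{max}\,\frac{T_{max}-T}{T_{max}-T_{opt}}
  \left(\frac{T-T_{min}}{T_{opt}-T_{min}}\right)^{(T_{opt}-T_{min})/(T_{max}-T_{opt})}$$
fitted to the median-percentile rates; $T_{opt}$ is the fitted argmax and
$T_{min}$, $T_{max}$ are reported as fitted bounds. With fewer than five
temperature levels this function is not identifiable and the estimate falls
back to the fastest observed temperature, flagged as a boundary estimate.

### The thermal-time distribution

Germination requirements are expressed in thermal time: degree-days
accumulated above $T_b$. Courses at sub/near-optimal temperatures are mapped
to thermal time ($\theta = (T - T_b)\,t$, constant incubator temperature),
stacked as empirical-CDF points, and fitted with a single Gompertz curve in
$\theta$; a diagnostic records the between-level RMS of fractions at matched
thermal times, warning when the courses do not collapse onto one curve
(tolerance 0.1). The fitted density is discretized into 5-degree-day classes
over 0–60 degree-days, normalized to sum to one; the pooled asymptote is the
seed lot's germinable fraction. Stacking each course's own scoring points —
rather than evaluating all courses on a common grid — matters: carrying
counts forward onto a foreign grid systematically delays the pooled curve by
about half a scoring interval (~2 degree-days at typical settings), which is
visible as a shifted requirement distribution.

The reference parameter sets shipped as `soybean_cultivar_params()` encode
laboratory values for three cultivars (base temperatures 4, 3 and 3.5 °C;
optima 28, 30, 30 °C; mean base potentials −0.58, −0.56, −0.71 MPa;
germinable fractions 0.97, 0.99, 0.97; requirement median 18 °Cd with <1%
of mass above 40 °Cd).

## The virtual seedbed

A seedbed is a population of seeds at depths drawn i.i.d. from the
configured sowing-depth distribution (default: truncated normal, mean 3 cm,
sd 0.7 cm, truncated to 1–6 cm), plus an aggregate population described by
areal densities per diameter class, buried or lying on the surface. The
seedbed is one-dimensional per seed: instead of a literal voxel grid, the
chance that a shoot meets aggregates on its way up is modelled statistically
from the areal densities (below). This statistical reading reproduces every
output the pipeline reports while keeping the builder transparent.

Surface crusting is a single threshold event: a crust forms on the first day
cumulative rainfall since sowing reaches a class-dependent threshold
(non-crusting soils: never; moderately crusting: 25 mm; highly crusting:
15 mm — calibration knobs, not measurements), persists for the rest of the
horizon, and is labelled wet on days with at least 2 mm of rain, dry
otherwise. Weather enters as a daily series of soil temperature at sowing
depth, rainfall, and water potential in the 0–3, 3–5 and 5–10 cm layers;
the model performs no soil physics of its own.

## The daily simulation loop

Each seed is processed independently at a daily time step, in a fixed
within-day order: germination accrual, germination check, post-germination
water-stress check, shoot growth, obstacle resolution.

1. **Germinability.** At sowing each seed is germinable with probability
   equal to the lab germinable fraction (one Bernoulli draw); the rest can
   never germinate. Both these seeds and seeds whose requirement is never
   met within the 30-day window are reported under the single cause
   `non_germination`, because field diagnosis cannot distinguish them.
2. **Hydrothermal accrual.** A germinable seed draws its thermal-time
   requirement from the cultivar distribution and accrues
   $\max(0, T_d - T_b)$ degree-days per day, but only on days when the water
   potential of its own depth layer exceeds $\Psi_b$. Germination occurs the
   first day the accrual reaches the requirement.
3. **Early water stress.** On the two days following germination, the
   seedling dies if the potential of the layer its radicle has reached
   (sowing depth + 0.06 cm per degree-day of growth thermal time) is below
   $\Psi_b$.
4. **Elongation.** From the day after germination the hypocotyl grows as
   $L(\theta) = L_{max}(1 - e^{-r\theta})$ in thermal time above the growth
   base temperature (defaults $L_{max} = 9$ cm, $r = 0.02$ per degree-day,
   base 4 °C — soybean-scale values chosen so a seed sown at 3 cm in warm
   soil emerges 3–4 days after germination).
5. **Aggregates.** The number of buried aggregates met is Poisson with mean
   (areal density) × (encounter cross-section of shoot + aggregate) ×
   (fraction of the tilled layer traversed); each encounter blocks
   permanently with a class-specific probability (default proportional to
   diameter), and each circumvented aggregate lengthens the path by a 0.5 cm
   detour. Surface aggregates are tested once at arrival with encounter
   probability equal to their areal cover.
6. **Crust.** A seedling arriving under no crust, or under a wet crust,
   emerges that day. Under a dry crust it waits up to 7 days
   (`crust_wait`) for a wet-crust day and emerges on the first one;
   otherwise it is blocked. Blocking-by-waiting was chosen over a one-shot
   blocking probability because it ties crust mortality to the actual
   rainfall sequence rather than to a new free parameter; the wait length is
   configurable. A wait window truncated by the simulation horizon without a
   wet day counts as blocked.

Every seed ends in exactly one state: `emerged`, `non_germination`,
`post_germination_water_stress`, `blocked_aggregate`, `blocked_crust` — or
`not_emerged` for a live seedling still underground when the horizon ends,
which only occurs in cold or deep-sown scenarios and is reported separately
rather than silently folded into a mortality cause.

All draws for one run derive from a single seed, with replicate runs using
substreams drawn from a master seed, so results are exactly reproducible.
`replicate_simulations()` reruns the whole chain (seedbed realization
included) and reports means and standard deviations; `run_protocol()`
crosses cultivars with scenarios (default 10 replicates × 1000 seeds) and
writes summary tables.

## Evaluation

Predicted ($P_j$) and observed ($O_j$) emergence percentages at the $n$
observation days are compared with model efficiency
$EF = 1 - \sum(P_j-O_j)^2 / \sum(O_j-\bar O)^2$ (1 = perfect, 0 = no better
than the observed mean), root mean square error of prediction
$RMSEP = \sqrt{\sum(P_j-O_j)^2/n}$, and mean deviation
$MD = \sum(P_j-O_j)/n$ (negative = underprediction). Observed counts at
irregular dates are paired with the simulated value at those days — no
interpolation is needed at daily resolution, and the pairing is an explicit,
configurable step (`align_courses()`) rather than an implicit convention.
Final rates are classed as poor (<50%), good (50–75%) or very good (>75%),
with both boundaries belonging to "good" since the poor class is defined by
a strict inequality. A weekly-rainfall indicator (`seedbed_water_status()`)
flags possible seedbed water stress below 10 mm of cumulative weekly rain,
inclusive at the threshold.

## What the synthetic data do and do not emulate

`generate_time_courses()` draws one uniform quantile per seed that sets both
its thermal-time requirement and its base water potential (comonotone:
fastest seeds, lowest $\Psi_b$), applies an independent germinability
Bernoulli, and scores cumulative counts on a fixed three-per-day grid —
binomial dish-to-dish noise therefore arises from the seed-level draws, not
from an added error term. The water-potential response is a linear rate
reduction in $\psi$, the same structure the x-intercept estimator assumes.
That makes recovery tests meaningful (the estimator sees data from its own
model family plus sampling noise) but also bounds what they show: passing
recovery says the estimators are consistent and unbiased under the stated
noise, not that real seed lots follow a linear hydrotime reduction.

`generate_weather()` produces template scenarios (warm/cold wet, a drying
spell, a crust-prone burst) as AR(1) temperature noise plus two-phase
Bernoulli–gamma rainfall, with layer potentials wetted by rain events and
decaying exponentially between them. Only envelope statistics are
calibrated (a warm-wet month accumulates 34–125 mm of rain in ≥90% of
draws); the generator does not reproduce any particular site-year, and
simulated cause partitions under generated weather should be read as
scenario studies, not predictions.

## Numerical choices and degenerate inputs

* Gompertz fits reject series with fewer than 4 distinct times or all-zero
  counts; non-convergence after the restart budget raises an error carrying
  the context rather than returning garbage.
* Unreachable percentiles ($p/100 \ge A$) yield `NA` rates that propagate
  through the regressions (a percentile needs at least 3 levels to enter).
* Regressions with non-positive slope raise a "no thermal response" error;
  a rate profile peaking at the lowest level falls back to the full level
  set so this diagnosis, not a window-selection artifact, is what the user
  sees.
* The percentile-time spacing identity $(T_p - t_m) \propto 1/k$ holds
  exactly; note that the germination *rate* $1/T_p$ increases with $k$ only
  for percentiles above the inflection fraction $A/e$ — steeper curves reach
  early percentiles later.
* Cause percentages are exact multiples of $100/n$ and sum to 100 by
  construction; tests assert identity, not tolerance.
* The non-germination window (30 days), crust thresholds, wet-day threshold
  (2 mm), and crust wait (7 days) are explicit arguments with the defaults
  stated here.

## Problem sizes

The shipped tests run the full chain at deliberately modest sizes: recovery
suites use 200 synthetic datasets of 4 dishes × 25 seeds per level,
simulation suites use 100–1000 seeds and 10 replicates, matching the
standard protocol of 10 runs × 1000 seeds. These sizes put Monte-Carlo
standard errors well inside the asserted tolerances (e.g. the mean of 200
base-temperature estimates has SE ≈ 0.04 °C against a ±0.5 °C band).

## Known limitations

* Aggregate blocking probabilities, crust thresholds and elongation defaults
  are calibration knobs, not measured values; any quantitative use requires
  setting them from data for the soil and cultivar at hand.
* The engine excludes high-temperature injury, waterlogging and biotic
  stresses by design; it partitions non-emergence among the four modelled
  causes only.
* Soil temperature and water potentials are inputs; no heat or water
  transfer is simulated.
* Crust blocking is permanent once the wait window closes; a retry on later
  rewetting is not modelled.

## A worked scenario

```{r example, eval = FALSE}
params <- soybean_cultivar_params("Ecudor")
weather <- generate_weather("crust_prone", horizon_days = 35, rng_seed = 11)
cfg <- seedbed_template("silty_loam", n_seeds = 1000)
runs <- replicate_simulations(cfg, weather, params,
                              n_replicates = 10, master_seed = 42)
runs$summary
```

The summary reports the final emergence rate and the percentage of seeds
per cause, as mean ± sd over the 10 replicates; the README walks through
this example with its printed output.
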