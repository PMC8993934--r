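---
title: "Methods: a hybrid process/learned model of terrestrial evaporation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a hybrid process/learned model of terrestrial evaporation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridevap)
```

## The model and its assumptions

`hybridevap` implements a stress-based evaporation model: daily potential
evaporation is computed from energy availability and then reduced by
multiplicative stress factors in [0, 1]. Total evaporation is the
fraction-weighted sum of transpiration from tall and short vegetation,
bare-soil evaporation, canopy interception loss, and (stubbed) open-water
evaporation and snow sublimation.

The novelty the package is organised around is the *transpiration stress*
term. Two formulations coexist behind one predictor interface:

* a **process formula**, `process_st()`, combining a phenology factor
  `sqrt(VOD/VOD_max)` with a quadratic soil-moisture response between
  wilting point and critical moisture, and
* a **learned function**, a feed-forward network mapping twelve covariates
  (absolute values and seasonal anomalies of plant-available water, vapour
  pressure deficit, air temperature, incoming shortwave radiation,
  vegetation optical depth and CO2) to the stress factor.

The coupling is bidirectional and daily: the soil water balance supplies
plant-available water (PAW) to the predictor; the predicted stress scales
the Priestley–Taylor potential; the resulting extraction updates the soil
column that produces the next day's PAW. `step_day()` is a pure function of
its inputs — covariate anomalies are taken against a climatology
pre-computed from the forcing archive rather than updated online, and the
PAW climatology comes from a preliminary process-mode pass, so a hybrid run
needs no iteration.

Key physical assumptions: the Priestley–Taylor coefficient is 1.26 and
ground heat flux is neglected at the daily scale; stress multiplies the
potential *before* land-cover-fraction weighting; interception is a simple
threshold `min(P, c * LAI)` standing in for a full analytical canopy model;
open-water evaporation and sublimation default to zero. The soil scheme is
a mass-conserving tipping bucket (saturation excess cascades downwards and
leaves the bottom of the column) with three layers under tall vegetation,
two under short, one for bare soil.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `w_r`, `w_wp`, `w_c`, `porosity` | 0.05 / 0.15 / 0.30 / 0.45 | m3/m3 | soil moisture anchors of both stress formulas and PAW |
| layer depths | 100/900/1500 (tall), 100/900 (short), 100 (bare) | mm | column discretisation |
| `alpha` | 1.26 | – | Priestley–Taylor coefficient |
| `c_canopy` | 0.5 | mm/day per LAI | interception capacity |
| rain threshold | 0.5 | mm/day | rain-day / post-rain-day classification |
| `ept_min` | 0.1 | mm/day | minimum potential before the target ratio is formed |
| anomaly window | 31 | days | smoothing of the day-of-year climatology |
| network | 3 × 64 ReLU, dropout 0.1, sigmoid out | – | learned stress |
| training | lr 0.000142, batch 100, ≤1000 epochs, 85:15 split, patience 20 | – | optimisation protocol |

The soil constants and layer depths are generic loam placeholders, not
calibrated values: the host-model family this design mirrors reads them
from soil maps, which are outside the package's scope. The learning rate,
batch size, epoch cap and split are the fixed training protocol; the
architecture is exposed entirely through `mlp_config()` and a user can run
their own search over it.

## Training-target construction

Targets are `S_t = E_t / E_pt`, clamped to [0, 1] (observed transpiration
occasionally exceeds the modelled potential; the network output is bounded,
so targets must be too). Days with `E_pt` at or below 0.1 mm/day are
dropped — the ratio is numerically unstable near zero — and counted rather
than failed. Rainy days are removed before target formation to limit
interception contamination of the observed flux.

When the observed series is total evaporation, transpiration is separated
with a monotone saturating LAI ratio `1 - exp(-k LAI)` (k = 0.45 tall,
0.75 short — configurable placeholders for fitted partitioning
coefficients). Sap-flow tables take the direct route instead: per-tree flow
is expressed per unit projected crown area using the allometric model
`ln A_c = -2.53 + 0.602 ln A_b + 0.0960 MAT - 5.48e-5 MAP` (natural logs,
areas in m², the interpretation adopted here), averaged within species, and
combined as a basal-area-weighted species mean.

Where the potential-transpiration series comes from a mismatched spatial
scale, `scale_ept()` applies an affine bias correction fitted on days
following rain: the raw series is mapped onto the observed flux moments of
that subset, under the assumption that ecosystems transpire at their
potential right after rainfall. The moments use the sample (n−1) standard
deviation. In the synthetic worlds shipped with the package the point and
"grid" scales coincide, so the default pipeline leaves the correction off;
it is exercised and tested on a world constructed to satisfy the
transpire-at-potential assumption exactly.

"Seasonal anomaly" is implemented as the raw departure from a smoothed
day-of-year climatology (31-day centred circular window), not a z-score:
keeping the departure in physical units lets the network weigh anomaly
magnitude itself.

## Training protocol and numerical choices

The objective is the set-level loss `1 - KGE`, not a pointwise error:
mini-batch gradients are the analytic derivative of the batch-level
(size 100) `1 - KGE` with respect to each prediction, while the
early-stopping criterion is the objective over the *full* validation set
each epoch, with the best weights restored afterwards. "Started degrading"
is operationalised as 20 epochs without validation improvement. The 15 %
validation split is pooled across sites (all rows treated equally), with a
site-stratified split available to users who restructure the table.

KGE conventions, applied consistently across the objective, the evaluation
module and the tests: sample standard deviations; correlation set to 0 for
a zero-variance prediction (this convention makes the mean-benchmark
reference `1 - sqrt(2) ≈ -0.41` an exact, reproducible number); degenerate
*observations* (zero variance or zero mean) are errors, not conventions.
The 99th-percentile VOD reference uses R's default linear-interpolation
quantile (type 7) — percentile conventions differ enough across software
that the choice is pinned and tested.

All randomness in training (weight initialisation, shuffling, dropout)
draws from R's RNG inside the compiled loop, so a seed plus single-threaded
execution reproduces a training run bit for bit. Features are standardised
with training-pool moments stored on the model. Non-finite objectives abort
training with a diagnostic rather than silently continuing.

Clamping decisions: PAW and both stress factors are clamped to [0, 1] even
where the raw formulas are unbounded (the quadratic soil response is
negative below wilting point and exceeds 1 above critical moisture, a
regime the originating formula leaves undiscussed); stress factors multiply
a potential flux and must be bounded, and moisture above critical simply
means no water limitation.

In the water balance, the transpiration extraction layer is the layer that
was wettest at the *start* of the day — the same state the stress factor
was computed from. Choosing the wettest layer after infiltration couples
the extraction target to the day's rainfall and can violate the otherwise
natural monotonicity property that more rain never leaves any layer drier.

## The synthetic world

Every experiment in the package runs against `generate_world()`: seeded
per-site climates (mean temperature 2–24 °C, varying rainfall regimes,
radiation and phenology), a first-order two-state rain occurrence chain
with exponential depths, AR(1) weather noise, and a known ground-truth
stress function — by default a smooth bounded product of a logistic PAW
response, exponential VPD decay, a Gaussian temperature optimum, a
saturating light response, `sqrt(VOD/VOD_max)` phenology and a weak linear
CO2 modifier, so every covariate carries signal. Observations are
`E_obs = S_true * E_pt + Gaussian noise` (truncated at zero) on dry days,
with an added interception-like term on rain days so the rain-day filter
has real work to do. The generator's soil column follows exactly the same
physics as the coupler's vegetated column, so covariates seen in training
and covariates produced during coupled runs come from the same dynamical
system.

The default experimental scale is 40 sites × 6 years with observation
noise sd 0.05 mm/day, subsampled to 50,000 training rows; the function-
recovery experiments in the test suite train the full 3×64 network on this
world in roughly half a minute and reach out-of-sample KGE > 0.95 against
the hidden truth, with a shuffled-target control collapsing to KGE ≈ 0.
Smaller configurations (the README example, the demo config) illustrate the
same pipeline at a fraction of the cost.

What the synthetic world does *not* emulate — and hence what passing tests
do not show about real data: satellite retrieval error structures
(systematic, spatially correlated, state-dependent), realistic biome
climatology, energy-balance closure gaps and sensor error of eddy
covariance, species-level sap-flow variability, and covariate
collinearity patterns of real archives. Recovery results here demonstrate
the *machinery* (targets, objective, coupling) is correct, not that the
learned function transfers to any particular ecosystem.

## Design choices where the design was open

* **No deep-learning framework dependency**: the network and its KGE
  training loop are compiled RcppArmadillo code authored in-package. The
  loss is the contribution; implementing its analytic gradient keeps the
  package self-contained and bit-reproducible.
* **Gridded I/O** is long-format CSV with explicit cell/time columns, and
  grid runs iterate independent cells; text formats keep runs inspectable
  and diffable at desk scale.
* **Anomalies in coupled runs** come from a fixed pre-computed climatology
  (drivers from the forcing archive, PAW from a process-mode pass) rather
  than a climatology updated online: this keeps the daily step pure and
  the run reproducible, at the cost of a small inconsistency early in
  records shorter than the climatological baseline.
* **Stress before weighting**: tall/short stress scales the potential
  first, and land-cover fractions weight the resulting component fluxes.
* **Pooled validation split**, matching a training protocol that treats
  all site-days equally.

## Known limitations

Soil parameters are uncalibrated placeholders; the interception stub has no
canopy storage memory; open-water evaporation and sublimation are constant
stubs; the bias correction assumes the post-rain subset is large enough
(at least two days) and raises an error otherwise; KGE-based training
requires targets with variance inside each batch, so pathological worlds
with near-constant stress can stall the objective; and training determinism
holds for single-threaded BLAS — multi-threaded linear algebra may permute
floating-point summation order.
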