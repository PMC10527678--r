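---
title: "Hybrid soft sensing of solutes in fed-batch E. coli cultivations: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid soft sensing of solutes in fed-batch E. coli cultivations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The estimation problem

Offline assays for soluble compounds (acetate above all, but also lactate,
glutamate, glutamine, isoleucine) interrupt fed-batch monitoring and arrive
hours late. Off-gas analysis, in contrast, is continuous and non-invasive:
the oxygen uptake rate (OUR) and carbon dioxide production rate (CPR)
track the culture's metabolic state in real time. `softsensr` builds a
*hybrid* estimator: a mechanistic layer first converts OUR into latent
physiological states, and a data-driven recurrent layer then maps measured
and latent signals onto solute concentrations.

# The mechanistic layer: latent physiological states

The strain-specific oxygen balance links OUR to biomass:

$$\mathrm{OUR}(t) = \alpha\,\frac{dX}{dt} + \beta\,(X - X_{cX})
\quad\text{once}\quad \int_0^t X\,d\tau > k_{cX},$$

with the maintenance term $\beta$ absent before the cumulative
biomass-time integral crosses $k_{cX}$. Here $\alpha$ (g O$_2$ per g
biomass) is the oxygen cost of growth and $\beta$ (g O$_2$ g$^{-1}$
h$^{-1}$) the maintenance respiration of standing biomass; both may be
constants or per-instant series, and their calibration is out of scope —
they are strain inputs. `latent_biomass()` inverts this balance with the
integrating-factor update

$$x_i = x_{i-1}\,e^{-(\beta/\alpha)\Delta t_i}
  + \frac{\mathrm{OUR}_i + \beta X_{cX}}{\alpha}\,\Delta t_i,$$

with an effective $\beta$ of zero until the threshold crossing. Writing
both regimes as one recursion guarantees continuity at the switch and
makes the maintenance-free branch an exact cumulative sum
$x_0 + \sum \mathrm{OUR}\,\Delta t/\alpha$ when $\beta = 0$. The update is
first-order accurate; the test suite verifies against a fine-grid RK4
reference that halving the sampling interval halves the inversion error.
Times are hours since inoculation; the first interval is `times[1] - 0`,
so the inoculum $x_0$ is the biomass at time zero.

From the biomass trajectory follow:

* `specific_growth_rate()`: $\mu = (dX/dt)/X$, by second-order central
  differences on the (possibly irregular) grid, one-sided at the ends.
  A length-1 series has no derivative; $\mu$ and the ages are defined 0
  there.
* `average_age()` / `cumulative_age()`: cohort bookkeeping in which the
  biomass laid down at each instant ages linearly,
  $\mathrm{Age}_i = \sum_j (t_i - t_j)\Delta X_j / X_i$ and
  $\mathrm{cAge}_i = \mathrm{Age}_i X_i$. The inoculum is one cohort born
  at the first instant ($\Delta X_0 := x_0$) — otherwise the sums would
  ignore the starting population. Negative increments (biomass decline)
  enter the sums as-is; clipping them would silently break the
  $\mathrm{cAge} = \mathrm{Age}\cdot X$ identity that the tests assert to
  $10^{-9}$ relative tolerance.

$X_{cX}$ is exposed but defaults to 0 (disabled): it acts as a reference
level offsetting maintenance in the second regime, and nothing in the
estimator requires it to be active.

# The data-driven layer: recurrent sensor

Each estimate is built from a sliding window of the 23 most recent
sampling instants. The layer stack is fixed: an LSTM of 23 units with ReLU
cell activations, dropout 0.2, a 10-unit ReLU dense layer, dropout 0.2,
and a single output unit whose kernel and bias are constrained
non-negative (concentrations cannot be negative; predictions are
additionally clipped at zero after inverse scaling). Features and target
are min–max scaled to $[0,1]$, with the scalers fitted on the training
split only; values beyond the fitted range scale beyond $[0,1]$
deliberately, and a constant feature maps by shift-only with a logged
warning.

Training minimizes the modified mean-square loss
$\mathrm{MMSE} = \tfrac1n\sum (|A_i^* - A_i| + 1)^2$: the unit offset
keeps the gradient magnitude of sub-unit errors near $2$, so small
concentration errors retain weight late in training. A perfect fit scores
exactly 1. The alternative reading $\sum(|e|+1)/(2n)$ is one configuration
flag away (`loss = "scaled_mae"`); the squared form is the default because
it is the one that is a *mean-square* error. Optimization is Adam at
learning rate 0.001, batch size 16, at most 1000 epochs with early
stopping on the validation loss (patience 50, best weights restored). The
engine (forward pass, backpropagation through time, Adam, dropout,
constraints) is implemented in C++ on Armadillo and is verified in the
test suite against central finite differences on every parameter block.

Three leakage and labelling rules matter more than any hyperparameter:

* the 80/20 train/validation split is applied at the *experiment* level —
  row-level splits would leak temporal context through overlapping
  windows;
* windows never span two experiments; the first instants of a run are
  edge-padded (first instant replicated) by default, because short
  campaigns cannot afford to drop 22 labelled points per run
  (`pad = "strict"` is available);
* training windows are built only at assayed instants: targets are
  measurements, never interpolations.

The early-stopping hold-out is the same 20% split used for model ranking;
a deliberate simplification (only one split is defined), documented here.

# Input groups, committee, and entropy

`enumerate_input_groups()` forms every subset of the variable pool with
sizes 3–11 (the pool is parameterized; the 12-variable registry covers
time, OUR, CPR, broth weight, both feeds, initial glucose, induction time,
and the four latent states). Each group is screen-trained once; groups
with hold-out MAE above 0.5 g/L are excluded, and a group is also dropped
when a *proper subset* of it achieves strictly lower MAE (its extra
variables bought nothing). Survivors are retrained over several trials
(best trial kept), ranked by MAE, and combined by RMSE-derived weights

$$w_i = \frac{\sum_j \mathrm{RMSE}_j - \mathrm{RMSE}_i}
             {\sum_j \mathrm{RMSE}_j\,(n-1)},$$

which sum to one and are anti-monotone in RMSE; a single member gets
weight 1 by convention, and the weighted average is used as-is (no
renormalization).

Committee size is chosen by information gain: for nested committees of
sizes $1..14$ built from the MAE ranking, each variable's probability is
the fraction of members whose group contains it, and
$H = -\sum p\log_2 p$ (with $0\log 0 = 0$) is computed *on those
occurrence frequencies literally* — they are presence frequencies, not a
normalized distribution, and are used exactly as defined. The
entropy-maximizing size wins; ties break toward the smallest committee. A
perturbation-based local-surrogate alternative
(`explanation_probabilities()`) ranks windowed features by local ridge
coefficients around each data point, collects each point's top 20
features, and maps them to source variables; it is the second probability
source for the entropy criterion.

# The synthetic campaign generator

No public data exist for either site, so `simulate_cultivation()`
generates the study conditions: Monod growth on glucose with overflow
metabolism — acetate is produced while specific glucose uptake exceeds the
oxidative capacity `qs_crit` and re-consumed once uptake is limiting —
exponential feeding with volume increase, and first-order
production/consumption laws (tied to growth and induction) for the
secondary solutes. All rate laws and defaults live in the scenario YAML
files under `inst/extdata/scenarios/`, not in code. The two shipped
scenarios mirror the two cultivation regimes: site 1 — 20 h, feed start
drawn in 5–7 h, dense 0.1 h sampling, 17 offline assays per run; site 2 —
66 h, feed start 21 h, isoleucine co-feed, four secondary solutes, 18
sparse assays per run.

The off-gas signal is emitted from the same discrete oxygen balance the
physiology layer inverts, so with zero observation noise the
OUR-to-biomass round trip is exact to machine precision — the simulator
and the estimator share the $\alpha/\beta$ model by construction, which is
precisely the property the hybrid structure assumes of real off-gas data.
CPR is OUR scaled by a slowly drifting respiratory quotient; observation
noise is multiplicative Gaussian (1–3% is realistic for off-gas
analyzers; 2% is the shipped default and configurable), assay noise 2%
relative plus a small absolute floor.

Campaigns add run-to-run variability: lognormal jitter on `mu_max`,
`qs_crit`, `Y_XS`, the feed magnitude and the inoculum, plus the site-1
feed-start window. The jitter scale defaults to 2%. This value is a
calibrated choice: the overflow switch amplifies kinetic jitter strongly
(the overflow flux is a small difference of two large rates, and the
glucose-exhaustion time compounds it exponentially), so 2% parameter
jitter already produces a ~12% coefficient of variation in acetate peak
height across runs. Substantially larger jitter yields campaigns whose
acetate trajectories vary severalfold between same-protocol runs — data on
which no estimator, however good, could reach the percent-level accuracy
that motivates the method, and which therefore would not emulate the
campaigns the method is designed for.

What the generator does *not* emulate: pH/DO control loops, product titer
dynamics, analyzer drift and recalibration events, missing or irregular
off-gas segments, and any thermodynamically rigorous metabolic coupling.
Tests passing on this generator show the pipeline's statistical machinery
works under its stated assumptions; they do not certify accuracy on real
cultivations.

# Numerical and reproducibility choices

* ODE integration: `deSolve::lsoda`, `rtol 1e-8` / `atol 1e-10`, states in
  amounts (not concentrations) so the glucose balance closes to $10^{-6}$
  relative.
* Every randomized step takes an explicit seed; weight initialization uses
  R's RNG (Glorot uniform, unit forget-gate bias, non-negative output
  init), while shuffling and dropout use a C++ Mersenne Twister seeded
  from it. Same seed, same thread count ⇒ identical results; across BLAS
  builds exact bitwise equality of *trained* weights is not promised,
  which is why training determinism is asserted at $10^{-12}$ tolerance
  rather than `identical()`.
* Degenerate inputs: length-1 records (μ, ages 0), constant features
  (shift-only scaling + warning), constant observations (nMAE and $R^2$
  are errors, not NaNs), empty committees and empty rankings are errors.

# Desk-scale problem sizes

The package documents and tests a "desk" profile chosen to keep a full
campaign in minutes on a single core: 12 training + 5 validation
simulated site-1 runs, a pool of 8 variables (time, OUR, CPR, broth
weight, glucose feed, latent biomass, μ, Age), group sizes 3–5 (182
groups), one screening pass per group (15 epochs), 3 retraining trials at
a 30-epoch cap for the filtered survivors, committees up to size 14. The
"full" profile mirrors the reference protocol (sizes 3–11, 20 trials,
1000-epoch cap) and is correspondingly expensive. The acceptance script
(`scripts/acceptance.R`) runs one desk campaign end-to-end and reports the
quantities it computes; the acceptance tests additionally check, over five
campaign seeds, that the best single sensor beats the train-mean baseline
at least fivefold on noiseless observations, that the entropy-selected
committee is at least as accurate as the best single model (median), and
that no committee size beats the selected one by more than 5% (median) —
the diminishing-returns shape.

# Known limitations

* The latent-state inversion is first-order in the sampling interval;
  very sparse grids (multi-hour gaps) bias the biomass estimate.
* The entropy criterion applied to literal occurrence frequencies tends to
  favor larger committees when the surviving groups are diverse; on easy
  synthetic campaigns the selected size often sits at the top of the
  candidate range rather than at an interior peak.
* Early stopping and ranking share one hold-out split, so the ranking is
  mildly optimistic; with more experiments a three-way split would be
  preferable.
* The local-surrogate explanations use Gaussian perturbations in scaled
  space with a ridge-regularized linear fit; they are a faithful
  *local-importance* ranking, not a causal attribution.
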