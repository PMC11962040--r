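---
title: "Movement, behavioural states and oxidative stress: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement, behavioural states and oxidative stress: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxmove)
```

`oxmove` turns raw seabird GPS deployments and paired plasma assays into a
joint behaviour–physiology analysis. This vignette documents the models, the
tunable constants and their defaults, the numerical choices, and the places
where the design was genuinely open and a decision had to be made.

## 1. Trajectory primitives

Distances are haversine great-circle distances on a sphere of radius
6371 km. At foraging-trip scales (tens to hundreds of km) the difference
from an ellipsoidal metric is well below GPS noise, so the spherical form is
used throughout, including the colony-distance series that drives trip
segmentation.

Turning angles are the signed difference between successive step bearings,
wrapped to $(-\pi, \pi]$ with **positive = counterclockwise** (a left turn).
Only a single convention matters to the symmetric von Mises emission used
later, but the sign is fixed and tested. Angles are undefined — and stored
as missing — at track endpoints and wherever an adjacent step has zero
length.

The ground-speed filter removes fixes implying more than `vmax_kmh`
(default 90 km/h, a conservative ceiling for both flapping gulls and
soaring shearwaters) in a single **forward sweep against the last kept
fix**: the first fix is kept, and each later fix survives iff the speed from
the previous survivor is at or below the ceiling. The sweep is idempotent
and guarantees every consecutive kept pair respects the bound. "Exceeding"
is read strictly: exactly 90 km/h is kept.

Resampling places fixes on an exact arithmetic grid from the first
timestamp and interpolates latitude and longitude independently and
linearly between the bracketing originals, after unwrapping longitude so
interpolation never crosses the antimeridian the long way. Grid points
falling in an observation gap longer than `max_gap_min` (default three
sampling intervals) are *dropped*, not fabricated, and the output is split
into numbered segments; no step or turning angle is ever formed across a
segment boundary. The gap rule is our addition: without it, a logger outage
of hours would be bridged by a fictitious straight line moving at implied
walking pace.

## 2. Trips and flight metrics

A foraging trip is a maximal run of consecutive fixes whose colony distance
strictly exceeds the species threshold, kept iff its first-to-last elapsed
time strictly exceeds the duration threshold (gulls 1 km / 1 h; shearwaters
3 km / 6 h). Both comparisons are strict because the definitions are worded
as "more than"; ties at the threshold are excluded. Trip boundaries are the
first and last fixes *beyond* the distance threshold — the colony-side
crossing fixes are excluded by default, with `include_boundary = TRUE`
available since the alternative reading is defensible. A data gap ends a
trip: we cannot certify the bird stayed away across an outage. Brief
re-approaches within the threshold split a trip in two (the maximal-run
definition); a gap-tolerant merge is deliberately not the default.

Flight vs stationary is a ground-speed threshold at 15 km/h. The boundary
value itself is classified as **flight** (≥ 15): the phase definitions
("more than 15" for flight, "less than 15" for stationary) leave exact
equality undefined, so a single documented convention is required; it is
exposed as a parameter. A takeoff is a stationary→flight switch between
consecutive fixes; a track that starts in flight contributes no initial
takeoff.

Per-individual aggregation follows the trip-mean rules: totals are sums
over trips; the average maximum distance is the sum of per-trip maxima
divided by the trip count; and the average takeoff frequency is the
**unweighted mean of per-trip frequencies**, which differs from total
takeoffs over total duration whenever trips have unequal durations — the
package deliberately implements the former and tests the distinction.
Individuals with no qualifying trips keep zero totals but *missing*
averages.

Land utilization is computed on the 1-min resampled grid: 100 × (trip fixes
in flight phase inside a land polygon) / (all trip fixes). Whether the
numerator should count only flight-phase fixes or all over-land fixes is
ambiguous; flight-only is the default and `numerator = "all"` is provided.
Point-in-polygon uses the even–odd rule with points on a boundary counted
as land — deterministic and resolution-agnostic. The polygon test is
implemented in the package (there is no spatial simple-features dependency)
and is verified in the tests against an independent implementation on
interior points.

## 3. The movement HMM

Ten-minute step lengths and turning angles are modelled by a 3-state hidden
Markov model: gamma step emissions parameterized by state mean and standard
deviation, von Mises angle emissions with state mean direction and
concentration $\kappa$, a row-stochastic transition matrix and an estimated
initial distribution. Multiple individuals (and post-gap segments)
contribute independent forward passes sharing one parameter set.

Fitting is EM (Baum–Welch). Both M-steps are exact weighted maximum
likelihood — the gamma shape via the standard log-mean relation solved by
`uniroot`, $\kappa$ via the Bessel-ratio equation — so the log-likelihood
trace is monotonically non-decreasing, and the tests assert it. EM stops at
a relative tolerance of 1e-6 or 100–200 iterations. Initialisation splits
steps into terciles and uses their moments; beyond the moment start,
restarts jitter the initial values (log-normal on means and sds), and the
best likelihood wins. The full-fit default is 10 restarts; the pipeline
default is 2, which is ample for well-separated seabird data where the
tercile start already lands in the right basin. A state capturing less than
1% of posterior weight triggers a warning and a restart.

Zero-length steps are floored at 1 m rather than modelled by a
zero-inflation mixture — a documented simplification; at 10-min resolution
true zero displacements are rare and the floor keeps the gamma density
finite. Missing angles contribute step-only emission terms.

States are labelled by ranking mean step length: smallest → resting, middle
→ foraging, largest → flight. As a consistency check the foraging state is
expected to have the lowest $\kappa$ (widest turns); if not, a warning is
raised but labels still follow step length, because the step ordering is
the primary definition. Ties in mean step length are an error, not a silent
choice. Decoding is global (Viterbi) by default; local posterior-maximum
decoding is available via `method = "local"`.

A foraging phase is a run of at least `run_min = 2` consecutive foraging
fixes; its duration is last-minus-first fix time. The run threshold is
ambiguous between "at least 2" and "at least 3" in common usage; 2 is the
permissive default (a single fix has zero duration anyway) and the knob is
exposed and tested under both readings.

## 4. Oxidative-stress statistics

Changes are retrieve minus deploy per individual and assay; duplicate
timepoints are an error and unpaired individuals stay missing. One U. CARR
converts to 0.08 mg H₂O₂/dL exactly.

**Tobit.** Levels are bounded by the analyzer's accurate detection ranges
(d-ROMs 40–1000 U. CARR, BAP 500–6000 µM/L). Values at or outside a limit
are censored at it; strictly interior values are uncensored. The censored
Gaussian likelihood is maximised by BFGS on $(\beta, \log\sigma)$ with
analytic gradients from an OLS start (relative tolerance 1e-14, two
passes), standard errors from the observed information with a delta-method
back-transform for $\sigma$. With no censoring the optimum *is* OLS, which
the tests assert to 1e-6; under 20% censoring the fit matches
`survival::survreg` (an independent interval-censored implementation) to
1e-4. Designs censored entirely on one side, or $\sigma$ collapsing to
zero, are rejected with diagnostics. The pipeline also reproduces the
exclusion convention for a cohort whose d-ROMs fall below the lower limit
(`exclude_below_range`, default on): those individuals leave the change
analyses rather than being imputed.

**VIF pruning.** VIF$_j = 1/(1-R^2_j)$ from regressing predictor $j$
(standardized) on the others; the single highest-VIF column is removed
repeatedly while any VIF ≥ 3. Ties — including the exactly symmetric
two-column case — drop the later column in input order, within a 1e-8
relative tolerance so floating-point noise cannot flip the choice.
Perfectly collinear columns get infinite VIF and go first. The per-round
table is returned for reporting.

**Bayesian regression.** Gaussian likelihood, flat priors on coefficients,
inverse-gamma(0.001, 0.001) on the error variance — weakly informative
choices under which the posterior mean tracks OLS, matching the
Gaussian-family usage without claiming equivalence to any particular
package default. Sampling is a conjugate Gibbs sampler (β | σ² multivariate
normal around OLS; σ² | β inverse gamma), 4 chains by default, with
split-R̂ checked on every coefficient and > 1.05 treated as an error —
conjugate chains mix essentially instantly, so a failure indicates a broken
design, not bad luck. A coefficient is called positive when its 95%
equal-tailed credible interval lies above zero, negative below, otherwise
no call. The tests verify ~5% null calls over 200 seeded replicates and
CI widths shrinking as $1/\sqrt n$.

No multiple-testing correction is applied across years or responses;
results are surfaced per coefficient, raw.

## 5. What the synthetic generator emulates — and what it does not

`simulate_tracks()` produces week-long (default), colony-centric
deployments at 1-min (gull) or 5-min (shearwater) GPS intervals.
Excursions alternate with colony dwell: an outbound transit toward a
randomly placed foraging site (mean range 25 km for gulls, 120 km for
shearwaters), a foraging bout with Markov switching among resting /
foraging / flight, and a return transit. Per-state speeds are ~0.6, ~9 and
~30 km/h — directed flight sits safely under the 90 km/h spike filter, so
the filter removes essentially nothing, as intended on clean data. The
foraging state has the lowest angular concentration; its self-transition at
1-min is 0.96, giving mean state runs of ~25 min so that behaviour is
reasonably pure within 10-min analysis windows. Between-individual
heterogeneity comes from log-normal multipliers on trip range (sd 0.5),
bout length (0.6), colony dwell (0.7) and a "restlessness" factor scaling
the foraging→flight switching rate (0.6). These four independent axes exist
so that the seven behavioural covariates are *not* structurally collinear
and mostly survive VIF pruning, as in the field data the generator imitates.

`simulate_assays()` draws deploy-time baselines (gull d-ROMs ~N(130, 45)
U. CARR, BAP ~N(1450, 320) µM/L) and sets retrieve = deploy + intercept +
effects·covariates + Gaussian noise (σ = 30 U. CARR, 300 µM/L). The default
true effects are +0.06 U. CARR per km of flight distance on the d-ROMs
change and +35 µM/L per foraging hour on the BAP change. Both are sized so
the full loop — simulate, segment, decode, prune, regress — detects them
with high power at the default 40-bird cohort: the sizing allows for the
attenuation introduced by HMM-decoded (rather than true) covariates and for
collinearity-inflated standard errors. The acceptance script reports sign
recovery aggregated over three replicate studies because a single study can
legitimately lose an effect's column to VIF pruning of a collinear proxy —
the analysis' own blank-cell behaviour.

What passing these tests does **not** show about real data: the generator
has no positional error, no environmental covariates (wind, prey), no
sex-linked behaviour, no tidal or diel structure, and its state process
really is Markov with gamma/von Mises emissions — the model is well
specified by construction. Recovery rates here are upper bounds on field
performance. One known resolution effect is documented rather than hidden:
HMM-decoded foraging *duration* is a noisier covariate than the
trip-derived metrics (takeoff/landing windows of each transit register
intermediate displacements), recovering truth with correlation ≈ 0.9 where
distances and counts recover at ≈ 1.0.

## 6. Problem sizes and determinism

The shipped tests and the acceptance script use 40-bird, 7-day gull studies
for the end-to-end checks, 20 × 500-point tracks over 10 seeds for HMM
recovery, n = 500 for censored-regression recovery and 200 replicates for
sign-rule calibration — sizes chosen to give stable statistics on a single
CPU in minutes. All randomness flows from explicit seeds; `run_pipeline()`
derives every stage seed from the config seed, and `write_report()` output
is byte-identical across reruns, which both suites assert.

## 7. Known limitations

- No positional-error filtering beyond the speed spike rule (no
  state-space smoothing, no error ellipses).
- No covariates on HMM transition probabilities and no model selection over
  the number of states; K = 3 is fixed by the scientific framing.
- The Tobit and Bayesian models have no individual-level random effects;
  each bird contributes one row per analysis.
- Land utilization depends entirely on the supplied mask's fidelity;
  the bundled GeoJSON is a synthetic rectangle for examples and tests, not
  a coastline.
- Below-range assay values are excluded (reproducing the analysis
  convention), not imputed; an imputation route is out of scope.
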