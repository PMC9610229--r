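---
title: "Modeling membrane-controlled release from reservoir implants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling membrane-controlled release from reservoir implants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dkimplant)
```

## The physical model and its assumptions

A reservoir implant is a polymer tube (here poly(ε-caprolactone), PCL)
enclosing a drug core formulated with an excipient. Release proceeds by
dissolution of the drug into the excipient, partitioning of dissolved drug
into the polymer, and diffusion through the wall. While excess solid drug
keeps the reservoir saturated, the concentration gradient across the
membrane is constant, and steady-state Fickian transport gives a constant
flux `J = Dk·CsE/L`: `D` (diffusion) and `k` (partition) are never
identifiable separately from release data, so the package treats the
product `Dk` (mm²/day) as the single empirical transport parameter
throughout. Cumulative release is then linear, `Mt = (Dk·CsE·A/L)·t`.

Assumptions inherited from this model, all deliberate:

* **Steady state only.** No pre-steady-state lag-time solution: the
  package models the regime in which dissolution curves are measured
  (days to months), not the first hours.
* **Slow polymer degradation.** PCL hydrolyzes over years; release over
  months is decoupled from degradation, so no erosion kinetics.
* **Sealed ends, thin-wall geometry.** Flux acts through the lateral
  wall. `lateral_surface_area()` uses the mid-wall cylinder
  `π(OD − L)·length`; the exact cylindrical-shell (log-mean) area is
  available via `correction = "logmean"` and differs by <1% for the
  wall-to-diameter ratios of these devices (70–200 µm walls on a 2.5 mm
  tube).
* **Sink conditions.** Back-diffusion from the release medium is ignored,
  matching dissolution protocols that exchange buffer twice weekly.

**The area convention.** The cumulative-release law is sometimes written
without an explicit area term, which makes the fitted `Dk` absorb the
device geometry. This package always normalizes by the mid-wall lateral
area, so `Dk` is a geometry-independent membrane property: implants of 10
and 40 mm length differ in rate exactly by their area ratio. Users
comparing against slopes fitted under an area-absorbing convention must
multiply by `A` themselves; the choice is surfaced here because it is the
one place two otherwise-identical analyses can silently disagree.

**Units.** Lengths mm, areas mm², time days, mass mg. Solubilities cross
the public API in mg/mL — the units in which they are tabulated and
measured — and are converted to mg/mm³ internally, so rates carry mg/day.
One exception is intentional: CsE enters the QSPR equation in mg/mL
exactly as tabulated, because the published coefficients embed that
scale. File I/O accepts wall thickness in µm (the bench convention) and
converts to mm on read.

## Estimating Dk from a release curve

`estimate_dk()` fits ordinary least squares to cumulative mass versus
time and rescales the slope by `L/(CsE·A)`. Two defaults matter:

* **A free intercept** is fitted (an origin-constrained option exists).
  A constant early offset — a burst — then biases only the intercept,
  not the slope; forcing the line through the origin transfers the burst
  into the slope and overestimates `Dk`.
* **The fit window defaults to the whole series**; callers exclude a
  burst window explicitly (e.g. `fit_window = c(14, 70)` to drop the
  first two weeks). Whether published slopes were origin-forced is
  generally unstated in the literature; with a window excluding the
  burst, the two options agree to within the slope's standard error.

The standard error of `Dk` is propagated linearly from the OLS slope
standard error, which assumes independent observation errors — see the
noise-model discussion below.

## The QSPR workflow

`fit_qspr()` reproduces the regression workflow behind the frozen
coefficients: the outcome is `log10(Dk)` (release parameters are
log-normally spread), candidate predictors are MW, CsE, CsP, pKa and
logP; each predictor is entered through whichever of four transforms —
raw, reciprocal, exponential, base-10 logarithm — has the largest
absolute Pearson correlation with the outcome (ties broken raw <
logarithm < reciprocal < exponential; transforms whose domain is violated
by non-positive values are skipped); then backward elimination repeatedly
drops the predictor with the largest Wald p-value ≥ 0.05 and refits. The
Wald test is realized as the OLS coefficient t-test on `n − p − 1`
degrees of freedom, the standard regression-output form at these sample
sizes. `published_model()` is one frozen instance of this workflow: CsE
logarithmic, all other predictors raw, with the reported diagnostics
(adjusted R² 0.75, training MSE 0.094 over 7 drugs, validation MSE 0.382
over 4 held-out drugs) carried as metadata. The experimental `Dk`
observations behind those numbers are not distributed with the package,
so they are metadata, not recomputable quantities; every diagnostic the
package itself reports is computed from data it can generate.

Numerical choices:

* **The exponential transform is `exp` of the z-scored predictor** (the
  centering and scale are stored in the model and reused at prediction
  time). Raw-scale `exp` overflows for MW ≈ 500; z-scoring keeps it
  finite, and Pearson-based selection is unaffected by monotone-linear
  rescaling of the input.
* **Rank-deficient designs fail loudly**, naming the aliased predictors,
  rather than silently dropping columns.
* **Rows are drug × excipient combinations treated as independent.**
  Within-drug correlation is real (four of five predictors are
  drug-level) and is not modeled; this mirrors the source workflow and is
  the main caveat on the reported standard errors.

### What transform selection can and cannot do

Univariate Pearson selection compares `|cor(f(x), y)|` across transforms
`f`. When `y` is generated from a single predictor with a clear signal,
the generating transform wins essentially always: at a 20:1
signal-to-noise ratio, selection is correct in ≈100% of replicates for
all five predictors (this is the scenario the package's acceptance checks
run, at n = 50, 200 replicates per predictor). But in multivariate data
the other predictors act as noise on `y`, and for a *weak* predictor the
margin between transforms collapses: raw `x` and `exp(z(x))` of a uniform
variable correlate at ≈0.97, so the population margin is ≈3% of that
predictor's already-small correlation — far below sampling noise at
n = 42. A noiseless multivariate table can therefore still draw the wrong
transform for a weak predictor, after which its coefficient lives in the
wrong basis. Consequences adopted in this package:

* `fit_qspr(..., transforms = )` accepts a fixed transform specification,
  and coefficient-recovery studies supply the generating spec: they test
  the regression machinery, which is the part with a testable contract.
* Transform *selection* is validated on single-predictor designs, the
  only regime where the method is statistically meaningful.
* The comparators reuse the linear workflow's transform spec by default,
  so all three models see identical design matrices.

### What backward elimination does at small n

With 42 rows, 0.3 log-units of noise and the default property ranges, the
weak predictors (CsP, pKa, logP) have Wald power of roughly 25–55%, so
elimination removes at least one of them in most replicates — retaining
all five happens only a few percent of the time. This is a fact about
power at that design size, not a defect: the laboratory finding that no
variable was excluded is a statement about its particular data, not a
property the workflow guarantees. The package therefore keeps the
pre-elimination (full-design) fit in `$full` — coefficients, standard
errors, p-values and 95% confidence intervals for all candidates — and
calibration is assessed there: across 200 synthetic replicates each
coefficient's 95% CI covers its generating value ≈91–97% of the time.
Elimination behavior itself is tested by its contract: a pure-noise
predictor appended to the generator is dropped in well over 90% of
replicates.

## Synthetic data: what it emulates, what it does not

`simulate_release()` produces cumulative curves under three regimes:

* **zero_order** — the ideal saturated reservoir, `Mt = rate·t`.
* **burst** — adds `B·(1 − exp(−t/τ))`: an implant whose membrane was
  pre-saturated during storage releases an early excess that saturates at
  `B`. The saturating-exponential form is this package's choice; the
  phenomenon is qualitative in the literature and no functional form is
  established. Defaults used in the worked analyses (B = 5 mg, τ = 3 d,
  i.e. the excess is spent within the first two weeks) are illustrative.
* **depletion** — zero-order until cumulative release reaches
  `loading − CsE·V_res` (the excess solid is exhausted), then first-order
  decay of the remaining dissolved mass with rate constant
  `Dk·A/(L·V_res)`. This is the same membrane conductance acting on a
  now-falling reservoir concentration, so the rate is continuous at the
  changeover and the curve asymptotes to the loading, never exceeding it.
  The reservoir volume defaults to the tube's inner volume.

**Noise model.** Measurement noise is additive Gaussian on each
*cumulative observation* (default), then the series is monotonized by
running maximum. A per-interval option (`noise_model = "interval"`) adds
noise to each interval mass before accumulation — arguably closer to how
an assay propagates error, but the accumulated error is then a random
walk, the OLS slope standard error understates the true uncertainty
(measured 2-SE coverage drops from ≈90–95% to ≈38%), and
uncertainty-calibrated checks are meaningless. The observation model is
the default precisely so that `estimate_dk()`'s standard errors mean what
they say on simulated data; analyses of real dissolution data should
treat the reported SE as a lower bound.

`sample_to_intervals()` and `accumulate_samples()` are exact inverses at
the sampling schedule, reproducing the dissolution-protocol bookkeeping
(concentration × buffer volume per interval, running sum, cumulative /
elapsed days). The default schedule is twice-weekly (3.5-day spacing).

`generate_qspr_table()` draws drug-level properties uniformly
(log-uniformly for the solubilities) from ranges bracketing the packaged
tables — MW 229–535 Da, CsP 0.0071–165.6 mg/mL, pKa 2.65–17.9, logP
−1.4–3.8, CsE 0.01–76 mg/mL — and sets `log10(Dk)` to the generating
model's prediction plus `N(0, 0.3²)` noise by default; 0.3² ≈ 0.09
matches the scale of the reported training MSE. The default table size,
7 drugs × 6 excipients = 42 rows, mirrors the laboratory panel.

What passing these checks does **not** show about real data: synthetic
properties are independent across drugs (real chemistry correlates MW,
logP and solubility), rows are exchangeable within drug (real replicates
share implant lots and assay days), and noise is homoscedastic Gaussian.
Recovery and calibration results here validate the estimators under the
model's own assumptions, not the assumptions themselves.

## Comparators

The SVM (radial kernel, ε-regression, standardized inputs) and random
forest (500 trees, p/3 feature subsampling) comparators use
`e1071` and `randomForest` defaults; no kernel or hyperparameters are
prescribed by the workflow being reproduced, so they are surfaced as
arguments rather than hidden, and both fits are seeded. On synthetic
splits the pattern matches the laboratory one: all three models are
comparable on training rows, and the linear equation generalizes best to
drugs outside the training panel — kernel and tree models cannot
extrapolate a linear trend beyond their support at n = 42.

Evaluation uses mean squared error on `log10(Dk)` plus the fraction of
predictions within 0.5 and 1 log10 of the observations (a 0.5-log band
spans roughly a 1/3×–3× fold range); adjusted R² is reported when the
model's degrees of freedom are supplied.

## Problem sizes and determinism

Every stochastic check fixes its seed, and every generator is a pure
function of (parameters, seed). The shipped analyses and checks use:
200 replicates for calibration and selection studies, 42-row training
tables, 1,000 random draws for the physics identities, 20–40 seeded
simulations for release-curve recovery. These sizes put Monte-Carlo error
comfortably below the tolerances being asserted while keeping any run in
minutes on one core.

## Known limitations

* `Dk` is a lumped empirical parameter: no mechanistic decomposition, no
  temperature or polymer-molecular-weight dependence.
* The QSPR equation is an interpolation over its training chemistry;
  extrapolating far outside the property ranges above is unvalidated.
* Burst and depletion simulators are phenomenological; their parameters
  are not identified from any packaged data.
* The excipient-solubility table covers only the training drugs; the
  validation drugs' `CsE` values are not distributed, so
  `property_grid(fx, "validation")` is empty and validation-drug release
  predictions require user-supplied solubilities.
* In vivo pharmacokinetics, implant fabrication variability, and assay
  chemistry are out of scope.
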