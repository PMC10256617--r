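---
title: "Methods: simulating and comparing co-deployed porpoise click detectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and comparing co-deployed porpoise click detectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Autonomous echolocation click loggers (the C-POD and its successor the
F-POD) are the workhorses of harbor porpoise monitoring. When a monitoring
program swaps one detector generation for the next, two questions decide
whether its time series stays interpretable: *by how much* do the devices
differ in detection capacity at each temporal scale, and *do they recover
the same ecological structure* (seasonal, diel, tidal and environmental
patterns of occurrence and foraging) despite that difference. `podcompare`
implements the full analysis chain needed to answer both questions for a
co-deployed detector pair, together with a ground-truthed simulator so that
every stage is testable without field data.

The chain is: simulate (or import) click-train detections for two
co-located devices; aggregate them into detection-positive minutes, hours
and days (DPM/DPH/DPD) and click counts (NClx) under nested train-quality
filters (Hi ⊂ HiMod ⊂ HiModLo); classify foraging buzzes from inter-click
intervals with a Gaussian mixture on the log scale; build hourly
environmental covariates; and fit negative-binomial additive models of
hourly occurrence and foraging rate with AR(1) residual structure.

## The simulator: what it emulates, and what it does not

The generator is a hierarchy of standard point-process components with
every latent quantity retained as ground truth.

**Occupancy.** Encounter starts follow an inhomogeneous Poisson process
(simulated by thinning) whose rate is a product of a base rate
(0.2 h^-1 by default), a cyclic month multiplier peaking in autumn
(amplitude 0.5) — the seasonal pattern typical of inshore porpoise sites —
a diel-period multiplier, and a cyclic multiplier in time-to-high-water.
Durations are exponential (12 min mean); an encounter is truncated at the
next start, which keeps the start process's instantaneous rate exactly
equal to the specified product (a property the tests use).

**Click trains.** Within an encounter, trains are separated by lognormal
inter-train gaps (~20 s median). Each train is a buzz train with
probability `buzz_train_probability` (0.2 by default); its inter-click
intervals are lognormal on the log10-millisecond scale around 5 ms
(buzz — below the canonical 10 ms foraging-buzz boundary) or 60 ms
(regular). Every click carries its behavior label. This collapses the
within-train structure of real trains (a terminal buzz at the end of an
approach) into whole-train regimes; the classification problem it poses —
separating three lognormal ICI regimes — is the one the mixture stage
actually solves, but the package cannot be used to study within-train buzz
onset.

**Observation model.** Each true click is detected independently with
probability `plogis(qlogis(p_click) + noise_slope * z)`, where `z` is the
standardized per-minute Nall (the count of unfiltered click-like events,
the field's noise proxy). Nall itself is a shared lognormal AR(1) ambient
series plus the true clicks emitted that minute, so porpoise activity
raises the noise proxy, as it does on real devices. Detected clicks of a
train register as an observed train when at least `min_clicks_train`
(default 5) survive; the Hi/Mod/Lo quality label is drawn from a
categorical table indexed by the train's completeness (detected/true), so
a more sensitive device earns more Hi trains. False-positive trains arrive
as a Poisson process (default ~1–2 per 100 h), mostly labelled Lo — the
range reported for these devices is a few percent of detections, and
keeping them mostly Lo is what makes the Lo-census validation protocol
meaningful. The logistic noise form is a deliberate stand-in: no published
quantitative form exists for how detection probability decays with noise,
only the qualitative contrast that the older device suffers more.

The default C-like profile (per-click sensitivity 0.15, strong negative
noise slope) and F-like profile (0.85, weak slope) reproduce the
qualitative field pattern — the successor detects a large multiple of the
clicks, more detection-positive time at every scale, detections on almost
all days for both, and a much larger share of buzz clicks — without being
calibrated to any particular deployment's numbers. Passing tests on this
generator demonstrates that the *pipeline* is correct, not that any real
detector pair differs by these particular amounts.

**Time.** All timestamps are UTC `POSIXct` with microsecond resolution;
minutes/hours are half-open clock-aligned bins, so "detection-positive
minute" has one unambiguous meaning throughout.

## Detection metrics and comparison statistics

A minute is detection-positive iff a train of the chosen quality grouping
overlaps it; by default a train occupies every minute between its first
and last click (`span = "start"` restricts to the start minute, for
comparison with exports that bin trains by start time — which convention a
given export uses is not always documented, so both are supported). DPM
per hour (0–60) rolls up to DPH per day (0–24) and DPD. Effort is
explicit: unmonitored minutes never enter denominators, and detection
rates are reported as `100 × positive / monitored` bins per season or
month, so periods with unequal recording effort are comparable.

Device agreement is summarized by Kendall's tau-b between the paired
series at each metric's native scale (hourly DPM and NClx, daily DPH and
DPD), by the detection ratio `CF = Det_F / Det_C` (overall and per
season), and by matched/unmatched positive-hour proportions. The tau point
estimate comes from `stats::cor`; the p-value uses the tie-corrected
normal approximation of the concordance statistic without continuity
correction, switching to exact permutation enumeration for n ≤ 8 (base R's
`cor.test` has no exact path under ties). The brute-force pair-counting
oracle in the test suite is an independent implementation.

## Foraging-buzz classification

Within-train ICIs, pooled with inter-train gaps so the pause regime is
identifiable, are log10-transformed and fitted with a univariate Gaussian
mixture by EM (multi-start, quantile-based initialization, restart with
jitter on degenerate components, stop at a log-likelihood gain below 1e-8
or 500 iterations). The component count is chosen by BIC over K ∈ {2,3,4}
by default: published ICI analyses name three behavioral categories but
fix neither K nor a selection criterion, so selection is left to the data;
an option restricts the fit to within-train ICIs only. Parameter
estimation subsamples at most 20,000 intervals (a univariate mixture has
at most 11 free parameters; beyond ~10^4 samples the estimates are stable
to well below the reporting precision) — classification always uses every
interval.

Behavior labels are assigned per component: every component whose mean ICI
is below 10 ms is the buzz regime — assignment is by *cluster*, not by
thresholding individual intervals, though a pure-threshold mode exists for
cross-checking — the largest-mean component is inter-train, the rest
regular. Posterior ties go to the lower-mean component. Buzz-positive
minutes (BPM) and hours (BPH) aggregate like DPM, and the hourly buzz rate
is `100 × BPM / DPM`, *missing* (not zero) where DPM = 0: an hour without
detections carries no information about foraging intensity.

## Covariates

Diel phases partition each day from a supplied sun table: morning spans
civil dawn to one hour after sunrise, day to one hour before sunset,
evening to civil dusk, night the rest. The ±1 h offsets are configurable;
published diel definitions vary and these defaults are documented choices,
not claims about any prior analysis. Tidal covariates come from a high/low
water table: signed hours to the nearest high water (negative before — the
sign convention is declared in output metadata since conventions differ),
phase (high/low within ±0.5 h of the event, else flow/ebb), and tidal
range (height difference between the nearest high and its adjacent low on
the side of the timestamp) as the spring/neap indicator. Device
temperature is pooled as the mean of the two devices' hourly means —
POD temperature is relative, so no absolute calibration is attempted —
and hourly noise is the mean (configurable: median/sum) of per-minute
Nall. Seasons are meteorological: spring = Mar–May, summer = Jun–Aug,
autumn = Sep–Nov, winter = Dec–Feb. Every hour of the effort period gets a
covariate row or an explicit missingness flag.

## The hourly additive models

The occurrence response is DPM per hour (a 0–60 count); the foraging
response defaults to hourly BPM with a `log(DPM)` offset on DPM-positive
hours — a statistically coherent way to model a rate with count error —
with a secondary mode that rounds the percentage buzz rate to an integer
and fits it directly as a count, for comparability with analyses that did
exactly that. Both are negative binomial with log link (hourly detection
counts are strongly zero-inflated and overdispersed).

The linear predictor combines a diel-period factor (reference level
`day`), cyclic smooths for month (basis dimension 12, wrapping at the year
boundary via explicit knots at 0 and 12) and time-to-high-water (k = 8,
wrapping at ±6.21 h, half a semidiurnal cycle), and shrinkage thin-plate
smooths (k = 10) for temperature, noise and tidal range, which can shrink
a null term to ~0 effective degrees of freedom. Fitting is two-step:

1. an uncorrelated penalized-likelihood fit (`mgcv::gam`, REML) profiles
   the NB dispersion θ; the lag-1 autocorrelation of its residuals
   (computed within contiguous hourly blocks — service gaps reset the
   recursion) gives ρ, clipped to [0, 0.99];
2. the final fit (`mgcv::bam`, fast-REML with discrete covariate methods)
   holds θ fixed and applies the AR(1) structure by whitening successive
   observations with ρ. `bam` only honours an AR(1) ρ for non-Gaussian
   families under its discrete fitting path, which is why that path is
   used.

The smoothing criterion is penalized likelihood ((f)REML) with the penalty
inflation γ = 1.2 that guards against overfitting splines; analyses in
this literature have used GCV with manually chosen knots instead — the
criterion is stated in the fit metadata, and basis dimensions are
configurable precisely because knot choice is subjective. Model quality is
reported as deviance explained and AUC (presence = count > 0, score =
`1 − P(NB(μ̂, θ) = 0)`, midrank rank statistic). Per-term concurvity
(`mgcv::concurvity`, 0 = independent, 1 = confounded) screens the smooths.
Stepwise selection drops the least significant term with p ≥ 0.05, refits,
and keeps the change only if AIC does not increase; θ and ρ are estimated
once on the full model and held fixed across candidate refits so AIC
differences reflect the terms, not re-profiled nuisance parameters. The
effect table mirrors conventional model summaries: the summary test
statistic per term, a sign (for a smooth, the sign of its average fitted
slope over the observed range), and strength symbols by statistic
magnitude.

### A note on AR(1) whitening diagnostics

For count data the lag-1 autocorrelation of *residuals* is an attenuated
version of any latent AR(1) coefficient on the log mean: the conditional
count noise is serially independent, so residual ACF ≈ a·σ²_ε/(σ²_ε+σ²_n).
Whitening with the latent coefficient therefore over-corrects whenever
count noise is non-negligible (at θ = 2 and low means the whitened lag-1
ACF sits near −0.07 rather than 0). The package's recovery check for
whitening correctness is accordingly run in an AR-dominated regime (high
mean, θ = 500), where whitening with the generating coefficient leaves
|ACF(1)| well inside ±0.05; for real fits ρ is estimated from the observed
residual ACF, which is the quantity whitening actually needs.

## Numerical choices and degenerate inputs

Detection draws for a detector use a uniform stream drawn before any other
profile-dependent randomness, so two profiles applied to the same truth
with the same seed are coupled: higher sensitivity detects a superset of
clicks (the monotonicity property tests rely on this). EM restarts with
jittered means when a component's weight or sd collapses; an all-starts
failure is reported as a flagged fit. `detectionRatio` returns missing
(with a warning) on a zero denominator; constant series give a missing
tau; single-class presence gives a missing AUC; zero monitored bins give a
missing rate. Exports are ISO-8601 with microseconds and round-trip
exactly at microsecond resolution; out-of-order files are an error unless
sorting on read is requested explicitly.

## Problem sizes

The test-suite simulations use a 60-day shared co-deployment, a 1000-day
two-detector experiment for ratio recovery (sparser 12-click trains so
train registration does not saturate at either sensitivity), 3000-sample
mixture recoveries, and 10,000-hour model recoveries; replicated
selection/shrinkage properties use 10–15 replicates at 2500–4000 hours.
These sizes put Monte-Carlo error well below each check's acceptance band
while keeping a full run of the suite within a few minutes.

## Known limitations

- Whole-train buzz regimes: no within-train behavioral transitions.
- The noise–detection logistic is a stand-in form, not a calibrated model
  of any real detector; conclusions about *this* simulated pair do not
  transfer to hardware.
- Train quality is simulated from completeness, not re-derived from click
  features; the proprietary train classifiers are out of scope.
- One site, no spatial structure, no propagation modeling, no waveforms.
- The foraging model's offset formulation conditions on DPM > 0 hours;
  hours where presence went undetected contribute nothing to foraging
  inference.
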