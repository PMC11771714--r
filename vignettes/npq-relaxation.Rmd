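---
title: "Phenotyping NPQ relaxation kinetics and pricing slow relaxation at the canopy scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping NPQ relaxation kinetics and pricing slow relaxation at the canopy scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npqdyn)
```

## The measurement and the model

Leaves dissipate excess absorbed light as heat through non-photochemical
quenching (NPQ). When light drops — a cloud passes, a leaf swings into
shade — NPQ does not switch off instantly, and the residual quenching
wastes light that could drive photosynthesis. `npqdyn` implements the full
analysis chain for a leaf-disk phenotyping assay of NPQ relaxation: dark
adapted leaf disks are exposed to a low–high–low actinic sequence (10 min
at 50, 15 min at 2000, 50 min at 50 µmol m⁻² s⁻¹) while saturating pulses
(4000 µmol m⁻² s⁻¹) measure the light-adapted maximal fluorescence Fm′.
At every pulse

$$\mathrm{NPQ}(t) = \frac{F_m}{F_m'(t)} - 1,$$

with $F_m$ from overnight dark adaptation (the Stern–Volmer definition;
the magnitudes it produces are the ones the assay's published summaries
report). Disk health is screened with $F_v/F_m = (F_m - F_0)/F_m$.

The decay of NPQ after the high→low transition is decomposed into three
canonical components — fast energy-dependent quenching qE (τ below ~2 min),
an intermediate pool qM (2–30 min, a mixture of xanthophyll-cycle and
state-transition processes that we do not attempt to separate), and a slow,
effectively constant photoinhibitory term qI — by least-squares fitting of

$$\mathrm{NPQ}(t) = A_{qI} + A_{qE}\,e^{-t/\tau_{qE}} + A_{qM}\,e^{-t/\tau_{qM}},$$

with $t$ in minutes from light-off. Maximum NPQ is the largest value
observed during the high-light phase.

## Fitting: bounds, starts, and the light-off anchor

The fit (`fit_relaxation()`) uses bounded Levenberg–Marquardt with
amplitudes ≥ 0, $\tau_{qE} \in (0.05, 10]$ and $\tau_{qM} \in (2, 120]$
min. The bounds prevent component swapping; components are relabeled after
fitting so $\tau_{qE} < \tau_{qM}$, with AIC-style ties broken toward the
smaller $\tau_{qE}$. Five parameters are started from a heuristic
($A_{qI}$ ← last relaxation point; the first-point excess split 55/45
between $A_{qE}$ and $A_{qM}$; τ = 1 and 20 min) plus six dispersed
restarts, and a coarse profiled grid over the two time constants (with
non-negative linear amplitudes at each grid point, then one more LM
polish) guards against local minima. Convergence tolerances are 10⁻¹⁴ on
cost and parameters; best residual sum of squares wins.

One choice deserves emphasis. The relaxation pulses sit at 2.5, 5, 10, …,
50 min, so only the single 2.5-min point carries appreciable qE signal.
A Fisher-information calculation for this schedule with multiplicative
pulse noise of 2% (so σ on NPQ grows as $1+\mathrm{NPQ}$) puts the
attainable relative standard error of $\tau_{qE}$ at roughly **266%**:
the fast time constant is essentially unidentified from the relaxation
pulses alone. The decay the model describes, however, starts at the
light-off instant, and its value there is measured by the last high-light
pulse. Including that value as a $t = 0$ anchor (the default,
`include_light_off = TRUE`) pins the amplitude sum and brings the
information bound to ~24%, i.e. a median absolute error floor of ~16% per
disk. This is a genuine property of the assay design, not of the solver:
per-disk $\tau_{qE}$ is noisy, and reliable genotype comparisons come from
averaging disks, plots and days, which is how the downstream statistics
use it. A simulated calibration (200 seeds, 2% noise) reproduces the
bound: median $|\hat\tau_{qE}-\tau_{qE}|/\tau_{qE} \approx 18\%$, with
per-parameter biases ≤ ~5%.

Quality control follows the assay's two published rules: disks with
$F_v/F_m < 0.75$ are excluded, as are disks whose fitted parameters contain
any negative value; exclusions are logged with reasons, and technical
replicates are averaged to plot level before statistics.

## Weather covariates

30-minute weather records are condensed to per-day covariates
(`daily_env_features()`): the 10:00 snapshot of air temperature, VPD and
shortwave radiation, precipitation summed from midnight to 10:00, and
3-day aggregates. VPD uses the Tetens saturation curve,
$e_s = 0.6106\,\exp(17.27\,T_a/(237.3+T_a))$ kPa, evaluated per 30-min
record *before* any averaging. The "past 3 days" is ambiguous in common
usage; the default here is the 3 complete calendar days preceding (and
excluding) the day, with an include-current-day variant available
(`window = "include"`). Gap filling is linear interpolation with
nearest-value extension at the boundaries and per-record flags — at the
gap rates such stations produce (a few percent), the method is immaterial.

## The inference layer

* `anova_gxe()` — sequential (type-I) ANOVA of
  `parameter ~ Day + Genotype + Day:Genotype` on plot-level data, day
  categorical. Its genotype F-test is exactly calibrated when plot effects
  are absent or modeled; persistent plot effects across repeated sampling
  days inflate it (classic pseudo-replication), which is precisely why the
  genotype screen below uses a mixed model instead.
* `stepwise_env_model()` — both-direction stepwise AIC over centred/scaled
  environmental covariates from an all-covariate start, refusing
  numerically collinear blocks (condition number > 10⁸).
* `run_cca()` — canonical correlation via SVD of the whitened
  cross-covariance, with Wilks' Lambda and Rao's F approximation per axis;
  morning temperature is conventionally excluded from the environment
  block for collinearity with its own 3-day mean.
* `pca_by_day()` — per-day PCA of the scaled parameters, genotype-mean
  coordinates, |z| > 2.5 outlier labels, and a one-way group ANOVA per
  component.
* `mixed_model_screen()` — the genotype screen. For each genotype and each
  modeling scenario it compares, by ML-AIC (maximum likelihood, because
  the fixed-effect structure changes between the full and null models),
  the full mixed model (all genotype indicators, treatment-coded against
  the reference line RC, plot random intercept) against the null model in
  which that genotype is merged into the RC baseline. A genotype is
  flagged only if the full model wins in *every* usable scenario and the
  sign of its coefficient agrees throughout. With one measurement per leaf
  disk, a disk random intercept is confounded with the residual, so "plot
  and disk" random effects reduce to a plot intercept with the disk as the
  residual level. The default scenario set crosses the data subsets (each
  year, plus both combined) with two fixed-effect structures: a
  sampling-day factor, or the daily environmental covariates in its place
  — the covariates are day-level quantities and cannot enter alongside a
  free day factor. Both the scenario list and the minimum number of usable
  scenarios are arguments.
* `genotype_mean_correlations()` — per-parameter Pearson correlation of
  genotype means between two tables (two seasons, or a season against an
  external trait such as yield).

Calibration, verified by the acceptance suite under the synthetic
generator: genotype-term type-I error 0.05 ± 0.02 (500 null data sets);
screen false-flag rate ≤ 5% (the six-scenario unanimity rule is the
safeguard — two scenarios on the same subset are highly correlated, but
the per-year subsets are independent); power ≥ 90% for a −0.10 shift in
$A_{qI}$ at 5 plots × 5 disks × 6 days with plot SD 0.03 and disk SD 0.05.

## The synthetic-data generator

Every stage is testable without any external data because the generator
produces inputs with known truth. Traces invert the NPQ definition,
$F_m'(t) = F_m/(1+\mathrm{NPQ}(t))$, with multiplicative Gaussian noise
(fluorescence noise scales with signal); induction under high light is a
single exponential toward the amplitude sum (the relaxation fit never sees
it, so the simplest shape that makes max-NPQ extraction meaningful
suffices). Experiments add, per disk, a genotype shift, a linear response
to the centred/scaled daily weather features, and Gaussian plot and disk
random effects; plots are re-randomized every season, so plot effects are
nested within year — without that nesting, a genotype's lucky plot draw
persists across years and masquerades as a consistent genotype effect
(simulations then show ~17% false flags instead of ~2%). Weather is a
sinusoidal diurnal cycle with autocorrelated day anomalies, humidity
anticorrelated with temperature, cloud-attenuated clear-sky radiation and
seeded precipitation events. Every stochastic function takes an explicit
seed and leaves the global RNG untouched.

What the generator does *not* emulate: induction biochemistry, image-level
fluorescence, spatial field structure beyond plot intercepts, weather
extremes, or measurement drift. Passing tests therefore demonstrate the
correctness and calibration of the *pipeline*, not the biology of any
particular field season.

## The dynamic canopy model

`simulate_canopy()` prices slow NPQ relaxation in daily carbon. Per leaf
pixel, a minimal dynamic layer sits on top of Farquhar–von Caemmerer–Berry
biochemistry ($A = \min(W_c, W_j) - R_d$, intercellular CO₂ held constant
to isolate the kinetics from stomatal dynamics): the fast and intermediate
NPQ pools relax toward light-dependent targets with $\tau_{qE}$ and
$\tau_{qM}$ (induction at half those constants by default), qI rides along
as a persistent baseline, and Rubisco activation follows first-order
kinetics with deactivation twice as slow as activation (default
$\tau_{act}$ = 4 min). Excess NPQ penalizes the light-limited drive
through $f = (1+\mathrm{NPQ}_{ss})/(1+\mathrm{NPQ}(t))$, capped at 1, and
assimilation is additionally capped at the steady-state rate for the
instantaneous light (surplus activation carried over from brighter moments
cannot be exploited — RuBP regeneration limits it). Integration is
exponential-Euler — exact for a constant target over a step and
unconditionally stable — at Δt = 10 s (60 must be divisible by Δt);
halving Δt changes daily totals by < 0.1%. Canopy uptake is
$A_c(t) = \sum_i A_i(t)\,S_i/S_{ground}$, integrated trapezoidally over
the day.

Light drivers: `synth_par_day()` generates a 1-min incident PAR series
(05:00–19:00) for a clear day or a broken-cloud day (two-state cloud
process, mean episode 8 min, overcast transmission 0.1–0.3, seeded), and
`make_toy_canopy()` spreads it over a layered synthetic canopy (default
LAI 5.5, extinction 0.7, absorptance 0.85) in which each pixel alternates
between sunlit and attenuated-shade states on a ~2-min sunfleck scale,
with a self-shading depth offset of 0.5 so even top-of-canopy pixels are
sunlit only ~78% of the time. These are synthetic stand-ins chosen for
realism, not measured traces.

**Known limitation.** Comparing the fastest
($\tau_{qE}=0.93,\ \tau_{qM}=19.95$) and slowest
($\tau_{qE}=1.29,\ \tau_{qM}=29.23$ min) kinetic extremes of the SoyNAM
founder panel, this minimal model yields a ~0.4–0.7% difference in daily
canopy assimilation (cloudy days larger than sunny, as expected — cloud
passages are long enough to expose the qM pool). Full dynamic
electron-transport models report ~1.6% (cloudy) and ~1.1% (sunny) for the
same kinetic spread. A ceiling experiment (single leaf, square-wave light
at the most sensitive shade level) shows the capped quantum-yield penalty
cannot exceed ~0.7% for this τ range, so the gap is structural to the
simplified leaf model, not a parameterization issue; the acceptance suite
states the published values and documents the shortfall rather than
tuning toward them. Relative orderings — monotonicity of loss in each τ,
cloudy > sunny, zero loss without fluctuations — are robust and tested.

## Numerical choices and degenerate inputs

* Constant relaxation series collapse to $A_{qI}$ = the constant,
  amplitudes 0 (via the profiled grid, since the gradient there is
  singular for LM).
* Fits are deterministic and invariant to row shuffling (pulses are
  sorted by time before fitting).
* `qc_filter()` is idempotent, and survivors + exclusions always add to
  the input count; plots with zero surviving disks are dropped with a
  warning, never imputed.
* Zero-variance columns are dropped (with a warning) before CCA;
  rank-deficient blocks lose dimensions rather than erroring.
* AIC ties (|Δ| < 10⁻⁶) resolve toward the smaller model.

## Problem sizes

The shipped test and acceptance runs use compact designs chosen to finish
in minutes while keeping every Monte-Carlo margin wide: 200-seed recovery
studies, 500 null data sets for the ANOVA calibration, 100 seeds each for
screen power and false-flag rates (4 genotypes × 5 plots × 5 disks × 6
days across two seasons), a 7-genotype end-to-end pipeline reproduction,
and 40-pixel canopy days. All of them scale up by changing arguments.
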