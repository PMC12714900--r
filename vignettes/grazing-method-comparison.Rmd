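---
title: "Evaluating grazing-rate estimators against a known-truth community model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating grazing-rate estimators against a known-truth community model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micrograze)
```

## Why a known-truth testbed

The dilution technique and the FLB-disappearance method are the two
workhorse field estimators of protistan grazing mortality on
picoplankton. Both rest on assumptions that cannot be verified in a field
sample: the dilution technique assumes grazers clear water at their
maximal rate at every dilution level (so that diluting prey reduces
encounters proportionally), and the FLB method assumes the surrogate prey
is consumed at the same per-capita rate as natural prey. `micrograze`
provides a community simulator in which the true grazing and lysis rates
are known exactly, so both estimators can be run as virtual experiments
and scored against truth.

## The community model

The truth layer is a deterministic system of coupled ordinary
differential equations with eight state variables: uninfected prey `P`,
infected prey `I`, grazers `G`, free viruses `V`, heterotrophic bacteria
`B`, FLB tracer `F`, and a dissolved organic matter pool `DOM`, plus a
cumulative loss ledger. Units are days and cells mL⁻¹ throughout.

* **Grazing.** The grazer has a type-II (saturating) functional response
  over its total edible pool `P_tot = P + I + pref_B·B + s_FLB·F`:
  effective clearance is `c_max / (1 + P_tot / K_sat)`, so per-grazer
  ingestion is `c_max·P_tot` at low abundance and saturates at
  `c_max·K_sat` cells grazer⁻¹ d⁻¹. Grazers convert ingestion to growth
  with gross growth efficiency `Y_G` and decline at background rate
  `d_G`.
* **Viral lysis.** Adsorption at rate `phi·V·P` moves prey into an
  explicit infected class; infected cells lyse at rate `1/tau` releasing
  `beta` virions. Infected cells remain countable prey (flow cytometry
  does not distinguish them), so counted prey is always `P + I`.
* **Cryptic bacterial growth.** Unassimilated grazed biomass and lysed
  cells feed `DOM`; bacteria grow on it with Monod kinetics
  (`mu_B_max`, `k_DOM`) and are themselves grazed with preference weight
  `pref_B`. This reproduces the late-incubation confounding in which
  byproduct-fueled bacteria become an alternative food source.
* **Tracer.** `F` has no growth term, is cleared at `s_FLB` times the
  prey-specific clearance, and additionally decays at `w` (non-grazing
  losses; the only loss term in grazer-free control bottles).
  `s_FLB = 1` encodes the FLB method's core assumption; `w` is what the
  control bottles correct for.

The **loss ledger** integrates prey births, grazing losses and lysis
losses alongside the state. `true_mortality()` converts ledger increments
over a window into per-capita rates by dividing by the log-mean prey
abundance times the window length; under exponential decline this equals
the instantaneous specific rate, making the ledger the recovery oracle.
A balance test (`births − losses` against the prey change) closes to
within 10⁻⁴ relative tolerance.

Demographic stochasticity is deliberately excluded from the truth layer:
all randomness lives in the sampling model (Poisson counting noise with
mean `abundance × analyzed_volume`), so estimator error can be attributed
cleanly to counting noise and to assumption violations. Integration uses
`deSolve::ode` (lsoda) at a relative tolerance of 10⁻⁸ with states
clipped at zero; the grazer/virus-free limit reproduces exponential
growth to better than 10⁻⁶ relative error.

## Virtual experiments

`dilute_state()` multiplies all particulate compartments by the retained
fraction of whole water. The dissolved pool is *not* diluted: the diluent
is nutrient-replete medium, so dissolved resources are never limiting and
prey intrinsic growth is dilution-invariant by construction — the regime
the laboratory design achieves with replete media and the field design
approximates with nutrient amendment.

`make_dilution_series()` defaults to the laboratory fractions
{1.0, 0.8, 0.4, 0.2} of whole water ("undiluted, 20%, 60%, 80% diluted");
field mode uses {0.25, 0.50, 0.75, 1.0} and can read bottles out as a
chlorophyll-like bulk proxy (a yield-weighted sum over phototroph
compartments) instead of cell counts. `make_flb_experiment()` spikes the
tracer at a fraction of prey abundance (default 0.25, within the 20–30%
laboratory design) or at a fixed field abundance (5 × 10⁴ mL⁻¹ preset),
and builds grazer-free control bottles containing tracer alone.
Incubation duration is an explicit parameter everywhere: real protocols
choose 3–12 h case by case depending on how fast abundances are moving,
and we found no principled single rule to hard-code, so scenario defaults
state their choice instead (6 h for laboratory windows, 12 h for the
recovery studies, 24 h for field mode).

## Estimator conventions

Several conventions that published protocols leave implicit are made
explicit and configurable:

* **Dilution axis and sign.** Regression is of apparent growth on the
  *fraction of whole water* `D ∈ (0, 1]`; mortality is `m = −slope`,
  reported positive. "20% diluted" means `D = 0.8`.
* **Non-detect rule.** "Undetectable from zero" is operationalized as a
  two-sided test at `alpha = 0.05`: the slope *t* test for regressions
  (detectable additionally requires a negative slope); a one-sample *t*
  test of replicate rates against zero for replicate-based rates (FLB,
  observed) when `n ≥ 3`; and a Poisson counting *z* test on pooled
  counts otherwise. Non-detects are reported as 0, as summaries expect,
  but the signed computed rate is always preserved (`raw_value`) for
  audit, including negative control-corrected FLB rates.
* **Replicate handling.** The Model I regression is unweighted OLS on all
  replicate points (not replicate means). The two-point variant uses
  replicate means at the two fractions; its detectability is a Welch
  two-sample *t* test of apparent growth between the two fractions, the
  natural replicate-based analogue when no regression residual exists.
  Whether real analyses pool points or average replicates is rarely
  stated; on exact linear data the choices coincide, and both routes are
  exposed for sensitivity checks.
* **Zero counts** are an error, not an infinite rate; an optional
  pseudo-count floor can be enabled deliberately (`pseudo_count`),
  never silently.
* **Comparison metrics.** Percent difference is undefined when the
  observed rate is a non-detect (0); such windows are excluded with a
  recorded reason rather than dropped silently. Outliers are removed per
  method with Tukey fences at `k = 1.5` (configurable). Abundance bins
  are half-open `[lo, lo + width)` at a default width of 0.5 log₁₀ units.
  Curve alignment defaults to a reference of log₁₀ = 5.6 — roughly midway
  through the crash — with the reference exposed as a knob (5.5 is a
  defensible alternative and some analyses use it). Window slopes are
  fitted on the open interval (4.5, 6.5) in log₁₀ abundance, where the
  decline is log-linear; above it grazers are still rare relative to
  prey, below it bacterial byproduct feeding makes treatments diverge.
* **Multiple testing.** The family for adjustment is the set of per-depth
  method comparisons within one field report; Bonferroni by default, with
  the unadjusted p always reported alongside.

## Scenario defaults and what they emulate

The built-in scenarios are the study conditions, chosen once:

* `lab_high_grazer` (and `_virus`): prey at 10⁷ cells mL⁻¹ with a
  2 × 10³ mL⁻¹ grazer inoculum. Defaults (`mu_P = 0.5` d⁻¹,
  `c_max = 3 × 10⁻⁴` mL grazer⁻¹ d⁻¹, `K_sat = 4 × 10⁶` cells mL⁻¹,
  `Y_G = 0.0025`, `d_G = 0.1` d⁻¹) give a maximal grazer growth rate of
  ~2.9 d⁻¹ and maximal ingestion of ~1200 prey grazer⁻¹ d⁻¹ — within the
  range reported for bacterivorous nanoflagellates — and produce the
  target phenomenology: a ~3 order-of-magnitude prey crash within 48 h,
  log-linear (R² ≈ 0.99) between log₁₀ 4.5 and 6.5, with mid-crash
  mortality near 10 d⁻¹. The low-inoculum variants (5 × 10²) crash
  ~12–15 h later, so suite alignment shifts relative to the high-grazer
  curve span roughly −15 to +1 h. Virus treatments add a lytic phage
  (`phi = 5 × 10⁻⁹` mL d⁻¹, `beta = 40`, `tau = 0.25` d) whose
  contribution stays small next to grazing, as intended.
* `linear_regime`: the ideal-recovery benchmark. `K_sat` is set
  effectively infinite, `Y_G` negligible and `d_G = 0`, so grazers are
  constant and true grazing mortality is exactly `c_max·G = 1` d⁻¹.
  Recovery studies use a 12-h window and 1 mL analyzed volume so every
  expected count is ≥ 10⁴; at that counting depth both estimators land
  within 5% of truth in ≥ 90 of 100 seeded replicates.
* `saturated`: prey at 10 × `K_sat`. Per-grazer ingestion is pinned at
  its maximum, so diluting prey barely changes it and per-capita
  mortality *rises* as `D` falls; the regression slope collapses or
  reverses and the dilution estimate falls below truth essentially
  always — the method's known saturation failure, in the direction
  expected.
* `selective_flb` and the field scenarios: the tracer is cleared at one
  tenth the prey rate (`s_FLB = 0.1`), so FLB estimates read ~10% of
  truth while the dilution estimate remains accurate — a ~10-fold method
  gap of the kind field intercomparisons report. Field scenarios use
  grazer abundances giving true rates of 0.48 and 0.31 d⁻¹ at the two
  depths (typical oligotrophic magnitudes), 24-h incubations, a small
  non-grazing tracer loss (`w = 0.02` d⁻¹) corrected by control bottles,
  and a chlorophyll-proxy readout for the dilution series.
* Light: an optional 14:10 square-wave photoperiod multiplier on `mu_P`
  (rescaled to preserve the daily mean) is available but off by default;
  with it off, windows are comparable regardless of start time, matching
  the absence of a clear light-cycle effect in the data this emulates.

Problem sizes used by the test suite and the acceptance script — 100
seeded replicates per recovery study, hourly trajectory grids, 48
integration steps per bottle — were chosen as the smallest sizes at which
the Monte Carlo summaries are stable to well under the tolerances tested.

## What passing tests do and do not show

The simulator emulates the *structure* the estimators assume: well-mixed
batch bottles, exponential within-bottle kinetics, Poisson counting
noise. Real data add grazer selectivity and satiation dynamics,
within-treatment biological variability between replicate vessels,
cytometer gating error (non-Poisson), and time-varying grazer physiology.
Recovery under this model therefore demonstrates *internal* consistency
of the estimators under their own assumptions — and the bias scenarios
demonstrate directional sensitivity to specific violations — but neither
certifies field accuracy, where several violations co-occur and cannot be
isolated. That limitation is intrinsic to the exercise, not incidental:
it is the reason the known-truth benchmark is informative.

Other known limitations: no multi-strain prey or temperature dependence;
a single aggregate DOM pool; no demographic stochasticity (small-number
extinction effects near the end of a crash are not represented, and the
deterministic crash proceeds below realistic detection floors); and the
infected class is counted as prey with the same cytometric yield, which
slightly flattens late-crash proxy readouts if per-cell fluorescence
actually declines during infection.
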