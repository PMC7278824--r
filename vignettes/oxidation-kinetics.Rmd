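---
title: "Determining autoxidation kinetic parameters from oxygen-uptake isotherms"
author: "oxikin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining autoxidation kinetic parameters from oxygen-uptake isotherms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxikin)
```

## The measurement this package models

A diluted oil sample (by default 1 mL oil in 7 mL high-boiling diluent) is
stirred in a sealed flask under an isotherm, and the oxygen content of the
accessible reservoir — headspace gas plus dissolved O₂ — is followed with a
headspace probe, sampling every 10 s. Because the uptake rate slows visibly
once most of the charge is gone, the vessel is re-aerated whenever about 75 %
of the O₂ has been consumed, and the acquisition continues; the O₂-starved
tails are discarded and the remaining pieces are joined into a single
cumulative-consumption curve. The first ~1000 s of a run are a dead time
(thermal equilibration, O₂ diffusion into the condenser) and are excluded.

Three descriptors are read off the joined curve:

* **τ** — the induction period, present when the oil carries a chain-breaking
  antioxidant;
* **R_in** — the O₂ uptake rate during the inhibited phase;
* **R_st** — the steady uptake rate after the antioxidant is spent (or from
  the start, if there is none).

Oils are classified by curve shape: **Type A** (linear from the start),
**Type B** (slow, then fast: an induction period), **Type C** (fast burst,
then slow: a trace of highly oxidizable material in an otherwise
hard-to-oxidize oil).

## Mechanism and closed forms

The chain is: initiation at constant rate $R_i$ producing carbon radicals;
$R^\bullet + O_2 \to ROO^\bullet$ (near diffusion controlled, $k \approx 10^9$
M⁻¹s⁻¹); propagation $ROO^\bullet + RH \to ROOH + R^\bullet$ ($k_p$);
termination $2ROO^\bullet \to$ products ($k_t$); and, with an antioxidant,
$ROO^\bullet + AH \to ROOH + A^\bullet$ ($k_{inh}$) followed by
$A^\bullet + ROO^\bullet \to ROOA$ ($k \approx 10^8$ M⁻¹s⁻¹). Steady-state
treatment of all radicals, with negligible substrate consumption, gives

$$R_{st} = \frac{k_p}{\sqrt{2k_t}}[RH]\sqrt{R_i} + R_i, \qquad
  R_{in} = \frac{k_p [RH] R_i}{n\,k_{inh}[AH]} + R_i, \qquad
  \tau = \frac{n[AH]}{R_i}.$$

Two model assumptions deserve emphasis, because the package inherits them:

* **Constant initiation, inert hydroperoxides.** If accumulated ROOH
  generated radicals, the uptake rate would accelerate with time. Steady
  uptake traces justify treating $R_i$ as constant and ROOH as a tracked but
  chemically inert product. The simulator therefore has no ROOH-feedback
  branch (and `oxikin` should not be trusted for systems where uptake
  visibly accelerates).
* **O₂ saturation of the chain.** The dilution is chosen so that gas/liquid
  transfer is not rate limiting; the model treats the reservoir as a single
  well-mixed pool with instantaneous equilibration and no mass-transfer
  coefficient. Data taken below ~25 % of the O₂ charge are discarded rather
  than modelled.

The stoichiometric factor $n$ is 2 when the antioxidant radical is persistent
enough to be removed quantitatively by a second peroxyl radical;
`stoichiometric_factor_from_simulation()` measures this directly from the
simulated mechanism by counting peroxyl radicals removed through the
antioxidant pathway per antioxidant molecule, and an optional first-order
$A^\bullet$ sink (`a_sink_s1`) models radical-wasting side reactions that
drive $n$ towards 1.

## The simulator

`simulate_autoxidation()` integrates the seven chemical states (R•, ROO•,
A•, AH, ROOH, a depletable trace impurity, and the O₂ reservoir) plus two
bookkeeping integrals (radicals trapped by the antioxidant pathway,
cumulative O₂ consumed) with `deSolve::lsodar`. Numerical choices:

* relative tolerance 1e-8; absolute tolerances per species (1e-17 M for
  radicals, whose steady-state concentrations sit near 1e-13–1e-9 M);
* re-aeration implemented as a terminal root on the O₂ state with an event
  that refills the reservoir and opens a new trace segment — chemistry is
  untouched, exactly as resealing the vessel leaves the liquid phase alone;
* negative concentrations are clipped to zero inside the right-hand side;
  clip events are counted and only reported if numerous;
* the radical steady state is reached within seconds for all default
  parameter sets, far inside the 1000 s dead time.

The vessel model converts between the liquid-phase molar rates of the rate
laws and the whole-vessel nmol/s of the probe via the liquid volume
(`vessel_rate_from_molar()`). The O₂ charge is computed from the headspace
volume, pressure, O₂ mole fraction and headspace temperature (ideal gas) plus
the dissolved pool. The headspace volume is not a measured quantity; the
default of 15 mL is an order-of-magnitude choice (a 10 mL flask plus
condenser volume, less the 8 mL liquid), and the dissolved-O₂ concentration
defaults to 2 mM, typical of an air-saturated organic solvent. Both are
configurable on `vessel_protocol()`, and all analyses in the package are
volume-consistent by construction (the same protocol object is used to
generate and to analyze).

Rate constants at the working temperature are taken as explicit inputs; no
Arrhenius extrapolation is attempted. For orientation,
`reference_rate_constants()` ships the literature 30 °C per-hydrogen
propagation constants (0.004, 0.22, 31 M⁻¹s⁻¹ for saturated, allylic and
bis-allylic positions) and $k_t \approx 10^7$ M⁻¹s⁻¹.

## Trace analysis

`join_segments()` discards, inside every segment, readings below
`o2_floor_fraction` (default 25 %) of the experiment's initial charge,
converts the rest to cumulative consumption, and concatenates the pieces so
consumption is continuous across seams; time gaps are closed by offset and
recorded in the provenance.

`estimate_features()` implements a tangent-intersection construction — the
convention of induction-time instruments, chosen here because it is
deterministic and auditable (how τ is read off a curve is rarely formalized):

1. cut the dead time (default 1000 s), smooth with a centered moving average
   (default 21 points ≙ 210 s at 10 s sampling, far below the 10⁴–10⁵ s τ
   scale);
2. compute local slopes over an adaptive half-window (at least 1.5 % of the
   trace length, so slope noise stays well below the steady slope);
3. fit the **steady line** over the maximal late window in which the local
   slope stays within `steady_tol` (default 20 %) of its late median;
4. fit the **initial tangent** over the leading `init_frac` (default 15 %) of
   the curve, then iterate: re-fit over the leading 60 % of the current τ
   estimate and re-intersect (the extent of the inhibited phase is only known
   once τ is estimated);
5. **τ** is the time coordinate of the two lines' intersection;
6. **R_in** is the derivative at the window start of a quadratic fit over a
   short leading window (≤ 30 % of τ): the inhibited phase accelerates as the
   antioxidant depletes, and a straight chord would inherit that curvature as
   an upward bias;
7. classify: Type A if R_in/R_st lies within ±`theta` (default 25 %) of 1 or
   τ is below `tau_min_s` (default 2000 s, unresolvable); Type B if R_in is
   distinctly smaller; Type C if distinctly larger. τ is reported as 0 for
   Types A and C. If the steady slope is statistically indistinguishable from
   zero the result is censored ("no oxidation observed") rather than typed.

The `theta` and `tau_min_s` thresholds are conventions, not measurements;
they are echoed in the output so classifications are auditable.

**Known limitation.** The tangent construction reads τ slightly early when
the inhibited slope is a large fraction of the steady slope (a gradual
transition): with $R_{in} \approx 0.5 R_{st}$ the bias approaches −5 %. For
potent antioxidants (gallate-like, $k_{inh}[AH]$ large) it is below 1 %.
Where the closed forms predict no resolvable induction step
($R_{in} \gtrsim 0.6 R_{st}$) the curve genuinely looks Type A and τ is not
reported — this is a property of the shape, not a detector failure.

## Standard addition of propyl gallate

Adding a fixed PG dose extends the induction period by $n_{PG}[PG]/R_i$, so
`estimate_Ri_over_n()` returns $[PG]/(\tau_{PG}-\tau)$. Because the
stoichiometric factor of PG at the working temperature is not established,
the package deliberately reports $R_i/n$ and never $R_i$. The standard dose
of 500 mg/L converts to 2.36 mM with PG's molar mass of 212.20 g/mol
(`pg_molar_from_mg_L()`). Oils in which PG produces no measurable extension —
characteristically those with high iron or high acidity, where the
antioxidant is destroyed by side chemistry — yield a *censored* result, not
an error, and are excluded (default thresholds: iron > 5 ppm or acid value
> 15 mg KOH/g, exposed in the generator config and echoed by the fits; the
exclusion *flag* is the contract, the thresholds are defaults).

## Regression models

* `fit_rst_model()`: OLS of R_st on MO/DI/TRI percent (optionally + acid
  value), with a condition-number guard against collinear panels. The
  packaged reference models (`rst_reference_models()`) carry the published
  coefficient sets (intercepts 20.1 and 9.82 nmol/s). Because measured
  uptake rates carry noise roughly proportional to their size, the fit
  reports heteroscedasticity-consistent (HC3) standard errors alongside the
  classical ones; recovery tests compare against the robust errors, which
  are the consistent choice under multiplicative noise.
* `fit_pg_effect_hyperbolic()`: nonlinear least squares of
  $\tau_{PG}-\tau = a/(b + [\text{bis-allylic}])$ — the form expected when
  $R_i$ is proportional to the bis-allylic content plus a small baseline —
  initialized from the linearized reciprocal fit (Levenberg–Marquardt,
  non-negativity bounds). Non-convergence raises an error carrying the
  linearized fallback values.
* `fit_pg_effect_linear_reciprocal()`: OLS of $1/(\tau_{PG}-\tau)$ on the
  bis-allylic concentration. Outliers (PG interacting with impurities) are
  flagged at externally studentized residual > 2.5 — a formalization of what
  is usually done graphically — and the line is refit without them; both
  fits are reported. Two guards handle edge cases: numerically exact fits
  flag nothing, and a point whose deletion residual is undefined because the
  remaining points fit perfectly is treated as the extreme outlier it is.

The bis-allylic concentration is counted as one CH₂ per di-unsaturated and
two per tri-unsaturated chain, converted to molar with the oil density
(0.92 g/mL) and a mean fatty-acid molar mass (280 g/mol), on the neat-oil
basis by default (the magnitude against which the hyperbola's offset
b ≈ 0.08 M makes sense); the diluted basis (×1/8) is available.

## Blend prediction

`predict_blend()` uses the mixing rule implied by the duration law: the
antioxidant pools ($n$[AH] $= \tau R_i$) and the initiation rates both mix
linearly in the volume fractions, so

$$\tau_{blend} = \frac{\sum_i \phi_i \tau_i R_i}{\sum_i \phi_i R_i},$$

computed on the $R_i/n$ basis so the unknown stoichiometric factor cancels.
R_st is predicted from the volume-weighted composition through a steady-rate
model. The rule reproduces the two qualitative regimes observed in practice:
a short-τ oil with *low* initiation (large PG effect) is effectively
stabilized by blending with a stable oil, while a short-τ oil with *high*
initiation drains the partner's antioxidants and the blend stays close to
the unstable behaviour. The rule is an idealization: it ignores antioxidant
synergy/antagonism between the components' inhibitors and any non-additivity
of initiation.

## The synthetic-data generator

`generate_oil_panel()` emulates a bench panel: compositions from a Dirichlet
on the SAT/MO/DI/TRI simplex; acid value and iron with a minority (20 %) of
heavily contaminated oils (acid 15–200 mg KOH/g; iron 5–50 ppm); an intrinsic
antioxidant pool $n$[AH] ∈ [0.002, 0.02] M with 30 % of oils carrying none.
Kinetic descriptors follow the package's own laws: $R_i = c\,(0.080 +
[\text{bis-allylic}])\cdot(1 + 0.2\,\text{Fe}_{ppm})$, with $c$ anchored so
that the PG effect of an average oil matches the packaged hyperbolic model at
the standard dose with $n_{PG}=2$ ($c = n_{PG}[PG]/3.0\times10^4 =
1.57\times10^{-7}$ s⁻¹); τ from the duration law; R_st from the
acidity-augmented reference model with 5 % multiplicative noise; the PG
extension suppressed to zero for flagged oils. The iron multiplier and the
flag thresholds are synthetic-only conventions — the phenomena are real, the
functional forms are not established — and are documented as such.
Generating truths (per-oil $R_i$, antioxidant pool, model coefficients) ride
along as a `truth` attribute for recovery tests.

`generate_trace_set()` maps an oil record back to kinetic parameters by
inverting the steady-rate law at $k_t = 10^7$ M⁻¹s⁻¹ (so the simulated trace
reproduces the record's R_st exactly), taking [AH] $= \tau R_i/n$ and a
gallate-like $k_{inh} = 10^5$ M⁻¹s⁻¹, then simulates and applies the
instrument model: 0.5 % multiplicative reading noise and a 2 % dead-time
ramp artifact decaying over the first 1000 s. A two-substrate extension (a
small, highly oxidizable impurity pool that depletes during the run) exists
solely to produce Type C shapes.

What the generator does **not** emulate — and therefore what passing tests do
not demonstrate about laboratory data: ROOH-feedback acceleration, volatile
acid formation, probe drift, gas/liquid transfer limitation near O₂
exhaustion, multi-antioxidant competition, and any temperature dependence.
The published per-oil values of a real oil panel are not reproducible from
synthetic data; the generator is held only to the qualitative regularities
(PG effect inversely ranked with bis-allylic content; R_st increasing with
polyunsaturation; τ ranking consistent with OSI).

## Problem sizes used by the test suite

The suite verifies the closed-form/simulation equivalence on a 27-point
(kp × R_i × [RH]) grid for the steady slope (1 % tolerance) and a 12-point
inhibited grid for τ and R_in (5 % each, with the per-point antioxidant load
chosen to put τ near 6 × 10⁴ s); the full generate → join → extract loop on
12 seeded oils (τ within 5 %, R_in within 10 %, R_st within 5 %, ≥ 95 %
pass); and coefficient recovery on 40 seeded 30-oil panels (all coefficients
within 3 robust SE in ≥ 95 % of panels). These sizes are the package's
choice of a thorough-but-quick default; all of them can be scaled up by
editing the loops.

## Degenerate inputs, by design

* `Ri = 0` with antioxidant: infinite induction period — `inhibition_duration()`
  errors rather than returning `Inf`.
* `AH0 = 0` or `kinh = 0`: `inhibited_rate()` refuses (there is no inhibited
  regime), `steady_rate()` is the relevant law.
* PG extension ≤ 0: censored estimate ("PG ineffective"), never an exception.
* A trace whose steady slope is indistinguishable from zero: censored
  features ("no oxidation observed").
* Segments entirely below the O₂ floor are dropped with a warning; a panel
  row violating the record invariants is rejected with a per-row diagnostic.
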