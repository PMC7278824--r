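# oxikin

Kinetic analysis of bio-oil autoxidation from headspace oxygen-uptake traces.

## The problem

Bio-oil feedstocks (triglycerides, free fatty acids, used cooking oils,
transesterified oils) degrade during high-temperature storage and processing
by radical-chain autoxidation. Classical single-number stability indices (OSI
and friends) conflate three distinct factors: how fast radicals are generated
(the initiation rate *R*<sub>i</sub>), how oxidizable the bulk oil is (the
propagation/termination balance), and how much chain-breaking antioxidant it
carries. `oxikin` implements the oximetric route to disentangling them: an
isotherm oxygen-consumption trace, recorded in the headspace of a sealed,
stirred, periodically re-aerated vessel, is reduced to three independent
descriptors — the induction period τ, the initial uptake rate
*R*<sub>in</sub>, and the steady uptake rate *R*<sub>st</sub> — which connect
directly to the kinetic parameters of the mechanism.

## The model

For a substrate RH oxidizing under constant initiation *R*<sub>i</sub>, with
propagation constant *k*<sub>p</sub>, termination constant *k*<sub>t</sub>,
and a chain-breaking antioxidant AH (inhibition constant *k*<sub>inh</sub>,
stoichiometric factor *n*), the steady-state solutions of the radical chain
give

- steady regime: −d[O₂]/dt = *R*<sub>st</sub> =
  (*k*<sub>p</sub>/√(2*k*<sub>t</sub>)) [RH] √*R*<sub>i</sub> + *R*<sub>i</sub>
- inhibited regime: −d[O₂]/dt = *R*<sub>in</sub> =
  *k*<sub>p</sub>[RH]*R*<sub>i</sub> / (*n* *k*<sub>inh</sub>[AH]) + *R*<sub>i</sub>
- induction period: τ = *n*[AH] / *R*<sub>i</sub>

The package provides these closed forms, a full stiff-ODE simulation of the
mechanism (including headspace O₂ accounting and re-aeration bookkeeping),
trace feature extraction with Type A/B/C profile classification, the
propyl-gallate standard-addition estimator of *R*<sub>i</sub>/*n* (adding a
known dose [PG] extends the induction period by *n*[PG]/*R*<sub>i</sub>),
composition-based regressions of *R*<sub>st</sub> and of the PG effect, a
blend-stability predictor, and seeded synthetic-data generators for the whole
pipeline.

## Worked example

Simulate a Type B oil (one that carries an intrinsic antioxidant), analyze
its trace, and estimate its initiation rate:

```r
library(oxikin)

protocol <- vessel_protocol()   # 1 mL oil + 7 mL diluent, re-aerate at 75 %
oil <- kinetic_params(kp = 10, kt = 1e7, Ri = 5e-8, RH0 = 1,
                      AH0 = 2.36e-3, kinh = 1e5)

set.seed(1)
trace <- simulate_autoxidation(oil, protocol, t_end_s = 2e5,
                               noise_model = list(rel_sd = 0.005))
trace
#> O2 uptake trace: 5 segment(s), 20001 readings
#>   time span 0..200000 s; O2 consumed 507015 nmol total

feats <- estimate_features(join_segments(trace, protocol))
feats
#> Trace features (Type B oil)
#>   tau   = 9.37e+04 s
#>   R_in  = 0.412 nmol/s
#>   R_st  = 4.41 nmol/s

estimate_Ri_over_n(0, feats$tau_s)   # standard-addition inversion
#>      Ri_over_n censored
#> 1 2.515186e-08    FALSE
```

The detected induction period (9.37 × 10⁴ s) agrees with the closed-form
τ = *n*[AH]/*R*<sub>i</sub> = 94 400 s within 1 %, and the steady rate
(4.41 nmol/s) with the closed-form 4.40 nmol/s. The estimated
*R*<sub>i</sub>/*n* of 2.5 × 10⁻⁸ M/s recovers the generating
*R*<sub>i</sub> = 5 × 10⁻⁸ M/s at *n* = 2. Only the ratio
*R*<sub>i</sub>/*n* is ever reported, because the stoichiometric factor of
propyl gallate at the working temperature is not known.

Panel-level analyses work from a data frame of oil records (one row per oil;
see `?read_panel_csv` for the column contract):

```r
panel <- generate_oil_panel(panel_generator_config(n_oils = 30, seed = 7))
fit_rst_model(panel, include_acidity = TRUE)   # R_st ~ MO + DI + TRI + acidity
fit_pg_effect_hyperbolic(panel)                # (tau_PG - tau) ~ a/(b + [bis-allylic])
```

A thin command-line wrapper is installed as `exec/oxikin`
(`oxikin synth panel --n 30 --seed 7 -o panel.csv`, `oxikin analyze
trace.csv`, `oxikin fit rst panel.csv`, `oxikin blend ...`).

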