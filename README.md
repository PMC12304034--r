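# heatward

Thermal-physiology analysis for small heterothermic endotherms: torpor
quantification from skin-temperature telemetry, flow-through respirometry
reduction, and segmented mixed-effects estimation of thermoregulatory
inflection points. The motivating system is heat tolerance in a
cold-climate population of an insectivorous bat, where the questions are
*when does an animal start spending water and energy on cooling as air
temperature rises*, and *do the sexes differ*.

## What it does

* **Telemetry** — detect torpor bouts (skin temperature below 28 °C for
  more than 30 min, both strict), classify arousals as active (steep,
  Ta-independent rewarming) or passive (an initial phase tracking rising
  ambient temperature), and build daily temperature summaries
  (`detect_torpor_bouts()`, `classify_arousal()`, `daily_summaries()`,
  `bout_statistics()`).
* **Calibration** — polynomial transmitter calibrations with automatic
  degree selection and extrapolation flagging (`fit_calibration()`,
  `pulse_to_temperature()`).
* **Respirometry** — reduce 5-s gas-analyser traces from a stepped
  protocol to per-setpoint physiology: drift/lag correction, lowest
  stable 5-min windows, the mass-balance equations
  VCO₂ = FRₑ·FeCO₂ − FRᵢ·FiCO₂ and EWL = (FRₑ·FeH₂O − FRᵢ·FiH₂O)·0.803
  mg ml⁻¹, conversion at RER 0.71 / 27.8 J ml⁻¹ CO₂ and latent heat
  2.406 J mg⁻¹, and the evaporative-heat-loss-to-metabolic-heat ratio
  (`correct_drift_lag()`, `select_stable_window()`, `reduce_trial()`).
* **Segmented mixed models** — estimate the breakpoint ψ of
  y = α + bᵢ + β·Ta + δ·(Ta − ψ)₊ + ε with a random intercept per
  individual, by iterative linearization with multi-start, delta-method
  CIs, likelihood-ratio choice of segmented vs linear, CI-overlap
  comparison of group breakpoints, backward model reduction, and
  estimated marginal means (`fit_segmented_lmm()`, `choose_model()`,
  `compare_breakpoints()`, `reduce_model()`,
  `estimated_marginal_means()`).
* **Synthetic data** — generators for telemetry traces, piecewise mixed
  responses and raw gas traces with known ground truth
  (`gen_telemetry()`, `gen_respirometry()`, `gen_raw_gas_trace()`), plus
  the reference study conditions (`study_params()`,
  `study_sim_config()`) and a full pipeline (`run_pipeline()`).

## Worked example

```r
library(heatward)

# simulate a female evaporative-water-loss experiment at the reference
# conditions (13 individuals, setpoints 28-44 degC, breakpoint 37.7)
sim <- gen_respirometry(study_sim_config("waewl", "female", seed = 21))
fit <- fit_segmented_lmm(sim$points, "waewl")
fit
#> Segmented mixed model for waewl
#>   breakpoint psi = 37.79 degC (95% CI 37.43-38.14)
#>   slope below 0.0001531, above 0.05539 (per degC)
#>   var(individual) 0.0002533, var(residual) 0.0003408; logLik(ML) 191.213
#>   converged in 17 iteration(s), |gamma| = 5.4e-05

lin <- fit_lmm(sim$points, waewl ~ ta, method = "ML")
choose_model(lin, fit)
#> Model choice: segmented (LRT = 186.345, df = 2, p = 3.433e-41)
```

The breakpoint estimate (37.79 °C) recovers the generating inflection
(37.7 °C): above it this simulated female raises water loss by ~55 mg
h⁻¹ °C⁻¹ (generating value 54), and the likelihood-ratio test prefers the
segmented over the linear model decisively. A worked field example:

```r
rec <- data.frame(id = paste0("f", 1:5), sex = "female",
                  max_ta = c(40, 42, 44, 44, 44))
heat_tolerance_limits(rec)
#>      sex max_ta n
#> 1 female     44 3
```

`run_pipeline(list(seed = 1), out_dir = "out")` chains everything on the
bundled scenario and writes bout, daily-summary, physiology and
summary-table CSVs plus fits as JSON.

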