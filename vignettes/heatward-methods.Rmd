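---
title: "Models and methods behind heatward"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind heatward}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatward)
```

heatward quantifies how a small heterothermic endotherm — the motivating
system is a cold-climate population of an insectivorous bat — responds to
heat: when it enters and leaves torpor in the field, how its metabolic rate
and evaporative water loss change as air temperature rises in a stepped
respirometry trial, and where the thermoregulatory inflection points lie.
This vignette explains each model, its assumptions and tunable parameters,
the design choices that were genuinely open, and what the synthetic-data
generators do and do not emulate.

## Torpor detection from skin-temperature telemetry

A transmitter glued between the scapulae reports skin temperature
(`Tskin`) roughly every 10 min; a shaded logger reports ambient
temperature (`Ta`) hourly. The operational torpor definition is the
conventional one for small bats: an animal is torpid while `Tskin` sits
*below* 28 °C for *more than* 30 min. Both comparisons are strict — a
sample exactly at 28 °C is not torpid, and a run spanning exactly 30 min
is not a bout — because that is what "below" and "more than" mean.

`detect_torpor_bouts()` takes maximal runs of sub-threshold samples. Two
situations censor a bout: it touches either end of the trace (entry or
arousal unobserved), or the run contains a recording gap longer than
`max_gap` (default 30 min), in which case the record cannot certify the
animal stayed torpid across the gap, so the run is split and both
fragments are censored. Censored bouts are counted but excluded from
duration statistics.

Arousals are classified by `classify_arousal()` on the rewarming segment
from the bout's `Tskin` minimum to the first sample at or above the
threshold. The field categories are qualitative — an *active* arousal is a
steep endogenous rise independent of `Ta`; a *passive* arousal first
tracks a rising `Ta` before the final endogenous rise — so the classifier
makes them operational with two rates: a passive phase rewarms at no more
than `r_passive` (default 0.3 °C min⁻¹) while matching the ambient rate
within `ta_match` (default 0.15 °C min⁻¹), and a passive label requires at
least three such samples before the rise. Steep arousals can jump from
torpid to normothermic within one 10-min sampling interval, leaving fewer
than three samples between the minimum and the crossing; the segment is
then padded backward into the bout so the Ta-dependence of the initial
steps can still be assessed, and remains `unclassified` when even that is
impossible or no ambient series exists. Ambient temperature at bout
timestamps is linearly interpolated from the hourly series; the resolution
mismatch is unavoidable. "Immediately before dawn" entries are
operationalised as bout starts within 120 min before sunrise.

## Respirometry reduction

Flow-through respirometry reports fractional CO₂ and H₂O on a baseline
(incurrent) and a chamber (excurrent) line at 5-s resolution while the
chamber steps through air temperatures (28, 32, 36, 40 °C, then 2-°C
steps). Reduction proceeds in four stages.

1. **Lag.** The analyser sees multiplexer switches late; `estimate_lag()`
   finds the backward shift (up to 60 s) minimising within-segment
   variance across the known switch schedule, and the channels are shifted
   back.
2. **Drift.** Baseline-segment means are interpolated linearly in time and
   the deviation from the first baseline's mean is subtracted per channel;
   the first baseline's mean is retained as the incurrent fraction (dried
   air keeps some CO₂, so it is not assumed zero). With linear drift this
   correction is exact. A single, non-bracketing baseline falls back to
   constant subtraction with a warning.
3. **Window.** At each setpoint, after dropping a 20-min equilibration
   prefix (the protocol holds each step at least 20–30 min), the lowest
   *stable* 5-min window is selected per channel: stability means
   |within-window slope| at most 2 % of the window mean per minute and a
   coefficient of variation at most 5 %. If nothing qualifies the
   lowest-CV window is used and flagged. CO₂ and H₂O windows are selected
   independently by default — the resting reading of each gas need not be
   simultaneous — with `shared_window = TRUE` available; subcutaneous
   temperature is averaged over the CO₂ window.
4. **Mass balance and energy units.** VCO₂ = excurrent flow × excurrent
   fraction − incurrent flow × incurrent fraction, and likewise for water
   vapour, converted at 0.803 mg H₂O ml⁻¹ vapour. Metabolic rate assumes a
   post-absorptive respiratory exchange ratio of 0.71 with 27.8 J ml⁻¹
   CO₂ (so 1 ml CO₂ min⁻¹ = 0.4633 W); evaporative heat loss assumes a
   latent heat of 2.406 J mg⁻¹ (so 1 g h⁻¹ = 0.6683 W).
   `rer_scenario_comparison()` quantifies the sensitivity of metabolic
   rate to the assumed RER as an RMSD and R² against the default. The
   EHL/MHP ratio is computed per individual per setpoint before any
   averaging; a table's "max EHL/MHP" is therefore generally *not* the
   ratio of the printed max-EHL and max-MHP cells.

Each trial's mass defaults to the starting mass ("interpolate" is
available) since mass rarely survives model reduction as a predictor.

## Segmented linear mixed-effects estimation

The statistical core models a response \(y\) (waRMR, waEWL, Tsub or
EHL/MHP) of individual \(i\) at air temperature \(Ta\) as piecewise linear
with a single breakpoint \(\psi\) and a random intercept per individual:

\[ y_{ij} = \alpha + b_i + \beta\,Ta_{ij} + \delta\,(Ta_{ij}-\psi)_+ +
\varepsilon_{ij}, \qquad b_i \sim N(0,\sigma_b^2),\;
\varepsilon_{ij}\sim N(0,\sigma^2). \]

\(\psi\) is estimated by iterative linearization: at the current
\(\psi_k\) the working model adds \(U=(Ta-\psi_k)_+\) and
\(V=-\mathbf 1\{Ta>\psi_k\}\); a first-order expansion shows the V
coefficient \(\hat\gamma\) estimates \(\delta\,(\psi-\psi_k)\), so
\(\psi_{k+1}=\psi_k+\hat\gamma/\hat\delta\). At convergence
\(\hat\gamma\approx 0\) and the delta method gives
\(SE(\hat\psi)=SE(\hat\gamma)/|\hat\delta|\), from which the 95 % CI uses
normal quantiles. Inner fits are `nlme::lme` maximum-likelihood fits (the
standard engine for this model class); the final reported coefficients
come from a REML refit at the converged \(\psi\), while model comparison
uses ML.

Numerical choices, all of which mattered in practice:

* **Stopping.** \(\hat\gamma(\psi)\) is a *discontinuous* function of
  \(\psi\) — it jumps whenever \(\psi\) crosses an observation — so
  demanding \(|\hat\gamma| < 10^{-4}\) alone can cycle forever between two
  adjacent intervals. The update is therefore damped (the step is halved
  whenever its sign flips) and iteration also stops when the damped step
  moves \(\psi\) by less than \(10^{-5}\) of the Ta range. Steps that
  would leave the allowed interval are halved up to 30 times.
* **Multi-start.** Seven starts at the 0.05/0.2/0.35/0.5/0.65/0.8/0.95
  Ta quantiles. The near-boundary starts are load-bearing: a breakpoint
  hugging the protocol floor (the male metabolic inflection sits at the
  first setpoint) is never reached by updates launched from mid-range
  quantiles alone.
* **Selection among starts.** Converged solutions whose ML log-likelihoods
  lie within \(q_{\chi^2_1}(0.95)/2\) of the best are statistically
  indistinguishable; among them the one with the smallest delta-method
  \(SE(\hat\psi)\) is preferred (ties then break on the smallest
  \(|\hat\gamma|\)). The rationale: weakly informative replicates often
  show a second, shallow likelihood ridge near the top of the Ta range
  whose "breakpoint" has an SE of several °C, while the genuine mode is
  sharply identified; when the likelihood cannot separate the two, the
  identifiable candidate is the scientifically reportable one.
* **Bounds.** `psi_bounds` optionally restricts the breakpoint domain. The
  study-level analyses cap it at the second-highest setpoint, because a
  post-inflection slope is only estimable with at least two setpoints
  above \(\psi\) — the same rank condition that makes the working model
  singular when a single temperature level lies on one side.

**Identifiability near the protocol floor.** With responses generated at
exact setpoints, the profile likelihood in \(\psi\) is *constant* on any
between-setpoint interval containing a single design point on one side:
the three fixed-effect parameters can absorb any \(\psi\) in that
interval. Real trials escape this because the regressor is the measured
chamber temperature, which scatters continuously around each setpoint; the
generator therefore draws a realized temperature per exposure
(`ta_jitter`, default SD 0.5 °C for a manually controlled chamber) and
both generates and regresses on it. Even so, a breakpoint at the first
setpoint with a weak slope change remains only marginally identified: in
roughly 15 % of replicates at the male-metabolic-rate conditions the
*global* ML optimum sits at a spurious interior mode (verified against a
grid profile likelihood), so averages of \(\hat\psi\) across replicates
are biased upward by 1–2 °C there no matter the estimator. Single-dataset
delta-method CIs are blind to such multimodality and should be read with
that caveat; a parametric bootstrap of the null is the rigorous
alternative where it matters.

**Model choice and comparison.** `choose_model()` compares the ML
segmented fit to the ML linear fit with a likelihood-ratio statistic on 2
df (breakpoint and slope change). The \(\chi^2_2\) reference is an
approximation — the breakpoint is not a regular parameter — but simulation
at the package's own conditions puts the empirical type-I rate at ~6 % for
a nominal 5 %. Group breakpoints are compared by CI overlap
(`compare_breakpoints()`): disjoint intervals are called significant, and
the signed gap is reported. "No inflection" for a group is operationalised
as the linear model being preferred, no start converging, or the
breakpoint CI covering more than 80 % of the observed Ta range.
`reduce_model()` performs backward elimination of fixed effects (Ta is
never dropped, marginality respected) using marginal Wald tests on ML
fits, with a REML refit of the final model;
`estimated_marginal_means()` delegates to emmeans on that refit.

## What the generators emulate — and what they do not

The telemetry generator builds a sinusoidal ambient day (default daily
range 12.3–25.0 °C, minimum 30 min before a 06:00 sunrise), a torpid skin
temperature tracking ambient plus a 2 °C offset (a modelling choice; field
within-bout offsets are unreported), and arousals whose final phase is a
1.0 °C min⁻¹ endogenous rise timed so the threshold is crossed exactly at
the configured bout end. Whether a bout reads active or passive is a
matter of timing relative to the ambient minimum — evening arousals under
falling ambient show only the jump; late-morning arousals first track the
ambient rise — which mirrors the biology (night foraging arousals versus
cheap morning rewarming). Entry is instantaneous, there is no cooling
curve, no transmitter dropout, and no behavioural microclimate selection;
passing detector tests therefore shows the rules are implemented exactly,
not that the classifier would be 90 % accurate on noisy field data.

The respirometry-response generator draws, per individual, a random
intercept, a body mass (8.9 ± 1.0 g females, 7.3 ± 0.9 g males), realized
chamber temperatures and residual noise, on a per-individual RNG stream
split deterministically from one scenario seed (so enlarging a scenario
leaves existing individuals' draws untouched). The reference conditions
(`study_params()`) are the reference per-sex estimates: inflections at
37.7/33.1 °C (waEWL, slopes 54/23 mg h⁻¹ °C⁻¹), 34.5/28.2 °C (waRMR,
slopes 10/7 mW °C⁻¹), 32.1 °C (male Tsub, slope 0.75), a linear female
Tsub (slope 0.61), and heat tolerance limits of 44 °C (females, attained
by 3 of 13) and 42 °C (males, 5 of 10). Below-inflection slopes are not
part of the reference set and were fixed once on physiological grounds: flat for waEWL and
female waRMR (a minimal floor and a thermoneutral zone respectively), flat
for Tsub below the defended range, and −14 mW °C⁻¹ for male waRMR — at
28 °C a cold-adapted 7-g bat sits below thermoneutrality, and the
allometric minimum thermal conductance of that body size gives the
magnitude of the thermogenic slope. Residual and random-intercept SDs are
0.02/0.02 g h⁻¹ (waEWL), 0.01/0.01 W (waRMR) and 0.3/0.3 °C (Tsub).

The raw gas-trace generator inverts the reduction: it emits the 5-s
multiplexed trace a stepped trial would have produced (first-order chamber
washout with a 45-s time constant, optional linear drift, lag, Gaussian
analyser noise of order 10⁻⁶ in fraction units, and an optional
mid-segment activity bump so the "lowest stable" search is a real choice).
Reducing a noiseless emitted trace reproduces the inputs to floating-point
tolerance, which is the reduction module's oracle. Chamber thermodynamics
beyond the single washout constant, RQ dynamics and behavioural
interference are out of scope.

## Problem sizes and reproducibility

The bundled checks use the sizes the analyses are designed for: 50
replicate datasets per parameter-recovery scenario (13 or 10 individuals,
5–6 setpoints), 500 replicates for the type-I calibration of the
segmented-vs-linear test and 200 for its power companion, 500 case
bootstrap resamples when bootstrap and delta-method intervals are
compared, and multi-week telemetry scenarios of 40–61 bouts. All
randomness flows from explicit integer seeds; rerunning any generator or
the pipeline with the same seed is bit-identical.

## Known limitations

* One breakpoint per response; no random slopes or random breakpoints
  (a subject-specific-breakpoint flag is deliberately out of scope).
* The \(\chi^2_2\) LRT reference and the delta-method CI are
  approximations; both are documented above and the CI caveat is real at
  weakly identified breakpoints.
* The arousal classifier inherits the sampling resolution: arousals
  faster than the sampling interval are classified from a padded segment
  and genuinely ambiguous records stay unclassified.
* Generated responses are Gaussian with homoscedastic noise;
  heavy-tailed analyser artefacts and serial correlation within a trial
  are not emulated.
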