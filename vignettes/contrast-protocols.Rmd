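---
title: "Personalised contrast-injection protocols: model and simulation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalised contrast-injection protocols: model and simulation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contrastflow)
```

## The problem

Coronary CT angiography (CCTA) needs the coronary lumen opacified to
roughly 300 HU or more at scan time. Fixed contrast-media (CM) protocols
over- or under-dose patients at the extremes of body habitus, and modern
scanners select low tube voltages (70–90 kV) per patient, which changes
iodine attenuation substantially. `contrastflow` implements a dosing rule
that personalises the injection to two quantities: the patient's
estimated total blood volume (BV) and the selected tube voltage (kV).

## The model

During a first-pass injection at flow $F$ (mL/s) of an agent with iodine
concentration $I_c$ (mgI/mL), the intravascular concentration follows a
single-compartment mixing model,

$$\frac{dc}{dt} = \frac{F I_c - \mathrm{CO}\, c}{V}, \qquad
c(t) = \frac{F I_c}{\mathrm{CO}}\left(1 - e^{-\mathrm{CO}\, t / V}\right),$$

with cardiac output $\mathrm{CO}$ (mL/s) and mixing volume $V$ (mL).
Attenuation is proportional to iodine concentration ($\mathrm{HU} = k\,c$),
approximately inversely proportional to tube voltage over the 70–120 kV
range, and is diluted by the patient's blood pool, for which the
sex-specific Nadler estimate is used as the patient factor:

$$\mathrm{BV}_{male} = 0.3669\,h^3 + 0.03219\,w + 0.6041, \qquad
\mathrm{BV}_{female} = 0.3561\,h^3 + 0.03308\,w + 0.1833,$$

with height $h$ in **metres** and weight $w$ in kg. The plateau
attenuation model is

$$\mathrm{HU}_{kVp} = \frac{k\,F\,I_c}{kV \cdot \mathrm{BV}}.$$

Two details deserve comment, because the source material for this rule
circulates with typographical ambiguities:

* *Height units.* The classical Nadler coefficients 0.3669/0.3561 apply
  to height in metres. Only metres reproduce the calibration anchor used
  below (a 1.80 m, 80 kg man has BV 5.319 L and receives 7.0 mL/s);
  centimetre heights would give absurd volumes. Heights entered as
  values above 3 are treated as centimetres and converted, purely as an
  operator convenience.
* *Direction of the patient factor.* BV must divide, not multiply:
  larger blood pools dilute iodine, so larger patients need more flow.
  Division is the only reading consistent with the flow rule below.

## Calibration and the flow rule

Rather than estimating $k$, CO and $V$ per patient, the model is
anchored at a **reference patient**: male, 1.80 m, 80 kg (BV 5.319 L),
scanned at 120 kV with flow 7.0 mL/s (IDR 2.1 gI/s at 300 mgI/mL),
taken to produce 350 HU — a deliberate safety margin above the 300 HU
diagnostic floor. Solving the attenuation model at the anchor gives

$$k = \frac{350 \times 120 \times 5.319}{7.0 \times 300} = 106.38,
\qquad c_{cal} = \frac{7.0}{5.319 \times 120} = 0.010967,$$

and inverting for flow yields the personalised rule

$$F = c_{cal} \cdot \mathrm{BV} \cdot kV,$$

which by construction maps every patient back to 350 HU predicted
attenuation. A literal constant of $2\times10^{-4}$ is sometimes quoted
for this rule; it is dimensionally inconsistent with the anchor (it
would give 0.128 mL/s for the reference patient) and is retained only
behind `flow_constant = "legacy"`, with a warning, for auditing old
worksheets. By default the constant is always derived from the anchor,
so recalibrating to a different agent, target or anchor patient is a
one-line change.

`cm_concentration()` exposes the closed-form $c(t)$; CO and $V$
(defaults 90 mL/s, 100 mL — generic adult first-pass values) affect only
that curve, never the flow rule, because the anchor absorbs them.

## From flow to a complete protocol

Scan mode follows heart rate: HR ≤ 70 bpm uses the prospective
high-pitch spiral (scan time 8 s), 70–90 bpm the adaptive-sequence mode
(10 s); above 90 bpm a retrospective helical protocol would be needed,
which is out of scope and raises an error. The injection time equals the
scan time (an optional `injection_time_buffer_s` adds site-level slack;
recorded clinical times are often 1 s longer than nominal), so

* main bolus = flow × injection time,
* test bolus = flow × `test_bolus_s` (default 2.1 s — not part of the
  published description; inferred from the reported test-bolus-to-flow
  ratios of ≈ 2.0–2.2 s across all groups),
* IDR = flow × $I_c$/1000 (gI/s), TIL = main bolus × $I_c$/1000 (gI;
  main bolus only, by the reporting convention).

Flows and volumes are rounded to 0.1 (injector granularity); IDR/TIL are
reported to 0.1 as injector software does. Flows above 7.5 mL/s are
flagged, since 18–22 G intravenous cannulae are not rated beyond that.
Saline chasers, multiphasic injections and bolus *timing* (the test
bolus is used clinically to set the scan delay) are not modelled.

```{r}
cal <- calibrate_attenuation()
generate_protocol(
  data.frame(sex = "F", height_m = 1.65, weight_kg = 60,
    heart_rate_bpm = 64),
  cal, kv = 70)
```

## The synthetic cohort generator

The generator emulates a 114-patient clinical CCTA population (55 men,
59 women) whose pooled height and weight were 1.71 ± 0.10 m and
77.5 ± 16.0 kg, heart rate 64.1 ± 11.2 bpm, and whose sex-specific mean
blood volumes were 5.4 L (men) and 4.1 L (women). Only pooled
anthropometrics were published, so the sex split is a package choice:
men 1.78 ± 0.07 m and 85 ± 14 kg, women 1.65 ± 0.07 m and 70 ± 13 kg,
chosen so that the 55:59 mixture reproduces both the pooled marginals
((55·1.78 + 59·1.65)/114 = 1.713 m; (55·85 + 59·70)/114 = 77.2 kg) and
the sex-specific blood-volume means (E[h³] = µ³ + 3µσ² in the Nadler
formula gives 5.42 L and 4.11 L). The height–weight correlation of 0.5
is a conventional physiological value, not a published one; it is
configurable and has negligible effect on the means. Heart rate is
truncated to [40, 90] bpm because faster hearts left the modelled
protocol pathway; under N(64.1, 11.2) truncation this gives a 70.3%
high-pitch share (the study observed 71.1%). Draws use `MASS::mvrnorm`
and an inverse-CDF truncated normal, fully reproducible from a seed.

### Tube-voltage-selection emulation

Vendor automated tube-voltage selection (ATVS) operates on topogram
attenuation, which is unavailable here; the emulator uses blood volume
as the body-size proxy and places thresholds at BV quantiles so that the
assigned shares match the observed kV distribution (70/80/90 kV in
52.6/32.5/14.9% of patients). Two variants exist:

* `atvs_emulator()` / `emulate_atvs()` — fixed thresholds in litres,
  piecewise-constant and monotone in BV;
* `assign_kv()` — quantile thresholds computed from the cohort, by
  default **within each sex**.

Sex stratification is the package's design choice for the default. With
pooled thresholds, a deterministic cut-off makes the few women above the
85th pooled percentile extreme outliers within their sex, and simulated
female 80/90 kV flow means drift above the published ranges; real
voltage selection tracks habitus within sex more closely. Stratified
quantiles preserve the overall kV shares exactly while keeping each
sex's kV groups representative. The emulator remains deliberately
simpler than reality in one respect: kV is assigned independently of
scan mode, whereas the observed kV distribution differed between modes.
Consequently group summaries for the very small adaptive-sequence 90 kV
cells (a handful of patients in the emulated study) can fall slightly
outside narrow published ranges; this is a fidelity limit of the
emulator, not a dosing error — the same patients' high-pitch ranges are
reproduced.

```{r}
study <- simulate_study(seed = 42)
glance(study)
```

`protocol_table()` (also `tidy(study)`) reports mean [min–max] per
scan mode × kV × sex, the layout of published protocol tables.

## Image-quality utilities

Objective metrics follow the standard ROI definitions: image noise is
the SD of the intravascular attenuation, SNR = vessel mean / vessel SD,
CNR = (vessel mean − epicardial-fat mean) / fat SD. A segment is
diagnostic by attenuation at ≥ 300 HU (inclusive — the threshold itself
is a convention; published usage spans 250–325 HU) and by contrast at
CNR strictly > 10. Bookkeeping uses the AHA 17-segment coronary model
(RCA 1–4 and 16, left main 5, LAD 6–10, circumflex 11–15, ramus
intermedius 17).

The ROI generator draws, per segment, attenuation about the calibrated
model prediction (SD 43 HU), image noise about a kV-specific mean
(42/41/43 HU at 70/80/90 kV, SD 6), epicardial fat from N(−80, 15) HU
with ROI SD about N(30, 5) — the fat prior is typical adipose
attenuation, not a published statistic — and marks segments
non-assessable with per-segment dropout probabilities taken from
observed non-assessability rates (segments 12 and 14: 13.2%, segment 9:
10.5%, segment 10: 7.9%, segment 4: 6.1%, segment 13: 4.4%, all others
1%), for an expected assessable fraction of 96.1%.

What this generator does *not* capture: between-patient attenuation
dispersion (noise is independent across segments, so per-patient means
are tight around 350 HU and essentially all simulated patients are
diagnostic, whereas real cohorts include bolus-timing failures), absent
vessels (all 17 segments are always generated; real cohorts average
\~14.6 present segments per patient), and any spatial correlation along
a vessel. Simulated image-quality summaries are therefore soft
consistency checks of the dosing model, not reproductions of clinical
image-quality rates; the per-patient "overall" aggregate is the simple
mean over assessable segments (the published aggregation rule is
unstated). Subjective Likert grading is a human procedure: the segment
CSV reader stores Likert values if supplied but the package never
generates them.

## Numerical choices and problem sizes

* Closed-form $c(t)$ is validated in the test suite against `deSolve`
  integration of the defining ODE at relative tolerance 1e-6.
* The flow rule is exactly linear, so calibration recovery (refitting
  $c_{cal}$ from generated flows) is tested to 1e-9.
* Rounding happens once, at report time; every internal identity
  (round trip to 350 HU, 10/8 bolus ratio between modes) is asserted
  pre-rounding.
* Quantile thresholds use the default type-7 sample quantile; ties are
  impossible for continuous BV except in degenerate zero-variance
  configurations.
* Simulation-based checks use 100,000 patients per sex for
  blood-volume means (Monte-Carlo SE ≈ 0.002 L), 1,000 replicates of
  n = 114 for the high-pitch share, and 100 replicates of n = 114 for
  protocol-table enclosure — sizes at which sampling error is well
  below the tolerances being checked while the whole suite runs in
  seconds.

## Limitations

The model ignores cardiac output variability between patients (the
anchor absorbs a population-average value; low-output patients peak
later and the scan delay, set clinically by a test bolus, is outside
scope), models no contrast recirculation, and treats tube-voltage
selection as a pure body-size function. Validation against the
published protocol tables is enclosure of simulated group means within
published min–max ranges, which is informative for the well-populated
groups and weak for the smallest ones.
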