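---
title: "Methods: thermal-niche estimation, mechanism classification and community inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal-niche estimation, mechanism classification and community inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoniche)
```

This vignette documents the models and procedures implemented in
`thermoniche`, the assumptions behind them, the defaults and why they were
chosen, and what the synthetic-data generator does and does not emulate.

## The measurement model

A tethered-flight thermography recording yields, per individual, three
temperature traces sampled at the camera frame rate: thorax `T_th` (the
flight motor), abdomen `T_abd`, and nearby environment `T_env`. Each trace
value is the **maximum** over a 3×3-pixel region of interest, not the mean:
legs sweeping through the ROI read colder than the cuticle, so the maximum is
the robust statistic for surface temperature (`extract_roi_trace()`).

Raw infrared readings are *apparent* temperatures. `correct_temperature()`
inverts a single-reflection greybody model on the T⁴ radiance scale,

$$W_\mathrm{obj} = \frac{W_\mathrm{meas} - (1-\varepsilon)\,\tau\,W_\mathrm{refl} - (1-\tau)\,W_\mathrm{atm}}{\varepsilon\,\tau},
\qquad W(T) \propto (T + 273.15)^4,$$

with emissivity $\varepsilon \in (0,1]$, path transmittance $\tau$
(default 1 — at half-metre working distances atmospheric absorption is
negligible, which also absorbs the distance and humidity terms), and the
reflected apparent temperature. The T⁴ proxy ignores the finite spectral
band of microbolometer cameras; over the 20–45 °C range of these recordings
the band-integrated and total radiance corrections differ by far less than
the sensor noise, so the simpler model is preferred. The correction is the
identity at $\varepsilon = \tau = 1$ and a fixed point when the object is
indistinguishable from its reflection; both properties are tested.

`estimate_emissivity()` solves the same forward model for $\varepsilon$ by
least squares through the origin, using paired cuticle/reference-tape
apparent temperatures recorded at matched true temperatures (the reference
emissivity defaults to 0.95, electrical tape). Because the measurement
protocol fixes no reflected-temperature value, the estimator takes one as an
argument (default 25 °C, laboratory ambient).

Only recordings with **at least 40 s of continuous flight** enter the
analysis (`flight_window()`, `detect_flight_window()`). When no take-off
annotation is available, take-off is placed at the largest forward
difference of the thorax trace — the take-off transient is the steepest
warming event in these recordings; the heuristic is exact for step-like
warm-up and is tested to within one frame on synthetic traces. ROIs are
static: recordings are assumed stabilised (tethered individuals), and no
per-frame re-centring is attempted. That is a real limitation for strongly
moving preparations; jitter of up to ±1 px is absorbed by the 3×3 maximum,
anything larger is not.

## Per-individual physiology

* **Endothermy (excess temperature)**: the mean of `T_th − T_env` over the
  flight window, in °C. It is invariant to any common shift of both traces
  (tested) and is the field's standard measure of the ability to hold the
  flight motor above ambient.
* **Slopes** `sT_th`, `sT_abd`, `sT_env`: ordinary least-squares slopes of
  temperature against time from take-off to 40 s into flight
  (`fit_slope()`; the window end is configurable via `slope_window`). The
  implementation is `stats::lm()`; tests pin it to the closed form
  $\sum(t-\bar t)(y - \bar y)/\sum(t-\bar t)^2$ at 1e-10.
* **Slope difference** `sT_th − sT_abd`: an inverse proxy of thorax→abdomen
  heat transfer — the larger the difference, the less heat moves backwards.
* **Take-off temperature**: the thorax temperature at the take-off frame,
  the tethered analogue of the minimum flight temperature.

## Mechanism classification

Physiological thermoregulation in dung beetles is classified per species
from the per-individual slopes (`classify_mechanism()`), with "similar"
meaning a Kruskal–Wallis test (tie-corrected H, χ² p-value, df = 1) at
P ≥ α, default α = 0.05, and slope sign taken from the species mean with
threshold exactly 0:

| call | `sT_th` vs `sT_abd` | sign conditions | `sT_abd` vs `sT_env` |
|------|--------------------|-----------------|----------------------|
| APHT | different | mean `sT_th` > 0 | similar |
| AAHT | similar | mean `sT_th` > 0 and mean `sT_abd` > 0 | different |
| UNDEFINED | anything else | | |

Two formulations of active abdominal transfer circulate in the literature:
the strict one above (the abdomen *diverges* from the environment because it
is actively loaded with heat) and a looser reading under which near-uniform
similarity of all slopes still counts. We implement the strict rule and
report every intermediate quantity (means, signs, both H/P pairs) so the
call can be re-derived — and re-thresholded — from the stored fields; a
purity test asserts exactly that. Only a species-level classifier is
provided: with single-flight protocols there is no principled
individual-level version of the rule, and per-individual anecdotes are left
to inspection of the individual physiology table.

When every slope in both groups is identical the rank statistic is
undefined; the package returns H = 0, "similar", with a warning —
a degenerate case that only arises with constructed data.

## Community inference

`indval()` implements specificity–fidelity indicator values:
$A_{ij}$ = mean abundance of species *i* across the sites of habitat *j*,
divided by the sum of those habitat means; $B_{ij}$ = fraction of habitat-*j*
sites occupied; $\mathrm{IndVal}_{ij} = A_{ij} B_{ij} \times 100$. For any
species with nonzero total abundance, $\sum_j A_{ij} = 1$ (tested), and the
statistic is invariant to rescaling a species' counts. Significance comes
from permuting the site→habitat assignment: the per-species null statistic
is the maximum IndVal over habitats, and the add-one estimator
$P = (1 + \#\{\text{permuted max} \ge \text{observed max}\})/(1 + N)$ is
reported (999 permutations by default, seeded). The max-statistic null makes
the test valid (super-uniform under habitat-unstructured communities — the
calibration test measures this at 500 species) and is the classic choice for
indicator-value inference. Categories: **indicator** above 70 % (strict)
with P < 0.05; **detector** in the closed band 45–70 % with P < 0.05. The
boundary convention (70 itself is a detector) is arbitrary but documented
and tested. Species never observed get $A$ undefined, IndVal 0, category
"none", with a message.

Daily activity (`classify_activity()`): captures are binned by local clock
time into the half-open periods [7:00, 18:00) and [18:00, 7:00) — the second
spans midnight — and a species is diurnal (or E/N/C) when ≥ 60 % of captures
fall in the corresponding period, boundary inclusive. Species below
`min_captures` total (default 25 — the rule needs enough captures for 60 %
to be meaningful, and this default is an explicit configuration choice, not
a published constant) fall back to a literature label when one is supplied,
else "unresolved".

Microclimate (`summarize_sensor_log()`): day/night means and extremes over
the whole record, with thermal amplitude = record-wide day maximum − night
minimum. A per-day variant (mean of daily amplitudes) is available via
`amplitude = "daily"`; the record-wide definition is the default because the
amplitude is meant to capture the extremes an organism must tolerate over
the deployment, not a typical day.

## Comparative statistics

`fit_thermal_lmm()` fits, by REML,
`response ~ habitat * activity + mass + (1 | species)` with sum-to-zero
contrasts — required for type-III tests to target the balanced-population
marginal hypotheses. Endothermy is log-transformed (its distribution is
right-skewed); non-positive values are dropped with a count. Singular fits
(species variance on the boundary) are reported with a warning, not an
error, and in that limit the fixed effects coincide with ordinary least
squares (tested at 1e-6).

`anova_type3()` performs Wald χ² tests per term; `tukey_contrasts()`
compares estimated marginal means at the covariate mean, pairwise within
activity class or within habitat, with studentized-range adjustment.
Inference is **z-based** (asymptotic): denominator degrees of freedom in
mixed models are approximation-dependent (Satterthwaite, Kenward–Roger and
package defaults all differ), so the package states its approximation
rather than imitating any particular one. Consequences: with few species
and strong species-level variance the Wald tests run anti-conservative.
The calibration test therefore checks type-I error where the approximation
is meant to hold — 24 species in balanced habitat×activity cells, 10
individuals each, species-level sd small next to the residual (intraclass
correlation ≈ 0.04) — and requires the interaction test's rejection rate
over 500 null simulations to sit in [0.03, 0.07]. With ~18 species and
intraclass correlation above ~0.1 the same test measures ≈ 0.08–0.09: that
is the df approximation, not a bug, and is the main caveat for small
assemblages.

`kruskal_conover()` provides the body-mass comparisons: tie-corrected
Kruskal–Wallis H plus Conover–Iman pairwise t statistics on mean ranks with
the pooled tie-corrected rank variance and N − k degrees of freedom.
Pairwise p-values are **unadjusted by default** — the analysis tradition
here runs each planned comparison at its nominal level rather than
correcting across them — with `p_adjust = "holm"` (or any
`stats::p.adjust()` method) as an option. The same no-correction stance
applies across the five modelled responses; `correlate_physiology()`
reports the Pearson correlations among the slope variables so the reader
can judge their non-independence.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions of the bundled assemblage.

**Flight traces** (`simulate_flight_trace()`): the environment drifts
linearly from its baseline (default 25 °C); the thorax excess rises during a
pre-take-off warm-up by exponential saturation (rate 1 s⁻¹) and during
flight follows a line *centred on the flight window*, so that at zero noise
the mean excess over the window equals the planted endothermy exactly and
the least-squares slope equals the planted slope exactly. This
centring is deliberate: endothermy is *defined* as the mean flight excess,
so the generator plants that definition rather than an uncentred line whose
mean would drift with the slope. The abdomen carries a mechanism-dependent
fraction of the thorax excess (0.15 for passive/no transfer, 0.8 for active
transfer) plus its own slope. Per-individual parameters (endothermy, three
slopes) are drawn around the species means with configurable
between-individual spreads; the default pool uses the published per-species
standard deviations, which is what makes the species-level rank tests
operate at realistic power rather than detecting arbitrarily small
differences from frame noise alone. Frame noise is i.i.d. Gaussian
(default 0.3 °C) — real microbolometer noise has spatial and temporal
correlation (drift, non-uniformity correction events) that this does not
emulate, so passing recovery tests bound estimator error under ideal noise
only. Defaults: 25 Hz frame rate (thermal video), take-off at 5 s, 40 s of
flight; the frame rate is a simulation choice, not an inferred property of
any particular camera.

**Frame stacks** (`simulate_frame_stack()`): three disjoint 3×3 patches
carry the trace values (patch maximum equals the trace value, off-centre
pixels decay), background is the environment trace; optional ±1 px jitter
exercises the extractor's tolerance. Stacks round-trip through 32-bit-float
multi-page TIFF with an affine scale and frame times in a CSV sidecar.

**Communities** (`simulate_community()`): negative-binomial counts
(default dispersion 2 — strongly overdispersed, as pitfall counts are) with
species means `mean_own` (default 30) at own-habitat sites and `mean_other`
(default 2) elsewhere; `mean_other = 0` plants perfect-specificity
indicators, `mean_other = mean_own` gives null communities for calibration.
Three habitats × three sites is the default layout.

**Captures** (`simulate_captures()`): binomial allocation of each species'
captures to the day period at its `diurnal_fraction`, uniform clock times
within periods, five sampling days. The pipeline uses 0.85/0.15 for
diurnal/E-N-C species — strong but imperfect period fidelity — and 40
captures per species.

**Sensor logs** (`simulate_sensor_log()`): a cosine diel cycle peaking at
14:00 plus Gaussian noise (0.2 °C, typical logger accuracy), 5-min samples,
12 days. The pipeline's per-habitat semi-amplitudes (5 / 6 / 10.5 °C)
produce thermal amplitudes of ≈ 10 / 12 / 21 °C for native forest /
agroforestry / open pasture. Note that the record-wide max-minus-min
estimator is upward-biased by noise extremes (a few tenths of a degree over
3456 samples); the tests account for that.

Every simulator accepts a seed and returns a ground-truth record
("truth sidecar") alongside its data, so recovery tests never re-derive the
truth from the data themselves. Fixed seeds give bit-identical outputs.

## Problem sizes and numerical choices in the test-suite

The statistical suites run at sizes chosen to make their answers sharp but
cheap: endothermy recovery uses ~1000-frame windows at 0.3 °C noise (the
estimator's standard error is then ≈ 0.013 °C, so the ±0.05 °C assertion is
a ≈ 4σ band); mechanism recovery uses 100 species per planted mechanism
with 10 individuals each and slope effects at 5× the per-individual slope
standard error; IndVal calibration uses 500 species over 9 sites at 999
permutations; Wald calibration uses 500 null fits of 24 species × 10.
One caveat is recorded openly: a planted-mechanism species is only
"recovered" if the slope pair that is truly null also *tests* similar,
which happens with probability 1 − α ≈ 0.95 by construction — the expected
recovery rate therefore sits essentially on the suite's 95 % bound, and
that check can fail by sampling noise without any defect in the estimators.

## Known limitations

* Static ROIs; no body-part tracking. Strongly moving preparations need
  re-centred ROIs upstream.
* The radiometric model is total-radiance greybody with single reflection;
  vendor raw formats and band-integrated radiometry are out of scope.
* Environment-trace correction: by default only thorax and abdomen traces
  are emissivity-corrected (the environment ROI is not cuticle); correcting
  all three is the caller's choice.
* Trace noise is i.i.d.; correlated camera noise would inflate slope
  standard errors relative to the generator's.
* z-based mixed-model inference runs anti-conservative for small species
  counts (see calibration section).
* Behavioural thermoregulation (perching, elytra posture, basking) is
  discussed in this literature but is not a computable quantity here; only
  the physiological classification is implemented.
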