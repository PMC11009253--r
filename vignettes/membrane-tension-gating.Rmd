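---
title: "Membrane tension gating analysis: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane tension gating analysis: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchtension)
```

## The problem

Mechanosensitive channels are gated by in-plane membrane tension, but a
pressure-clamp experiment controls pressure, not tension: the same pressure
step produces very different tensions in patches of different geometry.
Tension must therefore be *measured*, per patch and per step, by imaging the
patch membrane, fitting its radius of curvature `r`, and applying the
Young–Laplace relation

$$T = \frac{|\Delta P| \, r}{2},$$

with `ΔP` the transmembrane pressure difference. This package implements the
full chain from fluorescence frames and current sweeps to a Boltzmann
tension–response fit and channel energetics, plus a synthetic-experiment
generator with known ground truth so every stage is testable.

## The gating model

A two-state channel whose open conformation occupies an extra in-plane area
`ΔA` has open probability

$$P_O(T) = \frac{1}{1 + \exp\!\big((\Delta G - T\,\Delta A)/k_B T_{abs}\big)}
        = \frac{1}{1 + \exp\!\big((T_{50} - T)/k\big)},$$

so the empirical midpoint and slope factor identify the physics:
`ΔA = k_B T_abs / k` and `ΔG = (T50/k) · k_B T_abs`. The fit (`fit_boltzmann()`)
is least squares with the amplitude fixed at 1, because responses are
normalized to the patch's maximal evoked current; a free-amplitude variant
exists (`free_amplitude = TRUE`) for sensitivity analysis only. No basal
offset term is included: the two-state form already has a nonzero floor
`P_O(0) = 1/(1+\exp(T_{50}/k))`, and with the basal-activity QC cap an extra
offset would be unidentifiable.

Global fits (all patches pooled) are the primary mode — single patches
rarely span the full curve — and `mode = "per_patch"` reports the mean ± SEM
of per-patch parameters.

### Numerical choices

* Optimization: multi-start quasi-Newton (BFGS) on `(midpoint, log slope)`
  with an analytic gradient; one deterministic start (midpoint at the median
  stimulus, slope at a quarter of the stimulus span) plus 8 seeded jittered
  restarts; tolerance 1e-10 on the sum of squares. The log-slope
  parametrization enforces `k > 0` without constraints.
* Uncertainty: parameter covariance from the Jacobian at the optimum,
  t-based 95% intervals; `R² = 1 − SS_res/SS_tot`.
* Identifiability: fits whose data never cross half-activation are flagged
  `unbracketed_midpoint`; a confidence interval wider than the stimulus span
  flags `ci_exceeds_span`. Flagged fits are returned, not silently trusted.
* The test suite cross-checks the optimizer against an independent dense
  2000×2000 grid search on ≤30-point problems: the optimum must land within
  one grid cell.

## Peak currents and normalization

`peak_current()` takes the extremum of the (optionally smoothed) trace in a
step window. Two baseline conventions exist, and the distinction matters:

* `"pre_step"` subtracts the median of the 100 ms before the step. This
  measures the *evoked increment* — appropriate for questions about added
  current, and it is the package default for the bare function.
* `"none"` measures against the amplifier zero. The analysis pipeline uses
  this for Boltzmann fitting: the resting channel current *is* the floor of
  the two-state curve, and subtracting it before fitting a unit-amplitude
  sigmoid would distort the recovered midpoint by several percent.

A 50 ms running mean precedes peak picking in the pipeline because the raw
sample maximum of a noisy plateau is biased upward by the noise order
statistics (~3 SD for a 1000-sample window).

Normalization (`normalize_currents()`) divides peak magnitudes by the patch
maximum, so inward-current channels (MscS at −60 mV) map into [0, 1] the
same way. QC (`qc_patch()`) excludes patches whose basal current exceeds
0.25 of the maximum, and patches without a saturating response (the two
largest-stimulus responses must agree within 0.10 of the maximum) — without
saturation the normalization denominator is not pinned down.

## Imaging: arc detection and circle fitting

Detection picks the brightest pixel per ROI row (ties to the smallest
column, deterministically). Contrast enhancement, if requested, is a
1st–99th percentile clip applied to detection only. Coordinates are 1-based
(R convention), x = column, y = row, origin top-left.

Three continuity filters remove off-membrane detections; the published
procedure names three approaches without defining them, so the concrete
definitions here are this package's own:

* `max_jump` (threshold 5 px): sequential column-jump limit;
* `median_residual` (c = 3): iterated trimming on radial residuals about a
  provisional circle, refit until membership stabilizes (a single pass is
  not robust — outliers drag the provisional circle);
* `ransac_circle` (tol 2 px, 500 seeded draws): largest consensus set of
  exact three-point circles.

Circle fits: the exact three-point solution (manual method) and the
algebraic Kåsa least-squares fit, with optional geometric refinement
minimizing orthogonal residuals. On three points all routes agree to 1e-9 px;
on sampled arcs they agree to within the noise. Integer-pixel detection
limits accuracy on *shallow* arcs: radius recovery within 0.5 px holds when
the visible arc subtends a reasonable angle (the per-frame ROI covers up to
±0.85 r), and degrades for near-flat membranes — which is also why tensions
from radii above 25 µm are flagged `flat_patch`, and why tensions below
0.36 mN/m (the smallest value resolvable by this approach) are flagged
`below_range`.

## The synthetic world

The generator's defaults are the stated experimental conditions, not free
dials:

| quantity | default | basis |
|---|---|---|
| T50, slope | 4.4, 1.7 mN/m | printed TRAAK global fit |
| channels/patch | 400 × 1.5 pA | "hundreds" at ~1–2 pA |
| basal tension | 0.5 mN/m | low end of the ~0.5–4 mN/m resting range |
| current noise | 5% of max current | calibrated recovery level |
| arc image noise | 20% of arc intensity | calibrated recovery level |
| frame rate | 120 Hz | stated acquisition rate |
| cohort size | 12 patches | reference dataset size |

Patch mechanics are not modeled anywhere in the source material, so the
forward geometry model is a declared fixture: `r(ΔP) = r_pip (1 + P_c/|ΔP|)`,
capped at `50 r_pip` for a flat (unpressurized) patch. It is monotone (so
tension strictly increases with pressure magnitude), asymptotes to the
pipette radius, and reproduces the qualitative look of real patches; it
makes no physical claim. Pipette radius defaults to 1.5 µm (a 2–3 MΩ tip)
with a compliance scale of 20 mmHg; between-patch jitter (lognormal CV 0.2
on radius, 0.3 on compliance, 0.5 on channel count; basal tension SD
0.3 mN/m) reproduces the observed dispersion of current–pressure relations
that collapses in the tension domain. Gating parameters carry no jitter by
default: gating is a property of the channel, not the patch.

Two semantic choices deserve note:

* **Basal tension floors, it does not add.** The driving tension during a
  step is `max(basal, stimulus)`. The experimental analysis computes
  stimulus-induced tension with the resting tension unaccounted for; an
  additive model would bias every recovered midpoint downward by the basal
  tension and make fold activation inconsistent with the closed form
  `P_O(T_max)/P_O(T_basal)`.
* **The default protocol saturates.** Steps of −5, −10, −20, −40, −80,
  −140 mmHg drive the mean patch from ~2.5 to ~16 mN/m
  (`P_O(T_max) ≈ 0.999`). Because the fit fixes the amplitude at 1 while
  data are normalized to the finite-tension maximum, a top step that only
  reaches `P_O ≈ 0.99` compresses the recovered slope by >1% even with
  exact data. Genuine saturation is also what the experimental QC demands.

What the generator does **not** emulate: pipette-wall fluorescence and
debris, patch creep up the pipette, non-spherical cap geometry, correlated
(1/f) current noise, photobleaching, and acoustic-field physics (ultrasound
experiments specify the peak pressure at the patch directly). A green
recovery test therefore establishes that the analysis inverts its stated
forward model at realistic noise — not that it is robust to every artifact
of real recordings.

At the calibrated noise level the 100-replicate Monte-Carlo recovery of the
global midpoint shows a small systematic underestimate (~0.1 mN/m, ~2%),
from QC selection (patches whose jittered geometry under-saturates are
excluded asymmetrically) together with residual amplitude compression. The
acceptance suite asserts the mean recovered T50 within ±0.2 mN/m of truth —
the published uncertainty scale — and documents the bias rather than hiding
it.

## Ultrasound

Hydrophone voltage traces convert to pressure by the frequency-specific
Pa-per-volt calibration factor; acoustic intensity is

$$I = \frac{(p \times 0.707)^2}{1.48 \times 10^6\ \mathrm{kg\,m^{-2}\,s^{-1}}}
      \times \frac{1}{100^2}\ \mathrm{W/cm^2},$$

the RMS pressure squared over water's characteristic impedance. The 0.707
peak-to-RMS factor is kept as the literal constant (not 1/√2) so outputs
match the published arithmetic digit for digit; the impedance is
configurable for other media. The reported value is the intensity at the
peak pressure and is labelled as such — spatial/temporal averaging over the
burst is not modeled. Power-domain dose–response curves reuse the same
sigmoid machinery, but their parameters are empirical: `channel_energetics()`
refuses power-domain fits because `k_B T / k` has no area interpretation
when `k` is in W/cm².

## Worked quantities

```{r energetics}
# printed global fits -> energetics (25 C)
channel_energetics(c(4.4, 1.7))   # TRAAK
channel_energetics(c(6.4, 2.3))   # TREK-1
channel_energetics(c(5.8, 1.4))   # TREK-2
activation_range(c(5.8, 1.4))     # TREK-2 10-90% range: 2.7 - 8.9 mN/m
```

```{r pipeline, eval = FALSE}
co  <- generate_cohort(n_patches = 12, seed = 1, arc_noise_sd = 20)
rep <- run_analyze(co)
print(rep)
plot(rep$fit_tension)
```

## Known limitations

* Tension is computed from stimulus-induced curvature only; resting tension
  is real but unmeasured, so low-tension points are systematically
  under-reported — exactly as in the experimental analysis it mirrors.
* Integer-pixel detection caps radius accuracy on shallow arcs; sub-pixel
  localization is deliberately out of scope.
* The recovered global midpoint at calibrated noise carries a ~2% downward
  bias (documented above).
* Per-channel printed 10–90% ranges other than TREK-2's differ by up to
  0.2 mN/m from the closed form evaluated on the rounded printed parameters
  (the published fits presumably used unrounded values); derived-quantity
  checks anchor on the self-consistent case.
* Group-comparison statistics (ANOVA, paired t-tests) are out of scope; the
  exported tidy tables are structured for any standard stats tool.
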