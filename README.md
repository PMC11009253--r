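# patchtension

Quantifying activation of mechanosensitive ion channels by membrane tension
from simultaneous patch-clamp recording and patch fluorescence imaging.

Mechanosensitive K2P channels (TRAAK, TREK-1, TREK-2) and bacterial channels
such as MscS are gated by in-plane membrane tension, but most assays report
only applied pressure. This package implements the analysis that converts a
pressure-clamp experiment with patch imaging into a tension dose–response:

1. **Membrane arc extraction** — the brightest pixel in each row of a
   fluorescence frame traces the membrane; outliers are removed by one of
   three continuity filters (`max_jump`, `median_residual`, `ransac_circle`).
2. **Radius of curvature** — circle fits to the point list: an exact
   three-point solution (the determinant intermediates A, B, C, D with
   radius = sqrt((B² + C² − 4AD) / 4A²)) and an algebraic (Kåsa) least-squares
   fit with optional geometric refinement. Both agree to numerical precision
   on three points.
3. **Young–Laplace tension** — `T = |ΔP| · r / 2`, with explicit unit
   handling (mmHg → Pa, µm → m; reported in mN/m).
4. **Gating analysis** — peak current per pressure step, normalization to the
   patch maximum (`I/Imax`), QC (basal `I/Imax` ≤ 0.25; saturating response
   required), and the central model:

   ```
   I/Imax(T) = 1 / (1 + exp((T50 − T) / k))
   ```

   a two-state Boltzmann with midpoint `T50` and slope factor `k`, fitted
   per patch or globally across patches. From a tension-domain fit the
   channel energetics follow: in-plane area expansion `ΔA = kB·T_abs / k`
   and gating free energy `ΔG = (T50 / k) · kB·T_abs`, and the 10–90%
   activation range is `T50 ± ln(9)·k`.
5. **Ultrasound stimulation** — hydrophone volts → Pa via the calibration
   factor, acoustic intensity `I = (p·0.707)² / Z / 100²` W/cm² (Z =
   1.48×10⁶ kg m⁻² s⁻¹, water), and power-domain dose–response midpoints.
6. **Synthetic experiments** — a generator with known ground truth (pressure
   protocols, a phenomenological patch-geometry model, Boltzmann-gated
   macroscopic currents, rendered fluorescence arcs with seeded noise) so the
   entire pipeline is testable end to end without recorded data.

`fit_boltzmann()` returns a classed model object with the usual verbs:
`print`, `summary`, `coef`, `vcov`, `confint`, `predict`, `fitted`,
`residuals`, `plot`, `simulate`.

## Worked example

Simulate a 12-patch TRAAK-like cohort (true T50 = 4.4 mN/m, slope =
1.7 mN/m, 400 channels × 1.5 pA, 5% current noise, 20% arc-image noise,
between-patch geometry jitter) and analyze it end to end:

```r
library(patchtension)

co  <- generate_cohort(n_patches = 12, seed = 1, arc_noise_sd = 20)
rep <- run_analyze(co)
print(rep)
#> Analysis report: 12 patch(es), 0 excluded by QC
#> Tension-domain global fit:
#> Boltzmann global fit (mN/m domain)
#>              estimate     se  lower  upper
#> midpoint       4.3013 0.0071 4.2871 4.3155
#> slope_factor   1.7200 0.0091 1.7019 1.7382
#> n = 72 points, 12 patch(es); R^2 = 1.000
#> Channel energetics at 298.15 K (T50 = 4.30, slope = 1.72 mN/m):
#>   dA = 2.39 nm^2
#>   dG = 1.03e-20 J (2.50 kBT)

activation_range(rep$fit_tension)
#> 10-90% activation range: 0.5 - 8.1 mN/m
```

The global fit recovers the generator's midpoint within ~0.1 mN/m (a small
systematic underestimate from QC selection and finite saturation; see the
methods vignette) and the slope factor within ~1%. The energetics say the
open channel occupies ~2.4 nm² more membrane cross-section than the closed
one, and that opening costs ~2.5 kBT at zero tension — which is why the
channel is mostly closed at rest and opens steeply once tension pays that
cost.

Published global-fit parameters can be fed to the derived-quantity functions
directly, e.g. the TREK-2 activation range from its printed fit:

```r
activation_range(c(5.8, 1.4))
#>    lower    upper
#> 2.723917 8.876083   # 2.7 - 8.9 mN/m at one decimal
```

## Acceptance script

`scripts/acceptance.R` recomputes, from the installed package, the
desk-scale quantities that published parameters pin down exactly — the
TREK-2 10% and 90% activation-range bounds from its printed global-fit
parameters — and writes them as JSON. It also exercises the full
simulate-and-analyze pipeline at the given seed as a sanity check.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
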