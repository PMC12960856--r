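---
title: "A lumped-parameter model of ECMO circuit hydraulics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lumped-parameter model of ECMO circuit hydraulics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecmoflow)
```

## The model and its assumptions

`ecmoflow` treats a venovenous ECMO circuit as a single series hydraulic
loop: drainage cannula and connecting tube 1 on the suction side, a
centrifugal pump, then connecting tube 2, oxygenator, connecting tube 3
and return cannula back to the venous bath. Three principles carry the
whole model: passive components consume pressure, the pump supplies it,
and at steady state the pressure consumed equals the pressure supplied.

Each element is summarised by one quadratic pressure–flow curve
\(P(Q) = K_1 Q^2 + K_2 Q + K_3\) (mmHg; L/min). For cannulas and tubing
the quadratic term captures inertial (density-driven) losses and the
linear term viscous losses. The quadratic family is an engineering
approximation to the catalog curves, not a derivation from pipe-flow
theory, and it is what makes the operating point available in closed form.

Assumptions worth keeping in mind:

* **Steady, incompressible, Newtonian flow.** Pulsatility, tubing
  compliance and the shear-thinning rheology of blood are outside the
  model. The quadratic coefficients are whatever the catalog data imply
  for the fluid the catalog was measured with; no viscosity or hematocrit
  scaling is applied.
* **Series topology with a single pump.** Recirculation, shunts and
  suction-limited (collapsing-vein) drainage are not modelled; an
  excessively negative P1 is reported as a number, not as a dynamic event.
* **Two height levels.** The patient/bath level and the pump/oxygenator
  level are each internally flat; a single scalar bed height separates
  them.

## Step 1: curve fitting

`fit_quadratic_curve()` fits the quadratic by ordinary least squares
(`stats::lm`). Passive components are fitted with the intercept
constrained to zero: physically a passive element drops no pressure at
zero flow, and computationally the constraint is what lets the pressure
walk close exactly back on the CVP. Pump curves are fitted unconstrained
because their intercept is the shut-off head, a meaningful quantity
(validated positive at load time, with the head checked non-increasing
over the flow domain). With exactly as many points as free coefficients
the fit interpolates; with more points it smooths digitisation noise.
Whether a manufacturer's own fits constrain the intercept is generally
unknowable from catalogs, so the constraint is a deliberate package-level
choice, applied uniformly.

## Step 2: the operating point

Series components add their drops at equal flow, so the circuit curve is
the coefficient-wise sum of the passive curves. The operating flow solves
\(\mathrm{pump}(Q) = \mathrm{circuit}(Q)\), a quadratic equation solved by
the quadratic formula in `solve_operating_point()` /
`intersect_curves()`. Root selection: the stable operating point is the
positive root at which the head surplus \(d(Q) = \mathrm{pump}(Q) -
\mathrm{circuit}(Q)\) crosses zero from above (\(d'(Q^*) < 0\)); at a
crossing from below a perturbation runs away rather than restoring. For a
physically valid pump (positive shut-off head, falling curve) against a
passive circuit, \(d\) is a downward parabola with \(d(0) > 0\), so this
root exists and is unique; a negative discriminant or the absence of a
positive stable root is reported as "no operating point". The closed form
is cross-checked in the tests against an independent grid-scan oracle
(step \(10^{-4}\) L/min, agreement within \(10^{-3}\) L/min over 200
random circuits).

## Step 3: the pressure walk

Starting at the CVP, `walk_pressures()` subtracts each drainage-side drop
evaluated at \(Q^*\), adds the pump head, and subtracts each return-side
drop, recording every node. P1 is the node after the last drainage-side
component (pump inlet), P2 the node entering the oxygenator, P3 the node
leaving it. Because the pump head equals the total passive drop at
\(Q^*\), the final node equals the CVP to within \(10^{-9}\) mmHg — an
invariant the tests assert on every solvable circuit. Taps are positional
properties of the component order: a circuit without an oxygenator has no
P2/P3, and `tap_pressure()` refuses to invent them.

## Step 4: bed height

Raising the bed `h` cm above pump level converts potential energy into
pressure at the pump-level section: `apply_bed_height()` adds
\(h/1.36\) mmHg (the cmH\(_2\)O-to-mmHg conversion) to every interior
node, including P1, P2 and P3, leaving the bath-level endpoints and the
flow unchanged — the pressure "borrowed" from the height difference on the
way down is repaid on the way back up, so the operating point is
untouched. The blood specific-gravity factor 1.05 is available via
`include_specific_gravity = TRUE` but omitted by default; at 40 cm it
amounts to 1.5 mmHg, below gauge resolution. The offset is applied at full
precision; the 1-decimal rounding seen in printed output is presentation
only.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| tube coefficient `k1_per_m` | 4 | mmHg·min²/L² per m | calibrated so 1 m of 3/8-inch tubing drops 100 mmHg at 5 L/min, the Alfred ECMO guideline anchor; the split between K1 and K2 is not identifiable from that single anchor, so the default is a pure quadratic with both per-metre terms user-configurable |
| `q_max` | 10 | L/min | physical flow domain; evaluation beyond it extrapolates the fitted curves and is flagged with a warning rather than refused |
| `cvp` | 0 | mmHg | bench emulation: cannulas submerged in an open bath at bed level; clinical use passes the measured CVP |
| `include_specific_gravity` | off | — | see above |
| bench noise `sd_flow`, `sd_pressure` | 0.12, 10 | L/min, mmHg | see below |

## The synthetic bench

`generate_synthetic_bench()` stands in for a physical glycerin-primed rig:
it runs the factorial sweep (by default 2 drainage × 2 return cannulas ×
3 speeds × 3 bed heights = 36 combinations, in a fixed nested order) and
adds independent seeded Gaussian noise to each prediction. The default
noise levels — 0.12 L/min on flow, 10 mmHg on pressures — are the scale of
disagreement a careful bench comparison of this kind of model shows, so
the recovered validation statistics land in a realistic range (R² in the
mid-0.9s, pressure RMSDs around 10 mmHg).

What the generator deliberately does **not** emulate: systematic model
error (its measurements scatter around the model's own predictions, so
validation slopes converge to 1 by construction), flow-dependent or
heteroscedastic gauge error, drift, and any physics the model itself lacks
(non-Newtonian rheology, venous collapse, recirculation). Passing the
end-to-end tests therefore demonstrates that the pipeline is
self-consistent and that the statistics recover known inputs — not that
the model is accurate on real hardware; that requires a measurement table
from an actual rig fed to `validate_predictions()`.

The shipped component library is likewise synthetic: curve shapes follow
the field's qualitative facts (smaller cannulas steeper, higher speeds
higher shut-off head, flows in the 2.5–4.5 L/min range) but the
coefficients are invented, since manufacturers' coefficient tables are not
redistributable.

## Validation statistics

For each predicted/measured series `compute_validation_stats()` reports,
with the conventions fixed as: bias = predicted − measured; relative
error = (measured − predicted)/measured × 100 (signed, aggregated by the
median); quantiles by linear interpolation (`stats::quantile` type 7,
R's default); RMSD = \(\sqrt{\mathrm{mean}((\mathrm{pred}-\mathrm{meas})^2)}\).
Two R² variants exist and differ whenever the regression line is not the
identity: the headline `r2` is the observed-on-predicted regression R²,
and `r2_identity` (computed about the y = x line) is emitted alongside so
users can see both. A zero measured value makes the relative error
undefined and is reported as an error naming the offending combination
rather than silently dropped.

## Numerical choices and degenerate inputs

* Closure and energy-balance assertions at \(10^{-9}\) mmHg; the
  operating-point/oracle comparison at \(10^{-3}\) L/min (the grid
  resolution bound).
* Degenerate fits (too few points, all flows identical) fail with the
  offending source label; they are never silently regularised.
* Untabulated pump speeds are an error listing the tabulated ones — no
  interpolation between speed curves, and affinity-law scaling is
  deliberately out of scope, since only tabulated speeds are validated.
* A sweep keeps going past an unsolvable combination, flagging the row,
  so one bad configuration does not cost the other 35.
* The synthetic generator saves and restores the global RNG state, so a
  fixed spec is byte-reproducible without perturbing the caller's
  randomness.

## Problem sizes

The property suite runs 200 random circuits against the grid-scan oracle,
50 closure checks, 25–30 circuits per monotonicity family, and 200
Monte-Carlo repetitions of the 36-row bench for the RMSD-recovery check —
sizes chosen to make the statistical assertions stable under their fixed
seeds while the whole suite stays interactive (well under a minute for the
property tests).

## Known limitations

Everything listed under assumptions, plus: coefficients fitted from
glycerin-based catalog data transfer to blood only approximately; the
model has no notion of patient physiology (venous capacitance, cardiac
output), so it predicts what the circuit does at a given CVP, not how the
patient responds; and pressures are gauge pressures referenced to the
walk's starting CVP, so transducer-height conventions on a real rig must
match the two-level height model before comparing numbers.
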