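---
title: "Modeling an active lumbar exoskeleton: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling an active lumbar exoskeleton: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgabs)
```

## The problem

Industrial back-support exoskeletons apply external torques to the wearer's
trunk, and practitioners deciding whether to deploy one in a given job need
an estimate of the biomechanical effect *before* buying hardware. `lgabs`
models a generic active lumbar exoskeleton parametrically: given a motion
capture of the lumbar flexion angle and the device's assistance settings, it
computes the torque the device would apply frame by frame, resolves that
torque into the contact forces felt by the body, and recomputes a
motion-capture-based ergonomic risk score with and without the device.

The device modeled has two assistance modes that the wearer mixes on a
0–100 % dial (in steps of ten) for each mode:

* **Passive assistance** behaves like a spring: the supporting torque is a
  function of the lumbar flexion angle $\theta_C$ alone (measured against
  the global vertical; 0° upright, increasing with forward bending).
* **Active assistance** is motor-driven and supports *rising*: torque is a
  function of the trunk's ascent (extension) speed $\dot\theta_C$, and only
  engages when the wearer rises from a flexion deeper than an activation
  angle $\psi_A$.

Total device torque is the sum, $\tau_E = \tau_P + \tau_A$, applied per side
(left/right symmetric), so total torque on the body is twice the per-side
value.

## The torque model

### Passive curve family

The passive curve for one percentage is pinned by a keypoint table: five
*characteristic angles* $a_1 < \dots < a_5$ (deg), five *torque ratios*
$r_1 \le \dots \le r_5 = 1$, and a per-percentage maximum torque
$\tau_{max}(\eta_P)$. The curve passes through the five points
$(a_i,\ r_i \cdot \tau_{max}(\eta_P))$ and is interpolated section by
section with a shape-preserving (monotone Hermite, `monoH.FC`) cubic.
Unconstrained cubics can overshoot between knots and violate the device's
observed behavior — force grows progressively with flexion — so the
monotone dialect is used deliberately. Below $a_1$ the torque is held at
the first keypoint value (zero whenever $r_1 = 0$, the usual case); above
$a_5$ it is clamped at $\tau_{max}$. A single ratio vector is shared by all
percentages; only $\tau_{max}$ scales, which is what makes calibration from
three percentages sufficient.

### Active hinge law

Active torque follows a three-piece law in the ascent speed $v$:

$$
\tau_A(v) = \begin{cases}
0 & v < \dot\theta_{Lim} \\
s\,v + c & \dot\theta_{Lim} \le v \le \dot\theta_{max} \\
\tau_{A,max} & v > \dot\theta_{max}
\end{cases}
$$

where the line passes through $(\dot\theta_{Lim}, 0)$ and
$(\dot\theta_{max}, \tau_{A,max})$, so $c = -s\,\dot\theta_{Lim}$ always.
The law is continuous at both breakpoints, which makes the treatment of the
boundary speeds unobservable; the implementation puts the threshold speed in
the linear section (value 0) and the saturation speed at $\tau_{A,max}$, by
continuity. One row of the active keypoint table —
$[\tau_{A,max}, \dot\theta_{Lim}, s, c]$ — encodes the law for one
percentage.

### Scaling across percentages

Calibration measures a few percentages (100, 70 and 40 by default — the
levels a wearer actually uses for lifting and lowering work, plus the
maximum). The remaining multiples of ten are filled by *even distribution*:
maximum torques (passive) and both the saturation torque and the two
velocity thresholds (active) are linearly interpolated between adjacent
anchors, continued down to zero torque at 0 % and extended above the top
anchor with the last even spacing. Anchors are returned bit-exactly; each
generated active row recomputes its own slope and intercept from its own
thresholds. Percentages that are not multiples of ten are rejected rather
than interpolated, matching the device's own dial.

## Kinematics

Captures are uniformly sampled time series of $\theta_C$ (the rig samples
at 60 Hz). Velocity is estimated with central finite differences plus a
0.25 s centered moving average (linear signals pass through exactly).
Frames are labelled *descend* (flexing, $\dot\theta_C > +2$ deg/s),
*ascend* ($< -2$ deg/s) or *hold*; both defaults are configuration, not
constants baked into the math.

Cycles are delimited at upright turning points — the most-upright frame
inside each ascend-to-descend hand-over — so each cycle contains one
descent, its flexion peak and the full ascent back, including interrupted
ascents that pause and resume. An alternative convention delimits cycles at
flexion *maxima*; we rejected it because it attributes the ascent after a
shallow peak to a window that also contains the *next* (possibly deeper)
peak, which corrupts the activation rule below. Leading and trailing
partial cycles are kept and flagged.

The activation mask is the device's documented rule evaluated per frame:
active assistance applies exactly on ascend frames whose enclosing cycle
peaked beyond $\psi_A$. Whether the firmware latches activation when an
ascent is interrupted is not observable from outside; the per-frame
re-evaluation is the weakest assumption consistent with the device's
documented behavior, and the generator can produce interrupted-ascent
captures to exercise exactly this case.

## Statics

The free body of the device, per side: the chest pad reacts at lever
$D_{TT}$ above the trochanter, the leg pad at $D_{MT}$ below, a pelvis
force closes the horizontal balance, and the device weight splits between
shoulders and pelvis. Lever-arm division gives $F_C = \tau_E / D_{TT}$ and
$F_{Lg} = \tau_E / D_{MT}$; the pelvis force is computed as the residual
$F_R = F_C + F_{Lg}$, because no published quantification of it exists —
it is documented as a closure term, not a measurement. The leg-pad force is
given the same constant-lever reading as the chest force; a thigh-angle
dependence is plausible but unspecified, so the simpler reading is used and
flagged. Transfers of pad forces to skeletal points carry the induced
couple (planar cross product). The weight split defaults to 50/50 in the
absence of any published figure. The net force and moment of the full
action–reaction set is zero by construction; `equilibrium_residual()`
recomputes it as a diagnostic, and the test suite re-derives it
independently over randomized configurations.

Forces are carried internally in N and torques in N·m; chest loads are
*reported* in kgf (divide by $g$ = 9.80665) because load cells and force
tables in this field use kilograms.

## Calibration

Model development reduces repeated captures per percentage to one
averaged curve and extracts the keypoints:

1. **Averaging.** Traces (force vs. angle for passive, force vs. ascent
   speed for active) are resampled onto a common grid spanning the
   intersection of their ranges, then averaged pointwise. Two grids are
   supported: a uniform grid of `grid_size` points (the default), and the
   union of all source abscissae (`grid = "union"`), which represents each
   trace exactly at its own sample points. The calibration driver uses the
   union grid: with interpolation-free samples, the noise-free round trip
   recovers parameters to machine precision instead of being limited by
   grid resolution.
2. **Passive anchors.** The averaged force curve is converted to per-side
   torque through $D_{TT}$ (half the summed cell force per side). The
   maximum torque is read at the *last characteristic angle* — not the
   curve's global maximum, which under noise is biased upward — and ratios
   are the torques at each characteristic angle divided by it. Knot values
   are evaluated one-sidedly, by a local cubic least-squares fit over the
   half-section left of each knot: the model family is kinked at the knots
   (clamped flat above the last one), so interpolating across a knot has a
   chord bias proportional to the sample spacing, while the one-sided cubic
   is exact whenever the section is a cubic and averages noise otherwise.
3. **Active anchors.** The three-piece hinge is fitted by exhaustive search
   over candidate breakpoint pairs on the curve's own abscissa with the
   slope solved in closed form per candidate (deterministic, no random
   restarts), followed by a Nelder–Mead polish of the two breakpoints
   off-grid. A fit whose saturation speed touches the top of the measured
   range means the plateau was never observed, and calibration fails with a
   diagnostic rather than extrapolating.
4. **Assembly.** Anchors are scaled to all eleven percentages and bundled
   into a validated specification. Passive-only calibration produces an
   all-zero active table.

Hybrid captures are never used for calibration — the two modes are modeled
separately and hybrids serve only as validation material.

## Risk recomputation

The risk model mirrors motion-capture ergonomic methods that score each
posture on angle, angular acceleration, force, torque and grip, sum the
per-posture risks into a *risk per minute* percentage, and band it green
(< 25), yellow (25–40) or red (≥ 40). The exact score functions of the
commercial method this structure follows are proprietary; `lgabs` ships
surrogate piecewise-linear monotone maps, entirely exposed as
configuration. Every property the package guarantees — and every test —
relies only on the documented contract (monotone, non-negative), not on the
particular shape.

The package's contribution is the *delta*: the gravitational lumbar demand
(a static sagittal surrogate,
$(m_{trunk}\,g\,d_{com} + m_{hand}\,g\,d_{hand})\sin\theta_C$) is reduced
frame-wise by the device torque, clamped at zero — over-assistance is
modeled as zero residual demand, never negative loading. Only the force and
torque scores see the assisted demand; angle, acceleration and grip scores
are bit-identical with and without the device, which the suite asserts.
Per-posture risks fold in the normalization (score-to-percent factor and
repetition rate over the number of postures) so that the reported risk is
exactly their sum; doubling the repetition rate doubles the risk. How a
capture's duration maps to a workday repetition rate is workplace-specific,
so the rate is an explicit parameter with default 1, not a guess.

For validation against measured data the experimental branch converts the
measured chest force back to a device torque through $D_{TT}$ (the measured
force being the reaction to the device torque) and runs the *identical*
pipeline. With self-consistent noise-free data both branches coincide to
numerical precision.

## The synthetic study

No laboratory captures ship with the package; the generator reproduces the
structure of a characterization session from a known ground-truth model so
every claim is testable offline:

* raised-cosine flexion–extension cycles (peak sampled exactly), optional
  upright holds, optional mid-ascent pauses, additive white Gaussian angle
  noise before smoothing (IMU drift is out of scope);
* load-cell readings: the forward model's chest force plus Gaussian noise,
  plus a descent-phase contamination ramp proportional to descent speed —
  the simplest mechanism consistent with the observed artifact that cells
  keep measuring the user's return effort while lowering — plus an optional
  taring offset fixed at the frame of greatest flexion (cells are zeroed at
  deepest flexion in the rig). Default capacity 50 kg per cell; readings
  clip at twice the summed capacity with a warning;
* capture sets mirroring the experimental design: 3 repetitions × 3
  percentages for each mode (9 passive: one slow flexion–extension each;
  9 active: five faster cycles each, sweeping past the saturation speed)
  plus 2 hybrid captures at (100, 100) and (50, 50) with interrupted
  ascents.

All generators are bit-reproducible under fixed seeds. Default study sizes
(20 captures, 60 Hz, 20 Monte-Carlo seeds for the noise study at
$\sigma = 0.25$ kgf) keep the whole suite at desk scale — a few tens of
seconds — while leaving every estimate comfortably resolved.

What passing these tests shows — and what it does not: the synthetic data
exercise the *model family itself* (exact round trips, noise concentration
at the folded-normal mean $\sigma\sqrt{2/\pi}$, filter behavior), so they
validate the machinery, not the fidelity of any particular device's
parameter file. Real captures carry inertial forces, pad migration,
synchronization error and participant variability that the generator
deliberately does not emulate; deviations on real data will be dominated by
those, not by the numerics tested here. The shipped
`extdata/synthetic_device.yaml` is a plausible synthetic stand-in, not a
measured device.

## Numerical choices and degenerate inputs

* Keypoint tables validate on construction and on load: strictly increasing
  angles, ratios in [0, 1] ending at 1, non-decreasing maxima with zero at
  0 %, positive slopes wherever torque is positive, intercepts consistent
  with the threshold line to 1e-9.
* The 0 % active row cannot satisfy "slope > 0" (zero torque forces a zero
  slope); it is represented as an identically-zero law with thresholds
  carried along for continuity of the table.
* Velocity endpoints use one-sided differences; the smoother pads edges by
  replication, biasing only the outermost half-window.
* Hinge-fit tie-breaks are deterministic: grid search scans candidates in
  ascending order and keeps the first strict improvement.
* Degenerate calibration inputs fail loudly: flat zero passive curves,
  hinges without an observed plateau, non-overlapping trace ranges and
  non-monotone anchors all raise errors instead of producing a spec.

## Known limitations

* Sagittal-plane scalar mechanics only; no out-of-plane forces, no pressure
  distribution over pad surfaces.
* Hysteresis is not modeled (one curve for up and down motion), consistent
  with observations that the device compensates for it.
* The risk surrogate is a stand-in with the documented monotone contract;
  absolute risk percentages are not comparable to any commercial method's
  output, only paired differences computed within `lgabs` are meaningful.
* The activation rule is the observable per-frame contract; firmware-level
  latching, sensor fusion and control electronics are out of scope.
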