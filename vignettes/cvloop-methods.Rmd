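---
title: "cvloop: model, calibration and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cvloop: model, calibration and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cvloop` is a closed-loop, distributed lumped-parameter model of the
adult circulation with convective oxygen transport.  This vignette is
the package's own account of the science: the model and its
assumptions, the parameters that matter, how the preset was calibrated,
the numerical choices, and what the shipped tests do and do not
establish.

## 1. Model structure

The circulation is a network of 30 compartments — the four cardiac
chambers plus 26 vascular segments — connected by branches.  Branches in
the large vessels and across the valves carry their own flow
differential equation (blood inertance makes them second-order); the
high-resistance, negligible-inertia paths (carotid capillary beds into
the superior caval vein, the coronary microcirculation into the right
atrium) are quasi-static resistive branches.  The resulting state vector
of the default topology has exactly 62 differential states: 30 volumes,
24 segment flows, 4 valve flows and 4 valve open-fractions.  Oxygen
saturations are advanced by operator splitting after each hemodynamic
step and are not counted among the 62.

Unit system: pressure mmHg, volume ml, flow ml/s, time s, vessel
geometry cm.  Mechanical constants given in CGS (density, gravitational
acceleration) are converted with 1 mmHg = 1333.22 g cm⁻¹ s⁻².

### Chambers

Chamber pressure blends an active and a passive limb using the
normalised Double-Hill activation $a(\varphi)$ as a convex weight:

$$p = a\,E_{max,eff}(v)\,(v - V_0) + (1-a)\,E_{min}\varphi_d\!\left(e^{(v-V_{0d})/\varphi_d}-1\right) + R_{wall}\dot v .$$

This avoids any manual valve timing: systole and diastole emerge from
one continuous function.  The activation is the product of a rising and
a falling Hill sigmoid on the cycle-phase axis; its normalisation
constant is recomputed (dense scan plus ternary refinement) whenever the
shape constants or the period change, so the peak is always exactly 1.

*Ventricular shape constants.*  The published family fixes the form but
not the constants.  We use $\alpha_1 = 0.29$, $n_1 = 5$,
$\alpha_2 = 0.48$, $n_2 = 27.4$ (fractions of the period) for the
ventricles.  The often-quoted classic constants
($\alpha_1 = 0.303, n_1 = 1.32$) rise too early and too slowly: they cap
dp/dt$_{max}$ near 950 mmHg/s and, more importantly, let the ventricle
empty before peak elastance, which makes severe aortic stenosis plateau
near 120 mmHg instead of the published ≈180 mmHg.  A convex, late-rising
activation reproduces both the stenotic pressures and a realistic
upstroke.  The atria keep $n_1 = 1.32$, $n_2 = 27.4$ with
$\alpha_1 = 0.07$, $\alpha_2 = 0.125$ and contract at cycle onset; the
ventricles follow after a 160 ms atrioventricular delay.  When the heart
rate changes, both $\alpha$ are rescaled with the square root of the
rate ratio so systole shortens like $1/\sqrt{HR}$ (the clinical
QT-interval behaviour).

*Starling roll-off.*  $E_{max,eff} = E_{max}\,[1 - d\tanh(z^2)]$ with
$z = (v - v_{th})/w$ above the threshold $v_{th}$ and exactly
$E_{max}$ below it.  Defaults $v_{th} = 100$ ml, $w = 70$ ml,
$d = 0.5$ for both ventricles: contractility is untouched in the normal
operating range and declines smoothly during overload, curving the
end-systolic pressure-volume relation downward.

*Passive diastole.*  The exponential EDPVR is kept, but calibration
against the published baseline / systolic-failure / diastolic-failure
triplet (EDV 107/133/83 ml at LAP 4.8/8.1/9.2 mmHg with only $E_{max}$
or $E_{min}$ changed) forces a *nearly linear* relation over the
clinical range: those three states are mutually inconsistent with a
sharply convex single exponential whose slope scales with $E_{min}$.
Hence the large widths ($\varphi_d$ = 145 ml for the LV, 200 ml for the
RV) with intercepts near zero.

*Septa.*  A single septal displacement volume
$\Delta = (p_{LV}^{free} - p_{RV}^{free})/(E_{sv} + e_{lv} + e_{rv})$
(with $E_{sv} = E_{sv0}\,e_{lv}(t)$, stiffening in systole) is
subtracted from the left and added to the right effective volume, which
both reproduces the published pressure-transmission formula in the
fixed-right-pressure limit and conserves volume exactly.  The local
tangent elastance — not the basal $E_{min}$ — enters the denominator;
using $E_{min}$ underestimates the diastolic stiffness of a dilated
chamber by an order of magnitude and produces runaway septal shifts.
The atrial septum is identical with a constant stiffness.

*Pericardium.*  $p_{peri} = p_{min} + p_s e^{(V - V_{pc0})/\varphi_{pc}}$
over the total contained volume (chambers + 380 ml myocardium +
pericardial coronary blood), with $p_{min} = -2$ mmHg: baseline
pericardial pressure sits slightly negative (≈ −1.3 mmHg) and rises
steeply only with cardiac dilatation.

### Valves and shunts

Valve opening is pressure-difference driven,
$d\zeta/dt = K_{open}\,\Delta p\,(1-\zeta)$ for positive and
$K_{close}\,\Delta p\,\zeta$ for negative gradients; rate constants
(20–30 mmHg⁻¹s⁻¹) make healthy valves open in ≈20–30 ms.  The pressure
gradient is Bernoulli plus inertial with the inflow length equal to the
instantaneous diameter.  A closed valve is handled by flooring the
effective area at 10⁻⁴ cm² (the quadratic Bernoulli term then forces
the flow to microliters per second) so the state vector keeps a fixed
size.  Septal defects and the ductus use the Gorlin orifice law with
C = 1 and g = 980 cm/s²; all three shunt areas default to zero.

### Vascular network

Every segment is defined by the geometry of one representative vessel
(length, radius at normal mean pressure, wall thickness) and the number
of parallel vessels.  Named conduit arteries carry anatomical
dimensions; lumped beds (arteriolae, capillaries, venous reservoirs)
are reconstructed by inverting the Poiseuille/volume/elastance relations
from design targets — resistance, contained volume and compliance at the
normal mean pressure — chosen to meet the published systemic and
pulmonary pressures, the blood-volume distribution (≈72 % systemic
venous) and a 25.8 %-point arteriovenous oxygen saturation difference at
rest.  Each segment records whether its dimensions are "anatomical" or
"calibrated".  One incremental Young's modulus (3000 mmHg) serves every
segment, so vascular stiffness scenarios are a single-parameter patch.

Transmural pressure follows the anchored exponential
$p = p_0\,e^{(E_0/p_0)(v - v_{ref})}$; resistance, inertance and
elastance are re-evaluated every step from the instantaneous radius
$r = r_0\sqrt{v/v_{ref}}$.  The viscoelastic wall resistance
$\Omega = \lambda\sqrt{I\,E}$ ($\lambda = 0.5$ everywhere) sits in
series with the compliance, in parallel with the blood path, so it
damps the pulse without touching total peripheral resistance.  The
caval veins are intrathoracic: with them outside the thorax, a Valsalva
strain empties the right atrium into collapse, which the model does not
represent (the exponential wall law cannot go slack).

The two coronary branches leave the aortic root and drain into the
right atrium; the microvascular segments feel 0.4 × their ventricle's
pressure as external compression, producing the systolic impediment of
left coronary flow.

### Oxygen

Saturation is the transported state; content follows
$C = 0.0000136\,Hb\,Sat\,V$ (Hb in g/l, Sat in percent — the reading
that gives ≈183 ml O₂ per litre of arterial blood).  Transport is
upwind and conservative: donors export at their own saturation.  Blood
entering the pulmonary capillary arrives at the flow-weighted mixture
of 99.4 % (oxygenated fraction) and its own saturation (the 10 %
shunt), the difference being alveolar uptake.  The systemic sink
(250 ml/min) drains the capillary compartments in proportion to flow;
myocardial consumption is recomputed each beat from the
pressure-volume area ($a = 1.8\cdot10^{-5}$ ml O₂/(mmHg·ml),
$b = 0.0024$, $c = 0.014$ per 100 g, LV 150 g / RV 60 g) and drawn from
the coronary microvascular blood, putting coronary sinus saturation
near 30 %.

### Baroreflex

A first-order filter (τ = 2 s) of ascending-aortic pressure drives
three bounded linear actuators (gains 2 / 1.5 / 2 per fractional mmHg
error; limits 0.5–2) on heart rate, ventricular $E_{max}$ and systemic
arteriolar resistance.  Disabled (the default), the solver output is
bit-identical to a zero-gain run.

## 2. Numerics

Implicit Euler at dt = 0.25 ms, solved by chord Newton with a
finite-difference Jacobian (refreshed every 25 steps, on failure, or on
step-size change; LU factors reused between refreshes).  Convergence
requires a weighted-RMS correction or residual below 1 (relative
tolerance 10⁻⁹); solutions are additionally rejected when they leave
physically plausible per-step bounds — the quadratic valve law and the
exponential walls admit spurious Newton roots during violent transients,
and the bounds force sub-stepping onto the physical branch.  On repeated
failure the step halves recursively (≤10 levels).  Three guards keep
transient iterates finite without affecting accepted states: the
transmural exponential continues linearly beyond e²⁰, segment properties
evaluate volumes floored at 2 % of reference, and branch inertance is
floored at 5·10⁻⁵ mmHg·s²/ml so every flow state remains resolvable at
dt.  Halving dt to 0.05 ms changes beat-averaged cardiac output by
< 0.1 %.

Timed parameter events (scenario stages, Valsalva strain) are ramped
linearly over 1 s in eight sub-steps: instantaneous changes in, e.g.,
arteriolar radius re-anchor the stiff exponential wall and can shock the
solver; vasomotor adjustments over ~1 s are also the physiological
time scale.  Parameter "dilation" events act on the reference geometry,
so resistance falls only as the bed actually refills — an intentional,
physical delay.

Blood volume equal to the preset design total is distributed over
compartments by the stored fractions; any surplus or deficit (for
example the +10 % blood-volume sensitivity run) is distributed in
proportion to compliance, i.e. into the venous reservoirs, as volume
loading does clinically.

## 3. Calibration

Published values fix: blood volume 5600 ml, viscosity 0.00024 mmHg·s,
density 1.060 g/cm³, HR 72 min⁻¹, Hb 140 g/l, VO₂ 250 ml/min, pulmonary
capillary saturation 99.4 %, shunt 10 %, Y = 3000 mmHg, λ = 0.5,
dt = 0.25 ms, LV $E_{max}$ 2.8 and $E_{min}$ 0.05 mmHg/ml, aortic area
5.0 cm², and the scenario patches.  Everything else (per-segment
dimensions, atrial and right-ventricular elastances, Starling and
pericardial constants, valve rates, coronary resistances) was
calibrated once against the published normal-case table and pathology
table, and then frozen.  The headline checks after calibration: CO 5.13
(5.09) l/min, SV 71.8 (71.6) ml, SvO₂ 69.0 (68.3) %, SAP 115/61
(112/61) mmHg, and the five pathology key values within ±10 %.
Acceptance thresholds and tolerances were never adjusted to outcomes.

## 4. What the tests establish — and what they do not

The synthetic world *is* the stated physiology: a single resting adult
with fixed parameters.  Green tests establish internal consistency
(conservation of volume and oxygen to round-off/steady-state balance),
agreement with closed-form oracles (two-element Windkessel discharge,
two-compartment oxygen exchange), reproduction of the published
steady-state numbers within ±10 %, and the qualitative directions of
the published maneuvers.  They do *not* establish patient-specific
validity, correctness of absolute waveform shapes, wave-propagation
physics (a lumped ladder only mimics reflection timing), or behaviour
under collapse/overdistension, which the model excludes by design.

## 5. Known limitations

* dp/dt$_{max}$ ≈ 1300 mmHg/s and LV Tei ≈ 2 sit outside their
  published rows (2359; 0.41): with a single Double-Hill per chamber,
  an upstroke fast enough for the printed dp/dt while keeping the
  printed ejection pattern was not attainable, and the long
  low-activation interval after the atrial kick inflates the model's
  isovolumic-contraction marker.  Both are reported, not asserted.
* EF 71 % runs at the top of the published band (67 ± 10 %): the
  near-linear EDPVR that reconciles the three published disease states
  fills the ventricle slightly less at rest.
* No vascular collapse or overdistension: transmural pressure is
  strictly positive, so extreme hypovolemia and cardiac arrest are out
  of scope; very low damping (λ → 0) produces flagged numerical
  ringing rather than graceful degradation.
* The ECG is a schematic weighted sum of activation functions with a
  60 ms electromechanical advance — display only.
* Oxygen saturations need ≈3 min of simulated time to settle to the
  closed-loop steady state (venous pool turnover); the Fick-balance
  check therefore runs at 220 s.
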