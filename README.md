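# cvloop — closed-loop lumped-parameter cardiovascular simulation

`cvloop` simulates the adult human circulation as a closed-loop,
distributed lumped-parameter (0D) model with oxygen transport.  It is
aimed at physiologists, intensive-care and perfusion researchers, and
modellers who need a fast, whole-system view of central hemodynamics:
how preload, afterload, contractility, valve disease, vascular stiffness
and the baroreflex interact — rather than organ-level 3D detail.

## The model

* **Four cardiac chambers.**  Each chamber's pressure blends an active
  and a passive limb with a normalised Double-Hill activation `a(t)`
  (product of a rising and a falling Hill sigmoid, peak scaled to 1):

  `p = a(t) · E_max,eff(v) · (v − V0) + (1 − a(t)) · E_min φ (e^((v−V0d)/φ) − 1) + R_wall dv/dt`

  `E_max,eff` carries a Starling roll-off (contractility declines during
  volume overload, bending the ESPVR).  Interventricular and interatrial
  septa transmit pressure with stiffness `E_sv = E_sv0 · e_lv(t)`; the
  pericardium adds `p_peri = p_min + p_s e^((V_heart − V_pc0)/φ_pc)`
  (negative at low volume) to every intra-pericardial compartment, on
  top of the intrathoracic pressure.
* **Valves.**  Gradually opening/closing orifices,
  `dζ/dt = K_open Δp (1 − ζ)` or `K_close Δp ζ`, with a Bernoulli plus
  inertial gradient `Δp = ρ/(2A²) q|q| + L dq/dt`, `L = 2ρ/(π r)` (the
  inflow length equals the instantaneous valve diameter).  Setting the
  open/closed areas produces stenosis and regurgitation.  Septal defects
  and a ductus follow the Gorlin orifice law `Q = 44.3 A √Δp`.
* **26 vascular segments** (systemic, pulmonary, coronary) with
  `R0 = 8ηl/(πr⁴n)`, `I0 = ρl/(πr²n)`, `E0 = Y_inc h/(2πr³ln)`,
  an anchored-exponential transmural pressure-volume relation
  (stiffening with distension), volume-dependent property updates
  through the instantaneous radius, and a viscoelastic wall resistance
  `Ω = λ√(I·E)` in series with the compliance so the damping never
  alters total peripheral resistance.  The coronary branches are
  compressed by their ventricle's pressure, reproducing the systolic
  impediment of left coronary flow.
* **Oxygen.**  `C = 0.0000136 · Hb · Sat · Volume`; upwind convective
  transport between all compartments, pulmonary oxygenation to 99.4 %
  with a 10 % shunt, a 250 ml/min systemic sink, and beat-by-beat
  myocardial consumption from the pressure-volume area
  (`VO2 ∝ a·PVA + b·E_es + c`).
* **Baroreflex** (optional): filtered arterial pressure error drives
  bounded multipliers on heart rate, ventricular `E_max` and systemic
  arteriolar resistance.
* **Solver.**  The 62 differential states (30 volumes, 28 branch flows,
  4 valve open-fractions) advance by implicit Euler at `dt = 0.25 ms`
  (chord-Newton, finite-difference Jacobian with LU reuse, halved
  sub-steps on failure).  Blood volume is conserved to round-off.

## Worked example

```r
library(cvloop)
params <- cv_preset("normal")        # calibrated resting adult, 5600 ml
trace  <- cv_run(params, 60)         # 60 s of simulated time
m <- beat_metrics(trace, "last")     # clinical summary of the last beat
```

`m` is a one-row data frame; formatted, the key columns read:

```
CO 5.13 l/min | SV 71.8 ml | LVEF 71.3 % | SAP 115/61(76) mmHg
PAP 23/5(11) | LAP 5.1 | RAP 4.1 | SaO2 96.4 % | SvO2 69.0 %
```

i.e. a cardiac output of 5.13 l/min with systemic pressures 115/61 mmHg
and a mixed venous saturation of 69 % — a resting adult with every value
in the normal clinical range.  Pathologies are one-line scenarios:

```r
run_scenario("systolic_hf")$report   # LV E_max 2.8 -> 1.0 mmHg/ml
```

```
scenario: systolic_hf
HR 72 /min  SAP 93/51(63) mmHg  LAP 9.4 mmHg
LVEF 37 %  LVSV 52 ml  LVSW 4133 mmHg.ml
LVEDV 142 ml  LVESP 92 mmHg  CO 3.75 l/min
```

— the classic picture of systolic failure: ejection fraction down from
71 % to 37 %, the ventricle dilated, filling pressure doubled.  The
other shipped scenarios are `diastolic_hf`, `aortic_stenosis`,
`aortic_regurgitation`, `valsalva`, `exercise` and `arteriosclerosis`
(see `cv_scenarios()`), and `sensitivity_analysis()` reproduces the
one-at-a-time +10 % parameter study.

A command line interface is installed as `exec/cvsim`:

```sh
cvsim run --preset normal --duration 60 --out trace.csv
cvsim scenario aortic_stenosis
cvsim metrics trace.csv
```

## Further reading

The methods vignette (`vignettes/cvloop-methods.Rmd`) documents the
model equations and assumptions, every tunable parameter with units and
defaults, the calibration of quantities that are not fixed by published
values, numerical choices, and known limitations.
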