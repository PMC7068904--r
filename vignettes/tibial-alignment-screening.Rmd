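---
title: "Screening tibial-component alignment with an L9 orthogonal design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening tibial-component alignment with an L9 orthogonal design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneealign)
```

## The problem

In total knee arthroplasty (TKA) the tibial component can be implanted with
small deviations in three angles: coronal varus--valgus tilt, posterior
slope of the tibial cut, and external rotation of the tray. Each deviation
changes how the femoral condyles load the polyethylene liner, and the peak
contact pressure on the liner is the standard proxy for wear risk. The
question this package addresses is a screening one: *which* of the three
angles matters most for peak liner pressure, and *which* level combination
minimizes it, using as few evaluations as possible.

## Orthogonal design and range analysis

A full factorial over three 3-level factors needs 27 evaluations; the
Taguchi orthogonal array L9(3^4) needs 9. Its defining property is pairwise
orthogonality: in every pair of columns, each ordered pair of level indices
occurs exactly once, so each factor's levels are balanced against all
settings of the others. `build_orthogonal_array(3, 3)` returns the
tabulated L9 (the only array this package builds -- three 3-level factors is
exactly its use case); `validate_orthogonality()` re-checks balance and
pair counts and is run by the pipeline before every analysis. The standard
factor set is

```{r}
tka_factors()
```

Note the varus level order (0, 3, -3): levels are positions in a declared
sequence, not sorted angles, and combination labels such as `A3B2C1` always
refer to level indices. The fourth L9 column is an unassigned error column
and is dropped when the design is instantiated.

Given one response $y_r$ (peak contact pressure, MPa) per run, range
analysis computes the level means
$K_{ji} = \mathrm{mean}\{ y_r : \text{factor } j \text{ at level } i \}$,
the per-factor range
$R_j = \max_i K_{ji} - \min_i K_{ji}$,
ranks factors by descending $R_j$ (larger range = more influence), and
predicts the optimal combination by taking, per factor, the level
extremizing $K_{ji}$ under the stated objective (default: minimize).
All means and ranges are kept at full floating precision; the 2-decimal
figures in reports are display rounding only. Ties -- equal ranges or equal
level means -- resolve deterministically to the earlier factor or lower
level index. No ANOVA or signal-to-noise machinery is attached: the method
is deliberately the plain range analysis, which is what the screening
design supports.

The package ships a nine-run reference response table
(`fe_reference_responses()`) of peak liner pressures from a validated
finite-element study of this screening under a 1150 N axial load; it drives
the worked example in the README and the end-to-end tests. Those FE
magnitudes are consumed as data -- the surrogate below does not attempt to
reproduce them.

## The elastic-foundation contact surrogate

A full finite-element solve is far outside desk scale, so per-run responses
can instead come from a reduced contact model with the classic
"bed of springs" (elastic foundation) idealization, which is the standard
first-order model for a compliant conforming layer: the liner
(E = 685 MPa) is orders of magnitude softer than the metal components, so
the femoral component is rigid and the bonded liner layer of thickness $t$
responds locally with pressure $p = k\,\delta$ per unit penetration
$\delta$, where

$$k = \frac{E(1-\nu)}{(1+\nu)(1-2\nu)\,t}$$

is the confined modulus of the layer divided by its thickness
(163.1 MPa/mm for the default E = 685 MPa, nu = 0.4, t = 9 mm). Friction
(coefficient 0.04) is recorded as metadata but excluded: with a purely
axial load at 0 degrees flexion, tangential tractions are second order.

### Geometry

The articulation is idealized and symmetric: two spherical condyles
(radius 30 mm) in two spherical dishes (radius 45 mm) centred at
+/-24 mm on the medial--lateral axis, liner thickness 9 mm, plateau
2.5 mm above the dish bottoms, evaluated on a 0.5 mm grid. None of these
dimensions are vendor geometry -- the source FE study's surfaces are not
published -- so they are illustrative defaults, all overridable in the
configuration. Alignment is applied to the component about the tray centre
as extrinsic rotations in a fixed order: external rotation about the
proximal--distal axis, then effective posterior slope about the
medial--lateral axis, then varus--valgus about the anterior--posterior axis.
Spheres rotate exactly (a rotated sphere is a sphere), so the height field
needs no small-angle approximation. The *effective* slope is the cut slope
plus the component's built-in 3 degrees; the screening factor is the cut
slope.

Two deliberate departures from the perfectly spherical ideal are worth
stating because they carry the physics that makes the screening non-trivial:

* **Mechanical-axis deviation.** With symmetric dishes, vertical springs and
  a vertical load through the tray centre, moment balance pins the pressure
  centroid under the load line and the compartments share load equally *at
  any varus tilt*. What actually overloads the medial compartment of a varus
  knee is that the limb's load line passes medial to the joint centre. The
  load case therefore offsets the load line by
  $L_{ml}\sin(\text{varus})$ medially and $L_{ap}\sin(\text{effective
  slope})$ posteriorly, with reduced-order levers (defaults 100 mm and
  50 mm) standing in for the limb geometry above and below the joint.
* **Conformity falloff.** In an ideal spherical dish the peak pressure is
  invariant to where the patch sits, which would make slope and rotation
  have exactly zero effect. Real inserts are dished at the dwell point and
  flatten outward; this is modeled as an extra gap $c_4 d^4$ ($d$ =
  distance from the dwell point, default $c_4 = 2\times10^{-5}$ mm$^{-3}$,
  sized to drop the effective contact radius from ~90 mm to ~70 mm at a
  3.5 mm offset), so off-dwell contact concentrates pressure.

### Ligaments

The collateral ligaments are two point-to-point uniaxial incompressible
Neo-Hookean springs ($\psi = C_1(\tilde I_1 - 3)$, Cauchy stress
$\sigma = 2C_1(\lambda^2 - \lambda^{-1})$, tension $\sigma A_0/\lambda$,
zero below the reference length) with $C_1$ = 6.43 MPa medially and
6.06 MPa laterally, attached at +/-35 mm lever arms. The tangent modulus
at reference stretch is $6C_1$. Reference length (60 mm), cross-section
(30 mm^2) and lever arm are placeholders -- the anatomical values are not
model inputs -- and are flagged as such in the configuration schema. The
default prestretch is 0.95: an extended knee has a few degrees of passive
varus--valgus laxity, so the collaterals engage only under appreciable tilt
(about 5 degrees at the default lever) and act as a safety against gross
tilt and lift-off rather than adding compression across the articulation in
routine equilibria. This also keeps every routine pressure map integrating
to the applied 1150 N.

### Equilibrium solve

Three rigid-body DOFs are solved: vertical settlement, varus--valgus tilt,
and a sagittal (flexion--extension-like) tilt; in-plane translations are
neglected for a conforming dish, and the femoral flexion *angle* is fixed
at 0 (the flexed-knee load case is out of scope). The residuals are total
vertical force and the two horizontal-axis moments about the tray centre,
with ligament tensions entering both. A damped Newton iteration
(forward-difference Jacobian; step halving with factor 0.5 whenever the
scaled residual grows; convergence at 0.1% relative residual -- force
scaled by the applied load, moments by load x compartment offset; hard cap
100 iterations) solves the piecewise-linear system, typically in well under
20 iterations. Non-convergence raises an error carrying the last
residuals; a state with zero total contact ("both compartments lifted
off") is likewise an error, not a silent zero map. Peak-pressure ties
between compartments resolve medially, documented and deterministic.

Numerical verification is built into the tests: on a single condyle over a
flat foundation (dish radius infinite, conformity falloff 0, tilts off) the
solve must match the closed form $F = \pi k R \delta^2$, peak $= k\delta$,
within 1% at a 0.25 mm grid, with error decreasing under refinement.

## The planted response

For testing the design/analysis machinery independently of the mechanics,
a planted convex bowl maps alignment to response:
base 16.5 MPa plus per-factor quadratic terms with curvatures
(1.0, 0.8, 0.6) MPa/deg^2 for (varus, cut slope, rotation) and the optimum
at (0, 1, 4) degrees. The curvature ordering mirrors the factor influence
ordering the screening is expected to recover, and the magnitudes were
sized by a power argument: at Gaussian response noise of 2% of base
(sigma ~ 0.33 MPa), a level mean of three runs has sd ~ 0.19 MPa, so the
smallest level-mean contrast (rotation: 0.6 MPa between the optimum level
and its neighbours) sits ~2.2 sd away and full-combination recovery is
expected ~97% of the time. Noise always requires an explicit seed;
noise-free runs are fully deterministic.

What the planted-mode tests do show: the L9 + range-analysis pipeline
recovers any on-grid optimum exactly without noise, and robustly under
realistic response noise. What they do not show: anything about real knee
mechanics -- that burden falls on the surrogate's property tests (load
conservation, closed-form agreement, mirror symmetry, varus-to-medial load
transfer), which are qualitative-to-quantitative checks of the model, not
reproductions of published FE magnitudes.

## Parameters at a glance

| Parameter | Unit | Default | Meaning |
|---|---|---|---|
| axial force | N | 1150 | ~2x body weight at 0 deg flexion |
| liner E, nu | MPa, -- | 685, 0.4 | polyethylene layer |
| liner thickness | mm | 9 | foundation layer depth |
| condyle / dish radius | mm | 30 / 45 | illustrative articular spheres |
| compartment offset | mm | 24 | dish centres at +/- offset |
| conformity falloff c4 | mm^-3 | 2e-5 | off-dwell gap growth |
| ml / ap load lever | mm | 100 / 50 | mechanical-axis deviation |
| ligament C1 (med/lat) | MPa | 6.43 / 6.06 | Neo-Hookean shear modulus |
| ligament L0, A0, lever | mm, mm^2, mm | 60, 30, 35 | placeholder anatomy |
| ligament prestretch | -- | 0.95 | slack at neutral (VV laxity) |
| inherent slope | deg | 3 | built into the component |
| grid spacing | mm | 0.5 | pressure grid (0.25 in oracle tests) |
| solver tol / damping / cap | --, --, -- | 1e-3, 0.5, 100 | Newton controls |

All angles are bounded by |angle| < 15 degrees -- beyond that the
height-field and small-tilt idealizations are meaningless, so the bound is
enforced at construction, not silently extrapolated.

## Problem sizes

The default grid is 161 x 81 cells (0.5 mm over +/-40 x +/-20 mm), on
which one equilibrium solve takes a few tens of milliseconds; a full
nine-run screening plus verification runs in well under a second. The
closed-form oracle uses a 0.25 mm grid over +/-8 mm. The noisy-recovery
study uses 50 seeded replicates of the planted-mode pipeline. These sizes
were chosen so the entire analysis is interactive on a laptop while keeping
discretization error comfortably inside the stated tolerances.

## Known limitations

* The surrogate's pressures are qualitatively, not numerically, comparable
  to published FE results: geometry is illustrative, the foundation model
  ignores shear coupling between springs, and bone, cement and stem
  stresses are out of scope entirely.
* The surrogate's own emergent optimum over the standard levels need not
  coincide with the reference FE optimum (with the default geometry it
  prefers mild valgus and minimal external rotation); the package's claims
  about the reference optimum come from the reference response table, and
  planted mode is the ground-truth harness for pipeline correctness.
  Because the surrogate surface has genuine factor interactions (rotation
  couples the dish dwell points to the slope-driven load offset), the
  additive main-effects prediction of range analysis can fail to beat the
  best single design run; the verification record flags this honestly
  rather than erroring.
* Only the static 0-degree-flexion axial load case is modeled; gait-cycle
  loading, flexed poses, and wear-depth prediction are non-goals.
* The mechanical-axis levers and ligament placeholder dimensions are
  reduced-order constants, not patient-specific quantities; conclusions
  about an individual knee should not be drawn from the defaults.
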