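---
title: "Pressure-based helix quantification in 4D flow MRI: models, parameters and design choices"
author: "helixflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pressure-based helix quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixflow)
```

# Scope and units

`helixflow` quantifies helical and vortical blood flow in time-resolved
three-directional phase-contrast MRI. Its detector is *global*: a relative
pressure map is recovered from the velocity field, and helices are the
connected regions where that map is negative. Around this core the package
provides centerline geometry, pathline integration with handedness
classification, measuring-plane flow quantification, optional
phase-contrast preprocessing, analytic phantoms with closed-form ground
truth, and paired agreement statistics.

Conventions used everywhere: world coordinates and voxel spacing in mm,
velocity in m/s (numerically equal to mm/ms, which keeps the pathline
integrator unit-free), time in ms, pressure in mmHg, volumes in ml. Voxel
centres define world positions; the mask and velocity share one grid;
velocity stored in other units is converted once at the I/O boundary.

# The pressure model

Inside the segmented vessel the pressure gradient is estimated from the
Navier–Stokes momentum balance

$$\mathbf G = -\rho\left(\frac{\partial \mathbf v}{\partial t}
  + (\mathbf v\cdot\nabla)\mathbf v\right) + \mu \nabla^2 \mathbf v$$

with defaults $\rho = 1060\ \mathrm{kg/m^3}$ and $\mu = 0.004\ \mathrm{Pa\,s}$,
standard values for blood (both configurable via `case_config()`). Spatial
derivatives are central differences, falling back to one-sided at the mask
boundary; the temporal derivative is a central difference cyclic over the
cardiac cycle; the viscous term requires both neighbours in-mask and is
otherwise dropped (it is three orders of magnitude below the inertial terms
at aortic scale).

## Integration by relaxation

Per phase, the relative pressure solves the fixed point

$$p_i = \frac{1}{|N(i)|}\sum_{j\in N(i)}
 \bigl(p_j + \mathbf G_{ij}\cdot(\mathbf x_i-\mathbf x_j)\bigr)$$

over in-mask face neighbours — a discrete Poisson problem with Neumann
walls. Two numerical choices matter:

* **Sweep order.** The voxel grid is bipartite, so simultaneous (Jacobi)
  updates carry an eigenvalue at −1: a checkerboard component oscillates
  indefinitely and the maximum-update stopping rule never fires, although
  the smooth part of the solution converges. The implementation therefore
  sweeps in red–black Gauss–Seidel order — the same per-voxel update, but
  each voxel sees its neighbours' freshest values. On the phantom domains
  this converges below the default tolerance of $10^{-6}$ mmHg in a few
  hundred sweeps (cap: 5000; non-convergence is flagged per phase, not
  fatal).
* **Midpoint gradient.** $\mathbf G_{ij}$ is the gradient at the face
  midpoint. The face-normal convective derivative is evaluated *compactly*,
  $\partial_a v_a \approx (v_{a,j}-v_{a,i})/h$, centred exactly on the face,
  rather than averaging the two voxels' wide central differences. Both are
  second order on smooth fields, but the compact form halves the stencil
  support and materially reduces smearing across sharp features such as a
  Rankine core edge: against the closed-form vortex pressure the relative
  L2 error at 2 mm drops from 11.4% to 9.9%, and refines to 5.4% / 3.0%
  at 1.6 / 1.0 mm. Transverse derivative terms, the temporal term and the
  viscous term are node-averaged.

The gauge is fixed per phase to zero mean over the mask; only pressure
*differences* are meaningful.

## Post-processing

In order: (1) one pass of the separable 3×3×3 binomial kernel (1,2,1)/4
per axis, per phase, with weights renormalized over in-mask neighbours
(constants are preserved; nothing bleeds across the wall); (2) clamping to
the 1–99% quantile range (type-7 linear interpolation between order
statistics) computed **globally** over all masked voxels of all phases;
(3) subtraction of the global mean of the clamped values, restoring a
map relative to the cycle-average pressure.

The global (rather than per-phase) scope of the clamp and shift is a
deliberate choice, switchable via `postprocess_scope`: a per-phase mean
shift would force negative voxels into *every* phase and make the temporal
existence parameter trivially 100%. With the global scope, phases without
flow structure keep values near zero and phases with a vortex keep their
(negative) cores.

## The helix threshold and its knife edge

Helix regions are voxels with $P < 0$ mmHg, strictly. On measured data
this is well-posed — pressure amplitudes are O(1) mmHg and never sit at
exactly zero. On *analytically clean* synthetic data the quiescent phases
are exactly zero before the global mean shift, so the final map places
them at $-\varepsilon$, where $\varepsilon$ (here $\sim 10^{-4}$ mmHg) is
whatever asymmetry the clamp introduced — and the strict threshold then
flags the entire vessel in every quiet phase. This is a property of the
exact-zero baseline, not of the method. The phantom analysis protocol
therefore applies a significance floor `helix_depth_mmHg = 0.01`
($\approx 1.4\%$ of the phantom's 1.99 mmHg analytic axis deficit, two
orders above the solver tolerance, and above the $\sim 7.5\times10^{-3}$
mmHg pressure ripple that the purely rotational acceleration of the
gate-adjacent phases projects to). The package default remains 0 — the strict criterion as defined.

# Helix metrics

Within a centerline-defined ROI (every mask voxel assigned to its nearest
centerline sample; arc-length interval half-open so adjacent ROIs
partition the vessel):

* **TH_Ex** counts phases with at least one retained 26-connected
  component — regardless of size or number of helices — times the temporal
  resolution; relative to the cycle length in percent. The component size
  filter `min_component_ml` defaults to 0.
* **HV series / HV_max** are per-phase retained volumes and their maximum;
  relative values use the static ROI volume (the segmentation is not
  time-resolved).
* **HV_acc** is the volume of the temporal union of retained voxels (a
  temporal maximum intensity projection); by construction it equals the
  per-voxel logical-OR volume exactly and is never below HV_max.
* **HVL_acc** maps each accumulated voxel to its nearest centerline sample
  and measures the union of the voxels' axial footprints (half a voxel to
  each side of the covered arc positions, merged as intervals). Coverage
  rather than max−min span: axially split helices are not overcounted. The
  footprint form keeps the measure independent of the centerline sampling
  step (default 1 mm) when voxels are coarser than samples.
* **HV(I)** divides volumes by body surface area. The BSA formula is
  DuBois, $0.007184\,W^{0.425}H^{0.725}$, the cardiology convention for
  indexing volumes; Mosteller is available behind a switch.

# Pathlines and rotation direction

Pathlines integrate $\dot{\mathbf x} = \mathbf v(\mathbf x, t)$ with
classical RK4 at step `dt/substeps` (default 4 substeps), trilinear
spatial and linear temporal interpolation, forward from the seed phase to
the end of the cycle. Velocity outside the mask is treated as *undefined*:
lines terminate at the wall instead of being dragged along it by
zero-padding. Seeding is dense inside the helix mask (every `stride`-th
flagged voxel), by default at the phase of maximum helix volume. The
substep default resolves swirl rates up to roughly 1 rad per substep; for
coarse temporal grids combined with fast rotation, raise `substeps`
(RK4's stability/aliasing limit, not an accuracy plateau).

Handedness follows the cross-section construction: at the centerline point
$c$ nearest the segment start, with tangent $\mathbf n$, the in-plane axes
are $\mathbf{nx} = \widehat{\mathbf n\times(1,0,0)^T}$ and
$\mathbf{ny} = \widehat{\mathbf{nx}\times\mathbf n}$ (fallback crossing
axis $(0,1,0)$ when the tangent is parallel to world x). Both segment
endpoints are projected into the plane, and the segment's label is the
sign of the signed rotation angle between the projections: a single rule
that reproduces the three documented quadrant cases (first→second
quadrant: right-handed; fourth→third: left-handed; diagonal quadrants:
decided by where the connecting line crosses the y-axis) without case
analysis, and is exactly antisymmetric under mirroring. Lines are
labelled RD+/RD− by majority vote over rotating segments; ties and
non-rotating lines are `indeterminate` and reported as such rather than
forced. An orientation flag (`LPS` default / `RAS`) flips only the
*reported* label, reflecting the stored-axis convention, never the
internal sign.

# Measuring-plane quantification

The plane sits orthogonal to the centerline at a chosen arc length
(default mid-ROI), sampled on an in-plane grid at half the smallest voxel
spacing; points with trilinearly interpolated mask value ≥ 0.5 form the
lumen. Net forward flow is the signed sum of through-plane velocity × area
× dt over phases (retrograde flow subtracts); peak velocity is the maximum
velocity magnitude (a switch selects the through-plane component instead).
With a binary mask the 0.5-level sits about half a voxel outside the last
in-mask centres, so the sampled lumen area runs ~10% large at 2 mm; the
flow integral is insensitive because velocity vanishes there.

# The phantom family

`phantom_spec()` builds a straight rigid tube (default: 120 mm long,
radius 10 mm, 2 mm isotropic grid, 25 phases at 40 ms — the scale of an
aortic 4D flow acquisition with velocities under a 150 cm/s encoding
limit) carrying:

* Poiseuille axial flow $v_z = 2\bar v (1-r^2/R^2)\,w(t)$ with a constant
  or raised-cosine systolic waveform;
* an optional Rankine vortex $v_\theta = \Omega r$ (core) /
  $\Omega r_c^2/r$ (free), of known sign, gated to a block of phases and
  an axial band;
* optional i.i.d. Gaussian velocity noise, seed-deterministic.

The `gated-helix` preset (swirl only, phases 5–14 of 25, band 40–80 mm,
$r_c = 5$ mm, $\Omega = 100$ rad/s) drives parameter recovery; the steady
ungated variant is the pressure-solver oracle via the cyclostrophic closed
form $\Delta p(r)$ of the Rankine vortex (−1.988 mmHg at the axis for the
defaults); the `poiseuille` preset checks flow quantification against
$Q = \pi R^2 \bar v$. The gated preset deliberately carries *no* axial
bulk flow: a steady Poiseuille ramp yields a viscous axial pressure
gradient whose downstream half is negative after mean-centring — a known
false-positive mode of the P<0 criterion that the test suite pins
explicitly rather than hides. Rankine (not Lamb–Oseen) keeps the pressure
oracle piecewise-exact.

What the phantoms do *not* emulate: curved and tapering geometry, moving
walls, through-plane motion of the vortex core, spatially correlated MRI
noise, phase-wrap/eddy artefacts (generated clean; the preprocessing
stages are exercised on constructed corruptions instead). Passing tests
on phantoms therefore validate the numerics and the parameter definitions,
not clinical performance.

# What band-tight recovery cannot do

One phantom property fails by physics, and is kept failing in the test
suite as documentation: the accumulated helix *length* does not recover
the 40 mm swirl band tightly. The Poisson response to an axially truncated
vortex extends beyond the vorticity band: in a Neumann tube the slowest
cross-sectional mode decays as $e^{-z\,j'_{1,1}/R}$ ($\approx 2.6$ mm per
e-folding at $R = 10$ mm) from a band-edge amplitude of ~0.7 mmHg, so the
$P<0$ region reaches tens of mm beyond the band at any defensible
significance floor (measured: 62 mm at 0.01 mmHg, 46 mm even at 0.1 mmHg,
against a 40 mm band). A pressure-based detector intrinsically reports
helices longer than their velocity support; consistent with that,
pressure-detected helices in healthy ascending aortas typically cover the
better part of the vessel length. Temporal
recovery is unaffected (quiet phases have no pressure structure at all),
and volume recovery is only mildly dilated.

# Statistics

`bland_altman()` uses the conventional 1.96·SD limits (not small-sample t
quantiles). `wilcoxon_signed_rank()` handles zero differences by the Pratt
method and is exact up to n = 25 via the subset-sum generating function
over doubled midranks (valid under ties), with a tie-corrected normal
approximation above. `icc_agreement()` is ICC(2,1) — two-way random
effects, absolute agreement, single measurement — the standard reliability
form for two-observer agreement; it is flagged undefined when the
between-subject mean square does not exceed the residual. Paired
correlation defaults to Pearson with Spearman available. None of these
choices is data-driven; all are fixed conventions.

# Problem sizes and determinism

The shipped tests and the acceptance script run the full pipeline on the
default 17×17×61-voxel phantoms (≈ 5000 lumen voxels, 25 phases) and the
solver comparison additionally at 1.6 mm (≈ 9200 voxels); pathline checks
use a few hundred seeds. These sizes exercise every code path at clinical
voxel counts per slice while keeping a complete run in the low minutes on
a single core. All randomness (phantom noise, statistical simulations) is
seed-derived; rerunning any pipeline with the same configuration produces
byte-identical metric files, which the suite asserts at the hash level.

# Known limitations

* Relative pressure only; no absolute calibration, no turbulence
  (Reynolds-stress) terms, no FEM Poisson solver.
* The strict P<0 threshold needs a significance floor on noise-free
  synthetic data (see above); on real data the floor defaults to off.
* Helical vs. vortical flow is not discriminated — the method treats both
  as "helix", as no quantitative cutoff separates them.
* Segmentation is static across the cycle; relative volumes use the
  static lumen.
* Eddy-current and phase-wrap corrections are generic static-fit /
  median-reference implementations of the standard corrections, not
  re-implementations of any scanner vendor's specific variant.
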