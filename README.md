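# helixflow

Pressure-based extraction and quantification of helical blood-flow patterns
in 4D flow MRI velocity fields.

Time-resolved phase-contrast MRI ("4D flow MRI") measures all three velocity
components of blood over a 3D volume across the cardiac cycle. Helical and
vortical flow in the ascending aorta is a marker that separates normal from
pathological hemodynamics (e.g. bicuspid aortic valve), but the common
local detectors (λ₂, vorticity, helicity) are noise-sensitive. `helixflow`
implements the alternative *global* approach: recover a time-resolved
relative pressure map from the velocity field and segment helices as
connected regions of negative relative pressure, then quantify them.

## The method

1. **Relative pressure map.** The pressure gradient is estimated from the
   Navier–Stokes momentum balance inside the vessel segmentation,

   G = −ρ(∂v/∂t + (v·∇)v) + μ∇²v,

   with ρ = 1060 kg/m³ and μ = 0.004 Pa·s for blood, central differences
   inside the mask (one-sided at the wall, cyclic in time), and is
   integrated per cardiac phase by iterative relaxation: every voxel
   repeatedly takes the mean over its in-mask face neighbours *j* of
   (p_j + G_mid·(x_i − x_j)), to a zero-mean (relative) pressure in mmHg.
2. **Post-processing.** One pass of a 3×3×3 binomial filter (mask-aware),
   clamping to the 1–99% quantile range over all phases, and subtraction of
   the global mean of the filtered values.
3. **Helix regions.** Voxels with P < 0 mmHg, per phase; 26-connected
   components inside a centerline-defined region of interest; their
   temporal union is the "accumulated" helix (a temporal maximum intensity
   projection).
4. **Helix parameters.**
   * TH_Ex — temporal helical existence: dt × (number of phases with a
     helix), in ms and % of the cycle;
   * HV_max — largest per-phase helix volume (ml, % of ROI volume);
   * HV_acc — volume of the accumulated helix (ml, %);
   * HVL_acc — centerline length covered by the accumulated helix (mm, %
     of ROI length);
   * HV(I) — volumes indexed to body surface area (DuBois), ml/m².
5. **Pathlines and handedness.** Dense pathline seeding inside the helix
   mask, RK4 integration through the time-varying field, and per-segment
   rotation-direction classification (RD+ right-handed / RD− left-handed)
   by the sign of the rotation angle in the vessel cross-section about the
   centerline; lines are labelled by majority vote.
6. **Conventional quantification and agreement statistics.** Net forward
   flow (ml/cycle) and peak velocity (m/s) at a measuring plane; Wilcoxon
   signed-rank, Pearson correlation, Bland–Altman bias/LOA and ICC(2,1)
   for paired comparisons (scanners, observers).

Analytic tube-and-vortex phantoms (pulsatile Poiseuille flow with a gated,
axially banded Rankine swirl of known handedness) provide closed-form
ground truth for every stage; see the methods vignette
(`vignettes/helixflow-methods.Rmd`) for the model, parameter defaults and
known limitations.

## Worked example

```r
library(helixflow)

## gated swirl phantom: 25 phases at 40 ms, 2 mm grid, Rankine vortex
## (r_c = 5 mm, 100 rad/s, right-handed) on for phases 5-14 and confined
## to z in [40, 80) mm of a 120 mm tube
ph  <- make_tube_phantom(phantom_preset("gated-helix"))
cfg <- case_config(helix_depth_mmHg = 0.01)   # phantom significance floor

pm  <- compute_pressure_map(ph$field, ph$mask, cfg)
hm  <- helix_mask(pm, cfg$helix_depth_mmHg)
roi <- define_roi(ph$mask, ph$centerline)
rs  <- extract_helix_regions(hm, roi)
helix_metrics(rs, roi, ph$centerline, ph$field$dt, ph$field$cycle_length,
              subject_meta(170, 70))
#> <helix_metrics>
#>   TH_Ex   400.0 ms (40.0% of cycle)
#>   HV_max  6.52 ml (16.5%) at phase 5
#>   HV_acc  6.52 ml (16.5%)
#>   HVL_acc 62.0 mm (51.7%)
#>   HV(I)   max 3.60 / acc 3.60 ml/m2
```

The recovered TH_Ex equals the generator's gate exactly (10 of 25 phases =
400 ms = 40%). HV_max/HV_acc is the detected vortex core volume. HVL_acc
(62 mm) exceeds the 40 mm swirl band: the pressure signature of a
truncated vortex physically extends a decay length (~R/3.83 ≈ 2.6 mm per
e-folding from a ~0.7 mmHg band-edge amplitude) beyond the vorticity
support, so a pressure-based detector sees a longer helix than the
velocity support — an intrinsic property of the global method discussed in
the vignette. The HV(I) values divide the volumes by the DuBois body
surface area of a 170 cm / 70 kg subject (1.81 m²).

Rotation direction and flow quantification:

```r
seeds <- seed_helix(hm, 5, stride = 2)
lines <- integrate_pathlines(ph$field, seeds, ph$mask, seed_phase = 5)
classify_pathlines(lines, ph$centerline)$counts
#>           RD+           RD- indeterminate
#>            80             0            47

pf  <- make_tube_phantom(phantom_preset("poiseuille"))
r2  <- define_roi(pf$mask, pf$centerline)
pl  <- measuring_plane(pf$centerline, r2, pf$mask, "mid")
net_forward_flow(pf$field, pl)    # ml/cycle; analytic pi R^2 v_mean = 62.8
#> [1] 62.272
peak_velocity(pf$field, pl)       # m/s; analytic centreline value 0.4
#> [1] 0.4
```

Every rotating pathline is labelled RD+, matching the generator's
right-handed swirl (stationary lines outside the band are indeterminate).

A command-line entry point wraps the same functions:

```sh
Rscript scripts/helixflow.R synth --preset gated-helix --seed 7 --out case/
Rscript scripts/helixflow.R run case/ --depth 0.01
Rscript scripts/helixflow.R compare metrics_a.csv metrics_b.csv
```

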