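---
title: "Methods: simulating ventricular excitation and its non-invasive reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating ventricular excitation and its non-invasive reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`ecgisim` is an in silico laboratory for electrocardiographic imaging (ECGi):
it simulates ventricular excitation on idealized bi-ventricle geometries,
computes body-surface potentials (BSP) through a boundary-element volume
conductor, reconstructs epicardial potentials from the BSP by Tikhonov
regularization, and quantifies how two clinical variables — an out-of-date
anatomical scan (wall thickening or chamber dilation since imaging) and the
pacing rate — degrade the reconstruction. Everything is generated in-package;
there are no external data dependencies.

# Anatomy: truncated-ellipsoid bi-ventricles

The left ventricle is a thick-walled truncated ellipsoid centred at the
origin; the right ventricle is a thin-walled truncated ellipsoid offset
towards +x whose crescent-shaped wall attaches to the LV epicardium, forming
the septum. Both are cut by the basal plane `z = z_base`, and `z` increases
from apex to base. The published description of this family of models fixes
the wall thicknesses (12 mm LV, 4 mm RV), the LV wall volume (196.56 mL) and
the grid resolution (0.5 mm, about 2 million tissue voxels), but not the
ellipsoid semi-axes themselves. The shipped defaults were derived
analytically so that the closed-form truncated-shell volume of the LV equals
196.6 mL with a 12 mm wall at mid free wall:

* LV epicardial semi-axes (42, 42, 68) mm; endocardial = epicardial − wall.
* RV epicardial semi-axes (54, 38, 60) mm centred at (12, 0, 0) mm.
* Basal truncation at z = +19 mm.

Variants: `thick` scales both wall thicknesses by 1.5 (hypertrophy,
18 mm / 6 mm); `dilated` scales the anterior–posterior short-axis diameter of
both ventricles by 1.5 with thickness preserved, which raises the LV wall
volume to ~263 mL. (Scaling *both* short axes would give 341 mL, well above
the published 255 mL for this variant, so the single-diameter reading is
used.) Wall-volume ordering control < thick < dilated is preserved.

The transmural coordinate d is computed by the two-distance formula
`d = dist_endo / (dist_endo + dist_epi)` from exact Euclidean distance
transforms seeded at the cavity voxels and at the external voxels below the
basal cut; it is 0 on the endocardium, 1 on the epicardium, and exactly
linear on a slab. Cell types are assigned by half-open depth bands — ENDO
[0, 0.4), MCELL [0.4, 0.7), EPI [0.7, 1] — so the bands cover 40/30/30% of
the transmural range with a deterministic tie-break towards the epicardium.
Whether the published 40/30/30 split was by depth fraction or node count is
ambiguous; depth fraction was chosen (they agree only approximately on
curved walls).

Fibers follow the rule `alpha = R (1 - 2 d)^n` with R = 60 degrees and
n = 1: the helix angle rotates linearly from +60 at the endocardium through
0 at mid-wall to −60 at the epicardium (120 degrees total). The local frame
is transmural axis = normalized depth gradient, apico-basal axis = global z
projected orthogonal to it, circumferential axis = their cross product; the
transverse angle is 0 and no sheetlet structure is modelled. Near the
RV–septum junction fiber vectors are smoothed by two neighbor-averaging
passes blended over a 2 mm Gaussian window ("a small degree of smoothing");
apex-pole voxels with a degenerate frame fall back to a frame built from the
x (or y) axis and are counted in an attribute.

# Electrophysiology

Membrane kinetics are the 2006 ten Tusscher–Panfilov (TT06) human
ventricular model with its three transmural variants. Regional
heterogeneities:

* I_Kr maximal conductance ratio ENDO:EPI:MCELL = 1.0:1.6:1.0 (the EPI
  conductance is scaled 1.6×), reproducing the longer endocardial action
  potential.
* I_to and I_Ks scale linearly along the apico-basal axis from 50% of the
  apical value at the base (`f_AB = 0`) to 100% at the apex (`f_AB = 1`),
  giving basal cells a roughly 50 ms longer APD.
* The short-AP variant multiplies I_Kr and I_Ks conductances five-fold; it
  sustains 1:1 capture at a 150 ms cycle length (400 beats/min).

"Maximum of 50% reduction" is interpreted as `g_base = 0.5 g_apex` with
apical values equal to the published constants. The repolarization level for
"AP duration" is not stated in the source description; APD90 is used and the
level is an argument of `compute_apd()`.

Single cells integrate with forward Euler and Rush–Larsen gate updates at a
fixed 0.02 ms step (matching the tissue solver's minimum step). The
depolarizing stimulus is −52 pA/pF for 1 ms. The test suite checks the
integrator against an independent ODE transcription of the model solved by
`deSolve::lsoda`.

# Monodomain propagation

`dV/dt = div(D grad V) − I_ion / C_m` with
`D = D_perp I + (D_par − D_perp) A A^T`. `D_par = 0.18 mm^2/ms` gives
~70 cm/s conduction along fibers on a 0.5 mm cable; the anisotropy ratio is
4:1. The spatial operator is a conservative finite-volume stencil with
face-averaged tensors, face-tangential derivatives for the cross terms, and
no-flux boundaries by construction (zero face flux), which conserves the
spatial mean exactly in the passive limit.

Time stepping is Godunov splitting (reaction, then diffusion) with an
adaptive step bounded by dt_min = 0.02 ms and dt_max = 0.2 ms. The published
description gives the bounds but not the switching rule; the rule used is:
dt_min whenever any voxel's |dV/dt| exceeds a threshold, else dt_max. The
threshold defaults to 0.5 mV/ms: with the looser 1 mV/ms rule the adaptive
solution deviated from a fixed dt_min solution by up to 0.7 mV on the cable
fixture, above the 0.5 mV fidelity target the package tests enforce; at
0.5 mV/ms the deviation is below 0.3 mV. Voltage-dependent terms of TT06 are
tabulated over V (0.02 mV spacing, linear interpolation) with the gate
exponentials precomputed for both admissible steps.

Two desk-scale devices keep large studies tractable; both are explicit
options, off by default:

* **CV-matched coefficients** (`cv_matched_diffusion()`): explicit finite
  differences underestimate conduction velocity when the upstroke spans few
  voxels. On coarse grids the study drivers rescale D so that cable
  conduction matches the 0.5 mm discrete velocities (68.5 cm/s
  longitudinal, 22.8 cm/s transverse), calibrated once by bisection on 1D
  cables: D_par/D_perp = 0.2866/0.0916 at 1 mm and 0.3654/0.1277 at 4/3 mm.
* **Per-cell adaptive reaction stepping** (`local_adaptive`): quiescent
  cells (|dV/dt| below threshold, unstimulated) re-evaluate their ionic
  currents only every dt_max, advancing V with the cached reaction
  derivative between evaluations; wavefront cells are evaluated every step.
  Activation times and conduction velocity are unchanged; repolarization
  timing of individual cells can shift (observed pointwise voltage
  differences up to ~10 mV during phase 3 on the cable), which is immaterial
  for the activation-phase metrics the studies use. The experiment drivers
  enable it; the default solver does not.

# Stimulation protocols

Sinus rhythm is 28 localized endocardial patches (9–12 mm diameter,
−52 pA/pF, 1 ms) fired in quick succession: a small septal block initiates
the wavefront, then patches spread from apex to base ordered by `f_AB`, with
onsets on a linear ramp. Patch centres are placed by deterministic
farthest-point sampling of the endocardial surface; the published protocol
gives only the count, sizes and the qualitative sequence. The default 30 ms
ramp was calibrated once so the control geometry's total activation time is
~65 ms at the 1 mm surrogate resolution (the classic normal value); the test
suite verifies 65 ± 10 ms.

Ectopic foci are single 5 mm-diameter stimuli at four named sites (RV-LAT,
SEP, LV-LAT, LV-Apex). Anchors are defined relative to the geometry
parameters (mid-wall at the equatorial plane, or mid-wall on the long axis
for the apex), so each site maps to the homologous position on every
variant. Rate studies replicate the stimulus at multiples of the basic cycle
length; 60000/BCL is the rate in beats/min. Ectopic runs contain no sinus
beat.

# Forward problem (volumetric sources, heterogeneous-capable BEM)

Equivalent sources are per-voxel current dipoles `p = −D grad(V) dx^3`
(central differences, reflection at boundaries), optionally aggregated to a
coarser source lattice (default 2–2.5 mm) for tractable dense products. The
BSP amplitude scale is a single calibration constant left at 1: all
comparison metrics are either scale-free (PCC) or relative (rRMSe), so the
absolute mV scale is arbitrary and documented as such.

The volume conductor is a closed torso surface (ellipsoid by default,
sphere for analytic fixtures; semi-axes 170 × 120 × 280 mm) with optional
nested organ compartments, each an icosphere-mapped watertight mesh.
Compartment conductivities default to standard literature values (torso
0.22, lungs 0.05, blood 0.7, liver 0.15, bone 0.02 S/m) and are
configurable data. The potential on all surfaces solves the vertex-collocated
double-layer system `sigma_bar phi − (1/4 pi) sum_l (Delta sigma)_l W_l phi
= s` with analytic flat-triangle solid angles, diagonal entries enforcing
the closed-surface principal-value identity (row sums 2 pi), and rank-one
deflation of the Neumann null space (zero area-weighted mean on the outer
surface). Electrode potentials are mean-referenced. The solver is verified
against the closed-form dipole-in-sphere solution (< 2% at the default
642-vertex density) and interior evaluation against the same series.

Electrodes default to 128 vertices chosen by seeded farthest-point sampling
(the electrode count of the original mapping system is not published; it is
configurable).

# Inverse problem (surface potentials, homogeneous torso)

The transfer matrix Z maps epicardial-surface potentials to torso-surface
potentials through the *homogeneous* torso (even when the forward model is
heterogeneous), using the two-surface Green-identity formulation: collocated
equations on both surfaces couple the surface potentials and the epicardial
normal gradient through double-layer (solid angle) and single-layer
(analytic uniform-triangle potential) operators; eliminating the gradient
gives Z. Because the forward path uses volumetric dipoles against a
compartment operator and the inverse path uses an equivalent surface
potential against a two-surface operator, the reconstruction can never
exactly invert the simulation ("inverse crime" is structurally excluded, and
the suite asserts it).

The epicardial envelope is extracted from the voxel heart (tissue plus
cavities, basal cap closed) by star-shaped ray casting onto an icosphere:
per direction from an interior centre, the outermost filled-voxel crossing
plus a quarter-voxel pad, followed by a containment-repair pass that
locally inflates any facet whose chord cuts below a tissue voxel centre
(facets chord below the surface on steeply slanted regions). The result is
watertight with icosphere topology, contains every tissue voxel, and
matches the voxel volume within 5%. A marching-cubes/decimation pipeline would give a more conformal
surface; the star-shaped envelope was chosen because it is exact for the
convex-ish bi-ventricle envelope, needs no remeshing, and its vertex budget
is set directly by the subdivision level (level 3 = 642 vertices by
default).

Reconstruction minimizes `||Z x − y||^2 + lambda^2 ||R x||^2` (the squared
seminorm; the unsquared form that appears in some printed versions of the
functional is treated as a typo, consistent with GSVD filtering) with R the
identity (order 0), the edge-difference gradient (order 1) or the umbrella
mesh Laplacian (order 2; cotangent weights were considered but the uniform
umbrella operator is kept as the default on the near-uniform icosphere
meshes). The GSVD of (Z, R) is computed via QR of the stacked pair plus the
CS decomposition of the orthonormal factor, and solutions are filtered in
the generalized spectral basis; tests verify equality with dense
normal-equation solves to 1e-8 across orders and lambdas.

lambda is selected on the L-curve: the (log residual, log seminorm) curve
is evaluated over a 40-point grid spanning the informative part of the
generalized singular-value spectrum (a decade below its median to two
decades above its 95th percentile, so near-null modes cannot stretch the
grid), and the corner is the maximum finite-difference curvature point,
ties towards stronger regularization. Two guards make the selector stable
on noise-free data, where the classical L-curve criterion is known to
break down: the search excludes the degenerate over-regularized tail
(collapsed seminorm or saturated residual), and a corner is only accepted
when its curvature exceeds 1 — a sharp kink marking a genuine noise floor
(measured curvatures: 2-48 at true noise corners, 0.1-0.9 for the weak
spectral kinks of noise-free underdetermined systems). Without an accepted
corner the data can be fit to its floor and the smallest interior grid
lambda is used (the minimal-seminorm regime). Granularity:
`reconstruct_timeseries()` selects lambda per snapshot by default ("at each
instant of time"); the experiment drivers use one shared lambda per case
(selected at the snapshot of maximum BSP power) because per-snapshot jumps
in lambda inject artificial steps into the temporal derivative from which
activation times are computed — with per-snapshot selection the order-2
localization error on a control test case degraded from under 1 mm to over
20 mm purely through that artifact.

# Metrics

Per snapshot: RMS `sqrt(sum(phi^2)/N)`; rRMSe `||phi' − phi|| / ||phi'||`
with phi' the reference field; PCC, the standard Pearson correlation (the
printed formulas in the source description are typographically corrupted;
the standard definitions from the ECGi validation literature are used).
Activation maps take the time of maximal −dphi/dt per node for
extracellular/epicardial potentials and +dV/dt for transmembrane upstrokes.
Focal-localization error (ED) is the distance between the centroids of the
earliest-activated node sets, "earliest" meaning within 5 ms of each map's
minimum (the operational definition of "centre of earliest activation" is
not published; the window is an argument). Both mean and median
aggregations are available since the source description uses both. White
BSP noise at a requested SNR (dB) is available and seeded.

# Experiments

All studies share one context: control geometry, torso, electrodes, forward
system, control epicardial envelope, and the control transfer matrix (the
inverse problem always runs on the control anatomy).

* **Geometry mismatch**: ectopic activation simulated on control, thick and
  dilated hearts; forward solved on the actual variant; reconstruction only
  ever on the control anatomy; errors computed against the control-geometry
  activation of the matched site, so geometry differences need no mapping.
* **Heart rate**: control geometry paced at several BCLs; metrics on the
  final beat against the case's own forward solution; the short-AP variant
  is engaged automatically at BCL 150 ms.
* **Short-AP mechanism**: a 2×2 design (control/short AP × slow/rapid BCL)
  separating the two candidate causes of rate-dependent error — shortened
  wavelength versus tissue still active from the previous beat: the
  short-AP model at rapid pacing keeps the short wavelength while removing
  the residual activity.

Desk-scale study sizes (all stated in the shipped defaults and the test
suite): ectopic studies at 4/3 mm (the coarsest grid that resolves the 4 mm
RV wall with 3 voxels, ~105k tissue voxels), the sinus surrogate at 1 mm,
2 ms snapshots, 128 electrodes, level-3 icosphere surfaces, 2 ectopic sites
for the geometry means and the LV lateral site for the rate/mechanism legs,
one beat at slow rates (>= 750 ms, where the tissue is fully repolarized
before the next beat) and two beats at rapid rates. The full 0.5 mm scale is
supported by configuration. Determinism: given a configuration and seed,
reports are byte-identical.

# Known limitations

* The torso is a synthetic parametric stand-in (the anatomically detailed
  torso of the original study is not published); absolute BSP patterns and
  the printed per-condition metric values are therefore not reproducible —
  only the calibration numbers and the qualitative orderings are, and those
  are what the acceptance suite checks.
* The septum inherits a small transmural-depth range from the two-distance
  rule (both septal faces are endocardial), so septal fibers rotate less
  than free-wall fibers and septal cells are predominantly endocardial-type.
* The dilated variant follows the published wall-volume table rather than
  the more aggressive all-axes reading; mismatch errors for the dilated case
  are still the largest of the three variants.
* No Purkinje system, no repolarization-pattern reconstruction, no
  electrode-position error or cardiac motion, and no LV/RV
  electrophysiological differences.
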