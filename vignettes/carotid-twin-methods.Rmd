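---
title: "Methods: parametric carotid twins, flow solvers and agreement analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parametric carotid twins, flow solvers and agreement analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carotidtwin)
```

## Scope and model

`carotidtwin` implements a digital-twin workflow for extracranial carotid
artery disease: a parametric, meshable model of the (possibly stenosed)
carotid bifurcation; blood-flow solvers with physiological boundary
conditions; readouts that mirror what a vascular laboratory measures (ICA
peak systolic velocity, trans-stenotic pressure drop under simulated
hyperemia, an FFR-like pressure ratio); and the statistical machinery for
validating computed velocities against Doppler ultrasound (DUS).

Patient imaging is deliberately out of scope. Where a clinical workflow
segments a lumen from CT angiography, this package *generates* one from a
`bifurcation_spec()` — the geometric stand-in that makes every downstream
stage testable without any data download.

### Hemodynamic model

Blood is an incompressible Newtonian fluid with density
$\rho = 1060\,\mathrm{kg/m^3}$ and dynamic viscosity
$\mu = 0.004\,\mathrm{Pa\,s}$, adequate for vessels of this caliber. Walls
are rigid with no slip. At the CCA inlet a Poiseuille-type profile is
imposed,

$$v_\mathrm{in}(x, y) = v_\mathrm{peak}\left(1 - \frac{x^2 + y^2}{r_\mathrm{CCA}^2}\right),$$

with $v_\mathrm{peak}$ the CCA peak systolic velocity (cm/s). Each outlet
carries a two-element Windkessel,

$$Q = \frac{P}{R} + C\,\frac{dP}{dt},$$

and the two outlet resistances are split inversely to the outlet
cross-sectional areas,

$$\frac{R_\mathrm{ICA}}{R_\mathrm{ECA}} = \left(\frac{r_\mathrm{ECA}}{r_\mathrm{ICA}}\right)^2 ,$$

while their parallel combination reproduces the total peripheral
resistance. Since absolute peripheral parameters for the carotid bed are
not tabulated anywhere authoritative, `calibrate_outlet_parameters()`
derives them from two interpretable inputs: a target mean arterial pressure
(default 90 mmHg) at a baseline total flow (default 600 ml/min), and a
Windkessel decay constant $\tau = RC$ (default 1.3 s, the order of the
arterial diastolic decay). All three are user-settable; the defaults are a
documented convention of this package, not a reproduction of any published
calibration.

The inlet is quasi-steady at the systolic peak by default (`steady_peak`):
the clinically reported quantity is PSV, and a peak-systole solve reads it
out directly. A normalized pulsatile waveform can be supplied instead
(`waveform = "pulsatile"`); the choice is recorded in the solution objects.

### Two engines

The package ships two solvers with one boundary-condition model:

* **Reduced-order network** (`solve_reduced_order()`): each branch is a
  chain of Poiseuille conduits and quadratic stenosis elements
  $\Delta P = aQ + bQ^2$, where $a$ is the viscous (Poiseuille) resistance
  of the stenotic throat and $b = K_t \frac{\rho}{2}(1/A_s - 1/A_0)^2$ a
  Borda–Carnot expansion loss with $K_t = 1.52$ by default. The inlet flow
  is partitioned between ICA and ECA by bisection on the flow split until
  both paths meet at a single junction pressure; mass conservation is then
  exact by construction. This engine is fast (milliseconds), deterministic,
  and exactly testable against closed forms — it is the workhorse for
  sweeps and property tests.

* **3D finite elements** (`solve_fem3d()`): P1/P1 tetrahedral elements and
  an incremental pressure-correction (projection) scheme; viscosity is
  implicit, convection explicit, so the velocity and pressure operators are
  factorized once per mesh (sparse Cholesky). Outlet coupling is staggered:
  the Windkessel pressure applied at a step uses the flux of the previous
  step — a splitting error that is second-order in the step size and the
  price of keeping every linear system symmetric positive definite. Steady
  solves march in pseudo-time until the velocity changes by less than
  `steady_tol` ($10^{-4}$ by default, normalized to a 1 ms reference step);
  unsteady solves run to `t_end`. The explicit convection imposes a CFL
  limit; the default step is chosen from the mesh spacing and an estimate
  of the jet velocity through the tightest stenosis.

The quadratic element and the 3D engine agree in the regime the element is
built for: flows high enough that the expansion (inertial) loss dominates
and the post-stenotic jet genuinely dissipates. At low Reynolds number a
smooth, gradual narrowing recovers much of its dynamic pressure and the
Borda–Carnot term overestimates the drop — the cross-engine consistency
test therefore runs at hyperemic flow. Convective stabilization (SUPG or
upwinding) is not implemented; at throat Reynolds numbers beyond roughly
1500 the explicit convection can destabilize, and the solver then stops
with its residual history rather than returning a wrong answer.

### Geometry and meshing

Cross-sections are triangulated by a concentric-ring disk template whose
ring $j$ carries $8j$ nodes, so in-plane edges are near-uniform and the
vertical diameter is always a mesh polyline. Sections are swept along each
vessel; consecutive layers form prisms, split into tetrahedra by a
minimum-vertex-index diagonal rule that is globally conforming. At the
bifurcation the disk splits along its diameter: each half-disk extrudes
along its branch while morphing onto a circular section (septum to the
inner semicircle, wall arc to the outer, arc-length uniformly), the shared
diameter nodes forming a sharp flow divider — a deliberate idealization of
the real carotid apex. Branch axes turn over about two CCA radii with
axial steps locally enlarged by the bend-compression factor, so inner-curve
layers do not collapse.

Stenoses are axisymmetric diameter reductions (`cosine`-squared by
default, `gaussian` as alternative) parameterized by NASCET degree —
percent diameter reduction relative to the branch's normal distal
diameter — position, and length. The construction guarantees the minimal
lumen diameter equals $(1 - d/100)$ times the distal diameter; grading
round-trips through `nascet_degree()` within 2% across 10–90%.

Grid sizing is diameter-adaptive: in-plane spacing scales with the local
lumen radius and axial steps shrink through stenoses. `mesh_params()`
defaults to the 0.08–0.5 mm edge-length window, which on a full twin
produces grids in the hundreds of thousands to millions of tetrahedra —
the fidelity regime of the underlying model. The package's examples and
tests use coarser resolutions (`max_edge` around 1–1.6 mm) and shortened
vessels; these sizes are verification choices: they resolve the analytic
test solutions (Poiseuille profiles, quadratic drop laws) without aiming
at clinical accuracy. Flow extensions of at least three CCA diameters can
be appended to all openings (`add_flow_extensions()`), the accepted
validity threshold for letting flow develop before the region of interest.

Meshes export to Gmsh MSH 4.1 and VTU, surfaces to STL; `read_mesh_msh()`
re-imports the package's own MSH subset.

### Readouts

`extract_psv()` is the virtual DUS probe. Its default basis on 3D fields is
the maximum velocity magnitude within the branch — in a computed field the
peak *can* be searched for exactly, which is precisely the asymmetry to a
hand-held probe that motivates the offset adjustment below. For
reduced-order solutions the only meaningful basis is
`parabolic_from_flow`: $\mathrm{PSV} = 2Q/A$, the centerline value of a
parabolic profile carrying flow $Q$ through area $A$.

`hyperemia_sweep()` mimics hyperemia by scaling the inlet PSV (default
levels up to 2x baseline; no standardized carotid hyperemia protocol
exists to encode instead) and fits $\Delta P = aQ + bQ^2$ through the
origin by least squares, clipping negative coefficients to zero with a
constrained refit. The goodness measure is the uncentered $R^2$, the
natural choice for a through-origin model. `ffr_like()` is the distal to
proximal pressure ratio $1 - \Delta P / P_\mathrm{prox}$ under a hyperemic
solve, the CT-FFR convention carried over to the carotid; pressures are
relative to a venous reference of 0 mmHg. Measurement planes default to
two lumen diameters proximal and distal of the throat.

### Agreement analysis

`adjust_dus_psv()` corrects reported DUS PSVs for probe placement: a
sampling volume up to one probe sample-volume radius (0.4 mm) off the
centerline under-reads a parabolic profile by the factor
$1 - (d/R)^2$. The adjustment uses the full 0.4 mm deterministically
(configurable); "up to" would require an unknown per-measurement offset.

The agreement suite implements the standard toolbox: Bland–Altman bias and
1.96-SD limits of agreement (sample SD, $n-1$); ICC(2,1) — two-way random
effects, absolute agreement, single measurement — computed from the ANOVA
mean squares; ordinary least-squares regression of computed on measured
PSV with the slope's standard error; per-pair relative errors with the
mean-of-both-modalities denominator (the Bland–Altman convention; the
per-pair reading of "percentage of the mean of the measurements" is a
documented choice); the fraction of pairs within a ±30% DUS-relative
margin; and a per-grade subgroup table (`subgroup_report()`) whose rows
mirror the clinical severity bands. Grades with fewer than three pairs
report every column except the ICC, which is flagged undefined rather than
extrapolated. No multiple-testing correction is applied — the suite
estimates agreement, it does not screen hypotheses.

`sample_size_icc()` plans an ICC-based agreement study via the
Walter–Eliasziw–Donner log-variance approximation with a one-sided
$\alpha$; for minimum acceptable ICC 0.75, expected 0.9, $\alpha = 0.05$
and power 80% with two raters it returns `r sample_size_icc()` subjects, a
figure the test suite cross-checks against a simulation-based power
oracle.

### Synthetic cohorts

`simulate_cohort()` generates the study conditions end to end: grade
counts default to 7 free / 24 mild / 6 moderate (no severe — at severe
stenosis DUS PSV itself becomes unreliable, so such vessels are excluded
from validation), stenosis degrees drawn uniformly within each NASCET
band, and true ICA PSVs from per-grade normal distributions anchored to
the reported DUS means (free 94±23, mild 97±39, moderate 227±69 cm/s).
`simulate_paired_measurements()` then emulates the two modalities:
DUS $= T(1+\varepsilon_d)$ and computed $= T\beta(1+\varepsilon_c)$ with
independent relative errors truncated at ±3 CV (keeping factors positive)
and a multiplicative bias $\beta = 1.1$ by default — the direction of the
reported computed-over-measured overestimation, not a claim about its
exact size. Noise is multiplicative because velocity errors scale with
magnitude; a per-grade CV override exists because the reported
disagreement grows with grade, while the default keeps a single CV for
interpretability.

What passing tests on these cohorts demonstrate is internal consistency —
the generator's known $\beta$ and CV are recovered by the agreement suite
within Monte-Carlo error, with closed-form expectations accounting for the
truncation factor. What they cannot demonstrate is fidelity to real
DUS-vs-CFD disagreement, which also carries segmentation error,
probe-angle dependence and operator variability that no multiplicative
noise model reproduces.

## Numerical choices and degenerate inputs

* Occlusions (degree 100%) are rejected everywhere; retrograde flow is out
  of scope and negative flows error.
* The reduced-order flow split is solved by bisection (`uniroot`) on a
  strictly monotone residual; tolerance $10^{-12}$ relative.
* Backward Euler for the Windkessel: first order, unconditionally stable;
  the analytic constant-flow solution serves as its oracle, and the
  resistive limit $P = QR$ is taken exactly at $C = 0$.
* The mesh-independence rule compares each grid's ICA PSV to the
  *immediately preceding* grid, relative to the preceding value, and stops
  strictly below the tolerance (10% default); a zero tolerance errors.
* Meshing rejects zero-volume elements, branch sections dipping into the
  CCA lumen (over-aggressive angles), and stenoses that overlap the
  bifurcation transition zone, each with a diagnostic message.
* Degree-0 stenoses are exact no-ops, vertex for vertex.

## Known limitations

Rigid walls, Newtonian rheology, no ECA side branches, a sharp flow
divider, axisymmetric stenoses, and generic (calibrated, not
patient-specific) outlet parameters. The 3D engine is first-order in time,
unstabilized in convection, and intended for desk-scale verification
grids; production-scale hemodynamics at the million-element default would
want an HPC-grade solver behind the same interfaces. The agreement module
reproduces a validation *methodology*; with synthetic cohorts it cannot
validate the physics against patients, only the pipeline against itself.

## A worked desk-scale example

```{r example, eval = FALSE}
spec <- bifurcation_spec(r_cca = 3.5, r_ica = 2.5, r_eca = 2.0)
twin <- build_bifurcation(spec, resolution = 1.6) |>
  apply_stenosis(stenosis_spec("ica", 47, center_s = 12, length = 8))

net <- twin_network(twin)   # calibrated Windkessel outlets
sweep <- hyperemia_sweep(net, v_peak_values = c(100, 125, 150, 175, 200))
glance(sweep)               # a, b, R^2 of dP = aQ + bQ^2
autoplot(sweep)

cc <- cohort_config(seed = 1)
pairs <- simulate_paired_measurements(simulate_cohort(cc), cc)
pairs$psv_dus <- adjust_dus_psv(pairs$psv_dus, pairs$radius_mm)
subgroup_report(pairs)
```
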