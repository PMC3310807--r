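---
title: "Plane-stress structural analysis of calcified atherosclerotic plaque"
author: "plaquefem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plane-stress structural analysis of calcified atherosclerotic plaque}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquefem)
```

## The model

`plaquefem` computes the quasi-static stress state of an idealized,
two-dimensional cross-section of a stenosed artery under luminal blood
pressure, and derives from it the quantities used in plaque-rupture
assessment: the *critical stress* $\sigma_{cr}$ (peak maximum principal
stress on the fibrous cap), the peak cap deformation $D_{max}$, and the
pressure-normalized peak circumferential stress $\sigma_{max}/P$. A plaque
is flagged as rupture-prone when $\sigma_{cr}$ exceeds 300 kPa, and a cap is
*thin* below 65 µm — both thresholds are parameters of
`rupture_criteria()`.

The cross-section contains up to four tissues:

* the non-diseased wall (`ndw`), an annulus between the internal
  (3.6 mm) and external (4.0 mm) arterial diameters;
* fibrous plaque (`ft`) filling the space between the eccentric lumen and
  the wall, including the *fibrous cap*, the layer of thickness $d_{fc}$
  separating the lumen from the lipid;
* a lipid pool (`lp`): a 140° crescent of constant thickness 0.35 mm
  concentric with the lumen, its inner boundary a distance $d_{fc}$ outside
  the lumen surface;
* optionally a calcification agglomerate (`cag`): a crescent inside the
  lipid, separated from the cap backing by the *calcification gap*
  $d_{cg}$ and extending to the lipid's outer boundary, so its thickness is
  $d_{cag} = 0.35\,\mathrm{mm} - d_{cg}$.

The lumen diameter follows the degree of (diameter) stenosis,
$L = (1-s)\cdot 3.6$ mm, and the lumen centre is shifted 0.5 mm along the
symmetry axis away from the plaque bulk, so all crescents are bisected by
the symmetry line and a half model suffices.

All tissues are linear, orthotropic in local radial–circumferential axes,
and in plane stress. The constitutive constants (kPa) are the reference
values of `tissue_table()`; the agglomerate is homogenized by the rule of
mixtures

$$E_i^{cag} = \alpha E_i^{ft} + \beta E_i^{lp} + \gamma E_i^{Ca},$$

applied to the radial and circumferential Young moduli and the in-plane
shear modulus, with default fractions $\alpha = 5\%$ fibrous,
$\beta = 20\%$ lipid and $\gamma = 75\%$ calcium
(`mixture_fractions()`, `homogenize_agglomerate()`).

```{r materials}
tissue_table()$cag
```

## Parameters that matter

| parameter | meaning | default | units |
|---|---|---|---|
| `stenosis` | diameter stenosis, sets lumen diameter | — | fraction |
| `d_fc` | fibrous cap thickness | 0.05 | mm |
| `d_cg` | calcification gap (NULL = non-calcified) | NULL | mm |
| `lipid_arc`, `lipid_thickness` | crescent extent | 140, 0.35 | °, mm |
| `lumen_eccentricity` | lumen offset from the arterial centre | 0.5 | mm |
| `P` | luminal pressure | 14.6 | kPa |
| `E_lp`, `E_cag` | sweep overrides of lipid / agglomerate stiffness | 1, mixture | kPa |
| `stress_threshold` | rupture stress | 300 | kPa |
| `cap_thickness_threshold` | thin-cap limit | 0.065 | mm |
| `scale` | geometric similitude factor | 1 | — |

`scale` multiplies every length; under linear elasticity it leaves stresses
unchanged and scales displacements, so it only documents similitude with
larger-artery variants of the same cross-section.

## Geometry and meshing choices

The geometry module is the synthetic-input generator of the whole pipeline:
every analysis input is constructed from the printed parameters above, and
the defaults *are* the study conditions. Real plaques differ in ways this
generator does not emulate — non-circular lumens, tapering crescent tips,
heterogeneous calcium speckle, residual stress, axial variation — so
passing tests demonstrate correctness of the solver and of the parametric
trends, not patient-level realism.

Two geometric conventions deserve mention because the source material
under-determines them:

* **Stenosis convention.** Diameter-based stenosis relative to the healthy
  internal diameter is used. An area-based convention would pair the
  printed cap thicknesses with stenosis slightly better but reproduces the
  printed thick-cap deformation much worse; neither convention explains
  every printed pairing, and diameter stenosis is the clinical norm.
* **Crescent end-cuts.** The lipid and agglomerate crescents are annular
  sectors with flat radial end-cuts, so their areas equal the closed-form
  annular-sector value exactly. The resulting bi-material corners sit at
  the crescent tips, 70° away from the cap apex where $\sigma_{cr}$
  concentrates; grid-independence of the cap summaries is verified
  explicitly.

The mesher (`generate_mesh()`) is a deterministic structured mapped grid in
polar coordinates about the lumen centre (the half domain is star-shaped
about it), with six-node quadratic triangles whose midside nodes lie on the
exact parametric surface — circular interfaces are represented
isoparametrically and the region areas match the analytic values to
rounding error. Resolution is region-aware: the cap and the gap always
carry at least three elements through their thickness, the angular step
follows the thinnest crescent layer, thick blocks are subdivided to match,
and the fibrous bulk grows geometrically away from the lumen. Element
aspect ratios are held near 2.6 or better in both directions; on the
standard study configurations the minimum corner angle stays above 15°,
dipping to ≈14° only in the transition band of extreme sweep corners
(90% stenosis with a 0.02 mm agglomerate sliver, or 0.5 mm caps).

The levels `coarse`, `medium`, `fine` correspond to density factors 0.35,
0.75 and 1.0. They were calibrated on the thin-cap reference model, where
the reported cap stress is converged from the medium density upward (flat
to ±0.3% out to meshes nine times finer), and the fine level lands near
1.2–1.7·10⁴ elements per half model, the natural size for this geometry.

## Solver

`solve_plane_stress()` assembles small-strain linear equilibrium with
3-point Gauss quadrature; the local material axes are radial from the
*arterial* centre (wall fibres organize around the vessel, not the lumen).
The luminal pressure is a consistent normal traction on the (curved) lumen
edges; the symmetry line is constrained in its normal direction; one
outer-wall node on the symmetry line is pinned along the axis to remove the
residual rigid translation (its reaction vanishes by symmetry, which is
checked via the global equilibrium residual). The sparse symmetric system
is solved by direct Cholesky factorization; relative residuals are
typically below 10⁻¹².

Because the pin only fixes an arbitrary gauge, reported displacements are
re-expressed in the zero-net-translation frame (the area-weighted mean
in-plane translation is removed). For a concentric annulus this reproduces
the centred axisymmetric closed-form displacement exactly, which is one of
the solver's oracle tests alongside the Lamé thick-walled-cylinder hoop
stress (fine-level error well under 1%, converging monotonically) and an
orthotropic annulus closed form.

A plane-strain toggle is provided (`plane = "strain"`); it condenses the
axial direction assuming an axial modulus equal to the radial one and the
stated out-of-plane Poisson ratio. It is a secondary mode: all reported
results use plane stress.

## Stress recovery and summaries

Stresses are computed at the integration points. For reporting,
`principal_stress()` linearly extrapolates the integration-point tensor to
the element corners *without cross-element averaging* and takes the element
maximum (`recovery = "corner"`, the default). The cap peak sits at the
cap's outer fibre, a bending extreme that interior Gauss points
systematically under-read; corner extrapolation is the standard
surface-consistent recovery and is also what contour plots in commercial
FEM post-processors report, which is what the reference values of this
model family are read from. The raw Gauss-point maximum remains available
(`recovery = "gauss"`) and is used where an interior field is compared
against closed forms.

`summarize_solution()` restricts $\sigma_{cr}$ to the fibrous-cap elements
(falling back to the whole fibrous region for models without a crescent)
and reports the global maxima alongside as diagnostics; $D_{max}$ is the
peak displacement magnitude over cap nodes, and deformation means
displacement magnitude, not strain.

## Study drivers

`run_sweep()` expands the configured grids (model set A: homogeneous wall;
B: constant lipid; C: calcified), solves every feasible point, and flags
rupture risk; geometrically infeasible points are skipped with a warning,
not fatal. `find_threshold()` locates the 300 kPa crossing along a chosen
axis by linear interpolation between the bracketing grid points and reports
the cap deformation at the crossing — the deformation threshold. When the
criterion is never crossed the result is a flagged no-threshold outcome,
not an error. `pulsatile_envelope()` maps a pressure waveform through the
linear solution by quasi-static scaling; only the systolic peak affects the
extremes, so the two-harmonic template shape (peak 107 mmHg by default) is
inconsequential for the reported maxima.

Everything is deterministic: identical configurations produce bit-identical
meshes and tables; the sweep seed exists only to guard possible future
jittered grids.

## Numerical choices and degenerate inputs

* Thresholds are interpolated linearly; grids near an expected crossing
  should use a 0.01 mm step on `d_cg`.
* A zero calcification gap is valid (the agglomerate touches the cap
  backing); a gap equal to the lipid thickness leaves no agglomerate; a
  sliver thinner than 10⁻⁷ of the internal radius is rejected as
  unmeshable, with the region named.
* A zero pressure load returns the exact null field.
* Tie-break for the pin node: the outer-wall symmetry-line node with the
  smallest x-coordinate.

## Known limitations

The kinematics are deliberately small-strain linear. With a 1 kPa lipid
under 14.6 kPa pressure the thin-cap models respond in a regime where a
large-deflection analysis would stiffen the cap in membrane tension —
lowering the predicted cap deformation and raising the cap stress relative
to the linear solution. The thick-cap (small-deformation) results are
unaffected. Consequently the thin-cap deformation printed by this package
exceeds, and its cap stress undershoots, what a geometrically nonlinear
solver reports for the same inputs; the package keeps the linear model as
its defined scope and the acceptance suite documents the comparison
honestly rather than absorbing it into tolerances. For the same reason the
calcification-gap sweep's critical-stress plateau can remain below the
300 kPa rupture threshold, in which case no gap threshold exists and the
no-crossing flag is reported.

The agglomerate fills the lipid from the gap outward and is therefore
bonded to the stiff fibrous backing; an agglomerate floating with lipid on
both sides would stabilize the cap far less. The first reading follows the
geometric definition adopted here ($d_{cg} + d_{cag}$ equals the lipid
thickness); the difference matters mostly for stiff agglomerates at small
gaps.

## A worked example

```{r example, eval = FALSE}
spec <- plaque_geometry(stenosis = 0.70, d_fc = 0.05)
fit <- solve_model(spec, default_materials(E_lp = 1), load_spec(14.6),
                   level = "fine")
fit$summary
classify_plaque(fit$summary, spec)

## calcification-gap sweep with threshold detection
cfg <- sweep_config("C", stenosis = 0.70, d_fc = 0.05, E_lp = 1,
                    d_cg = seq(0.02, 0.12, by = 0.02), E_cag = 100,
                    level = "medium")
res <- run_sweep(cfg)
find_threshold(res, rupture_criteria(), "d_cg")
```

The full reproduction of the study's headline numbers is scripted in
`scripts/acceptance.R`; problem sizes there are fine-level half-model
meshes (about 1.2–3.3·10⁴ quadratic triangles per solve) and reduced 5×5
response-surface grids.
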