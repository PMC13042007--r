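---
title: "Modelling the honeycomb fracture lattice of spiny mouse skin"
author: "fracturelattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the honeycomb fracture lattice of spiny mouse skin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Spiny mice (*Acomys*) escape predators by shedding skin. Their dermis is not
a homogeneous felt of collagen but a tessellation of hexagonal, lipid-filled
cells bounded by thin collagen walls. Under a predator-like pinch the tissue
tears *along* those walls, cell boundary by cell boundary, producing a
sawtooth force-displacement record whose displacement increments are sums of
the two boundary lengths of the hexagon. This package implements the
mechanical side of that story: the lattice geometry, linear elastic stress
analysis of the patterned composite, a quasi-static cohesive-zone fracture
simulator, and the statistical analysis of sawtooth records. This vignette
documents the models, the parameters that matter, the numerical choices, and
the limits of what the simulations can show.

## 1. Lattice geometry

`lattice_spec()` describes a periodic tessellation of a rectangular sheet
(default 59.701 mm x 39.442 mm) into hexagons with long diagonal
`d_long = 0.674` mm along the body (x) axis and short diagonal
`d_short = 0.34` mm. A hexagon with vertices $(\pm c, 0)$, $(\pm a, \pm b)$
has one remaining shape freedom once $c = d_{long}/2$ and $b = d_{short}/2$
are fixed; we close it by requiring that the ratio of slanted (long) to
horizontal (short) edge lengths equals $d_{long}/d_{short}$, so one
geometric factor maps diagonals to edge lengths for both classes. Every
interior cell then has exactly four long and two short boundary segments,
the composition reported for the real tissue. With the default diagonals the
edges come out at 0.310 mm and 0.156 mm.

A note on the underlying measurements: the tissue-scale hexagon axes were
measured at roughly 1.4 mm x 1.1 mm, while the continuum model geometry uses
0.674/0.34 mm as diagonals - numerically identical to the reported *boundary
segment* lengths (0.674/0.340 mm). These cannot all hold for one hexagon.
We follow the model definition (diagonals 0.674/0.34 mm) for geometry and
keep the printed 0.674/0.340 mm as the default *boundary-length basis* of
the curve analysis, which is how those numbers are used downstream.

Other geometric defaults: collagen wall thickness 0.075 mm (mid-range of the
50-100 um measured spread; the full-sheet production stress models use
0.1 mm, the top of that range, so walls stay at least two pixels wide at the
production raster pitch); origin such that a hexagon centre sits at the
sheet centre; lengths in mm throughout, origin at the lower-left corner.
The 3D posterior tilt of the real lattice is ignored: all models here are
two-dimensional and in-plane.

`build_honeycomb_map()` rasterises the tessellation: a pixel is collagen
when its centre lies within half a wall thickness of a wall centreline.
`carve_defect()` produces the two wound archetypes: a circular cut that
removes every pixel in its disc regardless of label (transgranular), and a
"ripped" wound that empties the lipid interiors of a seeded, contiguously
grown set of whole cells while leaving every collagen wall pixel intact
(intergranular). The growth rule - seeded random frontier growth from the
cell under the wound centre - is a package choice; the published description does not state
how the 254 removed cells of the reference model were selected.

## 2. Elastic stress analysis

**In-plane stretch.** `triangulate()` meshes every non-void pixel into two
constant-strain triangles; `solve_plane_stress()` assembles the plane-stress
stiffness (collagen E = 92.2 kPa, nu = 0.3; fat E = 9.4 kPa, nu = 0.48;
densities stored but unused in quasi-statics) and solves with prescribed
edge displacements. The biaxial wound load applies 10% of the hexagon long
diagonal (0.0674 mm) as an outward normal displacement on each external
edge, the most literal reading of the stated boundary condition. Linear
small-strain kinematics are used throughout, as in the reference continuum models; no
hyperelasticity, contact, or dynamics.

Numerics: assembly groups elements by (orientation, material), places
precomputed 6x6 blocks at vectorised index patterns, and builds the
symmetric CSC matrix in one radix-sorted pass; the factorisation uses a
geometric nested-dissection elimination order computed by coordinate
bisection of the structured node grid. Systems beyond about 1.2M unknowns
are solved by conjugate gradients preconditioned with a symmetrised
two-grid V-cycle (damped Jacobi smoothing plus a direct coarse correction
on an 8x label-coarsened auxiliary field), initialised from the prolongated
coarse solution and iterated to a relative residual of 1e-10; the CG path
agrees with the direct factorisation to ~3e-9 in maximum von Mises stress.
Stresses are reported per element (constant within an element) in kPa, with
the plane-stress von Mises scalar
$\sqrt{\sigma_{xx}^2-\sigma_{xx}\sigma_{yy}+\sigma_{yy}^2+3\sigma_{xy}^2}$.

**Transverse (pinch-like) loading.** `solve_transverse()` idealises
out-of-plane loading as Kirchhoff-Love plate bending with pixel-wise
flexural rigidity $D = E t^3 / 12(1-\nu^2)$ (default thickness
t = 1.02 mm, the mean measured skin thickness), clamped edges, and a
prescribed deflection on a small central patch (default radius 0.15 mm,
comfortably below a cell, avoiding the point-load singularity). The
operator comes from the discrete plate energy with central differences, so
it is symmetric positive semi-definite before clamping by construction.
Surface bending stresses at $z = t/2$ provide the von Mises field. Whether the reference out-of-plane model was a shell or a solid is not
stated; the
plate is the minimal linear model that reproduces the two qualitative
regimes - maximum stress directly beneath the load in unpatterned sheets
versus along the collagen walls in patterned ones.

**The "fivefold" concentration ratio.** `stress_concentration_ratio()`
divides the maximum von Mises stress over collagen elements of the
patterned solution by the maximum of a reference solution under the same
load. The choice of reference material was genuinely open. We use the
*pattern-ablated* sheet: the same lipid-rich matrix with the collagen walls
removed. This matches the mechanistic claim being tested - that the soft
lipid redirects stress onto the collagen boundaries - in the way an
ablation experiment would: remove the feature, keep the matrix. A
homogeneous all-collagen reference cannot reproduce the reported fivefold
under displacement control (the patterned sheet is overall *softer*, so the
ratio falls below one); the ablation reading yields a ratio close to five
(about 5.7 in the 20 mm x 14 mm configuration the pipeline and acceptance
test compute). The 20 mm x 14 mm sheet at 0.05 mm pitch is used for this
study - still ~30 cells across, far above the unit-cell scale - to keep the
plate solves at ~10 s.

**Mesh independence.** `mesh_convergence()` freezes the rasterised
geometry at the production pitch and refines by nested pixel subdivision
(each pixel into four children of the same label), solving the biaxial
wound model at each level on the symmetric quadrant. The convergence
metric needs care: the voided cut has re-entrant raster corners at which
the elastic field is singular, so the raw element-wise maximum *grows*
under refinement (tens of percent per level) and no pointwise maximum can
be mesh-independent. The quantity this package tracks is the **maximum
segment-averaged wall stress**: von Mises averaged over the collagen
pixels of each boundary segment (pixel-to-segment assignment frozen at the
production raster), maximised over segments - the stress a lattice wall
carries at the scale at which the material is defined. The raw maximum and
the production-cell-averaged maximum are reported alongside for
transparency. For the full wound model (59.701 mm x 39.442 mm, 15 mm cut,
wall 0.1 mm) the study runs pitches 0.05/0.025/0.0125 mm; the acceptance
script reports the relative change between the two finest levels. The
observed convergence is first order in the pitch, limited by the two-pixel
wall resolution of the pixel-aligned mesh, and the final change sits above
the 1% independence criterion quoted for smooth body-fitted meshes; this
is a known, documented limitation of the raster discretization rather than
a property of the model.

`line_profile()` samples the piecewise-constant element field at equal
arc-length spacing (nearest meshed pixel near voids), as used for defect
perimeter profiles and for the circular-hole (Kirsch) verification
benchmark, where the concentration factor is read from a profile through
the pole of the hole and approaches the closed-form value 3 under
refinement.

## 3. Cohesive-zone fracture simulation

`cohesive_law()` is the triangular (bilinear) traction-separation law:
rise at `initial_slope` to `peak_traction`, linear softening to zero at
`failure_separation`; fracture energy per interface area
$G_c = T_p\,\delta_f/2$. **The cohesive parameters are a calibration, not
measurements**: no cohesive constants were reported for the tissue. Defaults
(walls: $T_p$ = 10 N/mm^2, slope 500 N/mm^3, $\delta_f$ = 0.1 mm) are
chosen once so that tearing a wall of the measured geometry transmits the
few-N/mm normalised forces characteristic of spiny mouse skin. Junctions -
the degree-3 vertices whose perpendicular, densely packed fibre bundles
fail first in out-of-plane shear - get both peak traction and failure
separation scaled by `junction_factor` (default 0.15), making them weaker
and more brittle: in every simulation the junction element at the front
fails before its wall, i.e. cracks initiate at junctions.

`build_spring_lattice()` turns the geometry into nodes (junction vertices
and cell centres) and bonds: wall segments as cohesive interfaces of area
(segment length x thickness), one small cohesive junction element per
interior vertex (area wall thickness x sheet thickness), and compliant,
*non-failing* lipid spokes from each cell centre to its six vertices.
Failure is therefore intergranular by construction, which is exactly the
observed phenomenology (tears follow collagen boundaries; lipid interiors
stay intact).

`simulate_quasistatic()` drives displacement-controlled fracture with a
secant-stiffness damage iteration: at each increment the elastic system is
re-solved, damage states advance monotonically along the envelope, and the
single most-overloaded element past its failure separation fails per
re-solve (largest overshoot ratio, ties to the lowest bond id), giving
fully deterministic cascades and event logs.

*Pinch and tearing* use peel kinematics along a tear path - the walk over
wall segments that always advances in +x, alternating long and short edges
as the crack rounds the hexagons. The pulled flap is a chain of stiff
(10^5 N/mm), tension-only springs which gain slack equal to each failed
wall's length: the pull must advance by the peeled length before the next
wall re-tensions. Load transfers no further than the current tear front
(a one-wall fracture process zone). These two ingredients are what make
the force-displacement curve a sawtooth whose peak-to-peak intervals equal
sums of wall lengths to within one increment - the package's central
closure property, connecting the simulator to the interval decomposition.
An earlier formulation with a transverse degree of freedom on every node
was implemented and rejected: with load spread over many walls the peak
spacings track cohesive separations instead of wall lengths, which is not
what the experiments show. *Opening* mode loads the intact ligament bonds
in parallel between grips, engaging many bonds at once; with full junction
adhesion in opening and the reduced junction law in tearing
(`compare_modes()`), opening strength always exceeds tearing strength, in
line with the experimental ordering. The tearing idealisation (reduced
junction adhesion plus serial unzipping) is a declared simplification of
the unreported mode-III model.

Numerical defaults: increment = (short edge length)/40 ~ 0.004 mm, chosen
so that the trapezoidal work integral resolves the cohesive-law kinks and
`energy_audit()` balances work = stored + dissipated to well under 1% of
the total work at every recorded step (cohesive dissipation is integrated
analytically along the damage envelope); cascade re-solves are capped and
non-convergence is an error naming the step. A tiny (1e-8 N/mm)
regularising anchor keeps fully detached nodes well-posed and is included
in the stored-energy bookkeeping.

## 4. Curve analysis

`normalize_curve()` divides force by sample thickness (N/mm), the
cross-sample convention. `detect_peaks()` finds local maxima by
topographic prominence (default threshold 5% of the curve maximum,
minimum spacing half the short boundary length, optional running-median
smoothing for noisy records). `extract_intervals()` takes successive
peak spacings and `decompose_interval()` searches integer combinations
$a L_{long} + b L_{short}$ ($a,b \le 6$; larger counts would trivially
overfit) minimising the residual, decomposable within a tolerance of
0.05 mm (~15% of the short boundary, matching the measured spread of
boundary lengths).

`discreteness_test()` formalises "the intervals are discrete, not random":
statistic = mean minimal residual against the combination lattice; null =
intervals uniform on the observed range. One refinement matters: null
replicates keep the observed minimum and maximum and redraw only the
interior values. Conditioned on its extremes, a uniform sample's interior
is i.i.d. uniform between them, so observed and null statistics are
exchangeable under the null and the Monte-Carlo p-value
$(1+\#\{null \le obs\})/(n_{mc}+1)$ is exactly calibrated (the
unconditioned version is measurably anti-conservative). The test is
seeded and reproducible. The original observation of discreteness was
qualitative; this statistic and null are this package's formalisation.

`fit_wlc()` fits the Marko-Siggia worm-like-chain interpolation
$F(x) = A[\tfrac{1}{4}(1-x/L_c)^{-2} - \tfrac{1}{4} + x/L_c]$ by
profiling out the linear amplitude and optimising the contour length on
one dimension (constrained above the largest displacement) - robust
without starting values. The amplitude is phenomenological (N/mm per unit
thickness); no literal thermal interpretation is intended at tissue scale.
`classify_curve()` labels a record sawtooth (>= 2 qualifying peaks before
final failure) or smooth (worm-like-chain fit within a relative residual
threshold), the operational distinction between lattice fracture and
ordinary skin fracture; an all-zero curve is "smooth" with a degenerate
flag.

## 5. Synthetic data

`gen_sawtooth_curve()` builds curves from a tooth plan (counts of long and
short boundaries per tooth), linear rise to a peak of a few N/mm, drop,
plus seeded Gaussian noise (default SD 2% of the peak - instrument noise was not characterised for the real tests, so this is an
assumption);
`gen_wlc_curve()` evaluates the worm-like-chain model with noise;
`gen_fixture_suite()` writes six labelled curves and three configurations
with a JSON manifest, byte-reproducible from its seed. The generators
emulate the *structure* of the experimental records (tooth widths on the
combination lattice, smooth divergent profiles), not the instrument:
no grip slippage, compliance, rate effects or drift. Tests passing on
these fixtures demonstrate that the analysis recovers known ground truth,
not that it is robust to every artefact of real testing machines.

## 6. Problem sizes and reproducibility

Study sizes were chosen once: transverse concentration on a 20 x 14 mm
sheet at 0.05 mm pitch; wound-model convergence on the full
59.701 x 39.442 mm sheet at 0.05/0.025/0.0125 mm via quadrant symmetry
(the acceptance script computes each level in its own R process);
fracture simulations on 6 x 3 to 8 x 4 mm strips (tens of cells, dozens
of sawtooth teeth); 200 replicates for the test-size calibration; 50
replicates for worm-like-chain recovery. Every stochastic component is
seeded; simulators and solvers are deterministic, so identical inputs
give identical event logs and reports.

## 7. Known limitations

* Linear small-strain elasticity at 10% boundary stretch; real skin is
  hyperelastic and the measured whole-skin modulus is far above the
  constituent moduli used in the patterned model.
* The plate idealisation of pinch loading ignores membrane-bending
  coupling and 3D effects; the concentration ratio's reference sheet is a
  declared modelling choice (pattern ablation).
* The pixel-aligned mesh converges first order at material interfaces, so
  wall-stress maxima change by more than 1% between feasible refinement
  levels of the wound model (Section 2).
* Cohesive parameters are calibrated, not measured; absolute forces from
  the fracture simulator should be read as scale-consistent, not
  predictive.
* Experimental magnitudes that depend on animal tissue (the ~46-fold
  strength difference between species, or post-treatment strength drops)
  are outside what desk-scale simulation can reproduce and are encoded
  only as qualitative orderings.
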