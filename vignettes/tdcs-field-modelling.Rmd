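---
title: "Volume-conduction modelling and montage optimization for tDCS"
author: "tdcsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volume-conduction modelling and montage optimization for tDCS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical model

Transcranial direct current stimulation drives a weak direct current (here
2 mA) between two sponge electrodes on the scalp. In the quasi-static
regime the electric potential $\phi$ in the head obeys the volume-conduction
equation

$$\nabla \cdot \sigma \nabla \phi = i,$$

with $\sigma$ the tissue conductivity (S/m), $i$ the volumetric current
source/sink density (A/m^3^, non-zero only inside the electrodes), and
homogeneous Neumann conditions on the outer surface: no current leaves the
head except through the electrodes. The electric field is
$\mathbf{E} = -\nabla\phi$; its magnitude $|\mathbf{E}|$ on the cortex is
the quantity that predicts stimulation efficacy and is the objective of the
montage optimization.

`tdcsim` discretizes this equation with first-order (trilinear) finite
elements on cubical voxels, one element per labelled voxel, with the
element conductivity equal to the label's table value (no sub-voxel
averaging, matching a label-per-voxel segmentation). The stiffness matrix
of a cubical trilinear element is the universal reference matrix scaled by
$\sigma h$, which the package computes once by 2-point Gauss quadrature
(exact for this integrand).

## Tissues and conductivities

The conductivity table (S/m) covers skin+fat (one label, 0.08), muscle
(0.16), compact bone (0.008), spongy bone (0.027), dura (0.16), blood
(0.7), CSF (1.8), gray matter (0.2), white matter (0.14), eye (1.5), the
saline-soaked sponge (1.6) and the rubber current-injection sheet. The
rubber sheet's conductivity has no established literature value; because
the package injects the current as a uniform volumetric source over the
rubber voxels, its conductivity has negligible influence on the tissue
field, and the default of 0.1 S/m is a neutral placeholder that the
sensitivity tests confirm to be inconsequential. All values can be
overridden per tissue:

```{r}
library(tdcsim)
conductivity_table(csf = 2.0)
```

## The synthetic head phantoms

Real pipelines of this kind run on dozens of MRI-segmented anatomical
models. No such data ship with this package; instead, the generator builds
concentric-sphere phantoms whose default shells are anatomically plausible
for an adult head: outer radius 92 mm, scalp 6 mm, compact bone 4 mm (with
an optional 2 mm spongy-bone core), dura 1.5 mm, CSF 3 mm, gray matter
4 mm, white matter filling the core. Voxelization labels each voxel by the
shell containing its center, on a grid with an odd voxel count per axis so
the phantom is exactly mirror-symmetric about its mid-planes.

A *population* of phantoms emulates inter-individual variability with two
knobs: a global size factor (CV 3%, typical of adult head-circumference
spread) and independent per-shell thickness jitter (CV 10%, typical of
reported skull/CSF thickness variability). Draws are truncated-normal:
proposals are resampled while any shell is non-positive or the white-matter
core would vanish, and a fixed seed reproduces the population exactly.

What the phantoms deliberately do **not** emulate: gyral folding (which
locally concentrates fields), the neck and lower head (the extracephalic
return is a patch antipodal to the vertex), tissue anisotropy, and real
anatomical covariance between layers. Consequently, passing tests
demonstrate the correctness of the *procedure* — solver, sampling,
ranking, sensitivity machinery — not cohort-level field magnitudes: a
smooth sphere with thin CSF yields cortical fields roughly twice those
reported for real heads, and per-montage field values from MRI cohorts are not
reproducible without the original 62 MRI models.

## Electrodes and candidate montages

Electrodes are 35 cm^2^ sponge assemblies (7 cm x 5 cm, the long edge
perpendicular to the anterior–posterior direction, so the extent along the
midline arc is 5 cm), modelled as a rubber sheet at mid-sponge depth inside
a saline sponge that conforms to the scalp. Sponge thickness (unspecified
in the source literature) defaults to 5 mm on each side of the 1 mm rubber
sheet. On a coarse grid the rubber sheet is the one voxel layer whose
radial depth band contains the mid-sponge depth.

Scalp sites are the midline 10-10 positions: fractions 0.1 (Fpz) through
1.0 (Iz) of the nasion–inion arc, the half great circle over the vertex.
Two footprints overlap when their centers are closer than 5 cm along the
arc; with 10% spacing this excludes exactly the adjacent pairs for any
plausible adult arc length (the candidate set is invariant from roughly
260 mm to 460 mm arcs). The candidate enumeration crosses first electrodes
{Fz, FCz, Cz, CPz, Pz} with second electrodes {extracephalic, Iz, Fpz,
POz, Pz}, adds POz–Fpz, and removes same-site, overlapping and duplicate
pairs, leaving 23 montages. The generating sets do not themselves produce
POz–Fpz, and produce no POz–extracephalic pair; the enumeration follows
the reference candidate table and documents rather than resolves this
asymmetry. The physical location of the extracephalic return electrode is
likewise unspecified in the source; it is modelled as a scalp patch
antipodal to Cz, where its exact position has little influence on midline
cortical ROIs.

```{r}
enumerate_candidates()
```

## Solver

The Neumann problem is singular (the potential is defined up to a
constant), so the conjugate-gradient iteration projects the constant mode
out of the residual and preconditioned residual each iteration and returns
a zero-mean potential. The preconditioner is zero-fill incomplete Cholesky
(IC(0)) on the assembled 27-point stencil, with a Jacobi fallback if the
factorization breaks down; on the default phantoms IC(0) converges in some
tens of iterations. Defaults: relative residual 1e-6, 10 000 iterations
maximum. A desk-scale resolution of h = 2 mm is the default; 0.5 mm —
the reference resolution of MRI-based pipelines — is available through the
same configuration for machines with the memory to hold the grid.
Sources are balanced exactly (the floating-point residue of the +I/-I
distribution is removed), and `check_current_conservation()` verifies a
solved system by evaluating the Galerkin flux through a closed surface
around an electrode matrix-free, independent of the CG iteration.

## Field recovery and cortical sampling

$\mathbf{E}$ is evaluated at element centers from the trilinear shape
functions. For off-grid sampling the components are first *recovered to
the nodes* by averaging the adjacent non-air elements and then
interpolated trilinearly, taking the norm last (component-then-norm).
Plain trilinear interpolation of the raw element-center values transmits
the staircase noise of voxelized curved interfaces into the sampled field:
on the 4-layer verification sphere at h = 2 mm it leaves an 11.6%
relative L2 error in $|\mathbf{E}|$ on the cortical shell, whereas the
recovered field achieves 5.2% with essentially zero mean bias. Gradient
recovery by local averaging is the standard finite-element post-processing
for exactly this purpose, and it is applied uniformly in the cortical
pipeline and in the oracle comparison. (Restricting the stencil to
brain-labelled elements was also evaluated and rejected: the noise
originates in near-boundary brain elements, not in contamination from the
CSF side.)

Cortical values are taken on the sphere 1 mm below the outer gray-matter
boundary. The sampling lattice is a Fibonacci-type quasi-uniform lattice
built on one hemisphere and completed by its mirror image in the mid-sagittal
plane (default 10 000 points, nearest-neighbor spacing CV below 8%). The
mirror construction gives exact point-for-point left/right correspondence,
so bilateral ROI comparisons measure genuine field asymmetry rather than
sampling noise — the phantom analog of registering both hemispheres to a
common template. All models of a population share the same angular
lattice, which plays the role of cross-subject surface registration.

## ROIs and the optimization objective

The four targets are bilateral M1 leg areas at template coordinates
[±9, −39, 54] mm and bilateral SMA at [±3, −9, 60] mm, each a 10 mm
geodesic disc on the sampling surface. The coordinate triples are
interpreted as MNI-style template millimeters (x right, y anterior,
z superior) — the source states the numbers without naming the space, and
this reading is flagged here as an assumption. The declared template-to-
phantom mapping is an isotropic affine about the head center followed by
radial projection onto the sampling surface, so only the direction of the
template coordinate matters on a sphere. ROI membership is geodesic rather
than Euclidean; at 10 mm radius the difference is negligible but the
convention is fixed.

The optimization objective is the unweighted mean of the four ROI means of
$|\mathbf{E}|$ — "averaged over all regions of interest" — computed per
model, then averaged over the population. The per-model optimum uses the
same four-ROI average; whether the original study's per-model optimum used
this criterion is implied but not stated, and the choice is flagged here.
Ties keep candidate-list order and are flagged in the output.

## Sensitivity analysis

Tissue conductivities are the dominant modelling uncertainty. The default
scenario set perturbs one tissue group at a time — bone (compact and
spongy jointly, as both are bone labels) by ±50% and CSF by ±10% — and
re-solves every (model, montage) pair per scenario, reporting one ranking
per scenario and the set of scenario-optimal montages. Whether bone and
CSF perturbations should be crossed is not specified in the source; the
one-at-a-time default keeps the scenario count at five, and crossed
designs can be supplied as a custom scenario list.

## Verification against a closed form

The FEM solver is verified against an independent Legendre-series solution
for an N-layer concentric sphere with a ±I point-electrode pair: per
degree $l$, layer coefficients of $A r^l + B r^{-(l+1)}$ are matched by
continuity of $\phi$ and $\sigma\,\partial\phi/\partial r$ at each
interface, with the point-source Neumann datum at the outer boundary. Two
numerical choices matter. First, the growing basis is normalized at each
layer's outer radius and the decaying basis at its inner radius, keeping
every matrix entry O(1) up to high degree (naive normalization loses the
solve to roundoff near l = 400). Second, the FEM comparison uses
single-voxel sources whose centers sit on the vertical grid axis; the
series therefore supports sources at an interior radius (free-space
particular solution plus homogeneous Neumann boundary), evaluated at the
exact voxel-center radius, so the comparison measures discretization error
rather than a source-placement mismatch. Both sources of a pair must share
a radius, which makes the monopole terms cancel exactly; the antipodal
placement guarantees this. The series is summed from l = 1 to L (default
300–400) with a cancellation-safe tail check on term magnitudes.

Default verification geometry: brain 80 mm (0.2 S/m), CSF 83 mm (1.8),
skull 87 mm (0.008), scalp 92 mm (0.08), evaluated on the shell 1 mm below
the brain surface excluding 10° caps around the electrodes. At h = 2 mm
the relative L2 error of $|\mathbf{E}|$ is ~5%, at h = 4 mm ~37%, and the
error decreases monotonically under refinement (also verified at
h = 6/3/1.5 mm on a homogeneous sphere against the single-shell closed
form, to which the series itself agrees at machine precision).

## Degenerate inputs and validation modes

Shells thinner than twice the voxel size cannot be voxelized faithfully.
`build_sphere_phantom()` exposes this as a policy: `check = "strict"`
errors (naming the shell), the default warns, `check = "none"` is silent.
A strict default would be self-contradictory at coarse resolutions — the
default head's 1.5 mm dura already violates the rule at h = 1 mm — while
coarse qualitative runs remain legitimate, which is why the lenient default
was chosen and the population sampler defaults to `"none"`. Other guarded
degeneracies: empty electrode voxel sets, unbalanced sources, queries at
the oracle's electrode singularities (within ~1° of arc), series
truncation too small for the requested points, ROIs that capture no sample
point (an ROI radius of zero selects the nearest point), and gray-matter
shells thinner than the sampling depth.

## Problem sizes used by the tests

The test suite and the acceptance script choose desk-scale sizes as the
package's own verification conditions: machinery tests run on a
thick-shelled phantom at h = 8 mm (25^3 grid, millisecond solves), physics
and symmetry checks on the default phantom at h = 4 mm (53^3 grid,
sub-second solves), and the oracle comparison at h = 2 mm (97^3 grid,
~800 000 elements, seconds). The population run evaluates all 23 montages
on five phantoms at h = 4 mm. These sizes exercise every code path at full
fidelity; production runs at 1 mm or the 0.5 mm reference resolution use
the identical configuration surface.

## Known limitations

* Spherical phantoms cannot reproduce per-montage field values reported
  from MRI cohorts; rankings on spheres are dominated by electrode–ROI
  geometry and are expected to be more clear-cut than in real anatomy.
* Isotropic conductivities only; no tensor (white-matter) anisotropy.
* The voxel FEM with label-per-voxel conductivity converges slowly where
  interfaces staircase; the gradient-recovery step mitigates but does not
  remove this, and fields within one voxel of an interface remain the
  least accurate.
* Uniform volumetric injection idealizes the electrode; an isopotential
  (complete-electrode) model is out of scope.
* The extracephalic return position and the rubber-sheet conductivity are
  declared defaults, not measured quantities.
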