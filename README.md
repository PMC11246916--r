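# tdcsim

Voxel finite-element simulation of transcranial direct current stimulation
(tDCS) electric fields, with electrode-montage optimization for joint
stimulation of the bilateral primary motor cortex (M1) and supplementary
motor area (SMA).

## What it does, and for whom

tDCS drives a weak direct current (2 mA here) between two 35 cm² sponge
electrodes on the scalp. Where that current actually goes — and how strong
the cortical electric field is — depends on the resistive head tissues in
between, so electrode placement is an optimization problem over a
volume-conduction model. `tdcsim` is for researchers who want a
self-contained, verifiable implementation of that pipeline:

1. **Forward model.** Solve the volume-conduction equation
   `div(σ grad φ) = i` with homogeneous Neumann boundary conditions on a
   conductivity-labelled voxel grid, using first-order cubical finite
   elements and an IC(0)-preconditioned conjugate-gradient solver (the
   singular Neumann system is handled by constant-mode projection). The
   electric field is `E = −∇φ`; its magnitude `|E|` in V/m is the outcome
   measure.
2. **Cortical sampling.** Interpolate `|E|` onto the surface 1 mm below the
   gray-matter boundary and average it over four 10-mm regions of interest:
   bilateral M1 at template coordinates `[±9, −39, 54]` mm and bilateral SMA
   at `[±3, −9, 60]` mm.
3. **Montage optimization.** Enumerate the 23 non-overlapping midline 10-10
   electrode pairs (first electrode Fz/FCz/Cz/CPz/Pz; second electrode
   extracephalic/Iz/Fpz/POz/Pz, plus POz–Fpz), evaluate each one over a
   population of head models, and rank montages by the population mean of
   the four-ROI average `|E|`.
4. **Sensitivity analysis.** Repeat everything under perturbed
   conductivities (bone ±50%, CSF ±10%) and report whether the optimal
   montage is robust.

Because no anatomical MRI data ship with the package, a synthetic-head
module generates layered-sphere phantoms (scalp, skull, dura, CSF, gray and
white matter, with standard conductivities such as CSF 1.8 S/m, compact
bone 0.008 S/m, gray matter 0.2 S/m) and phantom *populations* with
realistic size and layer-thickness variability. A closed-form
Legendre-series solution for layered spheres serves as an independent
oracle for the FEM solver. See the vignette
(`vignettes/tdcs-field-modelling.Rmd`) for the model, the numerical choices
and their rationale.

## Worked example

```r
library(tdcsim)

head(enumerate_candidates(), 3)
#>   anode       cathode current_mA
#> 1    Fz extracephalic          2
#> 2   FCz extracephalic          2
#> 3    Cz extracephalic          2

model <- build_sphere_phantom(default_head_spec(), h = 4, check = "none")
sim <- simulate_montage(model, montage("FCz", "POz"))
sim
#> tDCS simulation: FCz -> POz at 2 mA on 'phantom' (h = 4 mm)
#>   CG 62 iterations, relative residual 8.75e-07

round(roi_means(sim), 3)
#>  M1_left  M1_right  SMA_left SMA_right   average
#>    1.118     1.118     1.261     1.261     1.189
```

The FCz–POz montage puts ~1.2 V/m on the M1/SMA targets of this phantom at
2 mA. Left and right ROI means are identical because the phantom, the
montage and the sampling lattice are all mirror-symmetric; on real
anatomies the two columns differ slightly. (A smooth sphere with a thin CSF
layer concentrates more current than a folded cortex, so these magnitudes
run about twice the values reported for MRI-based head models — the
*ranking* of montages, not the absolute field, is the meaningful output at
phantom level.)

Verifying the solver against the analytic layered-sphere solution:

```r
compare_with_fem(layered_sphere_spec(), h = 2)
#> FEM vs layered-sphere oracle at h = 2 mm (97^3 grid, 73 CG iterations)
#>   shell r = 79.0 mm, 3938 points, sources at r = 92.00 mm
#>   phi : rel L2 0.0343, max rel 0.0791
#>   |E| : rel L2 0.0524, max rel 0.1101
```

Population-level optimization and the conductivity sensitivity analysis are
one call each (`evaluate_montages()` + `rank_montages()` +
`per_model_optima()`, and `sensitivity_analysis()`), or can be driven from
a YAML/JSON configuration through `run_optimize()` / `run_sensitivity()`.
A thin command-line front end ships in `inst/cli/tdcsim.R` with subcommands
`simulate`, `optimize`, `sensitivity` and `validate`.

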