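---
title: "Validating bilayer structure and dynamics analyses with closed-form ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating bilayer structure and dynamics analyses with closed-form ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilayr)
```

## Scope and model

`bilayr` analyses molecular-dynamics trajectories of planar lipid
bilayers whose membrane normal lies along z. Every observable it
computes is a standard quantity of membrane biophysics:

* **C–H bond order parameters.** For a carbon–hydrogen bond with tilt
  angle θ against the membrane normal,
  S~CH~ = ⟨(3 cos²θ − 1)/2⟩, averaged over the sampled conformations.
  S~CH~ is signed and bounded in [−0.5, 1]; it is the simulation-side
  counterpart of the deuterium/¹³C NMR order parameter. The ensemble
  estimate is formed hierarchically: a time average per lipid first,
  then mean and standard error of the mean (SEM) across lipids, so
  lipids — not frames — are the independent units. No time-correlation
  correction is applied within a lipid; this matches the hierarchical
  averaging convention and keeps the SEM honest as long as lipids are
  weakly coupled.
* **Forking.** The two hydrogens bonded to one carbon are
  distinguishable (pro-R/pro-S) and may sample different orientational
  distributions. We quantify forking as |S_R − S_S| and flag it when
  the difference exceeds `k_sigma` (default 2) combined SEMs. The
  threshold is a package choice: forking is usually judged visually,
  and 2σ is the weakest conventional significance level.
* **Electrometer response.** Headgroup α/β order parameters respond to
  charge bound at the membrane interface. The response ΔS at a salt
  concentration is measured against the *average of the R and S*
  salt-free order parameters, so baseline forking does not bias it;
  SEMs propagate in quadrature with the ½ factors.
* **Density profiles and SAXS form factors.** Number or
  electron-weighted densities are accumulated along z after re-centring
  each frame on the bilayer midplane (mean phosphorus z by default; the
  box centre when no anchor exists) and wrapping into [−L~z~/2,
  L~z~/2). The form factor is |F(q~z~)| = |∫(ρ~e~(z) − ρ~bulk~)
  e^{iq~z~z} dz| by midpoint quadrature over the profile bins, reported
  on a q grid in Å⁻¹ and normalised by the first-peak height, taken
  literally as the maximum of |F| in 0.1–0.2 Å⁻¹.
* **Area per lipid and lateral diffusion.** A~L~(t) = L~x~L~y~/n with n
  the lipids per leaflet (100 in the reference systems). Lateral
  diffusion comes from the mean squared displacement (MSD) of lipid
  centres of mass, xy components only, over all time origins; D~L~ is
  one quarter of the slope of the linear region. Errors follow the
  subgroup scheme: lipids split into five equal groups treated as
  independent measurements, SEM per lag across subgroups, and the
  steepest/gentlest straight lines passing within ±1 SEM of every
  windowed point bounding D~L~.

## Units and conventions

Internal units are fixed: nanometres, picoseconds, unified atomic
masses. Converters live only at the I/O boundary (PDB/DCD Ångströms,
q in Å⁻¹). θ is computed from the carbon→hydrogen direction; the
antiparallel convention maps θ → 180° − θ but leaves S~CH~ unchanged
because the second Legendre polynomial is even, so this is documented
rather than configurable. R/S identities are fixed properties of the
bonding graph, stored once in the topology's bond table and never
re-derived from coordinates. Non-orthorhombic boxes are rejected, not
approximated; every supported system is a planar bilayer in an
orthorhombic box.

## Tunable parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `bin_width` (densities) | 0.1 | nm | resolves headgroup features at desk-scale statistics; halve it for form-factor work so the midpoint quadrature stays below the target accuracy at q ≈ 1 Å⁻¹ |
| `bulk_density` (form factor) | outer 10% of bins | e nm⁻³ | the bulk-subtraction convention is not standardised; the outermost bins are solvent in any solvated slab |
| `k_sigma` (forking) | 2 | SEM units | weakest conventional significance level |
| `n_leaflet` | 100 | lipids | the reference systems contain 200 lipids, 100 per leaflet |
| `n_subgroups` (MSD) | 5 | groups | five subgroups of 40 lipids at the reference size |
| `tolerance_sd` (equilibration) | 1 | SD units | a sliding mean within one SD of the late-time mean is indistinguishable from the plateau |
| fit window (diffusion) | 20–50 ns, else 10–25% of span | ns | see below |

The diffusion fit window defaults to the 20–50 ns displacement-time
regime, where lipid MSD is diffusive in microsecond-scale bilayer
runs, but only when that regime lies within the first quarter of the
trajectory span. Beyond a quarter of the span each lipid contributes
too few independent displacement segments and the long-lag MSD is
dominated by correlated noise; shorter trajectories therefore fall
back to 10–25% of their span. The lag grid is logarithmic (48 points
up to half the span) so fits stay stable at bounded cost; all time
origins are used.

## Synthetic ensembles and what they prove

Reference trajectories at the microsecond scale are too large to carry
in a package, so every stage is validated against generators whose
observables are closed form:

* **Orientation ensembles** (`gen_orientation_ensemble`): bond vectors
  drawn i.i.d. per frame from a fixed-tilt, uniform-cone, isotropic or
  mixture model. Expected order parameters are exact: P₂(cos θ₀) for
  fixed tilt, cos θ₀(1 + cos θ₀)/2 for a uniform cone (verified
  against numerical integration in the tests), 0 for isotropy,
  weighted sums for mixtures.
* **Layered slabs** (`gen_ion_slab`): Gaussian surface peaks plus a
  uniform bulk, truncated (not reflected) at the box faces and
  renormalised analytically so the ground-truth density stays closed
  form.
* **Point-scatterer membranes** (`gen_gaussian_membrane`): electron
  densities sampled from Gaussian mixtures whose 1-D Fourier transform
  is analytic.
* **2-D Brownian walks** (`gen_brownian_bilayer`): per-axis step SD
  √(2D dt), wrapped into the box so the unwrapping code is exercised,
  with optional common drift to test collective-motion removal.

Each generator returns its ground truth alongside the data, and every
generator call takes a mandatory seed drawn through one named RNG
stream, so identical seeds give bit-identical data.

These ensembles deliberately omit features of real bilayers:
orientational time correlation (i.i.d. frames), conformational
coupling between bonds of one lipid, anomalous subdiffusion at short
lags, box-size fluctuations under a barostat, and hydrodynamic
finite-size effects. Passing the validation suite therefore shows the
*estimators* are correct, not that any force field is; on real
trajectories the SEMs additionally inherit whatever correlation the
dynamics carry. Periodic-boundary corrections to D~L~ require the
membrane and solvent viscosities and are out of scope; a hook
(`apply_finite_size_correction`) accepts an externally computed
multiplicative factor.

## Numerical choices

* **Degenerate inputs.** A zero-length C–H vector is an error naming
  the frame, rather than a silently skipped frame. Unevenly spaced
  frames are averaged unweighted with a warning (the reference
  trajectories are uniformly spaced at 10 ps). An all-equal-anchor
  bilayer cannot be split into leaflets and errors as degenerate.
* **Binning.** Density bins tile the maximum box height exactly, so
  particle conservation Σρ·V~bin~ = ⟨N⟩ holds to machine precision by
  construction and is asserted on every synthetic run.
* **Quadrature.** |F(0)| equals the integrated contrast to rounding;
  halving the q step changes smooth normalised curves by far less than
  0.1% RMS. At q = 1 Å⁻¹ a 0.1 nm bin incurs a ~4% midpoint-quadrature
  envelope error, which is why form-factor validation bins at 0.02 nm.
* **Band fit.** The steepest/gentlest-slope search is a two-variable
  feasibility problem; the feasibility gap is concave piecewise-linear
  in the slope, so the extreme slopes lie on intersections of
  constraint pairs and are found exactly by vertex enumeration. A
  brute-force slope scan is the test oracle. When no line passes
  within every error bar the band falls back to slope ± fit standard
  error, with a message.
* **Coverage of the band.** A ±1 SEM band is intrinsically a roughly
  one-sigma object: with five subgroups its per-lag half-width is a
  t₄-scale estimate, and because MSD errors are strongly correlated
  across lags the band covers the true D in only of order 70–90% of
  replicates depending on the fit window. It is an error *indication*
  in the source procedure, not a calibrated confidence interval; users
  needing calibrated intervals should multiply the SEMs or bootstrap
  lipids.
* **Equilibration detection.** The detector compares sliding means of
  length span/5 against the last-half mean within `tolerance_sd`
  last-half SDs, returning the earliest start from which all later
  windows conform; a start later than 90% of the span flags the series
  non-equilibrated. The window fraction and tolerance are package
  choices; only the resulting analysis intervals are comparable to
  published values.

## Design decisions that were genuinely open

* **Signed S~CH~.** Experimental magnitudes carry no sign; we report
  the signed simulation value and leave the comparison convention to
  the caller.
* **First-peak normalisation.** The maximum of |F| inside 0.1–0.2 Å⁻¹
  is used even when |F| is monotone there, keeping the operation total
  and reproducible.
* **Symmetrisation.** Profiles are transformed as computed;
  symmetrising the two leaflets before the transform is an explicit
  flag, since published pipelines differ silently on this point.
* **Leaflet anchor.** Phosphorus by default, configurable; the
  midplane is the mean anchor z, which makes the assignment invariant
  under global translation.
* **Windowing.** Analysis-window endpoints are inclusive on both
  sides, so "the last 100 ns" of a uniformly sampled microsecond run
  contains exactly the expected boundary frames. Windowed re-analysis
  tiles the span from the start and drops the trailing remainder with
  a message.
* **XTC.** Not read: its compressed-integer coordinate codec is a full
  codec in its own right, and TRR/DCD/GRO cover the interchange needs
  here. TRR I/O is implemented natively in plain XDR.

## Problem sizes used in validation

The shipped validation suite runs orientation ensembles at 200 lipids
× 2000 frames, forking nulls at 100 repeats of 50 × 200, slabs at a
few thousand particles × tens of frames, form factors at 10⁵
scatterers, and diffusion at 20 replicates of 200 lipids × 10⁴ frames
— sizes chosen so the whole suite completes on a single CPU in a few
minutes while keeping Monte-Carlo tolerances (3 SEM, Poisson 3σ per
bin) meaningful.

## A worked example

```{r example, eval = FALSE}
sim <- gen_orientation_ensemble(orientation_model("cone", theta0 = 60),
                                n_lipids = 200, n_frames = 2000, seed = 1)
ops <- order_parameters(sim$frames, sim$topology)
ops           # s_mean within 3 SEM of the closed form 0.375

b <- gen_brownian_bilayer(5e-12, n_lipids = 200, n_frames = 1e4, seed = 1)
paths <- com_trajectories(b$frames, b$topology)
est <- fit_diffusion(lateral_msd(paths))
est           # D_L near 5e-12 m^2/s with a subgroup-based band
```

## Known limitations

Stereochemistry is taken from the bond-definition table, never
perceived from 3-D coordinates. Triclinic boxes, neutron
scattering-length densities, absolute-scale intensities, membrane
viscosity and rotational diffusion are out of scope. The bundled
bond table follows CHARMM36-style POPC atom naming; other naming
schemes need a caller-supplied table.
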