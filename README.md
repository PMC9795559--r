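# bilayr

Structural and dynamical analysis of planar lipid-bilayer
molecular-dynamics trajectories, for simulators who validate membrane
force fields against NMR and small-angle X-ray scattering observables.

Given a bilayer trajectory with the membrane normal along z, `bilayr`
computes:

* **C–H bond order parameters** S<sub>CH</sub> = ⟨(3cos²θ − 1)/2⟩, θ
  the angle between the carbon→hydrogen vector and the normal —
  signed, averaged per lipid over time first, then mean ± SEM across
  lipids;
* **forking** diagnostics (unequal S<sub>CH</sub> of the pro-R and
  pro-S hydrogens of one carbon) and θ-angle distributions;
* **electrometer responses** ΔS<sub>CH</sub> of the headgroup α/β
  segments against the R/S-averaged salt-free baseline;
* **density profiles** along z (number or electron-weighted,
  midplane-centred) and concentration-normalised ion distributions;
* **SAXS form factors** |F(q<sub>z</sub>)| = |∫(ρ<sub>e</sub>(z) −
  ρ<sub>bulk</sub>)e<sup>iq<sub>z</sub>z</sup>dz|, normalised by the
  first-peak height in 0.1–0.2 Å⁻¹;
* **area per lipid** A<sub>L</sub> = L<sub>x</sub>L<sub>y</sub>/n per
  frame with equilibration-window detection and windowed re-analysis;
* **lateral diffusion** D<sub>L</sub> = slope/4 of the lateral
  mean-squared displacement of lipid centres of mass, with the
  five-subgroup SEM scheme and steepest/gentlest-line error bands.

Topologies load from GRO or PDB, trajectories from GRO, TRR, DCD or a
plain-text fixture dialect; all internal units are nm and ps. Seedable
synthetic-ensemble generators with closed-form ground truth (fixed-tilt
and cone orientation models, Gaussian-layered slabs, point-scatterer
membranes, 2-D Brownian walks) make every stage testable without any
reference trajectory.

## Worked example

```r
library(bilayr)

## order parameters of a uniform-cone ensemble (closed form: 0.375)
sim <- gen_orientation_ensemble(orientation_model("cone", theta0 = 60),
                                n_lipids = 200, n_frames = 500, seed = 2)
order_parameters(sim$frames, sim$topology)
#> C-H bond order parameters (1 bond classes)
#>  segment_label stereo_label s_mean      sem n_lipids n_frames
#>              α            R 0.3765 0.001037      200      500

## lateral diffusion of 2-D Brownian lipids (truth: 5e-12 m^2/s)
b <- gen_brownian_bilayer(5e-12, n_lipids = 100, n_frames = 2000, seed = 3)
paths <- com_trajectories(b$frames, b$topology)
fit_diffusion(lateral_msd(paths))
#> Lateral diffusion: D_L = 4.97e-12 m^2/s  [4.21e-12, 5.72e-12]  (fit 1.999-4.9975 ns, 6 lags)

## composition bookkeeping
salt_concentration(16, 8880)   # 0.1  (M)
water_per_lipid(4000, 200)     # 20
```

The order parameter lands within 3 SEM of the analytic cone value;
the diffusion band brackets the generator's true coefficient; the
bookkeeping values are exact ratios.

A YAML-driven pipeline (`parse_config()` / `run_pipeline()`, or the
`inst/cli/bilayr` script) ties the stages into reproducible runs:
every output TSV carries the config hash, and a `run_manifest.yaml`
replays any run byte for byte. See the vignette
(`vignettes/bilayer-analysis.Rmd`) for the models, defaults and
validation design.

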