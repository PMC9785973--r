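# hydrolayer

Layer-by-layer vibrational and infrared analysis of the hydration
shell around a solvated biomolecule, from molecular-dynamics
trajectories that store velocities.

Water near a protein surface is not bulk water: directly adsorbed
molecules are quasi-immobile and spectrally distinct, and successive
solvation sub-layers relax toward bulk behaviour within roughly 6–7 Å
of the surface. hydrolayer quantifies that transition for users of
classical MD. It:

- computes the **radial water density profile** from the solute
  surface using periodic **Voronoi cell volumes** (density in a bin is
  pooled molecular mass over pooled cell volume);
- partitions the shell into **sub-layers** at the minima of the
  smoothed profile, with the bulk onset as the outer boundary;
- selects each layer's population by a **residence criterion** — a
  molecule counts only if it spends ≥ 90 % of an analysis interval in
  the layer, with 20 ps intervals for layers 1–2 and 5 ps for the
  outer layers, averaged over 10 intervals of the final 200 ps (all
  configurable);
- computes per-layer and cumulative **VDOS** and **IR spectra** and
  summarises the water bands (acoustic < 130 cm⁻¹, libration, bend
  near 1650 cm⁻¹, stretch 3250–3750 cm⁻¹), including shoulders.

The spectral core, in the field's standard notation: the normalised
velocity autocorrelation of an atom group α,

    Z_α(t) = ⟨v_j(t0+t)·v_j(t0)⟩ / ⟨v_j(t0)·v_j(t0)⟩,

transforms to the vibrational density of states

    Z(ν̃) = Δt Σ_k w_k Z_α(t_k) cos(2πc ν̃ t_k)        (VDOS),

and the autocorrelation of the dipole-moment derivative of a molecule
selection, dM/dt = Σ_j e_j v_j, transforms the same way to the
classical IR lineshape I(ν̃) ∝ ∫ ⟨dM/dt(t)·dM/dt(0)⟩ cos(ωt) dt
(arbitrary units; intensity scales as e_j²). Estimators use all time
origins via FFT, with direct O(n²) reference paths tested to 1e-10.

Everything tabular is a tibble; results pipe into dplyr/ggplot2, carry
`tidy()`/`glance()` methods and `autoplot()`s. Seeded generators
(harmonic-mode waters, Ornstein–Uhlenbeck gases, layered density
boxes) provide analytic ground truth so the full pipeline is testable
without any MD engine.

## Input formats

- **TRR** (GROMACS binary, nm/ps — converted to Å/fs on read,
  orthorhombic boxes only), **GRO series** with velocity columns, or
  the package's plain-text **fixture format**.
- **Topology**: a CSV/whitespace table with columns
  `atom_id,element,mass,charge,molecule_id,role` and
  `role ∈ {protein, water, ion}`. Water is detected by `role`, never
  by residue-name heuristics; each water must be one O plus two H and
  electroneutral.

The fixture trajectory format is self-describing columnar text in
internal units (Å, fs). A 2-atom, 2-frame file:

```
# hydrolayer trajectory v1
n_atoms 2
box_A 60 60 60
frame 0 time_fs 0
1 30.1 30.0 30.0 0.01 0.00 0.00
2 31.0 30.0 30.0 -0.01 0.00 0.00
frame 1 time_fs 2
1 30.12 30.0 30.0 0.01 0.00 0.00
2 30.98 30.0 30.0 -0.01 0.00 0.00
```

## Worked example

Three harmonic modes are planted at 250, 1650 and 3300 cm⁻¹ with equal
velocity amplitudes; the hydrogen VDOS must recover all three at equal
weight:

```r
library(hydrolayer)

fix <- gen_harmonic_waters(100, mode_spec(c(250, 1650, 3300),
                                          c(0.20, 0.03, 0.015)),
                           dt_fs = 1, duration_fs = 10000, box = 60,
                           seed = 42)
vacf <- velocity_acf(fix$trajectory,
                     atoms = subset(fix$topology, element == "H")$atom_id)
vdos <- acf_to_spectrum(vacf, window = "hann", zero_pad_factor = 2)
band_summary(vdos)[, c("band", "peak_cm1", "peak_intensity", "fwhm_cm1")]
#>        band  peak_cm1 peak_intensity  fwhm_cm1
#> 1  acoustic  125.0865   8.386379e-04 0.5902815
#> 2 libration  250.1731   4.215241e+02 6.6892808
#> 3      bend 1649.4745   4.072842e+02 6.7681801
#> 4   stretch 3300.6167   4.048316e+02 6.7970596
```

Each planted mode is recovered within one grid step (1.67 cm⁻¹ here)
at near-equal intensity; the FWHM is the Hann window's resolution
limit for a 5 ps maximum lag, and the "acoustic" row is leakage at the
1e-6 level. On a real trajectory the whole workflow is one call:

```r
run <- run_pipeline(read_trajectory("md.trr"),
                    read_topology("topology.csv"),
                    hydrolayer_config(boundaries = "auto"),
                    out_dir = "out/")
autoplot(run$profile, partition = run$partition)
plot_layer_spectra(run, "vdos_H")
```

which writes `density_profile.csv`, `layers.json`, per-layer and
cumulative spectrum CSVs, `bands.json`, the effective `config.yaml`
and `run.log`, all stamped with the config hash. A thin CLI wrapping
the same functions ships in `inst/scripts/hydrolayer`.

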