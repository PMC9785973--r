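---
title: "Layer-resolved vibrational and IR spectra of hydration water"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layer-resolved vibrational and IR spectra of hydration water}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrolayer)
```

## The problem

Water within a nanometre of a protein surface behaves differently from
bulk water: the first adsorbed molecules are nearly immobile, hydrogen
bonded to surface donors, while successive shells relax toward bulk
behaviour over roughly 6–7 Å. hydrolayer dissects this transition from
a molecular-dynamics trajectory that stores velocities. The workflow
is:

1. compute the radial water mass-density profile relative to the
   solute surface, using periodic Voronoi cell volumes;
2. partition the hydration shell into sub-layers at the minima of that
   profile;
3. select each layer's molecular population with a residence-time
   criterion, over a tiling of the analysis window into intervals;
4. for each layer (and for cumulative unions of layers), estimate the
   velocity autocorrelation function (VACF) and the dipole-flux
   autocorrelation, and cosine-transform them into vibrational
   densities of states (VDOS) and infrared lineshapes;
5. summarise the conventional water bands (acoustic < 130 cm⁻¹,
   libration to ~1300 cm⁻¹, H–O–H bend near 1650 cm⁻¹, O–H stretch
   3250–3750 cm⁻¹), including shoulder detection.

## Model and estimators

**Units.** Internally everything is Å, fs, amu and elementary charges;
wavenumbers are cm⁻¹ with $\tilde\nu = \omega / (2\pi c)$,
$c = 2.99792458\times10^{-5}$ cm/fs. TRR and GRO inputs (nm, ps) are
converted on read.

**VACF.** For an atom selection $\alpha$,
$Z_\alpha(t) = \langle \mathbf v_j(t_0+t)\cdot\mathbf v_j(t_0)\rangle
/ \langle \mathbf v_j(t_0)\cdot\mathbf v_j(t_0)\rangle$, averaged over
atoms and over *all* time origins. The estimator divides the raw FFT
lag sums by the exact per-lag origin count; an $O(n^2)$ direct path is
kept and the two are tested to agree to $10^{-10}$.

**VDOS.** $Z(\tilde\nu) = \Delta t \sum_k w_k Z(t_k)
\cos(2\pi c\,\tilde\nu\, t_k)$ with trapezoidal end weights (half
weight at $k=0$ and the last lag). The end correction matters: with a
full-weight origin sample, a slowly decaying ACF acquires a constant
$\Delta t\,Z(0)/2$ offset across all frequencies, which for an
exponential ACF sampled at $\Delta t = \tau/10$ is a 5 % error at
$\tilde\nu = 0$ and grows with $(\omega\tau)^2$; the trapezoid form
reduces the residual to ~2 % at $\omega\tau = 5$. The wavenumber grid
is $\tilde\nu_m = m / (2 c\, t_{\max}\, z)$ up to Nyquist, where $z$
is the zero-padding factor, evaluated by real FFT (a literal cosine
sum is the cross-checked second path). The default window is a Hann
taper (1 at zero lag, 0 at $t_{\max}$), which suppresses truncation
ringing for production spectra; analytic validation uses `window =
"none"` because the taper broadens lines. For the rectangular window
the grid obeys the sum rule $\Delta\tilde\nu \sum_m S(\tilde\nu_m)
= Z(0)/(4c)$, which the tests verify to 2 % on pure cosines.

**IR.** The classical lineshape is the cosine transform of the
autocorrelation of $\mathrm dM/\mathrm dt = \sum_j e_j \mathbf v_j$,
the charge-weighted velocity sum of the selection. The proportionality
constant is fixed at 1 (arbitrary units): intensities are only
compared within this package's own conventions, and they scale exactly
as $e_j^2$ (doubling charges quadruples the spectrum — a test). A
neutral molecule translating rigidly contributes exactly zero flux.
Per layer, the IR is computed from the *collective* flux of the
layer's members, retaining cross-molecular dipole correlations within
the layer and excluding cross-layer ones; a per-molecule mode
(`ir_mode = "molecular"`, flux ACFs averaged per molecule) is provided
because either reading of a summed-then-averaged layer spectrum is
defensible, and the two coincide for a single molecule (a test).

**Voronoi density.** Generators are the water oxygens plus the solute
heavy atoms; each water's full molecular mass is assigned to its
oxygen's cell, and a bin's density is the pooled
$\sum m / \sum V_{\text{cell}}$ across frames (ratio of sums — an
empty frame contributes nothing to a bin rather than dragging the
average to zero). Cell volumes are computed by exact half-space
clipping of the half-box cuboid with bisector planes over 27 periodic
images, processed nearest-first with a sphere-bound early stop;
volumes tile the box to roundoff. Two properties of this estimator are
worth knowing: near the solute the water cells are truncated by the
solute's bisector, so the innermost one-to-two cell radii read
systematically high — this is a genuine feature of Voronoi densities
at surfaces, not a bug; and a cell's linear size at liquid density
(~3.1 Å) smooths any density feature narrower than that. For synthetic
step-profile recovery the package therefore also provides the
`bin_volume` estimator (exact spherical shells around a single-atom
solute proxy), which carries no such smoothing.

**Boundaries.** Sub-layer boundaries sit at local minima of the
moving-average-smoothed profile (default window 5 bins; plateau ties
break toward the smaller distance), between the first populated bin
and the bulk onset — the first distance from which the smoothed
density stays within `bulk_tolerance` (default 5 %) of the far-field
mean, itself taken over the outer quarter of the profile. The last
boundary is that bulk onset. The procedure is deterministic and
invariant to rescaling the density axis. When detection is not run,
the default partition {2.2, 3.4, 4.5, 7.0} Å brackets the
characteristic features of protein hydration shells (first density
peak near 1.8 Å, second near 2.6 Å, a narrow buffer zone, bulk onset
near 7 Å) and is always user-overridable.

**Residence membership and intervals.** A molecule belongs to a
layer's population for an interval only if it holds that layer's label
in at least 90 % of the interval's frames (the default threshold).
The final 200 ps of the trajectory are tiled into intervals of 20 ps
for layers 1–2 and 5 ps for the outer layers — inner-layer populations
exchange slowly and support long intervals, outer ones do not — and
spectra are averaged over the first 10 intervals of each layer. With
5 ps tiles a 200 ps window yields 40 tiles; averaging uses the first
`n_intervals` (default 10) so that every layer's average pools the
same number of interval estimates, and `n_intervals` is exposed for
users who prefer to average all tiles. Labels are half-open: a
molecule exactly on a boundary belongs to the outer layer; beyond the
last boundary it is bulk (label 0). At the 0.90 threshold membership
is necessarily unique; thresholds at or below 0.5 could tie, and the
scripted-label generator documents the tie rule (lowest layer index
wins).

**Cumulative spectra.** The "interface with $k$ layers" spectrum pools
the union of members of layers $1..k$ per interval, then averages
across intervals. Because layers natively use different interval
lengths, pooling is only well defined on a common scheme; the pipeline
evaluates cumulative membership on the layer-1 (coarsest, 20 ps)
scheme. With all layers plus bulk pooled, the result equals the
whole-selection spectrum to $10^{-10}$ — a completeness test.

## Synthetic data: what it does and does not emulate

No MD engine is run anywhere. Three seeded generators supply data with
known analytic structure:

- `gen_harmonic_waters()`: neutral three-site waters whose velocities
  are exact cosine superpositions at prescribed wavenumbers (default
  set {50, 250, 1650, 3300, 3650} cm⁻¹ mirroring the water band
  positions), random unit displacement patterns and per-molecule
  phases; positions are the analytic integrals. `amplitude` is a
  displacement in Å, so the velocity (and hence VDOS weight) of a mode
  scales as amplitude × ω — equal VDOS peaks require amplitudes
  scaled by 1/ω.
- `gen_ou_gas()`: atoms with exact Ornstein–Uhlenbeck velocity
  updates; the VACF is analytically $e^{-t/\tau}$ and the VDOS a
  Lorentzian $\propto \tau/(1+\omega^2\tau^2)$ — the closed-form
  oracle for the whole VACF→spectrum chain.
- `gen_layered_box()`: static geometry with a prescribed piecewise
  radial density around a single-atom solute proxy; each annulus
  receives a fixed count round(ρV/m) placed uniformly, redrawn per
  frame, so the planted density is exact up to count rounding.

These fixtures reproduce the *statistical structure* the analysis
assumes — mode frequencies, charges and neutrality, exponential
velocity memory, radial density layering, scripted layer occupancy —
but none of the physics of real hydration water: no anharmonicity, no
hydrogen-bond network, no coupling between layering and dynamics, no
molecular diffusion across layers. Passing tests therefore validate
the estimators and the bookkeeping, not force fields; the headline
observations on real systems (density peaks near 1.77/2.6 Å at
0.83/1.12 g cm⁻³, the 3300 cm⁻¹ stretch shoulder, bend blue-shifts)
require a production MD trajectory as input.

## Numerical choices and problem sizes

- ACF estimation uses all time origins with per-lag counts (`max_lag`
  default: half the interval), FFT-based with a direct $O(n^2)$
  reference path.
- Spectral defaults: Hann window, zero-padding factor 1 (pipeline uses
  what the config specifies); all recorded in each spectrum's `meta`.
- Voronoi clipping tolerance is $10^{-9}\,\min(\text{box})$;
  coincident generators (min-image distance < $10^{-8}$ Å) are
  rejected naming the pair. Orthorhombic boxes only; triclinic inputs
  are rejected on read.
- Shoulder detection smooths with a Savitzky–Golay filter (default
  window 11 points, order 3) and reports local minima of the second
  derivative away from the band's main peak; FWHM uses linear
  interpolation at half maximum and is NA when a flank leaves the
  band.
- Degenerate inputs: empty density bins report 0 with a note; a flat
  profile yields a single-layer partition with a warning; an interval
  whose member set is empty is skipped with a warning, and erroring
  only when all intervals are empty.
- Validation sizes are chosen so the whole suite runs on one CPU in
  minutes: frequency recovery uses 100 molecules × 10 ps at 1 fs; the
  OU oracle 2000 atoms × 400τ at 5 fs with lags to 10τ (the ~2 %
  statistical+discretization residual sits well inside the 5 %
  acceptance band); density recovery ~500 molecules × 1500 frames;
  Voronoi conservation 100 frames × 50 sites. The same code paths
  scale to production systems (~8000 waters) linearly in atoms and
  frames; only the Voronoi tessellation is super-linear in practice
  and remains the pipeline's cost centre, which is why the pipeline
  exposes `profile_frames` to subsample frames for the density stage.

## Known limitations

- No quantum/harmonic corrections to the classical spectra, no
  absolute absorption coefficients, no Raman, no protein–water
  cross-spectra.
- Distances are oxygen-to-heavy-atom minimum-image distances, not
  solvent-excluded-surface distances; `heavy_only = FALSE` switches to
  all protein atoms, since conventions differ.
- The stored sampling interval is treated as authoritative: capturing
  the stretch band at 3750 cm⁻¹ requires a stored Δt ≤ ~4.4 fs
  (`nyquist_wavenumber()` documents the bound; generators enforce it).
- XTC (velocity-free) input is rejected for spectral work by design.
- Layer exchange events are not tracked; the residence rule only
  filters populations.
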