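# bilayermech

Trajectory analysis of planar (binary) lipid bilayer simulations in R:
mechanics, acyl-tail ordering, lateral mixing statistics, and a
subunit-level decomposition of lipid–lipid interaction energies. It is
aimed at membrane simulators who have per-frame structures (GRO, multi-model
PDB, or a plain frames-table CSV) and pressure-tensor records, and who want
the standard bilayer observables with defensible error bars — without
rerunning any molecular dynamics.

## What it computes

**Surface tension** from the diagonal pressure tensor of a membrane normal
to z:

    γ = 0.01 · L_z · ( P_zz − (P_xx + P_yy)/2 )        [mN/m; bar, Å]

**Area compressibility modulus** K_A from the linear response γ = K_A ε_A,
with the area strain ε_A = (⟨A⟩ − ⟨A⟩₀)/⟨A⟩₀ measured relative to the mean
area per lipid at zero imposed tension. Imposed tensions are exact; the
statistical error lives in the strain, so the fit is a weighted regression
of γ on ε_A with strain uncertainties propagated through a preliminary
slope. Per-tension uncertainties are autocorrelation-corrected:
sem = sd·√(g/N) with statistical inefficiency g = 1 + 2τ, and τ the
integrated autocorrelation time truncated at the first non-positive
autocovariance.

**Order parameters** S_C(i) = ½⟨3cos²θᵢ − 1⟩, where θᵢ is the angle between
the membrane normal and the minimum-image vector joining carbons C(i−1) and
C(i+1) of an acyl chain; profiles per species and chain (SN1/SN2), both
leaflets pooled.

**Packing and mixing**: phosphorus–phosphorus lateral spacing histograms;
periodic 2D Voronoi tessellations of each leaflet (3×3 ghost tiling, cell
areas tile the box exactly) with per-species area statistics; the
mixed-contact fraction f_mix = 100·C_AB/(C_AA + C_AB) of phosphate contacts
within 11 Å, counted from the primary species' perspective so that ideal
mixing returns the secondary mole percentage; and neighbor-composition
tables from GL1 sites within 15 Å.

**Interaction energies**: pairwise Lennard-Jones (Lorentz–Berthelot,
switched between 10 and 12 Å) plus shifted-cutoff or reaction-field Coulomb,
summed over all intermolecular site pairs and accumulated by lipid subunit
(head, phosphate, glycol, tail). Reported as the total energy, the partial
energy (all like-group pairs removed), species-pair splits, and ion–head /
ion–phosphate terms.

A synthetic-bilayer module generates jittered-lattice leaflets, tilt-
controlled straight tails, AR(1) area series with a planted K_A, pressure
records with a planted γ, and charged toy systems — ground truth for every
stage, and the basis of the test suite.

## Worked example

Generate the default synthetic study — 100 lipids per leaflet at 65:35
DOPC:DSPG, planted K_A = 245.81 mN/m probed at γ ∈ {−7, 0, 7, 15} mN/m with
AR(1) area noise — and recover the modulus:

```r
library(bilayermech)

spec <- synthetic_spec(seed = 42)
gas  <- gen_gamma_area_series(spec)      # per-tension area-per-lipid series
fit_area_compressibility(gas)
#> K_A = 238.15 +/- 10.09 mN/m  (A0 = 66.03 A^2, r^2 = 0.9948)
```

The planted 245.81 mN/m is recovered within one standard error; `A0` is the
zero-tension area per lipid and r² the weighted goodness of the γ–strain
line. Mixing and packing statistics on frames from the same spec:

```r
frames <- gen_leaflet_frames(spec, n_frames = 5)
gmap   <- synthetic_group_map()

mixed_contact_fraction(frames, gmap)
#> f_mix (DOPC primary vs DSPG) = 41.34 % +/- 0.82

voronoi_leaflet(frames[[1]], gmap, "upper")$species_summary
#>   species mean_area median_area
#> 1    DOPC  66.63659    67.00219
#> 2    DSPG  65.79512    65.96782
```

f_mix tracks the *realized* secondary mole fraction (39.5% for this seed at
only 100 lipids per leaflet), the signature of a well-mixed leaflet; the
Voronoi cell areas average ~66 Å², the area per lipid the lattice was built
at. A command-line front end with `synth`, `ka`, `order`, `packing`,
`energy` and `run-all` subcommands is installed at
`system.file("cli", "bilayermech.R", package = "bilayermech")`.

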