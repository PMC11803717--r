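---
title: "Methods: bilayer mechanics, ordering and mixing in bilayermech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bilayer mechanics, ordering and mixing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilayermech)
```

## Scope and model

`bilayermech` analyzes planar lipid bilayers simulated in orthorhombic
boxes with the membrane normal along z. Everything in the package operates
on three ingredients: per-frame site coordinates with species/molecule
labels (`boxed_frame`), a per-species assignment of site labels to the four
lipid subunits — head, phosphate, glycol, tail — together with the
phosphorus (P/PO4) and first tail-linker (GL1) reference sites
(`group_map`), and per-frame pressure-tensor diagonals. Internal units are
fixed once: Ångström, bar, mN/m, kcal/mol, elementary charge. Readers
convert on ingest (GRO nm → Å); triclinic boxes are rejected because every
system this package targets is rectangular.

Leaflets are assigned by comparing each lipid's phosphorus z against the
global phosphorus midplane — cheap, deterministic, and correct for planar
bilayers, which is why no clustering is attempted. Assignment is
re-evaluated on every frame, so a lipid that flip-flops between leaflets is
simply counted where it currently sits; for the stationary planar systems
the package targets this choice has no measurable effect, and it avoids
carrying state between frames.

## Surface tension and the area compressibility modulus

The per-frame surface tension is the normal/lateral pressure imbalance
integrated over the box height, `γ = 0.01·Lz·(Pzz − (Pxx+Pyy)/2)` with
pressures in bar and Lz in Å (1 bar·Å = 0.01 mN/m). The area
compressibility modulus is the slope of the linear response `γ = K_A ε_A`,
where the strain `ε_A = (⟨A⟩ − ⟨A⟩₀)/⟨A⟩₀` uses the mean area per lipid of
the zero-tension run as the reference, and the area per lipid is the
lateral box area over the number of lipids in one leaflet.

Two genuinely open choices were settled as follows:

* **Regression direction.** γ is the controlled variable and is imposed
  exactly by the barostat, while the measured strain is noisy, so the
  natural error model has uncertainty on the x-axis. The package regresses
  γ on ε anyway (keeping K_A as a slope in its native units) and converts
  the strain uncertainties into effective tension uncertainties through a
  preliminary slope estimate, refining the weights once. With four to a few
  dozen tension points this converges immediately; iterating further
  changes nothing at double precision.
* **Uncertainty of the slope.** The standard error comes from the analytic
  weighted-least-squares formula with the per-point uncertainties treated
  as known variances, not from the two-degrees-of-freedom residual
  variance, which would be extremely noisy with four points. A resampling
  alternative was considered and rejected as strictly noisier at these
  design sizes.

Degenerate inputs are handled explicitly: a design without a γ = 0 series
has no strain reference and errors; fewer than three distinct tensions
error; noiseless collinear input (every sem = 0) falls back to unweighted
least squares so that exact lines are reproduced to machine precision with
a zero standard error.

Per-tension uncertainties use the integrated-autocorrelation error model:
the normalized autocovariance (computed by FFT) is summed until its first
non-positive value, giving τ; the statistical inefficiency is g = 1 + 2τ
and `sem = sd·sqrt(g/N)`. The initial-positive-sequence truncation is
standard and parameter-free; for an AR(1) process with coefficient φ it
recovers the closed-form g = (1+φ)/(1−φ) to within a few percent at the
series lengths used here (5·10³–10⁵ frames). A constant series returns
(mean, 0, 0) rather than erroring, since a perfectly rigid barostat is a
legitimate degenerate input of the synthetic generators. An equilibration
discard fraction is available on `gamma_area_series()` and defaults to 0:
the synthetic series are stationary by construction, and discard policy on
real data is the caller's decision.

## Order parameters

`S_C(i) = ½⟨3cos²θᵢ − 1⟩` with θᵢ the angle between +z and the
minimum-image vector from carbon C(i−1) to C(i+1); defined for interior
carbons 2…n−1. Both leaflets are pooled without flipping the lower
normal — the cosine enters squared, so the flip would be a no-op — and the
per-position standard error applies the same autocorrelation correction to
the per-frame means (plain sd/√n below 10 frames). Double bonds receive no
special treatment: the formula is position-agnostic, and any cis-bond
signature shows up in the profile itself, not in the estimator.

## Packing and mixing statistics

**Spacing histograms** accumulate phosphorus–phosphorus distances within
one leaflet, lateral (xy) minimum-image by default — the natural in-plane
spacing proxy for a planar leaflet — with a 3D toggle. Bins are 1 Å wide by
default over [0, min(Lx,Ly)/2], the unambiguous range under the minimum
image convention.

**Periodic Voronoi.** Generators (phosphorus xy positions) are tiled over a
3×3 array of image boxes, the tiled set is tessellated (Delaunay/Dirichlet
via deldir), and the central copy's cells are kept. This is exact whenever
nearest-generator distances are below half the box, which holds by orders
of magnitude at bilayer densities, and it makes the conservation law —
per-leaflet cell areas sum to Lx·Ly — hold to rounding error, which the
tests assert at 1e-6 relative. Coincident generators are jittered once by
1e-6 Å and retried, then rejected. Cell areas are validated against an
independent nearest-generator rasterization (512² grid) in the test suite.

**Mixed contacts.** Two lipids are in contact when their phosphate sites
lie within 11 Å (3D minimum-image; lateral and 3D differ negligibly for
planar leaflets, and 3D is the default). The mixed fraction
`f_mix = 100·C_AB/(C_AA + C_AB)` counts from the primary species'
perspective: an A–A pair contributes two A-contacts, an A–B pair one. This
counting is what makes f_mix of an ideally mixed leaflet converge to the
secondary mole percentage (the property the statistic is used for);
counting unordered pairs instead would converge to 2q/(1+q), and including
B–B contacts in the denominator to 2pq — both the wrong calibration.
Contacts are restricted to same-leaflet pairs, as are neighbor counts:
cross-leaflet phosphate distances exceed the cutoffs in any planar bilayer,
so the restriction only guards against pathological inputs. A
single-species system returns f_mix = 0 (no mixed contacts) rather than
erroring.

**Neighbor composition** uses the GL1 site and an inclusive 1.5 nm cutoff
and reports, per center species, mean neighbor counts and percentage
composition with sds over frames, leaflets pooled.

## Interaction-energy decomposition

Pairwise nonbonded energies — Lennard-Jones with Lorentz–Berthelot
combining, smoothly energy-switched between 10 and 12 Å, plus either
potential-shifted Coulomb or reaction-field electrostatics (dielectric 15,
the coarse-grained convention) — are summed over all **intermolecular**
site pairs and accumulated into cells indexed by the unordered
(species, subunit) pair. Intramolecular pairs are excluded entirely; no
1–4 scaling machinery exists because no bonded exclusions are needed at
the molecule level. The total energy sums every cell; the partial energy
removes all like-group cells (head–head, phosphate–phosphate,
glycol–glycol, tail–tail, between any two molecules of any species).
Species-pair splits and ion–head/ion–phosphate terms reuse the same pair
machinery, so closure (total = partial + like-group sum; species components
sum to the total) holds by construction and is still asserted against an
independent O(N²) double-loop oracle at 1e-10 relative in the tests. Both
Coulomb modes are continuous at the cutoff and zero beyond it.

Long-range electrostatics (Ewald/PME) is deliberately absent: the module's
contract is the decomposition bookkeeping under a well-defined short-range
model, not the reproduction of any particular MD engine's energies. The
Coulomb constant is fixed at 332.0636 kcal·Å/(mol·e²) for bit-exact
reproducibility. Counterions are treated as free ion species even when a
force field formally bundles them into a lipid's residue, since they are
dissociated in solution and the ion–lipid terms are reported separately.

## The synthetic generators: what they emulate, and what not

The generators provide ground truth, not physics. Lipids are geometric
stand-ins: jittered square-lattice leaflets at a prescribed composition
(random, checkerboard, or block labels), straight 18-carbon tails at
1.27 Å per carbon whose axes are drawn from a fixed-angle, von
Mises–Fisher, or isotropic tilt model about the inward normal, and
single-site head/phosphate/glycol beads. Area-per-lipid series are AR(1)
processes around `A0·(1 + γ/K_A_true)`; pressure records hold Pzz = 1 bar
and draw the lateral components around `Pzz − γ/(0.01·Lz)`. Every
generator is bit-reproducible from its seed, which is kept separate from
the caller's RNG stream.

Defaults mirror the scale of the atomistic systems the analyses target and
were fixed once: 100 lipids per leaflet (~81 × 81 Å box), 65:35
composition, A0 = 66.3 Å² (the DOPC zero-tension reference), tensions
{−7, 0, 7, 15} mN/m, planted K_A = 245.81 mN/m, AR(1) φ = 0.8 with
stationary sd 0.8 Å² — a realistic per-frame area-per-lipid fluctuation for
a ~100-lipid leaflet under a Langevin-piston barostat.

Because every statistic the package computes depends only on positions,
labels, charges and box — not on conformational realism — recovery of the
planted truth is an exact end-to-end check of the estimators. What passing
tests do **not** show: correctness of any force field, realism of tail
conformers or undulations (the generator has neither), or the behavior of
the estimators on phase-separated or highly curved membranes.

## Problem sizes and numerical tolerances

The test suite exercises, among others: K_A recovery over 200 replicates
of 5·10³-frame series at the four standard tensions (3-sigma coverage
≥ 95%, mean bias < 2%); the AR(1) inefficiency at φ = 0.9 on 10⁵ frames
(25% tolerance); order-parameter closed forms at fixed tilt to 1e-12 and
the isotropic null at 3/√N; Voronoi conservation at 1e-6 relative on 100
random 10–50-lipid leaflets plus raster-oracle agreement within 2% per
cell; energy-decomposition equality with the brute-force oracle at 1e-10
relative on ≤300-site systems in both Coulomb modes; and a 2025-lipid
label-randomization experiment for f_mix (±1 percentage point around the
35% secondary mole fraction). These sizes were chosen so the whole suite
runs in about a minute on one core while leaving every tolerance
comfortably resolvable.

## Known limitations

* Planar bilayers only: leaflet assignment by a global midplane fails on
  vesicles, stalks, or strongly undulating membranes.
* Orthorhombic boxes only; no triclinic support.
* The energy module is short-range by design; absolute energies are not
  comparable to PME-based engine output, though decomposition *ratios* and
  bookkeeping identities are.
* The Voronoi construction assumes generator separations below half the
  box, which is safe at physical lipid densities but not for adversarial
  near-empty leaflets.
* Binary mixtures are assumed where species-pair statistics are reported;
  f_mix is undefined for three or more species.
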