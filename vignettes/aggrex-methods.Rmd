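---
title: "aggrex: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{aggrex: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggrex)
```

aggrex analyzes the two ingredients that control excited states in
molecular aggregates: the packing geometry around a chromophore and the
electrostatic environment embedding it.  This vignette is the package's own
account of the models it implements, the parameters that matter, and the
design decisions taken where several defensible choices existed.

## Geometry containers and bonding

All geometry lives in an `aggrex_structure`: an ordered table of atom sites
(element, Cartesian position in Å, partial charge in e, covalent and vdW
radii from a built-in table), optional lattice row-vectors, and a bonding
scheme.  Two atoms are bonded when their distance falls below a threshold;
the threshold applies either to the nucleus–nucleus distance
(`center-distance`) or to the distance minus the two covalent or vdW radii
(`covalent-edge`, `vdw-edge`).  The default is covalent-edge with **0.4 Å**
of slack, a robust setting for organic molecules: covalent bonds sit well
inside the radius sum + 0.4 Å while non-bonded contacts sit well outside.
Bare point charges (empty element symbol) never bond and are excluded from
volumetrics.

Coordinates are Å everywhere in memory.  Cube files convert to Bohr on
write/read (1 Bohr = 0.529177210903 Å), and all electrostatics are
evaluated in atomic units internally.

### Periodic operations

`complete_molecules()` reassembles molecules cut by the periodic boundary:
each molecule is grown breadth-first from a seed atom, translating every
newly reached atom by the minimum-image lattice shift relative to its
parent, and finally each molecule's fractional centroid is folded into
[0, 1).  If any bond after the minimum-image shift exceeds half the
shortest cell height the completion is ambiguous (the molecule wraps around
the cell) and an error is raised rather than guessing.

`build_cluster()` extracts a sphere of whole molecules about the origin.
Two readings of "whole molecules within a radius" conflict: requiring *all*
atoms inside clips surface molecules, while the embedded-cluster convention
includes a molecule when *any* atom is inside and then keeps it whole.  The
default is any-atom inclusion; `strict_all_atoms = TRUE` implements the
literal all-atoms reading.  Duplicate images are removed with a 1e-6 Å
position tolerance.

## Voronoi packing volumes

A point belongs to a molecule's Voronoi region when the atom minimizing the
vdW-scaled distance `|p − r_a| / r_vdW(a)` belongs to that molecule; the
scaling grants larger atoms (O) more space than hydrogens.  The measure is
grid-based: a bounding box (cluster extent + largest vdW radius + 2 Å
padding) is voxelized at a default spacing of **0.2 Å**, every voxel is
assigned to its winning atom, and volumes are voxel counts times the voxel
volume.  Ties go to the lowest atom index, making the assignment
deterministic; since every voxel is assigned exactly once, per-molecule
Voronoi volumes sum to the box volume exactly — a conservation law the test
suite asserts.  The vdW volume is the grid measure of the union of the
molecule's vdW spheres (overlaps counted once), and the volumetric index
`Vi = V_V / V_vdW` normalizes the Voronoi volume into a packing-tightness
measure.  A 0.2 Å grid reproduces a single-sphere volume to better than 1%.

The Voronoi region of a molecule on the cluster surface is truncated by the
bounding box; such results carry `interior = FALSE` and should be read as
box-dependent.  Only interior molecules of a sufficiently padded cluster
give environment-determined volumes.

## Dimer analysis

Dimers are enumerated below a distance threshold under one of three
metrics: centroid–centroid, nearest intermolecular atom pair, or the atom
pair distance minus both vdW radii.  Each dimer's *fingerprint* is the
sorted vector of all intermolecular atom-pair distances — invariant under
rotations, translations and reflections — and two dimers are equivalent
when their fingerprints agree to an RMSD below **1e-4 Å**.  A greedy pass
keeps the first representative; for crystalline clusters the
equivalent/inequivalent RMSD gap is many orders of magnitude, so the result
is independent of input order.

Principal axes of a (near-planar) molecule follow a four-step
construction: (1) project all atoms onto the least-squares plane (SVD of
the centered coordinates; smallest singular direction is the normal);
(2) take the two longest projected interatomic distances as the diagonals
AC > BD of a quadrilateral ABCD labeled so that AB is the longest side
(equal-longest distances are broken lexicographically by atom index, so the
axes are deterministic); (3) with midpoints H = [AB], G = [BC], F = [CD],
E = [DA], the principal axis runs E→G and the secondary axis F→H; (4) the
two are symmetrically orthogonalized — rotated in their common plane by
equal and opposite half-angles — and the tertiary axis is c = a × b
(right-handed).  When one atom belongs to both longest distances, B and C
coincide and the construction degrades gracefully.  A `long_axis_mode`
takes the single longest distance as the principal axis instead, with the
in-plane perpendicular as secondary.

Inter-axis angles α, β, γ are reported unfolded in [0, 180°] (a dimer and
its inversion image are distinguishable); the slip angle is the smallest
acute angle between the centroid–centroid axis and either tertiary axis, in
[0, 90°] — 0° for perfect cofacial stacking, 90° for a fully in-plane
offset.  The archetype labels use heuristic thresholds (the field has no
canonical ones), all configurable: face-to-face when γ (folded to [0,90°])
< 30° and slip < 30°; parallel-displaced when γ < 30° but slip ≥ 30°;
edge-to-face when γ is within 30° of perpendicular; otherwise "other".

## Exciton classification

For a two-fragment system, the Mulliken density of MO *k* on fragment A is
`ρ_A^k = Σ_{μ∈A,ν} c_μk c_νk S_μν` (fragment-diagonal block plus the full
A–B cross term), so `ρ_A + ρ_B = 1` for an S-normalized orbital.  For a
single-excitation state with amplitudes `C_{i→j}` the indices

```
ΣP_A = Σ σ_ij C² (ρ_A^j + ρ_A^i),   ΔP_A = Σ σ_ij C² (ρ_A^j − ρ_A^i)
```

(σ = +1 for i < j, −1 otherwise) are in electrons with bounds 0 ≤ ΣP ≤ 2
and −1 ≤ ΔP ≤ 1.  The classifier labels a state whose index lies within
**0.5 e⁻** of an extreme: ΔP near −1 / +1 → CT(A→B) / CT(B→A); otherwise
ΣP near 2 / 0 → LOC(A) / LOC(B); otherwise DELOC.  Charge-transfer tests
take precedence — at the default threshold the regions are mutually
exclusive except for pathological corners, where the CT label is the
physically safer call.  Amplitude conventions differ between
quantum-chemistry programs, so inputs may be renormalized on request
(`renormalize = TRUE` divides by √|Σ σC²|); the indices' bounds require the
signed normalization Σ σC² = 1 and it is enforced to 1e-6.

## Exciton couplings

Four schemes, in increasing order of information used:

* **Half-gap**: `|J| = (E₂ − E₁)/2`, exact for a resonant dimer; exposed as
  a pure function of two energies.
* **Point-dipole (Kasha)**: `J = (μ_i·μ_j)/R³ − 3(μ_i·R)(R·μ_j)/R⁵` with R
  the centroid separation.  The first term is the scalar product of the two
  TDMs — the standard dipole–dipole interaction.
* **Atomic transition charges**: `J = Σ_a Σ_b q_a q_b / |R_a − R_b|`, which
  converges to the PDA value in the far field (asserted quantitatively in
  the tests at 80× the monomer size).
* **Diabatization**: with a per-state property (TDM or ATC vector) for the
  adiabatic states and for the isolated monomers in their aggregate
  orientation, the overlap matrix `M = (P^A)ᵀ P^ISO` is decomposed
  `M = UΣVᵀ` and `C = (UVᵀ)ᵀ` is the closest unitary adiabatic→diabatic
  map; `H_D = C diag(E) Cᵀ` has the couplings as off-diagonals and
  reproduces the adiabatic energies exactly.  The construction generalizes
  to N states (e.g. trimer Hamiltonians).  All algebra is real-orthogonal:
  the properties are real, so conjugations become transposes.  A zero
  singular value means the chosen property cannot distinguish the states
  (e.g. parallel TDMs) and the code errors with advice to pick another
  property.  An adiabatic state's sign is unobservable and absorbed by the
  SVD; flipping a *reference* property's sign flips the sign of that
  diabat's couplings — a phase convention, so only |J| is
  convention-independent.

Energy units follow the inputs; the CLI reports couplings in meV
(1 Hartree = 27.211386 eV).

## Ewald embedding

The lattice (Madelung) potential of a neutral periodic charge distribution
is conditionally convergent; the Ewald split evaluates it as a short-range
real-space sum of `q erfc(γr)/r` over images plus a reciprocal-space sum
over G ≠ 0 with Gaussian damping `exp(−G²/4γ²)`.  At a lattice site the
divergent self term is replaced by `−2γq_i/√π`, giving the potential felt
by that ion.  Defaults: γ = 5.6/h_min (h_min the shortest cell height in
Bohr), with cutoffs auto-validated by a doubling test until two successive
evaluations agree within `target_accuracy` (1e-6 Hartree/e); the result is
γ-independent by construction and the tests assert it.  The rocksalt test
recovers the Madelung constant to 1e-5 against an independent Evjen shell
sum.

`fit_ewald_charges()` builds a finite array that mimics the infinite
lattice: point charges on the crystal sites of a centered supercell
(~1000 sites by default; the classic recipe uses ~10⁴), with charges inside
a fixed zone (inner-region bounding sphere + 2 Å) pinned to nominal values
and the outer charges adjusted to reproduce the Ewald potential at the
inner-region atomic sites.  Because there are far more free charges than
match conditions, the system is underdetermined; the implementation takes
the minimal change from the nominal charges that satisfies the potential
match together with the exact constraints Σq = 0 and Σq·r = 0.  Fractional
charges are allowed throughout.

### Charge redistribution and self-consistency

Population-analysis charges are carried from a reference molecule onto any
ensemble of the same molecules by *connectivity fingerprints*: the
bond-order matrix B holds shortest bond-path lengths (all-pairs BFS on the
bond graph — the unique fixed point of iteratively extending first
connections through common neighbors), and an atom's identity is its
element plus the multiset of (element, bond distance) pairs over its
molecule.  Chemically equivalent atoms (a methyl's three hydrogens) share a
fingerprint and receive the mean reference charge, which preserves the
molecular total.

The self-consistent loop alternates: embed region 1 in a point-charge
array built from the current cell charges → population analysis by the
calculator (ground or excited state) → redistribute the fractional charges
onto the unit cell by fingerprint → rebuild the array, until the analysis
changes by less than **1e-4 e per atom** (default), optionally with linear
mixing (`mixing < 1`) for oscillatory cases.  The loop's array builder is
injectable, which is also how the tests drive it with analytic fixed-point
calculators.

## ONIOM QM:QM′

The subtractive energy is `E = E_high(1) + E_low(1∪2) − E_low(1)`; with
electrostatic embedding the two region-1 terms see the point-charge array
(`E = E_high^EE(1) + E_low(1∪2) − E_low^EE(1)`), while the full-system
low-level term does not — for a fixed environment the array would only add
a constant there.  Supported flavors: mechanical, OEC (region-2 atomic
charges), OEEC (Ewald-fitted array), SC-OEEC-S0/S1 (self-consistent arrays
from ground-/excited-state populations).  Regions must be unions of whole
molecules; crossing a covalent bond is rejected (no link atoms).  When both
levels and embeddings coincide the combination collapses to the full-system
energy at machine precision, and gradients are checked against central
finite differences — both are standing tests.

Optimization moves only region-1 coordinates (region 2 and the charges are
frozen, verified bit-identical after optimization).  Minima use L-BFGS-B
with convergence at max |gradient component| < **3e-4** Hartree per
coordinate unit.  Conical intersections are located without nonadiabatic
couplings by minimizing the gap penalty

```
F = (E₁ + E₀)/2 + σ ΔE²/(ΔE + α)
```

with defaults σ = 3.5 and α = 0.02 Hartree (standard penalty-method
practice — σ of a few and α well below typical gaps); if the gap stagnates
above `gap_tol` (default 1e-3 Hartree) σ doubles for up to `sigma_steps`
stages.  States are ordered by energy at each geometry; there is no
diabatic state tracking, which is acceptable for penalty-function MECI
search but can make plain minimization hop surfaces very near crossings —
a documented limitation.

Calculators receive the geometry's coordinate numbers verbatim and must
return gradients with respect to those same numbers; real program adapters
are expected to convert Å→Bohr at their boundary.  The analytic mocks
(quadratic bowl, double well, two-state conical model
`E± = ω/2 (x²+y²) ± √((κx)² + (cy)²)`) define energies directly over the
coordinates, keeping every gradient check exact.

## Synthetic fixtures and what the tests do (and do not) show

`make_toy_crystal()` provides rocksalt and CsCl ionic cells (known Madelung
constants), a minimal two-molecule herringbone motif (symmetry-equivalent
dimers for deduplication), and a planar rectangle molecule (axes with an
exact answer).  `random_cis_wavefunction()` generates seed-deterministic
two-fragment wavefunctions with identity AO overlap — identity overlap
keeps every Mulliken density hand-checkable, and a `localized` variant
yields fragment-pure orbitals that reach the index bounds exactly.
Problem sizes throughout the suite are chosen for sharp oracles: 8-site
cells, 10³-charge arrays, 10⁴-wavefunction sweeps, 0.1–0.4 Å grids.

These fixtures exercise the algebra and the algorithms exactly, but they do
not emulate real electronic structure: no basis-set overlap between
fragments (except where constructed), no exchange contributions to
couplings, no anharmonic PES topology beyond the model forms, and no
experimental crystal geometries.  Passing tests certify the machinery —
applying it to a real system still requires a quantum-chemistry backend
behind the calculator contract and RESP/Mulliken charges from it.

## Known limitations

* Voronoi volumes are box-truncated for surface molecules (flagged, not
  corrected).
* The principal-axes construction presumes a meaningful molecular plane;
  strongly 3D molecules need `ignore_elements` pruning or `long_axis_mode`.
* Dimer archetype thresholds are heuristics, intended for triage rather
  than as a definitive taxonomy.
* The Ewald fit places charges only on crystal sites; arbitrary charge
  lattices and polarizable embedding are out of scope.
* No link atoms: ONIOM regions must cut only intermolecular space.
* Exact transition-density Coulomb couplings and PCM corrections are not
  implemented; the ATC scheme is the highest-resolution Coulomb model here.
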