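---
title: "Building mineralized collagen fiber models and measuring their elastic response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building mineralized collagen fiber models and measuring their elastic response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(bonefiber)
```

## The modelling problem

At the nanoscale, bone is a fiber: a bundle of collagen fibrils, each a
staggered array of tropocollagen molecules with a ~67 nm axial repeat (the
D-period, one gap plus one overlap zone), mineralized by hydroxyapatite
(HA) and hydrated. Crucially, most of the mineral is not inside the
fibrils (the intra-fibrillar volume, IFV) but between them, in the
extra-fibrillar volume (EFV).

Crystallographic fibril models frustrate EFV mineralization: their unit
cells contain collagen molecules that are covalently continuous through
*all three* periodic boundaries. Enlarging such a cell laterally to make
room for mineral would sever covalent bonds that cross the x and y faces.
The route implemented here therefore proceeds in three steps:

1. `extract_nanofiber()` rewrites the fibril so that no covalent bond
   crosses a lateral boundary, by translating atoms with whole lattice
   vectors (z-crossing bonds, which carry the axial continuity of the
   fibril, are retained). This is a pure relabelling of periodic images:
   atom count, bond count and every bond length are invariant.
2. `build_fiber()` replicates the nanofiber on its own lattice vectors
   into an `nx * ny` bundle — lattice-vector placement preserves the
   quasi-hexagonal molecular packing — and wraps it in an orthorhombic
   simulation box with positive x/y margins. The IFV is an axis-aligned
   box around the collagen; EFV = simulation box minus IFV.
3. `pack_structures()` inserts HA formula units, water and ions into
   those regions under a minimum-distance constraint, with counts from
   the composition solver.

## Composition arithmetic

`solve_counts()` anchors everything on the collagen mass `m_CLG`, since
the collagen structure is fixed while mineral and water are added: total
mass `M = m_CLG / f_CLG`, then `n_HA = round(f_HA M / 1004.62)` and
`n_H2O = round(f_H2O M / 18.015)` (nearest-integer rounding; 44 atoms per
HA formula unit). The mineral is split `round(n_HA * efv_share)` to the
EFV — default share 0.80, the partition supported by experiments on
cortical bone — with the remainder to the IFV.

Ion handling is a policy, not a guess, because published ion counts are
generally not derivable from a stated molarity without knowing the volume
basis: `"neutralize"` adds counter-ions for the net charge, `"molarity"`
computes `round(c N_A V_water)` pairs, `"fixed"` passes counts through.

A consistency check, `fit_atom_totals()`, confronts a family of published
per-model atom totals with this arithmetic: with two free parameters (the
shared collagen atom count and collagen mass) and *integer* molecule
counts inside the prediction, the four totals 299,136 / 331,797 / 377,486
/ 446,018 for 55/60/65/70% mineral are reproduced to within 3 atoms. The
integer rounding matters: treating the counts as continuous leaves ~11
atoms of residual no matter the molar masses, because each HA unit moves
a total by 44 atoms at a time.

## Geometry conventions

- Cell matrix `H` is lower-triangular: a along x, b in the xy-plane (the
  crystallographic/VMD/LAMMPS convention); PDB outputs state this in a
  REMARK.
- Fractional wrapping uses the half-open interval `[0, 1)`; ties at 1 map
  to 0, so wrapping is deterministic and idempotent.
- Minimum-image distances are computed by reducing the fractional
  separation to the central cell and then minimizing over the 27
  neighbour images — exact for any pair separation that fits within one
  cell, which covers every use here (bond perception, packing,
  force evaluation).
- Per-molecule wrapping translates each connected component by one
  lattice vector using its unweighted geometric centre; mass weighting
  would change nothing material for placement and costs bookkeeping.

Bond perception (`infer_bonds()`, for structures that arrive without a
topology) uses consensus single-bond covalent radii with a 1.2 scale
factor, forbids H–H bonds, and treats more than 8 bonds on one atom as an
error (a clash indicator), never silently. The image shift of each bond
is recovered from geometry as the shift minimizing the bond length; a
shift is stored on the second atom of the pair (`i < j`).

## The tensile protocol

A box extension at constant engineering strain rate follows
`L_z(t) = L_z0 (ε̇ t + 1)`; 30 ps at ε̇ = 1e-5/fs gives exactly 30%
strain. At every step the atom z-coordinates are remapped affinely with
the box (the fix-deform convention). Stress comes from the virial
pressure tensor

`P_ij = (Σ_k m_k v_ki v_kj) / V + (Σ_pairs r_ij f_ij) / V`

where the configurational part is accumulated per pair over minimum-image
displacements — equivalent to the per-atom sum including ghost-atom
contributions, and correct for interactions that wrap the periodic
boundaries. Units are centralized: kcal/mol/Å³ → 6.9477 GPa (or
68568 atm); kinetic prefactor 1 amu (Å/fs)² = 2390.06 kcal/mol.

The reported uniaxial stress is σ_zz = −P_zz. The sign flip is applied at
the reporting boundary only: mechanical pressure is positive in
compression, while tensile-test moduli are conventionally positive under
tension; without the flip a stretched spring network would report a
negative modulus.

`fit_young_modulus()` is an ordinary least-squares regression (with
intercept) of stress on strain over a window, endpoints inclusive,
defaulting to 1–7% strain — the linear-elastic regime for these models;
below 1% the signal is noise-dominated, above 7% softening begins. The
fit reports the slope's standard error; an optional `block_average()`
preprocessor reduces thermostat noise without biasing the slope.

## The desk-scale engine and what it can show

`minidyn` integrates harmonic bonds plus Lennard-Jones pairs
(Lorentz–Berthelot mixing, energy-shifted at the cutoff so truncation
does not destroy energy conservation) with velocity Verlet or BAOAB
Langevin steps, a cell-list/Verlet-skin neighbour list (skin 2 Å), and a
Berendsen-style lateral barostat — chosen over Nosé–Hoover for
simplicity and unconditional stability at these system sizes. It
deliberately replaces a production force field: there are no
electrostatics, no constraint algorithms, no protein chemistry. Checks
that validate it: exact free-particle motion, harmonic-dimer period to
0.1%, relative NVE drift < 1e-4 over 100 steps of the 64-atom LJ gas at
dt = 2 fs, equipartition under the thermostat, and exact agreement
between its internal pressure and the virial recomputed from dumped
frames.

Consequences: quantitative moduli of real bone models (tens of GPa with
a protein/mineral force field at 3–4.5e5 atoms after ~100 ns
equilibration) are *not* reproducible here, and no desk-scale number
should be read as one. The mechanics layer is nevertheless
production-ready in the sense that it fits externally generated
stress–strain logs through the same `read_series()` →
`fit_young_modulus()` path exercised in the tests.

## Synthetic fixtures and the stiffening experiment

`make_toy_fibril()` generates five bead chains in a triclinic cell
(default 25 × 25 × 60 Å, γ = 105.58°): four span the cell axially and
bond to their own z-image; the fifth occupies only the overlap zone, so
gap cross-sections meet 4 molecules and overlap cross-sections 5 — after
2 × 2 replication, 16 and 20, the architecture signature asserted in the
tests. One chain hugs the x boundary so that per-atom wrapping provably
creates x-crossing bonds; the generator returns the true bond list with
image shifts as machine-checkable ground truth. Beads are carbon-like
pseudo-atoms (residue code `TOY`), 1.5 Å apart so the covalent-radius
heuristic re-derives exactly the generated bonds. What the fixture does
*not* emulate: amino-acid chemistry, the triple helix, crosslinks, and
realistic molecular masses — so a passing pipeline proves the geometry
and bookkeeping, not biochemistry.

The mineral-stiffening experiment (`make_toy_composite()` +
`composite_modulus()`) isolates the structural mechanism by which mineral
stiffens bone: load transfer across the axial discontinuities of the
collagen array. The bare fixture is four chains with staggered two-slot
gaps — no chain is axially continuous, so the bundle alone carries almost
no tensile load (measured E ≈ 0.1 GPa, pure matrix noise). Mineral
particles are packed at the Lennard-Jones contact distance and then
*cemented*: contacts within 4.2 Å become harmonic bonds at their
as-packed lengths, modelling the mineral as a solid phase (crystalline
platelets), not a fluid of free atoms. Two earlier designs failed
instructively and are worth recording: free adhesive mineral particles
either soften the fiber (when packed inside the repulsive core distance,
they depressurize under stretch) or contribute nearly nothing (a
quenched adhesive glass yields plastically within the fit window). The
cemented network carries elastic load across the gaps and raises the
modulus to ~8–12 GPa, mineralized > bare in every seed tested.

The protocol is athermal and quasi-static on purpose — Langevin at 1 K,
friction 0.05/fs, a 1 ps quench, then 10% strain over 5 ps — because at
tissue temperature the thermal stress fluctuations of a ~100-atom model
swamp the composite signal entirely; the comparison is about structure,
not temperature.

## Numerical choices and degenerate inputs

- Packing is rejection sampling with uniform SO(3) rotations from random
  unit quaternions, one derived RNG stream per task (adding a task never
  disturbs earlier placements), tolerance 2.0 Å by default; exhausting
  `max_attempts` is a loud error reporting the achieved count, never a
  silent partial pack. The z boundary is periodic during packing (the
  fiber continues axially); x/y are hard walls of the box. When the
  packed region itself will be simulated with full lateral periodicity,
  inset it by tolerance/2 — placements hugging opposite walls must not
  overlap through them.
- The IFV box derives from the 1st–99th coordinate percentiles of the
  collagen atoms (a visual-box definition is not an algorithm; the
  percentile rule is this package's explicit, overridable choice —
  literal corners can be supplied instead).
- Gap/overlap z-locations are detected as extrema of the molecule-count
  profile along z (`zone_profile()`), not hard-coded.
- PDB serials beyond 99,999 use hybrid-36 encoding; reading preserves
  serials verbatim (renumbering is opt-in at write time). Fixed-column
  parsing failures report the offending line number; an unresolvable
  element is an error, not a guess.
- `build_fiber()` warns when the source cell's c vector is strongly
  tilted: the orthorhombic simulation box then only approximates axial
  periodicity. The synthetic fixtures use α = β = 90° so the
  approximation is exact in tests.
- Problem sizes throughout (40-bead chains, ~150-atom composites, 500
  atom gases, 5-seed comparisons) are the package's chosen desk-scale
  study conditions; they keep every experiment deterministic, seconds-to-
  minutes fast, and statistically unambiguous at the assertions made.

## Known limitations

- The toy force field cannot and does not reproduce force-field-specific
  observables (absolute moduli, equilibration volume contraction).
- HA is packed as formula-unit clusters, not grown as crystalline
  platelets with experimental plate morphology.
- Gap-biased mineral placement inside the IFV is available only as a
  region choice; the default is uniform-in-region.
- Non-collagenous proteins, carbonate-substituted apatites and crosslink
  chemistry are out of scope.
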