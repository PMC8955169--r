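# bonefiber

Tools for building and mechanically testing all-atom models of bone at the
nanoscale, where bone is a *fiber*: a bundle of mineralized collagen
fibrils surrounded by water and hydroxyapatite (HA, Ca10(PO4)6(OH)2) in the
extra-fibrillar volume (EFV). Classical fibril models keep every collagen
molecule covalently continuous through the lateral periodic boundaries, so
there is no room to place mineral *between* fibrils — even though most of
the mineral in cortical bone sits exactly there. This package implements
the modelling route that fixes that:

1. **Fibril → nanofiber.** Starting from a collagen fibril in a triclinic
   unit cell (a = 39.970 Å, b = 26.950 Å, c = 677.900 Å, α = 89.24°,
   β = 94.59°, γ = 105.58° for the canonical type-I fibril crystal), every
   molecule is made whole in x and y by lattice translations, leaving a
   structure periodic only along the fibril axis z
   (`extract_nanofiber()`). The contract is checkable:
   `classify_periodic_bonds()` must report zero x/y-crossing bonds
   afterwards, with z-crossing bonds untouched.
2. **Nanofiber → fiber.** The nanofiber is replicated on its own lattice
   vectors into an `nx × ny` bundle inside an enlarged orthorhombic
   simulation box; the intra-fibrillar volume (IFV) is a parallelepiped
   around the collagen, and EFV = box − IFV (`build_fiber()`).
3. **Fiber → bone fiber.** Target mass fractions (e.g. 55% HA / 35%
   collagen / 10% water) are converted into molecule counts anchored on
   the collagen mass (`solve_counts()`), mineral is split 80/20 between
   EFV and IFV, and a seeded rejection-sampling packer inserts HA formula
   units, waters and ions at a minimum-distance tolerance
   (`pack_structures()`).
4. **Tensile test.** A constant-strain-rate uniaxial extension along z,
   `L_z(t) = L_z0 (ε̇ t + 1)`, with stress from the virial tensor
   `P_ij = (Σ_k m_k v_ki v_kj + Σ_k r_ki f_kj) / V` (tension reported as
   σ_zz = −P_zz) and the Young's modulus `E` as the least-squares slope of
   σ_zz(ε_zz) over the 1–7% strain window (`run_tensile()`,
   `fit_young_modulus()`).

A minimal MD engine (`minidyn`: velocity Verlet, BAOAB Langevin
thermostat, harmonic bonds + Lennard-Jones with a Verlet-skin neighbour
list) makes the whole protocol executable at desk scale on synthetic
fixtures — toy fibrils with a D-period gap/overlap structure and known
periodic bonds (`make_toy_fibril()`), a 44-atom HA template
(`make_mineral_template()`), and gap-fiber composites
(`make_toy_composite()`). It is a toy force field by design: production
moduli require a protein/mineral force field and equilibration far beyond
desk scale, and the package's mechanics layer consumes such externally
generated stress–strain logs through `read_series()`.

## Worked example

```r
library(bonefiber)

tf   <- make_toy_fibril(seed = 1)          # 5-molecule toy fibril, wrapped
nano <- extract_nanofiber(tf$structure)    # periodic along z only
periodic_bond_counts(nano)
#> x y z
#> 0 0 4

fiber <- build_fiber(nano, nx = 2, ny = 2) # 2x2 bundle + IFV/EFV boxes
zp <- zone_profile(fiber)
c(zp$overlap_count, zp$gap_count)
#> [1] 20 16

budget <- solve_counts(composition_spec(55, 35, 10), clg_mass = 35000)
budget
#> molecule budget (total mass 100000 amu):
#>   HA: 55 (EFV 44 / IFV 11)
#>   water: 555
#>   achieved fractions: HA 55.25% CLG 35.00% H2O 10.00%
```

The cross-section counts (20 molecules in an overlap zone, 16 in a gap
zone — gaps lack one molecule in five) and the 44/11 EFV/IFV mineral split
are the structural signatures of the fiber architecture. A tensile test on
a spring-network fiber recovers its closed-form modulus:

```r
fib <- make_spring_fiber()
sch <- strain_schedule(fib$state$cell$c, rate = 2e-5, duration = 5000)
fit <- fit_young_modulus(run_tensile(fib$state, fib$ff, sch, dt = 2))
c(fit$E, fib$E_closed_form)
#> [1] 57.89746 57.89746
```

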