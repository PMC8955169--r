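# Ground-truth fixture generators: toy fibrils with a D-period gap/overlap
# structure and known periodic bonds, a hydroxyapatite formula-unit
# template, rigid water, spring-network fibers with a closed-form modulus,
# and noisy stress-strain series. Every generator returns machine-checkable
# ground truth alongside the structure; the topology and fiber-builder
# tests consume it. Beads are carbon-like pseudo-atoms with the reserved
# residue code "TOY", not real amino acids.

#' Generate a toy collagen fibril with ground truth
#'
#' Builds `molecules` bead chains in a triclinic cell. All but one chain
#' span the full cell along z and bond to their own z image (axial
#' continuity, one z-crossing bond each); the last chain occupies only the
#' overlap zone, so a cross-section of the gap zone meets `molecules - 1`
#' chains and one of the overlap zone meets all of them (the D-period
#' structure: the gap lacks one molecule). Chains wiggle sinusoidally
#' around centres placed so that some stray across the lateral cell
#' boundary; per-atom wrapping (applied before return) therefore creates a
#' known set of x/y-crossing bonds.
#'
#' @param molecules chains per cell (default 5, the microfibril value).
#' @param beads beads per full-length chain (>= 8).
#' @param spacing axial bead spacing, angstrom (default 1.5, bondable by
#'   the covalent-radius heuristic for carbon).
#' @param radius lateral wiggle amplitude, angstrom.
#' @param gap_fraction fraction of the axial period occupied by the gap
#'   zone (default 0.54, the canonical D-period split).
#' @param cell a [triclinic_cell()]; default 25 x 25 x (beads * spacing)
#'   with gamma = 105.58 degrees (a laterally skewed cell).
#' @param seed integer seed for the centre placement jitter and phases.
#' @return a list with `structure` (wrapped, with ground-truth bonds),
#'   `molecule_id` (per atom), `bonds` (the ground-truth bond list with
#'   true image shifts), `n_z_crossing`, `n_xy_crossing`, `gap_range` and
#'   `overlap_range` (z intervals, angstrom).
#' @export
make_toy_fibril <- function(molecules = 5L, beads = 40L, spacing = 1.5,
                            radius = 1.0, gap_fraction = 0.54,
                            cell = NULL, seed = 1L) {
  if (beads < 8) stop("need at least 8 beads per chain")
  if (gap_fraction < 0 || gap_fraction >= 1)
    stop("gap_fraction must lie in [0, 1)")
  lz <- beads * spacing
  if (is.null(cell)) cell <- triclinic_cell(25, 25, lz, 90, 90, 105.58)

  local_seed(seed, {
    # chain centres in fractional xy: most interior, the last full-length
    # chain hugs the x boundary so its wiggle crosses it
    base_frac <- cbind(
      fx = c(0.15, 0.60, 0.15, 0.60, 0.999, 0.38, 0.85, 0.38)[
        seq_len(molecules)],
      fy = c(0.20, 0.20, 0.65, 0.65, 0.45, 0.90, 0.90, 0.42)[
        seq_len(molecules)]
    )
    if (molecules > 8) stop("at most 8 molecules per cell are supported")
    phases <- stats::runif(molecules, 0, 2 * pi)

    gap_len <- gap_fraction * lz
    # integer number of helical turns per period (continuity across the z
    # boundary), one turn per ~20 A so bead-bead links stay covalent-length
    turns <- max(1, round(lz / 20))
    atoms <- list(); bonds <- list(); molid <- list()
    offset <- 0L
    for (mchain in seq_len(molecules)) {
      partial <- mchain == molecules && gap_fraction > 0
      zidx <- if (partial) {
        nb <- max(3L, as.integer(ceiling((lz - gap_len) / spacing)) - 1L)
        seq_len(nb)
      } else seq_len(beads)
      z <- if (partial) gap_len + (zidx - 1L) * spacing
           else (zidx - 1L) * spacing
      ctr <- frac_to_cart(cell, cbind(base_frac[mchain, 1],
                                      base_frac[mchain, 2], 0))
      x <- ctr[1] + radius * cos(2 * pi * z / lz * turns + phases[mchain])
      y <- ctr[2] + radius * sin(2 * pi * z / lz * turns + phases[mchain])
      n <- length(zidx)
      atoms[[mchain]] <- data.frame(
        serial = offset + seq_len(n), name = "CA", element = "C",
        resname = "TOY", resid = mchain, chain = LETTERS[mchain],
        x = x, y = y, z = z, stringsAsFactors = FALSE)
      bb <- cbind(i = offset + seq_len(n - 1), j = offset + seq_len(n - 1) + 1,
                  sx = 0L, sy = 0L, sz = 0L)
      if (!partial)   # axial continuity: last bead bonds the z image of first
        bb <- rbind(bb, cbind(i = offset + n, j = offset + 1L,
                              sx = 0L, sy = 0L, sz = 1L))
      bonds[[mchain]] <- bb
      molid[[mchain]] <- rep(mchain, n)
      offset <- offset + n
    }
    atoms <- do.call(rbind, atoms)
    bonds <- do.call(rbind, bonds)
    # flip orientation of the z-closure bond (i > j): shift moves to j
    s <- mol_structure(atoms, bonds = bonds, cell = cell)

    # ground-truth image shifts from the unwrapped coordinates
    unwrapped_frac <- coords(s) %*% t(cell$hinv)
    wrap_shift <- floor(unwrapped_frac)
    sw <- wrap_structure(s, "atom")
    b <- sw$bonds
    # after wrapping atom k by -wrap_shift[k], a bond (i,j) with original
    # shift s0 needs shift s0 + wrap_shift[j] - wrap_shift[i]
    b[, c("sx", "sy", "sz")] <- b[, c("sx", "sy", "sz")] +
      wrap_shift[b[, "j"], , drop = FALSE] -
      wrap_shift[b[, "i"], , drop = FALSE]
    sw$bonds <- b

    list(structure = sw,
         molecule_id = unlist(molid),
         bonds = b,
         n_z_crossing = sum(b[, "sz"] != 0),
         n_xy_crossing = sum(b[, "sx"] != 0 | b[, "sy"] != 0),
         gap_range = c(0, gap_len),
         overlap_range = c(gap_len, lz))
  })
}

#' Hydroxyapatite formula-unit template
#'
#' A rigid 44-atom Ca10(PO4)6(OH)2 cluster with the correct stoichiometry
#' (10 Ca, 6 P, 26 O, 2 H) and formula mass 1004.62 amu, fitting inside a
#' 10 angstrom sphere. The geometry is an idealized cluster inspired by
#' the apatite unit-cell motif (a = b = 9.417, c = 6.875 angstrom, gamma =
#' 120 degrees): phosphate tetrahedra on a hexagonal ring, calcium in two
#' axial triads plus an equatorial ring, and the two hydroxyls on the
#' pseudo-sixfold axis. It is a packing template, not a relaxed crystal
#' fragment.
#'
#' @return a [mol_structure()] (no cell).
#' @export
make_mineral_template <- function() {
  po4 <- function(center, phase = 0) {
    # P at center, 4 O at tetrahedron vertices, P-O 1.54 A
    tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
      sqrt(3) * 1.54
    rot <- matrix(c(cos(phase), -sin(phase), 0,
                    sin(phase), cos(phase), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    rbind(center, sweep(tet %*% t(rot), 2, center, "+"))
  }
  ringp <- 3.6    # phosphate ring radius
  ang6 <- seq(0, 2 * pi, length.out = 7)[1:6]
  coords <- NULL; elem <- NULL; name <- NULL
  for (k in 1:6) {
    ctr <- c(ringp * cos(ang6[k]), ringp * sin(ang6[k]),
             1.7 * (-1)^k)
    blk <- po4(ctr, phase = ang6[k])
    coords <- rbind(coords, blk)
    elem <- c(elem, "P", rep("O", 4))
    name <- c(name, sprintf("P%d", k), sprintf("O%d%s", k, 1:4))
  }
  # calcium: two axial triads (CaI-like) and an equatorial ring of four
  tri <- seq(0, 2 * pi, length.out = 4)[1:3]
  ca <- rbind(
    cbind(2.0 * cos(tri), 2.0 * sin(tri), 3.3),
    cbind(2.0 * cos(tri + pi / 3), 2.0 * sin(tri + pi / 3), -3.3),
    cbind(5.6 * cos(tri + pi / 6), 5.6 * sin(tri + pi / 6), 0),
    c(5.6, 0, 0))
  coords <- rbind(coords, ca)
  elem <- c(elem, rep("Ca", 10)); name <- c(name, sprintf("CA%d", 1:10))
  # hydroxyls on the axis
  oh <- rbind(c(0, 0, 0.55), c(0, 0, 1.51), c(0, 0, -0.55), c(0, 0, -1.51))
  coords <- rbind(coords, oh)
  elem <- c(elem, "O", "H", "O", "H")
  name <- c(name, "OH1", "HO1", "OH2", "HO2")
  mol_structure(data.frame(
    serial = seq_along(elem), name = name, element = elem,
    resname = "HAP", resid = 1L, chain = "X",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    stringsAsFactors = FALSE))
}

#' Rigid three-site water template
#' @return a [mol_structure()] with one water molecule (O-H 0.9572
#'   angstrom, H-O-H 104.52 degrees).
#' @export
make_water_template <- function() {
  th <- 104.52 / 2 * pi / 180
  mol_structure(data.frame(
    serial = 1:3, name = c("OH2", "H1", "H2"), element = c("O", "H", "H"),
    resname = "TIP3", resid = 1L, chain = "W",
    x = c(0, 0.9572 * sin(th), -0.9572 * sin(th)),
    y = 0, z = c(0, 0.9572 * cos(th), 0.9572 * cos(th)),
    stringsAsFactors = FALSE),
    bonds = cbind(i = c(1, 1), j = c(2, 3)))
}

#' Spring-network fiber with a closed-form Young's modulus
#'
#' `nx * ny` parallel bead chains on a square lattice, each of `beads`
#' beads spanning the box axially and closed through the z boundary, so
#' every chain is a ring of `beads` springs of stiffness `k`. Under
#' uniaxial extension the exact modulus is
#' `E = n_chains * k * L0 / (beads * A)` with `A` the lateral box area.
#'
#' @param nx,ny chains per lateral direction.
#' @param beads beads (= springs) per chain.
#' @param spacing axial bead spacing, angstrom.
#' @param lateral chain-to-chain spacing, angstrom.
#' @param k spring stiffness, kcal/mol/A^2.
#' @param mass bead mass, amu.
#' @return a list with `state` ([sim_state()]), `ff`
#'   ([toy_forcefield()] with bonds only), and `E_closed_form` (GPa).
#' @export
make_spring_fiber <- function(nx = 2L, ny = 2L, beads = 10L, spacing = 3,
                              lateral = 6, k = 100, mass = 12.011) {
  lz <- beads * spacing
  cellv <- triclinic_cell(nx * lateral, ny * lateral, lz)
  pos <- NULL; bonds <- NULL; off <- 0L
  for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
    z <- (seq_len(beads) - 1) * spacing
    pos <- rbind(pos, cbind((ix - 0.5) * lateral, (iy - 0.5) * lateral, z))
    bonds <- rbind(bonds,
                   data.frame(i = off + seq_len(beads),
                              j = off + c(seq_len(beads - 1) + 1, 1),
                              k = k, r0 = spacing))
    off <- off + beads
  }
  n <- nrow(pos)
  area <- (nx * lateral) * (ny * lateral)
  e_gpa <- nx * ny * k * lz / (beads * area) * .KCAL_A3_TO_GPA
  list(state = sim_state(pos, rep(mass, n), cellv),
       ff = toy_forcefield(bonds = bonds, epsilon = 0, cutoff = 2.5,
                           skin = 2.0),
       E_closed_form = e_gpa)
}

#' Gap-fiber: bead chains with staggered axial discontinuities
#'
#' Four bead chains on a 2 x 2 lateral lattice, each missing two
#' consecutive axial slots at a chain-specific (staggered) position - a
#' minimal analogue of the D-period gap structure: no chain is axially
#' continuous, so the bare bundle carries almost no tensile load and the
#' modulus comes from whatever matrix bridges the gaps.
#'
#' @param lateral chain spacing, angstrom.
#' @param beads axial slots per chain (2 of which are vacant).
#' @param spacing axial bead spacing, angstrom.
#' @param k backbone spring stiffness, kcal/mol/A^2.
#' @return a list with `pos` (n x 3), `bonds` (data frame `i, j, k, r0`),
#'   `cell` and `n` (bead count).
#' @export
make_gap_fiber <- function(lateral = 6.0, beads = 10L, spacing = 3,
                           k = 20) {
  slots <- 0:(beads - 1)
  gapsof <- list(c(0, 1), c(5, 6), c(2, 3), c(7, 8))
  lz <- beads * spacing
  cellv <- triclinic_cell(2 * lateral, 2 * lateral, lz)
  pos <- NULL; bonds <- NULL; off <- 0L; cidx <- 0L
  for (ix in 1:2) for (iy in 1:2) {
    cidx <- cidx + 1L
    keep <- setdiff(slots, gapsof[[cidx]] %% beads)
    z <- keep * spacing; n <- length(keep)
    pos <- rbind(pos, cbind((ix - 0.5) * lateral, (iy - 0.5) * lateral, z))
    for (a in seq_len(n)) {
      b <- match((keep[a] + 1L) %% beads, keep)
      if (!is.na(b))
        bonds <- rbind(bonds, data.frame(i = off + a, j = off + b,
                                         k = k, r0 = spacing))
    }
    off <- off + n
  }
  bonds <- bonds[!duplicated(t(apply(bonds[, 1:2], 1, sort))), ]
  list(pos = pos, bonds = bonds, cell = cellv, n = off)
}

#' Mineralized toy composite fiber
#'
#' Packs point-mineral particles around a [make_gap_fiber()] bundle and
#' cements them: every contact pair involving a mineral particle within
#' `r_contact` becomes a harmonic bond at its as-packed length, modelling
#' the mineral as a solid phase (crystalline platelets bridge the chain
#' gaps) rather than a fluid of free particles. With `mineral_count = 0`
#' this is the bare gap-fiber; with mineral, the cemented network carries
#' axial load across the gaps, which is the structural origin of mineral
#' stiffening in these composites.
#'
#' @param mineral_count number of mineral particles (mass 40.08 amu).
#' @param seed integer seed for the packing.
#' @param eps_mineral LJ well depth of mineral particles, kcal/mol.
#' @param tolerance packing minimum distance, angstrom (also sets the
#'   as-packed contact lengths near the LJ minimum).
#' @param k_cement stiffness of cemented contacts, kcal/mol/A^2.
#' @param r_contact cementation radius, angstrom.
#' @return a list with `state` ([sim_state()]), `ff` ([toy_forcefield()])
#'   and `n_beads`, `n_mineral`, `mineral_mass_fraction`.
#' @export
make_toy_composite <- function(mineral_count = 40L, seed = 1L,
                               eps_mineral = 2.5, tolerance = 3.0,
                               k_cement = 30, r_contact = 4.2) {
  gf <- make_gap_fiber()
  pos <- gf$pos; mass <- rep(12.011, gf$n); bonds <- gf$bonds
  eps <- rep(0.1, gf$n); sig <- rep(3.0, gf$n)
  if (mineral_count > 0) {
    atoms <- data.frame(serial = seq_len(gf$n), name = "CA",
                        element = "C", resname = "TOY", resid = 1L,
                        chain = "A", x = pos[, 1], y = pos[, 2],
                        z = pos[, 3], stringsAsFactors = FALSE)
    base <- mol_structure(atoms, cell = gf$cell)
    tmpl <- mol_structure(data.frame(
      serial = 1L, name = "MIN", element = "Ca", resname = "MIN",
      resid = 1L, chain = "M", x = 0, y = 0, z = 0,
      stringsAsFactors = FALSE))
    # inset the region by tolerance/2: dynamics is periodic in x and y,
    # so placements hugging opposite walls must not overlap through them
    inset <- tolerance / 2
    reg <- region_box(c(inset, inset, 0),
                      c(gf$cell$a - inset, gf$cell$b - inset, gf$cell$c),
                      label = "mineral")
    pk <- pack_structures(base,
                          packing_task(tmpl, mineral_count, reg,
                                       tolerance = tolerance,
                                       max_attempts = 20000L),
                          seed = seed)
    pos <- coords(pk)
    mass <- c(mass, rep(40.08, mineral_count))
    eps <- c(eps, rep(eps_mineral, mineral_count))
    sig <- c(sig, rep(3.0, mineral_count))
    prs <- neighbor_pairs(pos, gf$cell, r_contact,
                          periodic = c(TRUE, TRUE, TRUE))
    ismin <- c(rep(FALSE, gf$n), rep(TRUE, mineral_count))
    prs <- prs[ismin[prs$i] | ismin[prs$j], , drop = FALSE]
    if (nrow(prs))
      bonds <- rbind(bonds, data.frame(i = prs$i, j = prs$j,
                                       k = k_cement, r0 = prs$d))
  }
  list(state = sim_state(pos, mass, gf$cell),
       ff = toy_forcefield(bonds = bonds, epsilon = eps, sigma = sig,
                           cutoff = 5.9, skin = 2.0),
       n_beads = gf$n, n_mineral = mineral_count,
       mineral_mass_fraction = mineral_count * 40.08 /
         (mineral_count * 40.08 + gf$n * 12.011))
}

#' Measure the tensile modulus of a toy composite
#'
#' The standard desk-scale protocol: damped thermal quench (Langevin, 1 K,
#' friction 0.05/fs, 1000 steps of 1 fs), then a constant-rate tensile
#' test (2e-5/fs for 5 ps, 10% final strain) and a modulus fit over the
#' 1-7% strain window.
#'
#' @param composite output of [make_toy_composite()].
#' @param seed integer seed for velocities and thermostat noise.
#' @return the fitted modulus in GPa.
#' @export
composite_modulus <- function(composite, seed = 1L) {
  local_seed(seed, {
    st <- run_md(composite$state, composite$ff, nsteps = 1000, dt = 1,
                 temperature = 1, friction = 0.05)
    sched <- strain_schedule(st$cell$c, 2e-5, 5000)
    series <- run_tensile(st, composite$ff, sched, dt = 1,
                          temperature = 1, friction = 0.05)
    fit_young_modulus(series)$E
  })
}

#' Synthetic stress-strain series
#'
#' `sigma = E_true * strain + N(0, noise)` at strains uniform on
#' `[0, 0.3]`.
#'
#' @param e_true true modulus, GPa.
#' @param noise Gaussian stress noise, GPa.
#' @param n number of points.
#' @param seed integer seed.
#' @return a [stress_strain_series()].
#' @export
make_stress_strain <- function(e_true, noise = 0, n = 600, seed = 1L) {
  local_seed(seed, {
    eps <- stats::runif(n, 0, 0.3)
    sig <- e_true * eps + stats::rnorm(n, 0, noise)
    stress_strain_series(eps, sig, label = sprintf("synthetic E=%g", e_true))
  })
}
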