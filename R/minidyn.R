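# A minimal molecular-dynamics engine: velocity-Verlet and BAOAB Langevin
# integration of a toy force field (harmonic bonds + Lennard-Jones pairs
# with a Verlet-skin neighbour list), an affine-remap uniaxial box
# deformation, and a Berendsen-style lateral barostat. Desk-scale by
# design: it executes the full tensile-test protocol on synthetic fibers
# with hundreds of atoms, standing in for a production engine plus a
# protein/mineral force field, which are deliberately out of scope.

#' Construct a toy force field
#'
#' Harmonic bonds `E = k/2 (r - r0)^2` plus Lennard-Jones interactions
#' `E = 4 eps ((sig/r)^12 - (sig/r)^6)` between non-bonded atom pairs with
#' Lorentz-Berthelot mixing. Bonded (1-2) pairs are excluded from LJ.
#'
#' @param bonds data frame with columns `i`, `j`, `k` (kcal/mol/A^2) and
#'   `r0` (angstrom); may be empty.
#' @param epsilon per-atom LJ well depth, kcal/mol (0 disables LJ for that
#'   atom).
#' @param sigma per-atom LJ diameter, angstrom.
#' @param cutoff LJ cutoff, angstrom.
#' @param skin Verlet-list skin, angstrom (default 2.0).
#' @return an object of class `toy_forcefield`.
#' @export
toy_forcefield <- function(bonds = NULL, epsilon = 0, sigma = 3.0,
                           cutoff = 10.0, skin = 2.0) {
  if (is.null(bonds) || NROW(bonds) == 0)
    bonds <- data.frame(i = integer(0), j = integer(0), k = numeric(0),
                        r0 = numeric(0))
  stopifnot(all(c("i", "j", "k", "r0") %in% names(bonds)))
  if (any(bonds$k < 0) || any(bonds$r0 < 0))
    stop("bond parameters must be non-negative")
  if (cutoff <= 0 || skin <= 0) stop("cutoff and skin must be positive")
  structure(list(bonds = bonds, epsilon = epsilon, sigma = sigma,
                 cutoff = cutoff, skin = skin),
            class = "toy_forcefield")
}

#' Construct a simulation state
#'
#' @param positions n x 3 matrix, angstrom.
#' @param mass numeric vector of masses, amu.
#' @param cell a [triclinic_cell()] (periodic in all directions during
#'   dynamics).
#' @param velocities n x 3 matrix, angstrom/fs (zeros when `NULL`).
#' @return an object of class `sim_state`.
#' @export
sim_state <- function(positions, mass, cell, velocities = NULL) {
  positions <- as_coord_matrix(positions)
  n <- nrow(positions)
  stopifnot(length(mass) == n, inherits(cell, "triclinic_cell"))
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  stopifnot(all(is.finite(positions)), all(is.finite(velocities)))
  structure(list(pos = positions, vel = velocities, mass = mass,
                 cell = cell, time = 0, pairlist = NULL),
            class = "sim_state")
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Samples each component from `N(0, kB T / m)` (converted to angstrom/fs)
#' and removes the centre-of-mass drift. Uses the current RNG state.
#'
#' @param state a [sim_state()].
#' @param temperature target temperature, K.
#' @return the state with velocities replaced.
#' @export
init_velocities <- function(state, temperature) {
  n <- nrow(state$pos)
  sd <- sqrt(.KB_KCALMOL * temperature / (state$mass * .MVV_TO_KCALMOL))
  v <- matrix(stats::rnorm(3 * n), n, 3) * sd
  vcm <- colSums(v * state$mass) / sum(state$mass)
  state$vel <- sweep(v, 2, vcm)
  state
}

# ---- neighbour list -------------------------------------------------------

needs_rebuild <- function(state, ff) {
  pl <- state$pairlist
  if (is.null(pl)) return(TRUE)
  disp <- state$pos - pl$ref
  max(abs(disp)) > ff$skin / 2
}

build_pairlist <- function(state, ff) {
  n <- nrow(state$pos)
  lj_active <- rep_len(ff$epsilon, n) > 0
  pairs <- NULL
  if (sum(lj_active) > 1) {
    minwidth <- min(diag(state$cell$h))
    cand <- neighbor_pairs(state$pos, state$cell,
                           min(ff$cutoff + ff$skin, minwidth / 2 - 1e-9))
    if (nrow(cand)) {
      keep <- lj_active[cand$i] & lj_active[cand$j]
      # exclude 1-2 bonded pairs
      if (nrow(ff$bonds)) {
        bkey <- paste(pmin(ff$bonds$i, ff$bonds$j),
                      pmax(ff$bonds$i, ff$bonds$j))
        keep <- keep & !(paste(cand$i, cand$j) %in% bkey)
      }
      pairs <- cand[keep, c("i", "j"), drop = FALSE]
    }
  }
  state$pairlist <- list(pairs = pairs, ref = state$pos)
  state
}

# scatter-add pair forces (acting on j; minus on i) into per-atom forces
accumulate_pairs <- function(n, i, j, fj) {
  out <- matrix(0, n, 3)
  s <- rowsum(rbind(fj, -fj), group = c(j, i))
  out[as.integer(rownames(s)), ] <- s
  out
}

#' Evaluate forces, energy and the pair virial
#'
#' @param state a [sim_state()].
#' @param ff a [toy_forcefield()].
#' @return a list with `forces` (n x 3, kcal/mol/A), `energy` (kcal/mol),
#'   `virial` (3 x 3 pair-sum `sum r_ij f_ij^T`, kcal/mol), and the
#'   possibly rebuilt `state`.
#' @export
evaluate_forces <- function(state, ff) {
  if (needs_rebuild(state, ff)) state <- build_pairlist(state, ff)
  n <- nrow(state$pos)
  forces <- matrix(0, n, 3)
  virial <- matrix(0, 3, 3)
  energy <- 0

  b <- ff$bonds
  if (nrow(b)) {
    d <- min_image_vector(state$cell, state$pos[b$i, , drop = FALSE],
                          state$pos[b$j, , drop = FALSE])
    r <- sqrt(rowSums(d^2))
    stretch <- r - b$r0
    energy <- energy + sum(0.5 * b$k * stretch^2)
    fmag <- -b$k * stretch / r            # >0 pushes j outward
    fj <- d * fmag
    forces <- forces + accumulate_pairs(n, b$i, b$j, fj)
    virial <- virial + crossprod(d, fj)
  }

  pl <- state$pairlist$pairs
  if (!is.null(pl) && nrow(pl)) {
    d <- min_image_vector(state$cell, state$pos[pl$i, , drop = FALSE],
                          state$pos[pl$j, , drop = FALSE])
    r2 <- rowSums(d^2)
    within <- r2 <= ff$cutoff^2
    if (any(within)) {
      i <- pl$i[within]; j <- pl$j[within]
      d <- d[within, , drop = FALSE]; r2 <- r2[within]
      eps <- sqrt(rep_len(ff$epsilon, n)[i] * rep_len(ff$epsilon, n)[j])
      sig <- (rep_len(ff$sigma, n)[i] + rep_len(ff$sigma, n)[j]) / 2
      sr6 <- (sig^2 / r2)^3
      src6 <- (sig^2 / ff$cutoff^2)^3   # energy-shift at the cutoff so the
      energy <- energy +                # truncated potential is continuous
        sum(4 * eps * (sr6^2 - sr6) - 4 * eps * (src6^2 - src6))
      fmag <- 24 * eps * (2 * sr6^2 - sr6) / r2  # >0 repulsive
      fj <- d * fmag
      forces <- forces + accumulate_pairs(n, i, j, fj)
      virial <- virial + crossprod(d, fj)
    }
  }
  list(forces = forces, energy = energy, virial = virial, state = state)
}

# instantaneous pressure tensor (GPa) from a force evaluation
state_pressure <- function(state, ev, units = "GPa") {
  virial_pressure(state$mass, state$vel, cell_volume(state$cell),
                  pair_r = NULL, pair_f = NULL, units = units) +
    ev$virial / cell_volume(state$cell) *
      switch(units, GPa = .KCAL_A3_TO_GPA, atm = .KCAL_A3_TO_ATM)
}

# ---- integrators ----------------------------------------------------------

#' One velocity-Verlet (NVE) step
#'
#' @param state a [sim_state()].
#' @param ff a [toy_forcefield()].
#' @param dt time step, fs.
#' @return the advanced state (cached forces updated).
#' @export
step_nve <- function(state, ff, dt) {
  step_langevin(state, ff, dt, temperature = 0, friction = 0)
}

#' One BAOAB Langevin step
#'
#' With `friction = 0` the noise and drag vanish and the update reduces to
#' velocity Verlet. Uses the current RNG state for the noise.
#'
#' @inheritParams step_nve
#' @param temperature target temperature, K.
#' @param friction Langevin friction, 1/fs.
#' @return the advanced state.
#' @export
step_langevin <- function(state, ff, dt, temperature = 310,
                          friction = 0.01) {
  if (dt <= 0) stop("time step must be positive")
  if (is.null(state$forces)) {
    ev <- evaluate_forces(state, ff)
    state <- ev$state; state$forces <- ev$forces; state$virial <- ev$virial
    state$energy <- ev$energy
  }
  inv_m <- .FORCE_TO_ACC / state$mass
  v <- state$vel + 0.5 * dt * state$forces * inv_m
  x <- state$pos + 0.5 * dt * v
  if (friction > 0) {
    c1 <- exp(-friction * dt)
    sd <- sqrt(.KB_KCALMOL * temperature * (1 - c1^2) /
                 (state$mass * .MVV_TO_KCALMOL))
    v <- c1 * v + matrix(stats::rnorm(length(v)), nrow(v), 3) * sd
  }
  x <- x + 0.5 * dt * v
  if (max(abs(x - state$pos)) > ff$skin)
    stop("atom displacement exceeded the neighbour skin in one step (blow-up guard)")
  state$pos <- x
  ev <- evaluate_forces(state, ff)
  state <- ev$state
  state$vel <- v + 0.5 * dt * ev$forces * inv_m
  state$forces <- ev$forces
  state$virial <- ev$virial
  state$energy <- ev$energy
  state$time <- state$time + dt
  state
}

#' Run constant-cell dynamics
#'
#' @inheritParams step_langevin
#' @param nsteps number of steps.
#' @param temperature `NULL` for NVE, else Langevin target temperature.
#' @param thermo_every record temperature/pressure/energy every this many
#'   steps (0 disables).
#' @return the final state; the thermo table (data frame with `step`,
#'   `time`, `temperature`, `pressure_xx/yy/zz`, `energy`) is attached as
#'   attribute `"thermo"`.
#' @export
run_md <- function(state, ff, nsteps, dt, temperature = NULL,
                   friction = 0.01, thermo_every = 0) {
  rows <- list()
  for (s in seq_len(nsteps)) {
    state <- if (is.null(temperature)) step_nve(state, ff, dt)
             else step_langevin(state, ff, dt, temperature, friction)
    if (thermo_every > 0 && s %% thermo_every == 0) {
      p <- state_pressure(state, list(virial = state$virial))
      rows[[length(rows) + 1]] <- data.frame(
        step = s, time = state$time,
        temperature = kinetic_temperature(state$mass, state$vel),
        pressure_xx = p[1, 1], pressure_yy = p[2, 2], pressure_zz = p[3, 3],
        energy = state$energy +
          0.5 * sum(state$mass * rowSums(state$vel^2)) * .MVV_TO_KCALMOL)
    }
  }
  attr(state, "thermo") <- if (length(rows)) do.call(rbind, rows) else NULL
  state
}

#' Run a uniaxial tensile test
#'
#' Deforms the box along z following the strain schedule (affine remap of
#' the atom z coordinates at every step), integrates with NVE or Langevin
#' dynamics, and records the engineering strain and the reported stress
#' `sigma_zz = -P_zz` (interval-averaged, GPa) every `output_every` steps.
#' With the lateral barostat on, the x and y box lengths are relaxed
#' towards the target pressure by Berendsen-style rescaling.
#'
#' @param state an equilibrated [sim_state()] with an orthorhombic cell.
#' @param ff a [toy_forcefield()].
#' @param schedule a [strain_schedule()]; its `l0` must match the cell.
#' @param dt time step, fs.
#' @param temperature `NULL` for NVE, else Langevin target.
#' @param friction Langevin friction, 1/fs.
#' @param lateral_barostat couple x and y to `p_target`?
#' @param p_target lateral target pressure, atm (default 1).
#' @param tau_p barostat relaxation time, fs.
#' @param output_every record every this many steps.
#' @return a [stress_strain_series()]; the final state is attached as
#'   attribute `"state"`.
#' @export
run_tensile <- function(state, ff, schedule, dt, temperature = NULL,
                        friction = 0.01, lateral_barostat = FALSE,
                        p_target = 1, tau_p = 5000, output_every = 20) {
  cellp <- state$cell
  if (abs(cellp$alpha - 90) > 1e-6 || abs(cellp$beta - 90) > 1e-6 ||
      abs(cellp$gamma - 90) > 1e-6)
    stop("run_tensile() requires an orthorhombic cell")
  if (abs(schedule$l0 - cellp$c) > 1e-6 * schedule$l0)
    stop("schedule l0 does not match the cell z length")
  nsteps <- max(1L, as.integer(round(schedule$duration / dt)))

  strains <- numeric(0); stresses <- numeric(0)
  acc_p <- 0; acc_n <- 0
  for (s in seq_len(nsteps)) {
    tnow <- s * dt
    lz_new <- box_length(schedule, min(tnow, schedule$duration))
    scale_z <- lz_new / state$cell$c
    state$pos[, 3] <- state$pos[, 3] * scale_z
    state$cell <- triclinic_cell(state$cell$a, state$cell$b, lz_new)

    state <- if (is.null(temperature)) step_nve(state, ff, dt)
             else step_langevin(state, ff, dt, temperature, friction)

    p <- state_pressure(state, list(virial = state$virial))
    acc_p <- acc_p + p[3, 3]; acc_n <- acc_n + 1

    if (lateral_barostat) {
      p_atm <- p / .KCAL_A3_TO_GPA * .KCAL_A3_TO_ATM
      mu <- (1 + dt / tau_p * c(p_atm[1, 1] - p_target,
                                p_atm[2, 2] - p_target) * 1e-4)^(1 / 3)
      mu <- pmin(pmax(mu, 0.9995), 1.0005)
      state$pos[, 1] <- state$pos[, 1] * mu[1]
      state$pos[, 2] <- state$pos[, 2] * mu[2]
      state$cell <- triclinic_cell(state$cell$a * mu[1],
                                   state$cell$b * mu[2], state$cell$c)
    }

    if (s %% output_every == 0 || s == nsteps) {
      strains <- c(strains, engineering_strain(lz_new, schedule$l0))
      stresses <- c(stresses, -acc_p / acc_n)
      acc_p <- 0; acc_n <- 0
    }
  }
  out <- stress_strain_series(strains, stresses)
  attr(out, "state") <- state
  out
}
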