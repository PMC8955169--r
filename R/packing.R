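# Seeded rejection-sampling packer: insert rigid template molecules
# (hydroxyapatite formula units, waters, ions) into region boxes under a
# minimum-distance constraint, in the spirit of Packmol's region-restricted
# packing. The z boundary is treated as periodic (the fiber continues
# axially); x and y boundaries are hard walls of the simulation box.

#' Define a packing task
#'
#' @param template a [mol_structure()] holding one rigid molecule (any
#'   position; it is recentred on its geometric centre).
#' @param count number of copies to place (>= 0).
#' @param region a [region_box()] in which molecule centres must lie.
#' @param exclusion optional [region_box()]; centres must fall outside it
#'   (e.g. region = simulation box with the IFV excluded packs the EFV).
#' @param tolerance minimum inter-molecular atom-pair distance, angstrom
#'   (default 2.0, the Packmol convention).
#' @param max_attempts placement attempts per molecule before giving up.
#' @return an object of class `packing_task`.
#' @export
packing_task <- function(template, count, region, exclusion = NULL,
                         tolerance = 2.0, max_attempts = 2000L) {
  stopifnot(inherits(template, "mol_structure"),
            inherits(region, "region_box"))
  if (tolerance <= 0) stop("tolerance must be positive")
  if (count < 0) stop("count must be >= 0")
  structure(list(template = template, count = as.integer(count),
                 region = region, exclusion = exclusion,
                 tolerance = tolerance,
                 max_attempts = as.integer(max_attempts)),
            class = "packing_task")
}

# uniform random rotation matrix from a unit quaternion
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Pack template molecules into regions around a base structure
#'
#' Processes the tasks in order. Each copy receives a uniform random
#' rotation (random unit quaternion) and a uniform random centre inside
#' `region` (minus `exclusion`), and is accepted iff every atom is at least
#' `tolerance` away from every previously present atom (minimum image
#' along z; x/y are hard walls). Placement is reproducible from the seed;
#' each task consumes its own derived RNG stream, so adding a task does
#' not disturb the placements of the preceding ones.
#'
#' @param base a [mol_structure()] whose atoms are never moved; its cell
#'   defines the simulation box for z periodicity.
#' @param tasks a list of [packing_task()] objects (or a single one).
#' @param seed integer seed controlling all randomness.
#' @return the base structure with all placed copies appended (bond lists
#'   of templates are carried along, re-indexed).
#' @export
pack_structures <- function(base, tasks, seed = 1L) {
  if (inherits(tasks, "packing_task")) tasks <- list(tasks)
  stopifnot(inherits(base, "mol_structure"))
  cell <- base$cell
  if (is.null(cell)) stop("pack_structures() requires the base to have a cell")
  periodic <- c(FALSE, FALSE, TRUE)

  maxtol <- max(vapply(tasks, function(t) t$tolerance, numeric(1)))
  # grid cutoff must cover tolerance plus the largest template radius so a
  # single centre query sees every atom that could clash
  out <- base
  result_atoms <- list(base$atoms)
  result_bonds <- list(base$bonds)
  nplaced_atoms <- natoms(base)

  for (ti in seq_along(tasks)) {
    task <- tasks[[ti]]
    if (task$count == 0) next
    tmpl <- task$template
    txyz <- coords(tmpl)
    txyz <- sweep(txyz, 2, colMeans(txyz))       # centre template
    trad <- sqrt(max(rowSums(txyz^2)))
    cutoff <- task$tolerance + 2 * trad + 1e-9

    allxyz <- do.call(rbind, lapply(result_atoms, function(a)
      as.matrix(a[, c("x", "y", "z")])))
    grid <- neighbor_grid(allxyz, cutoff, cell = cell, periodic = periodic)

    local_seed(seed + 7919L * ti, {
      for (m in seq_len(task$count)) {
        placed <- FALSE
        for (att in seq_len(task$max_attempts)) {
          ctr <- task$region$lower +
            stats::runif(3) * (task$region$upper - task$region$lower)
          if (!is.null(task$exclusion) && in_region(task$exclusion, ctr))
            next
          cand <- txyz %*% t(random_rotation())
          cand <- sweep(cand, 2, ctr, "+")
          ok <- TRUE
          for (a in seq_len(nrow(cand))) {
            hits <- grid_query(grid, cand[a, ], cutoff)
            if (length(hits)) {
              d <- min_image_distance(cell, matrix(cand[a, ], 1),
                                      grid$coords[hits, , drop = FALSE],
                                      periodic = periodic)
              if (any(d < task$tolerance)) { ok <- FALSE; break }
            }
          }
          if (!ok) next
          newatoms <- tmpl$atoms
          newatoms$x <- cand[, 1]; newatoms$y <- cand[, 2]
          newatoms$z <- cand[, 3]
          result_atoms[[length(result_atoms) + 1L]] <- newatoms
          b <- tmpl$bonds
          if (!is.null(b) && nrow(b) > 0) {
            b[, "i"] <- b[, "i"] + nplaced_atoms
            b[, "j"] <- b[, "j"] + nplaced_atoms
            result_bonds[[length(result_bonds) + 1L]] <- b
          }
          nplaced_atoms <- nplaced_atoms + nrow(newatoms)
          grid_insert(grid, cand)
          placed <- TRUE
          break
        }
        if (!placed) {
          stop(sprintf(
            "packing task %d ('%s'): placed %d of %d copies before exhausting %d attempts; region too dense",
            ti, task$region$label, m - 1L, task$count, task$max_attempts))
        }
      }
    })
  }

  atoms <- do.call(rbind, result_atoms)
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  mol_structure(atoms, bonds = do.call(rbind, result_bonds), cell = cell)
}

# run code under a temporary RNG state; restores the caller's state
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  code
}
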