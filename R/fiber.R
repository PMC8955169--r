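# From fibril unit cell to fiber model: unwrap molecules laterally so the
# structure is periodic only along z (the fibril axis), replicate it into a
# bundle, and define the intra-fibrillar volume (IFV) inside an enlarged
# orthorhombic simulation box. The extra-fibrillar volume (EFV) is the
# simulation box minus the IFV.

#' Construct an axis-aligned region box
#'
#' @param lower,upper cartesian corners (3-vectors, angstrom), `upper >
#'   lower` componentwise.
#' @param label region label, e.g. `"IFV"` or `"SIMBOX"`.
#' @return an object of class `region_box`.
#' @export
region_box <- function(lower, upper, label = "region") {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  stopifnot(length(lower) == 3, length(upper) == 3)
  if (any(upper <= lower)) stop("region upper corner must exceed lower")
  structure(list(lower = lower, upper = upper, label = label),
            class = "region_box")
}

#' @export
print.region_box <- function(x, ...) {
  cat(sprintf("region '%s': [%.1f, %.1f] x [%.1f, %.1f] x [%.1f, %.1f] A (%.0f A^3)\n",
              x$label, x$lower[1], x$upper[1], x$lower[2], x$upper[2],
              x$lower[3], x$upper[3], region_volume(x)))
  invisible(x)
}

#' Region volume
#' @param box a [region_box()].
#' @export
region_volume <- function(box) prod(box$upper - box$lower)

#' Point-in-region test
#' @param box a [region_box()].
#' @param points 3-vector or n x 3 matrix.
#' @return logical vector.
#' @export
in_region <- function(box, points) {
  p <- as_coord_matrix(points)
  p[, 1] >= box$lower[1] & p[, 1] <= box$upper[1] &
    p[, 2] >= box$lower[2] & p[, 2] <= box$upper[2] &
    p[, 3] >= box$lower[3] & p[, 3] <= box$upper[3]
}

#' Unwrap a fibril into a nanofiber periodic only along z
#'
#' Every molecule is made whole in x and y by translating atoms by lattice
#' vectors; z image shifts are retained, so axial continuity across the z
#' boundary is preserved. After extraction,
#' [classify_periodic_bonds()] reports zero x/y-crossing bonds while
#' z-crossing bonds are unchanged; atom count, bond count and all bond
#' lengths are preserved (atoms move only by rigid lattice translations).
#'
#' @param fibril a [mol_structure()] with cell and bonds.
#' @return the unwrapped structure.
#' @export
extract_nanofiber <- function(fibril) {
  if (is.null(fibril$cell)) stop("extract_nanofiber() requires a cell")
  if (is.null(fibril$bonds) || nrow(fibril$bonds) == 0)
    stop("extract_nanofiber() requires bonds")
  cell <- fibril$cell
  b <- classify_bond_shifts(fibril)
  n <- natoms(fibril)

  # breadth-first assignment of per-atom lattice offsets in x and y
  adj_i <- c(b[, "i"], b[, "j"])
  adj_j <- c(b[, "j"], b[, "i"])
  adj_s <- rbind(b[, c("sx", "sy"), drop = FALSE],
                 -b[, c("sx", "sy"), drop = FALSE])
  ord <- order(adj_i)
  adj_i <- adj_i[ord]; adj_j <- adj_j[ord]
  adj_s <- adj_s[ord, , drop = FALSE]
  starts <- c(match(seq_len(n), adj_i), length(adj_i) + 1L)
  starts <- cummin_na(starts)

  off <- matrix(NA_integer_, n, 2)
  mol <- molecule_index(fibril)
  for (root in seq_len(n)) {
    if (!is.na(off[root, 1])) next
    off[root, ] <- c(0L, 0L)
    queue <- root
    while (length(queue)) {
      a <- queue[[1]]; queue <- queue[-1]
      lo <- starts[a]; hi <- starts[a + 1L] - 1L
      if (hi < lo) next
      for (e in lo:hi) {
        jn <- adj_j[e]
        cand <- off[a, ] + adj_s[e, ]
        if (is.na(off[jn, 1])) {
          off[jn, ] <- cand
          queue <- c(queue, jn)
        } else if (any(off[jn, ] != cand)) {
          stop(sprintf(
            "molecule %d winds irreducibly around a lateral boundary and cannot be made x/y-contiguous",
            mol[a]))
        }
      }
    }
  }

  xyz <- coords(fibril) + cbind(off, 0L) %*% t(cell$h)
  # per-molecule lateral recentring: put each molecule's geometric centre
  # into [0,1) fractionally in x and y
  frac <- xyz %*% t(cell$hinv)
  ctr <- rowsum(frac, mol) / as.vector(table(mol))
  shift <- -floor(ctr)
  shift[, 3] <- 0
  xyz <- xyz + shift[mol, , drop = FALSE] %*% t(cell$h)

  out <- fibril
  coords(out) <- xyz
  out$bonds <- classify_bond_shifts(out)
  out
}

cummin_na <- function(starts) {
  # fill NA entries of match() (atoms without outgoing adjacency rows)
  # with the following defined value so lo > hi for them
  for (k in rev(seq_along(starts))) {
    if (is.na(starts[k])) starts[k] <- starts[k + 1L]
  }
  starts
}

#' Build a fiber model from a nanofiber
#'
#' Places `nx * ny` lateral copies of the nanofiber on the crystal lattice
#' vectors (preserving the quasi-hexagonal packing of the fibril), then
#' defines an orthorhombic simulation box around the bundle, expanded by
#' `margins` in x and y; the z length equals the z extent of the (scaled)
#' cell so axial periodicity is preserved. The IFV is the axis-aligned
#' bounding box of the collagen atoms after trimming coordinate outliers to
#' the `percentile` range, or explicit corners via `ifv_override`.
#'
#' @param nanofiber output of [extract_nanofiber()].
#' @param nx,ny lateral replication counts (>= 1).
#' @param margins numeric vector of x and y margins in angstrom (> 0); a
#'   third element, if given, is ignored (z stays periodic).
#' @param percentile two-sided coordinate percentile for the IFV bounding
#'   box (default `c(0.01, 0.99)`).
#' @param ifv_override optional [region_box()] taken verbatim as the IFV.
#' @return an object of class `fiber_model`: list with `structure`
#'   (cell set to the orthorhombic simulation box), `ifv`, `simbox` and
#'   `provenance` (the build recipe echo).
#' @export
build_fiber <- function(nanofiber, nx = 2L, ny = 2L, margins = c(14, 28),
                        percentile = c(0.01, 0.99), ifv_override = NULL) {
  if (any(margins[1:2] <= 0))
    stop("margins must be positive (no extra-fibrillar volume otherwise)")
  if (nx < 1 || ny < 1) stop("nx and ny must be >= 1")
  cell <- nanofiber$cell
  if (abs(cell$h[1, 3]) > 0.15 * cell$h[3, 3] ||
      abs(cell$h[2, 3]) > 0.15 * cell$h[3, 3])
    warning("c vector is strongly tilted; the orthorhombic simulation box only approximates z periodicity")

  rep_s <- replicate_structure(nanofiber, nx, ny, 1L)
  xyz <- coords(rep_s)
  lz <- rep_s$cell$h[3, 3]

  lo <- apply(xyz[, 1:2, drop = FALSE], 2, min) - margins[1:2]
  hi <- apply(xyz[, 1:2, drop = FALSE], 2, max) + margins[1:2]
  simbox <- region_box(c(lo[1], lo[2], 0), c(hi[1], hi[2], lz),
                       label = "SIMBOX")

  if (is.null(ifv_override)) {
    qs <- apply(xyz, 2, stats::quantile, probs = percentile, names = FALSE)
    ifv <- region_box(c(qs[1, 1], qs[1, 2], 0), c(qs[2, 1], qs[2, 2], lz),
                      label = "IFV")
  } else {
    ifv <- ifv_override; ifv$label <- "IFV"
  }
  if (any(ifv$lower < simbox$lower) || any(ifv$upper > simbox$upper))
    stop("IFV must lie inside the simulation box")

  simcell <- ortho_cell(simbox$upper - simbox$lower)
  out <- rep_s
  # shift coordinates so the simulation box starts at the origin
  coords(out) <- sweep(xyz, 2, simbox$lower)
  ifv <- region_box(ifv$lower - simbox$lower, ifv$upper - simbox$lower,
                    "IFV")
  simbox <- region_box(c(0, 0, 0), simbox$upper - simbox$lower, "SIMBOX")
  out$cell <- simcell

  structure(list(
    structure = out, ifv = ifv, simbox = simbox,
    provenance = list(nx = nx, ny = ny, margins = margins[1:2],
                      percentile = percentile,
                      ifv_override = !is.null(ifv_override),
                      source_cell = cell[c("a", "b", "c", "alpha", "beta",
                                           "gamma")])
  ), class = "fiber_model")
}

#' @export
print.fiber_model <- function(x, ...) {
  cat("fiber_model\n")
  print(x$simbox); print(x$ifv)
  cat(sprintf("  EFV volume: %.0f A^3\n",
              region_volume(x$simbox) - region_volume(x$ifv)))
  print(x$structure)
  invisible(x)
}

#' Count distinct molecules crossing a z slab
#'
#' Number of molecules with at least one atom within `z +/- delta`.
#'
#' @param model a `fiber_model` or a [mol_structure()] with bonds.
#' @param z slab centre, angstrom.
#' @param delta slab half-width, angstrom (default 2.5).
#' @return integer count (0 with a warning when the slab is empty).
#' @export
cross_section_count <- function(model, z, delta = 2.5) {
  s <- if (inherits(model, "fiber_model")) model$structure else model
  zc <- coords(s)[, 3]
  inslab <- abs(zc - z) <= delta
  if (!any(inslab)) {
    warning(sprintf("no atoms in slab z = %.1f +/- %.1f A", z, delta))
    return(0L)
  }
  length(unique(molecule_index(s)[inslab]))
}

#' Molecule-count profile along z and gap/overlap detection
#'
#' Evaluates [cross_section_count()] on a regular grid of z positions and
#' reports the locations of the minimum (gap zone) and maximum (overlap
#' zone) of the profile. Zones are detected from the data, not hard-coded:
#' the D-period structure guarantees the gap slab crosses fewer molecules.
#'
#' @param model a `fiber_model` or [mol_structure()].
#' @param nz number of slab positions (default 50).
#' @param delta slab half-width, angstrom.
#' @return a list with `profile` (data frame `z`, `count`), `gap_z`,
#'   `overlap_z`, `gap_count`, `overlap_count`.
#' @export
zone_profile <- function(model, nz = 50L, delta = 2.5) {
  s <- if (inherits(model, "fiber_model")) model$structure else model
  zc <- coords(s)[, 3]
  mol <- molecule_index(s)
  zs <- seq(min(zc) + delta, max(zc) - delta, length.out = nz)
  counts <- vapply(zs, function(z)
    length(unique(mol[abs(zc - z) <= delta])), integer(1))
  list(profile = data.frame(z = zs, count = counts),
       gap_z = zs[which.min(counts)], overlap_z = zs[which.max(counts)],
       gap_count = min(counts), overlap_count = max(counts))
}
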