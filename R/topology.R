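# Bond perception, molecule identification and periodic-bond
# classification. Bond perception uses the standard covalent-radius
# distance heuristic (force-field topologies, when available, should be
# preferred; perception exists for structures that ship without one).

# ---- neighbour grid -------------------------------------------------------

#' Build a neighbour grid over a structure
#'
#' Cell-list spatial index supporting fixed-radius queries in expected O(1)
#' per atom. Bins are at least `cutoff` wide along each (perpendicular)
#' cell direction; when the cell is too small for 3 bins on an axis the
#' query degrades gracefully towards all-pairs and stays exact.
#'
#' @param structure a [mol_structure()], or an n x 3 coordinate matrix.
#' @param cutoff query radius, angstrom (> 0).
#' @param cell a [triclinic_cell()]; taken from the structure when omitted.
#'   When `NULL`, a padded bounding box with non-periodic axes is used.
#' @param periodic logical 3-vector marking periodic axes.
#' @return a grid handle (environment) for [grid_query()] and
#'   [grid_insert()].
#' @export
neighbor_grid <- function(structure, cutoff, cell = NULL,
                          periodic = c(TRUE, TRUE, TRUE)) {
  if (cutoff <= 0) stop("cutoff must be positive")
  xyz <- if (inherits(structure, "mol_structure")) coords(structure)
         else as_coord_matrix(structure)
  if (is.null(cell) && inherits(structure, "mol_structure"))
    cell <- structure$cell
  if (is.null(cell)) {
    lo <- if (nrow(xyz)) apply(xyz, 2, min) - cutoff else c(0, 0, 0)
    hi <- if (nrow(xyz)) apply(xyz, 2, max) + cutoff else c(1, 1, 1)
    span <- pmax(hi - lo, 2 * cutoff)
    cell <- triclinic_cell(span[1], span[2], span[3])
    origin <- lo
    periodic <- c(FALSE, FALSE, FALSE)
  } else origin <- c(0, 0, 0)

  # perpendicular widths of the cell along each lattice direction
  h <- cell$h
  vol <- det(h)
  widths <- c(vol / norm2(cross3(h[, 2], h[, 3])),
              vol / norm2(cross3(h[, 3], h[, 1])),
              vol / norm2(cross3(h[, 1], h[, 2])))
  nb <- pmax(1L, pmin(64L, as.integer(floor(widths / cutoff))))

  g <- new.env(parent = emptyenv())
  g$cell <- cell; g$origin <- origin; g$periodic <- periodic
  g$cutoff <- cutoff; g$nb <- nb
  g$coords <- xyz
  g$binof <- grid_bin_index(g, xyz)
  g$bins <- split(seq_len(nrow(xyz)), g$binof)
  g
}

norm2 <- function(v) sqrt(sum(v^2))
cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                           u[3] * v[1] - u[1] * v[3],
                           u[1] * v[2] - u[2] * v[1])

grid_frac <- function(g, xyz) {
  f <- sweep(as_coord_matrix(xyz), 2, g$origin) %*% t(g$cell$hinv)
  for (k in 1:3) {
    if (g$periodic[k]) f[, k] <- f[, k] - floor(f[, k])
    else f[, k] <- pmin(pmax(f[, k], 0), 1 - 1e-12)
  }
  f
}

grid_bin_index <- function(g, xyz) {
  f <- grid_frac(g, xyz)
  if (nrow(f) == 0) return(integer(0))
  ijk <- vapply(1:3, function(k) pmin(g$nb[k] - 1L,
                                      as.integer(floor(f[, k] * g$nb[k]))),
                integer(nrow(f)))
  ijk <- matrix(ijk, ncol = 3)
  ijk[, 1] + g$nb[1] * (ijk[, 2] + g$nb[2] * ijk[, 3]) + 1L
}

grid_neighbor_bins <- function(g, bin1) {
  nb <- g$nb
  b0 <- bin1 - 1L
  i <- b0 %% nb[1]; j <- (b0 %/% nb[1]) %% nb[2]; k <- b0 %/% (nb[1] * nb[2])
  out <- integer(0)
  for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
    ii <- i + di; jj <- j + dj; kk <- k + dk
    if (g$periodic[1]) ii <- ii %% nb[1] else
      if (ii < 0 || ii >= nb[1]) next
    if (g$periodic[2]) jj <- jj %% nb[2] else
      if (jj < 0 || jj >= nb[2]) next
    if (g$periodic[3]) kk <- kk %% nb[3] else
      if (kk < 0 || kk >= nb[3]) next
    out <- c(out, ii + nb[1] * (jj + nb[2] * kk) + 1L)
  }
  unique(out)
}

#' Query a neighbour grid
#'
#' @param grid a [neighbor_grid()] handle.
#' @param p a cartesian position (3-vector).
#' @param cutoff query radius; defaults to the grid's build cutoff (must
#'   not exceed it).
#' @return integer indices of all stored atoms within `cutoff` of `p`
#'   (minimum image on periodic axes) - identical to brute force.
#' @export
grid_query <- function(grid, p, cutoff = grid$cutoff) {
  if (cutoff > grid$cutoff + 1e-12)
    stop("query cutoff exceeds the grid build cutoff")
  if (nrow(grid$coords) == 0) return(integer(0))
  cand <- unlist(grid$bins[as.character(
    grid_neighbor_bins(grid, grid_bin_index(grid, matrix(p, 1))))],
    use.names = FALSE)
  if (!length(cand)) return(integer(0))
  d <- min_image_distance(grid$cell, matrix(p, 1),
                          grid$coords[cand, , drop = FALSE],
                          periodic = grid$periodic)
  sort(cand[d <= cutoff])
}

#' Insert atoms into an existing neighbour grid
#' @param grid a [neighbor_grid()] handle.
#' @param xyz an n x 3 matrix of new positions.
#' @return the grid handle, invisibly (the grid is mutated in place).
#' @export
grid_insert <- function(grid, xyz) {
  xyz <- as_coord_matrix(xyz)
  idx <- nrow(grid$coords) + seq_len(nrow(xyz))
  grid$coords <- rbind(grid$coords, xyz)
  newbins <- grid_bin_index(grid, xyz)
  for (k in seq_along(idx)) {
    key <- as.character(newbins[k])
    grid$bins[[key]] <- c(grid$bins[[key]], idx[k])
  }
  grid$binof <- c(grid$binof, newbins)
  invisible(grid)
}

# all pairs within cutoff; returns data.frame(i, j, d) with i < j
neighbor_pairs <- function(xyz, cell, cutoff, periodic = c(TRUE, TRUE, TRUE)) {
  g <- neighbor_grid(xyz, cutoff, cell = cell, periodic = periodic)
  occupied <- as.integer(names(g$bins))
  ii <- integer(0); jj <- integer(0)
  for (b in occupied) {
    a_here <- g$bins[[as.character(b)]]
    nbins <- grid_neighbor_bins(g, b)
    cand <- unlist(g$bins[as.character(nbins)], use.names = FALSE)
    if (length(cand) < 2) next
    pi <- rep(a_here, each = length(cand))
    pj <- rep(cand, times = length(a_here))
    keep <- pi < pj
    ii <- c(ii, pi[keep]); jj <- c(jj, pj[keep])
  }
  if (!length(ii)) return(data.frame(i = integer(0), j = integer(0),
                                     d = numeric(0)))
  key <- (ii - 1) * nrow(xyz) + jj
  dedup <- !duplicated(key)
  ii <- ii[dedup]; jj <- jj[dedup]
  d <- min_image_distance(cell, xyz[ii, , drop = FALSE],
                          xyz[jj, , drop = FALSE], periodic = periodic)
  keep <- d <= cutoff
  data.frame(i = ii[keep], j = jj[keep], d = d[keep])
}

# ---- bond perception ------------------------------------------------------

#' Infer covalent bonds from interatomic distances
#'
#' Atoms i and j are bonded iff their minimum-image distance is at most
#' `scale * (r_cov(i) + r_cov(j))`. H-H bonds are never formed. An atom
#' acquiring more than 8 bonds indicates a steric clash and is an error.
#'
#' @param structure a [mol_structure()].
#' @param scale multiplier on the covalent-radius sum (default 1.2).
#' @param pbc use periodic minimum-image distances (requires a cell)?
#' @return the structure with the inferred bond list (replacing any
#'   existing bonds). Image shifts of periodic bonds are stored.
#' @export
infer_bonds <- function(structure, scale = 1.2, pbc = TRUE) {
  el <- normalize_element(structure$atoms$element)
  rcov <- covalent_radius(el)
  cutoff <- scale * 2 * max(rcov)
  periodic <- rep(pbc && !is.null(structure$cell), 3)
  cand <- neighbor_pairs(coords(structure), structure$cell, cutoff,
                         periodic = periodic)
  thr <- scale * (rcov[cand$i] + rcov[cand$j])
  keep <- cand$d <= thr & !(el[cand$i] == "H" & el[cand$j] == "H")
  b <- cand[keep, c("i", "j"), drop = FALSE]
  deg <- tabulate(c(b$i, b$j), nbins = natoms(structure))
  if (any(deg > 8)) {
    k <- which.max(deg)
    stop(sprintf("atom %d ('%s') acquires %d bonds - likely a clash",
                 k, structure$atoms$name[k], deg[k]))
  }
  out <- mol_structure(structure$atoms, bonds = as.matrix(b),
                       cell = structure$cell)
  if (any(periodic)) out$bonds <- classify_bond_shifts(out)
  out
}

# recompute minimal-image shifts for the stored bonds from geometry
classify_bond_shifts <- function(structure) {
  b <- structure$bonds
  if (nrow(b) == 0) return(b)
  cell <- structure$cell
  xyz <- coords(structure)
  fi <- xyz[b[, "i"], , drop = FALSE] %*% t(cell$hinv)
  fj <- xyz[b[, "j"], , drop = FALSE] %*% t(cell$hinv)
  df <- fj - fi
  base <- -round(df)
  res <- df + base                       # in [-0.5, 0.5]^3
  best <- res %*% t(cell$h)
  bestd2 <- rowSums(best^2)
  bests <- base
  for (r in seq_len(nrow(.shift27))) {
    s <- .shift27[r, ]
    if (all(s == 0)) next
    cand <- sweep(res, 2, s, "+") %*% t(cell$h)
    d2 <- rowSums(cand^2)
    better <- d2 < bestd2 - 1e-12
    if (any(better)) {
      bestd2[better] <- d2[better]
      bests[better, ] <- sweep(base[better, , drop = FALSE], 2, s, "+")
    }
  }
  b[, "sx"] <- as.integer(bests[, 1])
  b[, "sy"] <- as.integer(bests[, 2])
  b[, "sz"] <- as.integer(bests[, 3])
  b
}

# ---- molecules ------------------------------------------------------------

# per-atom molecule id; components numbered by smallest member index
molecule_index <- function(structure) {
  n <- natoms(structure)
  b <- structure$bonds
  if (is.null(b) || nrow(b) == 0) return(seq_len(n))
  gr <- igraph::graph_from_edgelist(cbind(b[, "i"], b[, "j"]),
                                    directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0, n - igraph::vcount(gr)))
  memb <- igraph::components(gr)$membership
  first <- tapply(seq_len(n), memb, min)
  rank <- match(memb, memb[sort(first)])
  as.integer(rank)
}

#' Partition atoms into molecules (connected components)
#'
#' Periodic bonds count as connections. Ordering is deterministic: the
#' molecule containing the smallest atom index comes first.
#'
#' @param structure a [mol_structure()] with bonds.
#' @return a list of integer atom-index vectors, one per molecule.
#' @export
molecules <- function(structure) {
  idx <- molecule_index(structure)
  unname(split(seq_len(natoms(structure)), idx))
}

# ---- periodic-bond classification -----------------------------------------

#' Classify bonds by the periodic boundaries they cross
#'
#' For each bond, finds the integer lattice shift (applied to atom `j`)
#' that minimises the bond length, i.e. the image shift needed to realise
#' the bond at minimum image. A bond with shift `(0,0,0)` does not cross
#' any boundary.
#'
#' @param structure a [mol_structure()] with a cell and bonds.
#' @param warn_length warn about bonds whose minimum-image length exceeds
#'   this covalent-plausibility bound (angstrom).
#' @return a data frame with columns `i`, `j`, `sx`, `sy`, `sz`, `length`.
#' @export
classify_periodic_bonds <- function(structure, warn_length = 2.5) {
  if (is.null(structure$cell)) stop("classification requires a cell")
  b <- classify_bond_shifts(structure)
  xyz <- coords(structure)
  if (nrow(b) == 0)
    return(data.frame(i = integer(0), j = integer(0), sx = integer(0),
                      sy = integer(0), sz = integer(0), length = numeric(0)))
  disp <- xyz[b[, "j"], , drop = FALSE] +
    b[, c("sx", "sy", "sz"), drop = FALSE] %*% t(structure$cell$h) -
    xyz[b[, "i"], , drop = FALSE]
  len <- sqrt(rowSums(disp^2))
  if (any(len > warn_length))
    warning(sprintf("%d bond(s) exceed %.1f A at minimum image",
                    sum(len > warn_length), warn_length))
  data.frame(i = b[, "i"], j = b[, "j"], sx = b[, "sx"], sy = b[, "sy"],
             sz = b[, "sz"], length = len)
}

#' Count boundary-crossing bonds per axis
#' @param classification output of [classify_periodic_bonds()], or a
#'   [mol_structure()] (classified on the fly).
#' @return named integer vector `c(x=, y=, z=)` of bonds with a non-zero
#'   image shift on each axis.
#' @export
periodic_bond_counts <- function(classification) {
  if (inherits(classification, "mol_structure"))
    classification <- classify_periodic_bonds(classification)
  c(x = sum(classification$sx != 0),
    y = sum(classification$sy != 0),
    z = sum(classification$sz != 0))
}

#' Dump a bond classification as TSV
#' @param classification output of [classify_periodic_bonds()].
#' @param path output path.
#' @export
write_bond_classification <- function(classification, path) {
  utils::write.table(classification, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
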