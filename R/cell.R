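# Triclinic cell algebra: lattice parameters, the fractional <-> cartesian
# transform, periodic wrapping, minimum-image distances and replication.
#
# Convention: the cell matrix H is lower-triangular with the a vector along
# x and the b vector in the xy-plane (the standard crystallographic
# convention, also used by VMD and LAMMPS). Columns of H are the lattice
# vectors; H %*% frac gives cartesian coordinates.

#' Construct a triclinic unit cell
#'
#' @param a,b,c lattice lengths in angstrom; must be positive.
#' @param alpha,beta,gamma lattice angles in degrees, strictly between 0 and
#'   180. `alpha` is the angle between b and c, `beta` between a and c,
#'   `gamma` between a and b.
#' @return an object of class `triclinic_cell` with fields `a, b, c, alpha,
#'   beta, gamma`, the 3x3 column matrix `h` (fractional to cartesian) and
#'   its inverse `hinv`.
#' @examples
#' cell <- triclinic_cell(39.970, 26.950, 677.900, 89.24, 94.59, 105.58)
#' cell_volume(cell)
#' @export
triclinic_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a = a, b = b, c = c)
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(len)) || any(len <= 0))
    stop("cell lengths must be positive and finite")
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    stop("cell angles must lie strictly between 0 and 180 degrees")
  ca <- cospi(alpha / 180); cb <- cospi(beta / 180)
  cg <- cospi(gamma / 180); sg <- sinpi(gamma / 180)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 0) stop("cell angles are geometrically inconsistent (zero volume)")
  h <- matrix(c(
    a, 0, 0,
    b * cg, b * sg, 0,
    c * cb, c * (ca - cb * cg) / sg, c * sqrt(v2) / sg
  ), nrow = 3, ncol = 3)
  structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
         h = h, hinv = solve(h)),
    class = "triclinic_cell"
  )
}

#' @export
print.triclinic_cell <- function(x, ...) {
  cat(sprintf(
    "triclinic cell: a=%.3f b=%.3f c=%.3f A  alpha=%.2f beta=%.2f gamma=%.2f deg  V=%.1f A^3\n",
    x$a, x$b, x$c, x$alpha, x$beta, x$gamma, cell_volume(x)))
  invisible(x)
}

#' Cell volume
#' @param cell a [triclinic_cell()].
#' @return volume in cubic angstrom.
#' @export
cell_volume <- function(cell) {
  stopifnot(inherits(cell, "triclinic_cell"))
  det(cell$h)
}

#' Orthorhombic cell from box edge lengths
#' @param lengths numeric 3-vector of box edge lengths in angstrom.
#' @return a [triclinic_cell()] with right angles.
#' @export
ortho_cell <- function(lengths) {
  stopifnot(length(lengths) == 3)
  triclinic_cell(lengths[1], lengths[2], lengths[3])
}

as_coord_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    x
  } else {
    stopifnot(length(x) == 3)
    matrix(x, nrow = 1)
  }
}

#' Cartesian to fractional coordinates
#'
#' @param cell a [triclinic_cell()].
#' @param pos cartesian position(s) in angstrom: a 3-vector or an n x 3
#'   matrix.
#' @return fractional coordinates with the same shape as `pos`.
#' @export
cart_to_frac <- function(cell, pos) {
  stopifnot(inherits(cell, "triclinic_cell"))
  p <- as_coord_matrix(pos)
  out <- p %*% t(cell$hinv)
  if (is.matrix(pos)) out else drop(out)
}

#' Fractional to cartesian coordinates
#'
#' @inheritParams cart_to_frac
#' @param frac fractional coordinate(s): a 3-vector or an n x 3 matrix.
#' @return cartesian coordinates in angstrom with the same shape as `frac`.
#' @export
frac_to_cart <- function(cell, frac) {
  stopifnot(inherits(cell, "triclinic_cell"))
  f <- as_coord_matrix(frac)
  out <- f %*% t(cell$h)
  if (is.matrix(frac)) out else drop(out)
}

# the 27 lattice shifts {-1,0,1}^3, one per row
.shift27 <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))

#' Minimum-image distance under a triclinic cell
#'
#' Computes the minimum over the 27 neighbour images of `|p - q + H s|`,
#' `s` in `{-1,0,1}^3`, after first reducing the fractional separation to
#' the central cell. Exact for separations that fit within one cell in each
#' lattice direction, i.e. any physically meaningful pair distance.
#'
#' @param cell a [triclinic_cell()].
#' @param p,q cartesian positions, 3-vectors or n x 3 matrices (recycled
#'   row-wise to a common length).
#' @param periodic logical 3-vector; axes marked `FALSE` are treated as
#'   non-periodic (no image shift applied on that axis).
#' @return numeric vector of distances in angstrom.
#' @export
min_image_distance <- function(cell, p, q, periodic = c(TRUE, TRUE, TRUE)) {
  sqrt(rowSums(min_image_vector(cell, p, q, periodic)^2))
}

#' Minimum-image displacement vectors
#'
#' @inheritParams min_image_distance
#' @return an n x 3 matrix of displacements `q - p` mapped to the minimum
#'   image, in angstrom.
#' @export
min_image_vector <- function(cell, p, q, periodic = c(TRUE, TRUE, TRUE)) {
  pm <- as_coord_matrix(p); qm <- as_coord_matrix(q)
  n <- max(nrow(pm), nrow(qm))
  if (nrow(pm) == 1 && n > 1) pm <- pm[rep(1, n), , drop = FALSE]
  if (nrow(qm) == 1 && n > 1) qm <- qm[rep(1, n), , drop = FALSE]
  df <- (qm - pm) %*% t(cell$hinv)
  # reduce to the central cell on periodic axes, then refine over 27 images
  for (k in 1:3) if (periodic[k]) df[, k] <- df[, k] - round(df[, k])
  best <- df %*% t(cell$h)
  bestd2 <- rowSums(best^2)
  for (r in seq_len(nrow(.shift27))) {
    s <- .shift27[r, ]
    if (all(s == 0)) next
    if (any(s != 0 & !periodic)) next
    cand <- sweep(df, 2, s, "+") %*% t(cell$h)
    d2 <- rowSums(cand^2)
    better <- d2 < bestd2
    if (any(better)) {
      best[better, ] <- cand[better, , drop = FALSE]
      bestd2[better] <- d2[better]
    }
  }
  best
}

#' Wrap a structure into its unit cell
#'
#' In `"atom"` mode every atom is translated by lattice vectors so that its
#' fractional coordinates lie in the half-open interval `[0, 1)`. In
#' `"molecule"` mode each connected component (bonds required) is rigidly
#' translated by one lattice vector so that its unweighted geometric centre
#' lies in `[0, 1)`; internal geometry is unchanged.
#'
#' @param structure a [mol_structure()] with a cell.
#' @param mode `"atom"` or `"molecule"`.
#' @return the wrapped structure.
#' @export
wrap_structure <- function(structure, mode = c("atom", "molecule")) {
  mode <- match.arg(mode)
  cell <- structure$cell
  if (is.null(cell)) stop("wrap_structure() requires a structure with a cell")
  xyz <- coords(structure)
  frac <- xyz %*% t(cell$hinv)
  if (mode == "atom") {
    shift <- -floor(frac)
  } else {
    if (is.null(structure$bonds) || nrow(structure$bonds) == 0)
      stop("per-molecule wrapping requires bonds")
    mol <- molecule_index(structure)
    ctr <- rowsum(frac, mol) / as.vector(table(mol))
    shift <- -floor(ctr)[mol, , drop = FALSE]
  }
  coords(structure) <- xyz + shift %*% t(cell$h)
  structure
}

#' Replicate a structure along the lattice vectors
#'
#' Produces `nx * ny * nz` images translated by integer combinations of the
#' lattice vectors. The cell lengths are scaled accordingly (angles
#' unchanged). Bonds are replicated within each image; bonds with periodic
#' image shifts are re-targeted to the correct neighbouring image, so bonds
#' periodic along an axis remain periodic in the super-cell.
#'
#' @param structure a [mol_structure()] with a cell.
#' @param nx,ny,nz positive integer replication counts.
#' @return the replicated structure with the enlarged cell.
#' @export
replicate_structure <- function(structure, nx = 1L, ny = 1L, nz = 1L) {
  n <- c(as.integer(nx), as.integer(ny), as.integer(nz))
  if (any(n < 1)) stop("replication counts must be >= 1")
  cell <- structure$cell
  if (is.null(cell)) stop("replicate_structure() requires a cell")
  if (all(n == 1)) return(structure)

  images <- as.matrix(expand.grid(ix = 0:(n[1] - 1), iy = 0:(n[2] - 1),
                                  iz = 0:(n[3] - 1)))
  nat <- natoms(structure)
  nimg <- nrow(images)
  xyz <- coords(structure)

  big <- structure$atoms[rep(seq_len(nat), nimg), , drop = FALSE]
  offs <- images %*% t(cell$h)           # one cartesian offset per image
  newxyz <- xyz[rep(seq_len(nat), nimg), , drop = FALSE] +
    offs[rep(seq_len(nimg), each = nat), , drop = FALSE]
  big$x <- newxyz[, 1]; big$y <- newxyz[, 2]; big$z <- newxyz[, 3]
  big$serial <- seq_len(nrow(big))
  rownames(big) <- NULL

  bonds <- structure$bonds
  newbonds <- NULL
  if (!is.null(bonds) && nrow(bonds) > 0) {
    bl <- vector("list", nimg)
    for (g in seq_len(nimg)) {
      img <- images[g, ]
      tgt <- sweep(bonds[, c("sx", "sy", "sz"), drop = FALSE], 2, img, "+")
      timg <- sweep(tgt, 2, n, function(t, nn) t %% nn)  # image of partner
      carry <- sweep(tgt, 2, n, function(t, nn) floor(t / nn))
      # linear index of the partner image in `images` row order
      tidx <- timg[, 1] + n[1] * timg[, 2] + n[1] * n[2] * timg[, 3]
      bl[[g]] <- cbind(
        i = bonds[, "i"] + (g - 1L) * nat,
        j = bonds[, "j"] + tidx * nat,
        sx = carry[, 1], sy = carry[, 2], sz = carry[, 3]
      )
    }
    newbonds <- do.call(rbind, bl)
  }

  newcell <- triclinic_cell(cell$a * n[1], cell$b * n[2], cell$c * n[3],
                            cell$alpha, cell$beta, cell$gamma)
  mol_structure(big, bonds = newbonds, cell = newcell)
}
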