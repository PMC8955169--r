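# The molecular structure container: an ordered atom table, a bond list
# with periodic image shifts, and an optional triclinic cell.

#' Construct a molecular structure
#'
#' @param atoms a data frame with (at least) columns `serial`, `name`,
#'   `element`, `resname`, `resid`, `chain`, `x`, `y`, `z`. Optional
#'   columns `occ`, `beta`, `charge` and `mass` are kept; `mass` is derived
#'   from `element` when absent.
#' @param bonds `NULL`, or a matrix/data frame with columns `i`, `j` (1-based
#'   atom indices) and optionally `sx`, `sy`, `sz` (integer lattice shifts
#'   applied to atom `j` to realise the bond; zero when absent). Bonds are
#'   stored with `i < j` once each.
#' @param cell `NULL` or a [triclinic_cell()].
#' @return an object of class `mol_structure`.
#' @export
mol_structure <- function(atoms, bonds = NULL, cell = NULL) {
  req <- c("serial", "name", "element", "resname", "resid", "chain",
           "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms table lacks column(s): ",
                         paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z)))
    stop("atom positions must be finite")
  if (is.null(atoms$occ)) atoms$occ <- rep(1, nrow(atoms))
  if (is.null(atoms$beta)) atoms$beta <- rep(0, nrow(atoms))
  if (is.null(atoms$mass))
    atoms$mass <- if (nrow(atoms)) element_mass(atoms$element) else numeric(0)
  if (any(atoms$mass <= 0)) stop("atom masses must be positive")
  if (any(nchar(trimws(atoms$chain)) > 1))
    stop("chain identifiers must be a single character")
  rownames(atoms) <- NULL

  bonds <- canonical_bonds(bonds, nrow(atoms))
  if (!is.null(cell)) stopifnot(inherits(cell, "triclinic_cell"))
  structure(list(atoms = atoms, bonds = bonds, cell = cell),
            class = "mol_structure")
}

canonical_bonds <- function(bonds, nat) {
  if (is.null(bonds) || NROW(bonds) == 0) {
    return(matrix(integer(0), ncol = 5,
                  dimnames = list(NULL, c("i", "j", "sx", "sy", "sz"))))
  }
  b <- as.matrix(as.data.frame(bonds))
  if (!all(c("i", "j") %in% colnames(b)))
    stop("bonds need columns i and j")
  for (s in c("sx", "sy", "sz")) if (!s %in% colnames(b)) {
    b <- cbind(b, 0L); colnames(b)[ncol(b)] <- s
  }
  b <- b[, c("i", "j", "sx", "sy", "sz"), drop = FALSE]
  storage.mode(b) <- "integer"
  if (any(b[, "i"] < 1 | b[, "i"] > nat | b[, "j"] < 1 | b[, "j"] > nat))
    stop("bond indices out of range")
  if (any(b[, "i"] == b[, "j"] & b[, "sx"] == 0 & b[, "sy"] == 0 &
          b[, "sz"] == 0))
    stop("self-bonds with zero image shift are not allowed")
  # orient so i <= j; the shift applies to j, so flipping negates it
  flip <- b[, "i"] > b[, "j"]
  if (any(flip)) {
    tmp <- b[flip, "i"]; b[flip, "i"] <- b[flip, "j"]; b[flip, "j"] <- tmp
    b[flip, c("sx", "sy", "sz")] <- -b[flip, c("sx", "sy", "sz"), drop = FALSE]
  }
  b[!duplicated(b[, c("i", "j", "sx", "sy", "sz"), drop = FALSE]), ,
    drop = FALSE]
}

#' Number of atoms
#' @param structure a [mol_structure()].
#' @export
natoms <- function(structure) nrow(structure$atoms)

#' Get atom coordinates as an n x 3 matrix
#' @param structure a [mol_structure()].
#' @return numeric matrix in angstrom, columns x, y, z.
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Replace atom coordinates
#' @param structure a [mol_structure()].
#' @param value an n x 3 numeric matrix.
#' @export
`coords<-` <- function(structure, value) {
  stopifnot(is.matrix(value), ncol(value) == 3,
            nrow(value) == natoms(structure))
  structure$atoms$x <- value[, 1]
  structure$atoms$y <- value[, 2]
  structure$atoms$z <- value[, 3]
  structure
}

#' Total mass of a structure
#' @param structure a [mol_structure()].
#' @return mass in amu.
#' @export
total_mass <- function(structure) sum(structure$atoms$mass)

#' Element counts
#' @param structure a [mol_structure()].
#' @return named integer vector of per-element atom counts.
#' @export
element_counts <- function(structure) {
  tab <- table(normalize_element(structure$atoms$element))
  out <- as.integer(tab); names(out) <- names(tab)
  out
}

#' Extract a subset of atoms as a new structure
#'
#' Bonds are re-indexed; bonds with an endpoint outside the subset are
#' dropped.
#' @param structure a [mol_structure()].
#' @param idx integer or logical index into the atom table.
#' @export
subset_atoms <- function(structure, idx) {
  if (is.logical(idx)) idx <- which(idx)
  map <- integer(natoms(structure)); map[idx] <- seq_along(idx)
  atoms <- structure$atoms[idx, , drop = FALSE]
  rownames(atoms) <- NULL
  b <- structure$bonds
  if (nrow(b) > 0) {
    keep <- map[b[, "i"]] > 0 & map[b[, "j"]] > 0
    b <- b[keep, , drop = FALSE]
    b[, "i"] <- map[b[, "i"]]; b[, "j"] <- map[b[, "j"]]
  }
  mol_structure(atoms, bonds = b, cell = structure$cell)
}

#' Concatenate two structures
#'
#' Atom tables are stacked (serials renumbered), bond indices of `y` are
#' offset. The cell of `x` is kept.
#' @param x,y [mol_structure()] objects.
#' @export
merge_structures <- function(x, y) {
  off <- natoms(x)
  ay <- y$atoms
  common <- intersect(names(x$atoms), names(ay))
  atoms <- rbind(x$atoms[, common, drop = FALSE], ay[, common, drop = FALSE])
  atoms$serial <- seq_len(nrow(atoms))
  by <- y$bonds
  if (nrow(by) > 0) {
    by[, "i"] <- by[, "i"] + off
    by[, "j"] <- by[, "j"] + off
  }
  mol_structure(atoms, bonds = rbind(x$bonds, by), cell = x$cell)
}

#' @export
print.mol_structure <- function(x, ...) {
  cat(sprintf("mol_structure: %d atoms, %d bonds, mass %.1f amu\n",
              natoms(x), nrow(x$bonds), total_mass(x)))
  ec <- element_counts(x)
  cat("  elements:", paste(sprintf("%s:%d", names(ec), ec), collapse = " "),
      "\n")
  if (!is.null(x$cell)) print(x$cell)
  invisible(x)
}
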