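# Fixtures built in code: small PDB files and structures used across the
# suite.

# a 3-atom water in a cubic 10 A cell, fixed-column records
write_water_pdb <- function(path, cell = TRUE) {
  lines <- c(
    if (cell) "CRYST1   10.000   10.000   10.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  OH2 TIP3W   1       5.000   5.000   5.000  1.00  0.00           O",
    "ATOM      2  H1  TIP3W   1       5.757   5.586   5.000  1.00  0.00           H",
    "ATOM      3  H2  TIP3W   1       4.243   5.586   5.000  1.00  0.00           H",
    "CONECT    1    2",
    "CONECT    1    3",
    "END")
  writeLines(lines, path)
  path
}

# fibril-cell PDB with one atom, for CRYST1 parsing
write_fibril_cell_pdb <- function(path) {
  writeLines(c(
    "CRYST1   39.970   26.950  677.900  89.24  94.59 105.58 P 1           1",
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END"), path)
  path
}

# bare structure from coordinates (carbon beads)
bead_structure <- function(xyz, cell = NULL, bonds = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  mol_structure(data.frame(
    serial = seq_len(nrow(xyz)), name = "CA", element = "C",
    resname = "TOY", resid = 1L, chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE),
    bonds = bonds, cell = cell)
}

empty_structure <- function(cell = NULL) {
  mol_structure(data.frame(
    serial = integer(0), name = character(0), element = character(0),
    resname = character(0), resid = integer(0), chain = character(0),
    x = numeric(0), y = numeric(0), z = numeric(0),
    stringsAsFactors = FALSE), cell = cell)
}

# brute-force 27-image minimum distance (independent oracle)
brute_min_image <- function(cell, p, q, periodic = c(TRUE, TRUE, TRUE)) {
  shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))
  shifts <- shifts[apply(shifts, 1, function(s) all(s == 0 | periodic)), ,
                   drop = FALSE]
  best <- Inf
  for (r in seq_len(nrow(shifts))) {
    d <- sqrt(sum((q + as.vector(cell$h %*% shifts[r, ]) - p)^2))
    best <- min(best, d)
  }
  best
}

fibril_cell <- function() {
  triclinic_cell(39.970, 26.950, 677.900, 89.24, 94.59, 105.58)
}
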