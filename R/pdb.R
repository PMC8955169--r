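# Fixed-column PDB v3.3 reading and writing, with hybrid-36 serials for
# structures beyond 99,999 atoms (mineralized fiber models routinely exceed
# that). ATOM/HETATM/CRYST1/CONECT/TER/END records are honoured; everything
# else is passed over. Coordinates are angstrom throughout; no unit
# conversion happens at the I/O boundary.

.H36_DIGITS <- c(0:9, LETTERS)
.H36_DIGITS_L <- c(0:9, letters)

encode_base36 <- function(value, width, digits) {
  out <- character(length(value))
  v <- value
  for (k in seq_len(width)) {
    out <- paste0(digits[v %% 36 + 1], out)
    v <- v %/% 36
  }
  out
}

#' Encode atom serial numbers as hybrid-36 strings of width 5
#'
#' Serials up to 99,999 print as plain decimal; 100,000 to 100,000 +
#' 26*36^4 - 1 use the uppercase base-36 range starting at "A0000";
#' the next block uses lowercase.
#' @param serial positive integer vector.
#' @return character vector of width-5 fields.
#' @export
hy36_encode <- function(serial) {
  s <- as.numeric(serial)
  if (any(s < 1)) stop("serials must be positive")
  out <- character(length(s))
  plain <- s <= 99999
  out[plain] <- formatC(s[plain], width = 5, format = "d")
  up <- !plain & s <= 99999 + 26 * 36^4
  if (any(up)) out[up] <- encode_base36(s[up] - 99999 + 10 * 36^4 - 1, 5,
                                        .H36_DIGITS)
  lo <- s > 99999 + 26 * 36^4 & s <= 99999 + 2 * 26 * 36^4
  if (any(lo)) out[lo] <- encode_base36(s[lo] - (99999 + 26 * 36^4) +
                                          10 * 36^4 - 1, 5, .H36_DIGITS_L)
  if (any(s > 99999 + 2 * 26 * 36^4))
    stop("serial out of hybrid-36 width-5 range")
  out
}

#' Decode width-5 hybrid-36 serial fields
#' @param field character vector of width-5 serial fields.
#' @return numeric vector of serials.
#' @export
hy36_decode <- function(field) {
  f <- trimws(field)
  out <- suppressWarnings(as.numeric(f))
  dec <- !is.na(out)
  todo <- which(!dec)
  for (k in todo) {
    chars <- strsplit(f[k], "")[[1]]
    upper <- grepl("^[0-9A-Z]+$", f[k])
    digits <- if (upper) .H36_DIGITS else .H36_DIGITS_L
    v <- 0
    for (ch in chars) v <- v * 36 + (match(ch, digits) - 1)
    out[k] <- if (upper) v - 10 * 36^4 + 99999 + 1 else
      v - 10 * 36^4 + 99999 + 26 * 36^4 + 1
  }
  out
}

pdb_field <- function(lines, from, to) substr(lines, from, to)

#' Read a PDB file
#'
#' Parses ATOM/HETATM records at fixed columns, a CRYST1 record into a
#' [triclinic_cell()], and CONECT records into the bond list. Elements come
#' from columns 77-78 when present, otherwise from the atom-name heuristic;
#' an unresolvable element is an error, never a guess.
#'
#' @param path path to a PDB file.
#' @param keep_hydrogens keep hydrogen atoms? When `FALSE`, H atoms are
#'   dropped and bonds re-indexed.
#' @return a [mol_structure()].
#' @export
read_pdb <- function(path, keep_hydrogens = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- pdb_field(lines, 1, 6)
  isatom <- rec == "ATOM  " | rec == "HETATM"
  at <- lines[isatom]
  if (length(at) == 0) stop("no ATOM/HETATM records in ", path)
  lineno <- which(isatom)

  xs <- suppressWarnings(as.numeric(pdb_field(at, 31, 38)))
  ys <- suppressWarnings(as.numeric(pdb_field(at, 39, 46)))
  zs <- suppressWarnings(as.numeric(pdb_field(at, 47, 54)))
  bad <- which(is.na(xs) | is.na(ys) | is.na(zs) | nchar(at) < 54)
  if (length(bad))
    stop(sprintf("malformed ATOM/HETATM record at line %d of %s",
                 lineno[bad[1]], path))

  name <- trimws(pdb_field(at, 13, 16))
  elem <- trimws(pdb_field(at, 77, 78))
  noel <- !nzchar(elem)
  if (any(noel)) elem[noel] <- element_from_name(name[noel], lineno[noel])
  elem <- normalize_element(elem)
  unknown <- !(elem %in% names(.ELEMENT_MASS))
  if (any(unknown)) {
    k <- which(unknown)[1]
    stop(sprintf("unknown element '%s' for atom '%s' (line %d)",
                 elem[k], name[k], lineno[k]))
  }

  occ <- suppressWarnings(as.numeric(pdb_field(at, 55, 60)))
  beta <- suppressWarnings(as.numeric(pdb_field(at, 61, 66)))
  atoms <- data.frame(
    serial = hy36_decode(pdb_field(at, 7, 11)),
    name = name,
    element = elem,
    resname = trimws(pdb_field(at, 18, 21)),
    resid = suppressWarnings(as.integer(pdb_field(at, 23, 26))),
    chain = pdb_field(at, 22, 22),
    x = xs, y = ys, z = zs,
    occ = ifelse(is.na(occ), 1, occ),
    beta = ifelse(is.na(beta), 0, beta),
    stringsAsFactors = FALSE
  )

  cell <- NULL
  cl <- lines[rec == "CRYST1"]
  if (length(cl) >= 1) {
    v <- suppressWarnings(as.numeric(c(
      pdb_field(cl[1], 7, 15), pdb_field(cl[1], 16, 24),
      pdb_field(cl[1], 25, 33), pdb_field(cl[1], 34, 40),
      pdb_field(cl[1], 41, 47), pdb_field(cl[1], 48, 54))))
    if (anyNA(v)) stop("malformed CRYST1 record in ", path)
    cell <- triclinic_cell(v[1], v[2], v[3], v[4], v[5], v[6])
  }

  bonds <- NULL
  co <- lines[rec == "CONECT"]
  if (length(co) > 0) {
    ser2idx <- seq_len(nrow(atoms)); names(ser2idx) <- atoms$serial
    bl <- list()
    for (ln in co) {
      base <- hy36_decode(substr(ln, 7, 11))
      partners <- c(substr(ln, 12, 16), substr(ln, 17, 21),
                    substr(ln, 22, 26), substr(ln, 27, 31))
      partners <- partners[nzchar(trimws(partners))]
      if (!length(partners)) next
      pv <- hy36_decode(partners)
      bl[[length(bl) + 1]] <- cbind(i = ser2idx[as.character(base)],
                                    j = ser2idx[as.character(pv)])
    }
    if (length(bl)) {
      bonds <- do.call(rbind, bl)
      if (anyNA(bonds)) stop("CONECT record references unknown serial in ",
                             path)
    }
  }

  s <- mol_structure(atoms, bonds = bonds, cell = cell)
  if (!keep_hydrogens) s <- subset_atoms(s, normalize_element(s$atoms$element) != "H")
  s
}

# atom-name heuristic used only when the element column is blank
element_from_name <- function(name, lineno) {
  two <- toupper(substr(name, 1, 2))
  one <- toupper(substr(name, 1, 1))
  # names starting with a digit (e.g. "1H") are hydrogens by PDB convention
  lead_digit <- grepl("^[0-9]", name)
  known2 <- c("CL", "NA", "CA", "MG", "FE", "ZN", "BR", "MN", "CU", "SE")
  out <- character(length(name))
  for (k in seq_along(name)) {
    if (lead_digit[k]) { out[k] <- "H"; next }
    # two-letter symbols only for ion/metal residue-style names; CA in a
    # protein is an alpha-carbon, so a bare two-letter match is accepted
    # only when the full trimmed name equals the symbol
    if (nchar(trimws(name[k])) == 2 && two[k] %in% known2) {
      out[k] <- two[k]
    } else if (one[k] %in% c("H", "C", "N", "O", "S", "P")) {
      out[k] <- one[k]
    } else {
      stop(sprintf("cannot infer element for atom '%s' (line %d)",
                   name[k], lineno[k]))
    }
  }
  out
}

#' Write a structure to a PDB file
#'
#' Fixed-column v3.3 records. Serials above 99,999 are written as
#' hybrid-36. CRYST1 lengths print to 3 decimals and angles to 2. Reading
#' back preserves atom count, names, chains, cell and coordinates to 3
#' decimals; a second write of the re-read structure is byte-identical.
#'
#' @param structure a [mol_structure()].
#' @param path output path.
#' @param renumber renumber serials 1..n before writing (default keeps the
#'   stored serials).
#' @param conect write CONECT records for the stored bonds?
#' @return invisibly, `path`.
#' @export
write_pdb <- function(structure, path, renumber = FALSE, conect = TRUE) {
  a <- structure$atoms
  if (any(nchar(trimws(a$chain)) > 1))
    stop("chain identifiers longer than one character cannot be written")
  ser <- if (renumber) seq_len(nrow(a)) else a$serial
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(structure$cell)) {
    cc <- structure$cell
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      cc$a, cc$b, cc$c, cc$alpha, cc$beta, cc$gamma), con)
    writeLines(
      "REMARK 285 CELL CONVENTION: A ALONG X, B IN XY-PLANE (LOWER-TRIANGULAR H)",
      con)
  }
  nm <- a$name
  # standard name justification: element symbols of width <= 1 start in
  # column 14; wider names are left-justified from column 13
  nmfield <- ifelse(nchar(nm) <= 3 & nchar(normalize_element(a$element)) == 1,
                    formatC(paste0(" ", nm), width = -4),
                    formatC(nm, width = -4))
  rn <- formatC(a$resname, width = -4)
  lines <- sprintf(
    "ATOM  %s %s %s%s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    hy36_encode(ser), substr(nmfield, 1, 4), substr(rn, 1, 4),
    ifelse(nzchar(trimws(a$chain)), a$chain, " "),
    a$resid %% 10000, a$x, a$y, a$z, a$occ, a$beta,
    formatC(normalize_element(a$element), width = 2))
  writeLines(lines, con)
  b <- structure$bonds
  if (conect && !is.null(b) && nrow(b) > 0) {
    si <- hy36_encode(ser[b[, "i"]]); sj <- hy36_encode(ser[b[, "j"]])
    writeLines(c(sprintf("CONECT%s%s", si, sj),
                 sprintf("CONECT%s%s", sj, si)), con)
  }
  writeLines("END", con)
  invisible(path)
}
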