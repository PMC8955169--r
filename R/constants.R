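# Physical constants and element tables.
#
# Internal unit system ("real"-style): lengths in angstrom, time in fs,
# mass in amu, energy in kcal/mol, force in kcal/mol/A, temperature in K.
# All conversions between this system and reported units (atm, GPa) go
# through the named constants below; nothing else converts units.

#' @keywords internal
#' @name units
NULL

# Avogadro constant, 1/mol
.NA_AVOGADRO <- 6.02214076e23

# Boltzmann constant, kcal/mol/K
.KB_KCALMOL <- 0.0019872041

# 1 amu * (A/fs)^2 expressed in kcal/mol (kinetic-energy conversion):
# 1e-3 kg/mol * 1e10 m^2/s^2 / 4184 J/kcal
.MVV_TO_KCALMOL <- 1e7 / 4184

# Acceleration in A/fs^2 produced by 1 kcal/mol/A acting on 1 amu
.FORCE_TO_ACC <- 1 / .MVV_TO_KCALMOL

# 1 kcal/mol/A^3 in Pa, then derived pressure conversions
.KCAL_A3_TO_PA <- 4184 / (.NA_AVOGADRO * 1e-30)
.KCAL_A3_TO_GPA <- .KCAL_A3_TO_PA / 1e9
.KCAL_A3_TO_ATM <- .KCAL_A3_TO_PA / 101325

# Molar masses used by the composition solver, g/mol
.MASS_HA_FORMULA <- 1004.62  # Ca10(PO4)6(OH)2, 44 atoms per formula unit
.MASS_WATER <- 18.015
.ATOMS_PER_HA <- 44L
.ATOMS_PER_WATER <- 3L

# Standard atomic weights (amu), consensus values to 4-5 significant figures
.ELEMENT_MASS <- c(
  H = 1.008, D = 2.014, He = 4.0026,
  Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305, Al = 26.982,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.948,
  K = 39.098, Ca = 40.078, Mn = 54.938, Fe = 55.845, Cu = 63.546,
  Zn = 65.38, Se = 78.971, Br = 79.904, I = 126.90
)

# Consensus single-bond covalent radii (angstrom)
.COVALENT_RADIUS <- c(
  H = 0.31, D = 0.31, He = 0.28,
  Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
  F = 0.57, Ne = 0.58, Na = 1.66, Mg = 1.41, Al = 1.21,
  Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Ar = 1.06,
  K = 2.03, Ca = 1.76, Mn = 1.39, Fe = 1.32, Cu = 1.32,
  Zn = 1.22, Se = 1.20, Br = 1.20, I = 1.39
)

#' Look up atomic masses by element symbol
#'
#' @param element character vector of element symbols (case-insensitive in
#'   the usual PDB sense: "CA" is calcium only when the element column says
#'   so; this function expects proper symbols like "Ca").
#' @return numeric vector of masses in amu.
#' @export
element_mass <- function(element) {
  el <- normalize_element(element)
  m <- .ELEMENT_MASS[el]
  if (anyNA(m)) {
    bad <- unique(element[is.na(m)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  unname(m)
}

#' Look up single-bond covalent radii by element symbol
#'
#' @inheritParams element_mass
#' @return numeric vector of radii in angstrom.
#' @export
covalent_radius <- function(element) {
  el <- normalize_element(element)
  r <- .COVALENT_RADIUS[el]
  if (anyNA(r)) {
    bad <- unique(element[is.na(r)])
    stop("no covalent radius for element(s): ", paste(bad, collapse = ", "))
  }
  unname(r)
}

# "CA"/"ca"/"Ca" -> "Ca"; "O" -> "O"
normalize_element <- function(element) {
  el <- trimws(as.character(element))
  bad <- !nzchar(el)
  if (any(bad)) stop("empty element symbol at position(s): ",
                     paste(which(bad), collapse = ", "))
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, nchar(el))))
}
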