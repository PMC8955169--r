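# Composition solver: convert target mass fractions of hydroxyapatite
# (HA), collagen (CLG) and water into molecule counts anchored on the
# collagen mass, split the mineral between extra- and intra-fibrillar
# volumes, and compute ion counts under an explicit policy.

#' Construct a composition specification
#'
#' @param ha,clg,h2o target mass fractions in percent; must sum to 100.
#' @param efv_share fraction of HA formula units assigned to the
#'   extra-fibrillar volume (default 0.80, the experimentally supported
#'   partition for cortical bone).
#' @param salt_molarity salt concentration in mol/L used by the
#'   `"molarity"` ion policy (default 0.16, physiological).
#' @param ion_policy `"neutralize"`, `"molarity"` or `"fixed"`.
#' @param fixed_ions integer 2-vector `c(n_cl, n_na)` for the `"fixed"`
#'   policy.
#' @return an object of class `composition_spec`.
#' @export
composition_spec <- function(ha, clg, h2o, efv_share = 0.80,
                             salt_molarity = 0.16,
                             ion_policy = c("neutralize", "molarity",
                                            "fixed"),
                             fixed_ions = c(0L, 0L)) {
  ion_policy <- match.arg(ion_policy)
  if (abs(ha + clg + h2o - 100) > 1e-9)
    stop("mass fractions must sum to 100%")
  if (any(c(ha, clg, h2o) < 0)) stop("mass fractions must be non-negative")
  if (efv_share < 0 || efv_share > 1) stop("efv_share must lie in [0, 1]")
  structure(list(ha = ha, clg = clg, h2o = h2o, efv_share = efv_share,
                 salt_molarity = salt_molarity, ion_policy = ion_policy,
                 fixed_ions = as.integer(fixed_ions)),
            class = "composition_spec")
}

#' Solve a composition specification into a molecule budget
#'
#' The collagen mass anchors the system: the total mass is `M = clg_mass /
#' f_CLG`, HA and water counts are the nearest integers to `f * M / molar
#' mass` (HA 1004.62 amu per Ca10(PO4)6(OH)2 formula unit, water 18.015
#' amu). The EFV receives `round(n_HA * efv_share)` formula units and the
#' IFV the remainder.
#'
#' @param spec a [composition_spec()].
#' @param clg_mass collagen mass in amu (> 0).
#' @return an object of class `molecule_budget`: counts `n_ha`, `n_ha_efv`,
#'   `n_ha_ifv`, `n_water`, the anchoring masses, and the achieved mass
#'   fractions in percent.
#' @export
solve_counts <- function(spec, clg_mass) {
  stopifnot(inherits(spec, "composition_spec"))
  if (clg_mass <= 0) stop("clg_mass must be positive")
  if (spec$clg <= 0)
    stop("the collagen fraction anchors the system and must be positive")
  total_mass <- clg_mass / (spec$clg / 100)
  n_ha <- round(spec$ha / 100 * total_mass / .MASS_HA_FORMULA)
  n_water <- round(spec$h2o / 100 * total_mass / .MASS_WATER)
  n_ha_efv <- round(n_ha * spec$efv_share)
  n_ha_ifv <- n_ha - n_ha_efv
  achieved_mass <- clg_mass + n_ha * .MASS_HA_FORMULA + n_water * .MASS_WATER
  structure(list(
    n_ha = n_ha, n_ha_efv = n_ha_efv, n_ha_ifv = n_ha_ifv,
    n_water = n_water, clg_mass = clg_mass, total_mass = total_mass,
    achieved = c(ha = 100 * n_ha * .MASS_HA_FORMULA / achieved_mass,
                 clg = 100 * clg_mass / achieved_mass,
                 h2o = 100 * n_water * .MASS_WATER / achieved_mass),
    spec = spec
  ), class = "molecule_budget")
}

#' @export
print.molecule_budget <- function(x, ...) {
  cat(sprintf(
    "molecule budget (total mass %.0f amu):\n  HA: %d (EFV %d / IFV %d)\n  water: %d\n",
    x$total_mass, x$n_ha, x$n_ha_efv, x$n_ha_ifv, x$n_water))
  cat(sprintf("  achieved fractions: HA %.2f%% CLG %.2f%% H2O %.2f%%\n",
              x$achieved["ha"], x$achieved["clg"], x$achieved["h2o"]))
  invisible(x)
}

#' Compute ion counts under an explicit policy
#'
#' * `"neutralize"`: counter-ions matching the system charge (chloride for
#'   positive charge, sodium for negative).
#' * `"molarity"`: `round(c * N_A * V_water)` of each species, plus the
#'   neutralizing excess.
#' * `"fixed"`: pass the given counts through unchanged.
#'
#' @param system_charge net charge in elementary charges (must be integer
#'   to within 1e-3).
#' @param policy one of `"neutralize"`, `"molarity"`, `"fixed"`.
#' @param water_volume water volume in litres (required for
#'   `"molarity"`).
#' @param molarity salt concentration in mol/L (default 0.16).
#' @param fixed integer 2-vector `c(n_cl, n_na)` for `"fixed"`.
#' @return named integer vector `c(n_cl = , n_na = )`.
#' @export
ion_counts <- function(system_charge, policy = c("neutralize", "molarity",
                                                 "fixed"),
                       water_volume = NULL, molarity = 0.16,
                       fixed = c(0L, 0L)) {
  policy <- match.arg(policy)
  q <- round(system_charge)
  if (abs(system_charge - q) > 1e-3)
    stop(sprintf("system charge %.4f is not integral", system_charge))
  base <- if (q > 0) c(n_cl = q, n_na = 0) else c(n_cl = 0, n_na = -q)
  out <- switch(policy,
    neutralize = base,
    molarity = {
      if (is.null(water_volume)) stop("molarity policy needs water_volume")
      npair <- round(molarity * .NA_AVOGADRO * water_volume)
      base + c(n_cl = npair, n_na = npair)
    },
    fixed = c(n_cl = fixed[1], n_na = fixed[2])
  )
  storage.mode(out) <- "integer"
  out
}

#' Cross-consistency fit of published atom totals
#'
#' Given per-model target mass fractions and printed total atom counts for
#' a family of models sharing one collagen structure, fits the two unknowns
#' (collagen atom count and collagen mass) such that
#' `total_i = A_clg + 3 * n_water_i + 44 * n_ha_i + n_ions`, with the
#' molecule counts rounded to integers exactly as [solve_counts()] rounds
#' them. The best pair is found by a golden-section-refined grid search on
#' the collagen mass (the counts are a step function of it, so the
#' objective is piecewise constant) minimising the maximum absolute
#' residual, with the atom count chosen optimally for each candidate mass.
#'
#' @param totals integer vector of printed total atom counts.
#' @param ha,clg numeric vectors of HA and CLG mass percentages (water
#'   making up the remainder to 100).
#' @param n_ions ions included in the totals (default 132 chloride).
#' @param mass_range search interval for the collagen mass, amu.
#' @return a list with `clg_atoms`, `clg_mass`, `residuals`, `predicted`,
#'   and the per-model molecule counts.
#' @export
fit_atom_totals <- function(totals, ha, clg, n_ions = 132L,
                            mass_range = c(1e5, 1e7)) {
  stopifnot(length(totals) == length(ha), length(ha) == length(clg))
  h2o <- 100 - ha - clg
  predict_rest <- function(cm) {
    m <- cm / (clg / 100)
    nw <- round(h2o / 100 * m / .MASS_WATER)
    nha <- round(ha / 100 * m / .MASS_HA_FORMULA)
    .ATOMS_PER_WATER * nw + .ATOMS_PER_HA * nha
  }
  objective <- function(cm) {
    rest <- totals - n_ions - predict_rest(cm)
    (max(rest) - min(rest)) / 2          # best achievable max |residual|
  }
  # coarse log-spaced scan, then fine linear refinement around the best
  grid <- exp(seq(log(mass_range[1]), log(mass_range[2]), length.out = 4000))
  vals <- vapply(grid, objective, numeric(1))
  best <- grid[which.min(vals)]
  fine <- seq(best * 0.98, best * 1.02, length.out = 8000)
  vals <- vapply(fine, objective, numeric(1))
  cm <- fine[which.min(vals)]

  rest <- predict_rest(cm)
  resid_base <- totals - n_ions - rest
  a_clg <- round((max(resid_base) + min(resid_base)) / 2)
  m <- cm / (clg / 100)
  list(clg_atoms = a_clg, clg_mass = cm,
       residuals = resid_base - a_clg,
       predicted = a_clg + rest + n_ions,
       n_water = round(h2o / 100 * m / .MASS_WATER),
       n_ha = round(ha / 100 * m / .MASS_HA_FORMULA))
}
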