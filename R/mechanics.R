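# Tensile-test mathematics: the strain schedule of a constant-rate box
# deformation, the virial stress tensor, Young's-modulus estimation over
# the elastic strain window, and the RMSD convergence diagnostic.
#
# Sign convention: the virial expression yields the mechanical pressure
# tensor P; the reported uniaxial stress is sigma_zz = -P_zz so that
# tension is positive and the fitted modulus of a stretched solid comes
# out positive. The flip is applied only at the reporting boundary
# (stress_zz(), run_tensile()); virial_pressure() itself returns P.

#' Construct a strain schedule
#'
#' A constant engineering strain-rate extension of the box length along z:
#' `L_z(t) = L_z0 * (rate * t + 1)`.
#'
#' @param l0 initial box length along z, angstrom (> 0).
#' @param rate engineering strain rate in 1/fs.
#' @param duration total deformation time, fs (>= 0).
#' @return an object of class `strain_schedule` with the derived edge
#'   velocity `v_z = rate * l0` (angstrom/fs).
#' @export
strain_schedule <- function(l0, rate, duration) {
  if (l0 <= 0) stop("initial box length must be positive")
  if (duration < 0) stop("duration must be non-negative")
  structure(list(l0 = l0, rate = rate, duration = duration,
                 vz = rate * l0),
            class = "strain_schedule")
}

#' Box length under a strain schedule
#' @param schedule a [strain_schedule()].
#' @param t time in fs, `0 <= t <= duration`.
#' @return box length in angstrom: `l0 * (rate * t + 1)`.
#' @export
box_length <- function(schedule, t) {
  if (any(t < 0)) stop("time must be non-negative")
  if (any(t > schedule$duration + 1e-9))
    stop("time exceeds the schedule duration")
  schedule$l0 * (schedule$rate * t + 1)
}

#' Engineering strain
#' @param l current length, angstrom.
#' @param l0 reference length, angstrom (> 0).
#' @return `(l - l0) / l0`, dimensionless.
#' @export
engineering_strain <- function(l, l0) {
  if (any(l0 <= 0)) stop("reference length must be positive")
  (l - l0) / l0
}

#' Virial pressure tensor
#'
#' `P = (sum_k m_k v_k v_k^T + W) / V`, where the configurational virial
#' `W` is either the per-atom sum `sum_k r_k f_k^T` (valid when no
#' interaction wraps a periodic boundary) or, preferably, the pair sum
#' `sum_pairs r_ij f_ij^T` over minimum-image pair displacements, which is
#' equivalent to including ghost-atom contributions.
#'
#' @param mass numeric vector of atom masses, amu.
#' @param velocity n x 3 matrix, angstrom/fs (zeros when `NULL`).
#' @param volume system volume, cubic angstrom (> 0).
#' @param positions,forces optional n x 3 matrices (angstrom,
#'   kcal/mol/angstrom) for the per-atom virial route.
#' @param pair_r,pair_f optional m x 3 matrices of pair displacement
#'   vectors and pair forces (force on the pair's second atom along
#'   `pair_r` from first to second) for the pair-sum route.
#' @param units `"GPa"` or `"atm"`.
#' @return symmetric 3 x 3 pressure tensor in the requested units.
#' @export
virial_pressure <- function(mass, velocity = NULL, volume,
                            positions = NULL, forces = NULL,
                            pair_r = NULL, pair_f = NULL,
                            units = c("GPa", "atm")) {
  units <- match.arg(units)
  if (volume <= 0) stop("volume must be positive")
  n <- length(mass)
  kin <- matrix(0, 3, 3)
  if (!is.null(velocity)) {
    stopifnot(nrow(velocity) == n)
    kin <- crossprod(velocity * mass, velocity) * .MVV_TO_KCALMOL
  }
  vir <- matrix(0, 3, 3)
  if (!is.null(positions) && !is.null(forces)) {
    stopifnot(nrow(positions) == n, nrow(forces) == n)
    vir <- vir + crossprod(positions, forces)
  }
  if (!is.null(pair_r) && !is.null(pair_f)) {
    vir <- vir + crossprod(pair_r, pair_f)
  }
  p <- (kin + vir) / volume
  p * switch(units, GPa = .KCAL_A3_TO_GPA, atm = .KCAL_A3_TO_ATM)
}

#' Reported uniaxial stress from a pressure tensor
#'
#' @param pressure 3 x 3 pressure tensor.
#' @return `-P[3,3]`: tension positive.
#' @export
stress_zz <- function(pressure) -pressure[3, 3]

#' Kinetic temperature from velocities
#' @param mass amu; @param velocity n x 3, angstrom/fs.
#' @param ndof degrees of freedom (default `3 n`).
#' @return temperature in K.
#' @export
kinetic_temperature <- function(mass, velocity, ndof = 3 * length(mass)) {
  ke <- 0.5 * sum(mass * rowSums(velocity^2)) * .MVV_TO_KCALMOL
  2 * ke / (ndof * .KB_KCALMOL)
}

#' Fit the Young's modulus over an elastic strain window
#'
#' Ordinary least-squares regression of stress on strain restricted to
#' strains inside `window` (endpoints inclusive); the slope estimates the
#' Young's modulus under Hooke's law. The default window 1-7% strain is
#' the linear-elastic regime adopted for these fiber models.
#'
#' @param series a [stress_strain_series()] (strain dimensionless, stress
#'   GPa).
#' @param window numeric 2-vector of strain bounds (default
#'   `c(0.01, 0.07)`).
#' @return a list with `E` (GPa), `intercept` (GPa), `stderr` (GPa, of the
#'   slope), `n_points` and `window`.
#' @export
fit_young_modulus <- function(series, window = c(0.01, 0.07)) {
  eps <- series$strain; sig <- series$stress
  keep <- eps >= window[1] & eps <= window[2]
  if (sum(keep) < 2)
    stop(sprintf("only %d point(s) inside the strain window [%g, %g]",
                 sum(keep), window[1], window[2]))
  fit <- stats::lm(sig[keep] ~ eps[keep])
  co <- suppressWarnings(summary(fit))$coefficients
  se <- if (nrow(co) >= 2 && ncol(co) >= 2) co[2, 2] else NA_real_
  if (is.nan(se)) se <- 0
  list(E = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       stderr = unname(se), n_points = sum(keep), window = window)
}

#' Block-average a stress-strain series
#'
#' Optional preprocessor: averages consecutive blocks of `n` points,
#' reducing thermal noise before fitting.
#' @param series a [stress_strain_series()].
#' @param n block size (>= 1).
#' @export
block_average <- function(series, n) {
  if (n <= 1) return(series)
  g <- (seq_len(nrow(series)) - 1) %/% n
  stress_strain_series(tapply(series$strain, g, mean),
                       tapply(series$stress, g, mean),
                       label = attr(series, "label"))
}

#' Root mean squared deviation between two structures
#'
#' @param reference,frame [mol_structure()] objects with matching
#'   selections.
#' @param selection atom-name filter (default `"CA"`, the alpha-carbon
#'   convergence diagnostic); `NULL` selects all atoms.
#' @param superpose rigidly superpose `frame` onto `reference`
#'   (least-squares rotation/translation) before measuring?
#' @return RMSD in angstrom.
#' @export
rmsd <- function(reference, frame, selection = "CA", superpose = FALSE) {
  pick <- function(s) {
    if (is.null(selection)) coords(s)
    else coords(s)[s$atoms$name %in% selection, , drop = FALSE]
  }
  a <- pick(reference); b <- pick(frame)
  if (nrow(a) != nrow(b))
    stop(sprintf("selection sizes differ: %d vs %d", nrow(a), nrow(b)))
  if (nrow(a) == 0) stop("empty selection")
  if (superpose) {
    fitted <- bio3d::fit.xyz(fixed = as.vector(t(a)),
                             mobile = matrix(as.vector(t(b)), nrow = 1),
                             fixed.inds = seq_len(3 * nrow(a)),
                             mobile.inds = seq_len(3 * nrow(a)))
    b <- matrix(fitted[1, ], ncol = 3, byrow = TRUE)
  }
  sqrt(mean(rowSums((a - b)^2)))
}

#' Emit a modulus fit report
#'
#' JSON report plus a plot-ready CSV of the windowed points.
#' @param series a [stress_strain_series()].
#' @param fit output of [fit_young_modulus()].
#' @param path_json,path_csv output paths (either may be `NULL`).
#' @export
write_fit_report <- function(series, fit, path_json = NULL,
                             path_csv = NULL) {
  if (!is.null(path_json))
    jsonlite::write_json(
      list(E_GPa = fit$E, intercept_GPa = fit$intercept,
           stderr_GPa = fit$stderr, n_points = fit$n_points,
           window = fit$window, label = attr(series, "label")),
      path_json, auto_unbox = TRUE, digits = NA)
  if (!is.null(path_csv)) {
    keep <- series$strain >= fit$window[1] & series$strain <= fit$window[2]
    utils::write.csv(as.data.frame(series)[keep, ], path_csv,
                     row.names = FALSE)
  }
  invisible(fit)
}
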