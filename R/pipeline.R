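# Config-driven pipeline stages chaining the package: extract a nanofiber
# from a fibril, build and mineralize a fiber model, and run a tensile
# test on a synthetic fiber. Each stage logs its fully resolved
# configuration and writes a JSON provenance sidecar next to its outputs.
# The thin command-line wrapper in inst/cli/bonefiber.R maps subcommands
# onto these functions.

default_build_config <- function() {
  list(
    seed = 1L,
    fibril = list(synthetic = TRUE, molecules = 5L, beads = 40L,
                  spacing = 1.5, gap_fraction = 0.54, path = NULL),
    fiber = list(nx = 2L, ny = 2L, margins = c(14, 28)),
    composition = list(ha = 55, clg = 35, h2o = 10, efv_share = 0.8,
                       ion_policy = "neutralize"),
    packing = list(tolerance = 2.0, max_attempts = 2000L,
                   water_scale = 1.0, ha_scale = 1.0),
    tensile = list(rate = 1e-5, duration = 10000, dt = 2,
                   temperature = NULL, window = c(0.01, 0.07))
  )
}

#' Read and validate a build configuration
#'
#' YAML key-value file; absent keys fall back to defaults (synthetic
#' five-molecule fibril, 2 x 2 replication, 55/35/10 composition, 2.0
#' angstrom packing tolerance, 1e-5/fs strain rate).
#'
#' @param path path to a YAML config, or `NULL` for pure defaults.
#' @return the resolved configuration list.
#' @export
read_build_config <- function(path = NULL) {
  cfg <- default_build_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    known <- names(cfg)
    bad <- setdiff(names(user), c(known, "out"))
    if (length(bad)) stop("unknown config key(s): ",
                          paste(bad, collapse = ", "))
    for (k in intersect(names(user), known)) {
      if (is.list(cfg[[k]])) {
        badsub <- setdiff(names(user[[k]]), names(cfg[[k]]))
        if (length(badsub)) stop(sprintf("unknown key(s) under '%s': %s", k,
                                         paste(badsub, collapse = ", ")))
        cfg[[k]][names(user[[k]])] <- user[[k]]
      } else cfg[[k]] <- user[[k]]
    }
  }
  cfg
}

load_or_make_fibril <- function(cfg) {
  f <- cfg$fibril
  if (isTRUE(f$synthetic)) {
    make_toy_fibril(molecules = f$molecules, beads = f$beads,
                    spacing = f$spacing, gap_fraction = f$gap_fraction,
                    seed = cfg$seed)$structure
  } else {
    s <- read_pdb(f$path)
    if (nrow(s$bonds) == 0) s <- infer_bonds(s)
    s
  }
}

sidecar <- function(path, payload) {
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Pipeline stage: extract a nanofiber
#'
#' Wraps [extract_nanofiber()]: reads or generates the fibril, unwraps it
#' laterally, writes `nanofiber.pdb` plus a JSON sidecar reporting the
#' periodic-bond counts before and after.
#'
#' @param config a configuration list from [read_build_config()].
#' @param out output directory (created if needed).
#' @return invisibly, a list with the output paths and the bond counts.
#' @export
cmd_extract <- function(config, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  fibril <- load_or_make_fibril(config)
  before <- periodic_bond_counts(fibril)
  nano <- extract_nanofiber(fibril)
  after <- periodic_bond_counts(nano)
  pdb <- file.path(out, "nanofiber.pdb")
  write_pdb(nano, pdb)
  side <- sidecar(file.path(out, "nanofiber.json"), list(
    config = config, crossing_bonds_before = as.list(before),
    crossing_bonds_after = as.list(after)))
  message(sprintf("nanofiber: x/y-crossing bonds %d+%d -> %d+%d, z %d -> %d",
                  before["x"], before["y"], after["x"], after["y"],
                  before["z"], after["z"]))
  invisible(list(pdb = pdb, sidecar = side, before = before, after = after))
}

#' Pipeline stage: build and mineralize a fiber model
#'
#' Wraps [build_fiber()], [solve_counts()] and [pack_structures()]: the
#' nanofiber is replicated laterally, the composition solved against the
#' collagen mass, hydroxyapatite split 80/20 between EFV and IFV, water
#' packed throughout, ions added per policy, and the model written as PDB
#' with a JSON sidecar echoing regions, budget and achieved fractions.
#' `packing$water_scale` / `ha_scale` (fractions of the solved counts)
#' keep desk-scale builds tractable.
#'
#' @inheritParams cmd_extract
#' @return invisibly, a list with paths, the `fiber_model`, the budget and
#'   the packed structure.
#' @export
cmd_build <- function(config, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  fibril <- load_or_make_fibril(config)
  nano <- extract_nanofiber(fibril)
  fib <- config$fiber
  model <- build_fiber(nano, nx = fib$nx, ny = fib$ny, margins = fib$margins)

  comp <- config$composition
  spec <- composition_spec(comp$ha, comp$clg, comp$h2o,
                           efv_share = comp$efv_share,
                           ion_policy = comp$ion_policy)
  budget <- solve_counts(spec, clg_mass = total_mass(model$structure))
  pk <- config$packing
  n_ha_efv <- round(budget$n_ha_efv * pk$ha_scale)
  n_ha_ifv <- round(budget$n_ha_ifv * pk$ha_scale)
  n_water <- round(budget$n_water * pk$water_scale)

  ha <- make_mineral_template()
  water <- make_water_template()
  tasks <- list(
    packing_task(ha, n_ha_efv, model$simbox, exclusion = model$ifv,
                 tolerance = pk$tolerance, max_attempts = pk$max_attempts),
    packing_task(ha, n_ha_ifv, model$ifv,
                 tolerance = pk$tolerance, max_attempts = pk$max_attempts),
    packing_task(water, n_water, model$simbox,
                 tolerance = pk$tolerance, max_attempts = pk$max_attempts)
  )
  packed <- pack_structures(model$structure, tasks, seed = config$seed)

  ions <- ion_counts(0, policy = comp$ion_policy)
  zones <- zone_profile(model)
  pdb <- file.path(out, "bone_fiber.pdb")
  write_pdb(packed, pdb)
  side <- sidecar(file.path(out, "bone_fiber.json"), list(
    config = config,
    simbox = list(lower = model$simbox$lower, upper = model$simbox$upper),
    ifv = list(lower = model$ifv$lower, upper = model$ifv$upper),
    budget = list(n_ha = budget$n_ha, n_ha_efv = budget$n_ha_efv,
                  n_ha_ifv = budget$n_ha_ifv, n_water = budget$n_water,
                  placed_ha_efv = n_ha_efv, placed_ha_ifv = n_ha_ifv,
                  placed_water = n_water),
    ions = as.list(ions),
    achieved_fractions = as.list(budget$achieved),
    zone_counts = list(overlap = zones$overlap_count,
                       gap = zones$gap_count)))
  invisible(list(pdb = pdb, sidecar = side, model = model, budget = budget,
                 structure = packed))
}

#' Pipeline stage: tensile test on a synthetic spring fiber
#'
#' Wraps [make_spring_fiber()], [run_tensile()] and
#' [fit_young_modulus()]: builds the spring-network fiber, deforms it
#' under the configured strain schedule, writes the stress-strain series
#' as CSV and the fit report as JSON.
#'
#' @inheritParams cmd_extract
#' @return invisibly, a list with paths, the series and the fit.
#' @export
cmd_tensile <- function(config, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  tc <- config$tensile
  if (tc$duration <= 0) stop("tensile duration must be positive")
  fiber <- make_spring_fiber()
  sched <- strain_schedule(fiber$state$cell$c, tc$rate, tc$duration)
  series <- run_tensile(fiber$state, fiber$ff, sched, dt = tc$dt,
                        temperature = tc$temperature)
  fit <- fit_young_modulus(series, window = tc$window)
  csv <- file.path(out, "stress_strain.csv")
  write_series(series, csv)
  write_fit_report(series, fit,
                   path_json = file.path(out, "fit_report.json"),
                   path_csv = file.path(out, "fit_window.csv"))
  side <- sidecar(file.path(out, "tensile.json"), list(
    config = config, E_GPa = fit$E, E_closed_form_GPa = fiber$E_closed_form,
    window = fit$window, n_points = fit$n_points))
  message(sprintf("tensile: E = %.4f GPa (closed form %.4f GPa)",
                  fit$E, fiber$E_closed_form))
  invisible(list(csv = csv, sidecar = side, series = series, fit = fit,
                 E_closed_form = fiber$E_closed_form))
}
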