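#' Simulation configuration
#'
#' Bundles everything a pipeline run needs: geometry, material registry,
#' mesh sizing, thermal boundary-condition parameters, acoustic impedance
#' for the equivalent-radiated-power estimate, and solver options.
#'
#' @param geometry a `cusa_geometry`.
#' @param materials named list of `cusa_material` per tissue class.
#' @param sizing a `cusa_sizing` (see [mesh_sizing()]).
#' @param h convection film coefficient on the exposed outer boundary,
#'   W/(m^2 C); a representative still-air value.
#' @param t_amb ambient temperature (C); 37 C models the thermally neutral
#'   surgical field around body-temperature tissue.
#' @param t_ref initial/reference tissue temperature (C).
#' @param impedance a [fluid_impedance()] for the ERP estimate.
#' @param erp_mode `"preset"` uses the published radiated power attached
#'   to a preset load case (see [load_case_preset()]); `"first_principles"`
#'   computes it from the harmonic solution and `impedance`.
#' @param loss_factor hysteretic (structural) damping loss factor applied
#'   to all stiffnesses in harmonic analyses.
#' @param efficiency fraction of radiated energy dissipated as heat.
#' @return an object of class `cusa_config`.
#' @export
simulation_config <- function(geometry = default_geometry(),
                              materials = default_materials(),
                              sizing = mesh_sizing(),
                              h = 10, t_amb = 37, t_ref = 37,
                              impedance = fluid_impedance(),
                              erp_mode = c("preset", "first_principles"),
                              loss_factor = 0.1,
                              efficiency = 1) {
  stopifnot(h >= 0, is.finite(t_amb), is.finite(t_ref),
            loss_factor >= 0, efficiency > 0, efficiency <= 1)
  structure(list(geometry = geometry, materials = materials,
                 sizing = sizing, h = h, t_amb = t_amb, t_ref = t_ref,
                 impedance = impedance, erp_mode = match.arg(erp_mode),
                 loss_factor = loss_factor, efficiency = efficiency),
            class = "cusa_config")
}

#' Toy simulation configuration
#'
#' Single-vertebra geometry with coarse sizing; runs every pipeline stage
#' in seconds.
#' @param ... passed to [simulation_config()].
#' @export
toy_config <- function(...) {
  simulation_config(geometry = toy_geometry(),
                    sizing = mesh_sizing(global_size = 12,
                                         influence_size = 6,
                                         tip_face_size = 3,
                                         influence_radius = 4), ...)
}

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Write a configuration to a flat key/value file
#'
#' TOML-style flat `section.key = value` lines covering the geometry, the
#' material registry and the scalar simulation parameters.  The file
#' round-trips exactly through [read_config()].
#'
#' @param config a `cusa_config`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  lines <- character(0)
  g <- config$geometry
  for (k in names(unclass(g)))
    lines <- c(lines, sprintf("geometry.%s = %s", k, fmt_num(g[[k]])))
  for (tis in names(config$materials)) {
    m <- config$materials[[tis]]
    for (k in names(unclass(m)))
      lines <- c(lines, sprintf("material.%s.%s = %s", tis, k, fmt_num(m[[k]])))
  }
  s <- config$sizing
  for (k in c("global_size", "influence_radius", "influence_size",
              "tip_face_size"))
    lines <- c(lines, sprintf("sizing.%s = %s", k, fmt_num(s[[k]])))
  for (k in c("h", "t_amb", "t_ref", "loss_factor", "efficiency"))
    lines <- c(lines, sprintf("thermal.%s = %s", k, fmt_num(config[[k]])))
  lines <- c(lines,
             sprintf("impedance.fluid_density = %s",
                     fmt_num(config$impedance$fluid_density)),
             sprintf("impedance.sound_speed = %s",
                     fmt_num(config$impedance$sound_speed)),
             sprintf("erp.mode = %s", config$erp_mode))
  writeLines(lines, path)
  invisible(path)
}

#' Read a configuration written by [write_config()]
#'
#' @param path file path.
#' @return a `cusa_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  keys <- vapply(kv, `[`, "", 2)
  vals <- trimws(vapply(kv, `[`, "", 3))
  getv <- function(prefix) {
    sel <- startsWith(keys, prefix)
    v <- vals[sel]
    names(v) <- substring(keys[sel], nchar(prefix) + 1)
    v
  }
  gv <- getv("geometry.")
  geometry <- do.call(geometry_config, as.list(as.numeric(gv)) |>
                        stats::setNames(names(gv)))
  materials <- default_materials()
  for (tis in names(materials)) {
    mv <- getv(paste0("material.", tis, "."))
    if (length(mv))
      materials[[tis]] <- do.call(material_properties,
                                  as.list(as.numeric(mv)) |>
                                    stats::setNames(names(mv)))
  }
  sv <- as.numeric(getv("sizing.")) |>
    stats::setNames(names(getv("sizing.")))
  tv <- as.numeric(getv("thermal.")) |>
    stats::setNames(names(getv("thermal.")))
  iv <- as.numeric(getv("impedance.")) |>
    stats::setNames(names(getv("impedance.")))
  simulation_config(
    geometry = geometry, materials = materials,
    sizing = mesh_sizing(global_size = sv[["global_size"]],
                         influence_radius = sv[["influence_radius"]],
                         influence_size = sv[["influence_size"]],
                         tip_face_size = sv[["tip_face_size"]]),
    h = tv[["h"]], t_amb = tv[["t_amb"]], t_ref = tv[["t_ref"]],
    impedance = fluid_impedance(iv[["fluid_density"]], iv[["sound_speed"]]),
    erp_mode = getv("erp.")[["mode"]],
    loss_factor = tv[["loss_factor"]], efficiency = tv[["efficiency"]])
}

#' Export the resolved model description as JSON
#'
#' @param model a `cusa_model`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
export_model_json <- function(model, path = NULL) {
  desc <- list(
    geometry = unclass(model$geometry),
    radii_mm = as.list(model$radii),
    z_bands = model$z_bands,
    regions = model$regions,
    tumour_centre_mm = model$tumour_centre,
    tumour_z_mm = model$tumour_z,
    tip_centre_mm = model$tip_centre,
    tip_radius_mm = model$tip_radius,
    drive_axis = model$drive_axis,
    volumes_mm3 = as.list(model_volume(model)))
  js <- jsonlite::toJSON(desc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
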