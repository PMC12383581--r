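#' Parametric geometry of the layered cervical-spine segment
#'
#' Describes a simplified C3--C7 cervical segment: five vertebrae
#' (cylindrical body plus a posterior arch ring enclosing the vertebral
#' cavity) alternating with intervertebral discs, and a coaxial stack of
#' cylindrical layers inside the cavity -- epidural fat, dura mater,
#' cerebrospinal fluid (CSF) and spinal cord -- with a cylindrical tumour
#' embedded in the cord near the C4--C5 interface.  All lengths are in mm.
#'
#' Defaults reproduce the reference anatomical dimensions of the modelled
#' segment.  Layer diameters must nest consistently:
#' `fat_outer - 2*fat_thickness == dura_outer`,
#' `dura_outer - 2*dura_thickness == csf_outer`,
#' `csf_outer - 2*csf_thickness == cord_diameter`, and the tumour must fit
#' inside the cord.  The small slack between the total height and the
#' summed part heights is absorbed into equal end-cap pads at the two
#' axial ends of the segment.
#'
#' @param total_height overall axial height of the segment (mm).
#' @param vertebra_body_height axial height of one vertebra (mm).
#' @param vertebra_ml_width mediolateral width of the vertebral body (mm).
#' @param vertebra_ap_width anteroposterior width of the vertebral body (mm).
#' @param cavity_diameter diameter of the vertebral cavity (mm); must equal
#'   `fat_outer_diameter` so the epidural fat fills the cavity.
#' @param disc_height axial height of one intervertebral disc (mm).
#' @param fat_outer_diameter,fat_thickness epidural fat layer (mm).
#' @param dura_outer_diameter,dura_thickness dura mater layer (mm).
#' @param csf_outer_diameter,csf_thickness CSF layer (mm).
#' @param cord_diameter spinal cord diameter (mm).
#' @param tumour_diameter,tumour_height embedded tumour cylinder (mm).
#' @param n_vertebrae number of vertebrae (discs are `n_vertebrae - 1`).
#' @param tip_face_diameter diameter of the circular device-tip application
#'   face on the tumour surface (mm).
#' @return an object of class `cusa_geometry` (a validated named list).
#' @seealso [build_model()], [default_materials()]
#' @export
geometry_config <- function(total_height = 90,
                            vertebra_body_height = 14,
                            vertebra_ml_width = 24.5,
                            vertebra_ap_width = 14,
                            cavity_diameter = 12,
                            disc_height = 4,
                            fat_outer_diameter = 12,
                            fat_thickness = 0.3,
                            dura_outer_diameter = 11.4,
                            dura_thickness = 0.2,
                            csf_outer_diameter = 11,
                            csf_thickness = 1,
                            cord_diameter = 9,
                            tumour_diameter = 7,
                            tumour_height = 25,
                            n_vertebrae = 5,
                            tip_face_diameter = 2) {
  g <- list(
    total_height = total_height,
    vertebra_body_height = vertebra_body_height,
    vertebra_ml_width = vertebra_ml_width,
    vertebra_ap_width = vertebra_ap_width,
    cavity_diameter = cavity_diameter,
    disc_height = disc_height,
    fat_outer_diameter = fat_outer_diameter,
    fat_thickness = fat_thickness,
    dura_outer_diameter = dura_outer_diameter,
    dura_thickness = dura_thickness,
    csf_outer_diameter = csf_outer_diameter,
    csf_thickness = csf_thickness,
    cord_diameter = cord_diameter,
    tumour_diameter = tumour_diameter,
    tumour_height = tumour_height,
    n_vertebrae = as.integer(n_vertebrae),
    tip_face_diameter = tip_face_diameter
  )
  class(g) <- "cusa_geometry"
  validate_geometry(g)
  g
}

#' Reference geometry of the modelled cervical segment
#'
#' Returns the default [geometry_config()], i.e. the dimensions of the
#' reference C3--C7 model (90 mm segment, 14 mm vertebrae, 4 mm discs,
#' 12/11.4/11/9 mm coaxial layer diameters, 7 x 25 mm tumour).
#' @return a `cusa_geometry` object.
#' @export
default_geometry <- function() geometry_config()

#' Reduced toy geometry for fast tests
#'
#' A single-vertebra segment with the same layer structure, used as a
#' cheap fixture for the meshing and solver stages.
#' @param total_height segment height (mm).
#' @param tumour_height tumour height (mm).
#' @return a `cusa_geometry` object.
#' @export
toy_geometry <- function(total_height = 20, tumour_height = 8) {
  geometry_config(total_height = total_height,
                  vertebra_body_height = 14,
                  tumour_height = tumour_height,
                  n_vertebrae = 1)
}

# numeric tolerance for the layer-nesting identities (mm)
.nest_tol <- 1e-9

validate_geometry <- function(g) {
  num <- unlist(g[setdiff(names(g), "n_vertebrae")])
  if (any(!is.finite(num)) || any(num <= 0))
    stop("geometry error: all dimensions must be finite and strictly positive")
  if (g$n_vertebrae < 1) stop("geometry error: n_vertebrae must be >= 1")
  nest <- function(outer, thick, inner, pair) {
    if (abs(g[[outer]] - 2 * g[[thick]] - g[[inner]]) > .nest_tol)
      stop(sprintf("geometry error: layer nesting violated between %s (%g - 2*%g) and %s (%g)",
                   pair[1], g[[outer]], g[[thick]], pair[2], g[[inner]]))
  }
  nest("fat_outer_diameter", "fat_thickness", "dura_outer_diameter",
       c("epidural_fat", "dura_mater"))
  nest("dura_outer_diameter", "dura_thickness", "csf_outer_diameter",
       c("dura_mater", "csf"))
  nest("csf_outer_diameter", "csf_thickness", "cord_diameter",
       c("csf", "spinal_cord"))
  if (g$tumour_diameter >= g$cord_diameter)
    stop("geometry error: layer nesting violated between tumour and spinal_cord (tumour_diameter must be < cord_diameter)")
  if (g$tip_face_diameter >= g$tumour_diameter)
    stop("geometry error: tip_face_diameter must be < tumour_diameter")
  if (abs(g$fat_outer_diameter - g$cavity_diameter) > .nest_tol)
    stop("geometry error: epidural fat must fill the vertebral cavity (fat_outer_diameter == cavity_diameter)")
  parts <- g$n_vertebrae * g$vertebra_body_height +
    (g$n_vertebrae - 1) * g$disc_height
  if (parts > g$total_height + .nest_tol)
    stop(sprintf("geometry error: vertebrae + discs (%g mm) exceed total_height (%g mm)",
                 parts, g$total_height))
  if (g$tumour_height >= g$total_height)
    stop("geometry error: tumour_height must be < total_height")
  invisible(g)
}

#' @export
print.cusa_geometry <- function(x, ...) {
  cat("<cusa_geometry>", x$n_vertebrae, "vertebrae,",
      x$total_height, "mm segment, tumour",
      x$tumour_diameter, "x", x$tumour_height, "mm\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# materials

#' Tissue material properties
#'
#' Properties are stored on their conventional published scales: density in
#' g/cm^3, Young's modulus in MPa, thermal conductivity in W/(m C), heat
#' capacity in J/(kg C).  Use [material_si()] to convert to SI for assembly.
#'
#' @param density g/cm^3.
#' @param youngs_modulus MPa.
#' @param poisson_ratio dimensionless, in \[0, 0.5).
#' @param thermal_conductivity W/(m C).
#' @param heat_capacity J/(kg C).
#' @return an object of class `cusa_material`.
#' @export
material_properties <- function(density, youngs_modulus, poisson_ratio,
                                thermal_conductivity, heat_capacity) {
  stopifnot(is.finite(density), density > 0,
            is.finite(youngs_modulus), youngs_modulus > 0,
            is.finite(poisson_ratio), poisson_ratio >= 0, poisson_ratio < 0.5,
            is.finite(thermal_conductivity), thermal_conductivity > 0,
            is.finite(heat_capacity), heat_capacity > 0)
  structure(list(density = density,
                 youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio,
                 thermal_conductivity = thermal_conductivity,
                 heat_capacity = heat_capacity),
            class = "cusa_material")
}

#' Reference material registry for the seven tissue classes
#'
#' Mechanical and thermal properties at the physiological reference
#' temperature of 37 C for bone, intervertebral disc, epidural fat, dura
#' mater, CSF (treated as a very soft solid), spinal cord and tumour
#' (glioma).  Values are on the printed scales of
#' [material_properties()].
#'
#' @return named list of `cusa_material`, keyed by tissue class
#'   (`bone`, `disc`, `fat`, `dura`, `csf`, `cord`, `tumour`).
#' @export
default_materials <- function() {
  list(
    bone   = material_properties(0.131, 7600,      0.3,    0.68, 1313),
    disc   = material_properties(1.1,   500,       0.3,    0.49, 3568),
    fat    = material_properties(0.911, 3,         0.49,   0.2,  2348),
    dura   = material_properties(1.174, 31.5,      0.3,    0.44, 3364),
    csf    = material_properties(1,     1e-3,      0.4887, 0.57, 4096),
    cord   = material_properties(1.075, 40.12e-3,  0.49,   0.51, 3630),
    tumour = material_properties(1.075, 1.8e-3,    0.3,    0.5,  3621)
  )
}

#' Convert a material to SI units
#'
#' @param m a `cusa_material`.
#' @return list with `rho` (kg/m^3), `E` (Pa), `nu`, `k` (W/(m C)),
#'   `cp` (J/(kg C)).
#' @export
material_si <- function(m) {
  list(rho = 1000 * m$density,
       E = 1e6 * m$youngs_modulus,
       nu = m$poisson_ratio,
       k = m$thermal_conductivity,
       cp = m$heat_capacity)
}

#' Map a mesh region tag to its tissue class
#'
#' Region tags `vertebra_1..n` map to `bone`, `disc_1..n-1` to `disc`,
#' `epidural_fat` to `fat`, `dura_mater` to `dura`, `csf`, `spinal_cord`
#' and `tumour` to themselves.
#' @param tag character vector of region tags.
#' @return character vector of tissue classes.
#' @export
region_tissue <- function(tag) {
  out <- tag
  out[grepl("^vertebra_", tag)] <- "bone"
  out[grepl("^disc_", tag)] <- "disc"
  out[tag == "epidural_fat"] <- "fat"
  out[tag == "dura_mater"] <- "dura"
  out[tag == "spinal_cord"] <- "cord"
  out
}

# ---------------------------------------------------------------------------
# load cases

#' Map a CUSA power setting to a peak-to-peak tip amplitude
#'
#' The device amplitude grows linearly with the front-panel power setting
#' up to the 355 um maximum of the handpiece/tip assembly, with a floor at
#' the 35 um transducer stroke: `max(35, 355 * power/100)` um peak-to-peak.
#'
#' @param power_percent power setting in (0, 100].
#' @return peak-to-peak displacement in um.
#' @export
power_to_amplitude <- function(power_percent) {
  if (!is.numeric(power_percent) || any(!is.finite(power_percent)) ||
      any(power_percent <= 0) || any(power_percent > 100))
    stop("power_percent must lie in (0, 100]")
  pmax(35, 355 * power_percent / 100)
}

#' Define a harmonic load case for the vibrating tip
#'
#' The tip imposes a sinusoidal displacement along the drive axis (model
#' y, normal to the tumour surface).  Solvers use the sinusoid amplitude
#' `displacement_pp / 2`; the device setting is quoted peak-to-peak.
#'
#' @param displacement_pp peak-to-peak displacement (um), in the 35--355 um
#'   device range.
#' @param frequency drive frequency in kHz; the device offers 23 and
#'   36 kHz handpieces.
#' @param power_percent optional power setting echo (%).
#' @param drive_axis unit drive direction in model coordinates.
#' @return an object of class `cusa_load_case` with fields
#'   `displacement_pp` (um), `amplitude` (um), `frequency` (kHz),
#'   `angular_frequency` (rad/s), `drive_axis`, `power_percent`.
#' @export
load_case <- function(displacement_pp, frequency = 36,
                      power_percent = NULL, drive_axis = c(0, 1, 0)) {
  if (!is.finite(displacement_pp) ||
      displacement_pp < 35 || displacement_pp > 355)
    stop("displacement_pp must lie in the 35-355 um device range")
  if (!frequency %in% c(23, 36))
    stop("frequency must be 23 or 36 kHz (available handpieces)")
  drive_axis <- drive_axis / sqrt(sum(drive_axis^2))
  structure(list(displacement_pp = displacement_pp,
                 amplitude = displacement_pp / 2,
                 frequency = frequency,
                 angular_frequency = 2 * pi * frequency * 1e3,
                 drive_axis = drive_axis,
                 power_percent = power_percent,
                 Q = NULL, A = NULL, label = NULL),
            class = "cusa_load_case")
}

#' Named reference load-case presets
#'
#' The two reference operating points: 70 um peak-to-peak (20% power) and
#' 213 um peak-to-peak (60% power), both at 36 kHz.  Each preset carries
#' the published radiated power `Q` (W) and tumour surface area `A` (m^2)
#' for that operating point, so the thermal stage can be driven by
#' `q = Q/A` without depending on the acoustic medium assumed by the
#' equivalent-radiated-power estimate.
#'
#' @param name `"paper-70um"` or `"paper-213um"`.
#' @return a `cusa_load_case` with `Q` and `A` fields set.
#' @export
load_case_preset <- function(name = c("paper-70um", "paper-213um")) {
  name <- match.arg(name)
  lc <- switch(name,
    "paper-70um"  = load_case(70, 36, power_percent = 20),
    "paper-213um" = load_case(213, 36, power_percent = 60))
  lc$Q <- switch(name, "paper-70um" = 0.3907, "paper-213um" = 3.6579)
  lc$A <- 6.5742e-4
  lc$label <- name
  lc
}

#' @export
print.cusa_load_case <- function(x, ...) {
  cat(sprintf("<cusa_load_case> %g um pp @ %g kHz (amplitude %g um)\n",
              x$displacement_pp, x$frequency, x$amplitude))
  invisible(x)
}

# ---------------------------------------------------------------------------
# labelled solid model

#' Build the labelled solid model from a geometry configuration
#'
#' Resolves the parametric geometry into tagged solids: `n` vertebrae,
#' `n - 1` intervertebral discs, the coaxial epidural-fat / dura / CSF /
#' cord layers and the embedded tumour, together with the named surfaces
#' used by the solvers (device tip application face, fixed supports on the
#' outer vertebrae, convection on the exposed outer boundary).
#'
#' The vertebra cross-section is a cylindrical posterior arch ring (outer
#' radius `arch_outer_radius`) around the cavity, merged with an
#' elliptical body footprint whose mediolateral/anteroposterior widths
#' come from the configuration; the body centre is offset anteriorly from
#' the cavity axis.  The tumour is centred on the segment axis at the
#' C4--C5 disc mid-plane (segment mid-height when `n_vertebrae < 4`).
#' The end-cap pads absorbing the slack between the summed part heights
#' and the total height are merged into the two outer vertebrae.
#'
#' @param geometry a `cusa_geometry`.
#' @param arch_outer_radius outer radius of the posterior arch ring (mm).
#' @param body_offset anterior offset of the elliptical body centre from
#'   the cavity axis (mm).
#' @return an object of class `cusa_model` with fields `geometry`,
#'   `radii` (named outer radii of the coaxial layers, mm), `z_bands`
#'   (data.frame of axial bands per bone/disc region), `regions` (all
#'   region tags), `tumour_centre`, `tumour_z`, `tip_centre`,
#'   `drive_axis`, `arch_outer_radius`, `ellipse` parameters.
#' @export
build_model <- function(geometry = default_geometry(),
                        arch_outer_radius = 8,
                        body_offset = 5) {
  g <- validate_geometry(geometry)
  n <- g$n_vertebrae
  radii <- c(tumour = g$tumour_diameter / 2,
             cord = g$cord_diameter / 2,
             csf = g$csf_outer_diameter / 2,
             dura = g$dura_outer_diameter / 2,
             fat = g$fat_outer_diameter / 2)
  if (any(diff(radii) <= 0))
    stop("geometry error: coaxial layer radii must increase outward")
  if (arch_outer_radius <= radii[["fat"]])
    stop("geometry error: arch_outer_radius must exceed the cavity radius")

  parts <- n * g$vertebra_body_height + (n - 1) * g$disc_height
  pad <- (g$total_height - parts) / 2
  # axial bands, counted from the top of the segment (vertebra_1 topmost);
  # the end pads are merged into the two outer vertebrae
  tags <- character(0); z0 <- numeric(0); z1 <- numeric(0)
  ztop <- g$total_height
  zcur <- ztop - pad
  for (i in seq_len(n)) {
    lo <- zcur - g$vertebra_body_height
    hi <- if (i == 1) ztop else zcur
    if (i == n) lo <- 0
    tags <- c(tags, paste0("vertebra_", i)); z0 <- c(z0, lo); z1 <- c(z1, hi)
    zcur <- zcur - g$vertebra_body_height
    if (i < n) {
      tags <- c(tags, paste0("disc_", i))
      z0 <- c(z0, zcur - g$disc_height); z1 <- c(z1, zcur)
      zcur <- zcur - g$disc_height
    }
  }
  z_bands <- data.frame(region = tags, z0 = z0, z1 = z1,
                        stringsAsFactors = FALSE)

  # tumour centre: mid-plane of the disc between vertebra 2 and 3
  # (C4-C5 for the 5-vertebra reference model), else segment mid-height
  zc <- if (n >= 4) mean(unlist(z_bands[z_bands$region == "disc_2",
                                        c("z0", "z1")]))
        else g$total_height / 2
  tum_z <- c(zc - g$tumour_height / 2, zc + g$tumour_height / 2)
  if (tum_z[1] < 0 || tum_z[2] > g$total_height)
    stop("geometry error: tumour does not fit axially inside the segment")

  regions <- c(z_bands$region, "epidural_fat", "dura_mater", "csf",
               "spinal_cord", "tumour")
  structure(list(
    geometry = g,
    radii = radii,
    z_bands = z_bands,
    regions = regions,
    tumour_centre = c(0, 0, zc),
    tumour_z = tum_z,
    tip_centre = c(0, radii[["tumour"]], zc),
    tip_radius = g$tip_face_diameter / 2,
    drive_axis = c(0, 1, 0),
    arch_outer_radius = arch_outer_radius,
    ellipse = list(a = g$vertebra_ml_width / 2, b = g$vertebra_ap_width / 2,
                   centre_y = -body_offset)
  ), class = "cusa_model")
}

#' @export
print.cusa_model <- function(x, ...) {
  cat("<cusa_model>", length(x$regions), "regions;",
      "tumour centre z =", x$tumour_centre[3], "mm\n")
  invisible(x)
}

# outer cross-section radius of the bone/disc annulus as a function of
# theta (rad, measured from +x; +y = dorsal): posterior arch ring merged
# with the anteriorly offset elliptical body footprint
outer_radius <- function(model, theta) {
  a <- model$ellipse$a; b <- model$ellipse$b; c0 <- -model$ellipse$centre_y
  A <- (cos(theta) / a)^2 + (sin(theta) / b)^2
  B <- 2 * c0 * sin(theta) / b^2
  C <- c0^2 / b^2 - 1
  disc <- B^2 - 4 * A * C
  rell <- ifelse(disc >= 0, (-B + sqrt(pmax(disc, 0))) / (2 * A), 0)
  pmax(model$arch_outer_radius, rell)
}

# analytic cross-section area of the bone/disc annulus (mm^2), by
# quadrature over theta (independent of any mesh)
annulus_area <- function(model, n = 20000) {
  th <- (seq_len(n) - 0.5) / n * 2 * pi
  r <- outer_radius(model, th)
  sum(r^2) / 2 * (2 * pi / n) - pi * model$radii[["fat"]]^2
}

#' Analytic volume of the labelled model and its regions
#'
#' Closed-form (core layers) and quadrature (bone/disc annulus) volumes of
#' every region, independent of any mesh; used as the reference for the
#' mesh volume-partition check.
#' @param model a `cusa_model`.
#' @return named numeric vector of volumes (mm^3), plus a `"total"` entry.
#' @export
model_volume <- function(model) {
  g <- model$geometry
  r <- model$radii
  ann <- annulus_area(model)
  zb <- model$z_bands
  vols <- (zb$z1 - zb$z0) * ann
  names(vols) <- zb$region
  h <- g$total_height
  tum <- pi * r[["tumour"]]^2 * g$tumour_height
  core <- c(
    epidural_fat = pi * (r[["fat"]]^2 - r[["dura"]]^2) * h,
    dura_mater = pi * (r[["dura"]]^2 - r[["csf"]]^2) * h,
    csf = pi * (r[["csf"]]^2 - r[["cord"]]^2) * h,
    spinal_cord = pi * r[["cord"]]^2 * h - tum,
    tumour = tum)
  out <- c(vols, core)
  c(out, total = sum(out))
}

#' Surface area of the tumour boundary
#'
#' Three modes: `"closed_form"` returns the sharp-cylinder area
#' `2*pi*r^2 + 2*pi*r*h` of the modelled tumour; `"reference"` returns the
#' published constant 6.5742e-4 m^2 for the smoothed-cylinder tumour used
#' in the equivalent-radiated-power flux conversion (the fillet geometry
#' behind that value is not parameterised); `"mesh"` sums the facet areas
#' of the tumour boundary on a supplied mesh.
#'
#' @param model a `cusa_model`.
#' @param mode one of `"closed_form"`, `"reference"`, `"mesh"`.
#' @param mesh a `cusa_mesh`, required for `mode = "mesh"`.
#' @return area in m^2.
#' @export
tumour_surface_area <- function(model, mode = c("closed_form", "reference",
                                                "mesh"),
                                mesh = NULL) {
  mode <- match.arg(mode)
  if (!"tumour" %in% model$regions)
    stop("lookup error: model has no tumour region")
  if (mode == "reference") return(6.5742e-4)
  r <- model$radii[["tumour"]]
  h <- model$geometry$tumour_height
  if (mode == "closed_form") return((2 * pi * r^2 + 2 * pi * r * h) * 1e-6)
  if (is.null(mesh)) stop("mode = 'mesh' requires a mesh")
  extract_surface(mesh, "tumour")$area * 1e-6
}
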