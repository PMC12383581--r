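#' Acoustic impedance of the radiating medium
#'
#' The equivalent-radiated-power (ERP) estimate treats the vibrating
#' surface as a piston radiating into a fluid of characteristic impedance
#' `rho_f * c_f`.  The default is air at room conditions.
#'
#' @param fluid_density kg/m^3.
#' @param sound_speed m/s.
#' @return an object of class `cusa_impedance` with the characteristic
#'   impedance in `rho_c` (Pa s/m).
#' @export
fluid_impedance <- function(fluid_density = 1.225, sound_speed = 343) {
  stopifnot(fluid_density > 0, sound_speed > 0)
  structure(list(fluid_density = fluid_density, sound_speed = sound_speed,
                 rho_c = fluid_density * sound_speed),
            class = "cusa_impedance")
}

#' Normal velocity amplitude on a facet set
#'
#' For a harmonic solution at angular frequency omega, the normal velocity
#' amplitude at each facet centroid is `|omega * u . n|`, with `u` the
#' (complex) facet-average displacement and `n` the facet normal.  Facets
#' must lie on a surface of the mesh (exterior boundary or an interface
#' between two regions); facets buried inside a single region are
#' rejected.
#'
#' @param solution a `cusa_harmonic` solution (displacements in m).
#' @param mesh the `cusa_mesh` the solution lives on.
#' @param surface a facet-set/surface as returned by [extract_surface()],
#'   or a name accepted by it.
#' @return list with `v_n` (m/s per facet), `areas` (m^2), `faces`.
#' @export
surface_normal_velocity <- function(solution, mesh, surface) {
  if (is.character(surface)) surface <- extract_surface(mesh, surface)
  faces <- surface$faces
  # reject facets interior to a single region
  tf <- tet_faces(mesh$tets)
  key_all <- face_key_fast(tf$faces)
  reg <- mesh$region[tf$tet]
  o <- order(key_all)
  k <- key_all[o]; r <- reg[o]
  n <- length(k)
  pair_same <- c(k[-1] == k[-n] & r[-1] == r[-n], FALSE)
  interior_keys <- unique(k[pair_same])
  key_f <- face_key_fast(faces)
  if (any(key_f %in% interior_keys))
    stop("facets interior to a region have no surface normal velocity")
  nrm <- triangle_normals(mesh$nodes, faces)
  ar <- triangle_areas(mesh$nodes, faces) * 1e-6   # mm^2 -> m^2
  u <- solution$u
  uc <- (u[faces[, 1], , drop = FALSE] + u[faces[, 2], , drop = FALSE] +
           u[faces[, 3], , drop = FALSE]) / 3
  un <- uc[, 1] * nrm[, 1] + uc[, 2] * nrm[, 2] + uc[, 3] * nrm[, 3]
  omega <- solution$load_case$angular_frequency
  list(v_n = omega * Mod(un), areas = ar, faces = faces)
}

#' Equivalent radiated power of a vibrating surface
#'
#' `Q = 1/2 * rho_f c_f * sum_i A_i v_{n,i}^2`: the acoustic power a
#' piston with the given facet normal-velocity amplitudes would radiate
#' into the impedance medium.  Here it serves as the dissipated-heat
#' budget of the vibrating tumour surface.
#'
#' @param velocities facet normal-velocity amplitudes (m/s).
#' @param facet_areas facet areas (m^2), aligned with `velocities`.
#' @param impedance a [fluid_impedance()].
#' @param frequency optional frequency echo (kHz).
#' @return an object of class `cusa_radiated_power` with fields `Q` (W),
#'   `impedance`, `frequency`.
#' @export
compute_erp <- function(velocities, facet_areas, impedance = fluid_impedance(),
                        frequency = NULL) {
  if (length(velocities) != length(facet_areas))
    stop("velocities and facet_areas must be aligned")
  if (any(facet_areas < 0)) stop("negative facet area")
  Q <- 0.5 * impedance$rho_c * sum(facet_areas * velocities^2)
  structure(list(Q = Q, impedance = impedance, frequency = frequency),
            class = "cusa_radiated_power")
}

#' Convert radiated power to a surface heat flux
#'
#' `q = Q / A`: the radiated (dissipated) power divided by the reference
#' tumour surface area gives the heat-flux density applied to the tip
#' application face.
#'
#' @param Q radiated power (W), >= 0.
#' @param A reference surface area (m^2), > 0.
#' @return an object of class `cusa_heat_source` with fields `q` (W/m^2),
#'   `A` (m^2), `Q` (W).
#' @export
flux_from_power <- function(Q, A) {
  if (!is.finite(A) || A <= 0) stop("domain error: surface area A must be > 0")
  if (!is.finite(Q) || Q < 0) stop("domain error: radiated power Q must be >= 0")
  structure(list(q = Q / A, A = A, Q = Q), class = "cusa_heat_source")
}
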