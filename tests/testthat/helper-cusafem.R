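# Shared fixtures and session-level caches.  The full-anatomy pipeline is
# expensive (mesh + harmonic + thermal ~ 1 min), so it is built lazily
# once and reused by the mesh, harmonic and acceptance tests.

.cache <- new.env(parent = emptyenv())

full_ctx <- function() {
  if (is.null(.cache$ctx)) {
    .cache$ctx <- simulation_context(simulation_config())
  }
  .cache$ctx
}

full_mesh <- function() cusafem:::ctx_mesh(full_ctx())

full_case <- function(preset) {
  key <- paste0("case_", preset)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- run_case(full_ctx(), preset, transient = FALSE)
  .cache[[key]]
}

toy_ctx <- function() {
  if (is.null(.cache$toy)) .cache$toy <- simulation_context(toy_config())
  .cache$toy
}

# single-material registry for fixtures (unit-ish properties)
unit_materials <- function(E = 1, nu = 0.3, rho = 1, k = 1, cp = 1) {
  list(solid = material_properties(rho, E, nu, k, cp))
}

# random valid geometry configs for property tests: sample thicknesses
# and derive nested diameters so the layer identities hold by
# construction
random_geometry <- function() {
  cord <- runif(1, 6, 10)
  csf_t <- runif(1, 0.5, 1.5)
  dura_t <- runif(1, 0.1, 0.4)
  fat_t <- runif(1, 0.2, 0.6)
  csf_d <- cord + 2 * csf_t
  dura_d <- csf_d + 2 * dura_t
  fat_d <- dura_d + 2 * fat_t
  geometry_config(
    cavity_diameter = fat_d, fat_outer_diameter = fat_d,
    fat_thickness = fat_t, dura_outer_diameter = dura_d,
    dura_thickness = dura_t, csf_outer_diameter = csf_d,
    csf_thickness = csf_t, cord_diameter = cord,
    tumour_diameter = runif(1, 3, cord - 1),
    tumour_height = runif(1, 10, 30),
    n_vertebrae = sample(3:5, 1))
}
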