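test_that("toy model meshes quickly into a small valid mesh", {
  cfg <- toy_config()
  t0 <- Sys.time()
  mesh <- generate_mesh(build_model(cfg$geometry), cfg$sizing)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 5)
  expect_lt(nrow(mesh$tets), 2000)
  q <- mesh_quality(mesh)
  expect_gt(q$min_dihedral_deg, 0)
  expect_true(all(is.finite(c(q$min_aspect, q$max_aspect))))
  # every element carries exactly one known region tag
  expect_true(all(mesh$region %in% build_model(cfg$geometry)$regions))
  # named facet sets are non-empty
  expect_gt(nrow(mesh$sets$convection$faces), 0)
  expect_gt(nrow(mesh$sets$fixed_support$faces), 0)
  expect_gt(nrow(mesh$sets$tip_application_face$faces), 0)
  expect_gte(length(mesh$tip_nodes), 1)
})

test_that("region volumes partition the mesh and match the analytic model volume", {
  mesh <- full_mesh()
  q <- mesh_quality(mesh)
  # partition identity: region volumes sum exactly to the total
  expect_equal(sum(q$region_volumes), q$total_volume, tolerance = 1e-12)
  v <- model_volume(mesh$model)
  expect_equal(q$total_volume, v[["total"]], tolerance = 0.01)
  # core layers are meshed with exact cross-section areas
  expect_equal(unname(q$region_volumes["csf"]), unname(v["csf"]),
               tolerance = 1e-9)
  expect_equal(unname(q$region_volumes["tumour"]), unname(v["tumour"]),
               tolerance = 1e-9)
  # tumour volume matches the cylinder closed form
  expect_equal(unname(q$region_volumes["tumour"]), pi * 3.5^2 * 25,
               tolerance = 0.01)
})

test_that("default sizing yields the reference-scale element count and tip face", {
  mesh <- full_mesh()
  expect_gte(nrow(mesh$tets), 25000)
  expect_lte(nrow(mesh$tets), 100000)
  tip <- extract_surface(mesh, "tip_application_face")
  expect_equal(tip$area, pi, tolerance = 0.05)
})

test_that("quality metrics reproduce the regular-tetrahedron dihedral angle", {
  q <- mesh_quality(fixture_regular_tet())
  expect_equal(q$min_dihedral_deg, 70.528779, tolerance = 1e-6)
  expect_equal(q$min_aspect, 1, tolerance = 1e-12)
  expect_error(mesh_quality(structure(list(tets = NULL), class = "cusa_mesh")),
               "empty")
})

test_that("unit-cube fixture meshes to exact volume and face areas", {
  cube <- fixture_unit_cube(3)
  q <- mesh_quality(cube)
  expect_equal(q$total_volume, 1, tolerance = 1e-12)
  f <- extract_surface(cube, "xmin")
  expect_equal(f$area, 1, tolerance = 1e-12)
  expect_error(extract_surface(cube, "no_such_surface"), "unknown")
})

test_that("tip refinement is monotone, conserves region tags and converges surface areas", {
  g <- toy_geometry()
  m <- build_model(g)
  sizes <- c(3, 1.5, 0.75)
  meshes <- lapply(sizes, function(s)
    generate_mesh(m, mesh_sizing(global_size = 12, influence_size = 6,
                                 tip_face_size = s, influence_radius = 4)))
  counts <- vapply(meshes, function(x) nrow(x$tets), 0)
  expect_true(all(diff(counts) >= 0))
  # region tags under refinement: identical volume fractions per region
  vol_frac <- lapply(meshes, function(x) {
    q <- mesh_quality(x)
    q$region_volumes / q$total_volume
  })
  for (i in 2:3)
    expect_equal(vol_frac[[i]], vol_frac[[1]], tolerance = 0.02)
  # facet areas Cauchy-converge: tip face and tumour boundary
  tips <- vapply(meshes, function(x) x$sets$tip_application_face$area, 0)
  expect_lt(abs(tips[3] - tips[2]) / tips[2], 0.02)
  tums <- vapply(meshes, function(x) extract_surface(x, "tumour")$area, 0)
  expect_lt(abs(tums[3] - tums[2]) / tums[2], 0.02)
  # and the tumour boundary approaches the modelled closed form
  expect_equal(tums[3] * 1e-6, tumour_surface_area(m, "closed_form"),
               tolerance = 0.02)
})

test_that("sizing contradictions and broken geometry are rejected", {
  expect_error(mesh_sizing(global_size = 1, influence_size = 2),
               "sizing contradiction")
  expect_error(mesh_sizing(tip_face_size = -1))
})

test_that("MSH round-trip preserves nodes, elements and region tags", {
  cfg <- toy_config()
  mesh <- generate_mesh(build_model(cfg$geometry), cfg$sizing)
  path <- tempfile(fileext = ".msh")
  write_msh(mesh, path)
  back <- read_msh(path)
  expect_equal(back$nodes, mesh$nodes, ignore_attr = TRUE)
  # same multiset of (element, region): compare region-sorted connectivity
  o1 <- order(mesh$region, mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3])
  o2 <- order(back$region, back$tets[, 1], back$tets[, 2], back$tets[, 3])
  expect_equal(unname(back$tets[o2, ]), unname(mesh$tets[o1, ]))
  expect_equal(back$region[o2], mesh$region[o1])
  vtu <- tempfile(fileext = ".vtu")
  write_vtu(mesh, vtu, point_data = list(z = mesh$nodes[, 3]))
  expect_true(file.exists(vtu))
  expect_match(readLines(vtu, n = 2)[2], "UnstructuredGrid")
})
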