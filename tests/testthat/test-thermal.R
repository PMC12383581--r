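test_that("thermal assembly matches the dense oracle with the expected structure", {
  mats <- unit_materials(k = 2.5, rho = 4, cp = 100)
  for (mesh in list(fixture_single_tet(), fixture_unit_cube(2))) {
    ops <- assemble_thermal(mesh, mats)
    dn <- dense_reference_solve(mesh, "thermal", mats)
    expect_lt(max(abs(as.matrix(ops$K) - dn$K)) / max(abs(dn$K)), 1e-12)
    expect_equal(ops$C, dn$M, tolerance = 1e-12)
    # constant fields are in the null space
    n <- nrow(mesh$nodes)
    expect_lt(max(abs(ops$K %*% rep(1, n))), 1e-12 * max(abs(ops$K)))
  }
  # total heat capacity = sum rho c_p V
  cube <- fixture_unit_cube(2)
  ops <- assemble_thermal(cube, mats)
  expect_equal(sum(ops$C), 4000 * 100 * 1e-9, tolerance = 1e-12)
  expect_error(assemble_thermal(cube, list()), "missing material")
})

test_that("no heating and a neutral ambient give a uniform 37 C field", {
  ctx <- toy_ctx()
  mesh <- cusafem:::ctx_mesh(ctx)
  ops <- cusafem:::ctx_thermal_ops(ctx)
  bcs <- thermal_bcs(mesh, q = 0, h = 10, t_amb = 37, t_ref = 37)
  f <- solve_steady(ops, bcs)
  expect_equal(f$T, rep(37, length(f$T)), tolerance = 1e-10)
  tr <- solve_transient(ops, bcs, duration = 0.1, dt = 0.02)
  expect_equal(max(abs(tr$series - 37)), 0, tolerance = 1e-10)
})

test_that("1-D slab with flux and convection reproduces the closed-form profile", {
  bar <- fixture_bar(L = 10, n = 20, w = 1, nw = 2)
  kc <- 0.5; q0 <- 500; h <- 25; tamb <- 37
  ops <- assemble_thermal(bar, unit_materials(k = kc, rho = 1, cp = 1000))
  bcs <- thermal_bcs(bar, q = q0, h = h, t_amb = tamb,
                     flux_set = "xmin", convection_set = "xmax")
  f <- solve_steady(ops, bcs)
  pr <- slab_problem(L = 0.01, k = kc, q0 = q0, h = h, t_amb = tamb)
  Texp <- slab_steady_profile(pr, bar$nodes[, 1] * 1e-3)
  expect_equal(f$T, Texp, tolerance = 1e-8)
  # surface balance limits of the oracle itself
  expect_equal(slab_steady_profile(pr, pr$L), tamb + q0 / h)
  expect_equal(slab_steady_profile(slab_problem(0.01, kc, 0, h, tamb), 0.003),
               tamb)
  # discrete energy balance: convective loss equals injected power
  inj <- q0 * bcs$flux_area
  expect_equal(convective_loss(f, bcs), inj, tolerance = 1e-10)
})

test_that("mixed-boundary cube agrees with the dense reference solve", {
  cube <- fixture_unit_cube(2)
  mats <- unit_materials(k = 1.3)
  ops <- assemble_thermal(cube, mats)
  bcs <- thermal_bcs(cube, q = 800, h = 15, t_amb = 35,
                     flux_set = "zmin", convection_set = "zmax")
  f <- solve_steady(ops, bcs)
  dn <- dense_reference_solve(cube, "thermal", mats,
                              robin_diag = bcs$Hdiag,
                              load = bcs$f_flux + bcs$f_robin)
  expect_lt(max(abs(f$T - dn$x)) / max(abs(dn$x)), 1e-10)
})

test_that("transient matches the lumped-capacitance decay and approaches steady state monotonically", {
  # high conductivity -> quasi-uniform body; convection on all faces
  cube <- fixture_unit_cube(2)
  kc <- 500; rho <- 1; cp <- 1000; h <- 20; tamb <- 37; t0 <- 47
  ops <- assemble_thermal(cube, unit_materials(k = kc, rho = rho, cp = cp))
  bcs <- thermal_bcs(cube, q = 0, h = h, t_amb = tamb, t_ref = t0,
                     convection_set = "boundary")
  tr <- solve_transient(ops, bcs, duration = 2, dt = 0.005)
  A_s <- 6 * 1e-6; V_s <- 1e-9
  tau <- rho * 1000 * cp * V_s / (h * A_s)
  Texp <- tamb + (t0 - tamb) * exp(-tr$times / tau)
  Tmean <- colSums(tr$series * ops$C) / sum(ops$C)
  expect_equal(Tmean, Texp, tolerance = 0.01)
  # monotone relaxation toward the steady (uniform ambient) state
  expect_true(all(diff(apply(tr$series, 2, max)) <= 1e-12))
  # heated toy model: monotone rise, final below steady
  ctx <- toy_ctx()
  mesh <- cusafem:::ctx_mesh(ctx)
  topo <- cusafem:::ctx_thermal_ops(ctx)
  bcs2 <- thermal_bcs(mesh, q = 5567.6, h = 10)
  trh <- solve_transient(topo, bcs2, duration = 1, dt = 0.05)
  mx <- apply(trh$series, 2, max)
  expect_true(all(diff(mx) >= -1e-12))
  st <- solve_steady(topo, bcs2)
  expect_lte(max(trh$T), max(st$T) + 1e-9)
})

test_that("heating without any convection surface is rejected as singular", {
  cube <- fixture_unit_cube(2)
  ops <- assemble_thermal(cube, unit_materials())
  bcs <- thermal_bcs(cube, q = 100, h = 0, flux_set = "zmin")
  expect_error(solve_steady(ops, bcs), "convection")
  expect_error(solve_transient(ops, bcs, duration = 1, dt = -0.1), "dt")
  expect_error(solve_transient(ops, bcs, duration = 0.01, dt = 0.1),
               "duration")
})

test_that("region maxima table aggregates tissues and guards mesh mismatch", {
  ctx <- toy_ctx()
  mesh <- cusafem:::ctx_mesh(ctx)
  n <- nrow(mesh$nodes)
  uni <- region_max_table(list(a = rep(37, n)), mesh)
  expect_true(all(uni$a == 37))
  expect_true(all(c("tumour", "cord", "csf", "bone") %in% uni$tissue))
  expect_error(region_max_table(list(a = rep(37, n - 1)), mesh),
               "mismatch")
})
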