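test_that("sparse elastic assembly matches the dense brute-force oracle", {
  mats <- unit_materials(E = 2, nu = 0.25, rho = 3)
  for (mesh in list(fixture_single_tet(), fixture_unit_cube(2))) {
    ops <- assemble_elastic(mesh, mats)
    dn <- dense_reference_solve(mesh, "elastic", mats)
    expect_lt(max(abs(as.matrix(ops$K) - dn$K)) / max(abs(dn$K)), 1e-12)
    expect_equal(ops$M, dn$M, tolerance = 1e-12)
    # exact symmetry
    expect_equal(max(abs(ops$K - Matrix::t(ops$K))), 0)
  }
})

test_that("stiffness annihilates rigid-body motion and mass totals rho V", {
  cube <- fixture_unit_cube(2)
  mats <- unit_materials(E = 5, nu = 0.3, rho = 2.5)
  ops <- assemble_elastic(cube, mats)
  n <- nrow(cube$nodes)
  scale <- max(abs(ops$K))
  for (comp in 1:3) {
    u <- numeric(3 * n); u[seq(comp, 3 * n, by = 3)] <- 1
    expect_lt(max(abs(ops$K %*% u)) / scale, 1e-12)
  }
  x <- cube$nodes * 1e-3
  rot <- as.vector(t(cbind(-x[, 2], x[, 1], 0)))   # linearized z-rotation
  expect_lt(max(abs(ops$K %*% rot)) / scale, 1e-9)
  # total mass = rho * V (per dof direction)
  expect_equal(sum(ops$M) / 3, 2.5 * 1000 * 1e-9, tolerance = 1e-12)
})

test_that("uniform-stretch patch test is exact", {
  cube <- fixture_unit_cube(2)
  ops <- assemble_elastic(cube, unit_materials(nu = 0))
  bnodes <- unique(as.vector(cube$sets$boundary$faces))
  alpha <- 0.05
  dofs <- as.vector(outer(1:3, 3L * (bnodes - 1L), `+`))
  vals <- as.vector(rbind(0, alpha * cube$nodes[bnodes, 2] * 1e-3, 0))
  lc <- load_case(70, 36); lc$angular_frequency <- 0
  sol <- solve_harmonic(ops, lc, loss_factor = 0,
                        dirichlet = list(dof = dofs, value = vals),
                        method = "lu")
  st <- strain_field(sol, ops)
  expect_equal(Re(st$eps[, 2]), rep(alpha, nrow(st$eps)), tolerance = 1e-10)
  expect_equal(max(st$amp[, c(1, 3:6)]), 0, tolerance = 1e-10 * alpha)
})

test_that("static limit of the end-driven bar is the exact linear ramp", {
  bar <- fixture_bar(L = 10, n = 10)
  ops <- assemble_elastic(bar, unit_materials(nu = 0))
  n <- nrow(bar$nodes)
  xmin <- unique(as.vector(bar$sets$xmin$faces))
  xmax <- unique(as.vector(bar$sets$xmax$faces))
  u0 <- 1e-6
  dofs <- c(3L * (xmin - 1L) + 1L, 3L * (xmax - 1L) + 1L,
            3L * (seq_len(n) - 1L) + 2L, 3L * (seq_len(n) - 1L) + 3L)
  vals <- c(rep(0, length(xmin)), rep(u0, length(xmax)), rep(0, 2L * n))
  lc <- load_case(70, 36); lc$angular_frequency <- 0
  sol <- solve_harmonic(ops, lc, loss_factor = 0,
                        dirichlet = list(dof = dofs, value = vals),
                        method = "lu")
  expect_equal(Re(sol$u[, 1]), u0 * bar$nodes[, 1] / 10, tolerance = 1e-10)
  st <- strain_field(sol, ops)
  expect_equal(Re(st$eps[, 1]), rep(u0 / 0.01, nrow(st$eps)),
               tolerance = 1e-10)
})

test_that("harmonic response is linear in the imposed amplitude", {
  ctx <- toy_ctx()
  ops <- cusafem:::ctx_elastic_ops(ctx)
  s1 <- solve_harmonic(ops, load_case(70, 36), loss_factor = 0.1)
  s2 <- solve_harmonic(ops, load_case(140, 36), loss_factor = 0.1)
  expect_equal(s2$u, 2 * s1$u, tolerance = 1e-9)
  st1 <- strain_field(s1, ops); st2 <- strain_field(s2, ops)
  expect_equal(st2$peak$value, 2 * st1$peak$value, tolerance = 1e-9)
})

test_that("prescribed tip displacement is echoed exactly and Krylov matches LU", {
  ctx <- toy_ctx()
  ops <- cusafem:::ctx_elastic_ops(ctx)
  mesh <- cusafem:::ctx_mesh(ctx)
  lc <- load_case(70, 36)
  s_lu <- solve_harmonic(ops, lc, loss_factor = 0.1, method = "lu")
  # constraint fidelity: hard constraint, reproduced to machine precision
  expect_equal(max(Mod(s_lu$u[mesh$tip_nodes, 2] - lc$amplitude * 1e-6)), 0,
               tolerance = 1e-12 * lc$amplitude * 1e-6)
  fix_nodes <- unique(as.vector(mesh$sets$fixed_support$faces))
  expect_equal(max(Mod(s_lu$u[fix_nodes, ])), 0)
  s_kr <- solve_harmonic(ops, lc, loss_factor = 0.1, method = "krylov",
                         tol = 1e-12)
  expect_lt(max(Mod(s_lu$u - s_kr$u)) / max(Mod(s_lu$u)), 1e-9)
})

test_that("undamped MINRES agrees with the dense oracle on an off-resonance fixture", {
  cube <- fixture_unit_cube(2)
  mats <- unit_materials(E = 10, nu = 0.2, rho = 1)
  ops <- assemble_elastic(cube, mats)
  n <- nrow(cube$nodes)
  bnodes <- unique(as.vector(cube$sets$zmin$faces))
  tnodes <- unique(as.vector(cube$sets$zmax$faces))
  u0 <- 1e-6
  dofs <- c(as.vector(outer(1:3, 3L * (bnodes - 1L), `+`)),
            3L * (tnodes - 1L) + 3L)
  vals <- c(rep(0, 3L * length(bnodes)), rep(u0, length(tnodes)))
  lc <- load_case(70, 36)
  omega <- lc$angular_frequency
  for (eta in c(0, 0.1)) {
    s_it <- solve_harmonic(ops, lc, loss_factor = eta,
                           dirichlet = list(dof = dofs, value = vals),
                           method = "krylov", tol = 1e-12)
    dn <- dense_reference_solve(cube, "elastic", mats, omega = omega,
                                loss_factor = eta,
                                dirichlet = list(dof = dofs, value = vals))
    un <- matrix(dn$x, ncol = 3, byrow = TRUE)
    expect_lt(max(Mod(s_it$u - un)) / max(Mod(un)), 1e-10)
  }
})

test_that("a rigid-motion displacement field has zero strain", {
  cube <- fixture_unit_cube(2)
  ops <- assemble_elastic(cube, unit_materials())
  n <- nrow(cube$nodes)
  x <- cube$nodes * 1e-3
  u <- cbind(1e-6 - 2e-6 * x[, 3], 2e-6 + 1e-6 * x[, 3],
             2e-6 * x[, 1] - 1e-6 * x[, 2])  # translation + linearized rotation
  sol <- structure(list(u = u + 0i, load_case = load_case(70, 36)),
                   class = "cusa_harmonic")
  st <- strain_field(sol, ops)
  expect_lt(max(st$amp), 1e-18)
})
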