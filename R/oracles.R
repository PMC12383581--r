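# Independent closed-form and brute-force references used by the test
# suite.  These deliberately do not share assembly code with the main
# solvers: the dense path builds element matrices from explicitly
# inverted shape-function coefficient matrices and full B-matrices.

#' One-dimensional slab conduction problem
#'
#' A slab of thickness `L` with conductivity `k`, uniform inward flux
#' `q0` on the face `x = 0` and convection `(h, t_amb)` on `x = L`.
#' @param L thickness (m).
#' @param k conductivity (W/(m C)).
#' @param q0 flux (W/m^2).
#' @param h film coefficient (W/(m^2 C)).
#' @param t_amb ambient temperature (C).
#' @return an object of class `cusa_slab_problem`.
#' @export
slab_problem <- function(L, k, q0, h, t_amb) {
  stopifnot(L > 0, k > 0, h > 0)
  structure(list(L = L, k = k, q0 = q0, h = h, t_amb = t_amb),
            class = "cusa_slab_problem")
}

#' Closed-form steady profile of the slab problem
#'
#' `T(x) = t_amb + q0/h + q0 (L - x)/k`.
#' @param problem a [slab_problem()].
#' @param x position(s) in \[0, L\] (m).
#' @return temperature(s) in C.
#' @export
slab_steady_profile <- function(problem, x) {
  stopifnot(all(x >= -1e-12), all(x <= problem$L + 1e-12))
  problem$t_amb + problem$q0 / problem$h +
    problem$q0 * (problem$L - x) / problem$k
}

#' Order-of-magnitude peak temperature rise of a heated disc
#'
#' `dT ~ q a / k` for a disc of radius `a` carrying flux `q` on a
#' conductive half-space: a scaling band, not an equality (the exact
#' uniform-flux half-space centre rise is `q a / k`, and an embedded
#' interface heated from both sides is about half that).
#' @param q flux (W/m^2).
#' @param a disc radius (m).
#' @param k conductivity (W/(m C)).
#' @return estimated rise in C.
#' @export
disc_source_peak_estimate <- function(q, a, k) {
  stopifnot(q >= 0, a > 0, k > 0)
  q * a / k
}

#' Closed-form peak strain of a damped plane compressional wave
#'
#' A rigid piston oscillating with amplitude `u0` against a viscoelastic
#' half-space of compressional modulus `M (1 + i eta)` radiates a plane
#' wave `u0 exp(i k y)` whose surface strain amplitude is
#' `|k| u0 = omega u0 sqrt(rho / M) / (1 + eta^2)^(1/4)`.  Independent
#' 1-D reference for the axisymmetric tip submodel.
#' @param material tumour `cusa_material`.
#' @param load_case a `cusa_load_case`.
#' @param loss_factor hysteretic loss factor.
#' @return strain amplitude (dimensionless).
#' @export
rod_wave_peak_strain <- function(material, load_case, loss_factor = 0.1) {
  si <- material_si(material)
  M <- si$E * (1 - si$nu) / ((1 + si$nu) * (1 - 2 * si$nu))
  omega <- load_case$angular_frequency
  u0 <- load_case$amplitude * 1e-6
  omega * u0 * sqrt(si$rho / M) / (1 + loss_factor^2)^(1 / 4)
}

# --- small fixtures ----------------------------------------------------------

#' Single reference tetrahedron fixture
#' @return a one-element `cusa_mesh` (unit right tetrahedron, mm).
#' @export
fixture_single_tet <- function() {
  structure(list(nodes = rbind(c(0, 0, 0), c(1, 0, 0),
                               c(0, 1, 0), c(0, 0, 1)),
                 tets = matrix(1:4, 1), region = "solid",
                 sets = list(), model = NULL, sizing = NULL, alpha = 1),
            class = "cusa_mesh")
}

#' Regular tetrahedron fixture (unit dihedral-angle reference)
#' @return a one-element `cusa_mesh`.
#' @export
fixture_regular_tet <- function() {
  structure(list(nodes = rbind(c(1, 1, 1), c(1, -1, -1),
                               c(-1, -1, 1), c(-1, 1, -1)),
                 tets = matrix(1:4, 1), region = "solid",
                 sets = list(), model = NULL, sizing = NULL, alpha = 1),
            class = "cusa_mesh")
}

#' Unit cube fixture
#' @param n elements per edge.
#' @return a `cusa_mesh` of the unit cube (mm).
#' @export
fixture_unit_cube <- function(n = 2) {
  s <- seq(0, 1, length.out = n + 1)
  box_mesh(s, s, s)
}

#' Bar fixture (quasi-1-D box)
#' @param L length (mm); `n` axial elements; `w` width (mm); `nw` lateral
#'   elements.
#' @return a `cusa_mesh`.
#' @export
fixture_bar <- function(L = 10, n = 10, w = 1, nw = 1) {
  box_mesh(seq(0, L, length.out = n + 1),
           seq(0, w, length.out = nw + 1),
           seq(0, w, length.out = nw + 1))
}

# --- dense reference assembly/solve -----------------------------------------

dense_elastic_element <- function(X, E, nu) {
  # X: 4x3 coords (m); explicit B-matrix route
  P <- cbind(1, X)
  Ci <- solve(P)                 # rows: coefficients; grads = Ci[2:4, ]
  g <- Ci[2:4, , drop = FALSE]   # 3 x 4: d/dx, d/dy, d/dz of N_a
  V <- abs(det(P)) / 6
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    cix <- 3 * (a - 1)
    B[1, cix + 1] <- g[1, a]
    B[2, cix + 2] <- g[2, a]
    B[3, cix + 3] <- g[3, a]
    B[4, cix + 1] <- g[2, a]; B[4, cix + 2] <- g[1, a]
    B[5, cix + 2] <- g[3, a]; B[5, cix + 3] <- g[2, a]
    B[6, cix + 1] <- g[3, a]; B[6, cix + 3] <- g[1, a]
  }
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D) <- c(lam + 2 * mu, lam + 2 * mu, lam + 2 * mu, mu, mu, mu)
  list(K = V * t(B) %*% D %*% B, V = V)
}

dense_thermal_element <- function(X, k) {
  P <- cbind(1, X)
  Ci <- solve(P)
  g <- Ci[2:4, , drop = FALSE]
  V <- abs(det(P)) / 6
  list(K = k * V * t(g) %*% g, V = V)
}

#' Dense brute-force reference solve on a small fixture
#'
#' Assembles the same discrete problem as the sparse pipeline through an
#' independent dense per-element path (explicit shape-function inversion
#' and full B-matrices) and solves it with base dense linear algebra.
#' Restricted to fixtures of at most 1000 degrees of freedom.
#'
#' @param mesh a small `cusa_mesh`.
#' @param physics `"elastic"` or `"thermal"`.
#' @param materials material registry (tissue-keyed, as for assembly).
#' @param omega angular frequency (rad/s) for the elastic dynamic
#'   stiffness `(1 + i eta) K - omega^2 M` (lumped mass).
#' @param loss_factor hysteretic loss factor `eta`.
#' @param dirichlet list with `dof` and `value` (prescribed dofs).
#' @param load nodal load vector (length = n dofs) or `NULL`.
#' @param robin_diag nodal Robin conductances (thermal; length n) or
#'   `NULL`; the load should already include `H T_amb`.
#' @return list with the full solution vector `x`, the assembled dense
#'   `K` and (elastic) lumped mass `M`.
#' @export
dense_reference_solve <- function(mesh, physics = c("elastic", "thermal"),
                                  materials = default_materials(),
                                  omega = 0, loss_factor = 0,
                                  dirichlet = list(dof = integer(0),
                                                   value = numeric(0)),
                                  load = NULL, robin_diag = NULL) {
  physics <- match.arg(physics)
  em <- element_materials(mesh, materials)
  n <- nrow(mesh$nodes)
  ndof <- if (physics == "elastic") 3L * n else n
  if (ndof > 1000) stop("dense reference restricted to <= 1000 dof")
  K <- matrix(0, ndof, ndof)
  Mlump <- numeric(ndof)
  for (e in seq_len(nrow(mesh$tets))) {
    ix <- mesh$tets[e, ]
    X <- mesh$nodes[ix, , drop = FALSE] * 1e-3
    if (physics == "elastic") {
      el <- dense_elastic_element(X, em$E[e], em$nu[e])
      dofs <- as.vector(outer(1:3, 3L * (ix - 1L), `+`))
      K[dofs, dofs] <- K[dofs, dofs] + el$K
      Mlump[dofs] <- Mlump[dofs] + em$rho[e] * el$V / 4
    } else {
      el <- dense_thermal_element(X, em$k[e])
      K[ix, ix] <- K[ix, ix] + el$K
      Mlump[ix] <- Mlump[ix] + em$rho[e] * em$cp[e] * el$V / 4
    }
  }
  A <- if (physics == "elastic") {
    (1 + 1i * loss_factor) * K - omega^2 * diag(Mlump, ndof)
  } else {
    K + diag(if (is.null(robin_diag)) numeric(ndof) else robin_diag, ndof)
  }
  b <- if (is.null(load)) rep(0, ndof) else load
  cd <- dirichlet$dof
  x <- NULL
  if (length(cd)) {
    x <- rep(if (is.complex(A)) 0 + 0i else 0, ndof)
    x[cd] <- dirichlet$value
    free <- setdiff(seq_len(ndof), cd)
    bf <- b[free] - A[free, cd, drop = FALSE] %*% x[cd]
    x[free] <- solve(A[free, free, drop = FALSE], bf)
  } else if (!is.null(load) || !is.null(robin_diag)) {
    x <- solve(A, b)
  }
  list(x = if (is.null(x)) NULL else as.vector(x), K = K, M = Mlump)
}
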