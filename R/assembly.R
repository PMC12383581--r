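# Vectorized P1 (linear tetrahedron) finite-element assembly.
# Geometry is carried in mm and converted to SI metres here, once.

# per-element shape-function gradients (1/m), volumes (m^3)
element_gradients <- function(nodes_mm, tets) {
  X <- nodes_mm * 1e-3
  x1 <- X[tets[, 1], , drop = FALSE]
  d2 <- X[tets[, 2], , drop = FALSE] - x1
  d3 <- X[tets[, 3], , drop = FALSE] - x1
  d4 <- X[tets[, 4], , drop = FALSE] - x1
  # det of [d2; d3; d4] rows
  det <- d2[, 1] * (d3[, 2] * d4[, 3] - d3[, 3] * d4[, 2]) -
    d2[, 2] * (d3[, 1] * d4[, 3] - d3[, 3] * d4[, 1]) +
    d2[, 3] * (d3[, 1] * d4[, 2] - d3[, 2] * d4[, 1])
  V <- det / 6
  # rows of the inverse of D = [d2 | d3 | d4] (columns): grad xi_i is the
  # i-th row of D^{-1}; build via cross products
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  # D^{-1} rows: (d3 x d4)/det, (d4 x d2)/det, (d2 x d3)/det
  g2 <- cr(d3, d4) / det
  g3 <- cr(d4, d2) / det
  g4 <- cr(d2, d3) / det
  g1 <- -(g2 + g3 + g4)
  list(V = V,
       gx = cbind(g1[, 1], g2[, 1], g3[, 1], g4[, 1]),
       gy = cbind(g1[, 2], g2[, 2], g3[, 2], g4[, 2]),
       gz = cbind(g1[, 3], g2[, 3], g3[, 3], g4[, 3]))
}

element_materials <- function(mesh, materials) {
  tis <- region_tissue(mesh$region)
  miss <- setdiff(unique(tis), names(materials))
  if (length(miss))
    stop(sprintf("missing material for region(s): %s",
                 paste(unique(mesh$region[tis %in% miss]), collapse = ", ")))
  si <- lapply(materials, material_si)
  list(tissue = tis,
       E = vapply(si, `[[`, 0, "E")[tis],
       nu = vapply(si, `[[`, 0, "nu")[tis],
       rho = vapply(si, `[[`, 0, "rho")[tis],
       k = vapply(si, `[[`, 0, "k")[tis],
       cp = vapply(si, `[[`, 0, "cp")[tis])
}

#' Assemble linear-elastic stiffness and mass operators
#'
#' Isotropic linear elasticity on linear tetrahedra: the sparse symmetric
#' stiffness matrix (Lame form `lambda g_a g_b^T + mu g_b g_a^T +
#' mu (g_a.g_b) I` per node pair) and a lumped (diagonal, positive) mass.
#' Degrees of freedom are ordered `(node-1)*3 + component`.
#'
#' @param mesh a `cusa_mesh` (coordinates in mm; converted to SI here).
#' @param materials named material registry per tissue class.
#' @return an object of class `cusa_elastic_ops` with fields `K`
#'   (dgCMatrix, N x N), `M` (numeric length N, lumped diagonal),
#'   gradient data, per-element `lambda`, `mu`, `rho`, `V`, and the mesh.
#' @export
assemble_elastic <- function(mesh, materials = default_materials()) {
  em <- element_materials(mesh, materials)
  gr <- element_gradients(mesh$nodes, mesh$tets)
  m <- nrow(mesh$tets); n <- nrow(mesh$nodes)
  lam <- em$E * em$nu / ((1 + em$nu) * (1 - 2 * em$nu))
  mu <- em$E / (2 * (1 + em$nu))
  V <- gr$V
  g <- list(gr$gx, gr$gy, gr$gz)
  tets <- mesh$tets
  nE <- 144L * m
  II <- integer(nE); JJ <- integer(nE); XX <- numeric(nE)
  pos <- 0L
  for (a in 1:4) for (b in 1:4) {
    dot_ab <- gr$gx[, a] * gr$gx[, b] + gr$gy[, a] * gr$gy[, b] +
      gr$gz[, a] * gr$gz[, b]
    for (al in 1:3) for (be in 1:3) {
      val <- V * (lam * g[[al]][, a] * g[[be]][, b] +
                    mu * g[[be]][, a] * g[[al]][, b])
      if (al == be) val <- val + V * mu * dot_ab
      idx <- pos + seq_len(m)
      II[idx] <- 3L * (tets[, a] - 1L) + al
      JJ[idx] <- 3L * (tets[, b] - 1L) + be
      XX[idx] <- val
      pos <- pos + m
    }
  }
  K <- Matrix::sparseMatrix(i = II, j = JJ, x = XX, dims = c(3L * n, 3L * n))
  mlump <- numeric(n)
  for (a in 1:4) {
    tab <- tapply(em$rho * V / 4, tets[, a], sum)
    mlump[as.integer(names(tab))] <- mlump[as.integer(names(tab))] + tab
  }
  M <- rep(mlump, each = 3)
  structure(list(K = K, M = M, grads = gr, V = V, lambda = lam, mu = mu,
                 rho = em$rho, mesh = mesh, n_dof = 3L * n),
            class = "cusa_elastic_ops")
}

#' Assemble heat-conduction and capacity operators
#'
#' Conduction matrix `k V (g_a . g_b)` on linear tetrahedra (symmetric
#' positive-semidefinite, constant fields in its null space) and a lumped
#' positive heat capacity `rho c_p V / 4` per node.
#'
#' @param mesh a `cusa_mesh`.
#' @param materials named material registry per tissue class.
#' @return an object of class `cusa_thermal_ops` with fields `K`
#'   (dgCMatrix, n x n), `C` (numeric length n), gradient data and the
#'   mesh.
#' @export
assemble_thermal <- function(mesh, materials = default_materials()) {
  em <- element_materials(mesh, materials)
  gr <- element_gradients(mesh$nodes, mesh$tets)
  m <- nrow(mesh$tets); n <- nrow(mesh$nodes)
  V <- gr$V
  tets <- mesh$tets
  nE <- 16L * m
  II <- integer(nE); JJ <- integer(nE); XX <- numeric(nE)
  pos <- 0L
  for (a in 1:4) for (b in 1:4) {
    val <- em$k * V * (gr$gx[, a] * gr$gx[, b] + gr$gy[, a] * gr$gy[, b] +
                         gr$gz[, a] * gr$gz[, b])
    idx <- pos + seq_len(m)
    II[idx] <- tets[, a]; JJ[idx] <- tets[, b]; XX[idx] <- val
    pos <- pos + m
  }
  K <- Matrix::sparseMatrix(i = II, j = JJ, x = XX, dims = c(n, n))
  C <- numeric(n)
  for (a in 1:4) {
    tab <- tapply(em$rho * em$cp * V / 4, tets[, a], sum)
    C[as.integer(names(tab))] <- C[as.integer(names(tab))] + tab
  }
  structure(list(K = K, C = C, grads = gr, V = V, kcond = em$k,
                 rho = em$rho, cp = em$cp, mesh = mesh, n_dof = n),
            class = "cusa_thermal_ops")
}
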