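# Axisymmetric refined submodel of the tissue under the vibrating tip.
#
# At 36 kHz the compressional wavelength in the very soft tumour
# (E ~ 1.8 kPa) is only ~40 um, far below any affordable global element
# size: the peak strain under the tip is governed by a boundary layer the
# full-anatomy mesh cannot resolve.  The submodel treats the tip as a
# rigid frictionless piston of the tip-face radius driving the tumour
# half-space along its normal, which is axisymmetric about the piston
# axis, and resolves the wave with a graded 2-D (r, y) mesh of
# axisymmetric linear triangles.

#' Refined axisymmetric harmonic submodel of the tip contact zone
#'
#' Solves the damped harmonic response of a cylinder of tumour material
#' (radius `domain_radius`, depth `depth`) whose top face carries the
#' piston: nodes with `r <= piston_radius` are driven at the sinusoid
#' amplitude of the load case along the axis (y), the rest of the top
#' face is traction-free, and the far boundaries are fixed (the damped
#' wave decays well before reaching them).  The axial mesh size tracks
#' the compressional wavelength (`lambda / n_per_wavelength`) near the
#' face and grows geometrically below the boundary layer.
#'
#' @param material the tumour `cusa_material`.
#' @param load_case a `cusa_load_case`.
#' @param loss_factor hysteretic loss factor of the tissue (> 0 required:
#'   the undamped interior problem is resonance-dense and ill-posed).
#' @param piston_radius tip face radius (mm).
#' @param domain_radius,depth submodel extent (mm).
#' @param n_per_wavelength axial elements per compressional wavelength in
#'   the refined zone.
#' @param fine_depth depth of the refined zone (mm).
#' @param growth geometric growth ratio below the refined zone.
#' @param dr radial element size near/under the piston (mm).
#' @return an object of class `cusa_tip_submodel`: `peak_strain`
#'   (peak |eps_yy|), `amp_yy`, complex strain components `eps`
#'   (columns rr, yy, tt, ry), element `centroids` (mm, columns r, y),
#'   `wavelength_mm`, solver size diagnostics.
#' @export
tip_strain_submodel <- function(material, load_case, loss_factor = 0.1,
                                piston_radius = 1, domain_radius = 2,
                                depth = 1.5, n_per_wavelength = 12,
                                fine_depth = 0.3, growth = 1.3,
                                dr = 0.05) {
  stopifnot(loss_factor > 0)
  si <- material_si(material)
  omega <- load_case$angular_frequency
  Mmod <- si$E * (1 - si$nu) / ((1 + si$nu) * (1 - 2 * si$nu))
  cp <- sqrt(Mmod / si$rho)
  lam_mm <- 2 * pi * cp / omega * 1e3
  dy <- lam_mm / n_per_wavelength
  rl <- grade_intervals(c(0, min(1.2 * piston_radius, domain_radius),
                          domain_radius), c(dr, 2 * dr))
  yl <- grade_intervals(c(0, fine_depth), dy)
  h <- dy; y <- fine_depth
  while (y < depth - 1e-12) {
    h <- h * growth
    y <- min(y + h, depth)
    yl <- c(yl, y)
  }
  nr <- length(rl); ny <- length(yl)
  nid <- function(i, j) i + nr * (j - 1)
  rr <- rep(rl, times = ny); yy <- rep(yl, each = nr)
  # quads -> 2 triangles, parity-alternating diagonal
  ci <- rep(seq_len(nr - 1), times = ny - 1)
  cj <- rep(seq_len(ny - 1), each = nr - 1)
  p <- (ci + cj) %% 2 == 0
  a <- nid(ci, cj); b <- nid(ci + 1, cj)
  c_ <- nid(ci + 1, cj + 1); d <- nid(ci, cj + 1)
  tri <- rbind(cbind(a, b, c_)[p, ], cbind(a, c_, d)[p, ],
               cbind(a, b, d)[!p, ], cbind(b, c_, d)[!p, ])
  nt <- nrow(tri)
  # element geometry (SI)
  r1 <- rr[tri[, 1]] * 1e-3; y1 <- yy[tri[, 1]] * 1e-3
  r2 <- rr[tri[, 2]] * 1e-3; y2 <- yy[tri[, 2]] * 1e-3
  r3 <- rr[tri[, 3]] * 1e-3; y3 <- yy[tri[, 3]] * 1e-3
  det <- (r2 - r1) * (y3 - y1) - (r3 - r1) * (y2 - y1)
  A <- abs(det) / 2
  bb <- cbind(y2 - y3, y3 - y1, y1 - y2) / det   # dN/dr
  cc <- cbind(r3 - r2, r1 - r3, r2 - r1) / det   # dN/dy
  rbar <- (r1 + r2 + r3) / 3
  lame_l <- si$E * si$nu / ((1 + si$nu) * (1 - 2 * si$nu))
  lame_m <- si$E / (2 * (1 + si$nu))
  Dm <- matrix(lame_l, 4, 4); Dm[4, ] <- 0; Dm[, 4] <- 0
  diag(Dm) <- c(lame_l + 2 * lame_m, lame_l + 2 * lame_m,
                lame_l + 2 * lame_m, lame_m)
  nn <- nr * ny
  ndof <- 2L * nn
  # assemble K (loop over 3x3 node blocks, vectorized over elements)
  w <- 2 * pi * rbar * A
  Brow <- function(aN) list(br = bb[, aN], cr = cc[, aN],
                            tt = 1 / (3 * rbar))
  II <- integer(0); JJ <- integer(0); XX <- numeric(0)
  for (aN in 1:3) for (bN in 1:3) {
    Ba <- Brow(aN); Bb <- Brow(bN)
    # columns: (u_r, u_y); B_a = [br 0; 0 cr; tt 0; cr br]
    k11 <- w * ((lame_l + 2 * lame_m) * Ba$br * Bb$br +
                  lame_l * (Ba$br * Bb$tt + Ba$tt * Bb$br) +
                  (lame_l + 2 * lame_m) * Ba$tt * Bb$tt +
                  lame_m * Ba$cr * Bb$cr)
    k12 <- w * (lame_l * Ba$br * Bb$cr + lame_l * Ba$tt * Bb$cr +
                  lame_m * Ba$cr * Bb$br)
    k21 <- w * (lame_l * Ba$cr * Bb$br + lame_l * Ba$cr * Bb$tt +
                  lame_m * Ba$br * Bb$cr)
    k22 <- w * ((lame_l + 2 * lame_m) * Ba$cr * Bb$cr +
                  lame_m * Ba$br * Bb$br)
    ia <- 2L * (tri[, aN] - 1L); ib <- 2L * (tri[, bN] - 1L)
    II <- c(II, ia + 1L, ia + 1L, ia + 2L, ia + 2L)
    JJ <- c(JJ, ib + 1L, ib + 2L, ib + 1L, ib + 2L)
    XX <- c(XX, k11, k12, k21, k22)
  }
  K <- Matrix::sparseMatrix(i = II, j = JJ, x = XX, dims = c(ndof, ndof))
  mass <- numeric(nn)
  for (aN in 1:3) {
    tb <- tapply(si$rho * w / 3, tri[, aN], sum)
    mass[as.integer(names(tb))] <- mass[as.integer(names(tb))] + tb
  }
  Md <- rep(mass, each = 2)
  # constraints
  u0 <- load_case$amplitude * 1e-6
  top <- which(abs(yy) < 1e-12)
  piston <- top[rl[((top - 1) %% nr) + 1] <= piston_radius + 1e-9]
  axis <- which(abs(rr) < 1e-12)
  outer_b <- which(abs(rr - domain_radius) < 1e-9 | abs(yy - max(yl)) < 1e-9)
  cons_dof <- c(2L * (piston - 1L) + 2L,             # u_y = u0 on piston
                2L * (axis - 1L) + 1L,               # u_r = 0 on axis
                as.vector(outer(1:2, 2L * (outer_b - 1L), `+`)))
  cons_val <- c(rep(u0, length(piston)), rep(0, length(axis)),
                rep(0, 2L * length(outer_b)))
  keep <- !duplicated(cons_dof)
  cons_dof <- cons_dof[keep]; cons_val <- cons_val[keep]
  free <- setdiff(seq_len(ndof), cons_dof)
  eta <- loss_factor
  rhs0 <- -as.numeric(K[free, cons_dof, drop = FALSE] %*% cons_val)
  rhs <- complex(real = rhs0, imaginary = eta * rhs0)
  Kff <- K[free, free]
  Ar <- Kff - omega^2 * Matrix::Diagonal(length(free), Md[free])
  Ai <- eta * Kff
  uf <- complex_lu_solve(Ar, Ai, rhs)
  u <- complex(ndof)
  u[free] <- uf; u[cons_dof] <- cons_val
  ur <- u[seq(1, ndof, by = 2)]; uyv <- u[seq(2, ndof, by = 2)]
  # strains at element centroids
  sum3 <- function(co, vv) co[, 1] * vv[tri[, 1]] + co[, 2] * vv[tri[, 2]] +
    co[, 3] * vv[tri[, 3]]
  err <- sum3(bb, ur)
  eyy <- sum3(cc, uyv)
  ett <- (ur[tri[, 1]] + ur[tri[, 2]] + ur[tri[, 3]]) / (3 * rbar)
  gry <- sum3(cc, ur) + sum3(bb, uyv)
  eps <- cbind(rr = err, yy = eyy, tt = ett, ry = gry)
  amp_yy <- Mod(eyy)
  pk <- which.max(amp_yy)
  structure(list(peak_strain = amp_yy[pk],
                 amp_yy = amp_yy, eps = eps,
                 centroids = cbind(r = rbar, y = (y1 + y2 + y3) / 3) * 1e3,
                 peak_location = c(r = rbar[pk] * 1e3,
                                   y = (y1 + y2 + y3)[pk] / 3 * 1e3),
                 wavelength_mm = lam_mm,
                 n_dof = ndof, n_elements = nt,
                 load_case = load_case, loss_factor = eta),
            class = "cusa_tip_submodel")
}

#' @export
print.cusa_tip_submodel <- function(x, ...) {
  cat(sprintf("<cusa_tip_submodel> peak |eps_yy| = %.3f at (r, y) = (%.2f, %.3f) mm; lambda = %.1f um\n",
              x$peak_strain, x$peak_location[1], x$peak_location[2],
              x$wavelength_mm * 1e3))
  invisible(x)
}

#' Strain-localization extent of the tip submodel field
#'
#' Diameter of the smallest sphere centred at the tip face centre
#' containing every submodel element whose `|eps_yy|` reaches the given
#' fraction of the peak.
#' @param submodel a `cusa_tip_submodel`.
#' @param threshold_fraction in (0, 1].
#' @return diameter in mm.
#' @export
submodel_extent <- function(submodel, threshold_fraction = 0.05) {
  stopifnot(threshold_fraction > 0, threshold_fraction <= 1)
  sel <- submodel$amp_yy >= threshold_fraction * submodel$peak_strain
  if (!any(sel)) return(0)
  cen <- submodel$centroids[sel, , drop = FALSE]
  2 * max(sqrt(cen[, 1]^2 + cen[, 2]^2))
}
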