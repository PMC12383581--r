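#' Solve the harmonic elastodynamic response to the vibrating tip
#'
#' Solves `((1 + i eta) K - w^2 M) u = 0` subject to a prescribed
#' displacement amplitude on the tip application face (hard constraint,
#' drive-axis component) and zero displacement on the fixed supports.
#' `eta` is a hysteretic (structural) loss factor: soft biological tissue
#' is strongly dissipative at ultrasonic frequency, and a nonzero `eta`
#' also regularizes the otherwise resonance-dense interior problem.
#'
#' Small systems are solved by a sparse LU of the (real-equivalent block)
#' system; large systems by preconditioned Krylov iteration (MINRES when
#' `eta = 0`, COCG otherwise) with an SPD `K + w^2 M` preconditioner
#' factored by CHOLMOD.
#'
#' @param operators a `cusa_elastic_ops` from [assemble_elastic()].
#' @param load_case a `cusa_load_case`; the imposed sinusoid amplitude is
#'   `displacement_pp / 2` along the drive axis.
#' @param loss_factor hysteretic damping loss factor `eta` (>= 0).
#' @param dirichlet optional explicit constraint override: list with
#'   integer `dof` and numeric `value` (m); when `NULL`, constraints come
#'   from the mesh's tip and fixed-support sets.
#' @param method `"auto"`, `"krylov"` or `"lu"`.
#' @param tol relative residual tolerance for Krylov solves.
#' @param maxit Krylov iteration cap.
#' @return an object of class `cusa_harmonic`: complex nodal displacement
#'   `u` (n x 3, metres), the load case, `loss_factor`, `omega`, and
#'   solver diagnostics.
#' @export
solve_harmonic <- function(operators, load_case, loss_factor = 0.1,
                           dirichlet = NULL, method = c("auto", "krylov", "lu"),
                           tol = 1e-10, maxit = 2000) {
  method <- match.arg(method)
  mesh <- operators$mesh
  n <- operators$n_dof
  omega <- load_case$angular_frequency
  if (is.null(dirichlet)) {
    if (is.null(mesh$tip_nodes) || !length(mesh$tip_nodes))
      stop("empty tip application face constraint set")
    fsup <- mesh$sets$fixed_support
    if (is.null(fsup) || !nrow(fsup$faces))
      stop("empty fixed support constraint set")
    comp <- which.max(abs(load_case$drive_axis))
    u0 <- load_case$amplitude * 1e-6 * sign(load_case$drive_axis[comp])
    tip_dof <- 3L * (mesh$tip_nodes - 1L) + comp
    fix_nodes <- unique(as.vector(fsup$faces))
    fix_dof <- as.vector(outer(1:3, 3L * (fix_nodes - 1L), `+`))
    dirichlet <- list(dof = c(tip_dof, fix_dof),
                      value = c(rep(u0, length(tip_dof)),
                                rep(0, length(fix_dof))))
  }
  o <- !duplicated(dirichlet$dof)
  cons_dof <- dirichlet$dof[o]
  cons_val <- dirichlet$value[o]
  free <- setdiff(seq_len(n), cons_dof)
  K <- operators$K; Md <- operators$M
  Kfc <- K[free, cons_dof, drop = FALSE]
  rhs0 <- -as.numeric(Kfc %*% cons_val)
  eta <- loss_factor
  rhs <- if (eta > 0) complex(real = rhs0, imaginary = eta * rhs0) else rhs0
  Kff <- K[free, free]
  Mf <- Md[free]
  nf <- length(free)
  if (method == "auto")
    method <- if (nf <= 6000) "lu" else "krylov"
  uf <- NULL; info <- list(method = method)
  if (method == "lu") {
    res <- try({
      if (eta > 0) {
        Ar <- Kff - omega^2 * Matrix::Diagonal(nf, Mf)
        Ai <- eta * Kff
        uf <- complex_lu_solve(Ar, Ai, rhs)
      } else {
        A <- Kff - omega^2 * Matrix::Diagonal(nf, Mf)
        uf <- as.numeric(Matrix::solve(A, rhs))
      }
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      stop("harmonic system is (near-)singular at this frequency; ",
           "likely a resonance -- consider a nonzero loss_factor")
    info$iter <- NA_integer_
  } else {
    P <- Kff + omega^2 * Matrix::Diagonal(nf, Mf)
    pfac <- chol_factor(P)
    if (eta > 0) {
      Amul <- function(v) {
        kv <- as.numeric(Kff %*% Re(v)) + 1i * as.numeric(Kff %*% Im(v))
        (1 + 1i * eta) * kv - omega^2 * (Mf * v)
      }
      sol <- cocg_solve(Amul, rhs, pfac, tol = tol, maxit = maxit)
    } else {
      Amul <- function(v) as.numeric(Kff %*% v) - omega^2 * (Mf * v)
      sol <- minres_solve(Amul, rhs, pfac, tol = tol, maxit = maxit)
    }
    if (sol$relres > 1e-6)
      stop(sprintf(paste0("harmonic Krylov solve did not converge ",
                          "(relres %.2e); likely near a resonance -- ",
                          "consider a nonzero loss_factor"), sol$relres))
    uf <- sol$x
    info$iter <- sol$iter
    info$relres <- sol$relres
  }
  u <- complex(n)
  u[free] <- uf
  u[cons_dof] <- cons_val
  um <- matrix(u, ncol = 3, byrow = TRUE)
  structure(list(u = um, load_case = load_case, loss_factor = eta,
                 omega = omega, solver = info,
                 dirichlet = list(dof = cons_dof, value = cons_val)),
            class = "cusa_harmonic")
}

#' @export
print.cusa_harmonic <- function(x, ...) {
  cat(sprintf("<cusa_harmonic> %d nodes, %g kHz, max |u| = %.3g um\n",
              nrow(x$u), x$load_case$frequency,
              max(Mod(x$u)) * 1e6))
  invisible(x)
}

#' Small-strain field of a harmonic solution
#'
#' Per-element complex small-strain tensor (Voigt order `xx, yy, zz, xy,
#' yz, zx`; engineering shear), its componentwise amplitudes, and the peak
#' directional strain along the drive axis.
#'
#' @param solution a `cusa_harmonic`.
#' @param operators the `cusa_elastic_ops` used for the solve.
#' @return an object of class `cusa_strain` with `eps` (m x 6 complex),
#'   `amp` (m x 6 moduli), `centroids` (mm), `peak` (list: `value`,
#'   `component`, `element`, `location`).
#' @export
strain_field <- function(solution, operators) {
  gr <- operators$grads
  tets <- operators$mesh$tets
  u <- solution$u
  ux <- matrix(u[tets, 1], ncol = 4)
  uy <- matrix(u[tets, 2], ncol = 4)
  uz <- matrix(u[tets, 3], ncol = 4)
  sumg <- function(g, w) g[, 1] * w[, 1] + g[, 2] * w[, 2] +
    g[, 3] * w[, 3] + g[, 4] * w[, 4]
  exx <- sumg(gr$gx, ux); eyy <- sumg(gr$gy, uy); ezz <- sumg(gr$gz, uz)
  gxy <- sumg(gr$gx, uy) + sumg(gr$gy, ux)
  gyz <- sumg(gr$gy, uz) + sumg(gr$gz, uy)
  gzx <- sumg(gr$gz, ux) + sumg(gr$gx, uz)
  eps <- cbind(xx = exx, yy = eyy, zz = ezz, xy = gxy, yz = gyz, zx = gzx)
  amp <- Mod(eps)
  nodes <- operators$mesh$nodes
  cen <- (nodes[tets[, 1], ] + nodes[tets[, 2], ] + nodes[tets[, 3], ] +
            nodes[tets[, 4], ]) / 4
  comp <- which.max(abs(solution$load_case$drive_axis))
  pk <- which.max(amp[, comp])
  structure(list(eps = eps, amp = amp, centroids = cen,
                 peak = list(value = amp[pk, comp],
                             component = colnames(eps)[comp],
                             element = pk, location = cen[pk, ])),
            class = "cusa_strain")
}

#' Time-averaged strain energy per region
#'
#' For complex strain amplitudes the cycle-averaged elastic energy per
#' element is `V/4 (lambda |tr eps|^2 + 2 mu sum |eps_ij|^2)`.
#'
#' @param strain a `cusa_strain`.
#' @param operators the matching `cusa_elastic_ops`.
#' @return list with `by_region` (named vector, J), `total` (J) and
#'   `confinement` (fraction of energy in tumour + spinal cord).
#' @export
strain_energy_by_region <- function(strain, operators) {
  e <- strain$eps
  tr2 <- Mod(e[, 1] + e[, 2] + e[, 3])^2
  frob <- Mod(e[, 1])^2 + Mod(e[, 2])^2 + Mod(e[, 3])^2 +
    (Mod(e[, 4])^2 + Mod(e[, 5])^2 + Mod(e[, 6])^2) / 2
  dens <- operators$V / 4 * (operators$lambda * tr2 + 2 * operators$mu * frob)
  byr <- tapply(dens, operators$mesh$region, sum)
  tot <- sum(dens)
  conf <- sum(byr[names(byr) %in% c("tumour", "spinal_cord")]) / tot
  list(by_region = byr, total = tot, confinement = conf)
}

#' Diameter of the strain-localization zone around the tip
#'
#' Diameter of the smallest sphere centred at the tip face centre that
#' contains every element whose drive-axis strain amplitude reaches
#' `threshold_fraction` of the peak.
#'
#' @param strain a `cusa_strain`.
#' @param threshold_fraction in (0, 1].
#' @param centre sphere centre (mm); defaults to the tip face centre of
#'   the originating model (if available via `centroids` attribute the
#'   caller must supply it for fixture meshes).
#' @return diameter in mm (0 if no element qualifies).
#' @export
strain_localization_extent <- function(strain, threshold_fraction,
                                       centre) {
  if (!(threshold_fraction > 0 && threshold_fraction <= 1))
    stop("threshold_fraction must lie in (0, 1]")
  comp <- match(strain$peak$component, colnames(strain$eps))
  a <- strain$amp[, comp]
  sel <- a >= threshold_fraction * strain$peak$value
  if (!any(sel)) return(0)
  cen <- strain$centroids[sel, , drop = FALSE]
  d <- sqrt((cen[, 1] - centre[1])^2 + (cen[, 2] - centre[2])^2 +
              (cen[, 3] - centre[3])^2)
  2 * max(d)
}
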