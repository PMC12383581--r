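#' Thermal boundary conditions
#'
#' Assembles the discrete Neumann flux load on the tip application face
#' (using the exact disc-clipped facet areas) and the Robin (convection)
#' boundary operator `h (T - T_amb)` on the convection facet set, both
#' with lumped (node-diagonal) facet integration.
#'
#' @param mesh a `cusa_mesh`.
#' @param q heat flux density applied to the flux facet set (W/m^2).
#' @param h convection film coefficient (W/(m^2 C)), >= 0.
#' @param t_amb ambient temperature (C).
#' @param t_ref initial/reference tissue temperature (C).
#' @param flux_set,convection_set names of the facet sets.
#' @return an object of class `cusa_thermal_bcs` with `f_flux`, `f_robin`
#'   (nodal loads, W), `Hdiag` (nodal Robin conductances, W/C), the
#'   parameters, and `flux_area` (m^2).
#' @export
thermal_bcs <- function(mesh, q, h = 10, t_amb = 37, t_ref = 37,
                        flux_set = "tip_application_face",
                        convection_set = "convection") {
  stopifnot(is.finite(q), h >= 0, is.finite(t_amb), is.finite(t_ref))
  n <- nrow(mesh$nodes)
  f_flux <- numeric(n); flux_area <- 0
  if (q != 0) {
    s <- mesh$sets[[flux_set]]
    if (is.null(s)) stop(sprintf("unknown facet set '%s'", flux_set))
    ar <- if (!is.null(s$clip_area)) s$clip_area
          else triangle_areas(mesh$nodes, s$faces)
    ar <- ar * 1e-6                      # mm^2 -> m^2
    flux_area <- sum(ar)
    for (cc in 1:3) {
      tb <- tapply(q * ar / 3, s$faces[, cc], sum)
      ii <- as.integer(names(tb))
      f_flux[ii] <- f_flux[ii] + tb
    }
  }
  Hdiag <- numeric(n); f_robin <- numeric(n)
  if (h > 0) {
    s <- mesh$sets[[convection_set]]
    if (is.null(s)) stop(sprintf("unknown facet set '%s'", convection_set))
    ar <- triangle_areas(mesh$nodes, s$faces) * 1e-6
    for (cc in 1:3) {
      tb <- tapply(h * ar / 3, s$faces[, cc], sum)
      ii <- as.integer(names(tb))
      Hdiag[ii] <- Hdiag[ii] + tb
    }
    f_robin <- Hdiag * t_amb
  }
  structure(list(f_flux = f_flux, f_robin = f_robin, Hdiag = Hdiag,
                 q = q, h = h, t_amb = t_amb, t_ref = t_ref,
                 flux_area = flux_area),
            class = "cusa_thermal_bcs")
}

#' Steady-state heat conduction solve
#'
#' Solves `(K + H) T = f_flux + H T_amb` with the Robin operator `H` on
#' the convection boundary; SPD, solved by CHOLMOD Cholesky.  A
#' configuration with heating but no convection (pure Neumann) is
#' singular and rejected with a remediation hint.
#'
#' @param operators a `cusa_thermal_ops`.
#' @param bcs a `cusa_thermal_bcs`.
#' @return an object of class `cusa_temp_field` with nodal temperatures
#'   `T` (C), the bcs, and the relative residual of the solve.
#' @export
solve_steady <- function(operators, bcs) {
  n <- operators$n_dof
  if (all(bcs$Hdiag == 0))
    stop("pure-Neumann thermal problem is singular: add a convection ",
         "boundary (h > 0) or a Dirichlet surface")
  A <- operators$K + Matrix::Diagonal(n, bcs$Hdiag)
  b <- bcs$f_flux + bcs$f_robin
  fac <- chol_factor(A)
  T <- chol_apply(fac, b)
  res <- sqrt(sum((as.numeric(A %*% T) - b)^2)) / max(sqrt(sum(b^2)),
                                                      .Machine$double.xmin)
  structure(list(T = T, times = NULL, series = NULL, bcs = bcs,
                 residual = res),
            class = "cusa_temp_field")
}

#' Transient heat conduction solve (implicit Euler)
#'
#' Backward-Euler time stepping of `C dT/dt + (K + H) T = f` from the
#' uniform initial state `T_ref`, with the lumped capacity `C`.
#' Unconditionally stable; for this linear problem the solution
#' approaches the steady state monotonically from a neutral start.
#'
#' @param operators a `cusa_thermal_ops`.
#' @param bcs a `cusa_thermal_bcs`.
#' @param duration total simulated time (s).
#' @param dt time step (s).
#' @return a `cusa_temp_field` whose `T` is the final state and whose
#'   `series` (n x steps+1) and `times` hold the trajectory.
#' @export
solve_transient <- function(operators, bcs, duration = 1, dt = 0.01) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (duration < dt) stop("duration must be >= dt")
  n <- operators$n_dof
  A <- operators$K + Matrix::Diagonal(n, bcs$Hdiag)
  b <- bcs$f_flux + bcs$f_robin
  Cdt <- operators$C / dt
  B <- A + Matrix::Diagonal(n, Cdt)
  fac <- chol_factor(B)
  nst <- round(duration / dt)
  Tk <- rep(bcs$t_ref, n)
  series <- matrix(0, n, nst + 1)
  series[, 1] <- Tk
  for (k in seq_len(nst)) {
    Tk <- chol_apply(fac, Cdt * Tk + b)
    series[, k + 1] <- Tk
  }
  structure(list(T = Tk, times = dt * (0:nst), series = series, bcs = bcs,
                 residual = NA_real_),
            class = "cusa_temp_field")
}

#' @export
print.cusa_temp_field <- function(x, ...) {
  cat(sprintf("<cusa_temp_field> %d nodes, range %.2f .. %.2f C%s\n",
              length(x$T), min(x$T), max(x$T),
              if (!is.null(x$times))
                sprintf(" (transient, %d steps)", length(x$times) - 1) else ""))
  invisible(x)
}

#' Per-tissue maximum temperature table
#'
#' Nodal maxima per tissue class (vertebrae aggregated to bone, discs to
#' intervertebral disc), one column per supplied temperature field.
#'
#' @param fields named list of `cusa_temp_field` (or numeric nodal
#'   vectors), all on `mesh`.
#' @param mesh the common `cusa_mesh`.
#' @return data.frame with a `tissue` column and one column per field.
#' @export
region_max_table <- function(fields, mesh) {
  n <- nrow(mesh$nodes)
  tis <- region_tissue(mesh$region)
  order_t <- c("tumour", "bone", "disc", "fat", "dura", "csf", "cord")
  order_t <- order_t[order_t %in% unique(tis)]
  node_sets <- lapply(order_t, function(tt)
    unique(as.vector(mesh$tets[tis == tt, , drop = FALSE])))
  out <- data.frame(tissue = order_t, stringsAsFactors = FALSE)
  for (nm in names(fields)) {
    Tv <- fields[[nm]]
    if (inherits(Tv, "cusa_temp_field")) Tv <- Tv$T
    if (length(Tv) != n)
      stop("temperature field does not match the mesh (mismatched meshes?)")
    out[[nm]] <- vapply(node_sets, function(s) max(Tv[s]), 0)
  }
  out
}

#' Total convective heat loss of a temperature field
#'
#' `sum_i H_i (T_i - T_amb)` over the convection boundary, with the same
#' lumped Robin operator used in the solve; at steady state this equals
#' the injected flux power to solver precision.
#' @param field a `cusa_temp_field`.
#' @param bcs the `cusa_thermal_bcs` used (defaults to the field's own).
#' @return power in W.
#' @export
convective_loss <- function(field, bcs = field$bcs) {
  sum(bcs$Hdiag * (field$T - bcs$t_amb))
}
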