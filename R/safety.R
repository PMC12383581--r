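#' Thermal safety thresholds for spinal cord tissue
#'
#' Animal hyperthermia studies place the tolerable spinal-cord
#' temperature after local heating near 44 C, with irreversible damage
#' (tissue destruction, loss of evoked potentials) from 46 C; dwell at a
#' single application point should stay within about 1 s.
#'
#' @param tolerable_max warning threshold (C).
#' @param damage_threshold failure threshold (C); must exceed
#'   `tolerable_max`.
#' @param max_dwell recommended maximum single-point application time (s).
#' @return an object of class `cusa_thresholds`.
#' @export
safety_thresholds <- function(tolerable_max = 44, damage_threshold = 46,
                              max_dwell = 1) {
  stopifnot(tolerable_max < damage_threshold, max_dwell > 0)
  structure(list(tolerable_max = tolerable_max,
                 damage_threshold = damage_threshold,
                 max_dwell = max_dwell),
            class = "cusa_thresholds")
}

#' Evaluate a temperature table against the safety thresholds
#'
#' @param table a region temperature table ([region_max_table()] layout:
#'   `tissue` column plus one numeric column per case).
#' @param thresholds a [safety_thresholds()].
#' @return an object of class `cusa_safety_report`: per-tissue maxima and
#'   flags, `global_max`, `margin` to the damage threshold, `pass`
#'   (no tissue above damage), `warn` tissues above the tolerable level,
#'   and the dwell recommendation.
#' @export
evaluate_safety <- function(table, thresholds = safety_thresholds()) {
  num <- table[, setdiff(names(table), "tissue"), drop = FALSE]
  if (nrow(table) == 0 || ncol(num) == 0) stop("empty temperature table")
  tmax <- apply(num, 1, max)
  fail <- tmax > thresholds$damage_threshold
  warn <- tmax > thresholds$tolerable_max & !fail
  gmax <- max(tmax)
  structure(list(
    tissue = table$tissue, tissue_max = tmax,
    fail = fail, warn = warn,
    flagged = table$tissue[fail | warn],
    global_max = gmax,
    margin = thresholds$damage_threshold - gmax,
    pass = !any(fail),
    thresholds = thresholds,
    recommendation = sprintf(
      "limit single-point application dwell to <= %g s", thresholds$max_dwell)),
    class = "cusa_safety_report")
}

#' @export
print.cusa_safety_report <- function(x, ...) {
  cat(sprintf("<cusa_safety_report> %s; global max %.2f C, margin %.2f C to %g C\n",
              if (x$pass) "PASS" else "FAIL", x$global_max, x$margin,
              x$thresholds$damage_threshold))
  if (length(x$flagged))
    cat("  flagged tissues:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# pipeline context: builds and caches the stage products shared by cases

#' Create a simulation context (cached pipeline state)
#'
#' Builds the model and mesh once and caches assemblies, the
#' reference-amplitude harmonic solution, the tip submodel and the
#' unit-flux steady thermal rise field, so that repeated [run_case()] and
#' [sweep_amplitudes()] calls reuse one factorization per stage and are
#' bit-reproducible.
#'
#' @param config a `cusa_config`.
#' @return an environment of class `cusa_context`.
#' @export
simulation_context <- function(config = simulation_config()) {
  ctx <- new.env(parent = emptyenv())
  ctx$config <- config
  class(ctx) <- "cusa_context"
  ctx
}

#' @export
print.cusa_context <- function(x, ...) {
  cat("<cusa_context>",
      if (is.null(x$mesh)) "(mesh not built yet)"
      else sprintf("%d elements cached", nrow(x$mesh$tets)), "\n")
  invisible(x)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE))
}

ctx_model <- function(ctx) {
  if (is.null(ctx$model))
    ctx$model <- .stage("build_model", build_model(ctx$config$geometry))
  ctx$model
}

ctx_mesh <- function(ctx) {
  if (is.null(ctx$mesh))
    ctx$mesh <- .stage("mesh", generate_mesh(ctx_model(ctx),
                                             ctx$config$sizing))
  ctx$mesh
}

ctx_thermal_ops <- function(ctx) {
  if (is.null(ctx$thermal_ops))
    ctx$thermal_ops <- .stage("thermal_assembly",
                              assemble_thermal(ctx_mesh(ctx),
                                               ctx$config$materials))
  ctx$thermal_ops
}

ctx_elastic_ops <- function(ctx) {
  if (is.null(ctx$elastic_ops))
    ctx$elastic_ops <- .stage("elastic_assembly",
                              assemble_elastic(ctx_mesh(ctx),
                                               ctx$config$materials))
  ctx$elastic_ops
}

# reference-amplitude (70 um pp) full-model harmonic solution + strain
ctx_harmonic_ref <- function(ctx, frequency) {
  key <- paste0("harm_", frequency)
  if (is.null(ctx[[key]])) {
    ctx[[key]] <- .stage("harmonic", {
      lc <- load_case(70, frequency)
      sol <- solve_harmonic(ctx_elastic_ops(ctx), lc,
                            loss_factor = ctx$config$loss_factor)
      st <- strain_field(sol, ctx_elastic_ops(ctx))
      en <- strain_energy_by_region(st, ctx_elastic_ops(ctx))
      list(solution = sol, strain = st, energy = en, ref_pp = 70)
    })
  }
  ctx[[key]]
}

# reference-amplitude tip submodel (peak strain scales linearly in pp)
ctx_submodel_ref <- function(ctx, frequency) {
  key <- paste0("sub_", frequency)
  if (is.null(ctx[[key]])) {
    ctx[[key]] <- .stage("tip_submodel", {
      lc <- load_case(70, frequency)
      sub <- tip_strain_submodel(
        ctx$config$materials$tumour, lc,
        loss_factor = max(ctx$config$loss_factor, 0.05),
        piston_radius = ctx_model(ctx)$tip_radius)
      list(submodel = sub, ref_pp = 70)
    })
  }
  ctx[[key]]
}

# unit-flux steady rise field: T(q) = t_amb + q * rise
ctx_steady_unit <- function(ctx) {
  if (is.null(ctx$steady_unit)) {
    ctx$steady_unit <- .stage("thermal_steady", {
      cfg <- ctx$config
      bcs <- thermal_bcs(ctx_mesh(ctx), q = 1, h = cfg$h,
                         t_amb = cfg$t_amb, t_ref = cfg$t_ref)
      f <- solve_steady(ctx_thermal_ops(ctx), bcs)
      list(rise = f$T - cfg$t_amb, flux_area = bcs$flux_area,
           residual = f$residual)
    })
  }
  ctx$steady_unit
}

# ---------------------------------------------------------------------------

#' Run one load case through the full pipeline
#'
#' Executes model -> mesh -> harmonic response -> tip submodel ->
#' equivalent-radiated-power heat source -> steady (and optionally 1 s
#' transient) heat conduction -> per-tissue maxima -> safety evaluation,
#' reusing every cached stage of the context.  All stages are
#' deterministic.
#'
#' The radiated power `Q` comes from the preset's published value when
#' the config's `erp_mode` is `"preset"` (scaled quadratically in
#' amplitude for non-preset amplitudes, calibrated at the 70 um preset);
#' in `"first_principles"` mode it is computed from the harmonic solution
#' over the tumour boundary and the configured acoustic impedance.
#'
#' @param ctx a `cusa_context` (or a `cusa_config`, in which case a fresh
#'   context is created).
#' @param load_case a `cusa_load_case` or preset name for
#'   [load_case_preset()].
#' @param transient run the 1 s transient in addition to the steady state.
#' @param thresholds a [safety_thresholds()].
#' @param duration,dt transient horizon and step (s).
#' @return an object of class `cusa_case_result`.
#' @export
run_case <- function(ctx, load_case, transient = TRUE,
                     thresholds = safety_thresholds(),
                     duration = 1, dt = 0.01) {
  if (inherits(ctx, "cusa_config")) ctx <- simulation_context(ctx)
  if (!inherits(ctx, "cusa_context")) stop("ctx must be a cusa_context")
  if (is.character(load_case)) load_case <- load_case_preset(load_case)
  lc <- load_case
  cfg <- ctx$config
  mesh <- ctx_mesh(ctx)
  model <- ctx_model(ctx)

  # harmonic stage (reference solve scaled linearly to this amplitude)
  href <- ctx_harmonic_ref(ctx, lc$frequency)
  scale <- lc$displacement_pp / href$ref_pp
  sref <- ctx_submodel_ref(ctx, lc$frequency)
  peak_strain <- sref$submodel$peak_strain * scale
  extent <- submodel_extent(sref$submodel, 0.05)

  # heat source
  hs <- .stage("erp", {
    if (cfg$erp_mode == "preset") {
      if (!is.null(lc$Q)) {
        flux_from_power(cfg$efficiency * lc$Q, lc$A)
      } else {
        ref <- load_case_preset("paper-70um")
        Qs <- ref$Q * (lc$displacement_pp / ref$displacement_pp)^2
        flux_from_power(cfg$efficiency * Qs, ref$A)
      }
    } else {
      sol <- href$solution
      sc <- lc$displacement_pp / href$ref_pp
      nv <- surface_normal_velocity(sol, mesh, "tumour")
      erp <- compute_erp(nv$v_n * sc, nv$areas, cfg$impedance,
                         frequency = lc$frequency)
      A <- tumour_surface_area(model, "mesh", mesh)
      flux_from_power(cfg$efficiency * erp$Q, A)
    }
  })

  # thermal stage: steady by exact linear scaling of the unit-flux rise
  su <- ctx_steady_unit(ctx)
  Tsteady <- cfg$t_amb + hs$q * su$rise
  steady <- structure(list(T = Tsteady, times = NULL, series = NULL,
                           bcs = NULL, residual = su$residual),
                      class = "cusa_temp_field")
  trans <- NULL
  if (transient) {
    trans <- .stage("thermal_transient", {
      bcs <- thermal_bcs(mesh, q = hs$q, h = cfg$h,
                         t_amb = cfg$t_amb, t_ref = cfg$t_ref)
      solve_transient(ctx_thermal_ops(ctx), bcs, duration = duration,
                      dt = dt)
    })
  }
  fields <- list(steady = steady)
  if (!is.null(trans)) fields$transient_end <- trans
  tab <- region_max_table(fields, mesh)
  steady_tab <- tab[, c("tissue", "steady")]
  names(steady_tab)[2] <- sprintf("pp_%gum", lc$displacement_pp)
  safety <- evaluate_safety(steady_tab, thresholds)

  injected <- hs$q * su$flux_area
  structure(list(
    load_case = lc,
    peak_strain = peak_strain,
    extent_mm = extent,
    confinement = href$energy$confinement,
    energy_by_region = href$energy$by_region,
    Q = hs$Q, A = hs$A, q = hs$q,
    flux_area_m2 = su$flux_area,
    injected_power_W = injected,
    steady = steady, transient = trans,
    region_table = tab,
    safety = safety,
    diagnostics = list(
      harmonic = href$solution$solver,
      steady_residual = su$residual,
      energy_bookkeeping = c(Q = hs$Q, q_times_tip_area = injected),
      submodel = list(n_dof = sref$submodel$n_dof,
                      wavelength_mm = sref$submodel$wavelength_mm))),
    class = "cusa_case_result")
}

#' @export
print.cusa_case_result <- function(x, ...) {
  cat(sprintf("<cusa_case_result> %g um pp @ %g kHz\n",
              x$load_case$displacement_pp, x$load_case$frequency))
  cat(sprintf("  peak strain %.3f, extent %.1f mm, confinement %.4f\n",
              x$peak_strain, x$extent_mm, x$confinement))
  cat(sprintf("  Q = %.4f W, A = %.5g m^2, q = %.1f W/m^2\n", x$Q, x$A, x$q))
  cat(sprintf("  tumour steady max %.2f C; %s\n",
              max(x$region_table$steady[x$region_table$tissue == "tumour"]),
              if (x$safety$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Amplitude sweep
#'
#' Runs a list of peak-to-peak amplitudes through [run_case()] on a
#' shared context (one mesh, one harmonic factorization, one unit-flux
#' thermal solve) and tabulates peak strain, radiated power, flux,
#' tissue maxima and safety flags.  Also reports the amplitude at which
#' the extrapolated tumour maximum crosses the damage threshold
#' (quadratic flux law, linear thermal response).
#'
#' @param ctx a `cusa_context` or `cusa_config`.
#' @param amplitudes peak-to-peak amplitudes (um).
#' @param frequency kHz.
#' @param thresholds a [safety_thresholds()].
#' @return data.frame with one row per amplitude and attribute
#'   `crossing_amplitude_um`.
#' @export
sweep_amplitudes <- function(ctx, amplitudes, frequency = 36,
                             thresholds = safety_thresholds()) {
  if (!length(amplitudes)) stop("empty amplitude list")
  if (inherits(ctx, "cusa_config")) ctx <- simulation_context(ctx)
  rows <- lapply(amplitudes, function(a) {
    cr <- run_case(ctx, load_case(a, frequency), transient = FALSE,
                   thresholds = thresholds)
    tum <- cr$region_table$steady[cr$region_table$tissue == "tumour"]
    cord <- cr$region_table$steady[cr$region_table$tissue == "cord"]
    data.frame(amplitude_pp_um = a, peak_strain = cr$peak_strain,
               Q_W = cr$Q, q_W_m2 = cr$q,
               tumour_max_C = tum, cord_max_C = cord,
               margin_C = cr$safety$margin,
               warn = length(cr$safety$flagged) > 0,
               pass = cr$safety$pass)
  })
  out <- do.call(rbind, rows)
  r1 <- out[1, ]
  dT <- r1$tumour_max_C - ctx$config$t_amb
  crossing <- if (dT > 0) {
    r1$amplitude_pp_um *
      sqrt((thresholds$damage_threshold - ctx$config$t_amb) / dT)
  } else NA_real_
  attr(out, "crossing_amplitude_um") <- crossing
  out
}
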