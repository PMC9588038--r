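#' Integrate the box model
#'
#' Advances an ecosystem state through `years` model years with the
#' fixed-step RK4 scheme and returns annual diagnostics. The default engine
#' is the compiled integrator; `engine = "R"` runs the pure-R reference
#' stepper ([step_state()]) and is intended for short cross-validation runs.
#'
#' @param state starting `ecosystem_state`.
#' @param geometry a [box_geometry()].
#' @param config an experiment configuration from [build_config()].
#' @param years number of model years to integrate.
#' @param dt time step, days; must divide the 365-day model year.
#' @param clip_eps negative-excursion clipping tolerance, mmol m^-3.
#' @param record_snapshots if `TRUE`, annual-mean states are kept in the
#'   result (`$snapshots`, an array `year x column x tracer x layer`).
#' @param engine `"cpp"` (default) or `"R"`.
#' @return An object of class `diazo_run`: list with `state_final`, the
#'   annual diagnostics data frame `annual` (global fixation and
#'   denitrification in Tg N yr^-1, diazotroph and ordinary biomass in
#'   Tg C, nitrogen/phosphorus inventories in mol and the excess-P
#'   inventory in mol N), the annual-mean surface chlorophyll matrix `chl`
#'   (mg Chl a m^-3 per column), per-column annual fixation `fix_box`
#'   (Tg N yr^-1), clipped mass (mol) and provenance.
#' @export
run_model <- function(state, geometry, config, years,
                      dt = config$dt, clip_eps = 1e-5,
                      record_snapshots = FALSE, engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  check_state(state, geometry)
  stopifnot(years >= 1)
  b <- geometry$boxes
  if (engine == "cpp") {
    e <- geometry$edges
    geom <- list(area = b$area, temp = b$temp, w_mix = b$w_mix,
                 iron = b$iron, J0 = b$J0, J_amp = b$J_amp, lat = b$lat,
                 denit_flag = as.numeric(b$denitrifying),
                 V_s = geometry$V_s, V_d = geometry$V_d,
                 e_from = if (is.null(e)) integer(0) else as.integer(e$from - 1L),
                 e_to = if (is.null(e)) integer(0) else as.integer(e$to - 1L),
                 e_qs = if (is.null(e)) numeric(0) else e$q_surface,
                 e_qd = if (is.null(e)) numeric(0) else e$q_deep)
    cfg <- list(warming = identical(config$scenario, "warming"),
                denit_enabled = isTRUE(config$denitrification_enabled),
                year0 = config$year0,
                start_year = config$warming$start_year,
                end_year = config$warming$end_year,
                dT_surface = config$warming$dT_surface,
                mix_reduction = config$warming$mix_reduction)
    res <- .cpp_run(as.numeric(state), unclass(config$params), geom, cfg,
                    as.integer(years), dt, clip_eps, record_snapshots)
    annual <- as.data.frame(res$annual)
    snaps <- NULL
    if (record_snapshots) {
      snaps <- array(res$snapshots,
                     dim = c(years, nrow(b), 6L, 2L),
                     dimnames = list(NULL, b$column, TRACERS,
                                     c("surface", "deep")))
    }
    out <- list(state_final = as_state(res$state_final, geometry),
                annual = annual, chl = res$chl, fix_box = res$fix_box,
                snapshots = snaps, clipped_mol = res$clipped_mol)
  } else {
    out <- run_model_r(state, geometry, config, years, dt, clip_eps,
                       record_snapshots)
  }
  out$config <- config
  out$geometry <- geometry
  out$dt <- dt
  out$years <- years
  class(out) <- "diazo_run"
  out
}

# Pure-R integration loop with identical bookkeeping; reference route.
#' @keywords internal
run_model_r <- function(state, geometry, config, years, dt, clip_eps,
                        record_snapshots) {
  spy <- round(365 / dt)
  if (abs(spy * dt - 365) > 1e-9)
    stop("dt must divide the 365-day year exactly", call. = FALSE)
  b <- geometry$boxes
  n <- nrow(b)
  p <- config$params
  mmol_to_TgN <- 1e-3 * 14 * 1e-12
  mmol_to_TgC <- 1e-3 * p$r_CN * 12 * 1e-12
  annual <- matrix(0, years, 8,
                   dimnames = list(NULL, c("year", "fixation_TgN_yr",
                                           "denit_TgN_yr", "biomass_diaz_TgC",
                                           "biomass_ord_TgC", "N_mol", "P_mol",
                                           "excessP_molN")))
  chl <- matrix(0, years, n)
  fix_box <- matrix(0, years, n)
  snaps <- if (record_snapshots) array(0, dim = c(years, n, 6L, 2L)) else NULL
  clipped <- 0
  t <- 0
  for (yr in seq_len(years)) {
    fixb <- numeric(n); den_year <- 0
    ymean <- array(0, dim = dim(state))
    for (s in seq_len(spy)) {
      st <- step_state(state, geometry, p, config, t, dt, clip_eps)
      state <- st$state
      t <- st$t
      clipped <- clipped + st$clipped
      fixb <- fixb + st$fixation * geometry$V_s * dt * mmol_to_TgN
      den_year <- den_year + sum(st$denit * geometry$V_d) * dt * mmol_to_TgN
      ymean <- ymean + state * (dt / 365)
    }
    mb <- mass_budget(state, geometry, p)
    bD <- sum(ymean[, 4L, 1L] * geometry$V_s + ymean[, 4L, 2L] * geometry$V_d)
    bO <- sum(ymean[, 3L, 1L] * geometry$V_s + ymean[, 3L, 2L] * geometry$V_d)
    annual[yr, ] <- c(config$year0 + yr, sum(fixb), den_year,
                      bD * mmol_to_TgC, bO * mmol_to_TgC,
                      mb$N_mol, mb$P_mol, mb$excess_P_molN)
    chl[yr, ] <- p$chl_per_N * (ymean[, 3L, 1L] + ymean[, 4L, 1L])
    fix_box[yr, ] <- fixb
    if (record_snapshots) snaps[yr, , , ] <- ymean
  }
  list(state_final = state, annual = as.data.frame(annual), chl = chl,
       fix_box = fix_box, snapshots = snaps, clipped_mol = clipped)
}

#' @export
print.diazo_run <- function(x, ...) {
  a <- x$annual
  last <- a[nrow(a), ]
  cat(sprintf("<diazo_run> %s, %d years (dt = %g d)\n",
              x$config$paradigm, x$years, x$dt))
  cat(sprintf("  final year %d: fixation %.1f Tg N/yr, denitrification %.1f Tg N/yr\n",
              as.integer(last$year), last$fixation_TgN_yr, last$denit_TgN_yr))
  cat(sprintf("  diazotroph biomass %.1f Tg C, excess-P %.3g Pmol N\n",
              last$biomass_diaz_TgC, last$excessP_molN / 1e15))
  invisible(x)
}
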