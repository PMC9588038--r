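#' Monod (Michaelis-Menten) limitation factor
#'
#' `conc / (k + conc)`: the saturating nutrient-limitation term, equal to
#' 0.5 at the half-saturation concentration and monotonically increasing in
#' `conc` towards 1.
#'
#' @param conc nutrient concentration, mmol m^-3 (>= 0). Vectorized.
#' @param k half-saturation constant, mmol m^-3 (> 0).
#' @return limitation factor in [0, 1).
#' @examples
#' monod(0, 0.7)    # 0
#' monod(0.7, 0.7)  # 0.5
#' @export
monod <- function(conc, k) {
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentration must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(k)) || any(k <= 0))
    stop("half-saturation must be finite and > 0", call. = FALSE)
  conc / (k + conc)
}

#' Ordinary-phytoplankton growth rate
#'
#' Liebig's law of the minimum over light and the two nutrients:
#' `min(J_IO, J_O_max * NO3/(k_N + NO3), J_O_max * PO4/(k_P + PO4))`, d^-1.
#'
#' @param J_IO light-limited growth rate, d^-1 (>= 0). Vectorized.
#' @param NO3,PO4 nutrient concentrations, mmol m^-3 (>= 0).
#' @param params an [ecosystem_params()].
#' @return realized growth rate, d^-1.
#' @export
growth_rate_ordinary <- function(J_IO, NO3, PO4, params) {
  if (any(!is.finite(J_IO)) || any(J_IO < 0))
    stop("J_IO must be finite and >= 0", call. = FALSE)
  pmin(J_IO,
       params$J_O_max * monod(NO3, params$k_N),
       params$J_O_max * monod(PO4, params$k_P))
}

#' Diazotroph growth rate
#'
#' Like the ordinary-phytoplankton rate but independent of nitrate by
#' construction (diazotrophs can meet their nitrogen demand by fixing N2):
#' `min(J_IO, J_D_max * PO4/(k_P_d + PO4))`, and zero below the temperature
#' cutoff `T_min_diaz`.
#'
#' @param J_IO light-limited growth rate, d^-1 (>= 0). Vectorized.
#' @param PO4 phosphate concentration, mmol m^-3 (>= 0).
#' @param temperature water temperature, degC (any real).
#' @param params an [ecosystem_params()].
#' @return realized growth rate, d^-1.
#' @export
growth_rate_diazotroph <- function(J_IO, PO4, temperature, params) {
  if (any(!is.finite(J_IO)) || any(J_IO < 0))
    stop("J_IO must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(temperature)))
    stop("temperature must be finite", call. = FALSE)
  r <- pmin(J_IO, params$J_D_max * monod(PO4, params$k_P_d))
  r * (temperature >= params$T_min_diaz)
}

#' Zooplankton grazing flux on one prey
#'
#' The linear-in-prey form `mu_max * Z * theta * prey` (mmol N m^-3 d^-1).
#' If `params$holling_saturating` is set, the caller-supplied saturating
#' denominator `denom` divides the flux (see [tendencies()], which assembles
#' the multiple-prey denominator).
#'
#' @param Z zooplankton biomass, mmol N m^-3 (>= 0). Vectorized.
#' @param prey prey biomass, mmol N m^-3 (>= 0).
#' @param theta preference for this prey, in [0, 1].
#' @param params an [ecosystem_params()].
#' @param denom optional saturating denominator (default 1).
#' @return grazing flux, mmol N m^-3 d^-1.
#' @examples
#' p <- ecosystem_params()
#' grazing_rate(1, 2, 0.3, p)  # 0.4 * 1 * 0.3 * 2 = 0.24
#' @export
grazing_rate <- function(Z, prey, theta, params, denom = 1) {
  if (any(Z < 0) || any(prey < 0))
    stop("Z and prey must be >= 0", call. = FALSE)
  if (any(theta < 0) || any(theta > 1))
    stop("theta must lie in [0, 1]", call. = FALSE)
  params$mu_max * Z * theta * prey / denom
}

#' Environmental forcing at a model time
#'
#' Evaluates surface temperature, vertical exchange and the light-limited
#' growth rate for every column at model time `t` (days since the start of
#' the run). Under the warming scenario a normalized quadratic ramp `w(t)`
#' rises from 0 at `start_year` to 1 at `end_year`; surface temperature
#' increases by `dT_surface * w` and the vertical exchange is scaled by
#' `(1 - mix_reduction * w)` --- the stratification proxy. The seasonal
#' cycle (if `J_amp > 0`) is a sinusoid in the light-limited rate with
#' opposite phase in the two hemispheres.
#'
#' @param t model time, days.
#' @param geometry a [box_geometry()].
#' @param config an [build_config()] experiment configuration.
#' @return list with `temp_s` (degC), `q_vert` (m^3 d^-1) and `J_IO` (d^-1),
#'   each per column, plus the ramp value `w`.
#' @export
forcing_at <- function(t, geometry, config) {
  b <- geometry$boxes
  w <- 0
  if (identical(config$scenario, "warming")) {
    yr <- config$year0 + t / 365
    x <- (yr - config$warming$start_year) /
      (config$warming$end_year - config$warming$start_year)
    x <- min(max(x, 0), 1)
    w <- x * x
  }
  temp_s <- b$temp + config$warming$dT_surface * w
  q_vert <- b$w_mix / 365 * b$area * (1 - config$warming$mix_reduction * w)
  phase <- ifelse(b$lat >= 0, 0.22, 0.72)
  J_IO <- b$J0 * (1 + b$J_amp * sin(2 * pi * (t / 365 - phase)))
  list(temp_s = temp_s, q_vert = q_vert, J_IO = pmax(J_IO, 0), w = w)
}

#' Tracer tendencies of the box-model ecosystem
#'
#' Computes d/dt of every tracer in every box (mmol m^-3 d^-1) plus the
#' diagnostic fluxes. Surface boxes carry growth (nitrate and phosphate
#' drawdown at the Redfield ratio; diazotrophs draw ambient NO3 first and
#' fix only the remainder `(k_N/(k_N+NO3))^fix_pow` of their nitrogen
#' demand, logged as fixation), grazing on the three prey with preferences,
#' linear mortality, detritus remineralization and sinking export. Deep
#' boxes remineralize detritus; in boxes flagged denitrifying a fraction
#' `f_denit` of the remineralized nitrogen is removed (a nitrogen sink),
#' unless the configuration disables denitrification (experiment DECAY).
#' Two-layer vertical exchange and lateral exchange along the edge list
#' close the transport. Iron-masked boxes have their maximum growth rates
#' scaled by the mask factor.
#'
#' The nitrogen budget closes by construction: the sum of nitrogen
#' tendencies over all tracers equals fixation minus denitrification in
#' every box; total phosphorus is exactly conserved.
#'
#' @param state an `ecosystem_state` (non-negative, finite).
#' @param geometry a [box_geometry()].
#' @param params an [ecosystem_params()] (defaults to `config$params`).
#' @param config an experiment configuration from [build_config()].
#' @param t model time in days (enters through the forcing).
#' @return list with `dstate` (array like `state`), `fixation` and `denit`
#'   (per column, mmol N m^-3 d^-1, referring to the surface and deep box
#'   respectively), and `grazing` (columns `PhyO`, `PhyD`, `Det`; surface
#'   fluxes, mmol N m^-3 d^-1).
#' @export
tendencies <- function(state, geometry, params = config$params, config, t = 0) {
  check_state(state, geometry)
  frc <- forcing_at(t, geometry, config)
  res <- rhs_core(state, geometry, params, config, frc, t)
  res$dstate <- as_state(res$dstate, geometry)
  res
}

# Internal RHS without input validation; `state` may carry transient small
# negatives during Runge-Kutta stages (limitation terms clamp at zero).
#' @keywords internal
rhs_core <- function(state, geometry, params, config, frc, t) {
  b <- geometry$boxes
  n <- nrow(b)
  p <- params
  V_s <- geometry$V_s; V_d <- geometry$V_d

  NO3s <- pmax(state[, 1L, 1L], 0); PO4s <- pmax(state[, 2L, 1L], 0)
  PhyOs <- pmax(state[, 3L, 1L], 0); PhyDs <- pmax(state[, 4L, 1L], 0)
  Zoos <- pmax(state[, 5L, 1L], 0); Dets <- pmax(state[, 6L, 1L], 0)
  NO3d <- pmax(state[, 1L, 2L], 0); PO4d <- pmax(state[, 2L, 2L], 0)
  PhyOd <- pmax(state[, 3L, 2L], 0); PhyDd <- pmax(state[, 4L, 2L], 0)
  Zood <- pmax(state[, 5L, 2L], 0); Detd <- pmax(state[, 6L, 2L], 0)

  # --- surface biology -----------------------------------------------------
  JmaxO <- p$J_O_max * b$iron
  JmaxD <- p$J_D_max * b$iron
  J_O <- pmin(frc$J_IO, JmaxO * NO3s / (p$k_N + NO3s),
              JmaxO * PO4s / (p$k_P + PO4s))
  J_D <- pmin(frc$J_IO, JmaxD * PO4s / (p$k_P_d + PO4s)) *
    (frc$temp_s >= p$T_min_diaz)
  G_O <- J_O * PhyOs
  G_D <- J_D * PhyDs
  f_fix <- (p$k_N / (p$k_N + NO3s))^p$fix_pow  # fixed fraction of diaz N demand
  fixation <- G_D * f_fix
  no3_uptake <- G_O + G_D * (1 - f_fix)
  po4_uptake <- (G_O + G_D) / p$r_NP

  denom <- if (p$holling_saturating) {
    1 + (p$theta_o * PhyOs + p$theta_d * PhyDs + p$theta_det * Dets) / p$k_graze
  } else 1
  gr_O <- p$mu_max * Zoos * p$theta_o * PhyOs / denom
  gr_D <- p$mu_max * Zoos * p$theta_d * PhyDs / denom
  gr_Det <- p$mu_max * Zoos * p$theta_det * Dets / denom
  gr_tot <- gr_O + gr_D + gr_Det

  remin_s <- p$remin_surface * Dets
  excr_s <- p$z_excrete * Zoos
  sink <- p$det_sink * Dets

  dNO3s <- -no3_uptake + remin_s + excr_s
  dPO4s <- -po4_uptake + (remin_s + excr_s) / p$r_NP
  dPhyOs <- G_O - gr_O - p$mortality * PhyOs
  dPhyDs <- G_D - gr_D - p$mortality * PhyDs
  dZoos <- p$z_assim * gr_tot - (p$z_excrete + p$z_mort) * Zoos
  dDets <- p$mortality * (PhyOs + PhyDs) + (1 - p$z_assim) * gr_tot +
    p$z_mort * Zoos - gr_Det - remin_s - sink

  # --- deep box ------------------------------------------------------------
  remin_d <- p$remin_deep * Detd
  excr_d <- p$z_excrete * Zood
  denit_on <- if (isTRUE(config$denitrification_enabled)) 1 else 0
  denit <- p$f_denit * remin_d * b$denitrifying * denit_on

  dNO3d <- remin_d - denit + excr_d
  dPO4d <- (remin_d + excr_d) / p$r_NP
  dPhyOd <- -p$mortality * PhyOd
  dPhyDd <- -p$mortality * PhyDd
  dZood <- -(p$z_excrete + p$z_mort) * Zood
  dDetd <- sink * V_s / V_d + p$mortality * (PhyOd + PhyDd) +
    p$z_mort * Zood - remin_d

  d <- array(0, dim = c(n, 6L, 2L))
  d[, 1L, 1L] <- dNO3s; d[, 2L, 1L] <- dPO4s; d[, 3L, 1L] <- dPhyOs
  d[, 4L, 1L] <- dPhyDs; d[, 5L, 1L] <- dZoos; d[, 6L, 1L] <- dDets
  d[, 1L, 2L] <- dNO3d; d[, 2L, 2L] <- dPO4d; d[, 3L, 2L] <- dPhyOd
  d[, 4L, 2L] <- dPhyDd; d[, 5L, 2L] <- dZood; d[, 6L, 2L] <- dDetd

  # --- transport (applied to the raw state, conservative by construction) --
  for (k in 1:6) {
    cs <- state[, k, 1L]; cd <- state[, k, 2L]
    d[, k, 1L] <- d[, k, 1L] + frc$q_vert / V_s * (cd - cs)
    d[, k, 2L] <- d[, k, 2L] + frc$q_vert / V_d * (cs - cd)
    e <- geometry$edges
    if (!is.null(e)) {
      for (j in seq_len(nrow(e))) {
        i1 <- e$from[j]; i2 <- e$to[j]
        d[i1, k, 1L] <- d[i1, k, 1L] + e$q_surface[j] / V_s[i1] * (cs[i2] - cs[i1])
        d[i2, k, 1L] <- d[i2, k, 1L] + e$q_surface[j] / V_s[i2] * (cs[i1] - cs[i2])
        d[i1, k, 2L] <- d[i1, k, 2L] + e$q_deep[j] / V_d[i1] * (cd[i2] - cd[i1])
        d[i2, k, 2L] <- d[i2, k, 2L] + e$q_deep[j] / V_d[i2] * (cd[i1] - cd[i2])
      }
    }
  }

  list(dstate = d, fixation = fixation, denit = denit,
       grazing = cbind(PhyO = gr_O, PhyD = gr_D, Det = gr_Det))
}

#' Advance the state by one time step
#'
#' One explicit fixed-step classical Runge-Kutta (RK4) step of length `dt`
#' days. Small negative concentrations produced by the explicit step are
#' clipped to zero when their magnitude is below `clip_eps`; the clipped
#' mass is returned so callers can audit it. A negative excursion beyond
#' `clip_eps` raises an error advising a smaller time step.
#'
#' @param state an `ecosystem_state`.
#' @param geometry a [box_geometry()].
#' @param params an [ecosystem_params()] (defaults to `config$params`).
#' @param config an experiment configuration from [build_config()].
#' @param t model time at the start of the step, days.
#' @param dt step length, days (> 0).
#' @param clip_eps clipping tolerance, mmol m^-3.
#' @return list with the advanced `state`, the new time `t`, `clipped`
#'   (total clipped mass, mol, nitrogen-currency tracers plus PO4 in mol P)
#'   and the RK4-weighted step-mean `fixation` and `denit` fluxes
#'   (per column, mmol m^-3 d^-1).
#' @export
step_state <- function(state, geometry, params = config$params, config,
                       t = 0, dt = 0.5, clip_eps = 1e-5) {
  if (!(is.numeric(dt) && length(dt) == 1L && dt > 0))
    stop("dt must be a single positive number of days", call. = FALSE)
  check_state(state, geometry)
  f <- function(tt, y) rhs_core(y, geometry, params, config,
                                forcing_at(tt, geometry, config), tt)
  k1 <- f(t, state)
  y2 <- state + dt / 2 * k1$dstate
  k2 <- f(t + dt / 2, y2)
  y3 <- state + dt / 2 * k2$dstate
  k3 <- f(t + dt / 2, y3)
  y4 <- state + dt * k3$dstate
  k4 <- f(t + dt, y4)
  out <- state + dt / 6 *
    (k1$dstate + 2 * k2$dstate + 2 * k3$dstate + k4$dstate)

  neg <- out < 0
  clipped <- 0
  if (any(neg)) {
    worst <- min(out[neg])
    if (worst < -clip_eps)
      stop(sprintf(paste0("negative tracer excursion %.3g mmol/m3 exceeds ",
                          "clip_eps = %.3g; reduce dt"), worst, clip_eps),
           call. = FALSE)
    V <- array(rep(cbind(geometry$V_s, geometry$V_d),
                   each = 0), dim = dim(out))
    Vfull <- aperm(array(rep(cbind(geometry$V_s, geometry$V_d), times = 6L),
                         dim = c(nrow(geometry$boxes), 2L, 6L)), c(1L, 3L, 2L))
    clipped <- -sum(out[neg] * Vfull[neg]) * 1e-3  # mol
    out[neg] <- 0
  }
  wmean <- function(field) {
    (k1[[field]] + 2 * k2[[field]] + 2 * k3[[field]] + k4[[field]]) / 6
  }
  list(state = as_state(out, geometry), t = t + dt, clipped = clipped,
       fixation = wmean("fixation"), denit = wmean("denit"))
}
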