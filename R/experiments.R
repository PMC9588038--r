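#' Build an experiment configuration
#'
#' The four experiments encode the competitive-advantage paradigms through
#' parameter relations:
#' * `CONTR` --- no advantage beyond N2 fixation itself: equal grazing
#'   pressure (`theta_d = theta_o`) and equal phosphate affinity
#'   (`k_P_d = k_P`).
#' * `GRAZ` --- selective grazing: `theta_d < theta_o` (default 0.1 vs 0.3),
#'   `k_P_d = k_P`.
#' * `OLIGO` --- high-affinity phosphate uptake: `k_P_d < k_P` (default
#'   0.012 mmol P m^-3, about a quarter of `k_P`), `theta_d = theta_o`.
#' * `DECAY` --- identical to `CONTR` but with the denitrification term
#'   nulled, so the diazotroph niche drains as fixation fills the global
#'   nitrogen deficit.
#'
#' Overrides may adjust any [ecosystem_params()] field or the configuration
#' fields (`scenario`, `warming`, `dt`, `seed`, `spinup`, `year0`), but must
#' not violate the paradigm relations above; violating overrides are
#' rejected with an error naming the offending keys.
#'
#' @param paradigm one of `"CONTR"`, `"GRAZ"`, `"OLIGO"`, `"DECAY"`.
#' @param overrides named list of parameter or configuration overrides.
#' @return An object of class `experiment_config`: list with `paradigm`,
#'   `params` (an `ecosystem_params`), `denitrification_enabled`,
#'   `scenario`, `year0`, `warming` (ramp spec: `start_year`, `end_year`,
#'   `dT_surface` degC, `mix_reduction` fraction), `dt`, `seed` and the
#'   `spinup` settings (`tol` drift per century, `max_years`,
#'   `block_years`).
#' @examples
#' cfg <- build_config("GRAZ")
#' cfg$params$theta_d  # 0.1
#' @export
build_config <- function(paradigm = c("CONTR", "GRAZ", "OLIGO", "DECAY"),
                         overrides = list()) {
  paradigm <- match.arg(paradigm)
  stopifnot(is.list(overrides))
  if (length(overrides) && is.null(names(overrides)))
    stop("overrides must be a named list", call. = FALSE)

  cfg_fields <- c("scenario", "warming", "dt", "seed", "spinup", "year0",
                  "denitrification_enabled")
  par_over <- overrides[setdiff(names(overrides), cfg_fields)]
  cfg_over <- overrides[intersect(names(overrides), cfg_fields)]

  defaults <- formals(ecosystem_params)
  unknown <- setdiff(names(par_over), c(names(defaults), "J_D_max"))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if ("J_D_max" %in% names(par_over))
    stop("J_D_max is derived from C_d * J_O_max; override C_d instead",
         call. = FALSE)

  preset <- switch(paradigm,
    CONTR = list(),
    DECAY = list(),
    GRAZ  = list(theta_d = 0.1),
    OLIGO = list(k_P_d = 0.012)
  )
  par_args <- utils::modifyList(preset, par_over)
  params <- do.call(ecosystem_params, par_args)

  # paradigm relations (rejected overrides name the keys involved)
  bad <- character()
  eq <- function(a, b) isTRUE(abs(a - b) < 1e-12)
  if (paradigm %in% c("CONTR", "DECAY")) {
    if (!eq(params$theta_d, params$theta_o)) bad <- c(bad, "theta_d")
    if (!eq(params$k_P_d, params$k_P)) bad <- c(bad, "k_P_d")
  } else if (paradigm == "GRAZ") {
    if (!(params$theta_d < params$theta_o)) bad <- c(bad, "theta_d")
    if (!eq(params$k_P_d, params$k_P)) bad <- c(bad, "k_P_d")
  } else if (paradigm == "OLIGO") {
    if (!(params$k_P_d < params$k_P)) bad <- c(bad, "k_P_d")
    if (!eq(params$theta_d, params$theta_o)) bad <- c(bad, "theta_d")
  }
  if (length(bad))
    stop(paradigm, " paradigm constraints violated by: ",
         paste(bad, collapse = ", "), call. = FALSE)

  cfg <- list(
    paradigm = paradigm,
    params = params,
    denitrification_enabled = paradigm != "DECAY",
    scenario = "preindustrial",
    year0 = 0,
    warming = list(start_year = 1800, end_year = 2150,
                   dT_surface = 4.0, mix_reduction = 0.5),
    dt = 0.5,
    seed = 1L,
    spinup = list(tol = 0.001, max_years = 9000, block_years = 200)
  )
  for (f in names(cfg_over)) {
    if (f == "warming" || f == "spinup")
      cfg[[f]] <- utils::modifyList(cfg[[f]], cfg_over[[f]])
    else cfg[[f]] <- cfg_over[[f]]
  }
  if (paradigm == "DECAY" && isTRUE(cfg$denitrification_enabled))
    stop("DECAY paradigm constraints violated by: denitrification_enabled",
         call. = FALSE)
  class(cfg) <- "experiment_config"
  cfg
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> %s (%s scenario)\n", x$paradigm, x$scenario))
  cat(sprintf("  theta_d = %.3g (theta_o = %.3g), k_P_d = %.4g (k_P = %.4g), denitrification %s\n",
              x$params$theta_d, x$params$theta_o, x$params$k_P_d, x$params$k_P,
              if (x$denitrification_enabled) "on" else "off"))
  invisible(x)
}

#' Integrate to quasi-equilibrium
#'
#' Runs the pre-industrial configuration in blocks until the relative drift
#' per century of global fixation, diazotroph biomass inventory and the
#' total nitrogen inventory all fall below `config$spinup$tol`, or until the
#' year cap is reached (in which case the result carries
#' `converged = FALSE` and a warning is issued, never a silent success).
#'
#' @param config an [build_config()] configuration (scenario is forced to
#'   pre-industrial during spin-up).
#' @param geometry a [box_geometry()].
#' @param state optional starting state; defaults to [initial_state()].
#' @param quiet suppress the per-block progress messages.
#' @return A `diazo_run` with the concatenated annual diagnostics and the
#'   extra fields `converged` (logical) and `drift` (named vector of the
#'   final per-century drifts).
#' @export
spinup_to_equilibrium <- function(config, geometry = box_geometry(),
                                  state = initial_state(geometry),
                                  quiet = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  config$scenario <- "preindustrial"
  block <- config$spinup$block_years
  tol <- config$spinup$tol
  maxy <- config$spinup$max_years
  stopifnot(block >= 40, maxy >= block)

  annual <- NULL
  run <- NULL
  drift <- c(fixation = Inf, biomass = Inf, nitrogen = Inf)
  total <- 0
  converged <- FALSE
  while (total < maxy) {
    run <- run_model(state, geometry, config, years = block)
    state <- run$state_final
    run$annual$year <- run$annual$year + total
    annual <- rbind(annual, run$annual)
    total <- total + block
    a <- run$annual
    head_m <- function(v) mean(v[1:20])
    tail_m <- function(v) mean(v[(block - 19):block])
    per_century <- 100 / (block - 20)
    rel <- function(v, floor) {
      abs(tail_m(v) - head_m(v)) / max(abs(mean(v)), floor) * per_century
    }
    drift <- c(fixation = rel(a$fixation_TgN_yr, 1),
               biomass = rel(a$biomass_diaz_TgC, 1),
               nitrogen = rel(a$N_mol, 1e12))
    if (!quiet)
      message(sprintf("spin-up year %d: drift/century fix %.2e bio %.2e N %.2e",
                      total, drift[1], drift[2], drift[3]))
    if (all(drift < tol)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf(paste0("spin-up reached the %d-year cap without meeting ",
                           "the %.3g/century drift tolerance (achieved: ",
                           "fixation %.2e, biomass %.2e, nitrogen %.2e)"),
                    maxy, tol, drift[1], drift[2], drift[3]))
  out <- run
  out$annual <- annual
  out$years <- total
  out$converged <- converged
  out$drift <- drift
  out
}

#' Run the warming-stratification scenario
#'
#' Applies the warming ramp (surface temperature up by `dT_surface`,
#' inter-layer mixing scaled down by `mix_reduction`, both following a
#' normalized quadratic ramp between `start_year` and `end_year`) to a
#' spun-up equilibrium state and integrates across the ramp period, emitting
#' annual diagnostics.
#'
#' @param config an [build_config()] configuration; its paradigm must match
#'   the paradigm of the supplied equilibrium.
#' @param equilibrium a `diazo_run` from [spinup_to_equilibrium()].
#' @param record_snapshots keep annual-mean states.
#' @return A `diazo_run` covering `start_year + 1 .. end_year`.
#' @export
run_scenario <- function(config, equilibrium, record_snapshots = FALSE) {
  stopifnot(inherits(config, "experiment_config"),
            inherits(equilibrium, "diazo_run"))
  if (!identical(config$paradigm, equilibrium$config$paradigm))
    stop("paradigm mismatch: scenario config is ", config$paradigm,
         " but the equilibrium was spun up under ",
         equilibrium$config$paradigm, call. = FALSE)
  config$scenario <- "warming"
  config$year0 <- config$warming$start_year
  years <- config$warming$end_year - config$warming$start_year
  run_model(equilibrium$state_final, equilibrium$geometry, config,
            years = years, record_snapshots = record_snapshots)
}

#' Parameter sensitivity scan
#'
#' Spins the model to equilibrium for each value of `theta_d` (selective
#' grazing paradigm) or `k_P_d` (high-affinity paradigm) and tabulates the
#' equilibrium global fixation and diazotroph biomass. The mean absolute
#' response is reported per reference step --- 0.02 in `theta_d` and 0.0088
#' in `k_P_d`, i.e. 20% of the covered parameter ranges (0.1 and 0.044).
#' Non-converged members are flagged and excluded from the response means.
#'
#' Consecutive scan members warm-start from the previous equilibrium, so a
#' monotone grid converges quickly.
#'
#' @param config base configuration ([build_config()]); the scanned
#'   parameter is overridden per member.
#' @param param_name `"theta_d"` or `"k_P_d"`.
#' @param values numeric vector of parameter values (scanned in the order
#'   given; the returned table is sorted by value).
#' @param geometry a [box_geometry()].
#' @param state starting state for the first member.
#' @return data frame with one row per member: `value`,
#'   `fixation_TgN_yr`, `biomass_TgC`, `biomass_outside_TgC` (diazotroph
#'   biomass outside the denitrification-fed columns), `converged`.
#'   Attribute `"response"`: list with the reference `step` and the mean
#'   absolute changes `dfix_per_step` (Tg N yr^-1) and `dbiomass_per_step`
#'   (Tg C); `NA` for scans of length 1.
#' @export
sensitivity_scan <- function(config, param_name = c("theta_d", "k_P_d"),
                             values, geometry = box_geometry(),
                             state = initial_state(geometry)) {
  param_name <- match.arg(param_name)
  stopifnot(is.numeric(values), length(values) >= 1, !anyNA(values))
  ord <- order(values)
  step_ref <- if (param_name == "theta_d") 0.02 else 0.0088

  rows <- vector("list", length(values))
  st <- state
  mmol_to_TgC <- 1e-3 * config$params$r_CN * 12 * 1e-12
  fed <- denit_fed_columns(geometry)
  for (k in seq_along(ord)) {
    v <- values[ord[k]]
    ov <- stats::setNames(list(v), param_name)
    cfg_v <- build_config(config$paradigm, overrides = ov)
    cfg_v$spinup <- config$spinup
    cfg_v$dt <- config$dt
    sp <- withCallingHandlers(
      spinup_to_equilibrium(cfg_v, geometry, st),
      warning = function(w) {
        if (grepl("drift tolerance", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    st <- sp$state_final
    a <- utils::tail(sp$annual, 20)
    pd <- st[, "PhyD", "surface"] * geometry$V_s +
      st[, "PhyD", "deep"] * geometry$V_d
    rows[[k]] <- data.frame(
      value = v,
      fixation_TgN_yr = mean(a$fixation_TgN_yr),
      biomass_TgC = mean(a$biomass_diaz_TgC),
      biomass_outside_TgC = sum(pd[-fed]) * mmol_to_TgC,
      converged = sp$converged
    )
  }
  tab <- do.call(rbind, rows)

  response <- list(step = step_ref, dfix_per_step = NA_real_,
                   dbiomass_per_step = NA_real_)
  ok <- which(tab$converged)
  if (length(values) >= 2 && length(ok) >= 2) {
    tt <- tab[ok, ]
    dv <- diff(tt$value)
    response$dfix_per_step <-
      mean(abs(diff(tt$fixation_TgN_yr) / dv)) * step_ref
    response$dbiomass_per_step <-
      mean(abs(diff(tt$biomass_TgC) / dv)) * step_ref
  } else if (length(values) == 1) {
    message("sensitivity_scan: single-member scan; response undefined")
  }
  attr(tab, "response") <- response
  attr(tab, "param") <- param_name
  tab
}

#' Detect a tipping point in a sensitivity scan
#'
#' Scans the table (ordered by parameter value) for the value at which the
#' diazotroph biomass outside the denitrification-fed columns collapses
#' below `frac` of its maximum across the scan --- the regime where all
#' diazotrophs retreat to the upwelling regions. Returns the parameter
#' value on the collapsed side of the first crossing, or `NA` if the scan
#' never crosses (flat scans have no tipping point).
#'
#' @param scan_table a data frame from [sensitivity_scan()] (or any table
#'   with columns `value` and `biomass_outside_TgC`).
#' @param frac collapse threshold as a fraction of the scan maximum.
#' @return the tipping parameter value, or `NA_real_` if none.
#' @export
detect_tipping_point <- function(scan_table, frac = 0.01) {
  stopifnot(is.data.frame(scan_table),
            all(c("value", "biomass_outside_TgC") %in% names(scan_table)))
  if (nrow(scan_table) < 5)
    stop("tipping-point detection needs a scan over >= 5 values",
         call. = FALSE)
  tab <- scan_table[order(scan_table$value), ]
  out <- tab$biomass_outside_TgC
  thr <- frac * max(out)
  below <- out < thr
  if (!any(below) || all(below)) return(NA_real_)
  cross <- which(below[-1] != below[-length(below)])[1]
  if (below[cross + 1]) tab$value[cross + 1] else tab$value[cross]
}

#' The calibrated niche-drainage (DECAY) experiment
#'
#' Runs the full pipeline behind the exponential-decline analysis: spin the
#' no-advantage control (CONTR) to quasi-equilibrium, rescale the nutrient
#' pools so the excess-P inventory in nitrogen equivalents equals
#' `target_excess_molN` (default 5.5 Pmol N), switch off denitrification
#' (DECAY) and integrate; then fit a log-linear decline to the global
#' diazotroph biomass. With denitrification nulled, fixation fills the
#' global nitrogen deficit and the diazotroph niche closes at the timescale
#' set by the ratio of the excess-P inventory to the fixation rate.
#'
#' @param geometry a [box_geometry()].
#' @param target_excess_molN calibration target for the initial excess-P
#'   inventory, mol N equivalents.
#' @param years length of the DECAY integration, model years.
#' @param fit_window years (indices into the DECAY run) used for the
#'   log-linear fit; the default drops a 100-year adjustment transient.
#' @param spinup_config optional CONTR configuration override.
#' @param equilibrium optional pre-computed CONTR equilibrium (`diazo_run`)
#'   to skip the spin-up.
#' @return list with `tau_fit_yr` (fitted e-folding time), `r_squared`,
#'   `fix0_TgN_yr` (initial fixation, mean of the first 10 DECAY years),
#'   `excess0_molN`, `tau_analytic_yr` (= inventory/fixation via
#'   [niche_closure_timescale()]), and the underlying `decay` and `spinup`
#'   runs.
#' @export
run_decay_experiment <- function(geometry = box_geometry(),
                                 target_excess_molN = 5.5e15,
                                 years = 1500,
                                 fit_window = 101:years,
                                 spinup_config = NULL,
                                 equilibrium = NULL) {
  cfg_c <- if (is.null(spinup_config)) build_config("CONTR") else spinup_config
  sp <- if (is.null(equilibrium)) {
    spinup_to_equilibrium(cfg_c, geometry)
  } else equilibrium
  st <- rescale_excess_p(sp$state_final, geometry, cfg_c$params,
                         target_excess_molN)
  cfg_d <- build_config("DECAY")
  cfg_d$dt <- cfg_c$dt
  dec <- run_model(st, geometry, cfg_d, years = years)
  a <- dec$annual
  fix0 <- mean(a$fixation_TgN_yr[1:10])
  fit <- fit_exponential_decay_timescale(a$biomass_diaz_TgC[fit_window],
                                         a$year[fit_window])
  list(
    tau_fit_yr = fit$tau_yr,
    r_squared = fit$r_squared,
    fix0_TgN_yr = fix0,
    excess0_molN = a$excessP_molN[1],
    tau_analytic_yr = niche_closure_timescale(target_excess_molN / 1e15, fix0),
    decay = dec,
    spinup = sp
  )
}
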