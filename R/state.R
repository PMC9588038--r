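#' @keywords internal
TRACERS <- c("NO3", "PO4", "PhyO", "PhyD", "Zoo", "Det")

#' Construct an ecosystem state
#'
#' The state holds the six tracers (NO3, PO4, ordinary phytoplankton `PhyO`,
#' diazotrophs `PhyD`, zooplankton `Zoo` and detritus `Det`) per column and
#' layer, all in mmol m^-3; biomass tracers are in nitrogen currency.
#'
#' @param geometry a [box_geometry()].
#' @param no3_surface,po4_surface,no3_deep,po4_deep initial dissolved
#'   nutrient concentrations, mmol m^-3. The deep defaults correspond to
#'   observed global means (NO3 ~30.9, PO4 ~2.17 mmol m^-3), which carry a
#'   realistic global excess-P inventory of ~5 Pmol N in nitrogen
#'   equivalents.
#' @param phy_o,phy_d,zoo,det initial surface biomass seeds, mmol N m^-3.
#'   Diazotroph seed is applied only in columns warmer than 15 degC.
#' @return A numeric array of class `ecosystem_state` with dimensions
#'   `(column, tracer, layer)`.
#' @examples
#' g <- box_geometry()
#' s <- initial_state(g)
#' dim(s)  # columns x 6 tracers x 2 layers
#' @export
initial_state <- function(geometry,
                          no3_surface = 2, po4_surface = 0.3,
                          no3_deep = 30.9, po4_deep = 2.17,
                          phy_o = 0.1, phy_d = 0.01,
                          zoo = 0.05, det = 0.02) {
  n <- nrow(geometry$boxes)
  s <- array(0, dim = c(n, 6L, 2L),
             dimnames = list(geometry$boxes$column, TRACERS,
                             c("surface", "deep")))
  s[, "NO3", "surface"] <- no3_surface
  s[, "PO4", "surface"] <- po4_surface
  s[, "NO3", "deep"] <- no3_deep
  s[, "PO4", "deep"] <- po4_deep
  s[, "PhyO", "surface"] <- phy_o
  warm <- geometry$boxes$temp >= 15
  s[warm, "PhyD", "surface"] <- phy_d
  s[, "Zoo", "surface"] <- zoo
  s[, "Det", "surface"] <- det
  class(s) <- c("ecosystem_state", class(s))
  s
}

#' @keywords internal
as_state <- function(x, geometry) {
  n <- nrow(geometry$boxes)
  s <- array(as.numeric(x), dim = c(n, 6L, 2L),
             dimnames = list(geometry$boxes$column, TRACERS,
                             c("surface", "deep")))
  class(s) <- c("ecosystem_state", class(s))
  s
}

#' @keywords internal
check_state <- function(state, geometry) {
  n <- nrow(geometry$boxes)
  if (!is.numeric(state) || !identical(dim(state), c(n, 6L, 2L)))
    stop("state must be a (", n, ", 6, 2) numeric array matching the geometry",
         call. = FALSE)
  if (any(!is.finite(state)))
    stop("state contains non-finite values", call. = FALSE)
  if (any(state < 0))
    stop("state contains negative tracer concentrations", call. = FALSE)
  invisible(state)
}

#' Mass budget of a state
#'
#' Volume-weighted tracer integrals: total bioavailable nitrogen and total
#' phosphorus (in moles), the same masses in teragrams, diazotroph and
#' ordinary phytoplankton biomass in Tg C, and the excess-P inventory in
#' nitrogen equivalents, `r_NP * P_total - N_total` (mol N) --- the resource
#' that defines the diazotroph niche.
#'
#' Nitrogen counts NO3 plus all biomass tracers; phosphorus counts PO4 plus
#' biomass converted at the Redfield ratio `1 / r_NP`. Carbon conversion
#' uses `r_CN` and 12 g mol^-1; nitrogen mass uses 14 g mol^-1.
#'
#' @param state an `ecosystem_state`.
#' @param geometry the matching [box_geometry()].
#' @param params an [ecosystem_params()].
#' @return A list with elements `N_mol`, `P_mol`, `N_Tg`, `P_Tg`,
#'   `excess_P_molN`, `biomass_diaz_TgC`, `biomass_ord_TgC`.
#' @examples
#' g <- box_geometry()
#' mass_budget(initial_state(g), g, ecosystem_params())
#' @export
mass_budget <- function(state, geometry, params) {
  check_state(state, geometry)
  V <- cbind(geometry$V_s, geometry$V_d)  # n x 2
  tot <- function(tr) {  # mmol -> mol, volume-weighted over both layers
    sum(state[, tr, "surface"] * V[, 1L] + state[, tr, "deep"] * V[, 2L]) * 1e-3
  }
  bio <- tot("PhyO") + tot("PhyD") + tot("Zoo") + tot("Det")
  N_mol <- tot("NO3") + bio
  P_mol <- tot("PO4") + bio / params$r_NP
  list(
    N_mol = N_mol,
    P_mol = P_mol,
    N_Tg = N_mol * 14 * 1e-12,
    P_Tg = P_mol * 31 * 1e-12,
    excess_P_molN = params$r_NP * P_mol - N_mol,
    biomass_diaz_TgC = tot("PhyD") * params$r_CN * 12 * 1e-12,
    biomass_ord_TgC = tot("PhyO") * params$r_CN * 12 * 1e-12
  )
}

#' Rescale the excess-phosphorus inventory
#'
#' Scales the dissolved phosphate deficit field
#' `PO4 - NO3 / r_NP` in every box by a common factor so that the global
#' excess-P inventory in nitrogen equivalents (`r_NP * P_total - N_total`)
#' equals `target_molN`. Biomass tracers are Redfield-neutral in the excess
#' bookkeeping, so scaling the dissolved deficit scales the inventory
#' exactly while preserving its spatial pattern --- the spun-up geography of
#' the diazotroph niche is retained, only its size is calibrated (e.g. to
#' 5.5 Pmol N for the DECAY experiment).
#'
#' This is a calibration reset, not a conservative operation: it changes
#' the total phosphorus inventory by construction.
#'
#' @param state an `ecosystem_state`.
#' @param geometry the matching [box_geometry()].
#' @param params an [ecosystem_params()].
#' @param target_molN target excess-P inventory, mol N equivalents.
#' @return The adjusted state.
#' @export
rescale_excess_p <- function(state, geometry, params, target_molN = 5.5e15) {
  stopifnot(is.numeric(target_molN), length(target_molN) == 1L,
            is.finite(target_molN))
  mb <- mass_budget(state, geometry, params)
  if (mb$excess_P_molN <= 0)
    stop("current excess-P inventory is not positive; cannot rescale",
         call. = FALSE)
  s <- target_molN / mb$excess_P_molN
  balanced <- state[, "NO3", ] / params$r_NP
  po4_new <- balanced + s * (state[, "PO4", ] - balanced)
  if (any(po4_new < 0))
    stop("rescaling would make PO4 negative in some box", call. = FALSE)
  state[, "PO4", ] <- po4_new
  state
}
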