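#' Ecosystem rate parameters
#'
#' Constructs the full parameter set of the box-model ecosystem: maximum
#' growth rates, Monod half-saturation constants, zooplankton grazing
#' preferences, stoichiometric conversions and the linear loss/recycling
#' rates. All rates are per day; concentrations are in mmol m^-3 (nitrogen
#' currency for biomass tracers).
#'
#' The printed, field-standard values are `mu_max = 0.4` d^-1 for zooplankton,
#' grazing preferences `theta_o = 0.3` on ordinary phytoplankton and
#' `theta_d = 0.1` on diazotrophs under the selective-grazing paradigm, and a
#' 15 degC lower temperature limit for diazotroph occurrence. The remaining
#' defaults are package calibration constants (see the methods vignette).
#'
#' @param J_O_max maximum ordinary-phytoplankton growth rate, d^-1.
#' @param C_d diazotroph growth handicap in (0, 1]; the diazotroph maximum
#'   growth rate is `J_D_max = C_d * J_O_max`.
#' @param k_N NO3 half-saturation for ordinary phytoplankton, mmol N m^-3.
#' @param k_P PO4 half-saturation for ordinary phytoplankton, mmol P m^-3.
#'   Default is `k_N / 16`, i.e. the Redfield-equivalent of `k_N`.
#' @param k_P_d PO4 half-saturation for diazotrophs, mmol P m^-3. Equal to
#'   `k_P` unless the high-affinity (OLIGO) paradigm lowers it.
#' @param mu_max zooplankton maximum grazing/growth rate, d^-1.
#' @param theta_o,theta_d,theta_det zooplankton preferences in [0, 1] for
#'   ordinary phytoplankton, diazotrophs and detritus.
#' @param T_min_diaz temperature cutoff below which diazotroph growth is
#'   zero, degC.
#' @param r_NP Redfield N:P molar ratio.
#' @param r_CN C:N molar ratio used for carbon-unit conversion.
#' @param chl_per_N chlorophyll conversion, mg Chl a per mmol N.
#' @param mortality linear phytoplankton mortality (both groups), d^-1,
#'   routed to detritus.
#' @param remin_surface,remin_deep detritus remineralization rates in the
#'   surface and deep layer, d^-1.
#' @param z_assim zooplankton assimilation efficiency in (0, 1]; the
#'   unassimilated fraction of grazing goes to detritus.
#' @param z_excrete zooplankton excretion rate, d^-1, returned to dissolved
#'   nutrients.
#' @param z_mort zooplankton mortality, d^-1, routed to detritus.
#' @param det_sink sinking-equivalent transfer rate of surface detritus to
#'   the deep box, d^-1.
#' @param f_denit fraction of deep remineralized nitrogen removed by
#'   denitrification in boxes flagged as denitrifying.
#' @param fix_pow sharpness exponent of the fixation switch: the fraction
#'   of diazotroph nitrogen demand met by fixation (rather than ambient
#'   NO3) is `(k_N / (k_N + NO3))^fix_pow`. With `fix_pow = 2` (default)
#'   fixation shuts down sharply once nitrate fills in, approximating the
#'   rule that diazotrophs draw ambient nitrate first and fix only the
#'   Redfield-balance deficit.
#' @param holling_saturating logical; if `TRUE` the grazing flux is divided
#'   by a saturating multiple-prey denominator
#'   `1 + (theta_o*P_O + theta_d*P_D + theta_det*Det) / k_graze`. Default
#'   `FALSE`: the linear-in-prey form.
#' @param k_graze half-saturation (mmol N m^-3) of the optional saturating
#'   grazing denominator.
#'
#' @return An object of class `ecosystem_params` (a validated named list,
#'   with the derived field `J_D_max`).
#' @examples
#' p <- ecosystem_params()
#' p$J_D_max / p$J_O_max  # the growth handicap C_d
#' @export
ecosystem_params <- function(J_O_max = 0.5,
                             C_d = 0.5,
                             k_N = 0.7,
                             k_P = k_N / r_NP,
                             k_P_d = k_P,
                             mu_max = 0.4,
                             theta_o = 0.3,
                             theta_d = 0.3,
                             theta_det = 0.1,
                             T_min_diaz = 15,
                             r_NP = 16,
                             r_CN = 106 / 16,
                             chl_per_N = 1.59,
                             mortality = 0.03,
                             remin_surface = 0.03,
                             remin_deep = 0.005,
                             z_assim = 0.7,
                             z_excrete = 0.004,
                             z_mort = 0.006,
                             det_sink = 0.10,
                             f_denit = 0.15,
                             fix_pow = 2,
                             holling_saturating = FALSE,
                             k_graze = 1.0) {
  p <- list(
    J_O_max = J_O_max, C_d = C_d, J_D_max = C_d * J_O_max,
    k_N = k_N, k_P = k_P, k_P_d = k_P_d,
    mu_max = mu_max, theta_o = theta_o, theta_d = theta_d,
    theta_det = theta_det, T_min_diaz = T_min_diaz,
    r_NP = r_NP, r_CN = r_CN, chl_per_N = chl_per_N,
    mortality = mortality, remin_surface = remin_surface,
    remin_deep = remin_deep, z_assim = z_assim, z_excrete = z_excrete,
    z_mort = z_mort, det_sink = det_sink, f_denit = f_denit,
    fix_pow = fix_pow,
    holling_saturating = isTRUE(holling_saturating), k_graze = k_graze
  )
  class(p) <- "ecosystem_params"
  validate_params(p)
  p
}

#' Validate an `ecosystem_params` object
#'
#' Checks strict positivity of all rates and half-saturations, `0 < C_d <= 1`
#' and preferences in [0, 1]. Called by [ecosystem_params()]; exported so
#' that configurations assembled by hand can be checked too.
#'
#' @param p an `ecosystem_params` object.
#' @return `p`, invisibly, or an error describing the offending field.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "ecosystem_params"))
  pos <- c("J_O_max", "J_D_max", "k_N", "k_P", "k_P_d", "mu_max", "r_NP",
           "r_CN", "chl_per_N", "mortality", "remin_surface", "remin_deep",
           "z_assim", "z_excrete", "z_mort", "det_sink", "k_graze", "fix_pow")
  for (f in pos) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", f, "' must be a single strictly positive number",
           call. = FALSE)
  }
  if (!(p$C_d > 0 && p$C_d <= 1))
    stop("C_d must lie in (0, 1]", call. = FALSE)
  for (f in c("theta_o", "theta_d", "theta_det")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop("preference '", f, "' must lie in [0, 1]", call. = FALSE)
  }
  if (!(p$z_assim <= 1))
    stop("z_assim must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(p$T_min_diaz) || length(p$T_min_diaz) != 1L ||
      !is.finite(p$T_min_diaz))
    stop("T_min_diaz must be a single finite number", call. = FALSE)
  if (abs(p$J_D_max - p$C_d * p$J_O_max) > 1e-12 * p$J_O_max)
    stop("J_D_max must equal C_d * J_O_max", call. = FALSE)
  invisible(p)
}

#' @export
print.ecosystem_params <- function(x, ...) {
  cat("<ecosystem_params>\n")
  cat(sprintf("  growth: J_O_max = %.3g /d, C_d = %.3g (J_D_max = %.3g /d)\n",
              x$J_O_max, x$C_d, x$J_D_max))
  cat(sprintf("  half-saturations: k_N = %.3g, k_P = %.4g, k_P_d = %.4g mmol/m3\n",
              x$k_N, x$k_P, x$k_P_d))
  cat(sprintf("  grazing: mu_max = %.3g /d, theta (O, D, Det) = %.3g, %.3g, %.3g%s\n",
              x$mu_max, x$theta_o, x$theta_d, x$theta_det,
              if (x$holling_saturating) " [saturating]" else ""))
  cat(sprintf("  diazotroph T cutoff: %.3g degC\n", x$T_min_diaz))
  invisible(x)
}
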