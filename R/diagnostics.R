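#' Construct a gridded field
#'
#' A minimal container for a 2-D (lat x lon) or per-box scalar field with a
#' mandatory units attribute, a validity mask and cell areas. Every metric
#' in the package checks units and respects the mask; mixing units raises
#' an error rather than silently converting.
#'
#' @param values numeric matrix (lat x lon) or vector (per box).
#' @param units units string, e.g. `"mmol N m-2 yr-1"`, `"mg C m-2"`,
#'   `"mg Chl a m-3"`. Mandatory.
#' @param area cell areas, m^2, same shape as `values`.
#' @param mask logical validity mask, same shape as `values`; `TRUE` means
#'   valid. Defaults to everything valid.
#' @param lat,lon optional coordinate vectors for matrix fields.
#' @return object of class `gridded_field`.
#' @export
gridded_field <- function(values, units, area, mask = NULL,
                          lat = NULL, lon = NULL) {
  if (missing(units) || !is.character(units) || length(units) != 1L ||
      !nzchar(units))
    stop("a units attribute is mandatory for gridded fields", call. = FALSE)
  values <- as.array(values) * 1  # force numeric storage
  if (is.null(mask)) mask <- array(TRUE, dim = dim(values))
  if (missing(area) || is.null(area))
    stop("cell areas are mandatory for gridded fields", call. = FALSE)
  area <- as.array(area) * 1
  if (!identical(dim(values), dim(mask)) || !identical(dim(values), dim(area)))
    stop("values, mask and area must have identical shapes", call. = FALSE)
  if (any(area[mask] <= 0) || any(!is.finite(area[mask])))
    stop("cell areas must be positive on the valid mask", call. = FALSE)
  f <- list(values = values, units = units, mask = mask, area = area,
            lat = lat, lon = lon)
  class(f) <- "gridded_field"
  f
}

#' @export
print.gridded_field <- function(x, ...) {
  cat(sprintf("<gridded_field> %s cells [%s], %d valid, range %.3g..%.3g\n",
              paste(dim(x$values), collapse = " x "), x$units,
              sum(x$mask), min(x$values[x$mask]), max(x$values[x$mask])))
  invisible(x)
}

#' @keywords internal
check_congruent <- function(a, b) {
  stopifnot(inherits(a, "gridded_field"), inherits(b, "gridded_field"))
  if (!identical(a$units, b$units))
    stop("unit mismatch: '", a$units, "' vs '", b$units,
         "'; regrid/convert explicitly first", call. = FALSE)
  if (!identical(dim(a$values), dim(b$values)))
    stop("grid mismatch: fields must be congruent (regrid first)",
         call. = FALSE)
  invisible(TRUE)
}

#' Root-mean-square misfit between two congruent fields
#'
#' Unweighted RMSE over the jointly valid cells, in the common units of the
#' two fields. An area-weighted variant is available via `area_weighted`.
#'
#' @param model,obs congruent `gridded_field`s with identical units.
#' @param area_weighted if `TRUE`, cells are weighted by area.
#' @return scalar misfit in the fields' units.
#' @examples
#' a <- gridded_field(matrix(1:4, 2), "mmol N m-2 yr-1", matrix(1, 2, 2))
#' rmse_misfit(a, a)  # 0
#' @export
rmse_misfit <- function(model, obs, area_weighted = FALSE) {
  check_congruent(model, obs)
  joint <- model$mask & obs$mask
  if (!any(joint))
    stop("empty joint validity mask", call. = FALSE)
  d2 <- (model$values[joint] - obs$values[joint])^2
  if (area_weighted) {
    w <- model$area[joint]
    sqrt(sum(w * d2) / sum(w))
  } else {
    sqrt(mean(d2))
  }
}

#' Bloom intensity: upper decile of positive values
#'
#' The 90th percentile of the strictly positive valid cell values (computed
#' with the linear-interpolation percentile, `stats::quantile` type 7) ---
#' a bloom-intensity summary of a patchy field. The alternative reading,
#' the mean of the top decile, is available via `method = "mean_top_decile"`.
#'
#' @param field a `gridded_field` with at least one positive valid value.
#' @param method `"p90"` (default) or `"mean_top_decile"`.
#' @return scalar in the field's units.
#' @export
bloom_intensity_p90 <- function(field, method = c("p90", "mean_top_decile")) {
  method <- match.arg(method)
  stopifnot(inherits(field, "gridded_field"))
  v <- field$values[field$mask]
  v <- v[v > 0]
  if (!length(v))
    stop("field has no positive valid values", call. = FALSE)
  if (method == "p90") {
    unname(stats::quantile(v, 0.9, type = 7))
  } else {
    q <- stats::quantile(v, 0.9, type = 7)
    mean(v[v >= q])
  }
}

#' Surface chlorophyll field from phytoplankton biomass
#'
#' Applies the constant conversion `chl = chl_per_N * (P_O + P_D)`
#' (default 1.59 mg Chl a per mmol N) to surface biomass concentrations.
#'
#' @param P_O,P_D surface biomass, mmol N m^-3 (vectors or matrices of
#'   identical shape, non-negative).
#' @param area cell areas, m^2.
#' @param params an [ecosystem_params()] (supplies `chl_per_N`).
#' @param mask optional validity mask.
#' @return a `gridded_field` in mg Chl a m^-3.
#' @export
chlorophyll_field <- function(P_O, P_D, area, params = ecosystem_params(),
                              mask = NULL) {
  if (any(P_O < 0) || any(P_D < 0))
    stop("biomass concentrations must be >= 0", call. = FALSE)
  gridded_field(params$chl_per_N * (P_O + P_D), "mg Chl a m-3",
                area = area, mask = mask)
}

#' Oligotrophic area fraction
#'
#' Area-weighted fraction of valid ocean cells whose surface chlorophyll is
#' below the threshold (default 0.07 mg Chl a m^-3, the standard
#' oligotrophy criterion).
#'
#' @param chl a `gridded_field` in mg Chl a m^-3.
#' @param threshold chlorophyll threshold, mg Chl a m^-3 (> 0).
#' @return fraction in [0, 1].
#' @export
oligotrophic_area_fraction <- function(chl, threshold = 0.07) {
  stopifnot(inherits(chl, "gridded_field"))
  if (!identical(chl$units, "mg Chl a m-3"))
    stop("oligotrophic_area_fraction expects units 'mg Chl a m-3', got '",
         chl$units, "'", call. = FALSE)
  if (!(is.numeric(threshold) && length(threshold) == 1L && threshold > 0))
    stop("threshold must be a single positive number", call. = FALSE)
  if (is.null(chl$area))
    stop("cell areas are required", call. = FALSE)
  m <- chl$mask
  sum(chl$area[m & (chl$values < threshold)]) / sum(chl$area[m])
}

#' Fit an exponential decay timescale
#'
#' Least-squares slope of `log(series)` against time; returns the e-folding
#' time `-1/slope` and the R^2 of the log-linear fit. A non-negative slope
#' (no decay) yields an infinite timescale.
#'
#' @param series strictly positive time series (>= 10 points).
#' @param t times, years, same length as `series`.
#' @return list with `tau_yr`, `r_squared` and the fitted `slope`
#'   (yr^-1).
#' @examples
#' t <- 0:200
#' fit_exponential_decay_timescale(exp(-t / 500), t)$tau_yr  # 500
#' @export
fit_exponential_decay_timescale <- function(series, t) {
  if (length(series) < 10)
    stop("need at least 10 points to fit a decay timescale", call. = FALSE)
  if (length(t) != length(series))
    stop("series and t lengths differ", call. = FALSE)
  if (any(!is.finite(series)) || any(series <= 0))
    stop("series must be strictly positive for a log-linear fit",
         call. = FALSE)
  fit <- stats::lm(log(series) ~ t)
  slope <- unname(stats::coef(fit)[2])
  y <- log(series)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  tau <- if (slope < 0) -1 / slope else Inf
  list(tau_yr = tau, r_squared = r2, slope = slope)
}

#' Analytic niche-closure timescale
#'
#' The time for nitrogen fixation to erase the global excess-phosphorus
#' niche: `tau = inventory / rate`, with the inventory given in Pmol N
#' equivalents (converted at 14 g mol^-1 to Tg N) and the fixation rate in
#' Tg N yr^-1. With the canonical inventory of 5.5 Pmol N and fixation
#' estimates of 70--200 Tg N yr^-1 this spans roughly 400--1100 years.
#'
#' @param excess_inventory_PmolN excess-P inventory in nitrogen
#'   equivalents, Pmol N (>= 0).
#' @param fixation_TgN_per_yr global fixation rate, Tg N yr^-1 (> 0).
#' @return timescale, years.
#' @examples
#' niche_closure_timescale(5.5, 70)   # 1100
#' niche_closure_timescale(5.5, 200)  # 385
#' @export
niche_closure_timescale <- function(excess_inventory_PmolN,
                                    fixation_TgN_per_yr) {
  if (!(is.numeric(excess_inventory_PmolN) && excess_inventory_PmolN >= 0))
    stop("inventory must be >= 0", call. = FALSE)
  if (!(is.numeric(fixation_TgN_per_yr) && fixation_TgN_per_yr > 0))
    stop("fixation rate must be > 0", call. = FALSE)
  inventory_TgN <- excess_inventory_PmolN * 1e15 * 14 * 1e-12
  inventory_TgN / fixation_TgN_per_yr
}

#' Diagnostics series of a model run
#'
#' Augments the annual diagnostics of a [run_model()] result with the
#' oligotrophic area fraction (from the annual-mean surface chlorophyll and
#' the 0.07 mg Chl a m^-3 threshold) and the biomass-to-fixation ratio
#' (Tg C per Tg N yr^-1), which is flagged undefined (NA) in years with
#' non-positive fixation.
#'
#' @param run a `diazo_run`.
#' @param threshold oligotrophy threshold, mg Chl a m^-3.
#' @return data frame: the run's annual table plus `oligo_frac` and
#'   `biomass_fixation_ratio`.
#' @export
diagnostics_series <- function(run, threshold = 0.07) {
  stopifnot(inherits(run, "diazo_run"))
  a <- run$annual
  area <- run$geometry$boxes$area
  a$oligo_frac <- apply(run$chl, 1L, function(v)
    sum(area[v < threshold]) / sum(area))
  a$biomass_fixation_ratio <- ifelse(
    a$fixation_TgN_yr > 0,
    a$biomass_diaz_TgC / a$fixation_TgN_yr, NA_real_)
  a
}

#' Linear trend of an annual diagnostic over a year window
#'
#' Convenience for scenario analysis: least-squares slope of a diagnostic
#' column over `year_range`, with a simple residual-bootstrap confidence
#' interval (a descriptive diagnostic, not a formal significance test).
#'
#' @param series data frame from [diagnostics_series()] (needs a `year`
#'   column).
#' @param column diagnostic column name.
#' @param year_range length-2 numeric, inclusive year window.
#' @param n_boot bootstrap replicates (0 disables the interval).
#' @param seed RNG seed for the bootstrap.
#' @return list with `slope` (units per year), and if bootstrapped,
#'   `ci95` (2.5/97.5 percentiles).
#' @export
trend_slope <- function(series, column, year_range,
                        n_boot = 0, seed = 1L) {
  stopifnot(column %in% names(series), length(year_range) == 2L)
  d <- series[series$year >= year_range[1] & series$year <= year_range[2], ]
  if (nrow(d) < 3) stop("fewer than 3 years in the window", call. = FALSE)
  fit <- stats::lm(d[[column]] ~ d$year)
  out <- list(slope = unname(stats::coef(fit)[2]))
  if (n_boot > 0) {
    set.seed(seed)
    res <- stats::residuals(fit)
    fv <- stats::fitted(fit)
    sl <- replicate(n_boot, {
      y <- fv + sample(res, replace = TRUE)
      unname(stats::coef(stats::lm(y ~ d$year))[2])
    })
    out$ci95 <- stats::quantile(sl, c(0.025, 0.975), names = FALSE)
  }
  out
}
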