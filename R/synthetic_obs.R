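#' Specification for a synthetic observation field
#'
#' Describes an observation-like global field of the kind compiled for
#' nitrogen fixation (mmol N m^-2 yr^-1) or depth-integrated diazotroph
#' biomass (mg C m^-2): a patchy, positively skewed field built from
#' Gaussian hotspots with multiplicative lognormal noise, hard zeros
#' outside a warm latitude band (the habitat constraint) and a prescribed
#' overall zero fraction. The generator returns the noise-free truth
#' alongside, so every diagnostic can be tested against known ground truth.
#'
#' @param nlat,nlon grid size (cell centers, regular lat/lon grid).
#' @param n_hotspots number of Gaussian hotspots.
#' @param length_scale hotspot e-folding length scale, degrees.
#' @param amplitude_meanlog,amplitude_sdlog lognormal hotspot amplitude
#'   parameters (field units).
#' @param sigma lognormal multiplicative noise sigma (>= 0); the noise
#'   factor is `exp(sigma * Z - sigma^2 / 2)`, mean 1.
#' @param zero_fraction target fraction of all grid cells that are exactly
#'   zero (must be at least the fraction of cells outside the warm band).
#' @param warm_lat half-width of the warm band, degrees latitude.
#' @param n_samples default sparse-sample count for [sample_sparse_points()].
#' @param units field units string.
#' @param seed RNG seed; all generators are pure functions of (spec, seed).
#' @return object of class `obs_gen_spec`.
#' @export
obs_gen_spec <- function(nlat = 90, nlon = 180,
                         n_hotspots = 25, length_scale = 8,
                         amplitude_meanlog = log(100), amplitude_sdlog = 0.5,
                         sigma = 0.5, zero_fraction = 0.7, warm_lat = 40,
                         n_samples = 500, units = "mmol N m-2 yr-1",
                         seed = 1L) {
  stopifnot(nlat >= 2, nlon >= 2, n_hotspots >= 0, length_scale > 0,
            sigma >= 0, zero_fraction >= 0, zero_fraction <= 1,
            warm_lat > 0, warm_lat <= 90, n_samples >= 0)
  spec <- list(nlat = nlat, nlon = nlon, n_hotspots = n_hotspots,
               length_scale = length_scale,
               amplitude_meanlog = amplitude_meanlog,
               amplitude_sdlog = amplitude_sdlog,
               sigma = sigma, zero_fraction = zero_fraction,
               warm_lat = warm_lat, n_samples = n_samples,
               units = units, seed = as.integer(seed))
  class(spec) <- "obs_gen_spec"
  spec
}

#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @keywords internal
obs_grid <- function(spec) {
  dlat <- 180 / spec$nlat
  dlon <- 360 / spec$nlon
  lat <- seq(-90 + dlat / 2, 90 - dlat / 2, length.out = spec$nlat)
  lon <- seq(-180 + dlon / 2, 180 - dlon / 2, length.out = spec$nlon)
  R <- 6.371e6
  area_row <- R^2 * (dlon * pi / 180) * (dlat * pi / 180) *
    cos(lat * pi / 180)
  list(lat = lat, lon = lon,
       area = matrix(area_row, spec$nlat, spec$nlon))
}

#' Generate a synthetic observation field with known ground truth
#'
#' Builds the noise-free truth as a sum of Gaussian hotspots (random warm
#' band centers, lognormal amplitudes), hard-zeroes it outside the warm
#' band, zeroes the smallest in-band values until the prescribed overall
#' zero fraction is met, and multiplies the remaining cells by mean-one
#' lognormal noise. Deterministic for a given spec and seed.
#'
#' @param spec an [obs_gen_spec()].
#' @return list with `field` (noisy `gridded_field`), `truth` (noise-free
#'   `gridded_field`) and `hotspots` (data frame of centers and
#'   amplitudes). The fields' validity mask is the warm band.
#' @export
generate_obs_field <- function(spec) {
  stopifnot(inherits(spec, "obs_gen_spec"))
  g <- obs_grid(spec)
  out <- with_seed(spec$seed, {
    latm <- matrix(g$lat, spec$nlat, spec$nlon)
    lonm <- matrix(g$lon, spec$nlat, spec$nlon, byrow = TRUE)
    truth <- matrix(0, spec$nlat, spec$nlon)
    hs <- data.frame(lat = numeric(0), lon = numeric(0),
                     amplitude = numeric(0))
    if (spec$n_hotspots > 0) {
      hs <- data.frame(
        lat = stats::runif(spec$n_hotspots, -spec$warm_lat + 5,
                           spec$warm_lat - 5),
        lon = stats::runif(spec$n_hotspots, -180, 180),
        amplitude = stats::rlnorm(spec$n_hotspots, spec$amplitude_meanlog,
                                  spec$amplitude_sdlog))
      L2 <- spec$length_scale^2
      for (j in seq_len(spec$n_hotspots)) {
        dlon <- abs(lonm - hs$lon[j])
        dlon <- pmin(dlon, 360 - dlon) * cos(hs$lat[j] * pi / 180)
        d2 <- (latm - hs$lat[j])^2 + dlon^2
        truth <- truth + hs$amplitude[j] * exp(-d2 / (2 * L2))
      }
    }
    band <- abs(latm) <= spec$warm_lat
    truth[!band] <- 0
    # thin the smallest in-band values until the overall zero fraction holds
    frac_out <- mean(!band)
    if (spec$zero_fraction > frac_out && any(truth > 0)) {
      need <- (spec$zero_fraction - frac_out) / mean(band)
      thr <- stats::quantile(truth[band], need, type = 7)
      truth[band & truth <= thr] <- 0
    }
    noisy <- truth
    pos <- truth > 0
    if (spec$sigma > 0 && any(pos)) {
      z <- stats::rnorm(sum(pos))
      noisy[pos] <- truth[pos] *
        exp(spec$sigma * z - spec$sigma^2 / 2)
    }
    list(truth = truth, noisy = noisy, band = band, hotspots = hs)
  })
  list(
    field = gridded_field(out$noisy, spec$units, g$area, out$band,
                          lat = g$lat, lon = g$lon),
    truth = gridded_field(out$truth, spec$units, g$area, out$band,
                          lat = g$lat, lon = g$lon),
    hotspots = out$hotspots
  )
}

#' Draw sparse point samples from a gridded field
#'
#' Uniform draw without replacement from the valid cells --- a stand-in for
#' anecdotal shipboard sampling of a patchy field.
#'
#' @param field a `gridded_field` with `lat`/`lon` coordinates.
#' @param n number of samples (<= number of valid cells).
#' @param seed RNG seed.
#' @return data frame with columns `lat`, `lon`, `value`.
#' @export
sample_sparse_points <- function(field, n, seed = 1L) {
  stopifnot(inherits(field, "gridded_field"),
            !is.null(field$lat), !is.null(field$lon))
  idx <- which(field$mask)
  if (n > length(idx))
    stop("requested ", n, " samples but only ", length(idx),
         " valid cells exist", call. = FALSE)
  sel <- with_seed(seed, sample(idx, n))
  rc <- arrayInd(sel, dim(field$values))
  data.frame(lat = field$lat[rc[, 1L]], lon = field$lon[rc[, 2L]],
             value = field$values[sel])
}

#' Grid point samples onto a model grid
#'
#' Nearest-cell binning with cell-mean aggregation; cells receiving no
#' points are masked invalid. Points outside the template grid are dropped
#' (with a message reporting the count).
#'
#' @param points data frame with `lat`, `lon`, `value`.
#' @param template a `gridded_field` defining the target grid, areas and
#'   units.
#' @return a `gridded_field` on the template grid.
#' @export
regrid_to_model <- function(points, template) {
  stopifnot(is.data.frame(points),
            all(c("lat", "lon", "value") %in% names(points)),
            inherits(template, "gridded_field"),
            !is.null(template$lat), !is.null(template$lon))
  if (nrow(points) < 1) stop("need at least one point", call. = FALSE)
  nearest <- function(x, centers) {
    i <- findInterval(x, c(-Inf, centers[-1] - diff(centers) / 2, Inf))
    pmin(pmax(i, 1L), length(centers))
  }
  inside <- points$lat >= -90 & points$lat <= 90 &
    points$lon >= -180 & points$lon <= 180 & is.finite(points$value)
  dropped <- sum(!inside)
  if (dropped > 0)
    message("regrid_to_model: dropped ", dropped, " point(s) outside the grid")
  pts <- points[inside, ]
  if (nrow(pts) < 1) stop("no points fall inside the grid", call. = FALSE)
  ri <- nearest(pts$lat, template$lat)
  ci <- nearest(pts$lon, template$lon)
  cell <- (ci - 1L) * length(template$lat) + ri
  vals <- tapply(pts$value, cell, mean)
  out <- array(NA_real_, dim = dim(template$values))
  out[as.integer(names(vals))] <- as.numeric(vals)
  mask <- !is.na(out)
  out[!mask] <- 0
  gridded_field(out, template$units, template$area, mask,
                lat = template$lat, lon = template$lon)
}
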