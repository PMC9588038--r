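#' Load an experiment configuration from a YAML file
#'
#' The file holds a flat description: a `paradigm` key plus optional
#' `params` (any [ecosystem_params()] field), `scenario`, `warming`, `dt`,
#' `seed`, `spinup` and `year0` blocks. Unknown keys are rejected and the
#' paradigm parameter relations are enforced at load time (see
#' [build_config()]), so a file violating them (e.g. OLIGO with
#' `k_P_d >= k_P`) fails with an error naming the offending keys.
#'
#' @param path path to a YAML configuration file.
#' @return an `experiment_config` (with its `params`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$paradigm))
    stop("config file must name a paradigm", call. = FALSE)
  known <- c("paradigm", "params", "scenario", "warming", "dt", "seed",
             "spinup", "year0", "denitrification_enabled")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  overrides <- c(raw$params,
                 raw[intersect(names(raw), setdiff(known,
                                                   c("paradigm", "params")))])
  build_config(raw$paradigm, overrides = overrides)
}

#' Write an experiment configuration to YAML
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, path))`
#' reproduces an identical configuration.
#'
#' @param config an `experiment_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  p <- unclass(config$params)
  p$J_D_max <- NULL  # derived
  p$holling_saturating <- isTRUE(p$holling_saturating)
  out <- list(paradigm = config$paradigm,
              params = p,
              scenario = config$scenario,
              year0 = config$year0,
              warming = config$warming,
              dt = config$dt,
              seed = config$seed,
              spinup = config$spinup)
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

# full-precision numeric formatting so CSV round-trips are bit-identical
#' @keywords internal
fmt_num <- function(x) sprintf("%.17g", x)

#' @keywords internal
hash_file <- function(path) unname(tools::md5sum(path))

#' @keywords internal
hash_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  con <- file(tmp, "wb")
  serialize(x, con, version = 3L)
  close(con)
  hash_file(tmp)
}

#' Write run outputs with a provenance manifest
#'
#' Writes the annual diagnostics (with units in the header row), the
#' per-column surface chlorophyll and fixation matrices, the trajectory of
#' annual-mean states (if the run recorded snapshots), the configuration,
#' and a manifest listing an MD5 digest of every file plus the package
#' version, seed and solver settings. Numeric values are written at full
#' (17 significant digit) precision so a read-back is bit-identical.
#'
#' @param run a `diazo_run`.
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly (also written to `manifest.yaml`).
#' @export
write_outputs <- function(run, dir) {
  stopifnot(inherits(run, "diazo_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  wr <- function(df, name) {
    path <- file.path(dir, name)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], fmt_num)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    written <<- c(written, path)
    path
  }
  tryCatch({
    diag <- diagnostics_series(run)
    units <- c(year = "yr", fixation_TgN_yr = "Tg N yr-1",
               denit_TgN_yr = "Tg N yr-1", biomass_diaz_TgC = "Tg C",
               biomass_ord_TgC = "Tg C", N_mol = "mol N", P_mol = "mol P",
               excessP_molN = "mol N", oligo_frac = "1",
               biomass_fixation_ratio = "Tg C per Tg N yr-1")
    names(diag) <- paste0(names(diag), " [", units[names(diag)], "]")
    wr(diag, "diagnostics.csv")

    cols <- run$geometry$boxes$column
    chl <- as.data.frame(run$chl)
    names(chl) <- paste0(cols, " [mg Chl a m-3]")
    wr(chl, "surface_chl.csv")
    fx <- as.data.frame(run$fix_box)
    names(fx) <- paste0(cols, " [Tg N yr-1]")
    wr(fx, "fixation_by_column.csv")

    if (!is.null(run$snapshots)) {
      d <- dim(run$snapshots)
      long <- expand.grid(year = seq_len(d[1]), column = cols,
                          tracer = TRACERS,
                          layer = c("surface", "deep"),
                          KEEP.OUT.ATTRS = FALSE)
      long$value <- as.numeric(run$snapshots)
      long$units <- "mmol m-3"
      wr(long, "trajectory.csv")
    }

    cfg_path <- file.path(dir, "config.yaml")
    write_config(run$config, cfg_path)
    written <- c(written, cfg_path)

    manifest <- list(
      package = "diazocomp",
      version = as.character(utils::packageVersion("diazocomp")),
      config_hash = hash_object(run$config),
      seed = run$config$seed,
      solver = list(scheme = "rk4", dt_days = run$dt, years = run$years,
                    clipped_mol = run$clipped_mol),
      created = format(Sys.time(), tz = "UTC"),
      files = stats::setNames(
        as.list(vapply(written, hash_file, character(1))),
        basename(written))
    )
    yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"),
                     precision = 17)
    invisible(manifest)
  }, error = function(e) {
    unlink(written)  # no partial outputs
    stop("write_outputs failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Read run outputs back
#'
#' Reads the CSV outputs of [write_outputs()]; numeric round-trips are
#' bit-identical thanks to full-precision formatting.
#'
#' @param dir directory written by [write_outputs()].
#' @return list with `diagnostics`, `chl`, `fix_box` (numeric), the
#'   `trajectory` array if present, `config` and the parsed `manifest`.
#' @export
read_outputs <- function(dir) {
  rd <- function(name) {
    utils::read.csv(file.path(dir, name), check.names = FALSE)
  }
  diag <- rd("diagnostics.csv")
  chl <- as.matrix(rd("surface_chl.csv"))
  fx <- as.matrix(rd("fixation_by_column.csv"))
  traj <- NULL
  tpath <- file.path(dir, "trajectory.csv")
  if (file.exists(tpath)) {
    long <- utils::read.csv(tpath, check.names = FALSE)
    d1 <- max(long$year)
    ncols <- length(unique(long$column))
    traj <- array(long$value, dim = c(d1, ncols, 6L, 2L),
                  dimnames = list(NULL, unique(long$column), TRACERS,
                                  c("surface", "deep")))
  }
  list(diagnostics = diag, chl = unname(chl), fix_box = unname(fx),
       trajectory = traj,
       config = load_config(file.path(dir, "config.yaml")),
       manifest = yaml::read_yaml(file.path(dir, "manifest.yaml")))
}

#' Write a gridded field to NetCDF (optional)
#'
#' Available when the `ncdf4` package is installed; the primary on-disk
#' format of this package is CSV. Units attributes are always written.
#'
#' @param field a `gridded_field` with lat/lon coordinates.
#' @param path output NetCDF path.
#' @param varname NetCDF variable name.
#' @return `path`, invisibly.
#' @export
write_field_netcdf <- function(field, path, varname = "field") {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("NetCDF output requires the 'ncdf4' package; use the CSV writers ",
         "otherwise", call. = FALSE)
  stopifnot(inherits(field, "gridded_field"),
            !is.null(field$lat), !is.null(field$lon))
  dims <- list(ncdf4::ncdim_def("lat", "degrees_north", field$lat),
               ncdf4::ncdim_def("lon", "degrees_east", field$lon))
  v <- ncdf4::ncvar_def(varname, field$units, dims[c(2, 1)], missval = NA,
                        prec = "double")
  m <- ncdf4::ncvar_def("mask", "1", dims[c(2, 1)], prec = "integer")
  a <- ncdf4::ncvar_def("cell_area", "m2", dims[c(2, 1)], prec = "double")
  nc <- ncdf4::nc_create(path, list(v, m, a))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, v, t(field$values))
  ncdf4::ncvar_put(nc, m, t(field$mask * 1L))
  ncdf4::ncvar_put(nc, a, t(field$area))
  invisible(path)
}

#' Read a gridded field from NetCDF (optional)
#'
#' @param path NetCDF file written by [write_field_netcdf()].
#' @param varname NetCDF variable name.
#' @return a `gridded_field`.
#' @export
read_field_netcdf <- function(path, varname = "field") {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("NetCDF input requires the 'ncdf4' package", call. = FALSE)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  vals <- t(ncdf4::ncvar_get(nc, varname))
  units <- ncdf4::ncatt_get(nc, varname, "units")$value
  mask <- t(ncdf4::ncvar_get(nc, "mask")) > 0
  area <- t(ncdf4::ncvar_get(nc, "cell_area"))
  gridded_field(vals, units, area, mask,
                lat = as.numeric(nc$dim$lat$vals),
                lon = as.numeric(nc$dim$lon$vals))
}
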