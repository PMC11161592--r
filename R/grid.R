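#' Gridded transpiration field
#'
#' In-memory container for a lat x lon x time field in mm/day. Latitudes
#' and longitudes must be ascending (readers normalize automatically);
#' the time axis may be an integer step index, day-of-year values, or
#' `Date`s.
#'
#' @param values numeric array with dim `c(length(lat), length(lon),
#'   length(time))`. `NA` marks missing cells.
#' @param lat,lon coordinate vectors, degrees north / degrees east,
#'   ascending.
#' @param time time axis (numeric or `Date`).
#' @param units units attribute, default `"mm day-1"`.
#' @param product optional product name.
#' @return An object of class `"grid_cube"`.
#' @export
grid_cube <- function(values, lat, lon, time, units = "mm day-1",
                      product = NULL) {
  values <- as.array(values)
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  if (!all(dim(values) == c(length(lat), length(lon), length(time))))
    stop("values must be a lat x lon x time array matching the coordinates",
         call. = FALSE)
  if (is.unsorted(lat, strictly = TRUE) || is.unsorted(lon, strictly = TRUE))
    stop("lat and lon must be strictly ascending", call. = FALSE)
  structure(list(values = values, lat = as.numeric(lat),
                 lon = as.numeric(lon), time = time, units = units,
                 product = product),
            class = "grid_cube")
}

#' @export
print.grid_cube <- function(x, ...) {
  cat("Grid cube", if (!is.null(x$product)) paste0(" [", x$product, "]"),
      ": ", length(x$lat), " x ", length(x$lon), " x ", length(x$time),
      " (lat x lon x time), ", x$units, "\n", sep = "")
  cat("  lat ", min(x$lat), "..", max(x$lat), ", lon ", min(x$lon), "..",
      max(x$lon), ", ", sprintf("%.1f%%", 100 * mean(is.na(x$values))),
      " missing\n", sep = "")
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-8) {
  length(a$lat) == length(b$lat) && length(a$lon) == length(b$lon) &&
    length(a$time) == length(b$time) &&
    max(abs(a$lat - b$lat)) < tol && max(abs(a$lon - b$lon)) < tol
}

FILL_VALUE <- -9999

#' Write a gridded product to netCDF
#'
#' Writes the published layout: dimensions/coordinate variables `lon`
#' (degrees_east), `lat` (degrees_north) and `day`, plus one
#' double-precision data variable on (lon, lat, day). Values round-trip
#' bit-identically through [read_product()].
#'
#' @param cube a [grid_cube()].
#' @param path output file path.
#' @param variable netCDF variable name (default `"Ec"`, standard name
#'   vegetation transpiration).
#' @param overwrite allow replacing an existing file?
#' @return The path, invisibly usable in pipelines.
#' @export
write_product <- function(cube, path, variable = "Ec", overwrite = FALSE) {
  stopifnot(inherits(cube, "grid_cube"))
  if (file.exists(path) && !overwrite)
    stop("refusing to overwrite existing file: ", path, call. = FALSE)
  day_vals <- if (inherits(cube$time, "Date"))
    as.integer(format(cube$time, "%j")) else as.numeric(cube$time)
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", cube$lon)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", cube$lat)
  dim_day <- ncdf4::ncdim_def("day", "day of year", day_vals)
  var <- ncdf4::ncvar_def(variable, cube$units,
                          list(dim_lon, dim_lat, dim_day),
                          missval = FILL_VALUE, prec = "double",
                          longname = "vegetation transpiration")
  nc <- ncdf4::nc_create(path, var)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, var, aperm(cube$values, c(2L, 1L, 3L)))
  if (!is.null(cube$product))
    ncdf4::ncatt_put(nc, 0, "product", cube$product)
  ncdf4::ncatt_put(nc, 0, "lon_convention", "[-180,180) degrees_east")
  path
}

#' Read a gridded product from netCDF
#'
#' Reads one variable and normalizes the grid: latitude rows flipped to
#' ascending order, longitudes wrapped into \[-180, 180) and sorted, fill
#' values masked as `NA`.
#'
#' @param path netCDF file.
#' @param variable variable name to read (default `"Ec"`).
#' @return A [grid_cube()].
#' @export
read_product <- function(path, variable = "Ec") {
  if (!file.exists(path))
    stop("no such file: ", path, call. = FALSE)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (!variable %in% names(nc$var))
    stop(sprintf("variable '%s' not found in %s (available: %s)", variable,
                 path, paste(names(nc$var), collapse = ", ")), call. = FALSE)
  v <- nc$var[[variable]]
  dim_names <- vapply(v$dim, function(d) d$name, "")
  i_lat <- grep("lat", dim_names, ignore.case = TRUE)[1L]
  i_lon <- grep("lon", dim_names, ignore.case = TRUE)[1L]
  if (is.na(i_lat) || is.na(i_lon))
    stop("could not identify lat/lon dimensions in ", path, call. = FALSE)
  i_time <- setdiff(seq_along(dim_names), c(i_lat, i_lon))[1L]
  vals <- ncdf4::ncvar_get(nc, variable, collapse_degen = FALSE)
  vals <- aperm(vals, c(i_lat, i_lon, i_time))
  lat <- v$dim[[i_lat]]$vals
  lon <- v$dim[[i_lon]]$vals
  time <- v$dim[[i_time]]$vals
  if (is.unsorted(lat)) {
    o <- order(lat); lat <- lat[o]; vals <- vals[o, , , drop = FALSE]
  }
  lon <- ((lon + 180) %% 360) - 180
  if (is.unsorted(lon)) {
    o <- order(lon); lon <- lon[o]; vals <- vals[, o, , drop = FALSE]
  }
  units <- if (nzchar(v$units)) v$units else "mm day-1"
  att <- ncdf4::ncatt_get(nc, 0, "product")
  grid_cube(vals, lat, lon, time, units = units,
            product = if (att$hasatt) att$value else NULL)
}

#' Write a merged yearly file in the published convention
#'
#' File name `Merged.Tveg.<year>.nc`, variables `lat`, `lon`, `day`
#' (day of year) and `Ec` (vegetation transpiration, mm/day).
#'
#' @param cube a [grid_cube()] covering one calendar year (its time axis
#'   supplies the `day` values; `Date`s are converted to day of year).
#' @param out_dir output directory (created if needed).
#' @param year calendar year used in the file name.
#' @param overwrite allow replacing an existing file?
#' @return The full file path.
#' @export
write_merged <- function(cube, out_dir, year, overwrite = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  path <- file.path(out_dir, sprintf("Merged.Tveg.%d.nc", as.integer(year)))
  write_product(cube, path, variable = "Ec", overwrite = overwrite)
  path
}

#' Regrid a cube to a target grid
#'
#' Simple statistical regridding: bilinear interpolation (default) or
#' nearest neighbour. Bilinear reproduces fields linear in lat/lon
#' exactly at target cell centers; any contributing missing source cell
#' makes the target cell missing (conservative mask propagation).
#'
#' @param cube a [grid_cube()].
#' @param lat_out,lon_out target coordinates, ascending.
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return A [grid_cube()] on the target grid.
#' @export
regrid <- function(cube, lat_out, lon_out,
                   method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(cube, "grid_cube"))
  if (max(lat_out) < min(cube$lat) || min(lat_out) > max(cube$lat) ||
      max(lon_out) < min(cube$lon) || min(lon_out) > max(cube$lon))
    stop("target grid extent is disjoint from the source grid", call. = FALSE)
  nt <- length(cube$time)
  out <- array(NA_real_, c(length(lat_out), length(lon_out), nt))
  if (method == "nearest") {
    ii <- vapply(lat_out, function(p) which.min(abs(cube$lat - p)), 1L)
    jj <- vapply(lon_out, function(p) which.min(abs(cube$lon - p)), 1L)
    for (k in seq_len(nt)) out[, , k] <- cube$values[ii, jj, k]
  } else {
    bi <- bracket(cube$lat, lat_out)
    bj <- bracket(cube$lon, lon_out)
    w_ll <- outer(1 - bi$f, 1 - bj$f); w_hl <- outer(bi$f, 1 - bj$f)
    w_lh <- outer(1 - bi$f, bj$f);     w_hh <- outer(bi$f, bj$f)
    eps <- 1e-12
    for (k in seq_len(nt)) {
      s <- cube$values[, , k]
      corners <- list(list(w_ll, s[bi$i, bj$i, drop = FALSE]),
                      list(w_hl, s[bi$i + 1L, bj$i, drop = FALSE]),
                      list(w_lh, s[bi$i, bj$i + 1L, drop = FALSE]),
                      list(w_hh, s[bi$i + 1L, bj$i + 1L, drop = FALSE]))
      acc <- matrix(0, length(lat_out), length(lon_out))
      bad <- matrix(FALSE, length(lat_out), length(lon_out))
      for (cn in corners) {
        w <- cn[[1L]]; v <- cn[[2L]]
        use <- w > eps
        bad <- bad | (use & is.na(v))
        acc <- acc + ifelse(use, w * ifelse(is.na(v), 0, v), 0)
      }
      acc[bad] <- NA_real_
      out[, , k] <- acc
    }
  }
  grid_cube(out, lat_out, lon_out, cube$time, units = cube$units,
            product = cube$product)
}

# bracketing source indices and fractional offsets for 1-d interpolation,
# clamped to the source extent
bracket <- function(src, target) {
  n <- length(src)
  i <- findInterval(target, src)
  i <- pmin(pmax(i, 1L), n - 1L)
  f <- (target - src[i]) / (src[i + 1L] - src[i])
  list(i = i, f = pmin(pmax(f, 0), 1))
}
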