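#' Per-pixel collocation error estimation on a grid
#'
#' Runs [colloc()] independently at every pixel of a set of cubes sharing
#' one grid and time axis. Pixels with too few complete steps, failed
#' fits, or all-missing data are masked, never raised.
#'
#' @param cubes named list of [grid_cube()]s, one per product.
#' @param method,ecc_pairs,min_samples,... passed to [colloc()].
#' @return An object of class `"error_field"`: list with per-product
#'   lat x lon matrices in `error_variance` and `sensitivity`, per-pair
#'   matrices in `error_covariance` and `ecc`, logical matrices in
#'   `valid` (per product) and `any_valid`, plus `lat`, `lon`,
#'   `product_ids`, `method`.
#' @export
grid_error_estimation <- function(cubes, method = "eivd", ecc_pairs = NULL,
                                  min_samples = 100L, ...) {
  ids <- names(cubes)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("cubes must be a named list (names = product ids)", call. = FALSE)
  for (k in seq_along(cubes))
    if (!same_grid(cubes[[1L]], cubes[[k]]))
      stop("all cubes must share one grid and time axis", call. = FALSE)
  nlat <- length(cubes[[1L]]$lat); nlon <- length(cubes[[1L]]$lon)
  pairs <- normalize_pairs(ecc_pairs, ids)
  pk <- vapply(pairs, function(p) pair_key(p[1L], p[2L]), "")
  mk_field <- function(nm) {
    out <- lapply(nm, function(i) matrix(NA_real_, nlat, nlon))
    names(out) <- nm
    out
  }
  ev <- mk_field(ids); sens <- mk_field(ids)
  ecov <- mk_field(pk); ecc <- mk_field(pk)
  valid <- lapply(stats::setNames(ids, ids),
                  function(i) matrix(FALSE, nlat, nlon))
  nmat <- matrix(0L, nlat, nlon)
  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    v <- vapply(cubes, function(cb) cb$values[i, j, ], numeric(length(cubes[[1L]]$time)))
    if (all(is.na(v))) next
    ser <- collocated_series(v, ids)
    fit <- tryCatch(
      colloc(ser, method = method, ecc_pairs = ecc_pairs,
             min_samples = min_samples, ...),
      error = function(e) NULL)
    if (is.null(fit)) next
    nmat[i, j] <- fit$n_samples
    if (!is.null(fit$failure)) next
    for (id in ids) {
      ev[[id]][i, j] <- fit$error_variance[id]
      sens[[id]][i, j] <- fit$sensitivity[id]
      valid[[id]][i, j] <- fit$valid$error_variance[id]
    }
    for (k in pk) {
      ecov[[k]][i, j] <- fit$error_covariance[k]
      ecc[[k]][i, j] <- fit$ecc[k]
    }
  }
  any_valid <- Reduce(`|`, valid)
  structure(list(error_variance = ev, sensitivity = sens,
                 error_covariance = ecov, ecc = ecc, valid = valid,
                 any_valid = any_valid, n_samples = nmat,
                 lat = cubes[[1L]]$lat, lon = cubes[[1L]]$lon,
                 product_ids = ids, declared_pairs = pairs,
                 method = method),
            class = "error_field")
}

#' @export
print.error_field <- function(x, ...) {
  cat("Per-pixel error field (", toupper(x$method), "), ",
      length(x$lat), " x ", length(x$lon), " pixels\n", sep = "")
  s <- summary(x)
  print(s)
  invisible(x)
}

#' @export
summary.error_field <- function(object, ...) {
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  rows <- lapply(object$product_ids, function(id) {
    v <- object$error_variance[[id]][object$valid[[id]]]
    v <- v[is.finite(v)]
    data.frame(quantity = paste0("error_variance.", id),
               mean = mean(v), sd = pop_sd(v), n_valid = length(v))
  })
  for (k in names(object$ecc)) {
    v <- object$ecc[[k]]
    v <- v[is.finite(v) & abs(v) <= 1]
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = paste0("ecc.", k), mean = mean(v), sd = pop_sd(v),
      n_valid = length(v))
  }
  do.call(rbind, rows)
}

# minimal per-pixel fit object reconstructed from an error field so the
# weighting code can run unchanged
pixel_fit <- function(field, i, j) {
  ids <- field$product_ids
  pk <- names(field$error_covariance)
  ev <- vapply(ids, function(id) field$error_variance[[id]][i, j], 0)
  sens <- vapply(ids, function(id) field$sensitivity[[id]][i, j], 0)
  ecov <- vapply(pk, function(k) field$error_covariance[[k]][i, j], 0)
  ecc <- vapply(pk, function(k) field$ecc[[k]][i, j], 0)
  structure(list(
    error_variance = ev, sensitivity = sens, error_covariance = ecov,
    ecc = ecc, n_samples = field$n_samples[i, j],
    method = field$method, product_ids = ids,
    declared_pairs = field$declared_pairs,
    valid = list(
      error_variance = vapply(ids, function(id) field$valid[[id]][i, j], TRUE),
      sensitivity = is.finite(sens) & sens >= 0,
      ecc = is.finite(ecc) & abs(ecc) <= 1),
    failure = NULL), class = "colloc")
}

#' Merge gridded products with per-pixel collocation weights
#'
#' Static per-pixel weights derived from an [grid_error_estimation()]
#' field (via [merge_weights()] with sanitization) are applied over the
#' full record. Pixels without a valid weighting are masked.
#'
#' @param cubes named list of [grid_cube()]s (same products as the field).
#' @param field an `"error_field"`.
#' @param reference reference product id for the common data space;
#'   default: per pixel, the product with the largest sensitivity.
#' @param na_policy missing-data policy, see [merge_series()].
#' @param min_samples passed to the per-pixel rescaling.
#' @return An object of class `"merged_grid"`: list with `cube` (the
#'   merged [grid_cube()]), `weights` (lat x lon x product array),
#'   `dominant` (lat x lon matrix of prevailing product ids),
#'   `predicted_error_variance` (lat x lon) and `counters`.
#' @export
merge_grid <- function(cubes, field, reference = NULL,
                       na_policy = "renormalize", min_samples = 100L) {
  ids <- field$product_ids
  stopifnot(setequal(names(cubes), ids))
  nlat <- length(field$lat); nlon <- length(field$lon)
  nt <- length(cubes[[1L]]$time)
  merged <- array(NA_real_, c(nlat, nlon, nt))
  wmap <- array(NA_real_, c(nlat, nlon, length(ids)),
                dimnames = list(NULL, NULL, ids))
  dominant <- matrix(NA_character_, nlat, nlon)
  pred <- matrix(NA_real_, nlat, nlon)
  counters <- c(n_pixels = nlat * nlon, n_merged = 0L, n_fallback = 0L,
                n_masked = 0L)
  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    fit <- pixel_fit(field, i, j)
    w <- if (any(fit$valid$error_variance))
      merge_weights(fit, reference = reference) else NULL
    if (is.null(w)) {
      counters["n_masked"] <- counters["n_masked"] + 1L
      next
    }
    v <- vapply(cubes[ids], function(cb) cb$values[i, j, ], numeric(nt))
    m <- tryCatch(
      merge_series(collocated_series(v, ids), w, na_policy = na_policy,
                   min_samples = min_samples),
      error = function(e) NULL)
    if (is.null(m)) {
      counters["n_masked"] <- counters["n_masked"] + 1L
      next
    }
    merged[i, j, ] <- m
    wmap[i, j, ] <- w$weights[ids]
    dominant[i, j] <- ids[which.max(w$weights[ids])]
    pred[i, j] <- w$predicted_error_variance
    counters["n_merged"] <- counters["n_merged"] + 1L
    if (isTRUE(w$fallback_applied))
      counters["n_fallback"] <- counters["n_fallback"] + 1L
  }
  structure(list(cube = grid_cube(merged, field$lat, field$lon,
                                  cubes[[1L]]$time,
                                  units = cubes[[1L]]$units,
                                  product = "Merged"),
                 weights = wmap, dominant = dominant,
                 predicted_error_variance = pred, counters = counters),
            class = "merged_grid")
}

#' @export
print.merged_grid <- function(x, ...) {
  cat("Merged grid:\n")
  print(x$cube)
  cat("  pixels merged ", x$counters["n_merged"], "/",
      x$counters["n_pixels"], ", fallbacks ", x$counters["n_fallback"],
      ", masked ", x$counters["n_masked"], "\n", sep = "")
  cat("  dominant products:", paste(names(table(x$dominant)),
                                    table(x$dominant), sep = ": ",
                                    collapse = ", "), "\n")
  invisible(x)
}

#' Run the full estimate-weight-merge pipeline
#'
#' Chains grid harmonization checks, per-pixel error estimation, weight
#' computation with sanitization, merging, and yearly netCDF output in
#' the published convention, writing a JSON run report alongside.
#'
#' The configuration is a list (or the path of a YAML file) with fields:
#' \describe{
#'   \item{products}{named list: either `path` (+ optional `variable`,
#'     default `"Ec"`) per product, or an in-memory [grid_cube()].}
#'   \item{method}{`"eivd"` (default), `"tc"` or `"ec"`.}
#'   \item{ecc_pair}{two product names with correlated errors (required
#'     for `"eivd"`).}
#'   \item{error_variances}{named per-product error variances; required
#'     when only two products are given (no collocation possible), which
#'     routes to the duo inverse-variance weights.}
#'   \item{reference}{reference product for the merged data space
#'     (optional).}
#'   \item{output_dir}{directory for merged files and the report.}
#'   \item{start_date, step_days}{map an integer time axis to dates
#'     (defaults `"2000-01-01"`, 8); ignored when the cubes carry dates.}
#'   \item{min_samples, overwrite}{optional tuning.}
#' }
#'
#' @param config list or YAML file path.
#' @return Invisibly, a list with `field`, `merged`, `files` and
#'   `report` (also written as `run_report.json` in `output_dir`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$products) || length(config$products) < 2L)
    config_error("config must name at least 2 products")
  if (is.null(config$output_dir))
    config_error("config must set output_dir")
  method <- config$method %||% "eivd"
  ids <- names(config$products)
  if (is.null(ids) || any(!nzchar(ids)))
    config_error("products must be a named list")
  if (!is.null(config$ecc_pair) && !all(config$ecc_pair %in% ids))
    config_error(sprintf("ecc_pair (%s) must name configured products (%s)",
                         paste(config$ecc_pair, collapse = ", "),
                         paste(ids, collapse = ", ")))
  if (method == "eivd" && length(ids) >= 3L && is.null(config$ecc_pair))
    config_error("method 'eivd' needs an ecc_pair")
  cubes <- lapply(ids, function(nm) {
    p <- config$products[[nm]]
    if (inherits(p, "grid_cube")) return(p)
    if (is.null(p$path)) config_error(paste("product", nm, "has no path"))
    read_product(p$path, p$variable %||% "Ec")
  })
  names(cubes) <- ids
  for (k in seq_along(cubes))
    if (!same_grid(cubes[[1L]], cubes[[k]]))
      stop("input products are not on a shared grid/time axis", call. = FALSE)
  min_samples <- config$min_samples %||% 100L

  if (length(ids) == 2L) {
    evs <- unlist(config$error_variances)[ids]
    if (length(evs) != 2L || any(is.na(evs)))
      config_error("two-product merging needs error_variances for both products")
    field <- NULL
    w <- weights_duo(evs[1L], evs[2L], product_ids = ids)
    merged <- merge_duo_grid(cubes, w, min_samples)
    weight_method <- w$method
  } else {
    field <- grid_error_estimation(
      cubes, method = method,
      ecc_pairs = if (is.null(config$ecc_pair)) NULL else list(config$ecc_pair),
      min_samples = min_samples)
    merged <- merge_grid(cubes, field, reference = config$reference,
                         min_samples = min_samples)
    weight_method <- "per-pixel optimal (sanitized)"
  }

  dates <- cube_dates(cubes[[1L]], config)
  files <- write_yearly(merged$cube, dates, config$output_dir,
                        overwrite = isTRUE(config$overwrite))
  report <- list(
    method = if (length(ids) == 2L) "duo" else method,
    weight_method = weight_method,
    products = ids,
    ecc_pair = config$ecc_pair,
    min_samples = min_samples,
    n_time_steps = length(cubes[[1L]]$time),
    counters = as.list(merged$counters),
    mean_weights = as.list(apply(merged$weights, 3L, mean, na.rm = TRUE)),
    files = basename(files))
  report_path <- file.path(config$output_dir, "run_report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(field = field, merged = merged, files = files,
                 report = report, report_path = report_path))
}

merge_duo_grid <- function(cubes, w, min_samples) {
  ids <- names(cubes)
  nlat <- length(cubes[[1L]]$lat); nlon <- length(cubes[[1L]]$lon)
  nt <- length(cubes[[1L]]$time)
  merged <- array(NA_real_, c(nlat, nlon, nt))
  wmap <- array(NA_real_, c(nlat, nlon, 2L), dimnames = list(NULL, NULL, ids))
  n_ok <- 0L
  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    v <- vapply(cubes, function(cb) cb$values[i, j, ], numeric(nt))
    if (all(is.na(v))) next
    m <- tryCatch(
      merge_series(collocated_series(v, ids), w, reference = ids[1L],
                   min_samples = min_samples),
      error = function(e) NULL)
    if (is.null(m)) next
    merged[i, j, ] <- m
    wmap[i, j, ] <- w$weights[ids]
    n_ok <- n_ok + 1L
  }
  structure(list(cube = grid_cube(merged, cubes[[1L]]$lat, cubes[[1L]]$lon,
                                  cubes[[1L]]$time,
                                  units = cubes[[1L]]$units,
                                  product = "Merged"),
                 weights = wmap,
                 dominant = matrix(ids[which.max(w$weights)], nlat, nlon),
                 predicted_error_variance =
                   matrix(w$predicted_error_variance, nlat, nlon),
                 counters = c(n_pixels = nlat * nlon, n_merged = n_ok,
                              n_fallback = 0L,
                              n_masked = nlat * nlon - n_ok)),
            class = "merged_grid")
}

cube_dates <- function(cube, config) {
  if (inherits(cube$time, "Date")) return(cube$time)
  start <- as.Date(config$start_date %||% "2000-01-01")
  step <- config$step_days %||% 8
  start + (seq_along(cube$time) - 1L) * step
}

write_yearly <- function(cube, dates, out_dir, overwrite = FALSE) {
  years <- as.integer(format(dates, "%Y"))
  vapply(sort(unique(years)), function(yr) {
    idx <- which(years == yr)
    sub <- grid_cube(cube$values[, , idx, drop = FALSE], cube$lat,
                     cube$lon, dates[idx], units = cube$units,
                     product = cube$product)
    write_merged(sub, out_dir, yr, overwrite = overwrite)
  }, "")
}
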