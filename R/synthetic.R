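#' Configuration for a synthetic truth signal
#'
#' The latent "truth" is a mean level plus a sinusoidal seasonal cycle plus
#' stationary AR(1) anomalies. Seasonality and/or autoregression give the
#' signal the non-zero lag-1 autocovariance that the EIVD instrumental
#' variables require. Defaults emulate an 8-day transpiration record in a
#' realistic regime: 46 steps per year, a mean of 2 mm/day and a seasonal
#' swing of +-1.5 mm/day.
#'
#' @param n_steps number of time steps (>= 2).
#' @param ar1_coeff lag-1 autoregressive coefficient of the anomalies,
#'   |phi| < 1.
#' @param seasonal_amplitude amplitude of the seasonal sine, mm/day.
#' @param seasonal_period seasonal period in steps (46 = one year of 8-day
#'   steps).
#' @param mean_level long-term mean, mm/day.
#' @param noise_sd standard deviation of the AR(1) innovations, mm/day.
#' @param clip_negative clip the generated truth at zero (transpiration is
#'   a non-negative flux)? Off by default so estimator algebra is exact.
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @return A list of class `"truth_config"`.
#' @export
truth_config <- function(n_steps = 966L, ar1_coeff = 0.7,
                         seasonal_amplitude = 1.5, seasonal_period = 46L,
                         mean_level = 2, noise_sd = 0.5,
                         clip_negative = FALSE, seed = NULL) {
  if (n_steps < 2L) stop("n_steps must be at least 2", call. = FALSE)
  if (abs(ar1_coeff) >= 1)
    stop("ar1_coeff must satisfy |phi| < 1 (stationarity)", call. = FALSE)
  if (seasonal_period < 1L) stop("seasonal_period must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  structure(list(n_steps = as.integer(n_steps), ar1_coeff = ar1_coeff,
                 seasonal_amplitude = seasonal_amplitude,
                 seasonal_period = as.integer(seasonal_period),
                 mean_level = mean_level, noise_sd = noise_sd,
                 clip_negative = clip_negative, seed = seed),
            class = "truth_config")
}

#' Simulate a truth signal
#'
#' @param config a [truth_config()].
#' @return Numeric vector of length `n_steps`; deterministic given
#'   `config$seed`.
#' @examples
#' th <- simulate_truth(truth_config(n_steps = 200, seed = 1))
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "truth_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_steps
  t <- seq_len(n)
  seasonal <- config$seasonal_amplitude *
    sin(2 * pi * (t - 1) / config$seasonal_period)
  if (config$noise_sd > 0) {
    innov <- stats::rnorm(n, sd = config$noise_sd)
    if (config$ar1_coeff != 0) {
      # stationary start so moments hold from step 1
      a0 <- stats::rnorm(1, sd = config$noise_sd /
                              sqrt(1 - config$ar1_coeff^2))
      anom <- as.numeric(stats::filter(innov, config$ar1_coeff,
                                       method = "recursive",
                                       init = a0))
    } else anom <- innov
  } else anom <- numeric(n)
  out <- config$mean_level + seasonal + anom
  if (config$clip_negative) out <- pmax(out, 0)
  out
}

#' Configuration for synthetic collocated products
#'
#' Each product i observes the truth through an affine relation
#' `alpha_i + beta_i * truth + eps_i`, with the error vector eps drawn at
#' every time step, independently across time (serially white), from a
#' zero-mean multivariate normal with the prescribed covariance matrix.
#' Defaults follow the global error regime of real transpiration
#' products: error variances (0.36, 0.29, 0.13) with an error covariance
#' of 0.10 between the first two (ECC about 0.31).
#'
#' @param alphas additive biases per product, mm/day.
#' @param betas multiplicative biases per product, dimensionless.
#' @param error_cov N x N symmetric positive-semidefinite error covariance
#'   matrix, (mm/day)^2.
#' @param product_ids product labels; default `"P1"..."PN"`.
#' @param seed integer RNG seed, or `NULL`.
#' @return A list of class `"product_config"`.
#' @export
product_config <- function(alphas = c(0, 0.2, -0.1),
                           betas = c(1, 0.8, 1.2),
                           error_cov = default_error_cov(),
                           product_ids = NULL, seed = NULL) {
  error_cov <- as.matrix(error_cov)
  n <- nrow(error_cov)
  alphas <- rep_len(alphas, n)
  betas <- rep_len(betas, n)
  if (!is_square_symmetric(error_cov))
    stop("error_cov must be a finite symmetric matrix", call. = FALSE)
  ev <- eigen(error_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    stop("error_cov must be positive semi-definite", call. = FALSE)
  if (any(diag(error_cov) < 0))
    stop("error variances must be non-negative", call. = FALSE)
  if (is.null(product_ids)) product_ids <- paste0("P", seq_len(n))
  structure(list(alphas = alphas, betas = betas, error_cov = error_cov,
                 product_ids = product_ids, seed = seed),
            class = "product_config")
}

#' Default synthetic error covariance
#'
#' Error variances (0.36, 0.29, 0.13) with covariance 0.10 between
#' products 1 and 2 and zero elsewhere — a realistic global regime for
#' gridded transpiration products.
#'
#' @param ecc_cov error covariance of the (1, 2) pair; set 0 for a
#'   zero-ECC scenario.
#' @return 3 x 3 covariance matrix.
#' @export
default_error_cov <- function(ecc_cov = 0.10) {
  m <- diag(c(0.36, 0.29, 0.13))
  m[1, 2] <- m[2, 1] <- ecc_cov
  m
}

#' Simulate collocated products from a truth series
#'
#' @param truth numeric truth series, e.g. from [simulate_truth()].
#' @param config a [product_config()].
#' @return A [collocated_series()] with attribute `"truth"` carrying the
#'   generating signal (for recovery experiments).
#' @examples
#' th <- simulate_truth(truth_config(n_steps = 500, seed = 1))
#' pr <- simulate_products(th, product_config(seed = 2))
#' @export
simulate_products <- function(truth, config) {
  stopifnot(inherits(config, "product_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- length(truth)
  p <- length(config$alphas)
  eps <- rmvnorm0(n, config$error_cov)
  v <- matrix(rep(config$alphas, each = n), n, p) +
    outer(truth, config$betas) + eps
  out <- collocated_series(v, config$product_ids)
  attr(out, "truth") <- truth
  out
}

# zero-mean multivariate normal draws via symmetric eigendecomposition,
# tolerating singular (e.g. all-zero) covariance matrices
rmvnorm0 <- function(n, sigma) {
  p <- nrow(sigma)
  e <- eigen(sigma, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  z <- matrix(stats::rnorm(n * p), n, p)
  z %*% (t(e$vectors) * sqrt(lam))
}

#' Simulate a gridded multi-product fixture
#'
#' Generates per-pixel independent truth/product realizations on a small
#' lat/lon grid and returns one [grid_cube()] per product, plus the truth
#' cube. Optionally writes each product as a netCDF fixture readable by
#' [read_product()].
#'
#' @param nlat,nlon grid dimensions.
#' @param truth_config a [truth_config()]; its `seed` seeds the whole grid.
#' @param product_config a [product_config()].
#' @param lat,lon coordinate vectors (ascending); defaults span a small
#'   0.1-degree window.
#' @param dir if non-`NULL`, write one netCDF file per product into this
#'   directory and record the paths in the result's `"paths"` attribute.
#' @return Named list of [grid_cube()]s (one per product) with attribute
#'   `"truth"` (a [grid_cube()] of the generating signal).
#' @export
simulate_grid <- function(nlat, nlon, truth_config, product_config,
                          lat = NULL, lon = NULL, dir = NULL) {
  stopifnot(inherits(truth_config, "truth_config"),
            inherits(product_config, "product_config"))
  if (!is.null(truth_config$seed)) set.seed(truth_config$seed)
  if (is.null(lat)) lat <- seq(0.05, by = 0.1, length.out = nlat)
  if (is.null(lon)) lon <- seq(0.05, by = 0.1, length.out = nlon)
  nt <- truth_config$n_steps
  p <- length(product_config$product_ids)
  tc2 <- truth_config; tc2$seed <- NULL
  pc2 <- product_config; pc2$seed <- NULL
  truth_arr <- array(NA_real_, c(nlat, nlon, nt))
  prod_arr <- lapply(seq_len(p), function(i) array(NA_real_, c(nlat, nlon, nt)))
  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    th <- simulate_truth(tc2)
    pr <- simulate_products(th, pc2)
    truth_arr[i, j, ] <- th
    for (k in seq_len(p)) prod_arr[[k]][i, j, ] <- unclass(pr)[, k]
  }
  cubes <- lapply(seq_len(p), function(k)
    grid_cube(prod_arr[[k]], lat, lon, seq_len(nt),
              product = product_config$product_ids[k]))
  names(cubes) <- product_config$product_ids
  attr(cubes, "truth") <- grid_cube(truth_arr, lat, lon, seq_len(nt),
                                    product = "truth")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- vapply(names(cubes), function(nm) {
      path <- file.path(dir, paste0(nm, ".nc"))
      write_product(cubes[[nm]], path, overwrite = TRUE)
    }, "")
    attr(cubes, "paths") <- paths
  }
  cubes
}

#' Configuration for a synthetic flux-tower record
#'
#' Builds daily ET, GPP and VPD series that satisfy the water-use
#' efficiency construction exactly before noise:
#' `GPP * sqrt(VPD) / T = uwue_p_true` with `T = t_over_et * ET`, so the
#' apparent-to-potential uWUE ratio recovers the prescribed T/ET schedule.
#' Multiplicative lognormal-style noise (relative sd `noise_cv`) on ET and
#' GPP emulates eddy-covariance measurement scatter.
#'
#' @param n_days number of days.
#' @param uwue_p_true potential uWUE, GPP * sqrt(VPD) per mm of T (units
#'   treated as opaque).
#' @param t_over_et T/ET schedule in \[0, 1\], recycled to `n_days`. The
#'   default seasonal schedule spans 0.4-1 so that near-potential days
#'   exist (the 95th-percentile regression needs them).
#' @param rain_days integer day indices with rainfall.
#' @param noise_cv relative noise on ET and GPP (default 0.05).
#' @param seed integer RNG seed, or `NULL`.
#' @return A list of class `"site_sim_config"`.
#' @export
site_sim_config <- function(n_days = 365L, uwue_p_true = 10,
                            t_over_et = 0.7 + 0.3 *
                              sin(2 * pi * (seq_len(n_days) - 91) / 365),
                            rain_days = integer(0), noise_cv = 0.05,
                            seed = NULL) {
  t_over_et <- rep_len(t_over_et, n_days)
  if (any(t_over_et < 0 | t_over_et > 1))
    stop("t_over_et must lie in [0, 1]", call. = FALSE)
  if (length(rain_days) && (min(rain_days) < 1L || max(rain_days) > n_days))
    stop("rain_days must index days within the record", call. = FALSE)
  if (uwue_p_true <= 0) stop("uwue_p_true must be positive", call. = FALSE)
  structure(list(n_days = as.integer(n_days), uwue_p_true = uwue_p_true,
                 t_over_et = t_over_et,
                 rain_days = as.integer(rain_days),
                 noise_cv = noise_cv, seed = seed),
            class = "site_sim_config")
}

#' Simulate a flux-tower site record
#'
#' @param config a [site_sim_config()].
#' @return A data.frame of class `"site_record"` with columns `date`,
#'   `ET` (mm/day), `GPP`, `VPD` (hPa), `P` (mm/day), `QC` (1 = good) and
#'   attributes `t_over_et_true` and `uwue_p_true`.
#' @export
simulate_site <- function(config) {
  stopifnot(inherits(config, "site_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_days
  day <- seq_len(n)
  # smooth positive drivers with a seasonal cycle
  et_clean <- 2.5 + 1.5 * sin(2 * pi * (day - 91) / 365) +
    0.3 * stats::rnorm(n)
  et_clean <- pmax(et_clean, 0.2)
  vpd <- pmax(8 + 5 * sin(2 * pi * (day - 105) / 365) + stats::rnorm(n), 0.5)
  t_series <- config$t_over_et * et_clean
  gpp_clean <- config$uwue_p_true * t_series / sqrt(vpd)
  et <- et_clean * exp(stats::rnorm(n, sd = config$noise_cv) -
                         config$noise_cv^2 / 2)
  gpp <- gpp_clean * exp(stats::rnorm(n, sd = config$noise_cv) -
                           config$noise_cv^2 / 2)
  p <- numeric(n)
  if (length(config$rain_days))
    p[config$rain_days] <- stats::rexp(length(config$rain_days), rate = 0.2)
  rec <- site_record(data.frame(
    date = as.Date("2001-01-01") + day - 1L,
    ET = et, GPP = gpp, VPD = vpd, P = p, QC = 1L))
  attr(rec, "t_over_et_true") <- config$t_over_et
  attr(rec, "uwue_p_true") <- config$uwue_p_true
  rec
}
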