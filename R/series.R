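#' Collocated product series
#'
#' Bundle N spatially/temporally collocated series (e.g. transpiration
#' products at one pixel or site) on a shared, uniformly spaced time axis.
#' Missing values are carried as `NA`; a time step is *complete* only when
#' all N products are valid there (listwise completeness), and all moment
#' computations use complete steps only.
#'
#' @param values numeric matrix, one column per product, one row per time
#'   step. `NA` marks missing observations.
#' @param product_ids character labels, one per column. Defaults to the
#'   column names of `values`, or `"P1"..."PN"`.
#' @param times optional time stamps (numeric or `Date`), strictly
#'   increasing with a uniform step. Defaults to `1:nrow(values)`.
#' @return An object of class `"collocated_series"`: the values matrix with
#'   attributes `product_ids` and `times`.
#' @examples
#' x <- collocated_series(cbind(a = rnorm(10), b = rnorm(10)))
#' n_complete(x)
#' @export
collocated_series <- function(values, product_ids = NULL, times = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) < 2L)
    stop("a collocated series needs at least 2 products", call. = FALSE)
  if (nrow(values) < 2L)
    stop("a collocated series needs at least 2 time steps", call. = FALSE)
  if (is.null(product_ids))
    product_ids <- colnames(values)
  if (is.null(product_ids))
    product_ids <- paste0("P", seq_len(ncol(values)))
  if (anyDuplicated(product_ids))
    stop("product_ids must be unique", call. = FALSE)
  if (is.null(times)) times <- seq_len(nrow(values))
  if (length(times) != nrow(values))
    stop("times must match the number of rows", call. = FALSE)
  if (is.unsorted(as.numeric(times), strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  colnames(values) <- product_ids
  structure(values,
            product_ids = product_ids,
            times = times,
            class = c("collocated_series", "matrix", "array"))
}

#' @export
print.collocated_series <- function(x, ...) {
  cat("Collocated series: ", ncol(x), " products (",
      paste(attr(x, "product_ids"), collapse = ", "), "), ",
      nrow(x), " steps, ", n_complete(x), " complete\n", sep = "")
  invisible(x)
}

#' Number of complete time steps
#'
#' @param x a [collocated_series()].
#' @return Integer count of rows where every product is valid.
#' @export
n_complete <- function(x) sum(stats::complete.cases(unclass(x)))

complete_rows <- function(x) stats::complete.cases(unclass(x))

#' Pairwise sample covariances of collocated products
#'
#' Covariances are computed over complete time steps only. The population
#' denominator (divide by n) is the default so that the closed-form triple
#' collocation identities hold exactly on finite samples; the sample
#' denominator (n - 1) is available for comparison with [stats::cov()].
#'
#' @param x a [collocated_series()].
#' @param min_samples minimum number of complete steps; fewer makes the
#'   result invalid (all-`NA` matrix, `valid = FALSE`).
#' @param denominator `"n"` (population, default) or `"n-1"`.
#' @return A list with `cov` (N x N symmetric matrix), `means`, `n`
#'   (complete steps used) and `valid`.
#' @export
pairwise_covariances <- function(x, min_samples = 100L, denominator = c("n", "n-1")) {
  denominator <- match.arg(denominator)
  v <- unclass(x)[complete_rows(x), , drop = FALSE]
  n <- nrow(v)
  p <- ncol(x)
  ids <- attr(x, "product_ids")
  if (n < max(2L, min_samples)) {
    cv <- matrix(NA_real_, p, p, dimnames = list(ids, ids))
    return(list(cov = cv, means = stats::setNames(rep(NA_real_, p), ids),
                n = n, valid = FALSE))
  }
  mu <- colMeans(v)
  vc <- sweep(v, 2L, mu)
  den <- if (denominator == "n") n else n - 1L
  cv <- crossprod(vc) / den
  dimnames(cv) <- list(ids, ids)
  list(cov = cv, means = stats::setNames(mu, ids), n = n, valid = TRUE)
}

#' Rescale collocated products to a reference data space
#'
#' Removes systematic (affine) differences between three products by
#' mapping each non-reference series y to `beta * (y - mean(y)) + mean(x)`
#' where x is the reference. The scaling factor beta for product Y is the
#' covariance ratio cov(X, Z) / cov(Y, Z) built from the third product Z,
#' which estimates the dynamic-range ratio beta_X / beta_Y without ever
#' observing the true signal.
#'
#' @param x a [collocated_series()] with exactly 3 products.
#' @param reference product id (or column index) kept unchanged.
#' @param min_samples passed to [pairwise_covariances()].
#' @return A list with `series` (the rescaled [collocated_series()]),
#'   `scaling` (named scaling factors, 1 for the reference), and `valid`
#'   (`FALSE` when a denominator covariance vanishes).
#' @export
tc_rescale <- function(x, reference = 1L, min_samples = 100L) {
  ids <- attr(x, "product_ids")
  ref <- resolve_product(reference, ids)
  if (ncol(x) != 3L)
    stop("tc_rescale needs exactly 3 products", call. = FALSE)
  pc <- pairwise_covariances(x, min_samples = min_samples)
  scaling <- stats::setNames(rep(NA_real_, 3L), ids)
  if (!pc$valid)
    return(list(series = x, scaling = scaling, valid = FALSE))
  cv <- pc$cov
  mu <- pc$means
  others <- setdiff(seq_len(3L), ref)
  scaling[ref] <- 1
  for (j in others) {
    k <- setdiff(others, j)               # the third product
    if (cv[j, k] == 0) {
      return(list(series = x, scaling = stats::setNames(rep(NA_real_, 3L), ids),
                  valid = FALSE))
    }
    scaling[j] <- cv[ref, k] / cv[j, k]
  }
  out <- unclass(x)
  for (j in others)
    out[, j] <- scaling[j] * (out[, j] - mu[j]) + mu[ref]
  list(series = collocated_series(out, ids, attr(x, "times")),
       scaling = scaling, valid = TRUE)
}

#' Lag-1 autocovariance of a series
#'
#' Mean-removed lag-1 autocovariance `<a_t a_(t-1)>`, the instrumental
#' quantity of the EIVD estimator. Only pairs of *adjacent* valid steps on
#' the native time axis contribute; the mean is taken over all valid
#' values, and the averaging denominator is the number of pairs
#' (population convention).
#'
#' @param v numeric vector (may contain `NA`).
#' @return Scalar autocovariance, or `NA` if no adjacent valid pair exists.
#' @export
lag1_autocovariance <- function(v) {
  ok <- is.finite(v)
  pair <- ok[-1L] & ok[-length(v)]
  if (!any(pair)) return(NA_real_)
  a <- v - mean(v[ok])
  mean((a[-1L] * a[-length(v)])[pair])
}
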