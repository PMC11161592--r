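#' Fit a collocation error model
#'
#' Estimates per-product random error variances, sensitivities and
#' (optionally) error cross-covariances of N collocated products that all
#' observe the same latent signal through an affine relation
#' `x_i = alpha_i + beta_i * theta + eps_i` with zero-mean random error
#' `eps_i`. Three estimators are available:
#'
#' * `"tc"` — classic triple collocation: N = 3, all error
#'   cross-correlations (ECC) assumed zero. Closed-form covariance-ratio
#'   solution.
#' * `"eivd"` — extended double instrumental variable: N = 3 with one
#'   declared non-zero ECC pair. Lag-1 shifted series act as instruments;
#'   a 10-equation least-squares system yields sensitivities, error
#'   variances and the error covariance of the declared pair. Requires a
#'   temporally autocorrelated signal (positive lag-1 autocovariance in
#'   every product) and serially white errors.
#' * `"ec"` — extended collocation for N >= 4 products with declared
#'   non-zero ECC pairs; solvable only when every product belongs to at
#'   least one triplet whose pairs are all ECC-free.
#'
#' Estimates that violate their constraints (negative variances,
#' correlations outside \[-1, 1\]) are flagged invalid rather than
#' truncated, so that downstream weighting can apply explicit fallbacks.
#'
#' @param x a [collocated_series()].
#' @param method `"eivd"` (default), `"tc"` or `"ec"`.
#' @param ecc_pairs declared non-zero ECC pair(s): a length-2 vector of
#'   product ids for `"eivd"`, a list of such pairs for `"ec"`, `NULL` for
#'   `"tc"`.
#' @param min_samples minimum complete steps per fit (default 100); below
#'   it the fit is flagged invalid.
#' @param denominator covariance denominator convention, see
#'   [pairwise_covariances()].
#' @param remove_climatology subtract a per-phase (seasonal) mean before
#'   estimating? Off by default; see [deseasonalize()].
#' @param period seasonal period in steps, required when
#'   `remove_climatology = TRUE`.
#' @param rcond_tol reciprocal-condition threshold below which the
#'   least-squares system is flagged unsolvable.
#' @return An object of class `"colloc"`: a list with components
#'   `error_variance`, `sensitivity` (named per product, units of the data
#'   squared), `error_covariance` and `ecc` (named per declared pair),
#'   `scaling_factors`, `lag1`, `n_samples`, `valid` (per-quantity flags),
#'   `failure` (reason string when the whole fit failed) and `method`.
#' @seealso [merge_weights()], [coef.colloc()]
#' @examples
#' tr <- simulate_truth(truth_config(n_steps = 2000, seed = 1))
#' pr <- simulate_products(tr, product_config(
#'   error_cov = diag(c(0.36, 0.29, 0.13)), seed = 2))
#' colloc(pr, method = "tc")
#' @export
colloc <- function(x, method = c("eivd", "tc", "ec"), ecc_pairs = NULL,
                   min_samples = 100L, denominator = c("n", "n-1"),
                   remove_climatology = FALSE, period = NULL,
                   rcond_tol = 1e-10) {
  method <- match.arg(method)
  denominator <- match.arg(denominator)
  stopifnot(inherits(x, "collocated_series"))
  ids <- attr(x, "product_ids")
  if (remove_climatology) {
    if (is.null(period)) stop("remove_climatology needs a period", call. = FALSE)
    x <- deseasonalize(x, period)
  }
  pairs <- normalize_pairs(ecc_pairs, ids)
  if (method == "tc" && length(pairs))
    stop("classic TC assumes zero ECC; use method = 'eivd' or 'ec'", call. = FALSE)
  if (method == "eivd" && length(pairs) != 1L)
    stop("EIVD needs exactly one declared ECC pair", call. = FALSE)
  if (method %in% c("tc", "eivd") && ncol(x) != 3L)
    stop(sprintf("method '%s' needs exactly 3 products", method), call. = FALSE)
  if (method == "ec" && ncol(x) < 4L)
    stop("extended collocation needs at least 4 products", call. = FALSE)
  if (method == "ec")
    check_ec_solvable(ids, pairs)

  pc <- pairwise_covariances(x, min_samples = min_samples,
                             denominator = denominator)
  if (!pc$valid)
    return(colloc_failed(ids, pairs, method, pc$n, "insufficient complete steps"))

  fit <- switch(method,
    tc   = tc_core(pc$cov, ids),
    eivd = eivd_core(pc$cov, x, ids, pairs[[1L]], denominator, rcond_tol),
    ec   = ec_core(pc$cov, ids, pairs, rcond_tol))
  fit$method <- method
  fit$product_ids <- ids
  fit$n_samples <- pc$n
  fit$declared_pairs <- pairs
  fit$call <- match.call()
  class(fit) <- "colloc"
  fit
}

# declared pairs -> list of sorted character pairs
normalize_pairs <- function(ecc_pairs, ids) {
  if (is.null(ecc_pairs) || length(ecc_pairs) == 0L) return(list())
  if (!is.list(ecc_pairs)) ecc_pairs <- list(ecc_pairs)
  lapply(ecc_pairs, function(p) {
    if (length(p) != 2L) stop("an ECC pair has exactly 2 products", call. = FALSE)
    p <- ids[vapply(p, resolve_product, 1L, ids = ids)]
    if (p[1L] == p[2L]) stop("an ECC pair needs two distinct products", call. = FALSE)
    sort(p)
  })
}

failed_core <- function(ids, pairs, reason) {
  pk <- vapply(pairs, function(p) pair_key(p[1L], p[2L]), "")
  list(
    error_variance = stats::setNames(rep(NA_real_, length(ids)), ids),
    sensitivity = stats::setNames(rep(NA_real_, length(ids)), ids),
    error_covariance = stats::setNames(rep(NA_real_, length(pk)), pk),
    ecc = stats::setNames(rep(NA_real_, length(pk)), pk),
    scaling_factors = NULL, lag1 = NULL,
    valid = list(
      error_variance = stats::setNames(rep(FALSE, length(ids)), ids),
      sensitivity = stats::setNames(rep(FALSE, length(ids)), ids),
      ecc = stats::setNames(rep(FALSE, length(pk)), pk)),
    failure = reason)
}

colloc_failed <- function(ids, pairs, method, n, reason) {
  fit <- failed_core(ids, pairs, reason)
  fit$n_samples <- n
  fit$method <- method
  fit$product_ids <- ids
  fit$declared_pairs <- pairs
  class(fit) <- "colloc"
  fit
}

flag_fit <- function(fit) {
  fit$valid <- list(
    error_variance = is.finite(fit$error_variance) & fit$error_variance >= 0,
    sensitivity = is.finite(fit$sensitivity) & fit$sensitivity >= 0,
    ecc = is.finite(fit$ecc) & abs(fit$ecc) <= 1)
  fit
}

# ---- classic triple collocation (zero ECC closed form) ----------------------

tc_core <- function(cv, ids) {
  ev <- sens <- stats::setNames(rep(NA_real_, 3L), ids)
  for (i in 1:3) {
    jk <- setdiff(1:3, i)
    if (cv[jk[1L], jk[2L]] != 0) {
      sens[i] <- cv[i, jk[1L]] * cv[i, jk[2L]] / cv[jk[1L], jk[2L]]
      ev[i] <- cv[i, i] - sens[i]
    }
  }
  flag_fit(list(error_variance = ev, sensitivity = sens,
                error_covariance = stats::setNames(numeric(0), character(0)),
                ecc = stats::setNames(numeric(0), character(0)),
                scaling_factors = NULL, lag1 = NULL, failure = NULL))
}

#' Triple collocation error variances
#'
#' Convenience wrapper: `colloc(x, method = "tc")`. The caller thereby
#' declares the zero-ECC assumption for all three product pairs.
#'
#' @inheritParams colloc
#' @param ... passed on to [colloc()].
#' @return A `"colloc"` fit, see [colloc()].
#' @export
tc_error_variances <- function(x, ...) colloc(x, method = "tc", ...)

#' Cross-multiplied-difference form of the TC error variances
#'
#' The averaging form of the triple collocation estimator: rescale two
#' products to the reference data space, then average cross-multiplied
#' dataset differences, e.g.
#' `var(eps_X) = <(X - Y^X)(X - Z^X)>`. Algebraically identical to the
#' covariance closed form used by [tc_error_variances()]; exposed so the
#' identity can be asserted on finite samples.
#'
#' @param x a [collocated_series()] with 3 products.
#' @param reference reference product id or index.
#' @param min_samples minimum complete steps.
#' @return Named vector of the three error variances in each product's own
#'   (unscaled) units.
#' @export
tc_cross_differences <- function(x, reference = 1L, min_samples = 100L) {
  ids <- attr(x, "product_ids")
  ref <- resolve_product(reference, ids)
  rs <- tc_rescale(x, reference = ref, min_samples = min_samples)
  if (!rs$valid) return(stats::setNames(rep(NA_real_, 3L), ids))
  v <- unclass(rs$series)[complete_rows(rs$series), , drop = FALSE]
  others <- setdiff(1:3, ref)
  out <- stats::setNames(rep(NA_real_, 3L), ids)
  o1 <- others[1L]; o2 <- others[2L]
  out[ref] <- mean((v[, ref] - v[, o1]) * (v[, ref] - v[, o2]))
  out[o1] <- mean((v[, o1] - v[, ref]) * (v[, o1] - v[, o2])) / rs$scaling[o1]^2
  out[o2] <- mean((v[, o2] - v[, ref]) * (v[, o2] - v[, o1])) / rs$scaling[o2]^2
  out
}

# ---- EIVD (three products, one ECC pair, lag-1 instruments) -----------------

eivd_core <- function(cv, x, ids, pair, denominator, rcond_tol) {
  # order products so the declared ECC pair occupies positions (X, Y)
  pi1 <- resolve_product(pair[1L], ids)
  pi2 <- resolve_product(pair[2L], ids)
  ord <- c(pi1, pi2, setdiff(1:3, c(pi1, pi2)))
  pk <- pair_key(pair[1L], pair[2L])

  v <- unclass(x)
  L <- vapply(seq_len(3L), function(j) lag1_autocovariance(v[, j]), 0)
  names(L) <- ids
  if (any(!is.finite(L)) || any(L <= 0)) {
    fit <- failed_core(ids, list(pair),
                       "non-positive lag-1 autocovariance (signal memory absent)")
    fit$lag1 <- L
    return(fit)
  }

  C <- cv[ord, ord]
  Lo <- L[ord]
  r <- function(a, b) sqrt(Lo[a] / Lo[b])
  y <- c(C[1, 1], C[2, 2], C[3, 3], C[1, 2],
         C[1, 3] * r(1, 3), C[2, 3] * r(2, 3),
         C[3, 1] * r(3, 1), C[3, 2] * r(3, 2),
         C[1, 3] * r(2, 3), C[2, 3] * r(1, 3))
  A <- eivd_design_matrix()
  AtA <- crossprod(A)
  if (rcond(AtA) < rcond_tol)
    return(failed_core(ids, list(pair), "ill-conditioned collocation system"))
  xs <- drop(solve(AtA, crossprod(A, y)))

  sens <- ev <- stats::setNames(rep(NA_real_, 3L), ids)
  sens[ord] <- xs[1:3]
  ev[ord] <- xs[5:7]
  ecov <- stats::setNames(xs[8L], pk)
  ecc <- stats::setNames(
    if (xs[5L] > 0 && xs[6L] > 0) xs[8L] / sqrt(xs[5L] * xs[6L]) else NA_real_,
    pk)
  flag_fit(list(error_variance = ev, sensitivity = sens,
                error_covariance = ecov, ecc = ecc,
                scaling_factors = sqrt(Lo / Lo[3L])[order(ord)],
                lag1 = L, failure = NULL))
}

# fixed 10 x 8 design: rows 1-4 relate moments to signal + error terms,
# rows 5-10 are the instrument-scaled redundant sensitivity estimates
eivd_design_matrix <- function() {
  top <- cbind(diag(4), diag(4))
  B <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0),
             c(0, 0, 1, 0), c(0, 0, 0, 1), c(0, 0, 0, 1))
  rbind(top, cbind(B, matrix(0, 6, 4)))
}

#' EIVD error model for a product triplet
#'
#' Convenience wrapper: `colloc(x, method = "eivd", ecc_pairs = ecc_pair)`.
#'
#' @inheritParams colloc
#' @param ecc_pair the two products whose errors are allowed to correlate.
#' @param ... passed on to [colloc()].
#' @return A `"colloc"` fit, see [colloc()].
#' @export
eivd_estimate <- function(x, ecc_pair, ...)
  colloc(x, method = "eivd", ecc_pairs = list(ecc_pair), ...)

# ---- extended collocation (N >= 4, declared ECC pairs) ----------------------

# every product must sit in at least one triplet whose three pairs are all
# declared ECC-free, otherwise the least-squares system loses rank
check_ec_solvable <- function(ids, pairs) {
  n <- length(ids)
  declared <- vapply(pairs, function(p) pair_key(p[1L], p[2L]), "")
  zero <- function(a, b) !(pair_key(ids[a], ids[b]) %in% declared)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ok <- FALSE
    for (j in others) for (k in others) {
      if (j < k && zero(i, j) && zero(i, k) && zero(j, k)) ok <- TRUE
    }
    if (!ok)
      stop(sprintf(paste0(
        "declared ECC pairs leave product '%s' outside any mutually ",
        "ECC-free triplet; the collocation system is unsolvable"), ids[i]),
        call. = FALSE)
  }
  invisible(TRUE)
}

ec_core <- function(cv, ids, pairs, rcond_tol) {
  n <- length(ids)
  declared <- vapply(pairs, function(p) pair_key(p[1L], p[2L]), "")
  zero <- function(a, b) !(pair_key(ids[a], ids[b]) %in% declared)

  # unknowns: signal terms theta_ab (a <= b), error variances, declared covs
  theta_id <- function(a, b) paste0("t:", pair_key(ids[a], ids[b]))
  var_id <- function(a) paste0("v:", ids[a])
  cov_id <- function(k) paste0("c:", k)
  unknowns <- c(
    unlist(lapply(seq_len(n), function(a)
      vapply(a:n, function(b) theta_id(a, b), ""))),
    vapply(seq_len(n), var_id, ""),
    vapply(declared, cov_id, ""))
  rows <- list(); yy <- numeric(0)
  add_row <- function(y, coefs) {
    r <- stats::setNames(numeric(length(unknowns)), unknowns)
    r[names(coefs)] <- coefs
    rows[[length(rows) + 1L]] <<- r
    yy[length(yy) + 1L] <<- y
  }
  for (a in seq_len(n)) for (b in a:n) {
    key <- pair_key(ids[a], ids[b])
    coefs <- stats::setNames(1, theta_id(a, b))
    if (a == b) coefs[var_id(a)] <- 1
    else if (!zero(a, b)) coefs[cov_id(key)] <- 1
    add_row(cv[a, b], coefs)
    # redundant instrument-free estimates of theta_ab from ECC-free triplets
    if (a == b) {
      others <- setdiff(seq_len(n), a)
      for (c1 in others) for (d1 in others) {
        if (c1 < d1 && zero(a, c1) && zero(a, d1) && zero(c1, d1) &&
            cv[c1, d1] != 0)
          add_row(cv[a, c1] * cv[a, d1] / cv[c1, d1],
                  stats::setNames(1, theta_id(a, b)))
      }
    } else {
      others <- setdiff(seq_len(n), c(a, b))
      for (c1 in others) for (d1 in others) {
        if (c1 != d1 && zero(a, c1) && zero(b, d1) && zero(c1, d1) &&
            cv[c1, d1] != 0)
          add_row(cv[a, c1] * cv[b, d1] / cv[c1, d1],
                  stats::setNames(1, theta_id(a, b)))
      }
    }
  }
  A <- do.call(rbind, rows)
  AtA <- crossprod(A)
  if (rcond(AtA) < rcond_tol)
    return(failed_core(ids, pairs, "ill-conditioned collocation system"))
  xs <- stats::setNames(drop(solve(AtA, crossprod(A, yy))), unknowns)

  ev <- stats::setNames(xs[vapply(seq_len(n), var_id, "")], ids)
  sens <- stats::setNames(
    xs[vapply(seq_len(n), function(a) theta_id(a, a), "")], ids)
  ecov <- stats::setNames(xs[vapply(declared, cov_id, "")], declared)
  ecc <- vapply(seq_along(declared), function(m) {
    p <- pairs[[m]]
    v1 <- ev[p[1L]]; v2 <- ev[p[2L]]
    if (is.finite(v1) && is.finite(v2) && v1 > 0 && v2 > 0)
      ecov[m] / sqrt(v1 * v2) else NA_real_
  }, 0)
  names(ecc) <- declared
  flag_fit(list(error_variance = ev, sensitivity = sens,
                error_covariance = ecov, ecc = ecc,
                scaling_factors = NULL, lag1 = NULL, failure = NULL))
}

#' Extended collocation for four or more products
#'
#' Convenience wrapper: `colloc(x, method = "ec", ecc_pairs = ecc_pairs)`.
#'
#' @inheritParams colloc
#' @param ... passed on to [colloc()].
#' @return A `"colloc"` fit, see [colloc()].
#' @export
ec_quadruplet_estimate <- function(x, ecc_pairs = NULL, ...)
  colloc(x, method = "ec", ecc_pairs = ecc_pairs, ...)

#' Remove a periodic climatology from collocated series
#'
#' Subtracts the per-phase mean (computed over valid values of each
#' product) so that estimation can optionally run on anomalies.
#'
#' @param x a [collocated_series()].
#' @param period seasonal period in time steps (e.g. 46 for an 8-day axis).
#' @return A [collocated_series()] of anomalies.
#' @export
deseasonalize <- function(x, period) {
  stopifnot(inherits(x, "collocated_series"), period >= 1)
  v <- unclass(x)
  phase <- ((seq_len(nrow(v)) - 1L) %% period) + 1L
  for (j in seq_len(ncol(v))) {
    clim <- tapply(v[, j], phase, mean, na.rm = TRUE)
    v[, j] <- v[, j] - clim[phase]
  }
  collocated_series(v, attr(x, "product_ids"), attr(x, "times"))
}

# ---- methods ----------------------------------------------------------------

#' @export
print.colloc <- function(x, digits = 4, ...) {
  cat("Collocation error model (", toupper(x$method), "), n = ",
      x$n_samples, " complete steps\n", sep = "")
  if (!is.null(x$failure)) {
    cat("  fit failed:", x$failure, "\n")
    return(invisible(x))
  }
  cat("  error variances: ",
      paste(sprintf("%s = %.*g", names(x$error_variance), digits,
                    x$error_variance), collapse = ", "), "\n", sep = "")
  if (length(x$ecc))
    cat("  ECC: ", paste(sprintf("%s: %.*g", names(x$ecc), digits, x$ecc),
                         collapse = ", "), "\n", sep = "")
  if (any(!unlist(x$valid)))
    cat("  (some estimates flagged invalid; see $valid)\n")
  invisible(x)
}

#' @export
summary.colloc <- function(object, ...) {
  structure(list(fit = object), class = "summary.colloc")
}

#' @export
print.summary.colloc <- function(x, ...) {
  f <- x$fit
  print(f)
  if (is.null(f$failure)) {
    tab <- data.frame(product = f$product_ids,
                      error_variance = unname(f$error_variance),
                      sensitivity = unname(f$sensitivity),
                      valid = unname(f$valid$error_variance))
    print(tab, row.names = FALSE)
    if (!is.null(f$lag1)) {
      cat("lag-1 autocovariances:\n")
      print(f$lag1)
    }
  }
  invisible(x)
}

#' Extract collocation estimates
#'
#' @param object a `"colloc"` fit.
#' @param what `"error_variance"` (default), `"sensitivity"`,
#'   `"error_covariance"` or `"ecc"`.
#' @param ... unused.
#' @return Named numeric vector of the requested estimates.
#' @export
coef.colloc <- function(object, what = c("error_variance", "sensitivity",
                                         "error_covariance", "ecc"), ...) {
  what <- match.arg(what)
  object[[what]]
}
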