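#' Merge collocated products into a single series
#'
#' Rescales all products to the reference product's data space (removing
#' systematic affine differences via the TC covariance-ratio scaling for
#' three products, or mean/variance matching otherwise) and combines them
#' step by step as the weighted sum `sum_i w_i x_i`.
#'
#' Rescaling uses, in order of preference: scaling factors carried by the
#' weight vector (set by [merge_weights()] from the fit's estimated
#' sensitivities, which stay unbiased under non-zero ECC because the
#' instrumental estimator is ECC-robust); else the TC covariance-ratio
#' scaling (whose factors are contaminated when an ECC pair exists);
#' else standard-deviation matching.
#'
#' Missing data policy: with `na_policy = "renormalize"` (default) the
#' weights are renormalized over the products available at each step, so
#' coverage is preserved; `"strict"` drops any step with a missing
#' weighted product. A step where every weighted product is missing is
#' always missing.
#'
#' @param x a [collocated_series()].
#' @param weights a `"weight_vector"` (e.g. from [merge_weights()]) or a
#'   bare numeric vector summing to 1.
#' @param reference product id defining the common data space; defaults to
#'   the weight vector's `reference_product`, else the first product.
#' @param na_policy `"renormalize"` or `"strict"`.
#' @param min_samples passed to the rescaling step.
#' @return Numeric merged series (one value per time step) with attributes
#'   `weights`, `reference`, `scaling`, and `n_renormalized` (steps merged
#'   from a product subset).
#' @examples
#' th <- simulate_truth(truth_config(n_steps = 3000, seed = 1))
#' pr <- simulate_products(th, product_config(seed = 2))
#' fit <- eivd_estimate(pr, ecc_pair = c("P1", "P2"))
#' w <- merge_weights(fit, reference = "P1")
#' merged <- merge_series(pr, w)
#' @export
merge_series <- function(x, weights, reference = NULL,
                         na_policy = c("renormalize", "strict"),
                         min_samples = 100L) {
  na_policy <- match.arg(na_policy)
  stopifnot(inherits(x, "collocated_series"))
  ids <- attr(x, "product_ids")
  fit_scaling <- NULL
  if (inherits(weights, "weight_vector")) {
    if (is.null(reference)) reference <- weights$reference_product
    w <- weights$weights[ids]
    # carried scaling is only valid for the data space it was derived in
    if (identical(reference, weights$reference_product))
      fit_scaling <- weights$scaling
  } else {
    w <- rep_len(as.numeric(weights), ncol(x))
    names(w) <- ids
  }
  if (any(is.na(w)))
    stop("weights do not cover every product in the series", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-8)
    stop("weights must sum to 1", call. = FALSE)
  if (is.null(reference)) reference <- ids[1L]
  ref <- resolve_product(reference, ids)

  if (!is.null(fit_scaling) && all(is.finite(fit_scaling[ids]))) {
    v <- unclass(x)
    mu <- colMeans(v, na.rm = TRUE)
    scaling <- fit_scaling[ids]
    for (j in seq_len(ncol(v)))
      v[, j] <- scaling[j] * (v[, j] - mu[j]) + mu[ref]
  } else if (ncol(x) == 3L) {
    rs <- tc_rescale(x, reference = ref, min_samples = min_samples)
    if (!rs$valid)
      stop("rescaling undefined (degenerate covariances)", call. = FALSE)
    v <- unclass(rs$series)
    scaling <- rs$scaling
  } else {
    # variance-matching rescale for N != 3
    v <- unclass(x)
    mu <- colMeans(v, na.rm = TRUE)
    sdv <- apply(v, 2L, stats::sd, na.rm = TRUE)
    scaling <- stats::setNames(sdv[ref] / sdv, ids)
    for (j in seq_len(ncol(v)))
      v[, j] <- scaling[j] * (v[, j] - mu[j]) + mu[ref]
  }

  active <- w != 0
  wv <- matrix(rep(w, each = nrow(v)), nrow(v), ncol(v))
  wv[is.na(v)] <- NA_real_
  wv[, !active] <- 0
  tot <- rowSums(wv, na.rm = TRUE)
  num <- rowSums(wv * v, na.rm = TRUE)
  merged <- ifelse(tot > 0, num / tot, NA_real_)
  full <- abs(tot - 1) < 1e-12
  if (na_policy == "strict") merged[!full] <- NA_real_
  n_renorm <- sum(!full & tot > 0)
  structure(merged, weights = w, reference = ids[ref], scaling = scaling,
            n_renormalized = if (na_policy == "strict") 0L else n_renorm)
}
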