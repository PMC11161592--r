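#' MSE-optimal merging weights from an error covariance matrix
#'
#' Minimizes the merged estimate's random error variance `W' Sigma W`
#' subject to the unbiasedness constraint `sum(W) = 1`:
#' `W = (I' Sigma^-1 I)^-1 Sigma^-1 I`, with predicted merged error
#' variance `(I' Sigma^-1 I)^-1`. Off-diagonal entries of `Sigma` carry
#' the error covariances of products whose random errors correlate (ECC).
#'
#' A singular or non-positive-definite matrix never raises: the result
#' falls back to equal weights with `fallback_applied = TRUE`.
#'
#' @param error_cov N x N symmetric error covariance matrix, with the
#'   products' error variances on the diagonal.
#' @param product_ids optional product labels.
#' @return An object of class `"weight_vector"`: list with `weights`
#'   (named, summing to 1), `predicted_error_variance`, `method`
#'   (`"general"` here), `fallback_applied` and `fallback_reason`.
#' @examples
#' optimal_weights(diag(c(0.36, 0.29, 0.13)))
#' @export
optimal_weights <- function(error_cov, product_ids = NULL) {
  error_cov <- as.matrix(error_cov)
  n <- nrow(error_cov)
  if (is.null(product_ids))
    product_ids <- colnames(error_cov) %||% paste0("P", seq_len(n))
  if (!is_square_symmetric(error_cov))
    return(equal_weight_fallback(product_ids, error_cov,
                                 "error covariance not symmetric/finite"))
  ones <- rep(1, n)
  si <- tryCatch(solve(error_cov, ones), error = function(e) NULL)
  if (is.null(si) || !all(is.finite(si)) ||
      min(eigen(error_cov, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    return(equal_weight_fallback(product_ids, error_cov,
                                 "singular or non-positive-definite error covariance"))
  z <- sum(si)
  w <- si / z
  new_weight_vector(stats::setNames(w, product_ids), "general",
                    predicted = 1 / z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_weight_vector <- function(weights, method, predicted,
                              fallback = FALSE, reason = NULL) {
  structure(list(weights = weights, method = method,
                 predicted_error_variance = predicted,
                 fallback_applied = fallback, fallback_reason = reason),
            class = "weight_vector")
}

equal_weight_fallback <- function(ids, error_cov = NULL, reason) {
  n <- length(ids)
  w <- stats::setNames(rep(1 / n, n), ids)
  pred <- if (!is.null(error_cov) && all(is.finite(error_cov)))
    drop(crossprod(w, error_cov %*% w)) else NA_real_
  new_weight_vector(w, "simple_average", pred, fallback = TRUE,
                    reason = reason)
}

#' @export
print.weight_vector <- function(x, digits = 4, ...) {
  cat("Merging weights (", x$method,
      if (x$fallback_applied) ", fallback" else "", "):\n", sep = "")
  print(round(x$weights, digits))
  cat("predicted merged error variance:",
      format(x$predicted_error_variance, digits = digits), "\n")
  if (x$fallback_applied) cat("fallback reason:", x$fallback_reason, "\n")
  invisible(x)
}

#' Two-product inverse-variance weights
#'
#' The classic duo case with independent errors:
#' `w1 = v2 / (v1 + v2)`, `w2 = v1 / (v1 + v2)`.
#'
#' @param var1,var2 error variances of the two products (> 0).
#' @param product_ids optional labels.
#' @return A `"weight_vector"`, method `"duo"`.
#' @export
weights_duo <- function(var1, var2, product_ids = c("P1", "P2")) {
  if (!is.finite(var1) || !is.finite(var2) || var1 <= 0 || var2 <= 0)
    return(equal_weight_fallback(product_ids,
                                 reason = "non-positive error variance"))
  s <- var1 + var2
  new_weight_vector(stats::setNames(c(var2, var1) / s, product_ids), "duo",
                    predicted = var1 * var2 / s)
}

#' Three-product weights with one non-zero ECC pair
#'
#' Closed form for the error covariance matrix in which products 1 and 2
#' share an error covariance `cov12` and product 3 is independent:
#' \deqn{w_1 = (v_2 - c) / ((v_1 v_2 - c^2) Z),\quad
#'       w_2 = (v_1 - c) / ((v_1 v_2 - c^2) Z),\quad
#'       w_3 = 1 / (v_3 Z)}
#' with `Z = (v1 + v2 - 2 c)/(v1 v2 - c^2) + 1/v3`. Identical to
#' [optimal_weights()] applied to the corresponding block matrix.
#'
#' @param var1,var2,var3 error variances (> 0).
#' @param cov12 error covariance of products 1 and 2;
#'   `cov12^2 < var1 * var2` required.
#' @param product_ids optional labels.
#' @return A `"weight_vector"`, method `"trio_ecc"`.
#' @export
weights_trio_ecc <- function(var1, var2, var3, cov12,
                             product_ids = c("P1", "P2", "P3")) {
  vars <- c(var1, var2, var3)
  if (!all(is.finite(c(vars, cov12))) || any(vars <= 0) ||
      cov12^2 >= var1 * var2)
    return(equal_weight_fallback(product_ids,
                                 reason = "degenerate ECC block (|rho| >= 1 or bad variance)"))
  det12 <- var1 * var2 - cov12^2
  z <- (var1 + var2 - 2 * cov12) / det12 + 1 / var3
  w <- c((var2 - cov12) / (det12 * z),
         (var1 - cov12) / (det12 * z),
         1 / (var3 * z))
  new_weight_vector(stats::setNames(w, product_ids), "trio_ecc",
                    predicted = 1 / z)
}

#' Repair merging weights against invalid error estimates
#'
#' Applies the package's explicit fallback ladder: products whose error
#' variance estimate is flagged invalid are dropped and the weights are
#' recomputed over the valid subset (duo or general path); if the
#' recomputed weights still leave \[0, 1\] (possible with strong ECC),
#' the result falls back to equal weights over the valid products — the
#' simple-average baseline. Dropped products keep weight 0.
#'
#' @param raw a `"weight_vector"` over all N products.
#' @param error_model a `"colloc"` fit (or a list with `error_variance`,
#'   `error_covariance` and `valid$error_variance`) for the same products.
#' @return A `"weight_vector"` over all N products (zeros for dropped
#'   ones); `NULL` when no product has a valid error variance (pixel
#'   masked).
#' @export
sanitize_weights <- function(raw, error_model) {
  stopifnot(inherits(raw, "weight_vector"))
  ids <- names(raw$weights)
  ok <- error_model$valid$error_variance[ids]
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) return(NULL)
  in_range <- all(raw$weights >= 0 & raw$weights <= 1)
  if (all(ok) && in_range && !raw$fallback_applied) return(raw)
  keep <- ids[ok]
  if (length(keep) == 1L) {
    w <- stats::setNames(as.numeric(ids %in% keep), ids)
    return(new_weight_vector(w, "single_product",
                             error_model$error_variance[keep],
                             fallback = TRUE,
                             reason = "only one valid product"))
  }
  sub <- error_cov_from_fit(error_model, keep)
  cand <- optimal_weights(sub, product_ids = keep)
  if (cand$fallback_applied || any(cand$weights < 0 | cand$weights > 1))
    cand <- equal_weight_fallback(keep, sub,
                                  reason = "recomputed weights left [0, 1]")
  w <- stats::setNames(numeric(length(ids)), ids)
  w[keep] <- cand$weights
  new_weight_vector(w, cand$method, cand$predicted_error_variance,
                    fallback = TRUE,
                    reason = cand$fallback_reason %||% "invalid products dropped")
}

# assemble the error covariance matrix of a subset of products from a fit,
# zero where no pair was declared
error_cov_from_fit <- function(fit, ids = fit$product_ids,
                               error_variance = fit$error_variance) {
  n <- length(ids)
  m <- diag(error_variance[ids], n)
  dimnames(m) <- list(ids, ids)
  for (k in seq_along(fit$error_covariance)) {
    p <- strsplit(names(fit$error_covariance)[k], "|", fixed = TRUE)[[1L]]
    if (all(p %in% ids) && isTRUE(fit$valid$ecc[k]))
      m[p[1L], p[2L]] <- m[p[2L], p[1L]] <- fit$error_covariance[k]
  }
  m
}

#' Merging weights from a collocation fit
#'
#' Builds the error covariance matrix of the fitted products — rescaled
#' into the reference product's data space using the estimated
#' sensitivities, since weights must be computed where the products have
#' been brought to a common scale — applies [optimal_weights()], and
#' sanitizes the result against invalid estimates.
#'
#' @param fit a `"colloc"` fit.
#' @param reference reference product id; default: the product with the
#'   largest estimated sensitivity.
#' @param sanitize apply [sanitize_weights()] (default `TRUE`).
#' @return A `"weight_vector"` with an extra `reference_product` field,
#'   or `NULL` when the fit supports no valid weighting.
#' @export
merge_weights <- function(fit, reference = NULL, sanitize = TRUE) {
  stopifnot(inherits(fit, "colloc"))
  if (!is.null(fit$failure)) return(NULL)
  ids <- fit$product_ids
  if (is.null(reference)) {
    sv <- ifelse(fit$valid$sensitivity, fit$sensitivity, -Inf)
    if (all(!is.finite(sv))) return(NULL)
    reference <- ids[which.max(sv)]
  } else reference <- ids[resolve_product(reference, ids)]
  # scale error covariance into the reference data space:
  # s_i = beta_ref / beta_i = sqrt(sens_ref / sens_i)
  s <- sqrt(fit$sensitivity[reference] / fit$sensitivity)
  s[!is.finite(s) | s <= 0] <- NA_real_
  scaled_fit <- fit
  scaled_fit$error_variance <- fit$error_variance * s^2
  for (k in seq_along(fit$error_covariance)) {
    p <- strsplit(names(fit$error_covariance)[k], "|", fixed = TRUE)[[1L]]
    scaled_fit$error_covariance[k] <- fit$error_covariance[k] *
      s[p[1L]] * s[p[2L]]
  }
  m <- error_cov_from_fit(scaled_fit, ids)
  raw <- optimal_weights(m, product_ids = ids)
  raw$reference_product <- reference
  raw$scaling <- s
  if (!sanitize) return(raw)
  scaled_fit$valid$error_variance <- fit$valid$error_variance &
    is.finite(scaled_fit$error_variance) & scaled_fit$error_variance > 0
  out <- sanitize_weights(raw, scaled_fit)
  if (!is.null(out)) {
    out$reference_product <- reference
    out$scaling <- s
  }
  out
}
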