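#' Evaluation metrics for an estimate against a reference
#'
#' Computes the six scores used throughout the package: RMSE, unbiased
#' RMSE (RMSE after removing each series' mean), MAE, relative bias
#' RB = (mean(est) - mean(ref)) / mean(ref) (signed), the modified
#' Kling-Gupta efficiency and the Pearson correlation. The modified KGE is
#' the variability-ratio variant
#' `KGE' = 1 - sqrt((r - 1)^2 + (beta - 1)^2 + (gamma - 1)^2)` with
#' `beta` the mean ratio and `gamma` the ratio of coefficients of
#' variation; the classic 2009 form (standard-deviation ratio `alpha`
#' instead of `gamma`) is available via `kge_variant = "2009"`.
#'
#' All means use the population convention, so the decomposition
#' `RMSE^2 = ubRMSE^2 + bias^2` holds exactly. Undefined quantities
#' (zero reference mean for RB, zero variance for r and gamma) are `NA`.
#'
#' @param est,ref numeric vectors; pairs with a missing member are
#'   dropped.
#' @param kge_variant `"2012"` (modified, default) or `"2009"` (classic).
#' @return An object of class `"metric_set"`: list with `rmse`, `ubrmse`,
#'   `mae`, `rb`, `kge`, `r`, `bias` and `n`.
#' @examples
#' compute_metrics(c(1, 2, 4), c(1, 2, 3))
#' @export
compute_metrics <- function(est, ref, kge_variant = c("2012", "2009")) {
  kge_variant <- match.arg(kge_variant)
  ok <- is.finite(est) & is.finite(ref)
  e <- est[ok]; o <- ref[ok]
  n <- length(e)
  if (n < 2L) stop("need at least 2 paired valid samples", call. = FALSE)
  bias <- mean(e) - mean(o)
  rmse <- sqrt(mean((e - o)^2))
  ubrmse <- sqrt(mean(((e - mean(e)) - (o - mean(o)))^2))
  mae <- mean(abs(e - o))
  rb <- if (mean(o) != 0) bias / mean(o) else NA_real_
  sde <- stats::sd(e); sdo <- stats::sd(o)
  r <- if (sde > 0 && sdo > 0) stats::cor(e, o) else NA_real_
  beta <- if (mean(o) != 0) mean(e) / mean(o) else NA_real_
  vr <- if (kge_variant == "2012") {
    cve <- if (mean(e) != 0) sde / mean(e) else NA_real_
    cvo <- if (mean(o) != 0) sdo / mean(o) else NA_real_
    if (is.finite(cve) && is.finite(cvo) && cvo != 0) cve / cvo else NA_real_
  } else {
    if (sdo > 0) sde / sdo else NA_real_
  }
  kge <- if (is.finite(r) && is.finite(beta) && is.finite(vr))
    1 - sqrt((r - 1)^2 + (beta - 1)^2 + (vr - 1)^2) else NA_real_
  structure(list(rmse = rmse, ubrmse = ubrmse, mae = mae, rb = rb,
                 kge = kge, r = r, bias = bias, n = n,
                 kge_variant = kge_variant),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, digits = 4, ...) {
  cat(sprintf(
    "n = %d | RMSE %.*g | ubRMSE %.*g | MAE %.*g | RB %.*g | KGE %.*g | R %.*g\n",
    x$n, digits, x$rmse, digits, x$ubrmse, digits, x$mae, digits, x$rb,
    digits, x$kge, digits, x$r))
  invisible(x)
}

#' @export
as.data.frame.metric_set <- function(x, ...) {
  data.frame(rmse = x$rmse, ubrmse = x$ubrmse, mae = x$mae, rb = x$rb,
             kge = x$kge, r = x$r, n = x$n)
}

#' Aggregate per-site metrics by group
#'
#' Summarizes a table of per-site metric values into per-group mean and
#' standard deviation, one row per group x metric, and flags the group
#' with the best mean per metric (lowest for error metrics, largest for
#' skill metrics, smallest magnitude for rb).
#'
#' @param df data.frame with one row per site: a grouping column plus
#'   numeric metric columns.
#' @param group name of the grouping column (e.g. `"pft"` or `"product"`).
#' @param metrics which metric columns to summarize; defaults to the
#'   standard six that are present.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return data.frame with columns `group`, `metric`, `mean`, `sd`, `n`,
#'   `best`.
#' @export
aggregate_by_group <- function(df, group,
                               metrics = intersect(
                                 c("rmse", "ubrmse", "mae", "rb", "kge", "r"),
                                 names(df)),
                               sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(group %in% names(df), length(metrics) > 0)
  pop_sd <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 1L) return(NA_real_)
    if (sd_type == "sample") return(if (length(v) > 1) stats::sd(v) else NA_real_)
    sqrt(mean((v - mean(v))^2))
  }
  lower_better <- c(rmse = TRUE, ubrmse = TRUE, mae = TRUE, rb = TRUE,
                    kge = FALSE, r = FALSE)
  out <- do.call(rbind, lapply(metrics, function(m) {
    sp <- split(df[[m]], df[[group]])
    means <- vapply(sp, function(v) mean(v[is.finite(v)]), 0)
    sds <- vapply(sp, pop_sd, 0)
    ns <- vapply(sp, function(v) sum(is.finite(v)), 0L)
    score <- if (isTRUE(lower_better[m])) {
      if (m == "rb") abs(means) else means
    } else -means
    data.frame(group = names(sp), metric = m, mean = unname(means),
               sd = unname(sds), n = unname(ns),
               best = seq_along(means) == which.min(score),
               row.names = NULL)
  }))
  out
}
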