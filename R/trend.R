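#' Mann-Kendall monotonic trend test
#'
#' Computes the Mann-Kendall S statistic and a two-sided p-value. For
#' short tie-free series (`n <= exact_max`) the p-value comes from the
#' exact permutation distribution of S (enumerated through the classical
#' inversion-count recurrence); otherwise the tie-corrected variance with
#' continuity-corrected normal approximation is used.
#'
#' @param y numeric series in time order (`NA` dropped).
#' @param exact_max largest tie-free n for which the exact distribution is
#'   used (default 10).
#' @return List with `s`, `var_s`, `p` (two-sided), `n` and `method`
#'   (`"exact"` or `"normal"`).
#' @export
mann_kendall <- function(y, exact_max = 10L) {
  y <- y[is.finite(y)]
  n <- length(y)
  if (n < 3L) return(list(s = NA_real_, var_s = NA_real_, p = NA_real_,
                          n = n, method = "undefined"))
  cmb <- utils::combn(n, 2L)
  s <- sum(sign(y[cmb[2L, ]] - y[cmb[1L, ]]))
  ties <- table(y)
  has_ties <- any(ties > 1L)
  if (!has_ties && n <= exact_max) {
    return(list(s = s, var_s = NA_real_, p = kendall_exact_p(s, n),
                n = n, method = "exact"))
  }
  t_p <- as.numeric(ties[ties > 1L])
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(t_p * (t_p - 1) * (2 * t_p + 5))) / 18
  z <- if (s > 0) (s - 1) / sqrt(var_s)
       else if (s < 0) (s + 1) / sqrt(var_s) else 0
  list(s = s, var_s = var_s, p = 2 * stats::pnorm(-abs(z)), n = n,
       method = "normal")
}

# exact two-sided tail of the tie-free Mann-Kendall S distribution:
# the number of permutations of 1..n with k inversions follows the
# Mahonian recurrence; S = n(n-1)/2 - 2k
kendall_exact_p <- function(s, n) {
  if (s == 0) return(1)
  counts <- 1
  for (m in 2:n) {
    cs <- cumsum(counts)
    len <- length(counts) + m - 1L
    counts <- vapply(0:(len - 1L), function(k) {
      hi <- min(k, length(cs) - 1L)
      lo <- max(0L, k - m + 1L)
      cs[hi + 1L] - if (lo > 0L) cs[lo] else 0
    }, 0)
  }
  max_s <- n * (n - 1) / 2
  k_at <- (max_s - abs(s)) / 2          # inversion count at |s|
  p_one <- sum(counts[seq_len(k_at + 1L)]) / sum(counts)
  min(1, 2 * p_one)
}

#' Theil-Sen slope
#'
#' Median of all pairwise slopes; robust to outliers, defined for any
#' two or more points with distinct time coordinates.
#'
#' @param y numeric values.
#' @param t time coordinates.
#' @return The slope (units of y per unit t).
#' @examples
#' theil_sen_slope(c(0, 1, 4), t = c(0, 1, 2))  # median of 1, 2, 3
#' @export
theil_sen_slope <- function(y, t = seq_along(y)) {
  ok <- is.finite(y) & is.finite(t)
  y <- y[ok]; t <- t[ok]
  if (length(y) < 2L) return(NA_real_)
  cmb <- utils::combn(length(y), 2L)
  dt <- t[cmb[2L, ]] - t[cmb[1L, ]]
  if (all(dt == 0)) return(NA_real_)
  stats::median((y[cmb[2L, ]] - y[cmb[1L, ]])[dt != 0] / dt[dt != 0])
}

#' Theil-Sen trend with Mann-Kendall significance
#'
#' Robust trend of an annual (or otherwise regularly sampled) series: the
#' slope is the median of all pairwise slopes, the intercept the median
#' residual level, and significance comes from [mann_kendall()] at the
#' requested level.
#'
#' @param y numeric values (e.g. annual totals, mm/year).
#' @param t time coordinates (default `1, 2, ...`; use calendar years for
#'   a slope per year).
#' @param level two-sided significance level (default 0.05).
#' @return An object of class `"trend_result"`: list with `slope`,
#'   `intercept`, `mk_p`, `significant`, `n` and `valid` (`FALSE` with
#'   all-`NA` estimates when fewer than 4 points are available).
#' @examples
#' theil_sen_trend(c(0, 1, 4, 5, 8), t = 0:4)
#' @export
theil_sen_trend <- function(y, t = seq_along(y), level = 0.05) {
  ok <- is.finite(y) & is.finite(t)
  y <- y[ok]; t <- t[ok]
  n <- length(y)
  if (n < 4L)
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          mk_p = NA_real_, significant = NA, n = n,
                          valid = FALSE, level = level),
                     class = "trend_result"))
  slope <- theil_sen_slope(y, t)
  intercept <- stats::median(y - slope * t)
  mk <- mann_kendall(y)
  structure(list(slope = slope, intercept = intercept, mk_p = mk$p,
                 significant = is.finite(mk$p) && mk$p < level, n = n,
                 valid = TRUE, level = level, mk_method = mk$method),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, digits = 4, ...) {
  if (!x$valid) {
    cat("Trend: not estimable (n =", x$n, "< 4)\n")
    return(invisible(x))
  }
  cat(sprintf("Theil-Sen slope %.*g, MK p = %.*g (%s)%s, n = %d\n",
              digits, x$slope, digits, x$mk_p, x$mk_method,
              if (x$significant) sprintf(" *significant at %g*", x$level)
              else "", x$n))
  invisible(x)
}

#' Latitudinal mean profile of a gridded field
#'
#' Mean over valid longitudes (and, for a cube, time) per latitude row.
#'
#' @param x a [grid_cube()] or a lat x lon matrix.
#' @param lat latitude coordinates (taken from the cube when omitted).
#' @param weights optional lat x lon matrix of cell weights (e.g. valid
#'   fractions); default unweighted.
#' @return Named numeric vector, one mean per latitude (`NA` for all
#'   masked rows).
#' @export
latitudinal_profile <- function(x, lat = NULL, weights = NULL) {
  if (inherits(x, "grid_cube")) {
    lat <- x$lat
    m <- apply(x$values, c(1L, 2L), function(v)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  } else {
    m <- as.matrix(x)
    if (is.null(lat)) lat <- seq_len(nrow(m))
  }
  if (is.null(weights)) weights <- matrix(1, nrow(m), ncol(m))
  stopifnot(all(dim(weights) == dim(m)))
  out <- vapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]; w <- weights[i, ]
    ok <- is.finite(v) & is.finite(w) & w > 0
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * w[ok]) / sum(w[ok])
  }, 0)
  stats::setNames(out, lat)
}

#' Annual totals from a sub-annual series
#'
#' Sums regularly spaced values within calendar years, scaling each step
#' by its length in days so the result is in mm/year. Used to feed
#' [theil_sen_trend()] from 8-day or daily merged series.
#'
#' @param values numeric series, mm/day.
#' @param dates `Date` vector aligned with `values`.
#' @param step_days length of each step in days (default 8).
#' @param min_coverage minimum fraction of non-missing steps per year
#'   (default 0.8); years below it are `NA`.
#' @return Named vector of annual sums (mm/year) by year.
#' @export
annual_totals <- function(values, dates, step_days = 8,
                          min_coverage = 0.8) {
  stopifnot(length(values) == length(dates))
  yr <- format(dates, "%Y")
  vapply(split(seq_along(values), yr), function(idx) {
    v <- values[idx]
    if (mean(is.finite(v)) < min_coverage) return(NA_real_)
    mean(v, na.rm = TRUE) * 365.25
  }, 0)
}
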