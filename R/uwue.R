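#' Flux-tower site record
#'
#' Light wrapper around a data.frame of daily (or finer) eddy-covariance
#' observations used by the uWUE partitioning benchmark. Required columns:
#' `date`, `ET` (mm/day), `GPP`, `VPD` (hPa), `P` (precipitation, mm).
#' Optional: `QC` (1 = measured or good-quality gap-filled, else bad).
#'
#' @param df data.frame with the columns above, strictly increasing dates.
#' @param pft optional IGBP plant-functional-type label (e.g. `"ENF"`).
#' @param site optional site id.
#' @return The data.frame with class `"site_record"` and attributes `pft`,
#'   `site`.
#' @export
site_record <- function(df, pft = NULL, site = NULL) {
  need <- c("date", "ET", "GPP", "VPD", "P")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("site record lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.unsorted(as.numeric(df$date), strictly = TRUE))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (any(df$VPD < 0, na.rm = TRUE))
    stop("VPD must be non-negative", call. = FALSE)
  if (!"QC" %in% names(df)) df$QC <- 1L
  structure(df, pft = pft, site = site,
            class = c("site_record", "data.frame"))
}

#' Read a FLUXNET-style daily CSV as a site record
#'
#' @param path CSV file with one row per day.
#' @param mapping named character vector mapping the required internal
#'   columns (`date`, `ET`, `GPP`, `VPD`, `P`, optionally `QC`) to the
#'   file's column names. Defaults to the internal names themselves.
#' @param pft,site passed to [site_record()].
#' @return A [site_record()].
#' @export
read_site_csv <- function(path, mapping = NULL, pft = NULL, site = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    for (internal in names(mapping)) {
      src <- mapping[[internal]]
      if (!src %in% names(df))
        stop(sprintf("column '%s' (mapped to %s) not in %s", src, internal,
                     path), call. = FALSE)
      df[[internal]] <- df[[src]]
    }
  }
  df$date <- as.Date(df$date)
  site_record(df[, intersect(c("date", "ET", "GPP", "VPD", "P", "QC"),
                             names(df))], pft = pft, site = site)
}

#' Filter rain days and poor-quality steps
#'
#' Removes days with rainfall above the threshold *and* the following day
#' (canopy evaporation contaminates ET on both), plus any step whose QC
#' flag is not good. The rain rule uses calendar adjacency, so a rain day
#' whose successor is itself rainy extends the exclusion window.
#'
#' @param record a [site_record()].
#' @param threshold rain threshold in mm/day (default 0.1).
#' @return The filtered [site_record()], with attributes `n_rain_removed`
#'   and `n_qc_removed`.
#' @export
filter_rain_days <- function(record, threshold = 0.1) {
  stopifnot(inherits(record, "site_record"))
  rain <- !is.na(record$P) & record$P > threshold
  rain_dates <- record$date[rain]
  drop_rain <- record$date %in% c(rain_dates, rain_dates + 1L)
  drop_qc <- !(record$QC %in% 1L) & !drop_rain
  out <- record[!(drop_rain | drop_qc), , drop = FALSE]
  attr(out, "pft") <- attr(record, "pft")
  attr(out, "site") <- attr(record, "site")
  attr(out, "n_rain_removed") <- sum(drop_rain)
  attr(out, "n_qc_removed") <- sum(drop_qc)
  class(out) <- class(record)
  out
}

#' Annual potential uWUE
#'
#' Potential underlying water-use efficiency per calendar year: the slope
#' of the zero-intercept 95th-percentile (quantile) regression of
#' `GPP * sqrt(VPD)` on ET. It characterizes days where carbon gain per
#' unit water loss is maximal, i.e. T ~ ET, and is held constant within
#' the year.
#'
#' @param record a [site_record()] (rain-filtered by the caller).
#' @param tau regression quantile (default 0.95).
#' @param min_fit_points minimum valid steps per year (default 50); years
#'   below it are `NA`.
#' @return Named numeric vector, one slope per calendar year.
#' @export
uwue_potential <- function(record, tau = 0.95, min_fit_points = 50L) {
  stopifnot(inherits(record, "site_record"))
  yr <- format(record$date, "%Y")
  out <- vapply(split(seq_len(nrow(record)), yr), function(idx) {
    x <- record$ET[idx]
    y <- record$GPP[idx] * sqrt(record$VPD[idx])
    ok <- is.finite(x) & is.finite(y) & x > 0
    if (sum(ok) < min_fit_points || sum(x[ok]^2) == 0) return(NA_real_)
    slope <- suppressWarnings(
      unname(stats::coef(quantreg::rq(y[ok] ~ x[ok] + 0, tau = tau))))
    if (!is.finite(slope) || slope <= 0) NA_real_ else slope
  }, 0)
  out
}

#' Moving-window apparent uWUE
#'
#' Apparent underlying water-use efficiency: the zero-intercept
#' least-squares slope of `GPP * sqrt(VPD)` on ET within a centered
#' moving window, assigned to the window's central step. Windows with too
#' few valid points yield `NA`.
#'
#' @param record a [site_record()].
#' @param window window width in steps (default 8 days).
#' @param min_points minimum valid points per window (default 8; capped at
#'   the window width).
#' @return Numeric vector of slopes, one per record step.
#' @export
uwue_apparent <- function(record, window = 8L, min_points = 8L) {
  stopifnot(inherits(record, "site_record"), window >= 1L)
  min_points <- min(min_points, window)
  x <- record$ET
  y <- record$GPP * sqrt(record$VPD)
  n <- length(x)
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window - 1L - half_lo
  vapply(seq_len(n), function(i) {
    idx <- max(1L, i - half_lo):min(n, i + half_hi)
    xs <- x[idx]; ys <- y[idx]
    ok <- is.finite(xs) & is.finite(ys)
    if (sum(ok) < min_points || sum(xs[ok]^2) == 0) return(NA_real_)
    sum(xs[ok] * ys[ok]) / sum(xs[ok]^2)
  }, 0)
}

#' T/ET ratio from apparent and potential uWUE
#'
#' @param uwue_a apparent uWUE series (per step).
#' @param uwue_p potential uWUE: a scalar, or a per-step vector matching
#'   `uwue_a` (e.g. the annual value expanded to the record's steps).
#' @param clip clip the ratio into \[0, 1\]? Default `TRUE`; the numbers
#'   clipped are counted in attributes `n_clipped_high` / `n_clipped_low`.
#' @return Ratio series with clipping-count attributes.
#' @export
t_over_et <- function(uwue_a, uwue_p, clip = TRUE) {
  if (length(uwue_p) == 1L) uwue_p <- rep(uwue_p, length(uwue_a))
  stopifnot(length(uwue_p) == length(uwue_a))
  ratio <- ifelse(is.finite(uwue_p) & uwue_p > 0, uwue_a / uwue_p, NA_real_)
  hi <- lo <- 0L
  if (clip) {
    hi <- sum(ratio > 1, na.rm = TRUE)
    lo <- sum(ratio < 0, na.rm = TRUE)
    ratio <- pmin(pmax(ratio, 0), 1)
  }
  structure(ratio, n_clipped_high = hi, n_clipped_low = lo)
}

#' Transpiration from a T/ET ratio
#'
#' @param record a [site_record()].
#' @param ratio per-step T/ET ratio, e.g. from [t_over_et()].
#' @return T series in mm/day.
#' @export
transpiration <- function(record, ratio) {
  stopifnot(inherits(record, "site_record"),
            length(ratio) == nrow(record))
  as.numeric(record$ET * ratio)
}

#' Partition ET into transpiration with the uWUE method
#'
#' End-to-end driver: rain-day and QC filtering, annual potential uWUE by
#' 95th-percentile regression, moving-window apparent uWUE, T/ET ratio
#' (clipped to \[0, 1\]) and the transpiration series.
#'
#' @param record a [site_record()].
#' @param window apparent-uWUE window in steps (default 8).
#' @param min_points minimum points per window.
#' @param tau potential-uWUE regression quantile.
#' @param min_fit_points minimum points per year for the potential fit.
#' @param rain_threshold rain filter threshold, mm/day.
#' @return An object of class `"uwue_partition"`: list with `record` (the
#'   filtered record), `uwue_p` (per year), `uwue_a`, `ratio`, `T` (per
#'   step of the filtered record) and `coverage` (fraction of steps with a
#'   T estimate).
#' @examples
#' rec <- simulate_site(site_sim_config(seed = 1))
#' fit <- partition_uwue(rec)
#' fit$coverage
#' @export
partition_uwue <- function(record, window = 8L, min_points = 8L,
                           tau = 0.95, min_fit_points = 50L,
                           rain_threshold = 0.1) {
  rec <- filter_rain_days(record, threshold = rain_threshold)
  up <- uwue_potential(rec, tau = tau, min_fit_points = min_fit_points)
  ua <- uwue_apparent(rec, window = window, min_points = min_points)
  up_step <- unname(up[format(rec$date, "%Y")])
  ratio <- t_over_et(ua, up_step)
  T <- transpiration(rec, ratio)
  structure(list(record = rec, uwue_p = up, uwue_a = ua, ratio = ratio,
                 T = T, coverage = mean(is.finite(T))),
            class = "uwue_partition")
}

#' @export
print.uwue_partition <- function(x, ...) {
  cat("uWUE partition: ", nrow(x$record), " filtered steps, coverage ",
      sprintf("%.1f%%", 100 * x$coverage), "\n", sep = "")
  cat("  potential uWUE per year:\n")
  print(round(x$uwue_p, 3))
  cat("  mean T/ET: ", sprintf("%.3f", mean(x$ratio, na.rm = TRUE)),
      " (", attr(x$ratio, "n_clipped_high"), " clipped at 1)\n", sep = "")
  invisible(x)
}

#' Benchmark transpiration as the mean over partitioning methods
#'
#' Averages the T series of several ET-partitioning methods step by step,
#' using whichever methods have a value at each step (methods with gaps
#' simply drop out there).
#'
#' @param methods a list (or matrix, one column per method) of aligned T
#'   series.
#' @return Numeric per-step mean; `NA` where no method has a value.
#' @export
benchmark_mean <- function(methods) {
  m <- if (is.list(methods)) do.call(cbind, methods) else as.matrix(methods)
  if (ncol(m) < 1L) stop("need at least one method series", call. = FALSE)
  out <- rowMeans(m, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  out
}
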