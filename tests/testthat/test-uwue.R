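make_record <- function(n = 30, et = NULL, gpp = NULL, vpd = NULL,
                        p = 0, qc = 1L, start = "2001-01-01") {
  if (is.null(et)) et <- rep(2, n)
  if (is.null(vpd)) vpd <- rep(4, n)
  if (is.null(gpp)) gpp <- 5 * et / sqrt(vpd)
  site_record(data.frame(date = as.Date(start) + seq_len(n) - 1L,
                         ET = et, GPP = gpp, VPD = vpd,
                         P = rep_len(p, n), QC = rep_len(qc, n)))
}

test_that("rain filtering removes rain days and their successors", {
  rec <- make_record(10)
  expect_equal(nrow(filter_rain_days(rec)), 10)

  p <- numeric(10); p[5] <- 3
  f <- filter_rain_days(make_record(10, p = p))
  expect_equal(as.integer(format(f$date, "%d")), setdiff(1:10, c(5, 6)))

  p2 <- numeric(10); p2[3:4] <- 2   # overlapping windows: days 3,4,5 out
  f2 <- filter_rain_days(make_record(10, p = p2))
  expect_equal(as.integer(format(f2$date, "%d")), setdiff(1:10, 3:5))

  # qc-bad steps are dropped too
  qc <- rep(1L, 10); qc[8] <- 0L
  f3 <- filter_rain_days(make_record(10, qc = qc))
  expect_equal(nrow(f3), 9)
})

test_that("potential uWUE equals the slope of exactly proportional data", {
  set.seed(131)
  et <- runif(100, 0.5, 4)
  rec <- make_record(100, et = et, gpp = 7 * et / sqrt(4))
  up <- uwue_potential(rec, min_fit_points = 50)
  expect_equal(unname(up["2001"]), 7, tolerance = 1e-8)
  # with half the points strictly below the line, the 95th-percentile
  # regression still hugs the upper edge
  gpp <- 7 * et / sqrt(4)
  gpp[seq(1, 99, 2)] <- gpp[seq(1, 99, 2)] * runif(50, 0.3, 0.8)
  rec2 <- make_record(100, et = et, gpp = gpp)
  up2 <- uwue_potential(rec2, min_fit_points = 50)
  expect_equal(unname(up2["2001"]), 7, tolerance = 1e-6)
  # too few points: year flagged NA
  expect_true(is.na(uwue_potential(make_record(20), min_fit_points = 50)))
})

test_that("apparent uWUE is the windowed through-origin slope", {
  set.seed(132)
  et <- runif(60, 0.5, 4)
  rec <- make_record(60, et = et, gpp = 3 * et / sqrt(4))
  ua <- uwue_apparent(rec, window = 8)
  # boundary windows are truncated below min_points and stay NA
  expect_true(all(is.na(ua[1:3])) && all(is.na(ua[57:60])))
  expect_equal(unname(ua[4:56]), rep(3, 53), tolerance = 1e-10)
  # a window starved of valid points yields NA
  et2 <- et; et2[1:7] <- NA
  rec2 <- make_record(60, et = et2, gpp = 3 * et2 / sqrt(4))
  ua2 <- uwue_apparent(rec2, window = 8, min_points = 8)
  expect_true(all(is.na(ua2[1:7])))
})

test_that("T/ET ratio clips with counters and scales ET", {
  r <- t_over_et(c(0.5, 1.2, -0.1, NA), 1)
  expect_equal(as.numeric(r), c(0.5, 1, 0, NA))
  expect_equal(attr(r, "n_clipped_high"), 1L)
  expect_equal(attr(r, "n_clipped_low"), 1L)
  rec <- make_record(4, et = c(2, 2, 2, 2))
  expect_equal(transpiration(rec, as.numeric(r)), c(1, 2, 0, NA))
})

test_that("full pipeline recovers a known T/ET schedule", {
  cfg <- site_sim_config(n_days = 730, seed = 133)
  rec <- simulate_site(cfg)
  fit <- partition_uwue(rec)
  tr <- attr(rec, "t_over_et_true")[match(fit$record$date, rec$date)]
  ok <- is.finite(fit$ratio)
  expect_gt(cor(fit$ratio[ok], tr[ok]), 0.95)
  expect_lt(mean(abs(fit$ratio[ok] - tr[ok])), 0.05)
  expect_equal(unname(fit$uwue_p), rep(cfg$uwue_p_true, 2), tolerance = 0.1)
  # scale invariance: common factor on ET and GPP leaves the ratio alone
  rec_s <- rec
  rec_s$ET <- rec$ET * 3.2
  rec_s$GPP <- rec$GPP * 3.2
  fit_s <- partition_uwue(rec_s)
  expect_equal(as.numeric(fit_s$ratio), as.numeric(fit$ratio),
               tolerance = 1e-8)
})

test_that("potential uWUE bounds the apparent value on sub-potential data", {
  # t_over_et <= 1 by construction, so uwue_a <= uwue_p up to noise
  exceed <- vapply(1:5, function(s) {
    fit <- partition_uwue(simulate_site(site_sim_config(seed = 140 + s)))
    mean(fit$uwue_a > unname(fit$uwue_p[1]) * 1.05, na.rm = TRUE)
  }, 0)
  expect_lt(mean(exceed), 0.05)
})

test_that("benchmark mean averages whatever methods are available", {
  a <- c(1, 1, NA); b <- c(3, NA, NA); c3 <- c(5, 4, NA)
  expect_equal(benchmark_mean(list(a, b, c3)), c(3, 2.5, NA))
  expect_equal(benchmark_mean(list(a)), a)
  expect_equal(benchmark_mean(list(rep(1, 3), rep(2, 3), rep(3, 3))),
               rep(2, 3))
})

test_that("site CSV round-trips through the reader with column mapping", {
  dir <- withr::local_tempdir()
  rec <- simulate_site(site_sim_config(n_days = 40, seed = 151))
  df <- as.data.frame(rec)
  names(df) <- c("TIMESTAMP", "ET_mm", "GPP_NT", "VPD_F", "P_F", "QC_FLAG")
  path <- file.path(dir, "site.csv")
  write.csv(df, path, row.names = FALSE)
  back <- read_site_csv(path, mapping = c(date = "TIMESTAMP", ET = "ET_mm",
                                          GPP = "GPP_NT", VPD = "VPD_F",
                                          P = "P_F", QC = "QC_FLAG"),
                        pft = "ENF")
  expect_equal(back$ET, rec$ET)
  expect_equal(attr(back, "pft"), "ENF")
  expect_error(read_site_csv(path, mapping = c(ET = "nope")), "not in")
})
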