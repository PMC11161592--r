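test_that("TC closed form matches direct substitution of the covariances", {
  cv <- matrix(c(2, 1, 1,
                 1, 2, 1,
                 1, 1, 2), 3, dimnames = rep(list(c("X", "Y", "Z")), 2))
  fit <- transcol:::tc_core(cv, c("X", "Y", "Z"))
  expect_equal(unname(fit$error_variance), c(1, 1, 1))   # 2 - 1*1/1
  expect_equal(unname(fit$sensitivity), c(1, 1, 1))
})

test_that("TC closed form equals the cross-multiplied-difference form", {
  # algebraic identity on any fixed sample, population denominators
  ser <- make_triplet(500, seed = 31)
  closed <- coef(tc_error_variances(ser, min_samples = 100))
  crossd <- tc_cross_differences(ser, reference = 1, min_samples = 100)
  expect_equal(closed, crossd, tolerance = 1e-10)
})

test_that("noiseless identical triplet has zero error variances", {
  th <- simulate_truth(truth_config(n_steps = 300, seed = 1))
  pr <- simulate_products(th, product_config(alphas = 0, betas = 1,
                                             error_cov = matrix(0, 3, 3),
                                             seed = 2))
  fit <- tc_error_variances(pr, min_samples = 100)
  expect_equal(unname(coef(fit)), rep(0, 3), tolerance = 1e-8)
})

test_that("TC recovers error variances of a zero-ECC triplet", {
  ser <- make_triplet(20000, seed = 41, error_cov = default_error_cov(0))
  fit <- tc_error_variances(ser, min_samples = 100)
  expect_equal(unname(coef(fit)), c(0.36, 0.29, 0.13), tolerance = 0.1)
  expect_true(all(fit$valid$error_variance))
})

test_that("EIVD recovers error variances and ECC under a non-zero ECC pair", {
  ser <- make_triplet(20000, seed = 51)
  fit <- eivd_estimate(ser, ecc_pair = c("P1", "P2"), min_samples = 100)
  expect_equal(unname(coef(fit)), c(0.36, 0.29, 0.13), tolerance = 0.1)
  true_ecc <- 0.10 / sqrt(0.36 * 0.29)
  expect_lt(abs(fit$ecc - true_ecc), 0.05)
  # zero-ECC data: the ECC estimate sits near zero
  ser0 <- make_triplet(20000, seed = 52, error_cov = default_error_cov(0))
  fit0 <- eivd_estimate(ser0, ecc_pair = c("P1", "P2"), min_samples = 100)
  expect_lt(abs(fit0$ecc), 0.05)
})

test_that("zero-ECC TC is biased when a true ECC exists, EIVD is not", {
  ser <- make_triplet(50000, seed = 61)
  tc <- tc_error_variances(ser, min_samples = 100)
  ei <- eivd_estimate(ser, ecc_pair = c("P1", "P2"), min_samples = 100)
  truth <- c(0.36, 0.29, 0.13)
  tc_bias <- abs(coef(tc)[1:2] / truth[1:2] - 1)
  ei_bias <- abs(coef(ei) / truth - 1)
  expect_true(all(tc_bias > 0.10))
  expect_true(all(ei_bias < 0.05))
})

test_that("EIVD reports a precondition failure on memoryless signals", {
  th <- simulate_truth(truth_config(n_steps = 3000, ar1_coeff = 0,
                                    seasonal_amplitude = 0, seed = 71))
  pr <- simulate_products(th, product_config(seed = 72))
  fit <- eivd_estimate(pr, ecc_pair = c("P1", "P2"), min_samples = 100)
  expect_match(fit$failure, "lag-1")
  expect_false(any(fit$valid$error_variance))
})

test_that("estimators are scale- and permutation-equivariant", {
  ser <- make_triplet(20000, seed = 81)
  fit <- eivd_estimate(ser, ecc_pair = c("P1", "P2"), min_samples = 100)
  # scale product 1 by c: its error variance scales by c^2, ECC unchanged
  c0 <- 3.7
  v <- unclass(ser); v[, 1] <- c0 * v[, 1]
  fit_s <- eivd_estimate(collocated_series(v, attr(ser, "product_ids")),
                         ecc_pair = c("P1", "P2"), min_samples = 100)
  expect_equal(unname(fit_s$error_variance["P1"]),
               unname(c0^2 * fit$error_variance["P1"]), tolerance = 1e-2)
  expect_equal(unname(fit_s$ecc), unname(fit$ecc), tolerance = 1e-2)
  # TC is exactly scale-equivariant (closed form)
  tc <- tc_error_variances(ser, min_samples = 100)
  tc_s <- tc_error_variances(collocated_series(v, attr(ser, "product_ids")),
                             min_samples = 100)
  expect_equal(unname(tc_s$error_variance["P1"]),
               unname(c0^2 * tc$error_variance["P1"]), tolerance = 1e-10)
  # permuting product order permutes the estimates exactly
  perm <- c(3, 1, 2)
  vp <- unclass(ser)[, perm]
  fit_p <- eivd_estimate(
    collocated_series(vp, attr(ser, "product_ids")[perm]),
    ecc_pair = c("P1", "P2"), min_samples = 100)
  expect_equal(fit_p$error_variance[c("P1", "P2", "P3")],
               fit$error_variance[c("P1", "P2", "P3")], tolerance = 1e-10)
  expect_equal(fit_p$ecc, fit$ecc, tolerance = 1e-10)
})

test_that("extended collocation recovers a quadruplet with one ECC pair", {
  ec4 <- diag(c(0.36, 0.29, 0.13, 0.20))
  ec4[1, 2] <- ec4[2, 1] <- 0.10
  th <- simulate_truth(truth_config(n_steps = 20000, seed = 91))
  pr <- simulate_products(th, product_config(
    alphas = c(0, 0.2, -0.1, 0.1), betas = c(1, 0.8, 1.2, 0.9),
    error_cov = ec4, seed = 92))
  fit <- ec_quadruplet_estimate(pr, ecc_pairs = list(c("P1", "P2")),
                                min_samples = 100)
  expect_equal(unname(coef(fit)), c(0.36, 0.29, 0.13, 0.20),
               tolerance = 0.1)
  expect_lt(abs(fit$error_covariance - 0.10), 0.02)
})

test_that("EC with no declared pairs agrees with TC on embedded triplets", {
  th <- simulate_truth(truth_config(n_steps = 20000, seed = 93))
  pr <- simulate_products(th, product_config(
    alphas = c(0, 0.2, -0.1, 0.1), betas = c(1, 0.8, 1.2, 0.9),
    error_cov = diag(c(0.36, 0.29, 0.13, 0.20)), seed = 94))
  ec <- ec_quadruplet_estimate(pr, min_samples = 100)
  tri <- collocated_series(unclass(pr)[, 1:3],
                           attr(pr, "product_ids")[1:3])
  tc <- tc_error_variances(tri, min_samples = 100)
  expect_equal(coef(ec)[1:3], coef(tc), tolerance = 0.1)
})

test_that("unsolvable ECC-pair declarations are rejected up front", {
  th <- simulate_truth(truth_config(n_steps = 1000, seed = 95))
  pr <- simulate_products(th, product_config(
    alphas = rep(0, 4), betas = rep(1, 4),
    error_cov = diag(4) * 0.1, seed = 96))
  expect_error(
    ec_quadruplet_estimate(pr, ecc_pairs = list(c("P1", "P2"),
                                                c("P3", "P4"),
                                                c("P1", "P3"))),
    "unsolvable")
})

test_that("negative variance estimates are flagged, never clipped", {
  # a shared error between X and Y inflates sigma_XY while sigma_XZ and
  # sigma_YZ stay small, driving the population TC estimate for X to -1
  set.seed(97)
  n <- 5000
  th <- rnorm(n)
  e0 <- rnorm(n)
  x <- th + e0
  y <- th + 2 * e0
  z <- 0.1 * th + rnorm(n, sd = 0.1)
  ser <- collocated_series(cbind(X = x, Y = y, Z = z))
  fit <- tc_error_variances(ser, min_samples = 100)
  neg <- fit$error_variance < 0
  expect_true(any(neg, na.rm = TRUE))
  expect_false(any(fit$valid$error_variance[which(neg)]))
})
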