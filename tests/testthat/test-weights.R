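test_that("optimal weights solve the constrained MSE minimization", {
  w <- optimal_weights(diag(3))
  expect_equal(unname(w$weights), rep(1 / 3, 3))
  expect_equal(w$predicted_error_variance, 1 / 3)

  # brute-force oracle: numeric minimization of w' S w on the simplex
  for (seed in 1:5) {
    S <- random_spd(3, seed)
    w <- optimal_weights(S)
    expect_equal(sum(w$weights), 1)
    obj <- function(p) {
      ww <- c(p, 1 - sum(p))
      drop(crossprod(ww, S %*% ww))
    }
    opt <- optim(c(1 / 3, 1 / 3), obj, method = "BFGS",
                 control = list(reltol = 1e-14))
    expect_equal(drop(crossprod(w$weights, S %*% w$weights)),
                 opt$value, tolerance = 1e-8)
  }
})

test_that("optimality holds against random simplex weightings", {
  S <- random_spd(3, 42)
  w <- optimal_weights(S)
  set.seed(43)
  for (k in 1:1000) {
    p <- -log(runif(3)); p <- p / sum(p)
    expect_gte(drop(crossprod(p, S %*% p)),
               w$predicted_error_variance - 1e-12)
  }
})

test_that("duo weights reduce to the diagonal matrix solution", {
  w <- weights_duo(0.5, 0.5)
  expect_equal(unname(w$weights), c(0.5, 0.5))
  w2 <- weights_duo(1e-9, 1)
  expect_gt(w2$weights[1], 0.999)
  w3 <- weights_duo(0.36, 0.13)
  wm <- optimal_weights(diag(c(0.36, 0.13)))
  expect_equal(unname(w3$weights), unname(wm$weights), tolerance = 1e-12)
  expect_true(weights_duo(-1, 1)$fallback_applied)
})

test_that("trio-ECC closed form equals the matrix solution", {
  # zero-ECC reduction: inverse-variance weights
  w0 <- weights_trio_ecc(0.36, 0.29, 0.13, 0)
  iv <- (1 / c(0.36, 0.29, 0.13)) / sum(1 / c(0.36, 0.29, 0.13))
  expect_equal(unname(w0$weights), iv, tolerance = 1e-12)
  # symmetry when var1 = var2
  ws <- weights_trio_ecc(0.3, 0.3, 0.13, 0.1)
  expect_equal(unname(ws$weights[1]), unname(ws$weights[2]))
  # equivalence with the block-matrix solution on 100 random tuples
  for (seed in 1:100) {
    tp <- random_trio_tuple(seed)
    S <- diag(tp[1:3]); S[1, 2] <- S[2, 1] <- tp[4]
    wc <- weights_trio_ecc(tp[1], tp[2], tp[3], tp[4])
    wm <- optimal_weights(S)
    expect_equal(unname(wc$weights), unname(wm$weights), tolerance = 1e-10)
    expect_equal(wc$predicted_error_variance, wm$predicted_error_variance,
                 tolerance = 1e-10)
  }
})

test_that("increasing the ECC shifts weight to the independent product", {
  covs <- seq(0, 0.25, by = 0.05)
  w3 <- vapply(covs, function(cc)
    weights_trio_ecc(0.3, 0.3, 0.13, cc)$weights[3], 0)
  expect_true(all(diff(w3) > 0))
})

test_that("weight sanitization drops invalid products and falls back", {
  fake_fit <- function(ev, valid) {
    list(error_variance = stats::setNames(ev, c("a", "b", "c")),
         error_covariance = stats::setNames(numeric(0), character(0)),
         valid = list(error_variance = stats::setNames(valid,
                                                       c("a", "b", "c"))))
  }
  # all valid, in range: identity
  raw <- optimal_weights(diag(c(0.2, 0.3, 0.4)), c("a", "b", "c"))
  out <- sanitize_weights(raw, fake_fit(c(0.2, 0.3, 0.4), rep(TRUE, 3)))
  expect_identical(out, raw)
  # one invalid variance: duo weights over the remaining two
  out2 <- sanitize_weights(raw, fake_fit(c(0.2, 0.3, -1),
                                         c(TRUE, TRUE, FALSE)))
  expect_equal(unname(out2$weights), c(0.6, 0.4, 0))
  expect_true(out2$fallback_applied)
  # strong ECC pushes a closed-form weight negative: equal-weight fallback
  w_neg <- weights_trio_ecc(0.1, 0.5, 0.3, 0.2)
  expect_true(any(w_neg$weights < 0))
  ff <- fake_fit(c(0.1, 0.5, 0.3), rep(TRUE, 3))
  ff$error_covariance <- stats::setNames(0.2, "a|b")
  ff$valid$ecc <- stats::setNames(TRUE, "a|b")
  names(w_neg$weights) <- c("a", "b", "c")
  out3 <- sanitize_weights(w_neg, ff)
  expect_equal(unname(out3$weights), rep(1 / 3, 3))
  expect_true(out3$fallback_applied)
  # no valid products: masked
  expect_null(sanitize_weights(raw, fake_fit(rep(-1, 3), rep(FALSE, 3))))
})

test_that("weights from a fit are expressed in the reference data space", {
  ser <- make_triplet(30000, seed = 101)
  fit <- eivd_estimate(ser, ecc_pair = c("P1", "P2"), min_samples = 100)
  w <- merge_weights(fit, reference = "P1")
  expect_equal(sum(w$weights), 1)
  # theory: scale errors into P1 space with s_i = beta_1 / beta_i
  s <- 1 / c(1, 0.8, 1.2)
  S <- diag(c(0.36, 0.29, 0.13) * s^2)
  S[1, 2] <- S[2, 1] <- 0.10 * s[1] * s[2]
  wt <- optimal_weights(S)
  expect_equal(unname(w$weights), unname(wt$weights), tolerance = 0.1)
  # default reference: the product with the largest sensitivity (P3)
  wd <- merge_weights(fit)
  expect_equal(wd$reference_product, "P3")
})
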