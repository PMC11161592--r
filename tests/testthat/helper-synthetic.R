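# shared fixture builders (all data generated in code, fixed seeds)

make_triplet <- function(n, seed, error_cov = default_error_cov(),
                         betas = c(1, 0.8, 1.2), alphas = c(0, 0.2, -0.1),
                         phi = 0.7, seasonal_amplitude = 1.5) {
  th <- simulate_truth(truth_config(
    n_steps = n, ar1_coeff = phi, seasonal_amplitude = seasonal_amplitude,
    seed = seed))
  simulate_products(th, product_config(
    alphas = alphas, betas = betas, error_cov = error_cov,
    seed = seed + 1000L))
}

# random symmetric positive-definite matrix
random_spd <- function(p, seed) {
  set.seed(seed)
  a <- matrix(rnorm(p * p), p)
  crossprod(a) + diag(p) * 0.1
}

# admissible (var1, var2, var3, cov12) tuple
random_trio_tuple <- function(seed) {
  set.seed(seed)
  v <- runif(3, 0.05, 1)
  rho <- runif(1, -0.9, 0.9)
  c(v, rho * sqrt(v[1] * v[2]))
}
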