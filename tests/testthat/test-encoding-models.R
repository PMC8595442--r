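test_that("XOR code uses the stated sign convention and flip corruption", {
  tt <- simulate_xor(500, flip_prob = 0, seed = 1)
  r <- responses(tt)
  # equal responses -> s = -1, opposite -> s = +1; shat = -r1 r2 is exact
  expect_true(all(tt$s[r[, 1] == r[, 2]] == -1))
  expect_true(all(tt$s[r[, 1] != r[, 2]] == 1))
  expect_equal(-r[, 1] * r[, 2], tt$s)

  flipped <- simulate_xor(4000, flip_prob = 0.2, seed = 2)
  acc <- mean(-responses(flipped)[, 1] * responses(flipped)[, 2] == flipped$s)
  # per-trial decoding survives iff both or neither response flipped
  expect_equal(acc, 0.8^2 + 0.2^2, tolerance = 0.03)

  expect_error(simulate_xor(0), "positive")
  expect_error(simulate_xor(10, flip_prob = 0.5), "flip_prob")
  expect_identical(simulate_xor(100, 0.1, seed = 7), simulate_xor(100, 0.1, seed = 7))
})

test_that("nuisance variation removes Gabor mean tuning but not variance tuning", {
  spec <- gabor_population(N = 4)
  s_vals <- seq(0, pi * 3 / 4, length.out = 4)
  tt <- simulate_gabor_population(spec, s_vals, "phase", n_trials = 10000, seed = 3)
  r <- responses(tt)
  n_c <- 2500
  for (i in seq_len(4)) {
    m <- tapply(r[, i], tt$s, mean)
    v <- tapply(r[, i], tt$s, var)
    se_m <- sqrt(v / n_c)
    expect_true(all(abs(m) < 3 * se_m))        # marginal mean flat
    se_v <- v * sqrt(2 / n_c)
    expect_gt(max(v) - min(v), 3 * max(se_v))  # variance tuned
  }
  # conditional mean is tuned when the nuisance is fixed
  f <- nlcc:::gabor_projection(spec, s_vals, rep(0, 4))
  expect_gt(max(f[, 1]) - min(f[, 1]), 1)
})

test_that("law of total covariance holds for the Gabor population", {
  spec <- gabor_population(N = 3)
  tt <- simulate_gabor_population(spec, 0.5, "phase", n_trials = 8000, seed = 5)
  r <- responses(tt)
  lhs <- cov(r)
  f <- nlcc:::gabor_projection(spec, tt$s, tt$nu)
  rhs <- cov(f) + diag(spec$noise_var, 3)  # conditional cov is noise_var * I
  expect_equal(lhs, rhs, tolerance = 0.05, ignore_attr = TRUE)

  expect_error(simulate_gabor_population(spec, numeric(0), "phase", 10), "non-empty")
  expect_error(gabor_population(3, noise_var = 0), "positive")
})

test_that("quadratic code has flat means and stimulus-dependent covariance", {
  spec <- quadratic_code(cov_fn = rotating_cov(0.6))
  tt <- simulate_quadratic_code(spec, c(-0.4, 0.4), n_trials = 100000, seed = 6)
  r <- responses(tt)
  for (v in c(-0.4, 0.4)) {
    idx <- tt$s == v
    expect_lt(max(abs(colMeans(r[idx, ]))), 4 / sqrt(sum(idx)))
    expect_equal(cov(r[idx, ]), spec$cov_fn(v), tolerance = 0.03,
                 ignore_attr = TRUE)
  }
  # identity covariance family carries no quadratic information
  flat <- quadratic_code(cov_fn = function(s) diag(2))
  tf <- simulate_quadratic_code(flat, c(-0.1, 0.1), 40000, seed = 7)
  smf <- signal_noise_summary(polynomial_features(tf, 2), tf, "fine")
  expect_lt(fisher_information(smf, ridge = 1e-8), 0.05)

  bad <- quadratic_code(cov_fn = function(s) matrix(c(1, 2, 2, 1), 2))
  expect_error(simulate_quadratic_code(bad, 0, 10), "positive-definite")
})

test_that("quadratic Fisher information matches the Gaussian log-likelihood oracle", {
  spec <- quadratic_code(cov_fn = rotating_cov(0.6))
  ds <- 0.1
  tt <- simulate_quadratic_code(spec, c(-ds / 2, ds / 2), 2e5, seed = 8)
  sm <- signal_noise_summary(polynomial_features(tt, 2), tt, "fine")
  J_feat <- fisher_information(sm, ridge = 1e-8)
  # oracle: J = tr[(Sigma^-1 Sigma')^2] / 2 for a Gaussian with constant mean
  h <- 1e-4
  Sp <- (spec$cov_fn(h) - spec$cov_fn(-h)) / (2 * h)
  M <- solve(spec$cov_fn(0), Sp)
  J_true <- sum(diag(M %*% M)) / 2
  expect_gt(J_feat, 0)
  expect_equal(J_feat, J_true, tolerance = 0.1)
})

test_that("pure cubic stage is tetrahedrally symmetric with a linear third moment", {
  spec <- cubic_code(gamma = 2)
  n <- 100000
  for (s in c(-0.3, 0.3)) {
    z <- nlcc:::with_seed(9, nlcc:::sample_pure_cubic(n, 1, spec$gamma, s, 0.8))
    expect_equal(colMeans(z), rep(0, 3), tolerance = 4 / sqrt(n))
    expect_equal(cov(z), diag(3), tolerance = 0.02, ignore_attr = TRUE)
    m3 <- mean(z[, 1] * z[, 2] * z[, 3])
    expect_equal(m3, 0.8^3 * spec$gamma * s, tolerance = 4 / sqrt(n))
    expect_equal(sign(m3), sign(spec$gamma * s))
  }
  z0 <- nlcc:::with_seed(10, nlcc:::sample_pure_cubic(n, 1, 0, 0.5, 0.8))
  expect_lt(abs(mean(z0[, 1] * z0[, 2] * z0[, 3])), 4 / sqrt(n))
  expect_error(nlcc:::sample_pure_cubic(10, 1, 10, 1, 0.8), "mixture undefined")
  expect_error(cubic_code(n_triplets = 0), "at least 1")
})

test_that("cubic simulator applies the stimulus-dependent affine transform", {
  spec <- cubic_code(gamma = 2, mean_slope = 0.5, cov_log_slope = 0.3)
  tt <- simulate_cubic_code(spec, 0.2, 50000, seed = 11)
  r <- responses(tt)
  expect_lt(max(abs(colMeans(r) - spec$mean_fn(0.2))), 0.02)
  expect_equal(diag(cov(r)), diag(spec$cov_fn(0.2)), tolerance = 0.05,
               ignore_attr = TRUE)
  expect_identical(simulate_cubic_code(spec, 0.1, 100, seed = 3),
                   simulate_cubic_code(spec, 0.1, 100, seed = 3))
})

test_that("information injection saturates the Fisher information at 1/epsilon", {
  # feature-space mode on an abstract linear code: J0 = 25, Jinf = 100 -> 20
  F_prime <- c(3, 4)
  tt <- gaussian_feature_table(F_prime, diag(2), n = 2e5, ds = 0.2, seed = 12)
  lim <- inject_information_limit(tt, epsilon = 0.01, mode = "feature",
                                  f_prime = F_prime, seed = 13)
  sm <- signal_noise_summary(polynomial_features(lim, 1), lim, "fine")
  expect_equal(fisher_information(sm), 20, tolerance = 0.8)

  # epsilon = 0 leaves the table untouched
  expect_identical(inject_information_limit(tt, 0), tt)
  expect_error(inject_information_limit(tt, 0.1, mode = "input"), "encoder")

  # input mode: no decoder can beat epsilon
  spec <- quadratic_code(cov_fn = rotating_cov(0.6))
  ds <- 0.1
  base <- simulate_quadratic_code(spec, c(-ds / 2, ds / 2), 60000, seed = 14)
  eps <- 0.05
  lim2 <- inject_information_limit(base, eps, mode = "input", seed = 15)
  sm2 <- signal_noise_summary(polynomial_features(lim2, 2), lim2, "fine")
  dec <- fit_optimal_decoder(sm2)
  shat <- predict(dec, polynomial_features(lim2, 2))
  expect_gt(estimator_variance(shat, lim2$s), eps)
})
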