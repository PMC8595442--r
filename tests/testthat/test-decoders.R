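test_that("optimal decoder attains the closed-form variance", {
  F_prime <- c(3, 4)
  tt <- gaussian_feature_table(F_prime, diag(2), n = 1e5, ds = 0.2, seed = 1)
  fs <- polynomial_features(tt, 1)
  sm <- signal_noise_summary(fs, tt, "fine")
  dec <- fit_optimal_decoder(sm)
  w <- coef(dec)
  expect_equal(unname(w[1] / w[2]), 3 / 4, tolerance = 0.05)
  expect_equal(dec$sigma2, 1 / 25, tolerance = 0.03)    # (F' G^-1 F')^-1
  shat <- predict(dec, fs)
  expect_equal(estimator_variance(shat, tt$s), 1 / 25, tolerance = 0.03)
  # local unbiasedness: unit gain
  means <- tapply(shat, tt$s, mean)
  expect_equal(unname(diff(means)) / 0.2, 1, tolerance = 0.05)
})

test_that("diagonal covariance and pure-noise features behave as expected", {
  set.seed(2)
  G <- diag(c(1, 4, 9))
  F_prime <- c(1, 2, 0)   # third feature is pure independent noise
  tt <- gaussian_feature_table(F_prime, G, 4e4, ds = 0.5, seed = 2)
  sm <- signal_noise_summary(polynomial_features(tt, 1), tt, "fine")
  dec <- fit_optimal_decoder(sm)
  w <- unname(coef(dec))
  expect_equal(w[2] / w[1], (2 / 4) / (1 / 1), tolerance = 0.1)  # F'_k/G_kk
  expect_lt(abs(w[3] / w[1]), 0.05)                              # ~zero weight
  expect_equal(dec$sigma2, 0.5, tolerance = 0.05)
  # dropping the noise feature leaves the variance unchanged
  tt2 <- gaussian_feature_table(F_prime[1:2], G[1:2, 1:2], 4e4, ds = 0.5, seed = 3)
  sm2 <- signal_noise_summary(polynomial_features(tt2, 1), tt2, "fine")
  expect_equal(fit_optimal_decoder(sm2)$sigma2, dec$sigma2, tolerance = 0.07)
})

test_that("no linear readout beats the optimal weights", {
  set.seed(4)
  d <- 6
  G <- nlcc:::random_pd_matrix(d)
  F_prime <- rnorm(d)
  w_opt <- solve(G, F_prime)
  v_opt <- drop(t(w_opt) %*% G %*% w_opt) / drop(crossprod(w_opt, F_prime))^2
  for (i in 1:100) {
    w <- w_opt + rnorm(d, sd = 0.3 * sqrt(mean(w_opt^2)))
    v <- drop(t(w) %*% G %*% w) / drop(crossprod(w, F_prime))^2
    expect_gte(v, v_opt - 1e-12)
  }
})

test_that("suboptimal decoders degrade in the stated order", {
  set.seed(5)
  d <- 10
  G <- nlcc:::random_pd_matrix(d, spread = 4)
  F_prime <- rnorm(d)
  tt <- gaussian_feature_table(F_prime, G, 2e4, seed = 5)
  sm <- signal_noise_summary(polynomial_features(tt, 1), tt, "fine")
  aligned <- make_suboptimal_decoder(sm, "signal-aligned")
  noflip <- make_suboptimal_decoder(sm, "sign-flipped", flip_fraction = 0, seed = 1)
  expect_equal(coef(noflip), coef(aligned))
  flipped <- make_suboptimal_decoder(sm, "sign-flipped", flip_fraction = 0.4, seed = 1)
  expect_equal(sum(sign(coef(flipped)) != sign(coef(aligned))), 4)  # 40% of 10

  varof <- function(w) drop(t(w) %*% G %*% w) / drop(crossprod(w, F_prime))^2
  w_o <- solve(G, F_prime)
  expect_gte(varof(sm$F_prime), varof(w_o) - 1e-12)
  raw_flip <- sm$F_prime; raw_flip[1:4] <- -raw_flip[1:4]
  expect_gte(varof(raw_flip), varof(sm$F_prime))

  # with white noise the signal-aligned decoder is the optimal one
  tw <- gaussian_feature_table(c(1, 2), diag(2), 4e4, seed = 6)
  smw <- signal_noise_summary(polynomial_features(tw, 1), tw, "fine")
  wa <- coef(make_suboptimal_decoder(smw, "signal-aligned"))
  wo <- coef(fit_optimal_decoder(smw))
  expect_equal(unname(wa / wo), rep(1, 2), tolerance = 0.05)
  expect_error(make_suboptimal_decoder(smw, "sign-flipped", flip_fraction = 2),
               "flip_fraction")
})

test_that("decode applies weights, thresholds, and validates terms", {
  tt <- simulate_xor(400, seed = 7)
  fs <- polynomial_features(tt, 2)
  # quadratic decoder with weight -1 on r1 r2 classifies XOR perfectly
  dec <- structure(list(weights = c(0, 0, 0, -1, 0), offset = 0,
                        kind = "custom", mode = "coarse",
                        terms = fs$terms, threshold = 0),
                   class = "nl_decoder")
  expect_equal(predict(dec, fs), tt$s, ignore_attr = TRUE)
  expect_equal(decode(dec, fs, "choice"), tt$s, ignore_attr = TRUE)
  # unit weight projects a single feature
  e3 <- structure(list(weights = c(0, 0, 1, 0, 0), offset = 0, kind = "custom",
                       terms = fs$terms, threshold = NULL),
                  class = "nl_decoder")
  expect_equal(predict(e3, fs), unname(fs$values[, 3]))
  zero <- structure(list(weights = rep(0, 5), offset = 2.5, kind = "custom",
                         terms = fs$terms, threshold = NULL),
                    class = "nl_decoder")
  expect_true(all(predict(zero, fs) == 2.5))
  fs1 <- polynomial_features(tt, 1)
  expect_error(predict(dec, fs1), "terms do not match")
})

test_that("binary threshold choices follow the variance-task rule", {
  expect_equal(binary_threshold_choice(c(-3, -1, 0, 1, 3), 2), c(1, -1, -1, -1, 1))
  expect_equal(binary_threshold_choice(c(2, -2), 2), c(-1, -1))  # tie -> narrow
  expect_true(all(binary_threshold_choice(rnorm(10), 0) == 1))   # theta 0 -> wide
  expect_error(binary_threshold_choice(1, Inf), "finite")
})
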