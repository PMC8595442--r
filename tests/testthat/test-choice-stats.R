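test_that("fine choice correlations match the closed form", {
  F_prime <- c(3, 4)
  tt <- gaussian_feature_table(F_prime, diag(2), n = 1e5, seed = 1)
  fs <- polynomial_features(tt, 1)
  sm <- signal_noise_summary(fs, tt, "fine")
  dec <- fit_optimal_decoder(sm)
  shat <- predict(dec, fs)
  cc <- choice_correlation_fine(fs, shat, tt)
  se <- 3 * (1 - cc^2) / sqrt(nrow(tt))
  expect_true(all(abs(cc - c(0.6, 0.8)) < pmax(se, 0.01)))
  expect_equal(cc_closed_form(diag(2), c(3, 4)), c(0.6, 0.8))

  # self-correlation and independence
  expect_equal(unname(choice_correlation_fine(fs, responses(tt)[, 1], tt)[1]), 1)
  # zero weight on an independent feature: its choice correlation vanishes
  ind <- rnorm(nrow(tt))
  shat_ind <- drop(responses(tt) %*% c(0, 1)) + ind
  expect_lt(abs(choice_correlation_fine(fs, shat_ind, tt)[1]), 0.03)
  expect_error(choice_correlation_fine(fs, rep(1, nrow(tt)), tt), "zero-variance")
})

test_that("closed-form correlation matches sampling for random weights and covariances", {
  set.seed(2)
  for (i in 1:5) {
    d <- sample(2:6, 1)
    G <- nlcc:::random_pd_matrix(d)
    w <- rnorm(d)
    n <- 40000
    R <- nlcc:::rmvn(n, rep(0, d), G)
    tt <- trial_table(s = rep(0, n), r = R)
    fs <- polynomial_features(tt, 1)
    shat <- drop(R %*% w)
    emp <- choice_correlation_fine(fs, shat, tt, min_trials = 2)
    expect_equal(unname(emp), unname(cc_closed_form(G, w)), tolerance = 0.03)
  }
})

test_that("NACCC averages conditional moments and is bounded by one", {
  set.seed(3)
  n <- 20000
  s <- rep(c(-1, 1), each = n / 2)
  R <- matrix(rnorm(2 * n), n, 2)
  R[, 1] <- R[, 1] * ifelse(s > 0, 3, 1)   # category-dependent variance
  tt <- trial_table(s = s, r = R)
  fs <- polynomial_features(tt, 1)
  shat <- R[, 1] + 0.5 * rnorm(n)
  B <- naccc(fs, shat, tt)
  expect_true(all(abs(B) <= 1))
  expect_equal(unname(naccc(fs, R[, 1], tt)[1]), 1)       # self
  expect_lt(abs(naccc(fs, rnorm(n) + s, tt)[2]), 0.03)    # independent
  # with identical conditional distributions NACCC converges to the fine CC
  tt0 <- gaussian_feature_table(c(1, 1), diag(2), 40000, ds = 1e-4, seed = 4)
  fs0 <- polynomial_features(tt0, 1)
  sh0 <- drop(responses(tt0) %*% c(2, 1))
  expect_equal(unname(naccc(fs0, sh0, tt0)),
               unname(choice_correlation_fine(fs0, sh0, tt0)), tolerance = 0.02)
  expect_error(naccc(fs, shat, trial_table(s = rep(1, n), r = R)), "two or more")
})

test_that("total-correlation discriminability transform is exact", {
  expect_equal(dprime_from_total_correlation(1 / sqrt(5)), 1)
  expect_equal(dprime_from_total_correlation(0), 0)
  D <- 1e-5
  expect_equal(dprime_from_total_correlation(D) / (2 * D), 1, tolerance = 1e-9)
  expect_warning(out <- dprime_from_total_correlation(c(0.5, 1)), "infinite")
  expect_equal(out[2], Inf)
  # Gaussian two-class simulation with true d' = 1
  set.seed(5)
  n <- 2e5
  s <- rep(c(-1, 1), each = n / 2)
  x <- rnorm(n, mean = ifelse(s > 0, 0.5, -0.5))
  expect_equal(dprime_from_total_correlation(x, s), 1, tolerance = 0.02)
  expect_error(dprime_from_total_correlation(x, rep(1, n)), "binary")
})

test_that("optimal predictions are ratios of discriminabilities", {
  expect_equal(unname(predict_optimal_cc(c(a = 2), 2)), 1)
  expect_equal(unname(predict_optimal_cc(c(a = 0), 2)), 0)
  expect_warning(p <- predict_optimal_cc(c(a = 3), 2), "exceed 1")
  expect_equal(unname(p), 1.5)                       # flagged, not clipped
  expect_true(all(predict_optimal_cc(c(-1, 1), 2) >= 0))
  expect_error(predict_optimal_cc(1, 0), "positive")
  # corrections scale the prediction
  expect_equal(unname(predict_optimal_cc(c(x = 1), 2, zeta = 0.8, delta = 1.25)),
               0.8 * 1 / (1.25 * 2))
})

test_that("the four information ratios agree to machine precision", {
  # consistent quadruple: d'_k/d' = 1/2
  expect_identical(equivalent_ratios(dprime = c(1, 2)), 0.5)
  expect_equal(equivalent_ratios(threshold = c(1, 2)), 0.5)
  expect_equal(equivalent_ratios(variance = c(0.01, 0.04)), 0.5)
  expect_equal(equivalent_ratios(fisher = c(1, 4)), 0.5)
  expect_error(equivalent_ratios(dprime = c(1, 2), fisher = c(1, 4)), "exactly one")
  expect_error(equivalent_ratios(), "exactly one")
})

test_that("Fisher information handles information limits and singularities", {
  expect_equal(fisher_information(c(3, 4), diag(2)), 25)
  F_prime <- c(3, 4)
  G <- diag(2) + 0.01 * F_prime %*% t(F_prime)
  expect_equal(fisher_information(F_prime, G), 20)        # 1/(1/100 + 1/25)
  Gbig <- diag(2) + 100 * F_prime %*% t(F_prime)
  expect_lt(fisher_information(F_prime, Gbig), 0.01)      # epsilon -> infinity
  expect_error(fisher_information(c(1, 1), matrix(1, 2, 2)), "singular")
})

test_that("threshold and corrections are estimable from a synthetic session", {
  spec <- variance_task(n_trials = 3000, n_neurons = 8, subject = "direct", seed = 1)
  tt <- generate_session(spec, seed = 2)
  est <- estimate_threshold(tt$nu, tt$choice)
  expect_equal(est$theta, optimal_threshold(225, 9), tolerance = 0.3)
  fs <- polynomial_features(tt, 1)
  u <- tt$nu^2
  cal <- cc_corrections(u, tt$choice, tt$s, n_rep = 20, seed = 3)
  expect_gt(cal$zeta, 0.2); expect_lt(cal$zeta, 1)
  expect_gt(cal$delta, 0)
  expect_equal(cal$threshold, optimal_threshold(225, 9)^2, tolerance = 3)
})
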