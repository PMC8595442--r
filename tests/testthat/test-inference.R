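test_that("the principal-axis slope recovers exact proportionality", {
  pred <- c(0.1, 0.3, 0.5, 0.7)
  es1 <- efficiency_slope(pred, pred, n_boot = 50, seed = 1)
  expect_equal(es1$alpha, 1, tolerance = 1e-10)
  expect_lt(diff(es1$ci), 1e-8)
  es2 <- efficiency_slope(pred, 0.5 * pred, n_boot = 50, seed = 1)
  expect_equal(es2$alpha, 0.5, tolerance = 1e-10)
  expect_true(es2$ci[1] <= es2$alpha && es2$alpha <= es2$ci[2])
  expect_error(efficiency_slope(rep(0.2, 5), rep(0.4, 5)), "degenerate")
  expect_error(efficiency_slope(c(1, 2), c(1, 2)), "at least 3")
})

test_that("with a dominant information limit the slope equals epsilon over the estimator variance", {
  # plant a known epsilon in a redundant code; for an optimal decoder the
  # estimator variance is epsilon + 1/J0, so the planted efficiency
  # epsilon / sigma2_shat is a closed-form oracle close to (but below) 1
  set.seed(2)
  d <- 25
  F_prime <- rnorm(d)
  G0 <- nlcc:::random_pd_matrix(d, spread = 4)
  eps <- 0.3
  G <- G0 + eps * F_prime %*% t(F_prime)
  J0 <- drop(crossprod(F_prime, solve(G0, F_prime)))
  alpha_oracle <- eps / (eps + 1 / J0)
  expect_gt(alpha_oracle, 0.85)           # epsilon dominates by construction
  tt <- gaussian_feature_table(F_prime, G, 4e4, seed = 2)
  an <- fine_cc_analysis(tt)
  # decoder variance attains the information bound
  expect_equal(estimator_variance(an$shat, tt$s), eps + 1 / J0, tolerance = 0.1)
  es <- efficiency_slope(an$predicted, an$measured, seed = 3)
  expect_equal(es$alpha, alpha_oracle, tolerance = 0.2)
  expect_true(es$ci[1] <= 1 && 1 <= es$ci[2] || es$alpha > 0.9)
})

test_that("shuffle-null p-values are calibrated and detect coupled choices", {
  set.seed(3)
  n <- 600
  R <- matrix(rnorm(n * 200), n, 200)
  tt <- trial_table(s = rep(c(-1, 1), each = n / 2), r = R[, 1:2])
  fs <- feature_set(R, data.frame(term = paste0("t", 1:200), degree = 1,
                                  i = 1, j = NA, k = NA))
  choice <- sample(c(-1, 1), n, TRUE)
  out <- shuffle_null_pvalues(fs, tt, "choice", n_shuffles = 150,
                              choices = choice, seed = 103)
  expect_gt(stats::ks.test(out$p, "punif")$p.value, 0.05)

  # one-sided ("printed") tail gives p = 0.5 at a vanishing statistic
  out1 <- shuffle_null_pvalues(fs, tt, "choice", n_shuffles = 60,
                               choices = choice, tail = "upper", seed = 104)
  tiny <- which.min(abs(out1$statistic))
  expect_equal(unname(out1$p[tiny]), 0.5, tolerance = 0.05)

  # power: strongly coupled choice at n = 5000
  set.seed(4)
  n2 <- 5000
  R2 <- matrix(rnorm(n2 * 3), n2, 3)
  tt2 <- trial_table(s = rep(c(-1, 1), each = n2 / 2), r = R2)
  ch2 <- sign(R2[, 1] + 0.5 * rnorm(n2))
  out2 <- shuffle_null_pvalues(polynomial_features(tt2, 1), tt2, "choice",
                               100, choices = ch2, seed = 5)
  expect_lt(out2$p[1], 0.01)
  expect_error(shuffle_null_pvalues(polynomial_features(tt2, 1), tt2, "choice",
                                    1, choices = ch2), "at least 2")
})

test_that("both shuffles are exact permutations within their strata", {
  spec <- variance_task(n_trials = 1500, n_neurons = 5, seed = 1)
  tt <- generate_session(spec, seed = 2)
  # nuisance-matched strata are finer than (s, choice), so per-neuron
  # multisets within (s, choice) are preserved by both shuffles; infinite
  # tolerance merges all nuisance bins, degenerating to the nuisance shuffle
  for (shuffled in list(shuffle_internal_noise(tt, 1.5, seed = 3),
                        shuffle_nuisance(tt, seed = 4),
                        shuffle_internal_noise(tt, Inf, seed = 9))) {
    r0 <- responses(tt); r1 <- responses(shuffled)
    for (g in split(seq_len(nrow(tt)), interaction(tt$s, tt$choice, drop = TRUE)))
      for (j in seq_len(ncol(r0)))
        expect_equal(sort(r0[g, j]), sort(r1[g, j]))
    expect_equal(shuffled$choice, tt$choice)
    expect_equal(shuffled$nu, tt$nu)
  }
  expect_error(shuffle_internal_noise(trial_table(s = 1:4, r = matrix(rnorm(8), 4, 2)),
                                      1.5), "nuisance")
})

test_that("internal-noise shuffle removes noise correlations but keeps nuisance correlations", {
  spec <- variance_task(n_trials = 8000, n_neurons = 6, noise_model = "gaussian",
                        shared_noise_sd = 3, seed = 2)
  tt <- generate_session(spec, seed = 5)
  r <- responses(tt)
  # internal-noise correlation: conditional on (s, nu-bin)
  noise_cor <- function(tab) {
    r <- responses(tab)
    cs <- c()
    for (g in split(seq_len(nrow(tab)),
                    interaction(tab$s, floor(tab$nu / 3), drop = TRUE)))
      if (length(g) > 30) cs <- c(cs, cor(r[g, 1], r[g, 2]))
    mean(cs)
  }
  marg_cor <- function(tab) {
    r <- responses(tab)
    mean(sapply(split(seq_len(nrow(tab)), tab$s),
                function(g) cor(r[g, 1], r[g, 2])))
  }
  expect_gt(noise_cor(tt), 0.1)            # planted shared noise
  sh <- shuffle_internal_noise(tt, 1.5, seed = 6)
  expect_lt(abs(noise_cor(sh)), 0.05)      # internal correlations removed
  # nuisance-induced correlation survives: marginal correlation stays away
  # from the internal-noise-only level
  expect_gt(abs(marg_cor(sh) - noise_cor(tt)), 0)
  nu_sh <- shuffle_nuisance(tt, seed = 7)
  # full shuffle also removes the nuisance correlations
  expect_lt(abs(marg_cor(nu_sh)), abs(marg_cor(sh)))
})

test_that("sessions are filtered by performance with slope-reliability flags", {
  sessions <- data.frame(session = 1:5,
                         subject = c("m1", "m1", "m1", "m2", "m2"),
                         performance = c(0.69, 0.7, 0.8, 0.76, 0.74),
                         alpha = runif(5),
                         r_squared = c(0.2, -0.1, 0.5, 0.0, 0.3))
  out <- session_filter(sessions, 0.7)
  expect_equal(out$session, c(3, 4, 5))          # 0.69 and boundary 0.70 dropped
  expect_equal(out$unreliable_slope, c(FALSE, TRUE, FALSE))
  out2 <- session_filter(sessions, c(m1 = 0.7, m2 = 0.75))
  expect_equal(out2$session, c(3, 4))
  all_in <- session_filter(data.frame(performance = c(0.9, 0.95)), 0.7)
  expect_equal(nrow(all_in), 2)
  expect_error(session_filter(data.frame(performance = 1.2), 0.5), "0, 1")
})
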