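# Shared fixtures, built in code.

# Abstract Gaussian feature model: trials of R ~ N(F0 + F_prime * (s - s0),
# Gamma) at two stimulus values s0 +/- ds/2, wrapped as a trial_table whose
# "responses" are the features themselves (degree-1 polynomial_features is
# then the identity basis).
gaussian_feature_table <- function(F_prime, Gamma, n, ds = 0.2, s0 = 0,
                                   seed = NULL) {
  d <- length(F_prime)
  nlcc:::with_seed(seed, {
    s <- rep(s0 + c(-ds / 2, ds / 2), each = n / 2)
    R <- nlcc:::rmvn(n, rep(0, d), Gamma) + outer(s - s0, F_prime)
    trial_table(s = s, r = R)
  })
}

# Fine-task analysis of a linear decoder on an abstract feature table:
# measured conditional choice correlations (sign-aligned), optimal
# predictions, and the decoder's estimator-based behavioral d'.
fine_cc_analysis <- function(table, decoder_kind = "optimal",
                             flip_fraction = 0.4, seed = NULL) {
  fs <- polynomial_features(table, 1)
  sm <- signal_noise_summary(fs, table, "fine")
  dec <- if (decoder_kind == "optimal") fit_optimal_decoder(sm)
         else make_suboptimal_decoder(sm, decoder_kind, flip_fraction, seed)
  shat <- predict(dec, fs)
  measured <- choice_correlation_fine(fs, shat, table) * sign(sm$F_prime)
  d_behav <- sm$ds / sqrt(estimator_variance(shat, table$s))
  predicted <- suppressWarnings(predict_optimal_cc(sm, d_behav))
  list(measured = measured, predicted = predicted, sm = sm, dec = dec,
       shat = shat)
}

# Per-degree correlation between aligned measured and information-based
# predicted choice correlations of a cc_test fit (splitting degree-2 terms
# into squares and cross products).
measured_predicted_cor <- function(fit) {
  st <- fit$stats
  ma <- st$measured * st$signal_sign
  is_cross <- st$degree == 2 &
    vapply(strsplit(sub("^q_", "", st$term), "_"),
           function(p) p[1] != p[2], TRUE)
  sel <- list(linear = st$degree == 1,
              square = st$degree == 2 & !is_cross,
              cross = is_cross)
  vapply(sel, function(i) stats::cor(ma[i], st$predicted_info[i]), 0)
}
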