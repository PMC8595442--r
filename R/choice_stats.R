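# Measured and predicted choice correlations: the fine-task conditional
# correlation, the coarse-task NACCC, discriminabilities via the total
# correlation, the optimality prediction C_opt = d'_k / d', and the
# closed-form identities connecting them.

#' Fine-task choice correlation per statistic
#'
#' For each feature `R_k`, the Pearson correlation `Corr(R_k, shat | s)`
#' between the statistic and the (continuous) estimate at fixed stimulus,
#' combined across stimulus conditions by a df-weighted average. For a linear
#' readout `shat = w . R + c` of Gaussian features this equals the closed
#' form `(Gamma w)_k / sqrt(Gamma_kk w' Gamma w)` ([cc_closed_form()]).
#'
#' @param features a `feature_set`.
#' @param choices per-trial estimates `shat`.
#' @param table the originating [trial_table()] (supplies the conditioning
#'   stimulus).
#' @param min_trials smallest usable condition (default 2).
#' @return Named numeric vector of per-term correlations.
#' @export
choice_correlation_fine <- function(features, choices, table, min_trials = 2) {
  R <- features$values
  if (length(choices) != nrow(R)) stop("`choices` must have one value per trial")
  groups <- split(seq_len(nrow(R)), table$s)
  groups <- groups[vapply(groups, length, 0L) >= min_trials]
  if (!length(groups)) stop("no stimulus condition with >= 2 trials")
  acc <- rep(0, ncol(R)); wsum <- 0
  for (g in groups) {
    if (stats::sd(choices[g]) == 0) stop("zero-variance estimate within a condition")
    sds <- apply(R[g, , drop = FALSE], 2, stats::sd)
    if (any(sds == 0)) stop("zero-variance feature within a condition")
    cc <- drop(stats::cor(R[g, , drop = FALSE], choices[g]))
    w <- length(g) - 1
    acc <- acc + w * cc; wsum <- wsum + w
  }
  stats::setNames(acc / wsum, features$terms$term)
}

#' Closed-form choice correlation for a linear readout
#'
#' `C_k = (Gamma w)_k / sqrt(Gamma_kk * w' Gamma w)`: the choice correlation
#' implied by feature covariance `Gamma` and readout weights `w`, whose
#' denominator contains the estimator variance `sigma2 = w' Gamma w`.
#'
#' @param Gamma feature covariance (conditional on the stimulus).
#' @param w readout weight vector.
#' @return Vector of per-term correlations.
#' @export
cc_closed_form <- function(Gamma, w) {
  gw <- drop(Gamma %*% w)
  gw / sqrt(diag(Gamma) * sum(w * gw))
}

#' Normalized average conditional choice correlation (NACCC)
#'
#' The coarse-task analogue of the choice correlation: conditional
#' covariances and variances are computed within each stimulus category and
#' then averaged before normalizing,
#' `B_k = <Cov(R_k, shat|s)>_s / sqrt(<Var(R_k|s)>_s <Var(shat|s)>_s)`.
#' This removes the stimulus-induced covariation between statistic and
#' choice, is bounded by 1 in absolute value, and converges to the fine
#' choice correlation as the conditional distributions across categories
#' coincide.
#'
#' @param features a `feature_set`.
#' @param choices per-trial estimates or binary choices.
#' @param table the originating [trial_table()].
#' @param weighting `"category"` (unweighted mean over categories, default)
#'   or `"trial"` (df-weighted).
#' @return Named numeric vector of per-term NACCC values.
#' @export
naccc <- function(features, choices, table, weighting = c("category", "trial")) {
  weighting <- match.arg(weighting)
  R <- features$values
  if (length(choices) != nrow(R)) stop("`choices` must have one value per trial")
  groups <- split(seq_len(nrow(R)), table$s)
  if (length(groups) < 2) stop("need two or more stimulus categories")
  if (any(vapply(groups, length, 0L) < 2)) stop("a category has fewer than 2 trials")
  wts <- if (weighting == "category") rep(1, length(groups))
         else vapply(groups, length, 0L) - 1
  wts <- wts / sum(wts)
  cov_k <- rep(0, ncol(R)); var_k <- rep(0, ncol(R)); var_c <- 0
  for (a in seq_along(groups)) {
    g <- groups[[a]]
    cov_k <- cov_k + wts[a] * drop(stats::cov(R[g, , drop = FALSE], choices[g]))
    var_k <- var_k + wts[a] * apply(R[g, , drop = FALSE], 2, stats::var)
    var_c <- var_c + wts[a] * stats::var(choices[g])
  }
  if (var_c == 0 || any(var_k == 0))
    stop("zero average conditional variance for the estimate or a feature")
  stats::setNames(cov_k / sqrt(var_k * var_c), features$terms$term)
}

#' Discriminability from the total correlation with a binary stimulus
#'
#' For binary discrimination, the separation `d'` of a (continuous) quantity
#' across the two categories follows from its total correlation
#' `D = Corr(x, s)` as `d' = 2 D / sqrt(1 - D^2)` (equivalently
#' `2 / sqrt(D^-2 - 1)`, with the sign of `D`); near zero, `d' ~ 2D`.
#'
#' @param x per-trial scalar (a feature or a continuous choice), or a matrix
#'   of such columns, or - when `s` is omitted - the correlation(s) `D`
#'   directly.
#' @param s per-trial binary category labels.
#' @return Signed discriminability (vector if `x` has columns). `|D| = 1` is
#'   flagged with a warning and returns `Inf` of the matching sign.
#' @export
dprime_from_total_correlation <- function(x, s = NULL) {
  if (!is.null(s) && length(unique(s)) != 2) stop("`s` must be binary")
  D <- if (is.null(s)) x else drop(stats::cor(as.matrix(x), s))
  out <- numeric(length(D))
  sat <- abs(D) >= 1
  if (any(sat)) {
    warning("|D| = 1: infinite discriminability flagged")
    out[sat] <- sign(D[sat]) * Inf
  }
  out[!sat] <- 2 * D[!sat] / sqrt(1 - D[!sat]^2)
  out
}

#' Predicted choice correlation under optimal decoding
#'
#' The central optimality prediction: when the brain decodes its nonlinear
#' statistics optimally, each statistic's choice correlation equals the ratio
#' of its discriminability to the behavioral discriminability,
#' `C_opt_k = d'_k / d'`. For binary (rather than continuous) choices the
#' prediction carries two order-1 correction factors: `zeta` scales the
#' prediction to the binarization-attenuated measured correlation, and
#' `delta` inflates the behavioral `d'` estimated from the binary total
#' correlation (see [cc_corrections()]); both default to 1 (continuous
#' choices). Predictions are nonnegative by construction; values above 1 are
#' flagged with a warning, not clipped.
#'
#' @param summary an `sn_summary`, or a numeric vector of per-term `d'_k`.
#' @param behavioral_dprime the behavioral discriminability `d'` (> 0).
#' @param zeta,delta binary-choice correction factors.
#' @return Named vector of predicted correlations.
#' @export
predict_optimal_cc <- function(summary, behavioral_dprime, zeta = 1, delta = 1) {
  if (behavioral_dprime <= 0) stop("`behavioral_dprime` must be positive")
  d_k <- if (inherits(summary, "sn_summary"))
    stats::setNames(summary$d_prime, summary$terms$term) else summary
  pred <- zeta * abs(d_k) / (delta * behavioral_dprime)
  if (any(pred > 1))
    warning(sum(pred > 1), " optimal prediction(s) exceed 1 (flagged, not clipped)")
  pred
}

#' Equivalent forms of the optimal choice-correlation prediction
#'
#' The optimal prediction can be written as a ratio of any one of four
#' measured quantities: discriminabilities `d'_k / d'`, thresholds
#' `theta / theta_k`, estimator variances `sqrt(sigma2 / sigma2_k)`, or
#' Fisher informations `sqrt(J_k / J)`. Exactly one pair may be supplied;
#' on exact inputs all four agree to machine precision.
#'
#' @param dprime `c(d'_k, d')`.
#' @param threshold `c(theta, theta_k)`.
#' @param variance `c(sigma2, sigma2_k)`.
#' @param fisher `c(J_k, J)`.
#' @return The predicted correlation.
#' @export
equivalent_ratios <- function(dprime = NULL, threshold = NULL,
                              variance = NULL, fisher = NULL) {
  given <- list(dprime = dprime, threshold = threshold,
                variance = variance, fisher = fisher)
  supplied <- !vapply(given, is.null, TRUE)
  if (sum(supplied) != 1)
    stop("supply exactly one of dprime, threshold, variance, fisher")
  x <- given[supplied][[1]]
  if (length(x) != 2) stop("supply a pair of values")
  switch(names(given)[supplied],
         dprime = x[1] / x[2],
         threshold = x[1] / x[2],
         variance = sqrt(x[1] / x[2]),
         fisher = sqrt(x[1] / x[2]))
}

#' Fisher information of a feature code
#'
#' The (nonlinear) Fisher information available from linear readout of the
#' statistics: `J = F'^T Gamma^-1 F'`. Under the information-limiting
#' decomposition `Gamma = Gamma_0 + epsilon F' F'^T` this obeys
#' `J = 1 / (1/J_inf + 1/J_0)` with `J_inf = 1/epsilon`.
#'
#' @param summary an `sn_summary`, or a numeric `F_prime` vector.
#' @param Gamma feature covariance (when `summary` is a plain vector).
#' @param ridge optional relative ridge; default 0 (singular `Gamma` errors).
#' @return Scalar `J >= 0`.
#' @export
fisher_information <- function(summary, Gamma = NULL, ridge = 0) {
  if (inherits(summary, "sn_summary")) {
    F_prime <- summary$F_prime; Gamma <- summary$Gamma
  } else F_prime <- summary
  if (ridge > 0) return(sum(F_prime * ridge_solve(Gamma, F_prime, ridge)))
  out <- try(solve(Gamma, F_prime), silent = TRUE)
  if (inherits(out, "try-error")) stop("singular feature covariance")
  sum(F_prime * out)
}

# complementary error function via the normal CDF
erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

# Probit regression of a binary choice on a continuous decision variable:
# recovers the decision threshold, the downstream-noise SD (1/slope), and
# the coefficient covariance for uncertainty propagation. The regressor is
# standardized internally for glm stability.
probit_threshold_fit <- function(u, choice) {
  y <- as.integer(choice > 0)
  sc <- stats::sd(u)
  if (sc == 0) stop("constant decision variable")
  fit <- suppressWarnings(
    stats::glm(y ~ I(u / sc), family = stats::binomial("probit"),
               control = stats::glm.control(maxit = 100)))
  b <- unname(stats::coef(fit)) / c(1, sc)
  if (!is.finite(b[2]) || b[2] <= 0)
    stop("threshold fit failed: choice does not increase with the readout")
  V <- unname(stats::vcov(fit)) / outer(c(1, sc), c(1, sc))
  list(threshold = -b[1] / b[2], noise_sd = 1 / b[2], coef = b, vcov = V)
}

#' Estimate the behavioral threshold and decision noise from choices
#'
#' Binomial regression of the binary choice on the squared orientation:
#' under the task model the subject chooses the wide category when
#' `phi_hat^2 + noise > theta^2`, so a probit fit of choice on `phi^2`
#' recovers `theta^2 = -intercept/slope` and the decision-noise SD
#' `1/slope`. A logit link is available; its scale is converted to the
#' equivalent Gaussian SD.
#'
#' @param phi per-trial orientations (task units).
#' @param choice per-trial choices in `{-1, +1}` (`+1` = wide).
#' @param link `"probit"` (default) or `"logit"`.
#' @return List with `theta`, `noise_sd` and the fitted model.
#' @export
estimate_threshold <- function(phi, choice, link = c("probit", "logit")) {
  link <- match.arg(link)
  y <- as.integer(choice > 0)
  x <- phi^2
  sc <- stats::sd(x)                    # standardize for glm stability
  if (sc == 0) stop("constant phi^2: cannot fit a threshold")
  fit <- suppressWarnings(
    stats::glm(y ~ I(x / sc), family = stats::binomial(link),
               control = stats::glm.control(maxit = 100)))
  b <- unname(stats::coef(fit)) / c(1, sc)
  if (!is.finite(b[2]) || b[2] <= 0)
    stop("threshold fit failed: choice does not increase with phi^2")
  theta2 <- -b[1] / b[2]
  noise_sd <- 1 / b[2]
  if (link == "logit") noise_sd <- noise_sd * sqrt(3) / pi  # logistic -> normal SD
  list(theta = sqrt(max(theta2, 0)), noise_sd = noise_sd, fit = fit)
}

#' Binary-choice correction factors for the optimality prediction
#'
#' Binarizing a continuous internal estimate attenuates choice correlations
#' and distorts the behavioral discriminability by order-1 factors. They are
#' computed here by trial-resampled Monte Carlo under an explicit subject
#' model: the subject's decision variable is the supplied continuous readout
#' `u` (normally the analyst's own optimal linear-in-features estimate) plus
#' zero-mean Gaussian downstream noise, thresholded to a choice. The noise SD
#' and threshold are estimated by probit regression of the observed choices
#' on `u`; simulated choices are then regenerated many times from the
#' session's own readout values.
#'
#' `zeta` is the NACCC the decision variable itself attains against its own
#' binarized choice - the attenuation that a perfectly decoded statistic
#' suffers, transferred multiplicatively to every other statistic. `delta`
#' converts the behavioral discriminability recovered from the binary total
#' correlation ([dprime_from_total_correlation()]) into the moment-based
#' discriminability of the continuous decision variable
#' (`|Delta mean| / sqrt(<Var|s>)`), so that the optimality prediction
#' compares like with like.
#'
#' @param u per-trial continuous decision-variable values.
#' @param choice observed binary choices in `{-1, +1}`.
#' @param s per-trial category labels (two levels).
#' @param n_rep Monte-Carlo replicates of the choice generation.
#' @param seed optional integer seed.
#' @return List with `zeta`, `delta`, `threshold`, `noise_sd`, and the
#'   model's implied fraction correct `pc_model`.
#' @export
cc_corrections <- function(u, choice, s, n_rep = 50, seed = NULL) {
  su <- sort(unique(s))
  if (length(su) != 2) stop("`s` must have exactly two categories")
  s01 <- ifelse(s == su[2], 1, -1)
  pf <- probit_threshold_fit(u, choice)
  threshold <- pf$threshold
  noise_sd <- pf$noise_sd
  idx_p <- s01 > 0; idx_m <- !idx_p
  d_mom <- function(x) abs(mean(x[idx_p]) - mean(x[idx_m])) /
    sqrt((stats::var(x[idx_p]) + stats::var(x[idx_m])) / 2)
  with_seed(seed, {
    zeta_r <- numeric(n_rep); delta_r <- numeric(n_rep); pc_r <- numeric(n_rep)
    for (b_i in seq_len(n_rep)) {
      ustar <- u + stats::rnorm(length(u), sd = noise_sd)
      ch <- ifelse(ustar > threshold, 1, -1)
      cov_b <- (stats::cov(ustar[idx_p], ch[idx_p]) +
                  stats::cov(ustar[idx_m], ch[idx_m])) / 2
      var_u <- (stats::var(ustar[idx_p]) + stats::var(ustar[idx_m])) / 2
      var_c <- (stats::var(ch[idx_p]) + stats::var(ch[idx_m])) / 2
      zeta_r[b_i] <- cov_b / sqrt(var_u * var_c)
      D_b <- stats::cor(ch, s01)
      delta_r[b_i] <- d_mom(ustar) / dprime_from_total_correlation(D_b)
      pc_r[b_i] <- mean(ch == s01)
    }
    list(zeta = mean(zeta_r), delta = mean(delta_r), threshold = threshold,
         noise_sd = noise_sd, pc_model = mean(pc_r))
  })
}
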