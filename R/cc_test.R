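#' Choice-correlation test of decoding efficiency
#'
#' The package's front-end analysis: from a table of trials (stimulus,
#' responses, behavioral choice, optionally a nuisance), compute for every
#' polynomial statistic of the responses its *measured* choice correlation
#' and its *predicted* correlation under optimal decoding (the ratio of the
#' statistic's discriminability to the behavioral discriminability), then
#' estimate the decoding-efficiency slope between the two with a bootstrap
#' interval. A slope of 1 is the signature of optimal decoding; a slope
#' `alpha < 1` means a fraction `1 - alpha` of the behavioral estimator
#' variance arises downstream of the recorded responses.
#'
#' In `task = "coarse"` mode (two stimulus categories, e.g. the
#' variance-discrimination task) the measured statistic is the NACCC and
#' discriminabilities come from total correlations; nonlinear statistics are
#' computed from responses residualized against the optimal linear estimate
#' (`delta_r`), so squares and cross products carry only genuinely nonlinear
#' information. For binary choices the optimal prediction is adjusted by the
#' order-1 factors `zeta` and `delta` ([cc_corrections()]), by default
#' calibrated under the task's Gaussian model with the threshold and decision
#' noise estimated from the choices ([estimate_threshold()]).
#'
#' In `task = "fine"` mode (continuous estimates near a reference) the
#' measured statistic is the conditional Pearson correlation and
#' discriminabilities come from the signal/noise summary.
#'
#' @param table a [trial_table()] with responses, stimulus and choices.
#' @param degree highest polynomial degree of the tested statistics (1-3).
#' @param task `"coarse"` or `"fine"`.
#' @param choice per-trial choices; defaults to `table$choice`.
#' @param residualize remove the linearly decodable component before forming
#'   nonlinear statistics (coarse default `TRUE`)?
#' @param corrections `"calibrate"` (trial-resampled Monte Carlo under the
#'   thresholded-readout subject model, binary coarse choices only;
#'   [cc_corrections()]), `"constant"` (use `zeta`, `delta` as given) or
#'   `"none"`.
#' @param zeta,delta constants used when `corrections = "constant"`.
#' @param weighting category averaging for the NACCC ([naccc()]).
#' @param dprime_method per-term discriminability convention: `"moment"`
#'   (`|DeltaF_k| / sqrt(Gamma_bar_kk)`, exact for the optimal-readout
#'   identity) or `"total-correlation"` (via [dprime_from_total_correlation()]
#'   on `Corr(R_k, s)`; coincides with `"moment"` for Gaussian statistics).
#' @param n_boot bootstrap resamples for the efficiency slope.
#' @param n_shuffles if positive, shuffle-null p-values are attached
#'   ([shuffle_null_pvalues()], 100 is customary).
#' @param ridge ridge for the linear-decoder fits.
#' @param n_rep Monte-Carlo replicates for correction calibration.
#' @param seed optional integer seed (bootstrap, shuffles, calibration).
#' @return An object of class `cc_test`; see [summary.cc_test()]. Components
#'   include `stats` (per-term table), `alpha` (an `efficiency_report`),
#'   `per_degree` (slopes by term degree), `behavioral` (discriminability and
#'   corrections).
#' @examples
#' spec <- variance_task(n_trials = 1500, n_neurons = 6, seed = 1)
#' tt <- generate_session(spec, seed = 2)
#' fit <- cc_test(tt, seed = 3)
#' fit
#' @export
cc_test <- function(table, degree = 2, task = c("coarse", "fine"),
                    choice = NULL, residualize = (task == "coarse"),
                    corrections = c("calibrate", "constant", "none"),
                    zeta = 1, delta = 1.2,
                    weighting = c("category", "trial"),
                    dprime_method = c("moment", "total-correlation"),
                    n_boot = 100, n_shuffles = 0, ridge = 1e-6,
                    n_rep = 50, seed = NULL) {
  task <- match.arg(task)
  corrections <- match.arg(corrections)
  weighting <- match.arg(weighting)
  dprime_method <- match.arg(dprime_method)
  force(residualize)
  choice <- choice %||% table$choice
  if (is.null(choice)) stop("no choices: supply `choice` or a table with choices")
  binary_choice <- length(unique(choice)) == 2

  # feature construction: linear terms from raw responses; higher terms from
  # residualized responses when requested
  fs_lin <- polynomial_features(table, 1)
  fs <- fs_lin
  if (degree >= 2) {
    tab_nl <- table
    if (residualize) {
      sm1 <- signal_noise_summary(fs_lin, table,
                                  if (task == "coarse") "coarse" else "fine")
      shat1 <- predict(fit_optimal_decoder(sm1, ridge), fs_lin)
      tab_nl <- residualize(table, shat1)
    }
    fs_nl <- polynomial_features(tab_nl, degree)
    keep <- fs_nl$terms$degree >= 2
    fs <- cbind_features(fs_lin,
                         feature_set(fs_nl$values[, keep, drop = FALSE],
                                     fs_nl$terms[keep, , drop = FALSE]))
  }

  calibrated <- FALSE
  if (task == "coarse") {
    su <- sort(unique(table$s))
    if (length(su) != 2) stop("coarse task needs exactly two stimulus categories")
    s01 <- ifelse(table$s == su[2], 1, -1)
    measured <- naccc(fs, choice, table, weighting)
    sm_full <- signal_noise_summary(fs, table, "coarse")
    d_k <- sm_full$d_prime
    if (dprime_method == "total-correlation")
      d_k <- abs(dprime_from_total_correlation(drop(stats::cor(fs$values, s01))))
    D_s <- stats::cor(choice, s01)
    d_behav_raw <- abs(dprime_from_total_correlation(D_s))
    corr <- list(zeta = 1, delta = 1, method = "none")
    if (binary_choice && corrections == "calibrate") {
      calibrated <- TRUE
      # plug-in estimate of the subject's decision variable: optimal readout
      # of the raw polynomial statistics (same basis a matched subject uses)
      fs_raw <- polynomial_features(table, degree)
      u_hat <- predict(fit_optimal_decoder(
        signal_noise_summary(fs_raw, table, "coarse"), ridge), fs_raw)
      cal <- calibrated_predictions(fs, table, u_hat, choice, s01,
                                    n_rep = n_rep, seed = child_seed(seed, 7))
      predicted <- cal$predicted
      corr <- list(zeta = cal$zeta, delta = cal$delta, method = "calibrate",
                   threshold = cal$threshold, noise_sd = cal$noise_sd)
      measured_aligned <- measured
    } else if (corrections == "constant") {
      corr <- list(zeta = zeta, delta = delta, method = "constant")
    }
    if (!calibrated) {
      if (!binary_choice) {
        # continuous estimates: moment-based behavioral discriminability on
        # the same footing as the per-term d'
        d_behav_raw <- abs(diff(vapply(split(choice, s01), mean, 0))) /
          sqrt(mean(vapply(split(choice, s01), stats::var, 0)))
      }
      predicted <- suppressWarnings(
        predict_optimal_cc(stats::setNames(d_k, fs$terms$term), d_behav_raw,
                           zeta = corr$zeta, delta = corr$delta))
      # compare magnitudes along each statistic's informative direction
      measured_aligned <- measured * sign(sm_full$F_prime)
    }
  } else {
    sm <- signal_noise_summary(fs, table, "fine")
    measured <- choice_correlation_fine(fs, choice, table)
    d_k <- sm$d_prime
    fit_b <- stats::lm(choice ~ table$s)
    slope_b <- abs(stats::coef(fit_b)[2])
    sd_b <- sqrt(mean(vapply(split(choice, table$s), stats::var, 0)))
    if (slope_b == 0 || sd_b == 0) stop("choices carry no stimulus signal")
    d_behav_raw <- slope_b * sm$ds / sd_b
    corr <- list(zeta = 1, delta = 1, method = "none")
    predicted <- suppressWarnings(
      predict_optimal_cc(stats::setNames(d_k, fs$terms$term), d_behav_raw))
    measured_aligned <- measured * sign(sm$F_prime)
  }

  rep_all <- efficiency_slope(predicted, measured_aligned, n_boot = n_boot,
                              seed = child_seed(seed, 11))
  if (calibrated)
    rep_all <- widen_by_calibration(rep_all, cal, measured_aligned)
  per_degree <- lapply(split(seq_along(predicted), fs$terms$degree), function(idx) {
    if (length(idx) < 3) return(NULL)
    r <- efficiency_slope(predicted[idx], measured_aligned[idx], n_boot = n_boot,
                          seed = child_seed(seed, 13))
    if (calibrated)
      r <- widen_by_calibration(r, cal, measured_aligned, idx)
    r
  })
  per_degree <- per_degree[!vapply(per_degree, is.null, TRUE)]

  sig_sign <- if (task == "coarse") sign(sm_full$F_prime) else sign(sm$F_prime)
  stats_df <- data.frame(term = fs$terms$term, degree = fs$terms$degree,
                         d_prime = unname(d_k), signal_sign = unname(sig_sign),
                         measured = unname(measured),
                         measured_aligned = unname(measured_aligned),
                         predicted = unname(predicted))
  # information-based prediction zeta * d'_k / (delta * d'): independent of
  # the trial-coupled calibration, the right object for measured-vs-predicted
  # correlation reports (identical to `predicted` in non-calibrated paths)
  stats_df$predicted_info <-
    if (calibrated) corr$zeta * unname(d_k) / (corr$delta * d_behav_raw)
    else unname(predicted)
  if (n_shuffles > 0) {
    pm <- shuffle_null_pvalues(fs, table, "choice", n_shuffles, choices = choice,
                               seed = child_seed(seed, 17))
    pp <- shuffle_null_pvalues(fs, table, "stimulus", n_shuffles, choices = choice,
                               seed = child_seed(seed, 19))
    stats_df$p_measured <- unname(pm$p)
    stats_df$p_predicted <- unname(pp$p)
  }

  structure(list(stats = stats_df, alpha = rep_all, per_degree = per_degree,
                 behavioral = list(d_prime = d_behav_raw * corr$delta,
                                   d_prime_raw = d_behav_raw,
                                   corrections = corr),
                 task = task, degree = degree, binary_choice = binary_choice,
                 n_trials = nrow(table), n_neurons = n_neurons(table),
                 call = match.call()),
            class = "cc_test")
}

# NACCC of every feature column against every choice column, given binary
# category labels: vectorized core used by the calibration machinery.
# Returns list(B = K x J matrix, var_ch = per-choice average conditional
# variance, cov_uc = average conditional covariance of `u` with each choice
# column when `u` is supplied).
naccc_mat <- function(R, CH, s01, u = NULL) {
  CH <- as.matrix(CH)
  K <- ncol(R); J <- ncol(CH)
  cov_rc <- matrix(0, K, J); var_r <- rep(0, K); var_c <- rep(0, J)
  cov_uc <- if (!is.null(u)) rep(0, J)
  var_u <- 0
  for (sgn in c(-1, 1)) {
    g <- which(s01 == sgn)
    n_g <- length(g)
    Rc <- sweep(R[g, , drop = FALSE], 2, colMeans(R[g, , drop = FALSE]))
    Cc <- sweep(CH[g, , drop = FALSE], 2, colMeans(CH[g, , drop = FALSE]))
    cov_rc <- cov_rc + crossprod(Rc, Cc) / (n_g - 1) / 2
    var_r <- var_r + colSums(Rc^2) / (n_g - 1) / 2
    var_c <- var_c + colSums(Cc^2) / (n_g - 1) / 2
    if (!is.null(u)) {
      uc <- u[g] - mean(u[g])
      cov_uc <- cov_uc + drop(crossprod(uc, Cc)) / (n_g - 1) / 2
      var_u <- var_u + sum(uc^2) / (n_g - 1) / 2
    }
  }
  B <- cov_rc / outer(sqrt(var_r), sqrt(var_c))
  list(B = B, var_c = var_c, cov_uc = cov_uc, var_u = var_u)
}

# One calibrated-analysis pass on a trial subset: probit fit of the observed
# choices on the readout, model choices regenerated n_rep times, and the
# model-implied per-term predicted NACCC
#   pred_k = <B_model_k> * (sigma2_u + noise^2)/sigma2_u * d'(model)/d'(data),
# which is the optimality prediction d'_k/d' corrected for binarization with
# all distribution-shape effects handled by trial resampling.
calibration_pass <- function(R, u_hat, choice, s01, n_rep) {
  pf <- probit_threshold_fit(u_hat, choice)
  idx_p <- s01 > 0
  s2u_hat <- (stats::var(u_hat[idx_p]) + stats::var(u_hat[!idx_p])) / 2
  d20_data <- abs(dprime_from_total_correlation(stats::cor(choice, s01)))
  n <- length(u_hat)
  USTAR <- u_hat + matrix(stats::rnorm(n * n_rep, sd = pf$noise_sd), n, n_rep)
  CH <- ifelse(USTAR > pf$threshold, 1, -1)
  ok <- apply(CH, 2, function(ch)
    stats::var(ch[idx_p]) > 0 && stats::var(ch[!idx_p]) > 0)
  if (!any(ok)) stop("degenerate model choices in calibration")
  CH <- CH[, ok, drop = FALSE]; USTAR <- USTAR[, ok, drop = FALSE]
  nm <- naccc_mat(R, CH, s01)
  D20 <- abs(dprime_from_total_correlation(drop(stats::cor(CH, s01))))
  B_model <- rowMeans(nm$B)
  d20_model <- mean(D20)
  g <- (1 + pf$noise_sd^2 / s2u_hat) * d20_model / d20_data
  # reported binarization factors: zeta for the perfectly decoded statistic,
  # delta mapping binary-total-correlation d' to the moment d' of the model
  # decision variable
  zeta <- delta <- NA_real_
  var_us <- (apply(USTAR, 2, function(x) stats::var(x[idx_p])) +
               apply(USTAR, 2, function(x) stats::var(x[!idx_p]))) / 2
  cov_us <- vapply(seq_len(ncol(CH)), function(j) {
    (stats::cov(USTAR[idx_p, j], CH[idx_p, j]) +
       stats::cov(USTAR[!idx_p, j], CH[!idx_p, j])) / 2
  }, 0)
  var_cs <- nm$var_c
  zeta <- mean(cov_us / sqrt(var_us * var_cs))
  dmom <- vapply(seq_len(ncol(USTAR)), function(j) {
    x <- USTAR[, j]
    abs(mean(x[idx_p]) - mean(x[!idx_p])) / sqrt(var_us[j])
  }, 0)
  delta <- mean(dmom / D20)
  list(predicted = B_model * g, threshold = pf$threshold,
       noise_sd = pf$noise_sd, zeta = zeta, delta = delta,
       alpha_model = s2u_hat / (s2u_hat + pf$noise_sd^2))
}

# Model-implied predictions for binary coarse choices plus a nonparametric
# trial bootstrap of the whole calibrated analysis (resample trials, refit
# the probit, regenerate model choices, recompute measured and predicted
# NACCCs), whose slope spread estimates the estimator's sampling
# variability with all couplings intact.
calibrated_predictions <- function(fs, table, u_hat, choice, s01,
                                   n_rep = 30, n_param = 30, seed = NULL) {
  R <- fs$values
  with_seed(seed, {
    point <- calibration_pass(R, u_hat, choice, s01, n_rep)
    pred_boot <- matrix(NA_real_, ncol(R), n_param)
    meas_boot <- matrix(NA_real_, ncol(R), n_param)
    for (j in seq_len(n_param)) {
      idx_t <- sample.int(nrow(R), replace = TRUE)
      s01_t <- s01[idx_t]
      if (length(unique(s01_t)) < 2) next
      pj <- try(calibration_pass(R[idx_t, , drop = FALSE], u_hat[idx_t],
                                 choice[idx_t], s01_t, max(10, n_rep %/% 3)),
                silent = TRUE)
      if (inherits(pj, "try-error")) next
      pred_boot[, j] <- pj$predicted
      meas_boot[, j] <- drop(naccc_mat(R[idx_t, , drop = FALSE],
                                       choice[idx_t], s01_t)$B)
    }
    list(predicted = stats::setNames(point$predicted, fs$terms$term),
         zeta = point$zeta, delta = point$delta,
         threshold = point$threshold, noise_sd = point$noise_sd,
         alpha_model = point$alpha_model,
         pred_boot = pred_boot, meas_boot = meas_boot)
  })
}

# Replace the term-bootstrap interval with one from the trial bootstrap of
# the calibrated analysis (t quantiles at the bootstrap's degrees of
# freedom, with a numerical floor: a noiseless in-sample subject reproduces
# its own choices exactly and would otherwise yield a zero-width interval).
widen_by_calibration <- function(report, cal, measured, idx = NULL) {
  idx <- idx %||% seq_along(measured)
  slopes_cal <- vapply(seq_len(ncol(cal$pred_boot)), function(j) {
    p <- cal$pred_boot[idx, j]; m <- cal$meas_boot[idx, j]
    if (anyNA(p) || anyNA(m)) return(NA_real_)
    pa_slope(p, m)
  }, 0)
  n_eff <- sum(is.finite(slopes_cal))
  se <- max(stats::sd(slopes_cal[is.finite(slopes_cal)]), 1e-6)
  z <- stats::qt(1 - (1 - report$level) / 2, df = max(3, n_eff - 1))
  report$ci <- c(report$alpha - z * se, report$alpha + z * se)
  report$se <- se
  report$boot_calibration <- slopes_cal
  report
}

#' @export
print.cc_test <- function(x, ...) {
  cat(sprintf("Choice-correlation optimality test (%s task, %d trials, %d neurons)\n",
              x$task, x$n_trials, x$n_neurons))
  cat(sprintf("  %d statistics up to degree %d\n", nrow(x$stats), x$degree))
  print(x$alpha)
  invisible(x)
}

#' Summarize a choice-correlation test
#'
#' @param object a `cc_test`.
#' @param ... unused.
#' @return The object, invisibly; prints the per-degree efficiency slopes,
#'   the behavioral discriminability, corrections used, and the most
#'   informative terms.
#' @export
summary.cc_test <- function(object, ...) {
  print(object)
  co <- object$behavioral$corrections
  cat(sprintf("  behavioral d' = %.3f (raw %.3f; corrections: %s, zeta = %.3f, delta = %.3f)\n",
              object$behavioral$d_prime, object$behavioral$d_prime_raw,
              co$method, co$zeta, co$delta))
  for (nm in names(object$per_degree)) {
    r <- object$per_degree[[nm]]
    cat(sprintf("  degree %s: alpha = %.3f [%.3f, %.3f] (%d terms)\n",
                nm, r$alpha, r$ci[1], r$ci[2], r$n_terms))
  }
  top <- object$stats[order(-object$stats$d_prime), ][seq_len(min(5, nrow(object$stats))), ]
  cat("  most informative statistics:\n")
  print(top[, c("term", "degree", "d_prime", "measured", "predicted")],
        row.names = FALSE, digits = 3)
  invisible(object)
}

#' @export
coef.cc_test <- function(object, ...) {
  out <- c(alpha = object$alpha$alpha)
  for (nm in names(object$per_degree))
    out[paste0("alpha_degree", nm)] <- object$per_degree[[nm]]$alpha
  out
}

#' @export
residuals.cc_test <- function(object, ...) {
  stats::setNames(object$stats$measured_aligned -
                    object$alpha$alpha * object$stats$predicted,
                  object$stats$term)
}

#' Plot measured against predicted choice correlations
#'
#' The diagnostic scatter of the optimality test: terms colored by degree,
#' the identity line (optimal decoding) dashed, the fitted principal-axis
#' slope solid.
#'
#' @param x a `cc_test`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cc_test <- function(x, ...) {
  st <- x$stats
  cols <- c("#1f77b4", "#2ca02c", "#d62728")[st$degree]
  lim <- range(0, st$predicted, st$measured_aligned)
  graphics::plot(st$predicted, st$measured_aligned, col = cols, pch = 19,
                 xlab = "predicted optimal choice correlation",
                 ylab = "measured choice correlation", xlim = lim, ylim = lim, ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  graphics::abline(0, x$alpha$alpha, lwd = 2)
  graphics::legend("topleft", bty = "n",
                   legend = c(paste("degree", sort(unique(st$degree))),
                              sprintf("alpha = %.2f", x$alpha$alpha)),
                   col = c(c("#1f77b4", "#2ca02c", "#d62728")[sort(unique(st$degree))], "black"),
                   pch = c(rep(19, length(unique(st$degree))), NA),
                   lty = c(rep(NA, length(unique(st$degree))), 1))
  invisible(x)
}
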