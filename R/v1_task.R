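# Coarse 2AFC orientation-variance discrimination: ideal-observer analytics
# and a synthetic V1-like session generator. The task stimulus is the
# variance s of a zero-mean orientation distribution: each trial draws a
# category (wide/narrow), a standard-normal nuisance nu, and presents the
# orientation phi = sqrt(s) * nu. The subject estimates phi from its neurons,
# squares it, and thresholds.

#' Optimal orientation threshold for variance discrimination
#'
#' The ideal observer classifies by comparing `phi^2` with `theta_opt^2`,
#' placed where the two zero-mean Gaussian orientation densities cross:
#' `theta_opt^2 = (log s_plus - log s_minus) / (1/s_minus - 1/s_plus)`.
#'
#' @param s_plus,s_minus category variances, `s_plus > s_minus > 0`
#'   (task units^2, e.g. deg^2).
#' @return Positive threshold `theta_opt` (task units).
#' @examples
#' optimal_threshold(225, 9)   # sigma = 15 vs 3 degrees -> ~5.49 deg
#' @export
optimal_threshold <- function(s_plus, s_minus) {
  if (!(s_plus > s_minus && s_minus > 0)) stop("need s_plus > s_minus > 0")
  sqrt((log(s_plus) - log(s_minus)) / (1 / s_minus - 1 / s_plus))
}

#' Ideal-observer fraction correct for variance discrimination
#'
#' With equiprobable categories and the optimal threshold, the probability of
#' a correct classification is
#' `1/2 * (erfc(theta/sqrt(2 s_plus)) + 1 - erfc(theta/sqrt(2 s_minus)))`.
#'
#' @inheritParams optimal_threshold
#' @return Probability in `(0.5, 1)`.
#' @examples
#' ideal_fraction_correct(225, 9)  # ~0.82
#' @export
ideal_fraction_correct <- function(s_plus, s_minus) {
  if (s_plus == s_minus) return(0.5)
  th <- optimal_threshold(s_plus, s_minus)
  0.5 * (erfc(th / sqrt(2 * s_plus)) + 1 - erfc(th / sqrt(2 * s_minus)))
}

#' Specification of a synthetic variance-discrimination session
#'
#' Defines the task (category SDs), the recorded population (orientation
#' tuning curves with period 180 degrees, randomized per neuron within
#' stated ranges), the noise model, and the synthetic subject. Three subject
#' models are available:
#' \describe{
#'   \item{`"regression"` (default)}{the subject's decision variable is the
#'     optimal linear readout of its own linear + quadratic response
#'     statistics (fit on the session itself), thresholded at the category
#'     midpoint. This is the decoder that is optimal in the
#'     estimator-variance sense measured by the efficiency slope, so a
#'     degraded subject's planted `alpha` (additive decision noise of
#'     variance `sigma2_u * (1/alpha - 1)`) is recoverable by [cc_test()].}
#'   \item{`"ideal-rule"`}{the subject squares its locally optimal linear
#'     orientation estimate `phihat` and thresholds at `theta_opt` - the
#'     accuracy-maximizing likelihood rule. Its binary choices are
#'     near-optimal, but its continuous decision variable is dominated by
#'     the wide category's tail, so planted inefficiencies are recovered
#'     only approximately.}
#'   \item{`"direct"`}{the subject thresholds the true orientation
#'     (a noiseless `phihat`), reproducing ideal-observer performance
#'     ([ideal_fraction_correct()]).}
#' }
#'
#' Tuning curves are von Mises in the doubled angle:
#' `f(phi) = baseline + gain * exp(kappa * (cos(2(phi - pref)) - 1))`.
#' Optionally a zero-mean shared Gaussian perturbation of SD
#' `shared_noise_sd` (in spike-count units) is added to all neurons on each
#' trial, creating internal noise correlations on top of the nuisance
#' correlations that the task itself induces.
#'
#' @param sigma_wide,sigma_narrow orientation SDs of the two categories
#'   (degrees); defaults 15 and 3.
#' @param n_trials trials per session.
#' @param n_neurons population size.
#' @param noise_model `"poisson"` spike counts or `"gaussian"`
#'   (variance = mean).
#' @param alpha target decoding efficiency of the subject in `(0, 1]`;
#'   1 = no added noise.
#' @param subject `"regression"`, `"ideal-rule"` or `"direct"` (see above).
#' @param shared_noise_sd SD of the shared (correlated) internal noise.
#' @param gain_range,baseline_range,kappa_range per-neuron tuning parameter
#'   ranges (uniform draws).
#' @param tuning optional data.frame (`pref`, `kappa`, `gain`, `baseline`)
#'   overriding the random draw.
#' @param seed integer seed for the tuning-parameter draw (so a spec is a
#'   reproducible population).
#' @return An object of class `variance_task`.
#' @export
variance_task <- function(sigma_wide = 15, sigma_narrow = 3,
                          n_trials = 4000, n_neurons = 12,
                          noise_model = c("poisson", "gaussian"),
                          alpha = 1,
                          subject = c("regression", "ideal-rule", "direct"),
                          shared_noise_sd = 0,
                          gain_range = c(10, 30), baseline_range = c(2, 6),
                          kappa_range = c(1, 3), tuning = NULL, seed = NULL) {
  noise_model <- match.arg(noise_model)
  subject <- match.arg(subject)
  if (!(sigma_wide > sigma_narrow && sigma_narrow > 0))
    stop("need sigma_wide > sigma_narrow > 0")
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]")
  tuning <- tuning %||% with_seed(seed, data.frame(
    pref = stats::runif(n_neurons, 0, 180),
    kappa = stats::runif(n_neurons, kappa_range[1], kappa_range[2]),
    gain = stats::runif(n_neurons, gain_range[1], gain_range[2]),
    baseline = stats::runif(n_neurons, baseline_range[1], baseline_range[2])))
  if (any(tuning$gain < 0)) stop("gains must be nonnegative")
  structure(list(sigma_wide = sigma_wide, sigma_narrow = sigma_narrow,
                 s_plus = sigma_wide^2, s_minus = sigma_narrow^2,
                 n_trials = n_trials, n_neurons = nrow(tuning),
                 noise_model = noise_model, alpha = alpha,
                 subject = subject, shared_noise_sd = shared_noise_sd,
                 tuning = tuning),
            class = c("variance_task", "encoding_model"))
}

# Mean firing (counts/window) at orientation phi (degrees) for every neuron.
tuning_rates <- function(spec, phi) {
  ang <- outer(phi, spec$tuning$pref, function(p, q) 2 * (p - q) * pi / 180)
  sweep(sweep(exp(sweep(cos(ang) - 1, 2, spec$tuning$kappa, "*")),
              2, spec$tuning$gain, "*"),
        2, spec$tuning$baseline, "+")
}

#' @export
sample_responses.variance_task <- function(model, s, nu = NULL, ...) {
  # here `nu` is the presented orientation phi in degrees
  if (is.null(nu)) nu <- sqrt(s) * stats::rnorm(length(s))
  f <- tuning_rates(model, nu)
  r <- if (model$noise_model == "poisson")
    matrix(stats::rpois(length(f), f), nrow(f), ncol(f))
  else f + matrix(stats::rnorm(length(f), sd = sqrt(pmax(f, 1e-9))),
                  nrow(f), ncol(f))
  if (model$shared_noise_sd > 0)
    r <- r + stats::rnorm(nrow(f), sd = model$shared_noise_sd)
  r
}

# Locally optimal linear orientation readout at phi = 0: w ~ C^-1 f'(0),
# scaled to unit gain, where C is the response covariance at phi ~ 0.
phi_readout <- function(spec) {
  d <- 1e-3
  f0 <- drop(tuning_rates(spec, 0))
  fp <- (drop(tuning_rates(spec, d)) - drop(tuning_rates(spec, -d))) / (2 * d)
  C <- diag(pmax(f0, 1e-9))
  if (spec$shared_noise_sd > 0)
    C <- C + spec$shared_noise_sd^2 * matrix(1, spec$n_neurons, spec$n_neurons)
  w <- solve(C, fp)
  g <- sum(w * fp)
  if (g <= 0) stop("population carries no local orientation signal")
  list(w = w / g, f0 = f0)
}

#' Generate a synthetic variance-discrimination session
#'
#' Per trial: draw the category equiprobably, the nuisance `nu ~ N(0, 1)`,
#' the orientation `phi = sqrt(s) * nu`; draw spike counts from the tuning
#' curves at `phi` under the noise model; form the subject's continuous
#' decision variable according to the spec's `subject` model, add decision
#' noise calibrated to the planted efficiency (`alpha < 1`), and threshold
#' (ties go to the narrow category). The regression subject fits its readout
#' on the session's own trials: it is optimal with respect to the session's
#' empirical statistics, the same plug-in optimum the analysis estimates,
#' which is what makes planted inefficiencies exactly recoverable. The planted
#' ground truth (efficiency, threshold, noise variances, achieved fraction
#' correct) is attached as the `ground_truth` attribute for recovery
#' experiments.
#'
#' @param spec a [variance_task()].
#' @param seed optional integer seed.
#' @return A [trial_table()] with `s` in `{-1, +1}` (narrow/wide), `nu` the
#'   presented orientation in degrees, spike counts `r_*`, and the binary
#'   `choice`.
#' @export
generate_session <- function(spec, seed = NULL) {
  with_seed(seed, {
    n <- spec$n_trials
    draw <- function(n) {
      cat_lab <- sample(c(-1, 1), n, replace = TRUE)
      s_var <- ifelse(cat_lab > 0, spec$s_plus, spec$s_minus)
      phi <- sqrt(s_var) * stats::rnorm(n)
      list(cat = cat_lab, phi = phi, r = sample_responses(spec, s_var, phi))
    }
    ses <- draw(n)
    theta <- optimal_threshold(spec$s_plus, spec$s_minus)
    if (spec$subject == "regression") {
      tt_ses <- trial_table(s = ses$cat, r = ses$r)
      fs_raw <- polynomial_features(tt_ses, 2)
      dec <- fit_optimal_decoder(
        signal_noise_summary(fs_raw, tt_ses, "coarse"))
      u <- predict(dec, fs_raw)
      thr_u <- 0
    } else {
      phihat <- if (spec$subject == "direct") ses$phi else {
        ro <- phi_readout(spec)
        drop(sweep(ses$r, 2, ro$f0) %*% ro$w)
      }
      u <- phihat^2
      thr_u <- theta^2
    }
    # plant the efficiency: additive decision noise scaled to the average
    # within-category variance of the undegraded decision variable
    sigma2_u <- mean(c(stats::var(u[ses$cat > 0]), stats::var(u[ses$cat < 0])))
    v_eta <- if (spec$alpha < 1) sigma2_u * (1 / spec$alpha - 1) else 0
    if (v_eta > 0) u <- u + stats::rnorm(n, sd = sqrt(v_eta))
    choice <- ifelse(u > thr_u, 1, -1)
    tab <- trial_table(s = ses$cat, r = ses$r, nu = ses$phi, choice = choice)
    attr(tab, "encoder") <- spec
    attr(tab, "ground_truth") <- list(
      alpha = spec$alpha, subject = spec$subject, theta = theta,
      sigma2_u = sigma2_u, v_eta = v_eta,
      fraction_correct = mean(choice == ses$cat),
      ideal_fraction_correct = ideal_fraction_correct(spec$s_plus, spec$s_minus))
    tab
  })
}
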