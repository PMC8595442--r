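# Linear-in-features decoders: the locally optimal readout w ~ Gamma^-1 F',
# controlled suboptimal variants, and the application of a decoder to trials.

#' Fit the optimal linear-in-features decoder
#'
#' The minimum-variance unbiased linear readout of the statistics `R(r)` has
#' weights `w ~ Gamma^-1 F'` (fine estimation) or `w ~ Gamma_bar^-1 DeltaF`
#' (coarse discrimination, equivalent to linear regression of the category on
#' the features). The returned decoder is scaled to be locally unbiased
#' (`<shat|s> = s` to first order); in coarse mode the decision threshold sits
#' midway between the two category means of `w . R`.
#'
#' @param summary an [signal_noise_summary()] (its `mode` is inherited).
#' @param ridge relative ridge added to `Gamma` before inversion
#'   (`lambda = ridge * trace(Gamma)/dim`); the default `1e-6` only guards
#'   conditioning.
#' @return An object of class `nl_decoder` with elements `weights`, `offset`,
#'   `kind`, `threshold` (coarse), `terms`, `sigma2` (the predicted estimator
#'   variance `(F'^T Gamma^-1 F')^-1`).
#' @examples
#' tt <- simulate_quadratic_code(quadratic_code(), s_values = c(-0.1, 0.1),
#'                               n_trials = 2000, seed = 1)
#' fs <- polynomial_features(tt, 2)
#' sm <- signal_noise_summary(fs, tt, "fine")
#' dec <- fit_optimal_decoder(sm)
#' @export
fit_optimal_decoder <- function(summary, ridge = 1e-6) {
  w0 <- ridge_solve(summary$Gamma, summary$F_prime, ridge)
  slope <- sum(w0 * summary$F_prime)
  if (slope <= 0) stop("degenerate summary: no signal along the optimal weights")
  w <- w0 / slope                       # unit gain: d<shat>/ds = 1
  J <- slope                            # F'^T Gamma^-1 F' (up to the ridge)
  mid_R <- colMeans(summary$cond_means)
  mid_s <- mean(summary$s_values)
  offset <- mid_s - sum(w * mid_R)
  structure(list(weights = w, offset = offset, kind = "optimal",
                 mode = summary$mode, terms = summary$terms,
                 threshold = if (summary$mode == "coarse") mid_s else NULL,
                 sigma2 = 1 / J, J = J),
            class = "nl_decoder")
}

#' Construct controlled suboptimal decoders
#'
#' `"signal-aligned"` weights follow the signal direction while ignoring the
#' noise covariance (`w ~ F'`), i.e. a decoder blind to higher-order
#' correlations; `"sign-flipped"` additionally negates a random fraction of
#' those weights. Both are scaled to unit gain where possible so their
#' estimates live on the stimulus scale.
#'
#' @param summary an [signal_noise_summary()].
#' @param kind `"signal-aligned"` or `"sign-flipped"`.
#' @param flip_fraction fraction of weights negated (sign-flipped kind only).
#' @param seed optional integer seed for the flip pattern.
#' @return An `nl_decoder`.
#' @export
make_suboptimal_decoder <- function(summary, kind = c("signal-aligned", "sign-flipped"),
                                    flip_fraction = 0.4, seed = NULL) {
  kind <- match.arg(kind)
  if (flip_fraction < 0 || flip_fraction > 1)
    stop("`flip_fraction` must be in [0, 1]")
  w <- summary$F_prime
  if (kind == "sign-flipped" && flip_fraction > 0) {
    k <- length(w)
    n_flip <- round(flip_fraction * k)
    idx <- with_seed(seed, sample.int(k, n_flip))
    w[idx] <- -w[idx]
  }
  slope <- sum(w * summary$F_prime)
  if (slope > 0) w <- w / slope
  mid_R <- colMeans(summary$cond_means)
  mid_s <- mean(summary$s_values)
  structure(list(weights = w, offset = mid_s - sum(w * mid_R), kind = kind,
                 mode = summary$mode, terms = summary$terms,
                 threshold = if (summary$mode == "coarse") mid_s else NULL,
                 sigma2 = NULL, J = NULL),
            class = "nl_decoder")
}

#' @export
print.nl_decoder <- function(x, ...) {
  cat(sprintf("Linear-in-features decoder (%s, %s mode): %d terms\n",
              x$kind, x$mode, length(x$weights)))
  if (!is.null(x$sigma2))
    cat(sprintf("  predicted estimator variance: %.4g\n", x$sigma2))
  invisible(x)
}

#' @export
coef.nl_decoder <- function(object, ...) {
  stats::setNames(object$weights, object$terms$term)
}

#' Apply a decoder to a feature set
#'
#' @param decoder an `nl_decoder`.
#' @param features a `feature_set` whose terms match the decoder's.
#' @param type `"estimate"` for continuous `shat = w . R + c`, `"choice"` for
#'   the binary category `sign(shat - threshold)` (coarse decoders only).
#' @return Numeric vector of per-trial estimates or choices.
#' @export
decode <- function(decoder, features, type = c("estimate", "choice")) {
  predict(decoder, features, type = match.arg(type))
}

#' @export
#' @rdname decode
#' @param object an `nl_decoder`.
#' @param ... unused.
predict.nl_decoder <- function(object, features, type = c("estimate", "choice"), ...) {
  type <- match.arg(type)
  if (!identical(as.character(object$terms$term),
                 as.character(features$terms$term)))
    stop("feature terms do not match decoder terms")
  shat <- drop(features$values %*% object$weights) + object$offset
  if (type == "estimate") return(shat)
  if (is.null(object$threshold))
    stop("no decision threshold: fit the decoder in coarse mode for choices")
  ifelse(shat > object$threshold, 1, -1)
}

#' Binarize squared estimates at an orientation threshold
#'
#' The coarse variance task's classifier: choose the wide category (`+1`)
#' exactly when the squared orientation estimate exceeds the squared
#' threshold; ties go to the narrow category (`-1`), a probability-zero event
#' for continuous estimates.
#'
#' @param estimates per-trial orientation estimates `phihat` (task units).
#' @param threshold orientation threshold `theta` (finite).
#' @return Vector of choices in `{-1, +1}`.
#' @export
binary_threshold_choice <- function(estimates, threshold) {
  if (!is.finite(threshold)) stop("`threshold` must be finite")
  ifelse(estimates^2 > threshold^2, 1, -1)
}
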