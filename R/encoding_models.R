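# Encoding models: populations whose task information lives in nonlinear
# response statistics. Each model spec has a sample_responses() method that
# draws response vectors given per-trial stimulus (and nuisance) values using
# the current RNG stream; the simulate_* front ends handle trial bookkeeping
# and seeding and return a trial_table.

#' Simulate the XOR code
#'
#' Two binary neurons whose responses jointly, but not individually, determine
#' the stimulus: equal responses mean `s = -1`, opposite responses mean
#' `s = +1`, so the stimulus is recoverable only from the product statistic
#' (`shat = -r1 * r2`). `flip_prob` independently corrupts each response,
#' degrading the correlation that carries the signal.
#'
#' @param n_trials number of trials.
#' @param flip_prob probability, in `[0, 0.5)`, that each response is flipped.
#' @param seed optional integer seed.
#' @return A [trial_table()] with columns `r_1`, `r_2` in `{-1, +1}`.
#' @export
simulate_xor <- function(n_trials, flip_prob = 0, seed = NULL) {
  if (n_trials < 1) stop("`n_trials` must be positive")
  if (flip_prob < 0 || flip_prob >= 0.5) stop("`flip_prob` must be in [0, 0.5)")
  with_seed(seed, {
    s <- sample(c(-1, 1), n_trials, replace = TRUE)
    r1 <- sample(c(-1, 1), n_trials, replace = TRUE)
    # equal responses -> s = -1; opposite -> s = +1
    r2 <- ifelse(s == -1, r1, -r1)
    flip <- function(r) r * ifelse(stats::runif(n_trials) < flip_prob, -1, 1)
    trial_table(s = s, r = cbind(flip(r1), flip(r2)))
  })
}

#' Gabor-filter population specification
#'
#' A bank of `N` linear Gabor receptive fields (idealized V1 simple cells)
#' observing a rendered Gabor image whose orientation is the task stimulus and
#' whose spatial phase or contrast polarity is an unknown nuisance. Responses
#' are the receptive-field projections plus white Gaussian noise of variance
#' `noise_var`. Receptive fields are unit-energy on a square pixel grid.
#'
#' @param N neuron count.
#' @param image_size pixels per side of the square image grid (default 32).
#' @param sf spatial frequency, cycles per image width, for stimulus and
#'   receptive fields.
#' @param sigma Gaussian envelope width of image and receptive fields, as a
#'   fraction of the image half-width.
#' @param noise_var additive internal-noise variance per neuron (> 0).
#' @param pref_orientation per-neuron preferred orientations in `[0, pi)`;
#'   default equally spaced.
#' @param rf_phase per-neuron receptive-field phases; default equally spaced
#'   over `[0, 2*pi)`.
#' @return An object of class `gabor_population` holding the receptive-field
#'   matrix and rendering parameters.
#' @export
gabor_population <- function(N, image_size = 32, sf = 2, sigma = 0.4,
                             noise_var = 0.05,
                             pref_orientation = NULL, rf_phase = NULL) {
  if (N < 1) stop("`N` must be at least 1")
  if (noise_var <= 0) stop("`noise_var` must be positive")
  pref_orientation <- pref_orientation %||% (seq_len(N) - 1) * pi / N
  rf_phase <- rf_phase %||% ((seq_len(N) - 1) * 2 * pi / max(N, 2)) %% (2 * pi)
  ax <- seq(-1, 1, length.out = image_size)
  grid <- expand.grid(x = ax, y = ax)
  env <- exp(-(grid$x^2 + grid$y^2) / (2 * sigma^2))
  rf <- matrix(0, N, image_size^2)
  for (i in seq_len(N)) {
    k <- pi * sf * c(cos(pref_orientation[i]), sin(pref_orientation[i]))
    g <- env * cos(k[1] * grid$x + k[2] * grid$y + rf_phase[i])
    rf[i, ] <- g / sqrt(sum(g^2))
  }
  structure(list(N = N, image_size = image_size, sf = sf, sigma = sigma,
                 noise_var = noise_var, pref_orientation = pref_orientation,
                 rf_phase = rf_phase, rf = rf, grid = grid, env = env),
            class = c("gabor_population", "encoding_model"))
}

# Noise-free receptive-field projections for a grating image at orientation s
# (radians in [0, pi)) and phase nu. The image is env(x) * cos(k(s).x + nu),
# so the projection separates into cos(nu) and sin(nu) components that are
# precomputed per orientation.
gabor_projection <- function(spec, s, nu) {
  su <- sort(unique(s))
  Cmat <- matrix(0, length(su), spec$N)
  Smat <- matrix(0, length(su), spec$N)
  for (a in seq_along(su)) {
    k <- pi * spec$sf * c(cos(su[a]), sin(su[a]))
    phase_arg <- k[1] * spec$grid$x + k[2] * spec$grid$y
    Cmat[a, ] <- spec$rf %*% (spec$env * cos(phase_arg))
    Smat[a, ] <- spec$rf %*% (spec$env * sin(phase_arg))
  }
  idx <- match(s, su)
  cos(nu) * Cmat[idx, , drop = FALSE] - sin(nu) * Smat[idx, , drop = FALSE]
}

#' Draw response vectors from an encoding model
#'
#' Low-level sampling interface shared by all encoding models: given
#' per-trial stimulus (and, where the model needs one, nuisance) values,
#' returns a trials x neurons response matrix using the current RNG stream.
#' Used by the `simulate_*` front ends and by
#' [inject_information_limit()]'s input-mode regeneration.
#'
#' @param model an encoding-model specification.
#' @param s per-trial stimulus values.
#' @param nu per-trial nuisance values (model-dependent).
#' @param ... unused.
#' @return Numeric matrix, trials x neurons.
#' @export
sample_responses <- function(model, s, nu = NULL, ...) UseMethod("sample_responses")

#' @export
sample_responses.gabor_population <- function(model, s, nu = NULL, ...) {
  if (is.null(nu)) stop("gabor model needs a nuisance value per trial")
  f <- gabor_projection(model, s, nu)
  f + matrix(stats::rnorm(length(f), sd = sqrt(model$noise_var)),
             nrow(f), ncol(f))
}

#' Simulate a Gabor population under nuisance variation
#'
#' Each trial draws a nuisance value (spatial phase uniform on `[0, 2*pi)`, or
#' polarity uniform on `{-1, +1}`, rendered as phase 0 or pi), renders the
#' grating at the trial's orientation, projects it onto every receptive field
#' and adds Gaussian noise. Averaged over the nuisance, every neuron's mean
#' response is flat in orientation while the response covariance remains
#' orientation-tuned: the code is purely nonlinear.
#'
#' @param spec a [gabor_population()].
#' @param s_values orientations in `[0, pi)`, recycled across trials.
#' @param nuisance `"phase"` or `"polarity"`.
#' @param n_trials number of trials.
#' @param seed optional integer seed.
#' @return A [trial_table()] with the nuisance stored in column `nu`.
#' @export
simulate_gabor_population <- function(spec, s_values, nuisance = c("phase", "polarity"),
                                      n_trials, seed = NULL) {
  nuisance <- match.arg(nuisance)
  if (length(s_values) == 0) stop("`s_values` must be non-empty")
  if (any(s_values < 0 | s_values >= pi)) stop("orientations must lie in [0, pi)")
  with_seed(seed, {
    s <- rep_len(s_values, n_trials)
    nu <- switch(nuisance,
                 phase = stats::runif(n_trials, 0, 2 * pi),
                 polarity = sample(c(0, pi), n_trials, replace = TRUE))
    r <- sample_responses(spec, s, nu)
    tab <- trial_table(s = s, r = r, nu = nu)
    attr(tab, "encoder") <- spec
    tab
  })
}

#' Quadratic (stimulus-dependent covariance) code specification
#'
#' A Gaussian population whose mean is constant in the stimulus while the
#' covariance `Sigma(s)` varies smoothly: all task information sits in the
#' second-order statistics, the textbook purely quadratic code.
#'
#' @param N neuron count.
#' @param mean constant mean vector (recycled to length `N`).
#' @param cov_fn function `s -> Sigma(s)` returning an `N x N` positive-definite
#'   matrix; default [rotating_cov()] for `N = 2`.
#' @param s_ref reference stimulus.
#' @return An object of class `quadratic_code`.
#' @export
quadratic_code <- function(N = 2, mean = 0, cov_fn = NULL, s_ref = 0) {
  mean <- rep_len(mean, N)
  cov_fn <- cov_fn %||% rotating_cov()
  structure(list(N = N, mean = mean, cov_fn = cov_fn, s_ref = s_ref),
            class = c("quadratic_code", "encoding_model"))
}

#' Rotating two-neuron covariance family
#'
#' `Sigma(s)` is an anisotropic covariance whose principal axis rotates with
#' the stimulus, the canonical picture of covariance tuning for a neuron pair
#' under phase nuisance.
#'
#' @param anisotropy eccentricity in `[0, 1)`: eigenvalues are `1 +/- anisotropy`.
#' @param rate rotation angle per stimulus unit.
#' @return A function `s -> 2 x 2` covariance matrix.
#' @export
rotating_cov <- function(anisotropy = 0.6, rate = 1) {
  force(anisotropy); force(rate)
  function(s) {
    th <- rate * s
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    R %*% diag(c(1 + anisotropy, 1 - anisotropy)) %*% t(R)
  }
}

#' @export
sample_responses.quadratic_code <- function(model, s, nu = NULL, ...) {
  su <- sort(unique(s))
  out <- matrix(0, length(s), model$N)
  for (v in su) {
    Sg <- model$cov_fn(v)
    if (any(eigen(Sg, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stop("cov_fn(", v, ") is not positive-definite")
    idx <- which(s == v)
    out[idx, ] <- rmvn(length(idx), model$mean, Sg)
  }
  out
}

#' Simulate a quadratic code
#'
#' @param spec a [quadratic_code()].
#' @param s_values stimulus values, recycled across trials.
#' @param n_trials number of trials.
#' @param seed optional integer seed.
#' @return A [trial_table()].
#' @export
simulate_quadratic_code <- function(spec, s_values, n_trials, seed = NULL) {
  if (length(s_values) == 0) stop("`s_values` must be non-empty")
  with_seed(seed, {
    s <- rep_len(s_values, n_trials)
    tab <- trial_table(s = s, r = sample_responses(spec, s))
    attr(tab, "encoder") <- spec
    tab
  })
}

#' Cubic (third-moment) code specification
#'
#' An exponential-family code whose stimulus information is carried by third
#' moments. For each disjoint triplet of units, a latent vector `z` is drawn
#' from a four-component Gaussian mixture placed at the vertices of a regular
#' tetrahedron (`(1,1,1), (1,-1,-1), (-1,1,-1), (-1,-1,1)`, all with
#' coordinate product +1), scaled by
#' `c(s) = sign(gamma * s) * |gamma * s|^(1/3) * vertex_scale` and given
#' isotropic component covariance `(1 - vertex_scale^2 * |gamma*s|^(2/3)) I`.
#' The tetrahedral symmetry makes the mean exactly zero and the covariance
#' exactly the identity for every `s`, while the third moment
#' `E[z1 z2 z3 | s] = vertex_scale^3 * gamma * s` is linear in the stimulus:
#' first- and second-order statistics carry no information at the pure-cubic
#' stage. A stimulus-dependent affine map `r = mean_fn(s) + chol(Sigma(s)) z`
#' then reintroduces linear and quadratic information.
#'
#' @param n_triplets number of disjoint 3-unit groups (`N = 3 * n_triplets`).
#' @param gamma cubic coupling strength.
#' @param vertex_scale tetrahedron vertex scale (`a` above); the pure-cubic
#'   stage requires `vertex_scale^2 * |gamma * s|^(2/3) < 1` over the stimulus
#'   range.
#' @param mean_fn function `s -> length-N mean vector`; default linear tuning
#'   with slope `mean_slope` per coordinate.
#' @param cov_fn function `s -> N x N` positive-definite matrix; default
#'   `diag(exp(cov_log_slope * s))`.
#' @param mean_slope,cov_log_slope slopes used by the default `mean_fn` /
#'   `cov_fn`.
#' @details The default parameters put the code in a strongly informative,
#'   cubic-dominated regime over a narrow stimulus range around `s0 = 0`
#'   (usable range `|s| < vertex_scale^-3 / gamma`, about 0.43 at the
#'   defaults): roughly 80 percent of the local Fisher information sits in
#'   the third-order statistics, and an optimal decoder attains useful
#'   single-trial precision, the setting in which a generic trained decoder
#'   can in principle extract most of the available information.
#' @return An object of class `cubic_code`.
#' @export
cubic_code <- function(n_triplets = 1, gamma = 4.5, vertex_scale = 0.8,
                       mean_fn = NULL, cov_fn = NULL,
                       mean_slope = 0.5, cov_log_slope = 0.3) {
  if (n_triplets < 1) stop("`n_triplets` must be at least 1")
  N <- 3L * as.integer(n_triplets)
  mean_fn <- mean_fn %||% (function(s) rep(mean_slope * s, N))
  cov_fn <- cov_fn %||% (function(s) diag(exp(rep(cov_log_slope * s, N)), N))
  structure(list(N = N, n_triplets = as.integer(n_triplets), gamma = gamma,
                 vertex_scale = vertex_scale, mean_fn = mean_fn,
                 cov_fn = cov_fn),
            class = c("cubic_code", "encoding_model"))
}

# Tetrahedron vertices with coordinate product +1.
tetra_vertices <- function() {
  rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
}

# Draw the pure-cubic latent vectors for one stimulus value: n x (3*n_triplets).
sample_pure_cubic <- function(n, n_triplets, gamma, s, a) {
  shift <- a^2 * abs(gamma * s)^(2 / 3)
  if (shift >= 1)
    stop("cubic mixture undefined: vertex_scale^2 * |gamma*s|^(2/3) must be < 1")
  cc <- sign(gamma * s) * abs(gamma * s)^(1 / 3) * a
  sdc <- sqrt(1 - shift)
  V <- tetra_vertices()
  z <- matrix(0, n, 3 * n_triplets)
  for (t in seq_len(n_triplets)) {
    comp <- sample.int(4, n, replace = TRUE)
    z[, 3 * (t - 1) + 1:3] <- cc * V[comp, , drop = FALSE] +
      matrix(stats::rnorm(3 * n, sd = sdc), n, 3)
  }
  z
}

#' @export
sample_responses.cubic_code <- function(model, s, nu = NULL, ...) {
  su <- sort(unique(s))
  out <- matrix(0, length(s), model$N)
  for (v in su) {
    idx <- which(s == v)
    z <- sample_pure_cubic(length(idx), model$n_triplets, model$gamma, v,
                           model$vertex_scale)
    Sg <- model$cov_fn(v)
    if (any(eigen(Sg, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stop("cov_fn(", v, ") is not positive-definite")
    out[idx, ] <- sweep(z %*% mat_sqrt(Sg), 2, model$mean_fn(v), "+")
  }
  out
}

#' Simulate a cubic code
#'
#' @param spec a [cubic_code()].
#' @param s_values stimulus values, recycled across trials.
#' @param n_trials number of trials.
#' @param seed optional integer seed.
#' @return A [trial_table()].
#' @export
simulate_cubic_code <- function(spec, s_values, n_trials, seed = NULL) {
  if (length(s_values) == 0) stop("`s_values` must be non-empty")
  with_seed(seed, {
    s <- rep_len(s_values, n_trials)
    tab <- trial_table(s = s, r = sample_responses(spec, s))
    attr(tab, "encoder") <- spec
    tab
  })
}

#' Inject information-limiting correlations
#'
#' Information-limiting noise is equivalent to jitter of the stimulus itself:
#' responses are distributed as if the stimulus were `s + ds` with
#' `ds ~ N(0, epsilon)`, so no decoder's estimator variance can fall below
#' `epsilon` however many neurons or statistics are decoded. The default
#' (`mode = "input"`) regenerates each trial's responses from the encoding
#' model at the jittered stimulus (the defining construction); `mode =
#' "feature"` instead adds `ds * f_prime` along the supplied signal direction,
#' a fast first-order approximation.
#'
#' @param table a [trial_table()].
#' @param epsilon variance of the information-limiting component (`1/J_inf`),
#'   in squared stimulus units; `epsilon = 0` leaves the table unchanged in
#'   distribution.
#' @param encoder encoding model used to regenerate responses (input mode);
#'   defaults to the encoder recorded on the table.
#' @param mode `"input"` (regenerate at `s + ds`) or `"feature"` (first-order
#'   shift along `f_prime`).
#' @param f_prime signal direction `d<r|s>/ds` (length `N`), required in
#'   feature mode.
#' @param seed optional integer seed.
#' @return A [trial_table()] with the same stimulus labels.
#' @export
inject_information_limit <- function(table, epsilon, encoder = NULL,
                                     mode = c("input", "feature"),
                                     f_prime = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (epsilon < 0) stop("`epsilon` must be nonnegative")
  if (epsilon == 0) return(table)
  with_seed(seed, {
    ds <- stats::rnorm(nrow(table), sd = sqrt(epsilon))
    if (mode == "input") {
      encoder <- encoder %||% attr(table, "encoder")
      if (is.null(encoder)) stop("input mode needs the generating `encoder`")
      nu <- if ("nu" %in% names(table)) table$nu else NULL
      r <- sample_responses(encoder, table$s + ds, nu)
    } else {
      if (is.null(f_prime)) stop("feature mode needs `f_prime`")
      r <- responses(table) + outer(ds, as.numeric(f_prime))
    }
    out <- set_responses(table, r)
    attr(out, "epsilon") <- epsilon
    out
  })
}
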