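# Generic feedforward network decoder: a small fully connected ReLU
# regression network trained by backpropagation, standing in for a brain
# whose nonlinearity is unknown to the analyst. Written directly in matrix
# form (forward/backward passes + Adam) since the networks involved are tiny.

mlp_init <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X) {
  L <- length(par$W)
  A <- vector("list", L + 1L)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% par$W[[l]], 2, par$b[[l]], "+")
    A[[l + 1]] <- if (l < L) pmax(Z, 0) else Z   # ReLU hidden, linear output
  }
  A
}

# Gradient of mean squared error wrt all weights and biases.
mlp_backward <- function(par, A, y) {
  L <- length(par$W)
  n <- nrow(A[[1]])
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- (A[[L + 1]] - y) * (2 / n)
  for (l in L:1) {
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) delta <- (delta %*% t(par$W[[l]])) * (A[[l]] > 0)
  }
  list(W = gW, b = gb)
}

#' Train a feedforward ReLU network decoder
#'
#' Fits a fully connected rectified-linear regression network (default two
#' hidden layers of 30 units) to estimate the stimulus from raw responses,
#' by minibatch backpropagation (Adam) on squared error. The network plays
#' the role of a generic decoder whose internal nonlinearity need not match
#' the code's sufficient statistics. Inputs and targets are standardized
#' internally; estimates are returned on the stimulus scale.
#'
#' If a held-out `eval_table` and the closed-form `optimal_variance` of an
#' ideal decoder are supplied, the fit also reports the fraction of optimal
#' information extracted, `sigma2_opt / sigma2_network`, with the network's
#' estimator variance measured on the held-out trials by
#' [estimator_variance()].
#'
#' @param table a [trial_table()] of training trials (responses + `s`).
#' @param hidden hidden layer sizes, default `c(30, 30)`.
#' @param n_train number of training pairs used (first `n_train` trials).
#' @param seed integer seed for initialization and batch order.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batch minibatch size.
#' @param patience epochs without improvement of the running loss before
#'   training is flagged divergent (reported via a warning and the
#'   `diverged` field, never silently accepted).
#' @param eval_table optional held-out [trial_table()] for the information
#'   fraction.
#' @param optimal_variance optional closed-form optimal estimator variance.
#' @return An object of class `network_decoder` with the trained parameters,
#'   the loss history, the training configuration, and (when evaluable)
#'   `info_fraction`.
#' @export
fit_network_decoder <- function(table, hidden = c(30, 30), n_train = nrow(table),
                                seed = NULL, epochs = 150, lr = 1e-3,
                                batch = 128, patience = 25,
                                eval_table = NULL, optimal_variance = NULL) {
  if (n_train > nrow(table)) stop("`n_train` exceeds available trials")
  if (any(hidden < 1)) stop("hidden sizes must be >= 1")
  X <- responses(table)[seq_len(n_train), , drop = FALSE]
  y <- table$s[seq_len(n_train)]
  mu_x <- colMeans(X); sd_x <- apply(X, 2, stats::sd); sd_x[sd_x == 0] <- 1
  mu_y <- mean(y); sd_y <- stats::sd(y); if (sd_y == 0) sd_y <- 1
  Xs <- sweep(sweep(X, 2, mu_x), 2, sd_x, "/")
  ys <- matrix((y - mu_y) / sd_y, ncol = 1)
  sizes <- c(ncol(X), hidden, 1L)
  with_seed(seed, {
    par <- mlp_init(sizes)
    m <- lapply(par, function(g) lapply(g, function(x) x * 0))
    v <- m
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
    loss_hist <- numeric(0)
    if (epochs > 0) for (ep in seq_len(epochs)) {
      idx <- sample.int(n_train)
      ep_loss <- 0; n_batch <- 0
      for (start in seq(1, n_train, by = batch)) {
        rows <- idx[start:min(start + batch - 1, n_train)]
        A <- mlp_forward(par, Xs[rows, , drop = FALSE])
        ep_loss <- ep_loss + mean((A[[length(A)]] - ys[rows, , drop = FALSE])^2)
        n_batch <- n_batch + 1
        g <- mlp_backward(par, A, ys[rows, , drop = FALSE])
        t <- t + 1
        for (p in c("W", "b")) for (l in seq_along(par[[p]])) {
          m[[p]][[l]] <- b1 * m[[p]][[l]] + (1 - b1) * g[[p]][[l]]
          v[[p]][[l]] <- b2 * v[[p]][[l]] + (1 - b2) * g[[p]][[l]]^2
          mh <- m[[p]][[l]] / (1 - b1^t)
          vh <- v[[p]][[l]] / (1 - b2^t)
          par[[p]][[l]] <- par[[p]][[l]] - lr * mh / (sqrt(vh) + eps)
        }
      }
      loss_hist[ep] <- ep_loss / n_batch
    }
    diverged <- FALSE
    if (length(loss_hist) > patience) {
      recent <- mean(utils::tail(loss_hist, patience))
      if (recent > 1.5 * min(loss_hist)) {
        diverged <- TRUE
        warning("network training loss increased well above its minimum (flagged divergent)")
      }
    }
    net <- structure(list(par = par, sizes = sizes, loss = loss_hist,
                          mu_x = mu_x, sd_x = sd_x, mu_y = mu_y, sd_y = sd_y,
                          config = list(hidden = hidden, n_train = n_train,
                                        epochs = epochs, lr = lr, batch = batch,
                                        optimizer = "adam", seed = seed),
                          diverged = diverged, kind = "network"),
                     class = "network_decoder")
    if (!is.null(eval_table) && !is.null(optimal_variance)) {
      shat <- predict(net, eval_table)
      net$sigma2 <- estimator_variance(shat, eval_table$s)
      net$info_fraction <- optimal_variance / net$sigma2
    }
    net
  })
}

#' @export
predict.network_decoder <- function(object, table, ...) {
  X <- if (is.matrix(table)) table else responses(table)
  Xs <- sweep(sweep(X, 2, object$mu_x), 2, object$sd_x, "/")
  A <- mlp_forward(object$par, Xs)
  drop(A[[length(A)]]) * object$sd_y + object$mu_y
}

#' @export
print.network_decoder <- function(x, ...) {
  cat(sprintf("ReLU network decoder: %s, %d training pairs, %d epochs\n",
              paste(x$sizes, collapse = "-"), x$config$n_train, x$config$epochs))
  if (length(x$loss))
    cat(sprintf("  final training loss: %.4g%s\n", x$loss[length(x$loss)],
                if (x$diverged) " (divergence flagged)" else ""))
  if (!is.null(x$info_fraction))
    cat(sprintf("  information fraction vs optimal: %.3f\n", x$info_fraction))
  invisible(x)
}

#' Fraction of optimal information extracted by a network decoder
#'
#' The reference experiment for decoding an unknown nonlinearity: responses
#' are drawn from a cubic code, a small ReLU regression network is trained on
#' `n_train` (response, stimulus) pairs with stimuli near the reference, and
#' the fraction of the optimal decoder's Fisher information it extracts is
#' measured as the ratio of inverse estimator variances on held-out trials at
#' `s0 +/- ds/2`. The optimal variance is the closed form
#' `(F' Gamma^-1 F')^-1` over the polynomial sufficient statistics (degree
#' 3), estimated from a large independent sample. The experiment is repeated
#' over `seeds` and reported as mean with per-seed values and the full
#' configuration (a run manifest).
#'
#' @param seeds integer seeds, one network per seed (>= 5 recommended).
#' @param spec a [cubic_code()].
#' @param n_train training pairs.
#' @param n_test held-out trials for the network's estimator variance.
#' @param n_opt sample size for the closed-form optimal variance.
#' @param s_sd SD of the training stimuli around the reference `s0 = 0`
#'   (normal truncated at `+/- 2 * s_sd`, snapped to a fine grid).
#' @param ds stimulus step of the held-out evaluation pair.
#' @param hidden,epochs,lr,batch network architecture and training
#'   configuration (see [fit_network_decoder()]).
#' @return List with `fraction` (mean over seeds), `per_seed`, `sd`,
#'   `optimal_variance`, `network_variance` (per seed) and `config`.
#' @export
network_information_experiment <- function(seeds = 1:5, spec = cubic_code(),
                                           n_train = 20000, n_test = 20000,
                                           n_opt = 2e5, s_sd = 0.13, ds = 0.2,
                                           hidden = c(30, 30), epochs = 400,
                                           lr = 0.01, batch = 256) {
  s_eval <- c(-ds / 2, ds / 2)
  base <- as.integer(seeds[1])
  opt_tab <- simulate_cubic_code(spec, s_eval, n_opt,
                                 seed = child_seed(base, 101))
  sm <- signal_noise_summary(polynomial_features(opt_tab, 3), opt_tab, "fine")
  sigma2_opt <- 1 / fisher_information(sm)
  per_seed <- vapply(seeds, function(sd_i) {
    train <- with_seed(child_seed(sd_i, 1), {
      # truncated normal: the mixture construction bounds the usable range
      s_train <- pmin(pmax(stats::rnorm(n_train, 0, s_sd), -2 * s_sd), 2 * s_sd)
      simulate_cubic_code(spec, round(s_train / 0.01) * 0.01, n_train)
    })
    test <- simulate_cubic_code(spec, s_eval, n_test, seed = child_seed(sd_i, 2))
    net <- fit_network_decoder(train, hidden = hidden, n_train = n_train,
                               seed = child_seed(sd_i, 3), epochs = epochs,
                               lr = lr, batch = batch)
    estimator_variance(predict(net, test), test$s)
  }, 0)
  list(fraction = mean(sigma2_opt / per_seed),
       per_seed = sigma2_opt / per_seed,
       sd = stats::sd(sigma2_opt / per_seed),
       optimal_variance = sigma2_opt, network_variance = per_seed,
       config = list(seeds = seeds, n_train = n_train, n_test = n_test,
                     n_opt = n_opt, s_sd = s_sd, ds = ds, hidden = hidden,
                     epochs = epochs, lr = lr, batch = batch,
                     gamma = spec$gamma, vertex_scale = spec$vertex_scale))
}

#' Slope-corrected estimator variance from held-out estimates
#'
#' The variance of an estimator per unit stimulus: within-condition variance
#' of the estimates divided by the squared sensitivity `d<shat>/ds`,
#' estimated by regressing the conditional means on the stimulus values.
#' With two stimulus conditions this is the usual discrimination-based
#' variance; an estimator with no stimulus sensitivity gets variance `Inf`.
#'
#' @param estimates per-trial estimates.
#' @param s per-trial stimulus values (>= 2 distinct values).
#' @return Estimator variance in squared stimulus units.
#' @export
estimator_variance <- function(estimates, s) {
  su <- sort(unique(s))
  if (length(su) < 2) stop("need at least two stimulus conditions")
  means <- vapply(su, function(v) mean(estimates[s == v]), 0)
  vars <- vapply(su, function(v) stats::var(estimates[s == v]), 0)
  slope <- unname(stats::coef(stats::lm(means ~ su))[2])
  if (!is.finite(slope) || slope == 0) return(Inf)
  mean(vars) / slope^2
}
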