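# Nonlinear response statistics R(r) and their signal/noise summaries.

#' Polynomial statistics of population responses
#'
#' Builds the feature matrix of polynomial sufficient statistics
#' `R(r) = {r_i, r_i r_j, r_i r_j r_k}` up to `max_degree`, with term
#' bookkeeping. Degree-2 terms are squares `q_i_i` and (optionally) cross
#' products `q_i_j` with `i < j`; degree-3 terms are all monomials
#' `c_i_j_k` with `i <= j <= k` (cubes only, when `include_cross_terms` is
#' `FALSE`).
#'
#' @param table a [trial_table()], or a numeric response matrix.
#' @param max_degree 1, 2 or 3.
#' @param include_cross_terms include products across distinct neurons?
#' @return An object of class `feature_set`: list with `values` (trials x
#'   terms matrix), `terms` (data.frame: `term`, `degree`, `i`, `j`, `k`) and
#'   `meta`.
#' @examples
#' tt <- simulate_xor(100, seed = 1)
#' fs <- polynomial_features(tt, max_degree = 2)
#' fs$terms
#' @export
polynomial_features <- function(table, max_degree = 2, include_cross_terms = TRUE) {
  if (!max_degree %in% 1:3) stop("`max_degree` must be 1, 2 or 3")
  r <- if (is.matrix(table)) table else responses(table)
  N <- ncol(r)
  vals <- list()
  terms <- list()
  for (i in seq_len(N)) {
    vals[[length(vals) + 1L]] <- r[, i]
    terms[[length(terms) + 1L]] <-
      data.frame(term = paste0("r_", i), degree = 1L, i = i, j = NA, k = NA)
  }
  if (max_degree >= 2) {
    for (i in seq_len(N)) for (j in i:N) {
      if (!include_cross_terms && j != i) next
      vals[[length(vals) + 1L]] <- r[, i] * r[, j]
      terms[[length(terms) + 1L]] <-
        data.frame(term = paste0("q_", i, "_", j), degree = 2L, i = i, j = j, k = NA)
    }
  }
  if (max_degree >= 3) {
    for (i in seq_len(N)) for (j in i:N) for (k in j:N) {
      if (!include_cross_terms && !(i == j && j == k)) next
      vals[[length(vals) + 1L]] <- r[, i] * r[, j] * r[, k]
      terms[[length(terms) + 1L]] <-
        data.frame(term = paste0("c_", i, "_", j, "_", k), degree = 3L,
                   i = i, j = j, k = k)
    }
  }
  values <- do.call(cbind, vals)
  terms <- do.call(rbind, terms)
  colnames(values) <- terms$term
  feature_set(values, terms)
}

#' Construct a feature set from a matrix and term table
#'
#' @param values trials x terms numeric matrix.
#' @param terms data.frame with at least columns `term` and `degree`.
#' @param meta optional list of provenance notes (e.g. residualization).
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(values, terms, meta = list()) {
  values <- as.matrix(values)
  if (nrow(terms) != ncol(values)) stop("one term row per feature column")
  if (!all(is.finite(values))) stop("feature values must be finite")
  rownames(terms) <- NULL
  structure(list(values = values, terms = terms, meta = meta),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("Feature set: %d trials x %d terms (degrees: %s)%s\n",
              nrow(x$values), ncol(x$values),
              paste(sort(unique(x$terms$degree)), collapse = ","),
              if (isTRUE(x$meta$residualized)) ", residualized" else ""))
  invisible(x)
}

#' Combine feature sets column-wise
#' @param ... `feature_set` objects over the same trials.
#' @return A single `feature_set`.
#' @export
cbind_features <- function(...) {
  fs <- list(...)
  feature_set(do.call(cbind, lapply(fs, `[[`, "values")),
              do.call(rbind, lapply(fs, function(f)
                f$terms[, c("term", "degree", "i", "j", "k")])),
              meta = fs[[1]]$meta)
}

#' Export a feature matrix as CSV
#'
#' Columns are named by term identity (`r_i`, `q_i_j`, `c_i_j_k`), preceded by
#' `trial` and `s` (and `choice` when supplied).
#' @param features a `feature_set`.
#' @param table the originating [trial_table()].
#' @param path file path.
#' @export
write_features <- function(features, table, path) {
  df <- data.frame(trial = table$trial, s = table$s)
  if ("choice" %in% names(table)) df$choice <- table$choice
  utils::write.csv(cbind(df, as.data.frame(features$values)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Remove the linearly decodable stimulus component from responses
#'
#' Computes `delta_r_i = r_i - E[r_i | shat1]`, where `shat1` is the estimate
#' from the optimal *linear* decoder on the same trials. Quadratic statistics
#' of the residuals (`delta_r_i^2`, `delta_r_i delta_r_j`) then carry no
#' linearly redundant stimulus dependence, isolating genuinely nonlinear
#' information. The conditional mean is estimated per stimulus condition by
#' linear regression of each response on `shat1` (`method = "regression"`), or
#' by means within `n_bins` quantile bins of `shat1` (`method = "binned"`).
#'
#' @param table a [trial_table()].
#' @param linear_estimate per-trial `shat1` from the linear decoder.
#' @param method conditional-mean estimator.
#' @param n_bins bins for `method = "binned"`.
#' @return A [trial_table()] whose response columns hold the residuals.
#' @export
residualize <- function(table, linear_estimate,
                        method = c("regression", "binned"), n_bins = 10) {
  method <- match.arg(method)
  if (length(linear_estimate) != nrow(table))
    stop("`linear_estimate` must have one value per trial")
  r <- responses(table)
  out <- r
  for (grp in split(seq_len(nrow(table)), table$s)) {
    x <- linear_estimate[grp]
    if (method == "regression" || length(unique(x)) < n_bins) {
      X <- cbind(1, x)
      # per-neuron least squares in one solve; constant shat1 degrades to
      # plain centering
      beta <- if (stats::sd(x) > 0) qr.solve(X, r[grp, , drop = FALSE])
              else rbind(colMeans(r[grp, , drop = FALSE]), 0)
      out[grp, ] <- r[grp, , drop = FALSE] - X %*% beta
    } else {
      bins <- cut(x, stats::quantile(x, seq(0, 1, length.out = n_bins + 1)),
                  include.lowest = TRUE)
      for (b in split(grp, bins)) {
        if (length(b) == 0) next
        out[b, ] <- sweep(r[b, , drop = FALSE], 2,
                          colMeans(r[b, , drop = FALSE]))
      }
    }
  }
  res <- set_responses(table, out)
  attr(res, "residualized") <- TRUE
  res
}

#' Signal and noise summaries of a feature set
#'
#' Estimates the signal slope `F' = d<R|s>/ds` (fine mode: central difference
#' over the two stimulus values nearest the median; coarse mode: `DeltaF /
#' Delta s` between the two categories), the noise covariance `Gamma =
#' Cov(R|s)` (fine: pooled within-condition covariance; coarse: the unweighted
#' average `Gamma_bar` of the two category covariances), and each term's
#' discriminability `d'_k = |F'_k| * Delta s / sqrt(Gamma_kk)`. Zero-variance
#' terms are flagged degenerate and get `d' = 0`.
#'
#' @param features a `feature_set`.
#' @param table the originating [trial_table()].
#' @param mode `"fine"` (>= 2 nearby stimulus values) or `"coarse"` (exactly
#'   two categories).
#' @param ds stimulus step used for the discriminability; defaults to the
#'   spacing of the two conditions used for the slope.
#' @return An object of class `sn_summary`: list with `F_prime`, `Gamma`,
#'   `d_prime`, `terms`, `ds`, `mode`, `cond_means`, `s_values`, `degenerate`.
#' @export
signal_noise_summary <- function(features, table, mode = c("fine", "coarse"),
                                 ds = NULL) {
  mode <- match.arg(mode)
  R <- features$values
  s <- table$s
  su <- sort(unique(s))
  if (mode == "coarse" && length(su) != 2)
    stop("coarse mode needs exactly two stimulus categories")
  if (mode == "fine" && length(su) < 2)
    stop("fine mode needs at least two stimulus values")
  if (mode == "fine") {
    # two unique values nearest the centre of the tested range
    mid <- stats::median(s)
    pick <- su[order(abs(su - mid))][1:2]
    pick <- sort(pick)
  } else pick <- su
  m_lo <- colMeans(R[s == pick[1], , drop = FALSE])
  m_hi <- colMeans(R[s == pick[2], , drop = FALSE])
  step <- pick[2] - pick[1]
  F_prime <- (m_hi - m_lo) / step
  covs <- lapply(pick, function(v) stats::cov(R[s == v, , drop = FALSE]))
  Gamma <- (covs[[1]] + covs[[2]]) / 2   # stimulus-average conditional covariance
  ds <- ds %||% step
  vars <- diag(Gamma)
  degenerate <- vars <= .Machine$double.eps * max(vars, 1)
  if (any(degenerate))
    warning(sum(degenerate), " zero-variance feature(s) flagged degenerate")
  d_prime <- ifelse(degenerate, 0, abs(F_prime) * ds / sqrt(vars))
  structure(list(F_prime = F_prime, Gamma = Gamma, d_prime = d_prime,
                 terms = features$terms, ds = ds, mode = mode,
                 cond_means = rbind(lo = m_lo, hi = m_hi), s_values = pick,
                 degenerate = degenerate),
            class = "sn_summary")
}

#' @export
print.sn_summary <- function(x, ...) {
  cat(sprintf("Signal/noise summary (%s mode): %d terms, ds = %g\n",
              x$mode, length(x$F_prime), x$ds))
  cat(sprintf("  d' range: [%.3g, %.3g]%s\n", min(x$d_prime), max(x$d_prime),
              if (any(x$degenerate))
                paste0(" (", sum(x$degenerate), " degenerate)") else ""))
  invisible(x)
}
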