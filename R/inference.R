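# Population-level efficiency estimation, shuffle controls and significance.

# Total-least-squares slope: tangent of the first principal axis angle of the
# bivariate scatter (second-moment matrix when constrained through the origin).
pa_slope <- function(x, y, origin = FALSE) {
  M <- if (origin) crossprod(cbind(x, y)) / length(x) else stats::cov(cbind(x, y))
  if (all(abs(M) < .Machine$double.eps)) return(NA_real_)
  v <- eigen(M, symmetric = TRUE)$vectors[, 1]
  if (abs(v[1]) < .Machine$double.eps) return(Inf)
  v[2] / v[1]
}

#' Decoding-efficiency slope from measured vs predicted choice correlations
#'
#' The efficiency of the brain's decoding is the slope of the relationship
#' between measured choice correlations and their optimal predictions,
#' estimated as the angle of the first principal axis of the bivariate
#' scatter (total least squares: both axes are correlations on a common
#' scale and both carry sampling error). Uncertainty comes from a bootstrap
#' over statistic terms (default 100 resamples). Theoretically the slope
#' equals `epsilon / sigma2_shat`, the fraction of the behavioral estimator
#' variance explained by information-limiting noise: 1 for optimal decoding,
#' smaller when variance is added downstream.
#'
#' @param predicted per-term predicted optimal choice correlations.
#' @param measured per-term measured choice correlations.
#' @param n_boot bootstrap resamples.
#' @param level confidence level for the percentile interval.
#' @param origin constrain the principal axis through the origin (uses the
#'   second-moment matrix instead of the covariance)?
#' @param seed optional integer seed for the bootstrap.
#' @return An object of class `efficiency_report`: list with `alpha`, `ci`,
#'   `boot`, `n_terms`, `r_squared` (of measured on predicted).
#' @export
efficiency_slope <- function(predicted, measured, n_boot = 100, level = 0.95,
                             origin = FALSE, seed = NULL) {
  stopifnot(length(predicted) == length(measured))
  keep <- is.finite(predicted) & is.finite(measured)
  x <- predicted[keep]; y <- measured[keep]
  if (length(x) < 3) stop("need at least 3 terms for a slope")
  if (all(x == x[1]) && all(y == y[1]))
    stop("degenerate scatter: all points identical")
  alpha <- pa_slope(x, y, origin)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(x), replace = TRUE)
      pa_slope(x[idx], y[idx], origin)
    }, 0)
  })
  boot_ok <- boot[is.finite(boot)]
  ci <- stats::quantile(boot_ok, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  r2 <- if (stats::sd(x) > 0 && stats::sd(y) > 0) stats::cor(x, y)^2 else NA_real_
  structure(list(alpha = alpha, ci = ci, boot = boot, n_terms = length(x),
                 r_squared = r2, level = level, origin = origin),
            class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf("Decoding efficiency: alpha = %.3f  [%.3f, %.3f] (%d%% bootstrap CI, %d terms)\n",
              x$alpha, x$ci[1], x$ci[2], round(100 * x$level), x$n_terms))
  invisible(x)
}

#' Shuffle-null p-values for choice correlations and stimulus information
#'
#' Builds null distributions by repeatedly shuffling either the choice labels
#' (within stimulus category, preserving all neural correlations: the null of
#' no choice-related activity given the stimulus) or the stimulus labels
#' (across trials: the null of no stimulus information), recomputing the
#' per-term statistic each time. The nulls are approximately zero-mean
#' Gaussian, so each term's p-value is the Gaussian tail probability at its
#' observed statistic with the null's standard deviation. The default is the
#' standard two-sided tail `p = erfc(|x| / (sqrt(2) * sigma_x))`, which is
#' uniform under the null; `tail = "upper"` gives the one-sided form
#' `1 - Phi(|x|/sigma_x)` (0.5 at `x = 0`).
#'
#' @param features a `feature_set`.
#' @param table the originating [trial_table()] (with choices for
#'   `which = "choice"`).
#' @param which shuffle `"choice"` labels (null for the measured NACCC) or
#'   `"stimulus"` labels (null for the total correlation `D_k`).
#' @param n_shuffles number of shuffles (>= 2; 100 is customary).
#' @param choices per-trial choices; defaults to `table$choice`.
#' @param tail `"two.sided"` or `"upper"`.
#' @param seed optional integer seed.
#' @return List with per-term `p`, observed `statistic`, null `sigma`, and
#'   the null matrix.
#' @export
shuffle_null_pvalues <- function(features, table, which = c("choice", "stimulus"),
                                 n_shuffles = 100, choices = NULL,
                                 tail = c("two.sided", "upper"), seed = NULL) {
  which <- match.arg(which); tail <- match.arg(tail)
  if (n_shuffles < 2) stop("need at least 2 shuffles")
  if (nrow(features$values) < 4) stop("too few trials to shuffle")
  choices <- choices %||% table$choice
  stat_fn <- if (which == "choice") {
    if (is.null(choices)) stop("choice shuffle needs choices")
    function(ch, s_lab) naccc(features, ch, table)
  } else {
    function(ch, s_lab) drop(stats::cor(features$values, s_lab))
  }
  observed <- stat_fn(choices, table$s)
  groups <- split(seq_len(nrow(table)), table$s)
  null_mat <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(b) {
      if (which == "choice") {
        ch <- choices
        for (g in groups) ch[g] <- ch[sample(g)]
        stat_fn(ch, table$s)
      } else {
        stat_fn(choices, table$s[sample.int(nrow(table))])
      }
    }, numeric(ncol(features$values)))
  })
  null_mat <- matrix(null_mat, ncol = n_shuffles)
  sigma <- sqrt(rowMeans(null_mat^2))    # zero-mean Gaussian fit
  z <- abs(observed) / sigma
  p <- if (tail == "two.sided") erfc(z / sqrt(2)) else stats::pnorm(z, lower.tail = FALSE)
  list(p = stats::setNames(p, features$terms$term), statistic = observed,
       sigma = sigma, null = null_mat, tail = tail)
}

# Per-neuron independent permutation of responses within strata; the
# workhorse of both shuffle controls. Returns the table plus a count of
# single-trial strata that were necessarily left unshuffled.
shuffle_within_strata <- function(table, strata, seed = NULL) {
  r <- responses(table)
  n_single <- 0L
  with_seed(seed, {
    for (g in split(seq_len(nrow(table)), strata)) {
      if (length(g) < 2) { n_single <- n_single + length(g); next }
      for (j in seq_len(ncol(r))) r[g, j] <- r[sample(g), j]
    }
    out <- set_responses(table, r)
    attr(out, "singleton_strata") <- n_single
    out
  })
}

#' Shuffle away internal noise correlations
#'
#' For each neuron independently, resamples responses among trials matched on
#' stimulus category, nuisance value (within `+/- nuisance_tolerance`, via
#' fixed bins of width `2 * nuisance_tolerance`) and choice. This destroys
#' internal (within-trial) noise correlations between neurons while
#' preserving every neuron's conditional marginals and the nuisance-induced
#' correlations. Strata with a single trial are left unshuffled and counted
#' in the `singleton_strata` attribute (with a message).
#'
#' @param table a [trial_table()] with a recorded nuisance column.
#' @param nuisance_tolerance half-width of the nuisance matching window
#'   (same units as `nu`); `Inf` merges all nuisance values, degenerating to
#'   [shuffle_nuisance()].
#' @param seed optional integer seed.
#' @return A shuffled [trial_table()].
#' @export
shuffle_internal_noise <- function(table, nuisance_tolerance = 1.5, seed = NULL) {
  if (!"nu" %in% names(table)) stop("nuisance must be recorded per trial")
  nu_bin <- if (is.infinite(nuisance_tolerance)) rep(0, nrow(table))
            else floor(table$nu / (2 * nuisance_tolerance))
  ch <- if ("choice" %in% names(table)) table$choice else rep(0, nrow(table))
  out <- shuffle_within_strata(table, interaction(table$s, nu_bin, ch, drop = TRUE),
                               seed)
  if (attr(out, "singleton_strata") > 0)
    message(attr(out, "singleton_strata"),
            " trial(s) in single-trial strata left unshuffled")
  out
}

#' Shuffle away nuisance correlations
#'
#' As [shuffle_internal_noise()], but matching only on stimulus category and
#' choice: responses of different neurons are drawn from trials with
#' *different* nuisance values, destroying nuisance-induced correlations
#' between neurons (while leaving each neuron's within-stratum marginal, and
#' hence all single-neuron statistics, intact).
#'
#' @param table a [trial_table()].
#' @param seed optional integer seed.
#' @return A shuffled [trial_table()].
#' @export
shuffle_nuisance <- function(table, seed = NULL) {
  ch <- if ("choice" %in% names(table)) table$choice else rep(0, nrow(table))
  out <- shuffle_within_strata(table, interaction(table$s, ch, drop = TRUE), seed)
  if (attr(out, "singleton_strata") > 0)
    message(attr(out, "singleton_strata"),
            " trial(s) in single-trial strata left unshuffled")
  out
}

#' Filter sessions by behavioral performance and slope reliability
#'
#' Drops sessions whose behavioral performance does not exceed the
#' (per-subject) threshold, and flags sessions whose measured-vs-predicted
#' correlation has a non-positive coefficient of determination as
#' `unreliable_slope` (retained in the data but conventionally excluded from
#' slope aggregation).
#'
#' @param sessions data.frame with columns `performance` (in `[0, 1]`),
#'   optionally `subject`, `r_squared`, and any efficiency results.
#' @param min_performance scalar threshold, or named vector keyed by subject.
#' @return The filtered data.frame with an added logical `unreliable_slope`.
#' @export
session_filter <- function(sessions, min_performance) {
  if (any(sessions$performance < 0 | sessions$performance > 1))
    stop("performance must lie in [0, 1]")
  thr <- if (length(min_performance) > 1 && !is.null(names(min_performance))) {
    if (!"subject" %in% names(sessions)) stop("per-subject thresholds need a `subject` column")
    unname(min_performance[as.character(sessions$subject)])
  } else rep(min_performance, nrow(sessions))
  out <- sessions[sessions$performance > thr, , drop = FALSE]
  out$unreliable_slope <- if ("r_squared" %in% names(out)) out$r_squared <= 0
                          else FALSE
  out
}
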