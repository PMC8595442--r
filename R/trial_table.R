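#' Per-trial records of stimulus, nuisance, responses and choice
#'
#' A `trial_table` is a data.frame with one row per trial and columns
#' `trial`, `s` (task-relevant stimulus: continuous value or binary category
#' label), optionally `nu` (nuisance value), optionally `choice` (behavioral
#' estimate, continuous or binary), and response columns `r_1 ... r_N`.
#' It is the common currency passed between the encoding models, the feature
#' constructors and the decoders: the processing chain is
#' stimulus + nuisance -> responses `r` -> statistics `R(r)` -> estimate.
#'
#' @param s numeric vector of stimulus values, one per trial.
#' @param r numeric matrix of responses, trials x neurons. Spike counts must
#'   be nonnegative; real-valued responses are allowed for abstract models.
#' @param nu optional numeric vector (or matrix) of nuisance values per trial.
#' @param choice optional numeric vector of behavioral estimates/choices.
#' @return A data.frame of class `trial_table`.
#' @examples
#' tt <- trial_table(s = c(1, 1, -1), r = matrix(rpois(6, 5), 3, 2))
#' n_neurons(tt)
#' @export
trial_table <- function(s, r, nu = NULL, choice = NULL) {
  r <- as.matrix(r)
  n <- length(s)
  if (n < 1L) stop("need at least one trial")
  if (nrow(r) != n) stop("`r` must have one row per trial")
  if (!all(is.finite(r))) stop("responses must be finite")
  df <- data.frame(trial = seq_len(n), s = as.numeric(s))
  if (!is.null(nu)) {
    nu <- as.matrix(nu)
    if (nrow(nu) != n) stop("`nu` must have one value per trial")
    if (ncol(nu) == 1L) df$nu <- as.numeric(nu)
    else for (j in seq_len(ncol(nu))) df[[paste0("nu_", j)]] <- nu[, j]
  }
  if (!is.null(choice)) {
    if (length(choice) != n) stop("`choice` must have one value per trial")
    df$choice <- as.numeric(choice)
  }
  colnames(r) <- paste0("r_", seq_len(ncol(r)))
  df <- cbind(df, as.data.frame(r))
  class(df) <- c("trial_table", "data.frame")
  df
}

#' @export
print.trial_table <- function(x, ...) {
  cat(sprintf("Trial table: %d trials, %d neurons%s%s\n",
              nrow(x), n_neurons(x),
              if ("nu" %in% names(x) || any(grepl("^nu_", names(x))))
                ", with nuisance" else "",
              if ("choice" %in% names(x)) ", with choices" else ""))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... (%d more trials)\n", nrow(x) - 6L))
  invisible(x)
}

#' Number of neurons in a trial table
#' @param table a [trial_table()].
#' @return integer count of response columns.
#' @export
n_neurons <- function(table) {
  sum(grepl("^r_[0-9]+$", names(table)))
}

#' Extract the response matrix from a trial table
#' @param table a [trial_table()].
#' @return numeric matrix, trials x neurons.
#' @export
responses <- function(table) {
  cols <- grep("^r_[0-9]+$", names(table), value = TRUE)
  m <- as.matrix(table[, cols, drop = FALSE])
  # restore numeric order r_1, r_2, ..., r_10, ...
  m[, order(as.integer(sub("^r_", "", cols))), drop = FALSE]
}

# Replace the response matrix, keeping all other columns.
set_responses <- function(table, r) {
  cols <- grep("^r_[0-9]+$", names(table), value = TRUE)
  r <- as.matrix(r)
  stopifnot(nrow(r) == nrow(table), ncol(r) == length(cols))
  ord <- order(as.integer(sub("^r_", "", cols)))
  table[, cols[ord]] <- r
  table
}

#' Read / write trial tables as flat CSV
#'
#' The CSV schema is `trial, s, nu, choice, r_1 ... r_N` (nuisance and choice
#' columns present only when recorded); round-trips losslessly at full
#' double precision. [serialize_trials()] / [unserialize_trials()] provide an
#' equivalent binary (RDS) container for large tables.
#'
#' @param table a [trial_table()].
#' @param path file path.
#' @return `read_trial_table` returns a [trial_table()];
#'   `write_trial_table` returns `path` invisibly.
#' @export
write_trial_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("trial", "s") %in% names(df)) || !any(grepl("^r_", names(df))))
    stop("not a trial-table CSV: need columns trial, s, r_1..r_N")
  class(df) <- c("trial_table", "data.frame")
  df
}

#' @rdname write_trial_table
#' @export
serialize_trials <- function(table, path) {
  saveRDS(table, path)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
unserialize_trials <- function(path) readRDS(path)
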