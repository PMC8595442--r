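#' Read a declarative model-specification file
#'
#' Encoding models and task specifications can be described in a small YAML
#' file with a `model` key naming the family (`xor`, `gabor`, `quadratic`,
#' `cubic`, `variance_task`) and the remaining keys mirroring the
#' corresponding constructor's arguments (e.g. `n_neurons`, `sigma_wide`,
#' `gamma`, `noise_var`). Used by the command-line interface; functions such
#' as [variance_task()] are the programmatic equivalent.
#'
#' @param path path to a YAML file.
#' @return A model specification object, or for `model: xor` a list of
#'   arguments for [simulate_xor()].
#' @export
read_model_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading config files requires the `yaml` package")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$model)) stop("config must name a `model`")
  model <- cfg$model
  cfg$model <- NULL
  switch(model,
         xor = cfg,
         gabor = do.call(gabor_population, cfg),
         quadratic = do.call(quadratic_code, cfg),
         cubic = do.call(cubic_code, cfg),
         variance_task = do.call(variance_task, cfg),
         stop("unknown model family: ", model))
}
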