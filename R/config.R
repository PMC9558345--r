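# YAML configuration for the synthetic-data generator: one file with
# `landscape`, `prey`, `predator` and `seed` blocks, each block holding
# arguments for the corresponding *_config() constructor.

#' Read a simulation configuration file
#'
#' @param path YAML file with optional blocks `landscape`, `prey`,
#'   `predator`, and a top-level `seed`.
#' @return list with `landscape` ([landscape_config()]), `prey`
#'   ([prey_config()]), `predator` ([predator_config()]), `seed`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  seed <- raw$seed %||% 1L
  ls_args <- raw$landscape %||% list()
  if (!is.null(ls_args$veg_props)) ls_args$veg_props <- unlist(ls_args$veg_props)
  if (is.null(ls_args$seed)) ls_args$seed <- seed
  pr_args <- raw$prey %||% list()
  pd_args <- raw$predator %||% list()
  if (!is.null(pd_args$beta_land)) pd_args$beta_land <- unlist(pd_args$beta_land)
  list(landscape = do.call(landscape_config, ls_args),
       prey = do.call(prey_config, pr_args),
       predator = do.call(predator_config, pd_args),
       seed = as.integer(seed))
}
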