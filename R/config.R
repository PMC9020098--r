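# YAML run configuration: one file mirroring the population design and
# the genetic architecture, with an optional seed override.

#' Read a simulation configuration from YAML
#'
#' The file may contain a `design` block (fields of
#' [population_design()]), an `arch` block (fields of
#' [genetic_architecture()], with `sigma2_ec` as a named map from cage
#' size to variance), and a `longitudinal` block (fields of
#' [longitudinal_params()]).  Omitted fields keep their defaults.
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file's `design$seed`.
#' @return List with `design` and `arch`.
#' @export
read_sim_config <- function(path, seed = NULL) {
  cfg <- yaml::read_yaml(path)
  des_args <- cfg$design %||% list()
  if (!is.null(seed)) des_args$seed <- as.integer(seed)
  design <- do.call(population_design, des_args)
  long_args <- cfg$longitudinal %||% list()
  arch_args <- cfg$arch %||% list()
  if (!is.null(arch_args$sigma2_ec))
    arch_args$sigma2_ec <- unlist(arch_args$sigma2_ec)
  arch_args$longitudinal <- do.call(longitudinal_params, long_args)
  arch <- do.call(genetic_architecture, arch_args)
  list(design = design, arch = arch)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
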