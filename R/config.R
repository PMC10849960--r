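## Run configuration: a YAML key-value file with a global seed and
## per-module sub-configs; round-trips losslessly.

#' Read a run configuration file
#'
#' YAML with fields \code{seed}, \code{out_dir}, \code{verbosity} and
#' optional module sub-configs (\code{sampler}, \code{threading},
#' \code{hallucination}, \code{gates}). Missing fields get defaults.
#'
#' @param path YAML file path; NULL returns the defaults.
#' @return named list with class \code{"RunConfig"}.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  defaults <- list(seed = 1L, out_dir = ".", verbosity = 1L,
                   sampler = list(), threading = list(min_hydrophobic = 0,
                                                      cutoff = 8),
                   hallucination = list(binder_length = 80L))
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "RunConfig")
}

#' Write a run configuration file
#'
#' @param config a RunConfig list.
#' @param path output YAML path.
#' @return invisibly, the path.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build a SamplingConfig from a RunConfig's sampler section
#'
#' @param config a RunConfig.
#' @return a \linkS4class{SamplingConfig}.
#' @export
samplerConfigFrom <- function(config) {
  s <- config$sampler
  args <- list(seed = config$seed)
  known <- names(formals(SamplingConfig))
  for (nm in intersect(names(s), known)) args[[nm]] <- s[[nm]]
  do.call(SamplingConfig, args)
}
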