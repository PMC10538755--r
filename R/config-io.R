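#' Read or write a simulation configuration file
#'
#' Plain YAML with keys mirroring [sim_config()] arguments; unknown keys are
#' rejected so typos fail loudly.
#'
#' @param path Path to a YAML config file.
#' @return `read_sim_config()` returns a `tort_config`;
#'   `write_sim_config()` invisibly returns `path`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    abort(paste0("unknown config keys: ", paste(bad, collapse = ", ")))
  }
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param config A [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
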