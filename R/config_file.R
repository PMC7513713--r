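#' Load a pipeline configuration from a YAML file
#'
#' Reads a flat YAML mapping whose keys are the arguments of
#' [run_config()] (e.g. `genotypes_gw`, `roster`, `analyses`, `n_sims`,
#' `seed`, `null_mode`, `delta_aicc`, `out_dir`) and validates it. Relative
#' paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return a validated [run_config()] object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) .fail("file not found: %s", path)
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  bad <- setdiff(names(vals), allowed)
  if (length(bad)) .fail("%s: unknown configuration key(s): %s",
                         path, paste(bad, collapse = ", "))
  base <- dirname(normalizePath(path))
  for (key in c("genotypes_gw", "genotypes_mhc", "roster", "pairs", "out_dir"))
    if (!is.null(vals[[key]]) && !grepl("^(/|[A-Za-z]:)", vals[[key]]))
      vals[[key]] <- file.path(base, vals[[key]])
  do.call(run_config, vals)
}
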