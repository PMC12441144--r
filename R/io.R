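# Config and parameter serialisation: agent parameters as JSON, the
# age-trend generator and design configs as YAML.

#' Serialize agent parameters to JSON
#'
#' @param params Named list/vector of parameters
#'   (`rho`, `kappa_desc`, `kappa_exp`, `psi_safe`, `psi_risky`, `tau`).
#' @param path File path.
#' @return `read_params()` returns the named list.
#' @export
write_params <- function(params, path) {
  jsonlite::write_json(as.list(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read configurations from YAML
#'
#' `read_design_config()` expects keys matching the [design_config()]
#' arguments; `read_age_model()` expects `age_range` and a `params` map
#' whose entries carry `intercept`, `b_lin`, `b_quad`, `sd`.
#'
#' @param path YAML file path.
#' @return The corresponding config object.
#' @export
read_design_config <- function(path) {
  do.call(design_config, yaml::read_yaml(path))
}

#' @rdname read_design_config
#' @export
read_age_model <- function(path) {
  y <- yaml::read_yaml(path)
  age_trend_config(
    age_range = unlist(y$age_range %||% c(10, 26)),
    params = y$params %||% list()
  )
}
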