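#' Read a simulation configuration from YAML
#'
#' Recognized blocks, all optional (missing values fall back to package
#' defaults):
#' \preformatted{
#' kinetics:   {a, b, c, m, n, epsilon0}
#' artery:     {C10, C20, C30, C40, C50, C60}
#' simulation: {dt, horizon, snapshot_interval, accumulation}
#' }
#'
#' @param path Path to a YAML file.
#' @return A list with elements `kinetics`
#'   ([degradation_coefficients()]), `artery` ([artery_coefficients()]) and
#'   `simulation` ([simulation_config()]).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  unknown <- setdiff(names(raw), c("kinetics", "artery", "simulation"))
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  kin <- do.call(degradation_coefficients,
                 keep_known(raw$kinetics, names(formals(
                   degradation_coefficients))))
  art <- do.call(artery_coefficients,
                 keep_known(raw$artery, names(formals(artery_coefficients))))
  sim_args <- keep_known(raw$simulation,
                         setdiff(names(formals(simulation_config)), "coeffs"))
  sim <- do.call(simulation_config, c(list(coeffs = kin), sim_args))
  list(kinetics = kin, artery = art, simulation = sim)
}

keep_known <- function(block, allowed) {
  if (is.null(block)) return(list())
  if (!is.list(block)) stop("config block must be a mapping", call. = FALSE)
  unknown <- setdiff(names(block), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  block
}
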