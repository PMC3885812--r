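#' Condition parameter presets
#'
#' Named parameter sets for the simulated study conditions. The shared actor
#' gains are `A_G = 2.5`, `A_N = 1`, `A_E = 1`, `lambda_G = 1`,
#' `lambda_N = -1`; the condition-specific parameters are the discount factor
#' `gamma`, the exploration width `sigma`, and the dopamine clamp
#' (`delta_lim`, `delta_med`):
#'
#' | preset               | gamma | sigma | delta_lim | delta_med |
#' |----------------------|-------|-------|-----------|-----------|
#' | `cowie_control`      | 0.80  | 0.30  | --        | 0         |
#' | `cowie_pd_off`       | 0.10  | 0.01  | -0.1      | 0         |
#' | `cowie_pd_on`        | 0.10  | 0.15  | -0.1      | 0.12      |
#' | `almeida_control`    | 0.85  | 0.23  | --        | 0         |
#' | `almeida_nonfreezer` | 0.80  | 0.22  | -0.1      | 0.12      |
#' | `almeida_freezer`    | 0.75  | 0.02  | -0.1      | 0.12      |
#'
#' The `cowie_*` presets model healthy controls and PD freezers OFF/ON
#' dopaminergic medication (stride-length study); the `almeida_*` presets
#' model controls, PD non-freezers and PD freezers, all ON medication
#' (step-length study).
#'
#' @param name Preset name (see table).
#' @param eta Critic learning rate (shared across conditions).
#' @return An object of class `condition_preset`: list with `name`, `study`,
#'   `condition`, `gen` ([gen_params()]), `dopamine`
#'   ([dopamine_condition()]), `gamma` and `eta`.
#' @export
condition_preset <- function(name = c("cowie_control", "cowie_pd_off",
                                      "cowie_pd_on", "almeida_control",
                                      "almeida_nonfreezer", "almeida_freezer"),
                             eta = 2e-4) {
  name <- match.arg(name)
  tab <- list(
    cowie_control      = list(study = "cowie",   gamma = 0.80, sigma = 0.30, mode = "control", delta_med = 0),
    cowie_pd_off       = list(study = "cowie",   gamma = 0.10, sigma = 0.01, mode = "pd_off",  delta_med = 0),
    cowie_pd_on        = list(study = "cowie",   gamma = 0.10, sigma = 0.15, mode = "pd_on",   delta_med = 0.12),
    almeida_control    = list(study = "almeida", gamma = 0.85, sigma = 0.23, mode = "control", delta_med = 0),
    almeida_nonfreezer = list(study = "almeida", gamma = 0.80, sigma = 0.22, mode = "pd_on",   delta_med = 0.12),
    almeida_freezer    = list(study = "almeida", gamma = 0.75, sigma = 0.02, mode = "pd_on",   delta_med = 0.12))
  p <- tab[[name]]
  structure(list(
    name = name, study = p$study,
    condition = sub("^(cowie|almeida)_", "", name),
    gen = gen_params(sigma = p$sigma),
    dopamine = dopamine_condition(p$mode, delta_lim = -0.1,
                                  delta_med = p$delta_med),
    gamma = p$gamma, eta = eta
  ), class = "condition_preset")
}

#' @export
print.condition_preset <- function(x, ...) {
  d <- x$dopamine
  cat(sprintf("Condition preset '%s' (%s study)\n", x$name, x$study))
  cat(sprintf("  gamma = %g, sigma = %g, mode = %s, delta_lim = %s, delta_med = %g, eta = %g\n",
              x$gamma, x$gen$sigma, d$mode,
              ifelse(is.na(d$delta_lim), "-", format(d$delta_lim)), d$delta_med,
              x$eta))
  invisible(x)
}

#' Build a custom condition preset
#'
#' Like [condition_preset()] but with explicit parameters, for parameter
#' sweeps.
#'
#' @param gamma Discount factor.
#' @param sigma Exploration width.
#' @param mode Dopamine mode.
#' @param delta_lim,delta_med Clamp parameters.
#' @param eta Critic learning rate.
#' @param name Label.
#' @export
custom_preset <- function(gamma, sigma, mode = "control",
                          delta_lim = -0.1, delta_med = 0, eta = 2e-4,
                          name = "custom") {
  structure(list(
    name = name, study = "custom", condition = mode,
    gen = gen_params(sigma = sigma),
    dopamine = dopamine_condition(mode, delta_lim = delta_lim,
                                  delta_med = delta_med),
    gamma = gamma, eta = eta
  ), class = "condition_preset")
}
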