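#' GO/EXPLORE/NOGO policy parameters
#'
#' The actor updates the displacement (velocity) command by blending three
#' regimes as a function of the value-difference signal `s`:
#' \deqn{\Delta X(t) = A_G\,\mathrm{sig}(\lambda_G s)\,\Delta X(t-1)
#'   + A_E\,\chi\,e^{-s^2/\sigma^2}
#'   - A_N\,\mathrm{sig}(\lambda_N s)\,\Delta X(t-1)}
#' with `sig(x) = 1/(1+exp(-x))` and `chi` a fresh uniform draw in
#' `[-0.5, 0.5]` per component. Rising value (GO) repeats and amplifies the
#' previous command, falling value (NOGO) damps or reverses it, and near-zero
#' value change opens the Gaussian exploration gate of width `sigma`.
#'
#' @param A_G,A_N,A_E Gains of the GO, NOGO and EXPLORE terms.
#' @param lambda_G,lambda_N Sigmoid slopes of the GO and NOGO terms.
#' @param sigma Exploration width (the Gaussian gate's scale).
#' @param D_hi,D_lo Thresholds of the discrete three-branch rule
#'   ([gen_step_discrete()]); unused by the continuous policy.
#' @return An object of class `gen_params`.
#' @export
gen_params <- function(A_G = 2.5, A_N = 1, A_E = 1,
                       lambda_G = 1, lambda_N = -1, sigma = 0.3,
                       D_hi = 0.1, D_lo = -0.1) {
  stopifnot(A_G >= 0, A_N >= 0, A_E >= 0, sigma > 0, D_lo < 0, D_hi > 0)
  structure(list(A_G = A_G, A_N = A_N, A_E = A_E,
                 lambda_G = lambda_G, lambda_N = lambda_N, sigma = sigma,
                 D_hi = D_hi, D_lo = D_lo), class = "gen_params")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Continuous GO/EXPLORE/NOGO displacement update
#'
#' @param delta_v Switching signal (value difference; under PD conditions the
#'   clamped TD error may be substituted, see [train_agent()]).
#' @param dx_prev Previous displacement command, numeric `c(vx, vy)`.
#' @param params A [gen_params()].
#' @param chi Optional injected exploration draw (numeric length 2); by
#'   default two uniforms in `[-0.5, 0.5]` are drawn from the R random stream.
#' @return New displacement command `c(vx, vy)`.
#' @export
gen_step <- function(delta_v, dx_prev, params, chi = NULL) {
  stopifnot(inherits(params, "gen_params"), length(dx_prev) == 2,
            all(is.finite(dx_prev)))
  if (is.null(chi)) chi <- stats::runif(2, -0.5, 0.5)
  go <- params$A_G * sigmoid(params$lambda_G * delta_v)
  nogo <- params$A_N * sigmoid(params$lambda_N * delta_v)
  explore <- params$A_E * exp(-delta_v^2 / params$sigma^2)
  (go - nogo) * dx_prev + explore * chi
}

#' Discrete GO/EXPLORE/NOGO rule
#'
#' The three-branch reference rule: repeat the previous displacement when the
#' value rose by more than `D_hi`, reverse it when the value fell below
#' `D_lo`, and move randomly in between. Used as a limit reference for the
#' continuous policy, not in the main experiments.
#'
#' @inheritParams gen_step
#' @export
gen_step_discrete <- function(delta_v, dx_prev, params, chi = NULL) {
  stopifnot(inherits(params, "gen_params"), length(dx_prev) == 2)
  if (is.null(chi)) chi <- stats::runif(2, -0.5, 0.5)
  if (delta_v > params$D_hi) return(dx_prev)
  if (delta_v <= params$D_lo) return(-dx_prev)
  chi
}
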