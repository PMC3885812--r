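#' Critic state
#'
#' The critic approximates the value of a view vector `phi` as
#' `V = tanh(sum(W * phi))` and is trained by the temporal-difference (TD)
#' rule `W <- W + eta * delta * phi`. The TD error `delta` is the model's
#' dopamine correlate.
#'
#' The default learning rate keeps the value field graded (unsaturated) over
#' the standard 100 training passes; see the methods vignette for the
#' calibration rationale.
#'
#' @param n_sectors Length of the weight vector (one weight per view sector).
#' @param eta Learning rate.
#' @param gamma Discount factor in `[0, 1]`.
#' @param W Optional initial weights (default all zero).
#' @return An object of class `critic_state`.
#' @export
critic_state <- function(n_sectors = 50, eta = 2e-4, gamma = 0.8, W = NULL) {
  if (is.null(W)) W <- numeric(n_sectors)
  stopifnot(length(W) == n_sectors, all(is.finite(W)),
            eta >= 0, gamma >= 0, gamma <= 1)
  structure(list(W = W, eta = eta, gamma = gamma), class = "critic_state")
}

#' Value of a view vector
#'
#' `V = tanh(sum(W * phi))`, bounded in `(-1, 1)`.
#'
#' @param critic A [critic_state()].
#' @param phi Binary view vector.
#' @return Scalar value.
#' @export
value <- function(critic, phi) {
  stopifnot(inherits(critic, "critic_state"))
  if (length(phi) != length(critic$W))
    stop("view vector length does not match critic weights")
  tanh(sum(critic$W * phi))
}

#' Temporal-difference error
#'
#' `delta = r + gamma * V(t) - V(t-1)`. At terminal states (passage or
#' collision ending the pass) the bootstrap value `V(t)` is taken as 0, so the
#' terminal TD error is `delta = r - V(t-1)`.
#'
#' @param r Reward received on the transition.
#' @param v_t Value of the new state (ignored when `terminal`).
#' @param v_tm1 Value of the previous state.
#' @param gamma Discount factor.
#' @param terminal Whether the transition ended the pass.
#' @export
td_error <- function(r, v_t, v_tm1, gamma, terminal = FALSE) {
  if (terminal) v_t <- 0
  r + gamma * v_t - v_tm1
}

#' Dopamine condition
#'
#' Parkinsonian conditions are modelled by constraining the TD error:
#' in the OFF state `delta` is clamped from above at `delta_lim`;
#' in the ON (medicated) state the clamped signal is raised by `delta_med`.
#' Controls are unconstrained.
#'
#' @param mode One of `"control"`, `"pd_off"`, `"pd_on"`.
#' @param delta_lim Clamp ceiling (TD-error units); ignored for controls.
#' @param delta_med Medication offset; must be 0 unless `mode = "pd_on"`.
#' @return An object of class `dopamine_condition`.
#' @export
dopamine_condition <- function(mode = c("control", "pd_off", "pd_on"),
                               delta_lim = -0.1, delta_med = 0) {
  mode <- match.arg(mode)
  if (mode == "pd_off" && delta_med != 0)
    stop("pd_off requires delta_med = 0")
  if (mode == "control") { delta_lim <- NA_real_; delta_med <- 0 }
  structure(list(mode = mode, delta_lim = delta_lim, delta_med = delta_med),
            class = "dopamine_condition")
}

#' Clamp the dopamine signal
#'
#' Control: identity. PD OFF: `min(delta, delta_lim)`. PD ON:
#' `min(delta, delta_lim) + delta_med` (the medication offset is added on both
#' branches of the clamp).
#'
#' @param delta Raw TD error.
#' @param condition A [dopamine_condition()].
#' @export
clamp_dopamine <- function(delta, condition) {
  stopifnot(inherits(condition, "dopamine_condition"))
  switch(condition$mode,
    control = delta,
    pd_off = pmin(delta, condition$delta_lim),
    pd_on = pmin(delta, condition$delta_lim) + condition$delta_med)
}

#' TD weight update
#'
#' `W <- W + eta * delta * phi`; only components with `phi_i = 1` change.
#'
#' @param critic A [critic_state()].
#' @param delta (Clamped) TD error driving the update.
#' @param phi View vector of the state whose value produced `V(t-1)`.
#' @return The updated `critic_state`.
#' @export
update_weights <- function(critic, delta, phi) {
  stopifnot(inherits(critic, "critic_state"),
            length(phi) == length(critic$W))
  critic$W <- critic$W + critic$eta * delta * phi
  critic
}

#' Value difference
#'
#' `delta_V = V(t) - V(t-1)`, the gradient signal driving the GO/EXPLORE/NOGO
#' policy. Coincides with the TD error when `gamma = 1` and the reward is zero.
#'
#' @param v_t,v_tm1 Successive values.
#' @export
value_difference <- function(v_t, v_tm1) v_t - v_tm1
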