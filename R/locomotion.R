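#' Velocity-to-amplitude gain
#'
#' The speed command from the actor modulates the oscillation amplitude
#' through the saturating gain `k = A_k * tanh(c_k * ||v||)`, with `A_k = 3`
#' and `c_k = 1` in all conditions, so `k` is in `[0, A_k)`.
#'
#' @param v_x,v_y Velocity command components (m/s).
#' @param A_k Gain amplitude.
#' @param c_k Gain slope.
#' @export
velocity_gain <- function(v_x, v_y, A_k = 3, c_k = 1) {
  stopifnot(A_k > 0, c_k > 0, is.finite(v_x), is.finite(v_y))
  A_k * tanh(c_k * sqrt(v_x^2 + v_y^2))
}

#' Modulate the learned output weights
#'
#' `alpha_f = alpha0 * k`: a uniform scaling of all output weights, which by
#' linearity of the network output scales the joint-angle trajectories by
#' exactly `k`.
#'
#' @param alpha0 Converged output weights (vector, or list of per-pool
#'   vectors).
#' @param k Gain from [velocity_gain()].
#' @export
modulate_amplitudes <- function(alpha0, k) {
  if (is.list(alpha0)) lapply(alpha0, `*`, k) else alpha0 * k
}

#' Kinematic leg geometry
#'
#' Thigh length `l1 = 0.5` m and shank length `l2 = 0.6` m. `mode` selects
#' whether displacements are full strides (two steps; both hip-angle extrema
#' terms) or single steps (first extremum term only).
#'
#' @param l1,l2 Segment lengths (m).
#' @param mode `"stride"` or `"step"`.
#' @export
gait_geometry <- function(l1 = 0.5, l2 = 0.6, mode = c("stride", "step")) {
  stopifnot(l1 > 0, l2 > 0)
  structure(list(l1 = l1, l2 = l2, mode = match.arg(mode)),
            class = "gait_geometry")
}

#' Second and third hip-angle extrema of a cycle
#'
#' Each extremum of the hip angle marks a step (the knee angles are
#' approximately zero there, so the legs are maximally split); the 2nd and
#' 3rd extrema of a cycle bound one stride. Returns their magnitudes.
#'
#' @param theta_h Hip-angle trajectory over one full cycle, starting at the
#'   first extremum (as stored by [train_cpg()]).
#' @return Named numeric `c(ext2, ext3)`, radians (magnitudes).
#' @export
joint_extrema <- function(theta_h) {
  if (all(abs(theta_h) < 1e-12)) stop("degenerate trajectory: no extrema")
  idx <- cycle_extrema(theta_h)
  if (length(idx) != 3L)
    stop(sprintf("expected 3 hip-angle extrema per cycle, found %d", length(idx)))
  n <- length(theta_h)
  val <- function(i) if (i > n) theta_h[1] else theta_h[i]
  c(ext2 = abs(val(idx[2])), ext3 = abs(val(idx[3])))
}

#' Stride or step length from hip-angle extrema
#'
#' `L = 2(l1+l2) sin(ext2/2) + 2(l1+l2) sin(ext3/2)` in stride mode; step
#' mode keeps only the first term.
#'
#' @param extrema Named numeric `c(ext2, ext3)` (radians, magnitudes, in
#'   `[0, pi)`).
#' @param geometry A [gait_geometry()].
#' @export
stride_length <- function(extrema, geometry = gait_geometry()) {
  stopifnot(inherits(geometry, "gait_geometry"))
  e2 <- extrema[["ext2"]]
  e3 <- if ("ext3" %in% names(extrema)) extrema[["ext3"]] else 0
  if (e2 < 0 || e3 < 0) stop("extrema must be non-negative magnitudes")
  leg <- 2 * (geometry$l1 + geometry$l2)
  if (geometry$mode == "step") leg * sin(e2 / 2)
  else leg * sin(e2 / 2) + leg * sin(e3 / 2)
}

#' Advance the agent's position
#'
#' Displaces the agent by `L_STR` along the unit vector of the velocity
#' command. When the forward component `v_y` is negative the displacement
#' magnitude is replaced by a small constant (0.0001 m) so the agent does not
#' make backward progress away from the door (`backward_rule = "tiny_step"`,
#' default) or, alternatively, holds its position (`"hold"`).
#'
#' @param position Numeric `c(x, y)`.
#' @param L_STR Stride/step length (m).
#' @param v_x,v_y Velocity command.
#' @param backward_eps Magnitude of the suppressed backward step (m).
#' @param backward_rule `"tiny_step"` or `"hold"`.
#' @return New position `c(x, y)`.
#' @export
advance_position <- function(position, L_STR, v_x, v_y,
                             backward_eps = 1e-4,
                             backward_rule = c("tiny_step", "hold")) {
  backward_rule <- match.arg(backward_rule)
  nrm <- sqrt(v_x^2 + v_y^2)
  if (nrm < 1e-12) return(c(position[[1]], position[[2]]))
  if (v_y < 0) {
    if (backward_rule == "hold") return(c(position[[1]], position[[2]]))
    L_STR <- backward_eps
  }
  c(position[[1]] + L_STR * v_x / nrm, position[[2]] + L_STR * v_y / nrm)
}
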