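#' Corridor-and-doorway track geometry
#'
#' Defines the simulated corridor: a track spanning `x` in `[-2, 2]` m and `y`
#' in `[0, 10]` m, with a doorway of width `d_length` centred at `x = 0` in the
#' end wall at `y = 10`. The walking agent has a circular body of diameter 1 m
#' (radius 0.5 m), so the passable slot of a door of half-width `d_pos` is
#' `|x| <= d_pos - agent_radius` at the door line.
#'
#' Door presets follow the simulated study conditions: 3 m ("wide"),
#' 2.5 m ("medium") and 2 m ("narrow").
#'
#' @param door Door preset name (`"wide"`, `"medium"`, `"narrow"`) or a numeric
#'   door width in metres.
#' @param x_max Half-width of the track (m); the track spans `[-x_max, x_max]`.
#' @param y_door Position of the door line along the track (m).
#' @param y_start Starting `y` position of the agent (m).
#' @param agent_radius Radius of the agent's circular body (m).
#' @return An object of class `track_geometry`.
#' @examples
#' geom <- track_geometry("narrow")
#' geom$d_pos  # 1 m half-width
#' @export
track_geometry <- function(door = c("narrow", "medium", "wide"),
                           x_max = 2, y_door = 10, y_start = 0.1,
                           agent_radius = 0.5) {
  if (is.character(door)) {
    door <- match.arg(door)
    d_length <- c(wide = 3, medium = 2.5, narrow = 2)[[door]]
    name <- door
  } else {
    stopifnot(is.numeric(door), length(door) == 1L, is.finite(door), door >= 0)
    d_length <- door
    name <- sprintf("%.3g m", door)
  }
  d_pos <- d_length / 2
  if (d_pos > 0 && d_pos <= agent_radius)
    stop("door is not passable: d_pos must exceed agent_radius")
  if (-d_pos < -x_max || d_pos > x_max)
    stop("door wider than the track")
  structure(list(
    x_min = -x_max, x_max = x_max,
    y_start = y_start, y_door = y_door,
    d_length = d_length, d_pos = d_pos,
    agent_radius = agent_radius, door = name
  ), class = "track_geometry")
}

#' @export
print.track_geometry <- function(x, ...) {
  cat(sprintf(
    "Track geometry: x in [%g, %g] m, door line at y = %g m\n  door '%s': width %g m (half-width %g m), agent radius %g m\n",
    x$x_min, x$x_max, x$y_door, x$door, x$d_length, x$d_pos, x$agent_radius))
  invisible(x)
}

#' Reward schedule of the doorway task
#'
#' Reward is delivered only at salient events: `+5` for successful passage
#' through the doorway, `-1` for collisions (door frame or track boundary),
#' `0` elsewhere.
#'
#' @param r_pass Reward for passing the door.
#' @param r_collision Reward (punishment) for a collision.
#' @param r_elsewhere Reward everywhere else.
#' @return An object of class `reward_schedule`.
#' @export
reward_schedule <- function(r_pass = 5, r_collision = -1, r_elsewhere = 0) {
  stopifnot(r_pass > 0, r_collision < 0)
  structure(list(r_pass = r_pass, r_collision = r_collision,
                 r_elsewhere = r_elsewhere), class = "reward_schedule")
}

#' Draw the starting position of a pass
#'
#' The agent starts every pass at `y = y_start` (0.1 m) with `x` drawn
#' uniformly over the interior in which its body fits,
#' `|x| <= x_max - agent_radius`. The initial orientation (set by the caller)
#' points at the door centre.
#'
#' @param geometry A [track_geometry()].
#' @param u Optional uniform deviate in `[0, 1]` replacing the random draw
#'   (used for deterministic tests); by default one deviate is drawn from the
#'   R random stream.
#' @return Numeric `c(x, y)` start position.
#' @export
reset_start <- function(geometry, u = NULL) {
  stopifnot(inherits(geometry, "track_geometry"))
  if (is.null(u)) u <- stats::runif(1)
  stopifnot(u >= 0, u <= 1)
  half <- geometry$x_max - geometry$agent_radius
  c(x = -half + 2 * half * u, y = geometry$y_start)
}

#' Evaluate the outcome of one displacement step
#'
#' Classifies the step from `old_position` to `new_position`:
#' * `passed_door` -- the segment crosses the door line with the crossing point
#'   inside the passable slot (`|x| <= d_pos - agent_radius`); terminal,
#'   reward `r_pass`.
#' * `hit_door_post` -- the segment crosses the door line outside the passable
#'   slot (the body overlaps a door post / end wall); terminal, reward
#'   `r_collision`.
#' * `hit_wall` -- the body overlaps a side wall (`|x| > x_max - agent_radius`).
#'   Under the default `wall_rule = "clip"` the agent is pushed back to the
#'   boundary, punished, and the pass continues (the position is reported in
#'   the `position` field); under `"terminal"` the pass ends.
#' * `ongoing` -- anything else; reward `r_elsewhere`.
#'
#' The door-line test is applied at the crossing point of the step's line
#' segment with `y = y_door`.
#'
#' @param geometry A [track_geometry()].
#' @param schedule A [reward_schedule()].
#' @param old_position,new_position Numeric `c(x, y)`.
#' @param wall_rule `"clip"` (punish and slide along the boundary) or
#'   `"terminal"` (end the pass).
#' @return A list of class `step_outcome` with fields `reward`, `terminal`,
#'   `cause` and `position` (the possibly corrected new position).
#' @export
evaluate_step <- function(geometry, schedule, old_position, new_position,
                          wall_rule = c("clip", "terminal")) {
  stopifnot(inherits(geometry, "track_geometry"),
            inherits(schedule, "reward_schedule"))
  wall_rule <- match.arg(wall_rule)
  if (geometry$d_pos <= geometry$agent_radius)
    stop("malformed geometry: door not passable (d_pos <= agent_radius)")
  ox <- old_position[[1]]; oy <- old_position[[2]]
  nx <- new_position[[1]]; ny <- new_position[[2]]
  out <- function(reward, terminal, cause, pos)
    structure(list(reward = reward, terminal = terminal, cause = cause,
                   position = pos), class = "step_outcome")

  if (oy < geometry$y_door && ny >= geometry$y_door) {
    # crossing point of the segment with the door line
    xc <- ox + (nx - ox) * (geometry$y_door - oy) / (ny - oy)
    if (abs(xc) <= geometry$d_pos - geometry$agent_radius)
      return(out(schedule$r_pass, TRUE, "passed_door", c(nx, ny)))
    return(out(schedule$r_collision, TRUE, "hit_door_post", c(xc, geometry$y_door)))
  }
  lim <- geometry$x_max - geometry$agent_radius
  if (abs(nx) > lim) {
    if (wall_rule == "terminal")
      return(out(schedule$r_collision, TRUE, "hit_wall", c(nx, ny)))
    return(out(schedule$r_collision, FALSE, "hit_wall", c(sign(nx) * lim, ny)))
  }
  out(schedule$r_elsewhere, FALSE, "ongoing", c(nx, ny))
}
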