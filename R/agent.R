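#' Simulation controls for doorway passes
#'
#' Collects the episode-lifecycle and policy-wiring options shared by
#' training and testing runs.
#'
#' @param max_steps Step cap per pass (bounds freezing runs).
#' @param wall_rule Side-wall handling: `"clip"` (punish and slide, default)
#'   or `"terminal"`.
#' @param clamp_switching If `TRUE`, the clamped TD error (rather than the raw
#'   value difference) is used as the GO/EXPLORE/NOGO switching signal under
#'   PD conditions.
#' @param orientation `"displacement"` (gaze follows the last executed step)
#'   or `"door"` (gaze always at the door centre).
#' @param backward_rule Handling of backward velocity commands, see
#'   [advance_position()].
#' @param backward_eps Magnitude of the suppressed backward step (m).
#' @param dx0 Magnitude of the initial forward displacement command seeding
#'   the policy recursion (m, aimed at the door centre).
#' @param n_sectors,fov View-vector resolution.
#' @export
pass_controls <- function(max_steps = 500, wall_rule = c("clip", "terminal"),
                          clamp_switching = FALSE,
                          orientation = c("displacement", "door"),
                          backward_rule = c("tiny_step", "hold"),
                          backward_eps = 1e-4, dx0 = 0.1,
                          n_sectors = 50, fov = 120) {
  structure(list(max_steps = max_steps, wall_rule = match.arg(wall_rule),
                 clamp_switching = isTRUE(clamp_switching),
                 orientation = match.arg(orientation),
                 backward_rule = match.arg(backward_rule),
                 backward_eps = backward_eps, dx0 = dx0,
                 n_sectors = n_sectors, fov = fov),
            class = "pass_controls")
}

# argument lists for the compiled engine
cpp_pars <- function(preset, controls) {
  g <- preset$gen; d <- preset$dopamine
  list(A_G = g$A_G, A_N = g$A_N, A_E = g$A_E,
       lambda_G = g$lambda_G, lambda_N = g$lambda_N, sigma = g$sigma,
       gamma = preset$gamma, eta = preset$eta,
       mode = match(d$mode, c("control", "pd_off", "pd_on")) - 1L,
       delta_lim = ifelse(is.na(d$delta_lim), 0, d$delta_lim),
       delta_med = d$delta_med,
       clamp_switching = controls$clamp_switching)
}

cpp_geom <- function(geometry, controls) {
  list(x_max = geometry$x_max, y_door = geometry$y_door,
       y_start = geometry$y_start, d_pos = geometry$d_pos,
       agent_radius = geometry$agent_radius,
       wall_terminal = controls$wall_rule == "terminal")
}

cpp_loco <- function(cpg, gait, controls) {
  list(e2 = cpg$hip_extrema[["ext2"]], e3 = cpg$hip_extrema[["ext3"]],
       leg = 2 * (gait$l1 + gait$l2), A_k = 3, c_k = 1,
       step_mode = gait$mode == "step",
       backward_eps = controls$backward_eps,
       backward_hold = controls$backward_rule == "hold",
       dx0 = controls$dx0)
}

outcome_levels <- c("max_steps", "passed_door", "hit_door_post", "hit_wall")

#' Run a single doorway pass (reference engine)
#'
#' Pure-R episode loop assembled from the exported module operations
#' ([view_vector_at()], [value()], [gen_step()], [td_error()],
#' [clamp_dopamine()], [update_weights()], [velocity_gain()],
#' [stride_length()], [evaluate_step()]). The compiled engine used by
#' [train_agent()] replicates these semantics step for step (including the
#' random-draw order), which the test suite verifies; this function is the
#' readable reference and is practical for small runs.
#'
#' @param critic A [critic_state()] (its `W`, `eta`, `gamma` are used).
#' @param learn Update the critic weights during the pass?
#' @param preset A [condition_preset()].
#' @param geometry A [track_geometry()].
#' @param cpg A [train_cpg()] fit.
#' @param gait A [gait_geometry()].
#' @param controls A [pass_controls()].
#' @return List with `record` (matrix: start position, executed velocity,
#'   stride, reward, value and switching signal per step), `outcome` and the
#'   updated `critic`.
#' @export
run_pass_r <- function(critic, learn, preset, geometry, cpg,
                       gait = gait_geometry(), controls = pass_controls()) {
  sched <- reward_schedule()
  start <- reset_start(geometry)
  x <- start[[1]]; y <- start[[2]]
  ro <- door_direction(c(x, y), geometry)
  dx <- controls$dx0 * ro
  phi <- view_vector_at(c(x, y), ro, geometry, controls$n_sectors, controls$fov)
  V <- value(critic, phi)
  sw <- 0
  e2 <- cpg$hip_extrema[["ext2"]]; e3 <- cpg$hip_extrema[["ext3"]]
  rec <- matrix(NA_real_, controls$max_steps, 8,
                dimnames = list(NULL, c("x", "y", "vx", "vy", "stride",
                                        "reward", "V", "signal")))
  outcome <- "max_steps"
  pd <- preset$dopamine$mode != "control"
  for (t in seq_len(controls$max_steps)) {
    dx <- gen_step(sw, dx, preset$gen)
    nv <- sqrt(sum(dx^2))
    if (nv < 1e-12) { vhat <- ro; k <- 0 } else {
      vhat <- dx / nv
      k <- velocity_gain(dx[1], dx[2])
    }
    L <- stride_length(c(ext2 = k * e2, ext3 = k * e3), gait)
    if (dx[2] < 0)
      L <- if (controls$backward_rule == "hold") 0 else controls$backward_eps
    proposed <- c(x, y) + L * vhat
    out <- evaluate_step(geometry, sched, c(x, y), proposed,
                         wall_rule = controls$wall_rule)
    rec[t, ] <- c(x, y, L * vhat[1], L * vhat[2], L, out$reward, V, sw)
    if (out$terminal) {
      pos <- proposed            # terminal position is not used further
    } else pos <- out$position
    x <- pos[[1]]; y <- pos[[2]]
    if (controls$orientation == "door") {
      if (y < geometry$y_door) ro <- door_direction(c(x, y), geometry)
    } else if (L > 1e-3) ro <- vhat
    if (out$terminal) {
      V2 <- 0
    } else {
      phi2 <- view_vector_at(c(x, y), ro, geometry, controls$n_sectors,
                             controls$fov)
      V2 <- value(critic, phi2)
    }
    delta <- td_error(out$reward, V2, V, preset$gamma, terminal = out$terminal)
    delta_c <- clamp_dopamine(delta, preset$dopamine)
    if (learn) critic <- update_weights(critic, delta_c, phi)
    sw <- if (controls$clamp_switching && pd) delta_c else value_difference(V2, V)
    if (out$terminal) {
      outcome <- out$cause
      rec <- rec[seq_len(t), , drop = FALSE]
      return(list(record = rec, outcome = outcome, critic = critic))
    }
    phi <- phi2; V <- V2
  }
  list(record = rec, outcome = outcome, critic = critic)
}

run_pass_engine <- function(W, learn, preset, geometry, cpg, gait, controls,
                            engine) {
  if (engine == "cpp") {
    res <- run_pass_cpp(W, learn, cpp_pars(preset, controls),
                        cpp_geom(geometry, controls),
                        cpp_loco(cpg, gait, controls),
                        controls$max_steps, controls$n_sectors, controls$fov,
                        ifelse(controls$orientation == "door", 1L, 0L))
    list(record = res$record,
         outcome = outcome_levels[res$outcome + 1L],
         W = res$W)
  } else {
    cr <- critic_state(controls$n_sectors, eta = preset$eta,
                       gamma = preset$gamma, W = W)
    res <- run_pass_r(cr, learn, preset, geometry, cpg, gait, controls)
    list(record = res$record, outcome = res$outcome, W = res$critic$W)
  }
}

#' Train a doorway-walking agent
#'
#' The model-fitting entry point: trains the critic of an actor-critic
#' basal-ganglia model by letting the agent repeatedly walk a corridor to a
#' doorway (100 passes by default) under a condition preset, with the
#' GO/EXPLORE/NOGO policy selecting velocity commands and the trained CPG
#' translating them into strides. Returns a fitted agent whose value weights
#' are frozen for subsequent test runs ([simulate.gait_agent()]).
#'
#' @param preset A [condition_preset()] (or preset name).
#' @param door Door preset or width, see [track_geometry()].
#' @param cpg A [train_cpg()] fit (required).
#' @param n_passes Number of training passes.
#' @param seed Optional integer seed (set before training).
#' @param gait_mode `"stride"` or `"step"`; defaults to `"step"` for the
#'   `almeida_*` presets and `"stride"` otherwise.
#' @param controls A [pass_controls()].
#' @param engine `"cpp"` (default) or `"R"` (reference engine, slow).
#' @return An object of class `gait_agent`.
#' @seealso [simulate.gait_agent()], [predict.gait_agent()],
#'   [doorway_statistics()]
#' @export
train_agent <- function(preset, door = "narrow", cpg, n_passes = 100,
                        seed = NULL, gait_mode = NULL,
                        controls = pass_controls(),
                        engine = c("cpp", "R")) {
  if (is.character(preset)) preset <- condition_preset(preset)
  stopifnot(inherits(preset, "condition_preset"), inherits(cpg, "cpg_network"))
  engine <- match.arg(engine)
  geometry <- if (inherits(door, "track_geometry")) door else track_geometry(door)
  if (is.null(gait_mode))
    gait_mode <- if (identical(preset$study, "almeida")) "step" else "stride"
  gait <- gait_geometry(mode = gait_mode)
  if (!is.null(seed)) set.seed(seed)
  W <- numeric(controls$n_sectors)
  outcomes <- character(n_passes)
  steps <- integer(n_passes)
  for (i in seq_len(n_passes)) {
    res <- run_pass_engine(W, TRUE, preset, geometry, cpg, gait, controls,
                           engine)
    W <- res$W
    outcomes[i] <- res$outcome
    steps[i] <- nrow(res$record)
  }
  structure(list(
    preset = preset, geometry = geometry, gait = gait, controls = controls,
    cpg = cpg, engine = engine, n_passes = n_passes, seed = seed,
    critic = critic_state(controls$n_sectors, eta = preset$eta,
                          gamma = preset$gamma, W = W),
    training = list(outcomes = table(factor(outcomes, outcome_levels)),
                    steps_per_pass = steps)
  ), class = "gait_agent")
}

#' @export
print.gait_agent <- function(x, ...) {
  cat(sprintf("Doorway-walking agent: preset '%s', door '%s' (%s mode)\n",
              x$preset$name, x$geometry$door, x$gait$mode))
  cat(sprintf("  trained %d passes; outcomes: %s\n", x$n_passes,
              paste(names(x$training$outcomes), as.integer(x$training$outcomes),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  critic |W| in [%.3g, %.3g]\n",
              min(x$critic$W), max(x$critic$W)))
  invisible(x)
}

#' @export
coef.gait_agent <- function(object, ...) object$critic$W

#' @export
summary.gait_agent <- function(object, ...) {
  mid <- vapply(seq(0.5, 9.5, by = 1), function(y)
    value(object$critic,
          view_vector_at(c(0, y), c(0, 1), object$geometry,
                         object$controls$n_sectors, object$controls$fov)),
    numeric(1))
  out <- list(agent = object, midline_value = mid,
              midline_y = seq(0.5, 9.5, by = 1))
  class(out) <- "summary.gait_agent"
  out
}

#' @export
print.summary.gait_agent <- function(x, ...) {
  print(x$agent)
  cat("  door-facing midline value V(0, y):\n")
  print(round(stats::setNames(x$midline_value, x$midline_y), 3))
  invisible(x)
}

#' Value landscape over the corridor
#'
#' Evaluates the trained value function on a spatial grid, either with the
#' door-facing orientation at every point or averaged over a uniform set of
#' orientations (those pointing away from the door see no door and contribute
#' the value of the empty view).
#'
#' @param object A `gait_agent`.
#' @param mode `"door_facing"` or `"orientation_averaged"`.
#' @param n_orientations Number of orientations averaged in
#'   `"orientation_averaged"` mode.
#' @param dx,dy Grid spacing (m).
#' @param ... Unused.
#' @return An object of class `value_landscape`: list with `x`, `y` and the
#'   value matrix `V` (`length(x)` x `length(y)`).
#' @export
predict.gait_agent <- function(object, mode = c("door_facing",
                                                "orientation_averaged"),
                               n_orientations = 36, dx = 0.1, dy = 0.1, ...) {
  mode <- match.arg(mode)
  value_landscape(object$critic, object$geometry, mode, n_orientations,
                  dx = dx, dy = dy,
                  n_sectors = object$controls$n_sectors,
                  fov = object$controls$fov)
}

#' @rdname predict.gait_agent
#' @param critic A [critic_state()].
#' @param geometry A [track_geometry()].
#' @param n_sectors,fov View-vector resolution.
#' @export
value_landscape <- function(critic, geometry,
                            mode = c("door_facing", "orientation_averaged"),
                            n_orientations = 36, dx = 0.1, dy = 0.1,
                            n_sectors = 50, fov = 120) {
  mode <- match.arg(mode)
  xs <- seq(geometry$x_min + geometry$agent_radius,
            geometry$x_max - geometry$agent_radius, by = dx)
  ys <- seq(geometry$y_start, geometry$y_door - dy, by = dy)
  angles <- 2 * pi * (seq_len(n_orientations) - 1) / n_orientations
  V <- matrix(NA_real_, length(xs), length(ys))
  for (j in seq_along(ys)) for (i in seq_along(xs)) {
    pos <- c(xs[i], ys[j])
    if (mode == "door_facing") {
      phi <- view_vector_at(pos, door_direction(pos, geometry), geometry,
                            n_sectors, fov)
      V[i, j] <- value(critic, phi)
    } else {
      vals <- vapply(angles, function(a)
        value(critic, view_vector_at(pos, c(sin(a), cos(a)), geometry,
                                     n_sectors, fov)), numeric(1))
      V[i, j] <- mean(vals)
    }
  }
  structure(list(x = xs, y = ys, V = V, mode = mode), class = "value_landscape")
}

#' @export
plot.value_landscape <- function(x, ...) {
  graphics::image(x$x, x$y, x$V, xlab = "x (m)", ylab = "y (m)",
                  main = sprintf("Value landscape (%s)", x$mode),
                  col = grDevices::hcl.colors(64, "RdYlBu", rev = TRUE), ...)
  graphics::contour(x$x, x$y, x$V, add = TRUE, drawlabels = FALSE,
                    col = grDevices::adjustcolor("black", 0.4))
  invisible(x)
}

#' @export
plot.gait_agent <- function(x, mode = "door_facing", ...) {
  plot(predict(x, mode = mode), ...)
  invisible(x)
}
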