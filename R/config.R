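#' Read a run configuration file
#'
#' YAML run configuration for the command-line tools. Recognised keys:
#' `preset`, `door`, `seed`, `n_train_passes`, `n_test_passes`,
#' `n_profiles`, `gait_mode`, `output_dir`, `cpg_file`, `eta`, and the nested
#' `flags` block (`wall_rule`, `clamp_switching`, `orientation`,
#' `backward_rule`, `max_steps`). Unknown keys are errors, not warnings, so
#' typos cannot silently change a run.
#'
#' @param path Path to a YAML file.
#' @return A named list of class `run_config` with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(preset = "cowie_control", door = "narrow", seed = 1L,
                   n_train_passes = 100L, n_test_passes = 100L,
                   n_profiles = 50L, gait_mode = NULL, output_dir = ".",
                   cpg_file = NULL, eta = 2e-4, flags = list())
  flag_defaults <- list(wall_rule = "clip", clamp_switching = FALSE,
                        orientation = "displacement",
                        backward_rule = "tiny_step", max_steps = 500L)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$flags)) {
    fu <- setdiff(names(cfg$flags), names(flag_defaults))
    if (length(fu))
      stop("unknown flag keys: ", paste(fu, collapse = ", "))
  }
  out <- utils::modifyList(defaults, cfg)
  out$flags <- utils::modifyList(flag_defaults,
                                 if (is.null(cfg$flags)) list() else cfg$flags)
  structure(out, class = "run_config")
}

#' Write a run configuration file
#'
#' @param config A list (or `run_config`).
#' @param path Output path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Pass controls from a run configuration
#'
#' @param config A [read_run_config()] result.
#' @export
controls_from_config <- function(config) {
  f <- config$flags
  pass_controls(max_steps = f$max_steps, wall_rule = f$wall_rule,
                clamp_switching = f$clamp_switching,
                orientation = if (f$orientation == "door") "door" else "displacement",
                backward_rule = f$backward_rule)
}

#' Emit deterministic test fixtures
#'
#' Writes small plain-text fixtures used by the unit tests and by downstream
#' checks: a scripted trajectory with its view vectors, a single-sinusoid
#' teaching signal, the free-run amplitude trace of a toy (single) Hopf
#' oscillator, and a hand-checkable three-pass training log of the critic.
#' All content is a deterministic function of `seed`.
#'
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(seed = 1, dir = tempfile("fixtures")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  geom <- track_geometry("narrow")

  # scripted trajectory + view vectors (door-facing)
  ys <- seq(0.5, 9.5, by = 1)
  xs <- round(stats::runif(length(ys), -1, 1), 3)
  vv <- t(vapply(seq_along(ys), function(i)
    view_vector_at(c(xs[i], ys[i]), door_direction(c(xs[i], ys[i]), geom),
                   geom), integer(50)))
  traj <- data.frame(x = xs, y = ys, ones = rowSums(vv))
  utils::write.csv(cbind(traj, vv), file.path(dir, "trajectory_views.csv"),
                   row.names = FALSE)

  # single-sinusoid teaching signal
  t <- (0:499) / 500
  utils::write.csv(data.frame(time = t, signal = 0.3 * sin(2 * pi * t)),
                   file.path(dir, "sinusoid_teach.csv"), row.names = FALSE)

  # toy Hopf oscillator amplitude relaxation (free run from z = 0.5)
  y <- c(0.5, 0)
  amp <- numeric(200)
  dt <- 1 / 500
  for (i in 1:200) {
    for (s in 1:5) {
      rhs <- function(v) {
        z2 <- v[1]^2 + v[2]^2
        c(8 * (1 - z2) * v[1] - 2 * pi * v[2],
          8 * (1 - z2) * v[2] + 2 * pi * v[1])
      }
      k1 <- rhs(y); k2 <- rhs(y + dt / 2 * k1)
      k3 <- rhs(y + dt / 2 * k2); k4 <- rhs(y + dt * k3)
      y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    amp[i] <- sqrt(sum(y^2))
  }
  utils::write.csv(data.frame(step = 1:200, amplitude = amp),
                   file.path(dir, "toy_hopf_amplitude.csv"), row.names = FALSE)

  # three-pass critic training log on a fixed two-state world
  cr <- critic_state(4, eta = 0.1, gamma = 0.8)
  phiA <- c(1L, 1L, 0L, 0L); phiB <- c(0L, 1L, 1L, 1L)
  log <- list()
  for (pass in 1:3) {
    vA <- value(cr, phiA); vB <- value(cr, phiB)
    d1 <- td_error(0, vB, vA, 0.8)
    cr <- update_weights(cr, d1, phiA)
    d2 <- td_error(5, 0, value(cr, phiB), 0.8, terminal = TRUE)
    cr <- update_weights(cr, d2, phiB)
    log[[pass]] <- data.frame(pass = pass, V_A = vA, V_B = vB,
                              delta_mid = d1, delta_end = d2,
                              W1 = cr$W[1], W2 = cr$W[2], W3 = cr$W[3],
                              W4 = cr$W[4])
  }
  utils::write.csv(do.call(rbind, log),
                   file.path(dir, "critic_training_log.csv"),
                   row.names = FALSE)

  invisible(list.files(dir, full.names = TRUE))
}
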