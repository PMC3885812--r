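#' Reproduce the stride-length study (controls, PD ON, PD OFF)
#'
#' Runs the full stride-length protocol: for each condition preset
#' (`cowie_control`, `cowie_pd_on`, `cowie_pd_off`) and each door (wide 3 m,
#' medium 2.5 m, narrow 2 m), trains the critic for `n_train` passes and runs
#' `n_profiles` x `n_passes` frozen-weight test passes; collects normalized
#' velocity profiles, the stride-length table (mean, SD, SE over the N =
#' `n_profiles` per-trial means) and Welch comparisons between doors within
#' each condition and between conditions within each door.
#'
#' @param seed Integer seed controlling the whole run.
#' @param cpg A [train_cpg()] fit (trained on demand when omitted).
#' @param doors Door presets to run.
#' @param n_train Training passes per cell.
#' @param n_profiles Test profiles (trials) per cell.
#' @param n_passes Test passes per profile.
#' @param controls A [pass_controls()].
#' @param engine Simulation engine.
#' @param verbose Print progress.
#' @return An object of class `gait_study`.
#' @export
reproduce_cowie <- function(seed = 1, cpg = NULL,
                            doors = c("wide", "medium", "narrow"),
                            n_train = 100, n_profiles = 50, n_passes = 100,
                            controls = pass_controls(),
                            engine = "cpp", verbose = interactive()) {
  run_study("cowie", c("control", "pd_on", "pd_off"), seed, cpg, doors,
            n_train, n_profiles, n_passes, controls, engine, verbose)
}

#' Reproduce the step-length study (controls, non-freezers, freezers)
#'
#' As [reproduce_cowie()] but with the step-length presets
#' (`almeida_control`, `almeida_nonfreezer`, `almeida_freezer`), running in
#' step mode and additionally reporting the within-trial step-length
#' coefficient of variation.
#'
#' @inheritParams reproduce_cowie
#' @export
reproduce_almeida <- function(seed = 1, cpg = NULL,
                              doors = c("wide", "medium", "narrow"),
                              n_train = 100, n_profiles = 50, n_passes = 100,
                              controls = pass_controls(),
                              engine = "cpp", verbose = interactive()) {
  run_study("almeida", c("control", "nonfreezer", "freezer"), seed, cpg,
            doors, n_train, n_profiles, n_passes, controls, engine, verbose)
}

run_study <- function(study, conditions, seed, cpg, doors, n_train,
                      n_profiles, n_passes, controls, engine, verbose) {
  if (is.null(cpg)) {
    if (verbose) message("training CPG ...")
    cpg <- train_cpg(generate_teach_signals())
  }
  set.seed(seed)
  cell_seeds <- matrix(sample.int(.Machine$integer.max %/% 2,
                                  2 * length(conditions) * length(doors)),
                       ncol = 2)
  cells <- list()
  i <- 0L
  for (cond in conditions) for (door in doors) {
    i <- i + 1L
    preset <- condition_preset(paste(study, cond, sep = "_"))
    if (verbose) message(sprintf("  %s / %s ...", cond, door))
    agent <- train_agent(preset, door, cpg, n_passes = n_train,
                         seed = cell_seeds[i, 1], controls = controls,
                         engine = engine)
    trials <- simulate(agent, nsim = n_profiles, seed = cell_seeds[i, 2],
                       n_passes = n_passes)
    cells[[paste(cond, door, sep = ".")]] <-
      list(agent = agent, trials = trials, stats = doorway_statistics(trials))
  }

  tab <- do.call(rbind, lapply(cells, function(cl) {
    s <- cl$stats
    data.frame(condition = sub("^(cowie|almeida)_", "", s$preset),
               door = s$door, mode = s$mode, N = s$N, mean = s$mean,
               sd = s$sd, se = s$se, cv = s$cv, row.names = NULL)
  }))

  door_cmp <- list()
  for (cond in conditions) {
    prs <- utils::combn(doors, 2, simplify = FALSE)
    for (pr in prs) {
      cmp <- compare_groups(cells[[paste(cond, pr[1], sep = ".")]]$trials,
                            cells[[paste(cond, pr[2], sep = ".")]]$trials)
      door_cmp[[paste(cond, pr[1], pr[2], sep = ".")]] <-
        data.frame(condition = cond, door_a = pr[1], door_b = pr[2],
                   mean_a = cmp$mean_a, mean_b = cmp$mean_b,
                   t = cmp$statistic, df = cmp$df, p = cmp$p_value)
    }
  }
  cond_cmp <- list()
  for (door in doors) {
    prs <- utils::combn(conditions, 2, simplify = FALSE)
    for (pr in prs) {
      cmp <- compare_groups(cells[[paste(pr[1], door, sep = ".")]]$trials,
                            cells[[paste(pr[2], door, sep = ".")]]$trials)
      cond_cmp[[paste(door, pr[1], pr[2], sep = ".")]] <-
        data.frame(door = door, condition_a = pr[1], condition_b = pr[2],
                   mean_a = cmp$mean_a, mean_b = cmp$mean_b,
                   t = cmp$statistic, df = cmp$df, p = cmp$p_value)
    }
  }

  structure(list(
    study = study, seed = seed, doors = doors, conditions = conditions,
    table = tab,
    door_comparisons = do.call(rbind, c(door_cmp, list(make.row.names = FALSE))),
    condition_comparisons = do.call(rbind, c(cond_cmp, list(make.row.names = FALSE))),
    cells = cells, cpg = cpg,
    n_profiles = n_profiles, n_passes = n_passes, n_train = n_train
  ), class = "gait_study")
}

#' @export
print.gait_study <- function(x, digits = 4, ...) {
  cat(sprintf("Doorway gait study '%s' (seed %d): %d conditions x %d doors, N = %d trials/cell\n\n",
              x$study, x$seed, length(x$conditions), length(x$doors),
              x$n_profiles))
  print(x$table, digits = digits, row.names = FALSE)
  cat("\nDoor comparisons within condition (Welch t):\n")
  print(x$door_comparisons, digits = digits, row.names = FALSE)
  cat("\nCondition comparisons within door (Welch t):\n")
  print(x$condition_comparisons, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
plot.gait_study <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, length(x$doors)), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  cols <- stats::setNames(c("black", "tomato", "steelblue"), x$conditions)
  for (door in x$doors) {
    first <- TRUE
    for (cond in x$conditions) {
      tr <- x$cells[[paste(cond, door, sep = ".")]]$trials
      avg <- colMeans(tr$normalized, na.rm = TRUE)
      if (first) {
        graphics::plot(tr$grid, avg, type = "l", col = cols[cond], lwd = 2,
                       ylim = c(0, 160), xlab = "y (m)",
                       ylab = "velocity (% far-field)", main = door, ...)
        first <- FALSE
      } else graphics::lines(tr$grid, avg, col = cols[cond], lwd = 2)
    }
    graphics::abline(h = 100, lty = 3)
    graphics::legend("bottomleft", x$conditions, col = cols, lwd = 2,
                     bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Parameter sweep of the dopamine clamp, exploration width or discount
#'
#' Sweeps one of `delta_lim` (with the clamp active and all other parameters
#' at control levels), `sigma`, or `gamma` (both swept unclamped at control
#' levels), running the full train/test protocol per value on one door and
#' returning per-trial mean stride lengths with all pairwise Welch
#' comparisons.
#'
#' @param param `"delta_lim"`, `"sigma"` or `"gamma"`.
#' @param values Values to sweep.
#' @param seed Integer seed.
#' @param door Door preset.
#' @param cpg A [train_cpg()] fit (trained on demand when omitted).
#' @param gamma,sigma Base (control-level) parameters.
#' @param n_train,n_profiles,n_passes Protocol sizes.
#' @param controls A [pass_controls()].
#' @param engine Simulation engine.
#' @return An object of class `gait_sweep`: list with `table` (per-value mean
#'   and SD), `pairwise` (data frame of pairwise p-values) and `per_trial`.
#' @export
sweep_parameter <- function(param = c("delta_lim", "sigma", "gamma"), values,
                            seed = 1, door = "narrow", cpg = NULL,
                            gamma = 0.8, sigma = 0.3,
                            n_train = 100, n_profiles = 50, n_passes = 100,
                            controls = pass_controls(), engine = "cpp") {
  param <- match.arg(param)
  if (is.null(cpg)) cpg <- train_cpg(generate_teach_signals())
  set.seed(seed)
  cell_seeds <- matrix(sample.int(.Machine$integer.max %/% 2,
                                  2 * length(values)), ncol = 2)
  per_trial <- list()
  for (i in seq_along(values)) {
    v <- values[i]
    preset <- switch(param,
      delta_lim = custom_preset(gamma, sigma, mode = "pd_off", delta_lim = v,
                                name = sprintf("delta_lim=%g", v)),
      sigma = custom_preset(gamma, v, mode = "control",
                            name = sprintf("sigma=%g", v)),
      gamma = custom_preset(v, sigma, mode = "control",
                            name = sprintf("gamma=%g", v)))
    agent <- train_agent(preset, door, cpg, n_passes = n_train,
                         seed = cell_seeds[i, 1], gait_mode = "stride",
                         controls = controls, engine = engine)
    trials <- simulate(agent, nsim = n_profiles, seed = cell_seeds[i, 2],
                       n_passes = n_passes)
    per_trial[[as.character(v)]] <- trials$window_mean
  }
  tab <- data.frame(value = values,
                    mean = vapply(per_trial, mean, numeric(1)),
                    sd = vapply(per_trial, stats::sd, numeric(1)),
                    row.names = NULL)
  prs <- utils::combn(seq_along(values), 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(prs, function(pr) {
    cmp <- compare_groups(per_trial[[pr[1]]], per_trial[[pr[2]]])
    data.frame(value_a = values[pr[1]], value_b = values[pr[2]],
               t = cmp$statistic, p = cmp$p_value)
  }))
  structure(list(param = param, door = door, table = tab, pairwise = pw,
                 per_trial = per_trial, seed = seed),
            class = "gait_sweep")
}

#' @export
print.gait_sweep <- function(x, digits = 4, ...) {
  cat(sprintf("Sweep of %s (door '%s'):\n", x$param, x$door))
  print(x$table, digits = digits, row.names = FALSE)
  cat("\nPairwise Welch comparisons:\n")
  print(x$pairwise, digits = digits, row.names = FALSE)
  invisible(x)
}
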