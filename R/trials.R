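#' Linear velocity interpolation
#'
#' Exact linear interpolation of a velocity between two track positions:
#' `v_res = v_a + (v_b - v_a) * (X_res - X_a) / (X_b - X_a)`. Used to fill
#' velocity profiles between the discrete per-stride samples.
#'
#' @param v_a,v_b Velocities at `X_a` and `X_b`.
#' @param X_a,X_b Distinct positions.
#' @param X_res Query position(s).
#' @export
interpolate_velocity <- function(v_a, v_b, X_a, X_b, X_res) {
  if (any(X_a == X_b)) stop("zero-length interval")
  v_a + (v_b - v_a) * (X_res - X_a) / (X_b - X_a)
}

# per-pass forward-velocity profile on a fixed y grid (NA outside the pass)
pass_profile <- function(y, vy, grid) {
  ok <- is.finite(y) & is.finite(vy)
  y <- y[ok]; vy <- vy[ok]
  if (length(unique(y)) < 2) return(rep(NA_real_, length(grid)))
  stats::approx(y, vy, xout = grid, ties = mean, rule = 1)$y
}

#' Run test trials with a trained agent
#'
#' Testing protocol: the trained value weights are frozen and the agent runs
#' `n_passes` passes per velocity profile, `nsim` profiles in total. Each
#' profile's forward velocity `v_y` is linearly interpolated onto a fixed `y`
#' grid per pass and averaged across the profile's passes; stride/step
#' statistics are collected per profile ("trial"): the mean executed
#' stride/step length inside the pre-door analysis window
#' (`y` within 2 m of the door, `|x| <= 2 d_pos` clipped to the track) and
#' the within-trial step-length coefficient of variation (see
#' [doorway_statistics()]).
#'
#' @param object A [train_agent()] fit.
#' @param nsim Number of velocity profiles ("trials").
#' @param seed Optional seed.
#' @param n_passes Passes averaged per profile.
#' @param grid_dy Velocity-profile grid spacing (m).
#' @param keep_records Keep every per-pass step record (memory-heavy for
#'   large runs).
#' @param cv_steps CV convention: `"executed"` (default) computes the
#'   within-trial CV over executed steps (stride > 1 mm), excluding the
#'   stand-in-place placeholder steps emitted under the backward-suppression
#'   rule; `"all"` includes them.
#' @param ... Unused.
#' @return An object of class `gait_trials`.
#' @export
simulate.gait_agent <- function(object, nsim = 50, seed = NULL,
                                n_passes = 100, grid_dy = 0.1,
                                keep_records = FALSE,
                                cv_steps = c("executed", "all"), ...) {
  cv_steps <- match.arg(cv_steps)
  if (!is.null(seed)) set.seed(seed)
  geometry <- object$geometry
  grid <- seq(0, geometry$y_door, by = grid_dy)
  W <- object$critic$W
  xwin <- min(2 * geometry$d_pos, geometry$x_max)
  ywin <- c(geometry$y_door - 2, geometry$y_door)

  prof_v <- matrix(NA_real_, nsim, length(grid))
  window_mean <- cv <- numeric(nsim)
  n_passed <- integer(nsim)
  records <- if (keep_records) vector("list", nsim) else NULL

  for (p in seq_len(nsim)) {
    vsum <- numeric(length(grid)); vcnt <- numeric(length(grid))
    win <- c(); exec <- c(); allst <- c()
    if (keep_records) records[[p]] <- vector("list", n_passes)
    for (q in seq_len(n_passes)) {
      res <- run_pass_engine(W, FALSE, object$preset, geometry, object$cpg,
                             object$gait, object$controls, object$engine)
      rc <- res$record
      if (res$outcome == "passed_door") n_passed[p] <- n_passed[p] + 1L
      vy <- pass_profile(rc[, "y"], rc[, "vy"], grid)
      ok <- !is.na(vy)
      vsum[ok] <- vsum[ok] + vy[ok]; vcnt[ok] <- vcnt[ok] + 1
      inwin <- rc[, "y"] >= ywin[1] & rc[, "y"] <= ywin[2] &
        abs(rc[, "x"]) <= xwin
      win <- c(win, rc[inwin, "stride"])
      allst <- c(allst, rc[, "stride"])
      if (keep_records) records[[p]][[q]] <- list(record = rc,
                                                  outcome = res$outcome)
    }
    prof_v[p, ] <- ifelse(vcnt > 0, vsum / vcnt, NA_real_)
    window_mean[p] <- if (length(win)) mean(win) else 0
    steps <- if (cv_steps == "executed") allst[allst > 1e-3] else allst
    cv[p] <- if (length(steps) > 1 && mean(steps) > 0)
      stats::sd(steps) * sqrt((length(steps) - 1) / length(steps)) /
        mean(steps) else 0
  }

  far <- grid >= geometry$y_door - 6 & grid <= geometry$y_door - 5
  norm_v <- t(apply(prof_v, 1, function(v) {
    base <- mean(v[far], na.rm = TRUE)
    if (!is.finite(base) || base == 0) rep(NA_real_, length(v))
    else 100 * v / base
  }))

  structure(list(
    preset = object$preset, geometry = geometry, gait = object$gait,
    grid = grid, profiles = prof_v, normalized = norm_v,
    window_mean = window_mean, cv = cv, n_passed = n_passed,
    nsim = nsim, n_passes = n_passes, cv_steps = cv_steps,
    records = records
  ), class = "gait_trials")
}

#' @export
print.gait_trials <- function(x, ...) {
  cat(sprintf("Gait trials: preset '%s', door '%s', %d profiles x %d passes (%s mode)\n",
              x$preset$name, x$geometry$door, x$nsim, x$n_passes, x$gait$mode))
  cat(sprintf("  mean %s length in pre-door window: %.3f m (SD %.3f); mean within-trial CV: %.3f\n",
              x$gait$mode, mean(x$window_mean), stats::sd(x$window_mean),
              mean(x$cv)))
  cat(sprintf("  passes ending in passage: %.1f%%\n",
              100 * sum(x$n_passed) / (x$nsim * x$n_passes)))
  invisible(x)
}

#' @export
plot.gait_trials <- function(x, normalized = TRUE, ...) {
  m <- if (normalized) x$normalized else x$profiles
  avg <- colMeans(m, na.rm = TRUE)
  graphics::plot(x$grid, avg, type = "l", lwd = 2,
                 xlab = "y position (m)",
                 ylab = if (normalized) "velocity (% of far-field)" else
                   "forward velocity (m/s)",
                 main = sprintf("%s, door '%s'", x$preset$name,
                                x$geometry$door), ...)
  if (normalized) graphics::abline(h = 100, lty = 3)
  graphics::abline(v = x$geometry$y_door, lty = 2)
  invisible(x)
}

#' Stride/step statistics of a set of trials
#'
#' Group summary over the `N` per-trial means: the group mean, SD and
#' standard error of the mean stride/step length inside the pre-door window,
#' and the within-trial step-length coefficient of variation (population SD /
#' mean within each trial) averaged across trials.
#'
#' @param trials A [simulate.gait_agent()] result.
#' @return An object of class `doorway_statistics` (also a plain list).
#' @export
doorway_statistics <- function(trials) {
  stopifnot(inherits(trials, "gait_trials"))
  if (trials$nsim < 1) stop("empty trial set")
  m <- trials$window_mean
  structure(list(
    preset = trials$preset$name, door = trials$geometry$door,
    mode = trials$gait$mode, N = trials$nsim,
    per_trial_mean = m, mean = mean(m), sd = stats::sd(m),
    se = stats::sd(m) / sqrt(length(m)),
    cv = mean(trials$cv), cv_per_trial = trials$cv
  ), class = "doorway_statistics")
}

#' @export
print.doorway_statistics <- function(x, ...) {
  cat(sprintf("%s / door '%s': mean %s length %.3f m (SD %.3f, SE %.4f, N = %d); mean CV %.3f\n",
              x$preset, x$door, x$mode, x$mean, x$sd, x$se, x$N, x$cv))
  invisible(x)
}

#' Compare two groups of per-trial means
#'
#' Welch two-sample t-test on the per-trial mean stride/step lengths (or any
#' two numeric vectors). Degenerate inputs (both groups constant) are handled
#' with an exact-equality fast path.
#'
#' @param a,b `gait_trials`, `doorway_statistics`, or numeric vectors of
#'   per-trial means.
#' @param what For trial objects: compare `"length"` (window means) or
#'   `"cv"` (within-trial CVs).
#' @return List with `statistic`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
compare_groups <- function(a, b, what = c("length", "cv")) {
  what <- match.arg(what)
  pull <- function(z) {
    if (inherits(z, "gait_trials"))
      return(if (what == "cv") z$cv else z$window_mean)
    if (inherits(z, "doorway_statistics"))
      return(if (what == "cv") z$cv_per_trial else z$per_trial_mean)
    as.numeric(z)
  }
  va <- pull(a); vb <- pull(b)
  stopifnot(length(va) >= 2, length(vb) >= 2)
  if (stats::sd(va) == 0 && stats::sd(vb) == 0) {
    eq <- isTRUE(all.equal(mean(va), mean(vb)))
    return(list(statistic = if (eq) 0 else Inf, df = NA_real_,
                p_value = if (eq) 1 else 0,
                mean_a = mean(va), mean_b = mean(vb)))
  }
  tt <- stats::t.test(va, vb)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(va), mean_b = mean(vb))
}

#' @rdname simulate.gait_agent
#' @param agent A [train_agent()] fit.
#' @param n_profiles Number of velocity profiles ("trials").
#' @export
run_test_trials <- function(agent, n_profiles = 50, n_passes = 100,
                            seed = NULL, ...) {
  simulate(agent, nsim = n_profiles, seed = seed, n_passes = n_passes, ...)
}
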