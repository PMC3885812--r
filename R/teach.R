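#' Generate hip/knee teaching signals
#'
#' Builds one gait cycle (default 500 samples spanning 1 s) of hip and knee
#' joint-angle profiles as truncated Fourier series. The hip angle is
#' \deqn{\theta_h(t) = A_h\,[\cos(2\pi t) + 0.1\cos(4\pi t)]}
#' which has exactly three extrema over the closed cycle (the two step peaks
#' and the shared cycle boundary peak, i.e. 2 steps per 1 s cycle). Each knee
#' flexes once per cycle during its leg's swing; the knee profile is the
#' Fourier truncation (constant term plus two harmonics) of a
#' half-wave-rectified squared sinusoid,
#' \deqn{s(t) = \tfrac14 - \tfrac14\cos(4\pi t) + \tfrac{4}{3\pi}\sin(2\pi t),}
#' which is exactly zero at the hip extrema (knee angles are approximately 0
#' at the extremes of the hip swing, which is what makes the hip-extremum
#' stride formula valid). Knee 2 is the half-cycle shift of knee 1. Each knee
#' signal thus holds three Fourier components (constant, 1 Hz, 2 Hz) for the
#' three oscillators of its pool, and the hip two (1 Hz, 2 Hz) for its two.
#'
#' @param T Samples per gait cycle (the cycle spans 1 s of simulated time).
#' @param amplitudes Named numeric: `hip` and `knee` amplitudes in radians.
#' @return An object of class `teach_signals`: list with `time` (seconds),
#'   `hip`, `knee1`, `knee2` (radians), `T` and `amplitudes`.
#' @examples
#' ts <- generate_teach_signals()
#' length(ts$hip)  # 500
#' @export
generate_teach_signals <- function(T = 500, amplitudes = c(hip = 0.35, knee = 0.6)) {
  stopifnot(T >= 100, c("hip", "knee") %in% names(amplitudes))
  t <- (seq_len(T) - 1) / T
  hip <- amplitudes[["hip"]] * (cos(2 * pi * t) + 0.1 * cos(4 * pi * t))
  s <- function(u) 0.25 - 0.25 * cos(4 * pi * u) + (4 / (3 * pi)) * sin(2 * pi * u)
  knee1 <- amplitudes[["knee"]] * s(t)
  knee2 <- amplitudes[["knee"]] * s(t - 0.5)
  structure(list(time = t, hip = hip, knee1 = knee1, knee2 = knee2,
                 T = T, amplitudes = amplitudes),
            class = "teach_signals")
}

#' @export
print.teach_signals <- function(x, ...) {
  cat(sprintf("Teaching signals: %d samples / 1 s gait cycle\n", x$T))
  cat(sprintf("  hip amplitude %g rad, knee amplitude %g rad\n",
              x$amplitudes[["hip"]], x$amplitudes[["knee"]]))
  invisible(x)
}

#' @export
plot.teach_signals <- function(x, ...) {
  graphics::matplot(x$time, cbind(x$hip, x$knee1, x$knee2), type = "l",
                    lty = 1, col = c("black", "tomato", "steelblue"),
                    xlab = "time within gait cycle (s)",
                    ylab = "joint angle (rad)", ...)
  graphics::legend("topright", c("hip", "knee 1", "knee 2"), lty = 1,
                   col = c("black", "tomato", "steelblue"), bty = "n")
  invisible(x)
}

#' Count extrema of a periodic trajectory over one closed cycle
#'
#' Local extrema of one recorded cycle, treating the trajectory as periodic:
#' interior extrema are sign changes of the first difference, and the cycle
#' boundary counts (twice, as the first and last extremum) when the slope
#' changes sign across the wrap, mirroring how the three hip-angle extrema of
#' a gait cycle are counted.
#'
#' @param x Numeric trajectory over one cycle (first sample = cycle start).
#' @return Integer vector of extrema indices (boundary reported as both
#'   `1` and `length(x) + 1` when it is an extremum).
#' @export
cycle_extrema <- function(x) {
  n <- length(x)
  stopifnot(n >= 3)
  d <- diff(x)
  interior <- which(d[-length(d)] * d[-1] < 0) + 1L
  idx <- interior
  if (d[length(d)] * d[1] < 0) idx <- c(1L, idx, n + 1L)
  sort(idx)
}
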