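#' Build the fan of gaze rays
#'
#' The agent sees the world through a 120 degree field of view split into
#' `n_sectors` sectors (50 by default). Sector `i` looks along the unit vector
#' obtained by rotating the orientation vector by the sector's centre angle
#' `theta_i`; angles are the uniformly spaced sector centres over
#' `[-fov/2, +fov/2]`. The rotation uses the convention
#' `R_i = [cos t, sin t; -sin t, cos t] %*% R_o` (clockwise for positive
#' angles), and for every ray the intersection of its supporting line with the
#' door line can then be computed from its slope.
#'
#' @param position Numeric `c(x, y)` viewing point.
#' @param orientation Numeric `c(vx, vy)` gaze direction (any nonzero length;
#'   normalised internally).
#' @param n_sectors Number of sectors (>= 2).
#' @param fov Field of view in degrees, in `(0, 180)`.
#' @return An object of class `ray_fan`: list with `position`, `angles_deg`,
#'   `vectors` (`n_sectors` x 2 matrix of unit vectors) and `slopes`.
#' @export
build_ray_fan <- function(position, orientation, n_sectors = 50, fov = 120) {
  stopifnot(length(position) == 2, length(orientation) == 2,
            n_sectors >= 2, fov > 0, fov < 180)
  nrm <- sqrt(sum(orientation^2))
  if (!is.finite(nrm) || nrm < 1e-12)
    stop("degenerate orientation vector")
  ro <- orientation / nrm
  th <- (-fov / 2 + (seq_len(n_sectors) - 0.5) * fov / n_sectors) * pi / 180
  rx <- cos(th) * ro[1] + sin(th) * ro[2]
  ry <- -sin(th) * ro[1] + cos(th) * ro[2]
  structure(list(position = c(position[[1]], position[[2]]),
                 angles_deg = th * 180 / pi,
                 vectors = cbind(rx, ry, deparse.level = 0),
                 slopes = ry / rx),
            class = "ray_fan")
}

#' Binary view vector of the doorway
#'
#' For each gaze ray the intersection `x_door` of the ray with the door line
#' `y = y_door` is computed; the corresponding view-vector entry is 1 when the
#' intersection falls inside the door opening `[-d_pos, d_pos]`, else 0. Rays
#' pointing away from the door line (non-positive forward component) cannot hit
#' the opening and are assigned 0.
#'
#' @param ray_fan A [build_ray_fan()] object.
#' @param geometry A [track_geometry()].
#' @return Integer vector of 0/1 of length `n_sectors`.
#' @export
view_vector <- function(ray_fan, geometry) {
  stopifnot(inherits(ray_fan, "ray_fan"), inherits(geometry, "track_geometry"))
  y <- ray_fan$position[2]
  if (y >= geometry$y_door)
    stop("agent at or behind the door line")
  rx <- ray_fan$vectors[, 1]
  ry <- ray_fan$vectors[, 2]
  # (y_door - y) / m + x written as (y_door - y) * rx / ry + x so that
  # vertical rays (rx = 0, infinite slope) come out exactly at x
  xd <- (geometry$y_door - y) * rx / ry + ray_fan$position[1]
  as.integer(ry > 0 & xd >= -geometry$d_pos & xd <= geometry$d_pos)
}

#' View vector at a pose
#'
#' Convenience wrapper building the ray fan and evaluating the view vector in
#' one call.
#'
#' @inheritParams build_ray_fan
#' @inheritParams view_vector
#' @export
view_vector_at <- function(position, orientation, geometry,
                           n_sectors = 50, fov = 120) {
  view_vector(build_ray_fan(position, orientation, n_sectors, fov), geometry)
}

# unit vector from a pose toward the door centre
door_direction <- function(position, geometry) {
  v <- c(0 - position[[1]], geometry$y_door - position[[2]])
  v / sqrt(sum(v^2))
}
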