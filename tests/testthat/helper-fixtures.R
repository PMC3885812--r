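# shared fixtures; heavyweight objects are built once per test run
.fixture_env <- new.env(parent = emptyenv())

test_cpg <- function() {
  if (is.null(.fixture_env$cpg))
    .fixture_env$cpg <- train_cpg(generate_teach_signals())
  .fixture_env$cpg
}

narrow_geom <- function() track_geometry("narrow")

# analytic view-vector oracle: a sector sees the opening iff its centre
# bearing lies inside the angular interval subtended by the door edges
# (bearing = clockwise angle from +y, matching the fan's rotation convention)
oracle_view_count <- function(position, orientation, geometry,
                              n_sectors = 50, fov = 120) {
  bearing <- function(v) atan2(v[1], v[2])
  b0 <- bearing(orientation / sqrt(sum(orientation^2)))
  e1 <- bearing(c(-geometry$d_pos - position[1],
                  geometry$y_door - position[2]))
  e2 <- bearing(c(geometry$d_pos - position[1],
                  geometry$y_door - position[2]))
  lo <- min(e1, e2); hi <- max(e1, e2)
  th <- (-fov / 2 + (seq_len(n_sectors) - 0.5) * fov / n_sectors) * pi / 180
  sum(b0 + th >= lo & b0 + th <= hi)
}

# dense ray-casting oracle: 720 rays over the field of view binned into the
# sectors; a sector counts as seeing the door when most of its rays hit
dense_view_count <- function(position, orientation, geometry,
                             n_sectors = 50, fov = 120, n_rays = 720) {
  o <- orientation / sqrt(sum(orientation^2))
  th <- (-fov / 2 + (seq_len(n_rays) - 0.5) * fov / n_rays) * pi / 180
  rx <- cos(th) * o[1] + sin(th) * o[2]
  ry <- -sin(th) * o[1] + cos(th) * o[2]
  xd <- (geometry$y_door - position[2]) * rx / ry + position[1]
  hit <- ry > 0 & xd >= -geometry$d_pos & xd <= geometry$d_pos
  per <- n_rays / n_sectors
  sum(vapply(seq_len(n_sectors), function(i)
    mean(hit[((i - 1) * per + 1):(i * per)]) > 0.5, logical(1)))
}
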