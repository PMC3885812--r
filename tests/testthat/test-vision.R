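test_that("ray fan applies the rotation convention with unit-norm sectors", {
  fan <- build_ray_fan(c(0, 0), c(0, 1))
  expect_equal(nrow(fan$vectors), 50)
  norms <- sqrt(rowSums(fan$vectors^2))
  expect_equal(norms, rep(1, 50))
  # hand-evaluated rotation of R_o = (0,1): O(t) %*% (0,1) = (sin t, cos t)
  th <- fan$angles_deg * pi / 180
  expect_equal(fan$vectors[, 1], sin(th))
  expect_equal(fan$vectors[, 2], cos(th))
  # a 3-sector fan over 120 degrees has centres -40, 0, +40: the middle ray
  # is the orientation itself
  f3 <- build_ray_fan(c(0, 0), c(0, 1), n_sectors = 3)
  expect_equal(f3$angles_deg, c(-40, 0, 40))
  expect_equal(f3$vectors[2, ], c(0, 1))
  expect_error(build_ray_fan(c(0, 0), c(0, 0)), "degenerate")
})

test_that("view vector saturates near the door and empties without one", {
  g <- narrow_geom()
  # door subtends atan(1/0.1) = 84 deg > 60 deg half-FOV: every sector hits
  phi <- view_vector_at(c(0, 9.9), c(0, 1), g)
  expect_equal(phi, rep(1L, 50))
  # zero-width door: nothing to see
  phi0 <- view_vector_at(c(0, 0.1), c(0, 1), track_geometry(0))
  expect_equal(phi0, rep(0L, 50))
  # rays pointing away from the door line never hit
  back <- view_vector_at(c(0, 5), c(0, -1), g)
  expect_equal(back, rep(0L, 50))
  expect_error(view_vector_at(c(0, 10), c(0, 1), g), "door line")
})

test_that("view-vector counts match the independent analytic and dense ray-casting oracles", {
  g <- narrow_geom()
  poses <- list(
    list(p = c(0, 0.1), o = c(0, 1)),
    list(p = c(0.7, 3), o = c(0, 1)),
    list(p = c(-1.2, 6), o = c(0.3, 1)),
    list(p = c(0.4, 8), o = c(-0.2, 1)),
    list(p = c(1.1, 5.5), o = c(-0.5, 0.9)))
  for (ps in poses) {
    n <- sum(view_vector_at(ps$p, ps$o, g))
    expect_equal(n, oracle_view_count(ps$p, ps$o, g))
    expect_equal(n, dense_view_count(ps$p, ps$o, g))
  }
})

test_that("view vector is monotone in door width and distance, and mirror symmetric", {
  gn <- track_geometry("narrow"); gw <- track_geometry("wide")
  set.seed(3)
  for (i in 1:50) {
    p <- c(runif(1, -1.4, 1.4), runif(1, 0.1, 9))
    o <- c(runif(1, -1, 1), runif(1, 0.1, 1))
    phin <- view_vector_at(p, o, gn)
    phiw <- view_vector_at(p, o, gw)
    expect_true(all(phin <= phiw))
    # mirror pose reverses the view vector
    phim <- view_vector_at(c(-p[1], p[2]), c(-o[1], o[2]), gn)
    expect_equal(phim, rev(phin))
  }
  # door-facing on the midline: nearer doors fill more of the field
  counts <- vapply(seq(0.5, 9.5, by = 0.5), function(y)
    sum(view_vector_at(c(0, y), c(0, 1), gn)), numeric(1))
  expect_true(all(diff(counts) >= 0))
})
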