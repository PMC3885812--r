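test_that("velocity gain saturates at A_k", {
  expect_equal(velocity_gain(0, 0), 0)
  expect_equal(velocity_gain(0, 50), 3, tolerance = 1e-12)  # asymptote
  expect_equal(velocity_gain(0, 1), 3 * tanh(1))            # 2.2854
  expect_equal(velocity_gain(0.6, 0.8), 3 * tanh(1))
})

test_that("amplitude modulation is a uniform scaling of the output weights", {
  a0 <- list(hip = c(0.3, 0.05), knee1 = c(0.2, 0.1, 0.15))
  expect_equal(modulate_amplitudes(a0, 0), lapply(a0, `*`, 0))
  expect_equal(modulate_amplitudes(a0, 1), a0)
  expect_equal(modulate_amplitudes(c(1, 2), 2), c(2, 4))
})

test_that("hip-angle extrema are located as a dense argmax oracle does", {
  t <- (0:499) / 500
  tri <- cos(2 * pi * t)             # extrema at samples 1, 251 and the wrap
  ext <- joint_extrema(tri)
  expect_equal(unname(ext), c(1, 1))
  expect_error(joint_extrema(rep(0, 500)), "degenerate")
  net <- test_cpg()
  hip <- net$cycle$output[, 1]
  ext <- joint_extrema(hip)
  expect_equal(unname(ext[["ext2"]]), abs(min(hip)), tolerance = 1e-12)
  expect_equal(unname(ext[["ext3"]]), max(hip), tolerance = 1e-12)
})

test_that("stride and step lengths follow the two-extremum sine formula", {
  expect_equal(stride_length(c(ext2 = 0, ext3 = 0)), 0)
  expect_equal(stride_length(c(ext2 = 0.5, ext3 = 0.5)),
               2 * 1.1 * sin(0.25) * 2)          # 1.0885 m
  expect_equal(stride_length(c(ext2 = 0.5, ext3 = 0.5),
                             gait_geometry(mode = "step")),
               2 * 1.1 * sin(0.25))              # 0.5442 m
  expect_error(stride_length(c(ext2 = -0.1, ext3 = 0)), "non-negative")
  # geometric bound: 4 (l1 + l2)
  expect_lt(stride_length(c(ext2 = pi - 1e-6, ext3 = pi - 1e-6)), 4.4 + 1e-9)
})

test_that("position advances by exactly the stride along the velocity direction", {
  expect_equal(advance_position(c(0, 2), 0.5, 0, 1), c(0, 2.5))
  expect_equal(advance_position(c(0, 0), 1, 3, 4), c(0.6, 0.8))
  back <- advance_position(c(0, 2), 0.7, 0.1, -1)
  expect_equal(sqrt(sum((back - c(0, 2))^2)), 1e-4)   # suppressed magnitude
  hold <- advance_position(c(0, 2), 0.7, 0.1, -1, backward_rule = "hold")
  expect_equal(hold, c(0, 2))
  set.seed(5)
  for (i in 1:100) {
    v <- runif(2, -1, 1); L <- runif(1, 0, 2); p0 <- runif(2, -1, 1)
    p1 <- advance_position(p0, L, v[1], v[2])
    expect_equal(sqrt(sum((p1 - p0)^2)), if (v[2] < 0) 1e-4 else L)
  }
})

test_that("commanded speed raises stride length monotonically through the gain chain", {
  net <- test_cpg()
  e <- net$hip_extrema
  speeds <- seq(0.05, 3, by = 0.05)
  L <- vapply(speeds, function(s) {
    k <- velocity_gain(0, s)
    stride_length(c(ext2 = k * e[["ext2"]], ext3 = k * e[["ext3"]]))
  }, numeric(1))
  expect_true(all(diff(L) > 0))
  expect_true(all(L <= 4.4))
})
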