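test_that("velocity interpolation is exact linear interpolation", {
  expect_equal(interpolate_velocity(1, 2, 0, 4, 0), 1)      # endpoint
  expect_equal(interpolate_velocity(1, 2, 0, 4, 2), 1.5)    # midpoint
  expect_equal(interpolate_velocity(1, 2, 0, 4, 1), 1.25)
  expect_error(interpolate_velocity(1, 2, 3, 3, 3), "zero-length")
  # reproduces any affine velocity field exactly
  a <- 0.3; b <- -0.07
  X <- sort(runif(10, 0, 10))
  v <- a + b * X
  for (i in 1:9) {
    xr <- runif(5, X[i], X[i + 1])
    expect_equal(interpolate_velocity(v[i], v[i + 1], X[i], X[i + 1], xr),
                 a + b * xr)
  }
})

test_that("within-trial CV uses the population SD convention", {
  # population SD of {0.4, 0.6} is 0.1, so CV = 0.1 / 0.5 = 0.2
  st <- c(0.4, 0.6)
  n <- length(st)
  cv <- sd(st) * sqrt((n - 1) / n) / mean(st)
  expect_equal(cv, 0.2)
  # the trial pipeline applies the same convention
  net <- test_cpg()
  ag <- train_agent("cowie_control", "wide", net, n_passes = 5, seed = 9)
  tr <- simulate(ag, nsim = 2, seed = 10, n_passes = 5)
  expect_true(all(tr$cv >= 0))
})

test_that("group comparison handles identical and degenerate samples", {
  x <- c(0.5, 0.5, 0.5)
  out <- compare_groups(x, x)
  expect_equal(out$p_value, 1)
  y <- c(0.5, 0.6, 0.55, 0.62)
  out2 <- compare_groups(y, y + 0.2)
  expect_lt(out2$p_value, 0.05)
  expect_equal(out2$mean_b - out2$mean_a, 0.2)
})

test_that("the two-sample test is calibrated at the nominal level", {
  set.seed(2024)
  n_rep <- 1e4
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    a <- rnorm(15); b <- rnorm(15)
    rej[i] <- compare_groups(a, b)$p_value < 0.05
  }
  expect_equal(mean(rej), 0.05, tolerance = 0.2)  # ~5% +- binomial noise
})
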