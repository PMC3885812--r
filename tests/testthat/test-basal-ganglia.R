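test_that("value is the tanh of the weighted view and stays inside (-1, 1)", {
  cr <- critic_state()
  expect_equal(value(cr, rep(1L, 50)), 0)                 # W = 0
  cr$W <- rep(0.1, 50)
  expect_equal(value(cr, rep(0L, 50)), 0)                 # empty view
  phi <- c(rep(1L, 10), rep(0L, 40))
  expect_equal(value(cr, phi), tanh(1))                   # 10 ones x 0.1
  expect_error(value(cr, rep(1L, 10)), "length")
  set.seed(1)
  for (i in 1:100) {
    cr$W <- runif(50, -0.2, 0.2)
    expect_lt(abs(value(cr, sample(0:1, 50, TRUE))), 1)
  }
})

test_that("TD error follows r + gamma V(t) - V(t-1) with terminal bootstrap 0", {
  expect_equal(td_error(0, 0.7, 0.7, gamma = 1), 0)
  expect_equal(td_error(5, 0.9, 0.4, gamma = 0.8, terminal = TRUE), 4.6)
  expect_equal(td_error(0, 0.5, 0.1, gamma = 0.8), 0.3)
})

test_that("dopamine clamping matches the OFF/ON rules and bounds", {
  ctrl <- dopamine_condition("control")
  off <- dopamine_condition("pd_off", delta_lim = -0.1)
  on <- dopamine_condition("pd_on", delta_lim = -0.1, delta_med = 0.12)
  expect_equal(clamp_dopamine(0.9, ctrl), 0.9)
  expect_equal(clamp_dopamine(0.5, off), -0.1)
  expect_equal(clamp_dopamine(0.5, on), 0.02)
  expect_equal(clamp_dopamine(-0.5, on), -0.38)
  expect_error(dopamine_condition("pd_off", delta_med = 0.1), "delta_med")
  deltas <- seq(-2, 2, by = 0.01)
  expect_true(all(clamp_dopamine(deltas, off) <= -0.1))
  expect_true(all(clamp_dopamine(deltas, on) <= -0.1 + 0.12))
})

test_that("weight updates touch only active view components and build value toward saturation", {
  cr <- critic_state(n_sectors = 5, eta = 0.1)
  phi <- c(0L, 0L, 1L, 0L, 0L)
  same <- update_weights(cr, 0, phi)
  expect_equal(same$W, rep(0, 5))
  up <- update_weights(cr, 1, phi)
  expect_equal(up$W, c(0, 0, 0.1, 0, 0))
  # repeated rewarded visits to a fixed state: V rises monotonically
  v <- numeric(30)
  for (i in 1:30) {
    d <- td_error(1, 0, value(cr, phi), 0.8, terminal = TRUE)
    cr <- update_weights(cr, d, phi)
    v[i] <- value(cr, phi)
  }
  expect_true(all(diff(v) > 0))
  expect_lt(v[30], 1)
})

test_that("value difference equals the TD error when gamma = 1 and r = 0", {
  expect_equal(value_difference(0.4, 0.4), 0)
  expect_equal(value_difference(0.5, 0.2), 0.3)
  v_t <- 0.63; v_tm1 <- -0.21
  expect_equal(value_difference(v_t, v_tm1), td_error(0, v_t, v_tm1, gamma = 1))
})

test_that("the continuous policy blends GO, EXPLORE and NOGO as the value difference dictates", {
  p <- gen_params(A_G = 2.5, A_N = 1, A_E = 1, lambda_G = 1, lambda_N = -1,
                  sigma = 0.3)
  dx <- c(0.4, 0.3)
  # saturated GO: sigmoids at their limits, exploration gated shut
  expect_equal(gen_step(50, dx, p, chi = c(0.2, -0.1)), 2.5 * dx)
  # saturated NOGO: pure reversal
  expect_equal(gen_step(-50, dx, p, chi = c(0.2, -0.1)), -dx)
  # dead centre: sig(0) = 1/2 on both terms, full exploration
  expect_equal(gen_step(0, dx, p, chi = c(0.2, -0.1)),
               0.75 * dx + c(0.2, -0.1))
})

test_that("exploration draws are zero mean so the expected update is the GO-NOGO part", {
  p <- gen_params(sigma = 0.5)
  dx <- c(0.2, 0.1)
  set.seed(99)
  draws <- t(replicate(2e4, gen_step(0.1, dx, p)))
  det <- gen_step(0.1, dx, p, chi = c(0, 0))
  expect_equal(colMeans(draws), det, tolerance = 0.02)
})

test_that("the discrete three-branch rule is the steep-sigmoid, narrow-gate limit of the continuous policy", {
  p <- gen_params(D_hi = 0.1, D_lo = -0.1)
  dx <- c(0.3, -0.2)
  chi <- c(0.11, -0.42)
  expect_equal(gen_step_discrete(0.5, dx, p, chi = chi), dx)    # GO
  expect_equal(gen_step_discrete(-0.5, dx, p, chi = chi), -dx)  # NOGO
  expect_equal(gen_step_discrete(0.05, dx, p, chi = chi), chi)  # EXPLORE
  lim <- gen_params(A_G = 1, A_N = 1, A_E = 1, lambda_G = 200, lambda_N = -200,
                    sigma = 1e-3)
  for (dv in c(0.5, -0.5)) {
    expect_equal(gen_step(dv, dx, lim, chi = chi),
                 gen_step_discrete(dv, dx, p, chi = chi), tolerance = 1e-8)
  }
  expect_equal(gen_step(0, dx, lim, chi = chi),
               gen_step_discrete(0, dx, p, chi = chi), tolerance = 1e-8)
})
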