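test_that("teaching signals carry the gait-cycle structure", {
  ts <- generate_teach_signals()
  expect_length(ts$hip, 500)
  # exactly 3 hip extrema over the closed cycle
  expect_length(cycle_extrema(ts$hip), 3)
  # knee angles vanish at the hip extrema (under 5% of the knee peak)
  hip_ext_t <- c(1L, 251L)   # hip extrema at t = 0 and t = 0.5
  for (k in list(ts$knee1, ts$knee2))
    expect_true(all(abs(k[hip_ext_t]) < 0.05 * max(k)))
  # zero amplitudes give flat signals
  z <- generate_teach_signals(amplitudes = c(hip = 0, knee = 0))
  expect_equal(z$hip, rep(0, 500))
  expect_equal(z$knee1, rep(0, 500))
})

test_that("instantaneous phase is the signed arccos of the oscillator coordinates", {
  expect_equal(instantaneous_phase(1e-9, -1), 0)
  expect_equal(instantaneous_phase(1, 0), pi / 2)
  expect_equal(instantaneous_phase(-1, 0), -pi / 2)
  expect_error(instantaneous_phase(0, 0), "z = 0")
})

test_that("pool derivatives have the Hopf limit cycle and adapt only under forcing", {
  const <- pool_constants("hip")
  st <- list(p = sqrt(const$mu), q = 0, omega = 2 * pi, alpha = 0.3, psi = 0,
             psiG = 0)
  d <- hopf_derivatives(st, const, forcing = 0)
  # on the limit cycle z = sqrt(mu): radial derivative vanishes
  dz <- (st$p * d$p + st$q * d$q) / sqrt(st$p^2 + st$q^2)
  expect_equal(dz, 0)
  expect_equal(d$omega, 0)   # no adaptation without error
  expect_equal(d$alpha, 0)
  # perturbed amplitude relaxes at the linearised rate 2 xi mu
  z0 <- 1.05
  y <- c(z0, 0)
  dt <- 1 / 500
  for (s in 1:100) {   # 0.2 s
    k <- function(v) {
      dd <- hopf_derivatives(list(p = v[1], q = v[2], omega = 2 * pi,
                                  alpha = 0, psi = 0, psiG = 0),
                             const, 0)
      c(dd$p, dd$q)
    }
    k1 <- k(y); k2 <- k(y + dt / 2 * k1); k3 <- k(y + dt / 2 * k2)
    k4 <- k(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  z <- sqrt(sum(y^2))
  expect_equal(log(z - 1) - log(z0 - 1), -2 * const$xi * const$mu * 0.2,
               tolerance = 0.05)
})

test_that("a single adaptive oscillator locks onto a sinusoid's frequency within 1 percent", {
  const <- pool_constants("hip")
  target <- 2 * pi * 1.2
  st <- c(p = 1, q = 0, omega = 2 * pi * 1.1, alpha = 0)
  dt <- 1 / 200
  amp <- 0.4
  rhs <- function(t, v) {
    forcing <- amp * sin(target * t) - v[4] * v[1]
    d <- hopf_derivatives(list(p = v[1], q = v[2], omega = v[3], alpha = v[4],
                               psi = 0, psiG = 0), const, forcing)
    c(d$p, d$q, d$omega, d$alpha)
  }
  t <- 0
  for (s in 1:(60 / dt)) {
    k1 <- rhs(t, st); k2 <- rhs(t + dt / 2, st + dt / 2 * k1)
    k3 <- rhs(t + dt / 2, st + dt / 2 * k2); k4 <- rhs(t + dt, st + dt * k3)
    st <- st + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
  }
  expect_equal(st[["omega"]], target, tolerance = 0.01)
})

test_that("the compiled integrator agrees with the reference pool dynamics", {
  ts <- generate_teach_signals()
  y0 <- gaitfog:::cpg_initial_state()
  tab <- cbind(ts$hip, ts$knee1, ts$knee2)
  n_steps <- 250
  cpp <- gaitfog:::cpg_integrate_cpp(y0, tab, n_steps, 0.08, 1 / 500)
  sol <- deSolve::rk4(y0, seq(0, n_steps / 500, by = 1 / 500),
                      gaitfog:::cpg_rhs,
                      list(teach_fun = gaitfog:::teach_interp_fun(ts),
                           eta_a = 0.08))
  expect_equal(unname(cpp[nrow(cpp), ]), unname(sol[nrow(sol), -1]),
               tolerance = 1e-8)
})

test_that("the trained network reproduces the gait rhythm", {
  net <- test_cpg()
  expect_true(net$converged)
  # frequencies lock to the cycle harmonics within 1 percent
  expect_equal(net$omega0$hip[1], 2 * pi, tolerance = 0.01)
  expect_equal(net$omega0$hip[2], 4 * pi, tolerance = 0.01)
  expect_equal(net$omega0$knee1[1], 2 * pi, tolerance = 0.01)
  # free-run output reproduces the teaching signals within the rad tolerance
  res <- residuals(net)
  expect_true(all(sqrt(colMeans(res^2)) < 0.01))
  # three hip extrema per stored cycle, 2 steps per second
  expect_length(cycle_extrema(net$cycle$output[, 1]), 3)
  expect_equal(cadence(net), 2, tolerance = 0.005)
})

test_that("free-running pools stay phase locked", {
  net <- test_cpg()
  fr <- free_run(net, 5)
  T <- nrow(net$cycle$output)
  first <- fr$output[1:T, ]
  last <- fr$output[(4 * T + 1):(5 * T), ]
  # after 4 further cycles the waveform has not drifted
  expect_lt(max(abs(last - first)), 0.05)
  # the two knees stay half a cycle apart
  k1 <- fr$output[1:T, 2]
  k2 <- fr$output[1:T, 3]
  k2_shift <- c(k2[(T / 2 + 1):T], k2[1:(T / 2)])
  expect_lt(sqrt(mean((k1 - k2_shift)^2)), 0.03)
})

test_that("output amplitude scales exactly linearly with the gain", {
  net <- test_cpg()
  expect_equal(network_output(net, 2), 2 * network_output(net, 1))
  expect_equal(network_output(net, 0), 0 * network_output(net, 1))
  # the stored cycle agrees with re-integrating the free-running network
  expect_equal(network_output(net, 1.7, mode = "integrate"),
               network_output(net, 1.7, mode = "stored"), tolerance = 1e-6)
})
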