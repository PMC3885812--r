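test_that("the compiled and reference engines take identical passes", {
  net <- test_cpg()
  geom <- narrow_geom()
  ctl <- pass_controls(max_steps = 120)
  for (pname in c("cowie_control", "cowie_pd_off", "cowie_pd_on")) {
    preset <- condition_preset(pname)
    for (seed in 1:2) {
      set.seed(seed)
      a <- gaitfog:::run_pass_engine(numeric(50), TRUE, preset, geom, net,
                                     gait_geometry(), ctl, "cpp")
      set.seed(seed)
      b <- gaitfog:::run_pass_engine(numeric(50), TRUE, preset, geom, net,
                                     gait_geometry(), ctl, "R")
      expect_identical(a$outcome, b$outcome)
      expect_equal(unname(a$record), unname(b$record), tolerance = 1e-12)
      expect_equal(a$W, b$W, tolerance = 1e-12)
    }
  }
})

test_that("training is reproducible, and zero passes leave the critic untouched", {
  net <- test_cpg()
  a1 <- train_agent("cowie_control", "wide", net, n_passes = 20, seed = 31)
  a2 <- train_agent("cowie_control", "wide", net, n_passes = 20, seed = 31)
  expect_identical(coef(a1), coef(a2))
  a3 <- train_agent("cowie_control", "wide", net, n_passes = 20, seed = 32)
  expect_false(identical(coef(a1), coef(a3)))
  a0 <- train_agent("cowie_control", "wide", net, n_passes = 0, seed = 31)
  expect_equal(coef(a0), rep(0, 50))
})

test_that("testing runs freeze the value weights", {
  net <- test_cpg()
  ag <- train_agent("cowie_pd_on", "narrow", net, n_passes = 30, seed = 5)
  W0 <- coef(ag)
  tr <- simulate(ag, nsim = 3, seed = 6, n_passes = 10)
  expect_identical(coef(ag), W0)
  expect_equal(dim(tr$profiles), c(3, length(tr$grid)))
  tr2 <- simulate(ag, nsim = 3, seed = 6, n_passes = 10)
  expect_equal(tr$window_mean, tr2$window_mean)
})

test_that("a trained control builds a value landscape rising toward the door", {
  net <- test_cpg()
  ag <- train_agent("cowie_control", "wide", net, seed = 41)
  mid <- summary(ag)$midline_value
  # positive value gradient along the approach (the final half metre before
  # the door line is dominated by door-post punishment and is excluded; see
  # the methods vignette)
  expect_gt(mid[9], mid[1] + 0.03)
  expect_gt(mean(diff(mid[1:9])), 0)
  expect_gt(mid[9], 0)
  land <- predict(ag, mode = "door_facing", dx = 0.5, dy = 0.5)
  expect_true(all(dim(land$V) == c(length(land$x), length(land$y))))
  expect_true(all(abs(land$V) < 1))
  # orientation averaging dilutes the landscape: most gaze directions miss
  # the door and contribute the empty-view value 0
  land1 <- value_landscape(ag$critic, ag$geometry, "door_facing",
                           dx = 1, dy = 1)
  land2 <- predict(ag, mode = "orientation_averaged", n_orientations = 8,
                   dx = 1, dy = 1)
  expect_equal(dim(land2$V), dim(land1$V))
  expect_lt(mean(abs(land2$V)), mean(abs(land1$V)))
  expect_true(all(abs(land2$V) < 1))
})

test_that("a clamped agent learns the inverted value profile", {
  net <- test_cpg()
  ag <- train_agent("cowie_pd_off", "narrow", net, seed = 42)
  mid <- summary(ag)$midline_value
  expect_true(all(mid < 0))
  expect_lt(mid[10], mid[1])   # dips toward the door
})
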