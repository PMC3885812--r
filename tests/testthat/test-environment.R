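test_that("door presets and geometry invariants hold", {
  g <- track_geometry("wide")
  expect_equal(g$d_length, 3)
  expect_equal(g$d_pos, 1.5)
  expect_equal(track_geometry("medium")$d_length, 2.5)
  expect_equal(track_geometry("narrow")$d_length, 2)
  expect_gt(g$d_pos, g$agent_radius)
  expect_true(g$x_min < -g$d_pos && g$d_pos < g$x_max)
  expect_error(track_geometry(0.8), "passable")
  expect_error(track_geometry(5), "wider than the track")
})

test_that("passes start at y = 0.1 with x confined to where the body fits", {
  g <- narrow_geom()
  expect_equal(reset_start(g, u = 0.5), c(x = 0, y = 0.1))
  set.seed(42)
  xs <- replicate(1e4, reset_start(g)[["x"]])
  expect_true(all(xs >= -1.5 & xs <= 1.5))
  # draws actually fill the admissible interval
  expect_lt(min(xs), -1.45)
  expect_gt(max(xs), 1.45)
  expect_equal(unname(reset_start(g, u = 0.1)[["y"]]), 0.1)
})

test_that("step outcomes classify passage, frame hits, wall contact and ongoing motion", {
  g <- narrow_geom()
  s <- reward_schedule()
  pass <- evaluate_step(g, s, c(0, 9.9), c(0, 10.1))
  expect_equal(pass$cause, "passed_door")
  expect_equal(pass$reward, 5)
  expect_true(pass$terminal)

  mid <- evaluate_step(g, s, c(0.3, 4), c(0.4, 4.6))
  expect_equal(mid$cause, "ongoing")
  expect_equal(mid$reward, 0)
  expect_false(mid$terminal)

  # crossing at x = 0.9 overlaps the post: 0.9 > d_pos - radius = 0.5
  post <- evaluate_step(g, s, c(0.9, 9.9), c(0.9, 10.1))
  expect_equal(post$cause, "hit_door_post")
  expect_equal(post$reward, -1)
  expect_true(post$terminal)

  # wall contact punishes and slides under the default rule
  wall <- evaluate_step(g, s, c(1.4, 5), c(1.8, 5.2))
  expect_equal(wall$cause, "hit_wall")
  expect_equal(wall$reward, -1)
  expect_false(wall$terminal)
  expect_equal(wall$position[1], 1.5)
  wall_t <- evaluate_step(g, s, c(1.4, 5), c(1.8, 5.2), wall_rule = "terminal")
  expect_true(wall_t$terminal)

  expect_error(evaluate_step(track_geometry(1.00001), s, c(0, 1), c(0, 2)),
               NA)  # barely passable door is fine
})

test_that("crossings are exclusively passage or frame hit, and widening the door enlarges the passing set", {
  s <- reward_schedule()
  xs <- seq(-1.9, 1.9, by = 0.05)
  passing <- function(door) {
    g <- track_geometry(door)
    vapply(xs, function(x) {
      out <- evaluate_step(g, s, c(x, 9.9), c(x, 10.1))
      expect_true(out$cause %in% c("passed_door", "hit_door_post"))
      expect_true(out$terminal)
      out$cause == "passed_door"
    }, logical(1))
  }
  p2 <- passing("narrow"); p25 <- passing("medium"); p3 <- passing("wide")
  expect_true(all(p2 <= p25))
  expect_true(all(p25 <= p3))
  expect_true(sum(p2) < sum(p3))
})

test_that("reward is nonzero only on terminal or wall-contact steps", {
  g <- narrow_geom()
  s <- reward_schedule()
  set.seed(7)
  for (i in 1:200) {
    old <- c(runif(1, -1.4, 1.4), runif(1, 0.1, 9.5))
    new <- old + c(runif(1, -1, 1), runif(1, -0.2, 1.2))
    out <- evaluate_step(g, s, old, new)
    if (out$reward != 0)
      expect_true(out$terminal || out$cause == "hit_wall")
    else expect_false(out$terminal)
  }
})
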