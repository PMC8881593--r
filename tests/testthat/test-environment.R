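test_that("angle wrapping lands in the principal interval with the stated boundary", {
  expect_equal(wrap_angle(pi), pi)
  expect_equal(wrap_angle(-pi), pi)
  expect_equal(wrap_angle(3 * pi / 2), -pi / 2)
  expect_equal(wrap_deg(180), 180)
  expect_equal(wrap_deg(-180), 180)
  expect_equal(wrap_deg(270), -90)
  x <- seq(-20, 20, by = 0.37)
  expect_true(all(wrap_angle(x) > -pi & wrap_angle(x) <= pi))
  u <- unwrap_angle(wrap_angle(x))
  expect_equal(u - u[1], x - x[1], tolerance = 1e-12)
})

test_that("rotation trajectories integrate the angular-speed profile", {
  # zero velocity: identity
  traj <- make_rotation_trajectory(1, 0, heading0 = 0.4)
  expect_true(all(traj$heading == 0.4))
  expect_true(all(traj$x == 0 & traj$linear_speed == 0))
  # full revolution wraps back
  traj <- make_rotation_trajectory(2 * pi, 1, heading0 = 0.2)
  n <- nrow(traj)
  expect_equal(traj$heading[n], wrap_angle(0.2 + traj$t[n]), tolerance = 1e-9)
  expect_lt(abs(angle_diff(traj$heading[n], 0.2)), 0.002)
  # closed-form integration oracle: h(0.5 s) = h0 + 2 * 0.5
  traj <- make_rotation_trajectory(1, 2, dt = 0.001)
  expect_equal(traj$heading[traj$t == 0.5], 1.0, tolerance = 1e-9)
  # discrete consistency invariant
  expect_equal(traj$heading[-1],
               wrap_angle(traj$heading[-nrow(traj)] +
                          traj$angular_velocity[-nrow(traj)] * 0.001),
               tolerance = 1e-9)
  expect_error(make_rotation_trajectory(-1, 0), "positive")
  expect_error(make_rotation_trajectory(1, 0, dt = 0), "positive")
})

test_that("translation trajectories interpolate waypoints at constant speed", {
  traj <- make_translation_trajectory(1, rbind(c(0, 0), c(1, 0)),
                                      heading_profile = function(t) 0 * t)
  expect_equal(unique(round(traj$linear_speed, 6)), 1)
  expect_true(all(traj$angular_velocity == 0))
  # finite-difference speed consistency
  fd <- sqrt(diff(traj$x)^2 + diff(traj$y)^2) / 0.001
  expect_equal(fd, traj$linear_speed[-nrow(traj)], tolerance = 1e-6)
  # L-shaped path length
  traj <- make_translation_trajectory(2, rbind(c(0, 0), c(1, 0), c(1, 1)))
  expect_equal(path_length(traj), 2, tolerance = 1e-3)
  expect_error(
    make_translation_trajectory(1, rbind(c(0, 0), c(0, 0), c(1, 0))),
    "degenerate")
})

test_that("landmark bearings follow the egocentric convention", {
  lm_x <- landmark(1, 1, 0)
  lm_y <- landmark(2, 0, 1)
  expect_equal(landmark_bearing(0, 0, 0, lm_x), 0)
  expect_equal(landmark_bearing(0, 0, 0, lm_y), 90)
  expect_equal(landmark_bearing(0, 0, pi / 2, lm_y), 0)
  expect_error(landmark_bearing(1, 0, 0, lm_x), "degenerate")
})

test_that("bearings are equivariant under joint world/heading rotation", {
  set.seed(42)
  for (i in 1:20) {
    p <- runif(2, -3, 3); h <- runif(1, -pi, pi); rot <- runif(1, -pi, pi)
    lm <- landmark(1, runif(1, -9, 9), runif(1, -9, 9))
    b1 <- landmark_bearing(p[1], p[2], h, lm)
    # rotate landmark and agent position about the origin by rot, and the
    # heading by rot: egocentric bearing is unchanged
    R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
    lm2 <- landmark(1, sum(R[1, ] * lm$position), sum(R[2, ] * lm$position))
    p2 <- R %*% p
    b2 <- landmark_bearing(p2[1], p2[2], wrap_angle(h + rot), lm2)
    expect_equal(b1, b2, tolerance = 1e-9)
  }
})

test_that("distal landmarks have nearly position-invariant world bearings", {
  # for a landmark at distance d and a path of length l, the world-bearing
  # change is bounded by 2*asin(l / (2*d))
  traj <- default_translation_trajectory(duration = 10)
  l <- path_length(traj)
  for (d in c(50, 200)) {
    lm <- landmark(1, d, 0)
    wb <- atan2(lm$position[2] - traj$y, lm$position[1] - traj$x)
    spread <- max(wb) - min(wb)
    expect_lt(spread, 2 * asin(min(1, l / (2 * d))) + 1e-9)
  }
})

test_that("field-of-view test is symmetric and boundary-inclusive", {
  expect_true(in_fov(0, 270))
  expect_false(in_fov(180, 270))
  expect_true(in_fov(135, 270))
  expect_true(in_fov(-135, 270))
  expect_false(in_fov(135.01, 270))
})

test_that("trajectories and worlds round-trip through CSV", {
  traj <- make_rotation_trajectory(0.05, function(t) sin(t * 37))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  traj2 <- read_trajectory(f)
  for (col in names(traj))
    expect_equal(traj2[[col]], traj[[col]], tolerance = 1e-12)
  expect_equal(attr(traj2, "dt"), attr(traj, "dt"), tolerance = 1e-12)

  wld <- default_rotation_world()
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_world(wld, f2)
  wld2 <- read_world(f2)
  expect_equal(wld2$fov, wld$fov)
  for (k in 1:3) {
    expect_equal(wld2$landmarks[[k]]$position, wld$landmarks[[k]]$position,
                 tolerance = 1e-12)
    expect_identical(wld2$landmarks[[k]]$id, wld$landmarks[[k]]$id)
  }
})

test_that("default study worlds satisfy their geometric design", {
  wr <- default_rotation_world()
  d <- vapply(wr$landmarks, function(l) sqrt(sum(l$position^2)), numeric(1))
  expect_equal(d, rep(10, 3))
  ang <- sort(vapply(wr$landmarks, function(l)
    atan2(l$position[2], l$position[1]), numeric(1)))
  expect_equal(diff(ang), rep(2 * pi / 3, 2), tolerance = 1e-9)

  traj <- default_translation_trajectory()
  wt <- default_translation_world()
  d <- vapply(wt$landmarks, function(l)
    sqrt(sum((l$position - c(mean(traj$x), mean(traj$y)))^2)), numeric(1))
  expect_gt(min(d[1:2]) / path_length(traj), 2)   # distal pair far away
  expect_lt(d[3], 2 * max(diff(range(traj$x)), diff(range(traj$y))))
})
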