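test_that("population layout has the anatomical counts and angle tiling", {
  lay <- build_layout()
  expect_equal(nrow(lay), 141)
  counts <- table(lay$population)
  expect_equal(unname(counts[c("ring", "E-PG", "P-EN", "P-EG", "PIntr")]),
               c(81, 18, 16, 16, 10), ignore_attr = TRUE)
  # one more E-PG per hemisphere than P-EN / P-EG
  epg <- lay[lay$population == "E-PG", ]
  pen <- lay[lay$population == "P-EN", ]
  expect_equal(sum(epg$hemisphere == "L"), sum(pen$hemisphere == "L") + 1)
  # preferred angles tile the circle at 40 degree spacing per hemisphere
  for (h in c("L", "R")) {
    a <- sort(epg$preferred_angle[epg$hemisphere == h])
    expect_equal(diff(a), rep(2 * pi / 9, 8), tolerance = 1e-9)
  }
})

test_that("fixed connectome has the printed sign and block structure", {
  W <- build_connectome()
  post <- dimnames(W)$post
  is_pop <- function(nm, p) startsWith(nm, p)
  epg <- is_pop(post, "E-PG"); pen <- is_pop(post, "P-EN")
  peg <- is_pop(post, "P-EG"); pintr <- is_pop(post, "PIntr")

  # every present E-PG -> PIntr entry is 20
  blk <- W[pintr, epg]
  expect_true(all(blk[blk != 0] == 20))
  # every present PIntr -> P-EN / P-EG entry is -15
  expect_true(all(W[pen, pintr] == -15))
  expect_true(all(W[peg, pintr] == -15))
  # PIntr -> PIntr all -20
  expect_true(all(W[pintr, pintr] == -20))
  # PIntr never contact E-PG; E-PG have no self-excitation
  expect_true(all(W[epg, pintr] == 0))
  expect_true(all(W[epg, epg] == 0))
  # excitatory blocks are non-negative and bounded by the block weight
  for (blk in list(W[pen, epg], W[peg, epg], W[epg, pen], W[epg, peg])) {
    expect_true(all(blk >= 0))
    expect_true(all(blk <= 20 + 1e-12))
    expect_gt(max(blk), 10)
  }
  # no other connections exist
  expect_true(all(W[pen, pen] == 0) && all(W[peg, peg] == 0) &&
              all(W[pen, peg] == 0) && all(W[pintr, pen] == 0))
})

test_that("the connectome is mirror-symmetric between hemispheres", {
  W <- build_connectome()
  eg <- function(h, g) (h - 1) * 9 + g
  pn <- function(h, k) 18 + (h - 1) * 8 + k
  pg <- function(h, k) 34 + (h - 1) * 8 + k
  pi_ <- function(h, i) 50 + (h - 1) * 5 + i
  perm <- integer(60)
  for (g in 1:9) {
    gp <- ((1 - g) %% 9) + 1
    perm[eg(1, g)] <- eg(2, gp); perm[eg(2, g)] <- eg(1, gp)
  }
  for (k in 1:8) {
    kp <- ((1 - k) %% 8) + 1
    perm[pn(1, k)] <- pn(2, kp); perm[pn(2, k)] <- pn(1, kp)
    perm[pg(1, k)] <- pg(2, kp); perm[pg(2, k)] <- pg(1, kp)
  }
  servedL <- lapply(1:5, function(i) which(((1:9 - 1) %% 5) + 1 == i))
  servedR <- lapply(1:5, function(i) which((((1 - 1:9) %% 9) %% 5) + 1 == i))
  refl <- function(v) sort(((1 - v) %% 9) + 1)
  same <- function(a, b) length(a) == length(b) && all(sort(a) == sort(b))
  for (i in 1:5) {
    j <- which(vapply(servedR, same, logical(1), b = refl(servedL[[i]])))
    perm[pi_(1, i)] <- pi_(2, j[1])
    j2 <- which(vapply(servedL, same, logical(1), b = refl(servedR[[i]])))
    perm[pi_(2, i)] <- pi_(1, j2[1])
  }
  expect_lt(max(abs(W[perm, perm] - W)), 1e-9)
})

test_that("discrete LIF dynamics match the closed-form rate", {
  # current chosen so the continuous threshold-crossing time is an exact
  # multiple of the timestep (8 ms -> 100 Hz with the 2 ms refractory)
  i100 <- lif_current_for_rate(100)
  expect_equal(lif_rate_closed_form(i100), 100, tolerance = 1e-9)
  expect_equal(lif_rate_discrete(i100, duration_s = 4), 100, tolerance = 2)
  # subthreshold current never fires
  expect_equal(lif_rate_discrete(0.99), 0)
  expect_equal(lif_rate_closed_form(0.5), 0)
})

test_that("a bump persists without input and drifts less than one glomerulus per second", {
  wld <- default_rotation_world()
  traj <- make_rotation_trajectory(1.2, 0, heading0 = 1)
  for (s in 1:3) {
    set.seed(100 + s)
    run <- simulate_trial(wld, traj, config = "av_only", snapshot_every_s = 0)
    dec <- suppressWarnings(decode_heading(run$epg_trace))
    drift <- abs(angle_diff(dec$heading[1200], 1))
    expect_lt(drift, 2 * pi / 9)
    expect_gt(mean(run$epg_trace[1000:1200, ]) * 1000, 5)  # still alive
  }
})

test_that("angular-velocity input shifts the bump in the correct direction", {
  wld <- default_rotation_world()
  shift_speed <- function(av, seed = 5) {
    traj <- make_rotation_trajectory(4, av, heading0 = 0)
    set.seed(seed)
    run <- simulate_trial(wld, traj, config = "av_only", snapshot_every_s = 0)
    dec <- suppressWarnings(decode_heading(run$epg_trace))
    uh <- unwrap_angle(dec$heading[300:4000])
    unname(coef(stats::lm(uh ~ traj$t[300:4000]))[2])
  }
  # positive (counter-clockwise) and negative (clockwise) drive
  expect_gt(shift_speed(1.5), 0.5)
  expect_lt(shift_speed(-1.5), -0.5)
  # shift speed grows with |drive| over the linear range
  slow <- mean(vapply(1:2, function(s) shift_speed(0.7, s), numeric(1)))
  fast <- mean(vapply(1:2, function(s) shift_speed(2, s), numeric(1)))
  expect_gt(fast, slow)
})

test_that("inhibition prevents runaway excitation", {
  wld <- default_rotation_world()
  traj <- make_rotation_trajectory(5, function(t) 2 * sin(2 * pi * t / 20))
  set.seed(2)
  run <- simulate_trial(wld, traj, config = "av_only", snapshot_every_s = 0)
  lay <- build_layout()
  epg_rates <- run$spike_count[lay$population == "E-PG"] / 5
  expect_lt(mean(epg_rates), 400)
})

test_that("the network maintains a single activity bump", {
  wld <- default_rotation_world()
  traj <- make_rotation_trajectory(2, 0.5, heading0 = 2)
  set.seed(3)
  run <- simulate_trial(wld, traj, config = "av_only", snapshot_every_s = 0)
  # count contiguous circular clusters of active E-PG (per hemisphere) on
  # the smoothed late-trial trace
  for (hemi in list(1:9, 10:18)) {
    tr <- colMeans(run$epg_trace[1500:2000, hemi])
    on <- tr > 0.25 * max(tr)
    transitions <- sum(on != c(on[-1], on[1]))
    expect_equal(transitions, 2)  # one contiguous bump = 2 edges
  }
})

test_that("identical seeds give identical simulations", {
  wld <- default_rotation_world()
  traj <- make_rotation_trajectory(1, 1)
  set.seed(9)
  a <- simulate_trial(wld, traj, config = "online", snapshot_every_s = 0)
  set.seed(9)
  b <- simulate_trial(wld, traj, config = "online", snapshot_every_s = 0)
  expect_identical(a$epg_trace, b$epg_trace)
  expect_identical(a$w_final, b$w_final)
  expect_identical(a$spike_count, b$spike_count)
})

test_that("bump initialisation places the decoded heading at the target", {
  wld <- default_rotation_world()
  for (h0 in c(0, pi, -2)) {
    traj <- make_rotation_trajectory(0.4, 0, heading0 = h0)
    set.seed(4)
    run <- simulate_trial(wld, traj, config = "av_only", snapshot_every_s = 0)
    dec <- suppressWarnings(decode_heading(run$epg_trace))
    expect_lt(abs(angle_diff(dec$heading[300], h0)), 2 * pi / 9)
  }
})
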