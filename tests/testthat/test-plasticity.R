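test_that("ring input current is the weighted sum of activations", {
  inst <- random_plasticity_instance()
  expect_equal(input_current(inst$W, inst$r * 0), rep(0, 4))
  expect_equal(input_current(inst$W * 0, inst$r), rep(0, 4))
  W <- matrix(0, 4, 7); W[2, 3] <- -0.5
  r <- rep(0, 7); r[3] <- 2
  expect_equal(input_current(W, r), c(0, -1, 0, 0))
  expect_true(all(input_current(inst$W, inst$r) <= 0))
  expect_error(input_current(inst$W, 1:3), "shape")
})

test_that("the Hebbian rule evaluates as stated and is presynaptically gated", {
  p <- hebbian_params()
  expect_equal(p$eta, 0.29)
  expect_equal(p$a, 1.7e-6)
  expect_equal(p$b, 1.7e-4)

  # hand-computed single-synapse update: eta * (a*50 + b) at r = 1, w = 0
  W <- matrix(0, 1, 1)
  dW <- hebbian_update(W, r = 1, c = 50, p, clip = FALSE) - W
  expect_equal(dW[1, 1], 7.395e-5, tolerance = 1e-12)

  # inactive presynaptic channels never change
  inst <- random_plasticity_instance()
  r <- inst$r; r[c(2, 5)] <- 0
  W2 <- hebbian_update(inst$W, r, inst$c, p, clip = FALSE)
  expect_equal(W2[, c(2, 5)], inst$W[, c(2, 5)])

  # fixed point at w = a*c + b
  Wfp <- outer(p$a * inst$c + p$b, rep(1, 7))
  expect_equal(hebbian_update(Wfp, inst$r, inst$c, p, clip = FALSE), Wfp)

  # repeated updates converge geometrically to the (clipped) fixed point
  W <- matrix(-0.3, 4, 7)
  for (i in 1:500) W <- hebbian_update(W, inst$r, inst$c, p)
  active <- inst$r > 1e-8
  expect_equal(W[, active],
               clip_nonpositive(Wfp)[, active], tolerance = 1e-6)
})

test_that("the Hebbian update descends its objective (gradient equivalence)", {
  for (seed in 1:3) {
    inst <- random_plasticity_instance(seed)
    p <- hebbian_params()
    f <- function(W) hebbian_objective(W, inst$r, inst$c, p$a, p$b)
    G <- fd_gradient(f, inst$W, h = 1e-3)
    dW <- hebbian_update(inst$W, inst$r, inst$c, p, clip = FALSE) - inst$W
    # dW = -eta * grad(phi), checked elementwise at 1e-6 relative tolerance
    expect_equal(dW, -p$eta * G, tolerance = 1e-6)
  }
  # objective special cases
  inst <- random_plasticity_instance()
  expect_equal(hebbian_objective(inst$W, inst$r * 0, inst$c), 0)
  b <- 1.7e-4
  expect_equal(hebbian_objective(matrix(b, 4, 7), inst$r, inst$c, a = 0, b = b), 0)
})

test_that("the error-minimising rule descends the squared-error objective", {
  beta <- 0.0025
  for (seed in 4:6) {
    inst <- random_plasticity_instance(seed)
    p <- errmin_params(eta = 0.29, beta = beta)
    f <- function(W) errmin_objective(W, inst$r, inst$c, beta)
    G <- fd_gradient(f, inst$W, h = 1e-3)
    dW <- errmin_update(inst$W, inst$r, inst$c, p, clip = FALSE) - inst$W
    # dW = -eta/(2 beta) * grad(phi'), per the chain-rule derivation
    expect_equal(dW, -p$eta / (2 * beta) * G, tolerance = 1e-6)
  }
  inst <- random_plasticity_instance()
  # exact match is the objective's zero and the rule's fixed point
  cfit <- beta * input_current(inst$W, inst$r)
  expect_equal(errmin_objective(inst$W, inst$r, cfit, beta), 0)
  expect_equal(errmin_update(inst$W, inst$r, cfit, errmin_params(), clip = FALSE),
               inst$W)
  # beta = 0 reduces to the raw activity norm; always non-negative
  expect_equal(errmin_objective(inst$W, inst$r, inst$c, 0), sum(inst$c^2))
  expect_gte(errmin_objective(inst$W, inst$r, inst$c, 0.1), 0)
  # presynaptic gating shared with the Hebbian rule
  r <- inst$r; r[1:3] <- 0
  W2 <- errmin_update(inst$W, r, inst$c, errmin_params(), clip = FALSE)
  expect_equal(W2[, 1:3], inst$W[, 1:3])
})

test_that("weight clipping is the non-positive projection", {
  W <- matrix(c(-1, 0.1, 0, -0.2), 2)
  expect_equal(clip_nonpositive(W), matrix(c(-1, 0, 0, -0.2), 2))
  expect_equal(clip_nonpositive(clip_nonpositive(W)), clip_nonpositive(W))
  Wn <- -abs(matrix(rnorm(4), 2))
  expect_equal(clip_nonpositive(Wn), Wn)
})

test_that("the target compass profile peaks at matched headings and is equivariant", {
  pref <- epg_preferred_angles()
  h <- seq(-pi, pi, length.out = 41)[-41]
  ct <- target_compass_activity(h, pref)
  # at each timestep the most active neuron is the one nearest the heading
  for (j in seq_along(h)) {
    best <- which.max(ct[, j])
    expect_lt(abs(angle_diff(pref[best], h[j])), 2 * pi / 18 + 1e-9)
  }
  # hemisphere partners at equal angular distance receive equal targets
  expect_equal(max(ct), cx_defaults()$target_amp)
  # shifting all headings by one glomerulus permutes the response profile
  ct2 <- target_compass_activity(wrap_angle(h + 2 * pi / 9), pref)
  for (n in 1:18) {
    # neuron n's response to the shifted headings equals the response of
    # the neuron one glomerulus clockwise to the originals: the rows
    # permute by one glomerulus
    partner <- which.min(abs(angle_diff(pref, pref[n] - 2 * pi / 9)))
    expect_equal(ct2[n, ], ct[partner, ], tolerance = 1e-9)
  }
})

test_that("the offline optimiser recovers planted non-negative weights", {
  set.seed(21)
  Tn <- 600; M <- 81
  r <- matrix(runif(Tn * M), Tn, M)
  w_true <- matrix(0, 18, M)
  w_true[cbind(rep(1:18, 3), sample(1:M, 54))] <- runif(54, 0.5, 2)
  alpha <- runif(18, 5, 6)
  # exact generative model in the disinhibition form: targets equal a
  # per-neuron baseline minus the non-negative weighted ring activation
  c_target <- -r %*% t(w_true) + matrix(alpha, Tn, 18, byrow = TRUE)
  fit <- optimize_weights_offline(r, t(c_target), lambda = 0)
  expect_equal(fit$w_raw, w_true, tolerance = 1e-3)
  expect_true(all(fit$w <= 0))
  expect_equal(fit$w, -0.0025 * fit$w_raw)

  # independent oracle: non-negative least squares, neuron by neuron, with
  # the intercept expressed as a difference of two non-negative columns
  skip_if_not_installed("pracma")
  for (n in c(3, 11)) {
    A <- cbind(-r, 1, -1)
    z <- pracma::lsqnonneg(A, as.numeric(c_target[, n]))$x
    expect_equal(z[1:M], w_true[n, ], tolerance = 1e-3)
  }

  # a dominating penalty drives all weights to zero
  fit0 <- optimize_weights_offline(r, t(c_target), lambda = 1e6)
  expect_true(all(fit0$w_raw == 0))
  expect_error(optimize_weights_offline(r * 0, t(c_target), lambda = 0),
               "degenerate")
})

test_that("offline fit residual does not increase with more data", {
  set.seed(22)
  wld <- default_rotation_world()
  traj <- default_rotation_trajectory(duration = 20)
  bank <- ring_tuning_bank()
  r <- ring_activation_matrix(trajectory_bearings(traj, wld), bank)
  keep1 <- seq(1, 10000, by = 20); keep2 <- seq(1, 20000, by = 20)
  ct1 <- target_compass_activity(traj$heading[keep1])
  ct2 <- target_compass_activity(traj$heading[keep2])
  f1 <- optimize_weights_offline(r[keep1, ], ct1, lambda = 1e-4)
  f2 <- optimize_weights_offline(r[keep2, ], ct2, lambda = 1e-4)
  rss <- function(fit, rr, ct) {
    pred <- -rr %*% t(fit$w_raw) - matrix(fit$alpha, nrow(rr), 18, byrow = TRUE)
    mean((t(ct) - pred)^2)
  }
  # mean residual on the shared early block does not get worse with the
  # nested larger fit (both fits see that block)
  expect_lt(rss(f2, r[keep1, ], ct1), rss(f1, r[keep1, ], ct1) * 1.5)
})
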