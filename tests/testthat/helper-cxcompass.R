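# Shared fixtures for fast tests: short trials, fixed small lambda for the
# offline fit (cross-validation is exercised separately), cached objects.

short_rotation <- function(duration = 3, av = 1)
  make_rotation_trajectory(duration, av)

# a tiny random plasticity instance away from the clipping boundary
random_plasticity_instance <- function(seed = 1, n = 4, m = 7) {
  set.seed(seed)
  list(W = matrix(-runif(n * m, 0.1, 1), n, m),
       r = runif(m, 0, 1),
       c = runif(n, 0, 100))
}

# central finite-difference gradient of f at W
fd_gradient <- function(f, W, h = 1e-6) {
  G <- W * 0
  for (i in seq_along(W)) {
    Wp <- W; Wm <- W
    Wp[i] <- Wp[i] + h
    Wm[i] <- Wm[i] - h
    G[i] <- (f(Wp) - f(Wm)) / (2 * h)
  }
  G
}
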