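#' Hebbian learning-rule parameters
#'
#' Presynaptically-gated Hebbian rule
#' `dw_nm = eta * r_m * (a * c_n + b - w_nm)`, with r_m the (normalised)
#' ring-neuron activation and c_n the E-PG activation trace in Hz.
#'
#' @param eta learning rate.
#' @param a,b rule constants.
#' @return a `cx_hebbian_params` list.
#' @export
hebbian_params <- function(eta = 0.29, a = 1.7e-6, b = 1.7e-4) {
  stopifnot(eta > 0)
  structure(list(eta = eta, a = a, b = b), class = "cx_hebbian_params")
}

#' Error-minimising rule parameters
#'
#' `dw_nm = eta * r_m * (c_n - beta * I_n)` with `I_n` the total ring input
#' current to E-PG neuron n; gradient descent on the squared mismatch
#' between E-PG activity and its scaled ring input.
#'
#' @param eta learning rate.
#' @param beta current-to-activity scaling.
#' @return a `cx_errmin_params` list.
#' @export
errmin_params <- function(eta = 0.29, beta = 0.0025) {
  stopifnot(eta > 0, beta > 0)
  structure(list(eta = eta, beta = beta), class = "cx_errmin_params")
}

check_w_shapes <- function(W, r, c = NULL) {
  if (!is.matrix(W)) stop("W must be a matrix")
  if (ncol(W) != length(r)) stop("shape mismatch: ncol(W) != length(r)")
  if (!is.null(c) && nrow(W) != length(c))
    stop("shape mismatch: nrow(W) != length(c)")
  invisible(TRUE)
}

#' Total ring input current to each E-PG neuron
#'
#' `I_n = sum_m r_m * w_nm`; non-positive elementwise whenever `r >= 0`
#' and `W <= 0`.
#'
#' @param W 18 x 81 plastic weight matrix (rows: E-PG, cols: ring).
#' @param r ring activation vector.
#' @return numeric vector of length `nrow(W)`.
#' @export
input_current <- function(W, r) {
  check_w_shapes(W, r)
  drop(W %*% r)
}

#' Clip weights to the non-positive orthant
#'
#' Ring neurons are inhibitory, so the maximum effective ring-to-E-PG
#' weight is zero.
#'
#' @param W weight matrix.
#' @return `pmin(W, 0)`, idempotent.
#' @export
clip_nonpositive <- function(W) pmin(W, 0)

#' One step of the presynaptically-gated Hebbian rule
#'
#' @param W current weights (post x pre).
#' @param r presynaptic (ring) activations, `>= 0`.
#' @param c postsynaptic (E-PG) activation traces, `>= 0`.
#' @param p [hebbian_params()].
#' @param clip clip the result to `<= 0` (the stated weight constraint);
#'   set `FALSE` to inspect the raw update.
#' @return updated weight matrix.
#' @export
hebbian_update <- function(W, r, c, p = hebbian_params(), clip = TRUE) {
  check_w_shapes(W, r, c)
  dW <- p$eta * (outer(p$a * c + p$b, r) - W * rep(r, each = nrow(W)))
  W <- W + dW
  if (clip) clip_nonpositive(W) else W
}

#' Objective function minimised by the Hebbian rule
#'
#' `phi = -a * sum_n c_n I_n + 1/2 * sum_n sum_m r_m (b - w_nm)^2`: the
#' first term rewards alignment of E-PG activity with its total ring input
#' current, the second regularises every presynaptically-active weight
#' towards b.  The Hebbian update equals `-eta * d(phi)/dW`.
#'
#' @inheritParams hebbian_update
#' @param a,b rule constants.
#' @return scalar objective value.
#' @export
hebbian_objective <- function(W, r, c, a = 1.7e-6, b = 1.7e-4) {
  check_w_shapes(W, r, c)
  I <- input_current(W, r)
  -a * sum(c * I) + 0.5 * sum(rep(r, each = nrow(W)) * (b - W)^2)
}

#' Squared-error objective of the error-minimising rule
#'
#' `phi' = sum_n (c_n - beta * I_n)^2`, zero exactly when the scaled ring
#' input current reproduces the E-PG activity.
#'
#' @inheritParams hebbian_update
#' @param beta current-to-activity scaling.
#' @return scalar, `>= 0`.
#' @export
errmin_objective <- function(W, r, c, beta = 0.0025) {
  check_w_shapes(W, r, c)
  sum((c - beta * input_current(W, r))^2)
}

#' One step of the error-minimising rule
#'
#' `dw_nm = eta * r_m * (c_n - beta * I_n)`; proportional to the negative
#' gradient of [errmin_objective()] (factor `eta / (2 beta)`).
#'
#' @inheritParams hebbian_update
#' @param p [errmin_params()].
#' @return updated weight matrix.
#' @export
errmin_update <- function(W, r, c, p = errmin_params(), clip = TRUE) {
  check_w_shapes(W, r, c)
  err <- c - p$beta * input_current(W, r)
  W <- W + p$eta * outer(err, r)
  if (clip) clip_nonpositive(W) else W
}

#' Target compass activation profile for the offline fit
#'
#' For each timestep, each E-PG neuron's target is a circular Gaussian of
#' the wrapped difference between the true heading and the neuron's
#' preferred angle (sd one glomerulus = 40 degrees), scaled by `amplitude`.
#'
#' @param headings vector of true headings, radians (wrapped).
#' @param preferred_angles E-PG preferred angles, radians (default the
#'   18-neuron layout).
#' @param amplitude peak target activation.
#' @param sigma profile standard deviation, radians.
#' @return matrix `length(preferred_angles)` x `length(headings)`.
#' @export
target_compass_activity <- function(headings,
                                    preferred_angles = epg_preferred_angles(),
                                    amplitude = cx_defaults()$target_amp,
                                    sigma = 2 * pi / 9) {
  d <- outer(preferred_angles, headings, angle_diff)
  amplitude * exp(-d^2 / (2 * sigma^2))
}

#' Offline optimal plastic weights by lasso-regularised positive regression
#'
#' For each E-PG neuron n, solves
#' `min_{wt >= 0, alpha} sum_t (ct_n(t) - sum_m(-r_m(t) wt_nm) + alpha_n)^2
#'  + lambda * sum_m wt_nm`
#' and returns the simulation weights `w_nm = -beta_scale * wt_nm`
#' (non-positive).  The fit is performed with coordinate-descent lasso
#' (`glmnet`) on the negated ring activations with non-negativity bounds.
#'
#' @param r_ts T x 81 matrix of ring activations over the fitted trial.
#' @param c_target 18 x T matrix of target compass activations
#'   ([target_compass_activity()]).
#' @param lambda lasso penalty; `"cv"` selects it by 5-fold blocked
#'   cross-validation (contiguous time blocks, so the folds respect the
#'   serial dependence of a trajectory).
#' @param beta_scale scaling applied with the sign flip (0.0025).
#' @return list with `w` (18 x 81, `<= 0`), `w_raw` (the non-negative
#'   fitted weights), `alpha` (per-neuron intercepts, the disinhibition
#'   baseline), and `lambda` (the value used).
#' @export
optimize_weights_offline <- function(r_ts, c_target, lambda = "cv",
                                     beta_scale = 0.0025) {
  r_ts <- as.matrix(r_ts)
  if (nrow(r_ts) < ncol(r_ts)) stop("need at least as many timesteps as ring channels")
  if (all(r_ts == 0)) stop("degenerate design: all-zero ring activations")
  c_target <- as.matrix(c_target)
  if (ncol(c_target) != nrow(r_ts))
    stop("shape mismatch: ncol(c_target) must equal nrow(r_ts)")
  X <- -r_ts
  n_epg <- nrow(c_target)
  Tn <- nrow(X)

  if (identical(lambda, "cv")) {
    folds <- rep(1:5, each = ceiling(Tn / 5))[seq_len(Tn)]  # blocked folds
    cvs <- vapply(seq_len(n_epg), function(n) {
      cv <- glmnet::cv.glmnet(X, c_target[n, ], lower.limits = 0,
                              standardize = FALSE, foldid = folds)
      cv$lambda.min
    }, numeric(1))
    lambda <- stats::median(cvs)
  }

  w_raw <- matrix(0, n_epg, ncol(X))
  alpha <- numeric(n_epg)
  for (n in seq_len(n_epg)) {
    y <- c_target[n, ]
    if (stats::sd(y) == 0) {        # constant target: intercept-only fit
      alpha[n] <- mean(y)
      next
    }
    fit <- glmnet::glmnet(X, y, lambda = lambda,
                          lower.limits = 0, standardize = FALSE)
    w_raw[n, ] <- as.numeric(fit$beta)
    alpha[n] <- as.numeric(fit$a0)
  }
  list(w = clip_nonpositive(-beta_scale * w_raw), w_raw = w_raw,
       alpha = -alpha, lambda = lambda)
}

#' Offline optimal weights for a world/trajectory pair
#'
#' Convenience wrapper: builds the analytic ring activations and the target
#' compass profile for a trial and fits [optimize_weights_offline()].  The
#' fit is deterministic given the trajectory, so a single solution serves
#' all simulation seeds.
#'
#' @param wld a `cx_world`.
#' @param traj a `cx_trajectory`.
#' @param thin fit every `thin`-th timestep (the 1 ms grid is redundant for
#'   a regression across a 60 s trial).
#' @param ... passed to [optimize_weights_offline()].
#' @return see [optimize_weights_offline()].
#' @export
fit_optimal_weights <- function(wld, traj, thin = 10, ...) {
  keep <- seq(1, nrow(traj), by = thin)
  bank <- ring_tuning_bank(fov = wld$fov)
  r_ts <- ring_activation_matrix(trajectory_bearings(traj, wld), bank)[keep, ]
  c_t <- target_compass_activity(traj$heading[keep])
  optimize_weights_offline(r_ts, c_t, ...)
}
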