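#' Ring-neuron tuning bank
#'
#' 27 ring neurons per landmark, receptive-field centres spaced 10 degrees
#' spanning the 270 degree field of view, each with a Gaussian tuning curve
#' of standard deviation 6.44 degrees (adjacent curves overlap at half
#' maximum).  Three landmark-specific sub-populations give 81 channels.
#'
#' @param n_landmarks number of landmark sub-populations.
#' @param n_per_landmark ring neurons per landmark.
#' @param fov field of view in degrees spanned by the centres.
#' @param sigma tuning-curve standard deviation, degrees.
#' @param peak_current input current injected at the receptive-field centre
#'   (model current units; drives the ring LIF neuron).
#' @return a `cx_ring_bank` object with a `centers` vector in degrees.
#' @export
ring_tuning_bank <- function(n_landmarks = 3, n_per_landmark = 27, fov = 270,
                             sigma = 6.44, peak_current = 6) {
  stopifnot(sigma > 0, n_per_landmark > 1)
  spacing <- fov / n_per_landmark
  centers <- seq(-(fov / 2) + spacing / 2, (fov / 2) - spacing / 2,
                 length.out = n_per_landmark)
  structure(list(n_landmarks = n_landmarks, n_per_landmark = n_per_landmark,
                 fov = fov, sigma = sigma, peak_current = peak_current,
                 centers = centers),
            class = "cx_ring_bank")
}

#' Normalised ring activation profile for one landmark bearing
#'
#' Gaussian of the wrapped angular distance to each centre; zero everywhere
#' if the landmark is outside the field of view or not detected (`NA`).
#'
#' @param bearing degrees in (-180, 180], or `NA` for an undetected
#'   landmark (e.g. sensor frame dropout).
#' @param bank a [ring_tuning_bank()].
#' @return numeric vector of length `bank$n_per_landmark` in `[0, 1]`.
#' @keywords internal
ring_activation_one <- function(bearing, bank) {
  if (is.na(bearing) || !in_fov(bearing, bank$fov))
    return(numeric(bank$n_per_landmark) * 0)
  d <- wrap_deg(bearing - bank$centers)
  exp(-d^2 / (2 * bank$sigma^2))
}

#' Ring input currents from per-landmark bearings
#'
#' @param bearings numeric vector, one egocentric bearing per landmark
#'   (degrees; `NA` = not detected).
#' @param bank a [ring_tuning_bank()].
#' @return 81-vector of input currents (non-negative, bounded by
#'   `peak_current`).
#' @export
ring_drive <- function(bearings, bank) {
  if (length(bearings) != bank$n_landmarks)
    stop(sprintf("expected %d landmark bearings, got %d",
                 bank$n_landmarks, length(bearings)))
  bank$peak_current *
    unlist(lapply(bearings, ring_activation_one, bank = bank))
}

#' Normalised ring activation matrix for a whole trajectory
#'
#' @param bearings T x n_landmarks matrix of degrees (`NA` = dropout).
#' @param bank a [ring_tuning_bank()].
#' @return T x (n_landmarks * n_per_landmark) matrix in `[0, 1]`.
#' @export
ring_activation_matrix <- function(bearings, bank) {
  bearings <- as.matrix(bearings)
  if (ncol(bearings) != bank$n_landmarks)
    stop("bearing matrix has the wrong number of landmark columns")
  out <- matrix(0, nrow(bearings), bank$n_landmarks * bank$n_per_landmark)
  for (k in seq_len(bank$n_landmarks)) {
    b <- bearings[, k]
    ok <- !is.na(b) & in_fov(b, bank$fov)
    if (any(ok)) {
      d <- outer(b[ok], bank$centers, function(bb, cc) wrap_deg(bb - cc))
      cols <- (k - 1) * bank$n_per_landmark + seq_len(bank$n_per_landmark)
      out[ok, cols] <- exp(-d^2 / (2 * bank$sigma^2))
    }
  }
  out
}

#' Angular-velocity encoder for P-EN neurons
#'
#' Eight P-EN neurons per hemisphere; the right hemisphere is driven by
#' positive (counter-clockwise) angular velocity, the left by negative.
#' The current injected at the 10 rad/s saturation speed is fixed so that
#' an isolated P-EN LIF neuron fires at 250 Hz; below saturation the
#' current grows linearly with a slope calibrated so that the attractor
#' bump rotates at the commanded angular speed (see the package vignette).
#'
#' @param n_per_hemisphere P-EN neurons per hemisphere.
#' @param saturation_speed rad/s at which the drive saturates.
#' @param target_peak_rate steady-state firing rate (Hz) of an isolated
#'   P-EN neuron at the saturation speed.
#' @param gain current per rad/s below saturation; `NULL` uses the
#'   calibrated package default.
#' @param baseline current injected into every P-EN regardless of angular
#'   velocity (default 0: purely rectified encoding).  The simulator's
#'   trial conditions use a nonzero baseline (see [cx_defaults()]), which
#'   keeps both hemispheres' P-EN near their recruitment threshold so that
#'   the velocity differential steers the bump smoothly.
#' @param exponent shape of the speed-to-current curve between zero and the
#'   saturation speed (1 = linear).  The simulator uses a mildly concave
#'   curve calibrated so that the emergent bump-shift speed - which grows
#'   supralinearly with the current differential - matches the commanded
#'   angular velocity across the trial's speed range.
#' @param gain current per rad/s at the saturation speed; `NULL` anchors
#'   the curve so the saturation current is reached exactly at
#'   `saturation_speed`.
#' @param calibration optional closed-loop calibration of the
#'   speed-to-current curve: a list with `speeds` (rad/s) and `drives`
#'   (currents above baseline), interpolated monotonically.  This maps
#'   each commanded speed to the differential current that makes the
#'   attractor bump rotate at that speed (the bump-speed response to
#'   current has a recruitment dead zone and a linear region, measured
#'   once for the packaged operating point; see the vignette).  The last
#'   entry anchors the saturation current at the saturation speed.
#' @param lif [lif_params()] used to anchor the saturation current.
#' @return a `cx_av_encoder`.
#' @export
av_encoder <- function(n_per_hemisphere = 8, saturation_speed = 10,
                       target_peak_rate = 250, gain = NULL, baseline = 0,
                       exponent = 1, calibration = NULL, lif = lif_params()) {
  sat_current <- lif_current_for_rate(target_peak_rate, lif)
  if (is.null(gain))
    gain <- (sat_current - baseline) / saturation_speed
  structure(list(n_per_hemisphere = n_per_hemisphere,
                 saturation_speed = saturation_speed,
                 target_peak_rate = target_peak_rate,
                 sat_current = sat_current, gain = gain,
                 baseline = baseline, exponent = exponent,
                 calibration = calibration),
            class = "cx_av_encoder")
}

#' Packaged bump-shift calibration curve
#'
#' Recruitment dead zone of ~0.7 current below which the bump does not
#' move, then an approximately linear response up to ~2.3 rad/s (knots
#' measured by commanding constant speeds and recording the bump's
#' rotation rate), then a linear continuation to the anchored saturation
#' current at 10 rad/s.
#'
#' @param baseline the encoder baseline current (subtracted from the
#'   saturation current for the last knot).
#' @param lif [lif_params()].
#' @return a calibration list for [av_encoder()].
#' @export
av_shift_calibration <- function(baseline = cx_defaults()$av_baseline,
                                 lif = lif_params()) {
  sat <- lif_current_for_rate(250, lif)
  list(speeds = c(0, 0.02, 0.3, 0.6, 1, 1.5, 2, 2.3, 10),
       drives = c(0, 0.70, 0.81, 0.90, 1.12, 1.45, 1.85, 2.05,
                  sat - baseline))
}

#' P-EN input currents from an angular velocity
#'
#' @param av angular velocity, rad/s (scalar or vector).
#' @param enc an [av_encoder()].
#' @return for scalar `av`, a 16-vector (left hemisphere first, then
#'   right); for vector `av`, a T x 2 matrix of (left, right) currents that
#'   the simulator expands per neuron.
#' @export
pen_drive <- function(av, enc) {
  stopifnot(all(is.finite(av)))
  vs <- enc$saturation_speed
  shape <- function(a) {
    a <- pmin(a, vs)
    if (!is.null(enc$calibration))
      return(stats::approx(enc$calibration$speeds, enc$calibration$drives,
                           xout = a, rule = 2)$y)
    enc$gain * vs * (a / vs)^enc$exponent
  }
  right <- pmin(enc$baseline + shape(pmax(av, 0)),  enc$sat_current)
  left  <- pmin(enc$baseline + shape(pmax(-av, 0)), enc$sat_current)
  if (length(av) == 1L)
    return(c(rep(left, enc$n_per_hemisphere), rep(right, enc$n_per_hemisphere)))
  cbind(left = left, right = right)
}

#' Noise model for simulated trials
#'
#' Zero-mean Gaussian noise with standard deviation 0.1 rad/s is added to
#' the angular-velocity signal each timestep; independent Gaussian state
#' noise with standard deviation 0.1 (current units) is added to P-EG and
#' PIntr neurons.  All randomness flows from R's seeded generator.
#'
#' @param av_sigma angular-velocity noise, rad/s.
#' @param state_sigma current noise on P-EG and PIntr neurons.
#' @return a `cx_noise_model`.
#' @export
noise_model <- function(av_sigma = 0.1, state_sigma = 0.1) {
  stopifnot(av_sigma >= 0, state_sigma >= 0)
  structure(list(av_sigma = av_sigma, state_sigma = state_sigma),
            class = "cx_noise_model")
}

#' Add angular-velocity measurement noise
#'
#' @param av angular velocity (rad/s), scalar or vector.
#' @param noise a [noise_model()].
#' @return `av` plus one N(0, av_sigma^2) draw per element.
#' @export
add_av_noise <- function(av, noise = noise_model()) {
  stopifnot(all(is.finite(av)))
  if (noise$av_sigma == 0) return(av)
  av + stats::rnorm(length(av), 0, noise$av_sigma)
}
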