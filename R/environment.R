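#' Construct a landmark
#'
#' @param id small integer identifier, unique within a world.
#' @param x,y position in metres, world frame.
#' @param color label used for reporting only.
#' @return a `cx_landmark` list.
#' @export
landmark <- function(id, x, y, color = NA_character_) {
  stopifnot(is.finite(x), is.finite(y))
  structure(list(id = as.integer(id), position = c(x, y), color = color),
            class = "cx_landmark")
}

#' Construct a world of landmarks with a limited field of view
#'
#' The order of landmarks is fixed and meaningful: landmark k drives the
#' k-th sub-population of ring neurons.
#'
#' @param landmarks list of [landmark()] objects (three by default usage).
#' @param fov angular width of the visual field in degrees, centred on the
#'   heading (default 270).
#' @return a `cx_world` object.
#' @export
world <- function(landmarks, fov = 270) {
  stopifnot(fov > 0, fov <= 360)
  ids <- vapply(landmarks, function(l) l$id, integer(1))
  if (anyDuplicated(ids)) stop("landmark ids must be unique within a world")
  structure(list(landmarks = landmarks, fov = fov), class = "cx_world")
}

#' Print a world summary
#' @param x a `cx_world`.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
print.cx_world <- function(x, ...) {
  cat(sprintf("<cx_world: %d landmarks, %g degree field of view>\n",
              length(x$landmarks), x$fov))
  invisible(x)
}

new_trajectory <- function(t, x, y, heading, angular_velocity, linear_speed,
                           dt) {
  df <- data.frame(t = t, x = x, y = y, heading = heading,
                   angular_velocity = angular_velocity,
                   linear_speed = linear_speed)
  structure(df, dt = dt, class = c("cx_trajectory", "data.frame"))
}

#' Rotation-only trajectory
#'
#' The agent stays at the origin and rotates according to an angular-speed
#' profile; headings are the Euler integral of the profile, wrapped to
#' (-pi, pi].
#'
#' @param duration trial duration in seconds.
#' @param angular_speed_fn function of time (s) returning angular velocity
#'   in rad/s, or a single number for constant speed.
#' @param dt timestep in seconds (default 0.001).
#' @param heading0 initial heading, radians.
#' @return a `cx_trajectory` data frame with one row per timestep.
#' @export
make_rotation_trajectory <- function(duration, angular_speed_fn, dt = 0.001,
                                     heading0 = 0) {
  if (duration <= 0) stop("duration must be positive")
  if (dt <= 0) stop("dt must be positive")
  if (is.numeric(angular_speed_fn)) {
    av_const <- angular_speed_fn
    angular_speed_fn <- function(t) rep(av_const, length(t))
  }
  n <- round(duration / dt)
  t <- (seq_len(n) - 1) * dt
  av <- angular_speed_fn(t)
  stopifnot(length(av) == n)
  heading <- wrap_angle(heading0 + c(0, cumsum(av[-n]) * dt))
  new_trajectory(t, 0, 0, heading, av, 0, dt)
}

#' Translation trajectory through waypoints
#'
#' Positions interpolate the waypoints at constant speed; heading follows an
#' arbitrary profile (default: the smoothed path tangent, emulating a
#' vehicle that roughly faces its direction of travel).  Angular velocity is
#' the exact discrete derivative of the heading so that
#' `heading[t+1] == wrap(heading[t] + av[t]*dt)` holds to machine precision.
#'
#' @param duration trial duration, seconds.
#' @param waypoints numeric matrix (k x 2) of metres, k >= 2.
#' @param heading_profile optional function of time (s) returning heading in
#'   radians; `NULL` uses the smoothed tangent.
#' @param dt timestep, seconds.
#' @param smooth_sd standard deviation (s) of the Gaussian smoothing applied
#'   to the tangent heading when `heading_profile` is `NULL`.
#' @return a `cx_trajectory`.
#' @export
make_translation_trajectory <- function(duration, waypoints,
                                        heading_profile = NULL, dt = 0.001,
                                        smooth_sd = 0.5) {
  if (duration <= 0) stop("duration must be positive")
  waypoints <- as.matrix(waypoints)
  if (nrow(waypoints) < 2L) stop("need at least 2 waypoints")
  seg <- diff(waypoints)
  seg_len <- sqrt(rowSums(seg^2))
  if (any(seg_len == 0)) stop("coincident consecutive waypoints (degenerate segment)")
  total_len <- sum(seg_len)

  n <- round(duration / dt)
  t <- (seq_len(n) - 1) * dt
  # arc-length position at constant overall speed
  s <- total_len * t / duration
  cum <- c(0, cumsum(seg_len))
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx > length(seg_len)] <- length(seg_len)
  frac <- (s - cum[idx]) / seg_len[idx]
  pos <- waypoints[idx, , drop = FALSE] + frac * seg[idx, , drop = FALSE]

  if (is.null(heading_profile)) {
    tang <- atan2(seg[idx, 2], seg[idx, 1])
    heading <- smooth_heading(tang, dt, smooth_sd)
  } else {
    heading <- wrap_angle(heading_profile(t))
  }
  av <- c(wrap_angle(diff(heading)) / dt, 0)
  speed <- c(sqrt(rowSums(diff(pos)^2)) / dt, total_len / duration)
  new_trajectory(t, pos[, 1], pos[, 2], heading, av, speed, dt)
}

# Gaussian-smooth an angle series (handles wrap-around via unwrapping)
smooth_heading <- function(theta, dt, smooth_sd) {
  u <- unwrap_angle(theta)
  if (smooth_sd <= 0) return(wrap_angle(u))
  half <- ceiling(3 * smooth_sd / dt)
  k <- stats::dnorm(seq(-half, half) * dt, sd = smooth_sd)
  k <- k / sum(k)
  padded <- c(rep(u[1], half), u, rep(u[length(u)], half))
  sm <- stats::filter(padded, k, sides = 2)
  wrap_angle(as.numeric(sm[(half + 1):(half + length(u))]))
}

#' Path length of a trajectory
#' @param traj a `cx_trajectory`.
#' @return total ground-truth path length in metres.
#' @export
path_length <- function(traj) {
  sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
}

#' Egocentric bearing of a landmark
#'
#' The bearing is the landmark's world-frame direction minus the agent's
#' heading, wrapped to (-180, 180] degrees, counter-clockwise positive.  A
#' landmark dead ahead has bearing 0.
#'
#' @param x,y agent position (metres).
#' @param heading agent heading (radians).
#' @param lm a [landmark()].
#' @return bearing in degrees.
#' @export
landmark_bearing <- function(x, y, heading, lm) {
  dx <- lm$position[1] - x
  dy <- lm$position[2] - y
  if (any(dx == 0 & dy == 0))
    stop("landmark coincides with agent position (degenerate geometry)")
  wrap_deg(rad2deg(atan2(dy, dx) - heading))
}

#' Field-of-view membership test
#'
#' The field of view is centred on the heading and symmetric; the boundary
#' is inclusive.
#'
#' @param bearing egocentric bearing, degrees in (-180, 180].
#' @param fov field-of-view width, degrees.
#' @return logical vector.
#' @export
in_fov <- function(bearing, fov) abs(bearing) <= fov / 2

#' Per-step landmark bearings for a trajectory
#'
#' @param traj a `cx_trajectory`.
#' @param wld a `cx_world`.
#' @return numeric matrix, `nrow(traj)` x number of landmarks, degrees.
#'   Out-of-FOV entries are retained (clipping happens in the encoder).
#' @export
trajectory_bearings <- function(traj, wld) {
  sapply(wld$landmarks, function(lm)
    landmark_bearing(traj$x, traj$y, traj$heading, lm))
}

# ---- default study conditions -------------------------------------------

#' Default rotation-trial world and trajectory
#'
#' Three distal landmarks at 120 degree spacing, 10 m from the origin; the
#' agent rotates in place under a sinusoidal angular-velocity profile
#' peaking at +/- 2 rad/s (period 20 s), for 60 s by default.  These are the
#' package's canonical rotation-trial conditions.
#'
#' @param duration seconds.
#' @param dt timestep, seconds.
#' @return `default_rotation_world()`: a `cx_world`;
#'   `default_rotation_trajectory()`: a `cx_trajectory`.
#' @export
default_rotation_world <- function() {
  world(list(landmark(1, 10 * cos(deg2rad(90)),  10 * sin(deg2rad(90)),  "blue"),
             landmark(2, 10 * cos(deg2rad(210)), 10 * sin(deg2rad(210)), "green"),
             landmark(3, 10 * cos(deg2rad(330)), 10 * sin(deg2rad(330)), "red")),
        fov = 270)
}

#' @rdname default_rotation_world
#' @export
default_rotation_trajectory <- function(duration = 60, dt = 0.001) {
  make_rotation_trajectory(duration,
                           function(t) 2 * sin(2 * pi * t / 20),
                           dt = dt)
}

#' Default translation-trial world and trajectory
#'
#' The agent drives forward at constant speed while steering under the
#' same sinusoidal angular-velocity profile as the rotation trial (peak
#' +/- 2 rad/s, period 20 s), tracing a meandering path of about 12 m -
#' the rotational task is matched between the two trials and translation
#' is the added challenge, with heading equal to the direction of motion
#' so that path integration is well posed.  Two distal landmarks sit at
#' 50 m (egocentric bearing essentially position-invariant over the
#' path); one proximal landmark sits ~2.5 m from the path centre, so its
#' bearing varies strongly with position (parallax).
#'
#' @param duration seconds.
#' @param dt timestep, seconds.
#' @param speed forward speed, m/s.
#' @return see [default_rotation_world()].
#' @export
default_translation_world <- function() {
  world(list(landmark(1, 50 * cos(deg2rad(70)),  50 * sin(deg2rad(70)),  "blue"),
             landmark(2, 50 * cos(deg2rad(200)), 50 * sin(deg2rad(200)), "green"),
             landmark(3, 1.4 + 2.5 * cos(deg2rad(320)),
                      0.1 + 2.5 * sin(deg2rad(320)), "red")),
        fov = 270)
}

#' @rdname default_translation_world
#' @export
default_translation_trajectory <- function(duration = 60, dt = 0.001,
                                           speed = 0.2) {
  n <- round(duration / dt)
  t <- (seq_len(n) - 1) * dt
  av <- 2 * sin(2 * pi * t / 20)
  heading <- wrap_angle(c(0, cumsum(av[-n]) * dt))
  x <- c(0, cumsum(speed * cos(heading[-n]) * dt))
  y <- c(0, cumsum(speed * sin(heading[-n]) * dt))
  new_trajectory(t, x, y, heading, av, speed, dt)
}

# ---- serialization ------------------------------------------------------

fmt_full <- function(x) formatC(x, digits = 17, format = "g")

#' Read and write trajectories and worlds as CSV
#'
#' Trajectories serialise one row per pose sample; worlds as a landmark
#' table (`id,x,y,color`) preceded by a `# fov=<deg>` header line.  Floats
#' round-trip to better than 1e-12 relative error.
#'
#' @param traj,wld objects to write.
#' @param path file path.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  df[] <- lapply(df, fmt_full)
  utils::write.csv(cbind(df, dt = fmt_full(attr(traj, "dt"))[1]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  new_trajectory(df$t, df$x, df$y, df$heading, df$angular_velocity,
                 df$linear_speed, dt = df$dt[1])
}

#' @rdname write_trajectory
#' @export
write_world <- function(wld, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fov=%s", fmt_full(wld$fov)), con)
  df <- data.frame(
    id = vapply(wld$landmarks, function(l) l$id, integer(1)),
    x = fmt_full(vapply(wld$landmarks, function(l) l$position[1], numeric(1))),
    y = fmt_full(vapply(wld$landmarks, function(l) l$position[2], numeric(1))),
    color = vapply(wld$landmarks, function(l) l$color, character(1)))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_world <- function(path) {
  header <- readLines(path, n = 1)
  fov <- as.numeric(sub("# fov=", "", header, fixed = TRUE))
  df <- utils::read.csv(path, skip = 1)
  world(lapply(seq_len(nrow(df)), function(i)
    landmark(df$id[i], df$x[i], df$y[i], df$color[i])), fov = fov)
}
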