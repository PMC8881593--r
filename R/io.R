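#' Read and write weight matrices as delimited text
#'
#' Tab-separated numeric matrix with a header row naming the ring channels
#' and row names naming the E-PG neurons.
#'
#' @param W 18 x 81 weight matrix.
#' @param path file path.
#' @export
write_weights <- function(W, path) {
  rownames(W) <- paste0("EPG_", rep(c("L", "R"), each = 9), 1:9)
  colnames(W) <- paste0("ring_", rep(1:3, each = 27), "_", rep(1:27, 3))
  utils::write.table(format(W, digits = 17), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              row.names = 1, check.names = FALSE))
}

#' Read a recorded sensor stream
#'
#' Delimited table with columns `t`, `bearing_landmark1..3` (degrees;
#' blank/`NA` = landmark not detected that frame, emulating frame
#' dropout), and `angular_velocity` (rad/s).  Frames are expected on the
#' simulation timestep grid.
#'
#' @param path CSV file path.
#' @return list with `t`, `bearings` (T x 3, `NA` for dropped frames),
#'   `angular_velocity`, `dt`.
#' @export
read_sensor_stream <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", "bearing_landmark1", "bearing_landmark2",
            "bearing_landmark3", "angular_velocity")
  if (!all(need %in% names(df)))
    stop("sensor stream must have columns: ", paste(need, collapse = ", "))
  dt <- stats::median(diff(df$t))
  list(t = df$t,
       bearings = as.matrix(df[, c("bearing_landmark1", "bearing_landmark2",
                                   "bearing_landmark3")]),
       angular_velocity = df$angular_velocity, dt = dt)
}

#' Simulate a trial driven by a recorded sensor stream
#'
#' Replaces the analytic bearing/angular-velocity generation of
#' [simulate_trial()] with externally recorded per-frame landmark bearings
#' (with dropout) and angular velocity.  No further measurement noise is
#' added (the stream is assumed to carry its own).
#'
#' @param stream a [read_sensor_stream()] result.
#' @param config,w_rc,rule,mode,lif,defaults,snapshot_every_s,learn_every
#'   as in [simulate_trial()].
#' @return a `cx_run` (its `traj` slot holds only time, heading estimate
#'   inputs; ground truth is not part of a sensor stream).
#' @export
simulate_sensor_stream <- function(stream, config = "online", w_rc = NULL,
                                   rule = "hebbian", mode = "rate",
                                   lif = lif_params(),
                                   defaults = cx_defaults(),
                                   snapshot_every_s = 0, learn_every = 1) {
  d <- defaults
  dt_s <- stream$dt
  bank <- ring_tuning_bank(peak_current = d$ring_peak)
  vis <- ring_activation_matrix(stream$bearings, bank)
  enc <- av_encoder(gain = d$av_gain, baseline = d$av_baseline,
                    exponent = d$av_exp,
                    calibration = av_shift_calibration(d$av_baseline, lif),
                    lif = lif)
  av_lr <- pen_drive(stream$angular_velocity, enc)
  conn <- build_connectome()
  fanout <- structural_fanout(conn)

  if (config == "av_only") {
    w0 <- matrix(0, 18, 81); rule_id <- 0L
  } else if (config == "online") {
    w0 <- if (is.null(w_rc))
      matrix(stats::runif(18 * 81, -d$w_init, 0), 18, 81) else w_rc
    rule_id <- if (rule == "hebbian") 1L else 2L
  } else {
    if (is.null(w_rc)) stop("config 'optimal' requires w_rc")
    w0 <- w_rc; rule_id <- 0L
  }

  pref <- epg_preferred_angles()
  # initialise the bump at the heading implied by the first detected
  # landmark frame, or 0 if the first frame is dropped
  pulse <- d$pulse_amp * exp(-angle_diff(pref, 0)^2 / (2 * (2 * pi / 9)^2))
  pulse_steps <- as.integer(round(d$pulse_ms / lif$dt_ms))

  par <- list(dt_ms = lif$dt_ms, tau_m = lif$tau_m,
              threshold = lif$threshold, reset = lif$reset,
              ref_steps = lif$ref_steps, tau_syn = d$tau_syn,
              tau_trace = d$tau_trace, g_rec = d$g_rec, g_vis = d$g_vis,
              i_bias = d$i_bias, ring_peak = d$ring_peak,
              state_sigma = noise_model()$state_sigma,
              pulse_steps = pulse_steps, rule = rule_id,
              eta_step = d$eta * d$learn_gain * dt_s,
              heb_a = d$heb_a, heb_b = d$heb_b,
              beta = d$beta, learn_every = as.integer(learn_every),
              learn_start = pulse_steps,
              ring_mode = if (mode == "rate") 0L else 1L, r_ref = d$r_ref,
              snap_every = as.integer(round(
                if (snapshot_every_s > 0) snapshot_every_s / dt_s else 0)),
              fanout = as.numeric(fanout))
  res <- .simulate_core(vis, av_lr, conn, w0, pulse, par)
  structure(list(epg_trace = res$epg_trace, t = stream$t,
                 w_init = w0, w_final = res$w_final, w_snaps = list(),
                 snap_t = numeric(0),
                 spike_count = as.numeric(res$spike_count),
                 comm_events = res$comm_events, n_steps = nrow(vis),
                 dt = dt_s, preferred_angles = pref, config = config,
                 traj = NULL),
            class = "cx_run")
}

#' Write a synthetic sensor stream CSV
#'
#' Generates the sensor table a recording platform would produce for a
#' trajectory in a world: per-frame landmark bearings (blank when outside
#' the field of view or dropped), plus noisy angular velocity.  Useful for
#' exercising the ingestion path end to end.
#'
#' @param wld,traj world and trajectory.
#' @param path output CSV.
#' @param dropout_prob per-frame probability that a frame's visual
#'   detections are dropped (all bearings blank), emulating disk-write
#'   frame dropping.
#' @param dropout_len mean run length (frames) of a dropout burst.
#' @param noise a [noise_model()] for the angular-velocity column.
#' @return the path, invisibly.
#' @export
write_sensor_stream <- function(wld, traj, path, dropout_prob = 0.1,
                                dropout_len = 50, noise = noise_model()) {
  b <- trajectory_bearings(traj, wld)
  b[!in_fov(b, wld$fov)] <- NA
  n <- nrow(b)
  # bursty dropout: geometric run lengths
  drop <- logical(n); i <- 1L
  while (i <= n) {
    if (stats::runif(1) < dropout_prob / dropout_len) {
      len <- stats::rgeom(1, 1 / dropout_len) + 1L
      drop[i:min(n, i + len - 1L)] <- TRUE
      i <- i + len
    } else i <- i + 1L
  }
  b[drop, ] <- NA
  df <- data.frame(t = traj$t, bearing_landmark1 = b[, 1],
                   bearing_landmark2 = b[, 2], bearing_landmark3 = b[, 3],
                   angular_velocity = add_av_noise(traj$angular_velocity,
                                                   noise))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
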