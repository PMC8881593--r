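#' Leaky integrate-and-fire parameters
#'
#' Membrane time constant 20 ms, 1 ms timestep, threshold 1, reset 0,
#' refractory period 2 ms.  The threshold/reset/refractory values are
#' standard defaults; only the time constant and timestep are anatomically
#' anchored.
#'
#' @param tau_m membrane time constant, ms.
#' @param dt_ms timestep, ms.
#' @param threshold,reset firing threshold and reset potential, model units.
#' @param t_ref refractory period, ms.
#' @return a `cx_lif_params` list.
#' @export
lif_params <- function(tau_m = 20, dt_ms = 1, threshold = 1, reset = 0,
                       t_ref = 2) {
  stopifnot(dt_ms <= tau_m, t_ref >= 0)
  structure(list(tau_m = tau_m, dt_ms = dt_ms, threshold = threshold,
                 reset = reset, t_ref = t_ref,
                 ref_steps = as.integer(round(t_ref / dt_ms))),
            class = "cx_lif_params")
}

#' Closed-form steady-state LIF firing rate
#'
#' For constant suprathreshold current I the interspike interval is
#' `t_ref + tau * log((I - reset) / (I - threshold))`; the rate is its
#' reciprocal (Hz).  Subthreshold currents give rate 0.
#'
#' @param current constant input current (model units).
#' @param p [lif_params()].
#' @return firing rate in Hz.
#' @export
lif_rate_closed_form <- function(current, p = lif_params()) {
  r <- numeric(length(current))
  sup <- current > p$threshold
  isi <- p$t_ref + p$tau_m *
    log((current[sup] - p$reset) / (current[sup] - p$threshold))
  r[sup] <- 1000 / isi
  r
}

#' Current producing a target steady-state LIF rate
#'
#' Inverse of [lif_rate_closed_form()].
#'
#' @param rate_hz target firing rate (must satisfy `1000/rate > t_ref`).
#' @param p [lif_params()].
#' @return constant current.
#' @export
lif_current_for_rate <- function(rate_hz, p = lif_params()) {
  isi <- 1000 / rate_hz
  stopifnot(isi > p$t_ref)
  x <- exp((isi - p$t_ref) / p$tau_m)
  (p$threshold * x - p$reset) / (x - 1)
}

#' Empirical discrete-time LIF rate (single neuron, no noise)
#'
#' Reference implementation of the simulator's membrane update for one
#' neuron under constant current; used to calibrate input encoders and as
#' an oracle in tests.
#'
#' @param current constant input current.
#' @param p [lif_params()].
#' @param duration_s simulated seconds.
#' @return firing rate in Hz.
#' @export
lif_rate_discrete <- function(current, p = lif_params(), duration_s = 5) {
  n <- round(1000 * duration_s / p$dt_ms)
  decay <- exp(-p$dt_ms / p$tau_m)
  v <- p$reset; refr <- 0L; spikes <- 0L
  for (i in seq_len(n)) {
    if (refr > 0L) { refr <- refr - 1L; v <- p$reset; next }
    v <- current + (v - current) * decay
    if (v >= p$threshold) { spikes <- spikes + 1L; v <- p$reset; refr <- p$ref_steps }
  }
  1000 * spikes / (n * p$dt_ms)
}

#' Calibrated model constants
#'
#' The printed connectome weights (20 / -15 / -20) and the learning-rule
#' constants are unit values; mapping them onto the LIF current scale
#' (threshold 1) requires a handful of calibration scalars, fixed once for
#' the package (see the methods vignette for how each was set):
#'
#' * `g_rec` - global gain converting connectome-weighted synaptic traces
#'   (spikes/ms) into current.
#' * `i_bias` - constant excitatory bias to E-PG neurons against which the
#'   non-positive ring weights act by disinhibition.
#' * `g_vis` - gain of the plastic ring-to-E-PG pathway.
#' * `av_gain` - P-EN current per rad/s below saturation (closed-loop
#'   calibrated so the bump rotates at the commanded speed).
#' * `ring_peak` - ring-neuron input current at the receptive-field centre.
#' * `tau_syn`, `tau_trace` - synaptic and activation-trace time constants
#'   (ms); the 50 ms trace feeds both the decoder and the learning rules.
#' * `pulse_amp`, `pulse_ms` - bump initialisation pulse.
#' * `eta`, `heb_a`, `heb_b` - Hebbian rule constants (eta interpreted as a
#'   continuous-time rate; the per-step rate is `eta * learn_gain * dt`).
#' * `w_init` - scale of the random uniform initialisation of the plastic
#'   weights for the online configuration.
#' * `learn_gain` - unit conversion between the rule's presynaptic
#'   activation scale and the simulator's normalised ring activation,
#'   chosen so the weight relaxation reaches its fixed point within a
#'   fraction of a trial.
#' * `beta` - current-to-activity scaling shared by the offline solution
#'   and the error-minimising rule.
#' * `target_amp` - amplitude of the offline fit's target compass profile.
#' * `r_ref` - ring-trace normalisation (kHz) for spiking-mode activation.
#'
#' @return named list of defaults.
#' @export
cx_defaults <- function() {
  list(g_rec = 1.6, i_bias = 0.98, g_vis = 10000, av_gain = NULL,
       av_baseline = 0.85, av_exp = 1, ring_peak = 6, tau_syn = 10, tau_trace = 50,
       pulse_amp = 4, pulse_ms = 100,
       eta = 0.29, heb_a = 1.7e-6, heb_b = 1.7e-4, w_init = 1e-4,
       learn_gain = 4, beta = 0.0025, target_amp = 0.2, r_ref = 0.15)
}

#' Population layout of the 141-neuron network
#'
#' 81 ring, 18 E-PG (9 per hemisphere, preferred angles uniformly spanning
#' the circle at 40 degree spacing), 16 P-EN and 16 P-EG (8 per
#' hemisphere, glomeruli 1-8), 10 PIntr (5 per hemisphere): one more E-PG
#' per hemisphere than P-EN/P-EG.  The two hemispheres' tilings are offset
#' by half a glomerulus (+/-10 degrees) by default, interleaving their
#' wedges so the population codes heading at twice the single-hemisphere
#' angular resolution while keeping the network mirror-symmetric.
#'
#' @param hemisphere_offset angular offset (radians) of the right
#'   hemisphere's preferred angles (0 = identical tiling).
#' @return a `cx_layout` data frame with one row per neuron: `neuron`
#'   (1-141), `population`, `hemisphere` ("L"/"R", `NA` for ring),
#'   `glomerulus`, and `preferred_angle` (radians, E-PG only).
#' @export
build_layout <- function(hemisphere_offset = pi / 9) {
  pref_l <- wrap_angle((0:8) * 2 * pi / 9 - hemisphere_offset / 2)
  pref_r <- wrap_angle((0:8) * 2 * pi / 9 + hemisphere_offset / 2)
  df <- rbind(
    data.frame(population = "ring", hemisphere = NA_character_,
               glomerulus = NA_integer_,
               preferred_angle = NA_real_)[rep(1, 81), ],
    data.frame(population = "E-PG",
               hemisphere = rep(c("L", "R"), each = 9),
               glomerulus = rep(1:9, 2),
               preferred_angle = c(pref_l, pref_r)),
    data.frame(population = "P-EN",
               hemisphere = rep(c("L", "R"), each = 8),
               glomerulus = rep(1:8, 2), preferred_angle = NA_real_),
    data.frame(population = "P-EG",
               hemisphere = rep(c("L", "R"), each = 8),
               glomerulus = rep(1:8, 2), preferred_angle = NA_real_),
    data.frame(population = "PIntr",
               hemisphere = rep(c("L", "R"), each = 5),
               glomerulus = rep(1:5, 2), preferred_angle = NA_real_))
  df <- cbind(neuron = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  structure(df, class = c("cx_layout", "data.frame"))
}

# local (1-based) indices within the 60 non-ring neurons
.epg_i   <- function(h, g) (h - 1) * 9 + g
.pen_i   <- function(h, g) 18 + (h - 1) * 8 + g
.peg_i   <- function(h, g) 34 + (h - 1) * 8 + g
.pintr_i <- function(h, i) 50 + (h - 1) * 5 + i

#' Fixed signed connectome among the non-ring populations
#'
#' Glomerular wiring with the printed block weights and the canonical
#' one-glomerulus P-EN offset: E-PG excite the hemisphere-matched P-EN,
#' P-EG and PIntr; P-EG re-excite E-PG at the same angle (bump
#' maintenance); right-hemisphere P-EN excite E-PG one angular step
#' counter-clockwise, left-hemisphere one step clockwise (bump shift);
#' PIntr inhibit all P-EN and P-EG at -15 and all PIntr (including
#' themselves) at -20.  PIntr never contact E-PG and E-PG have no direct
#' self-excitation.
#'
#' Because each hemisphere has one fewer P-EN/P-EG than E-PG, the two
#' discretisations are coupled by angular wedge overlap: E-PG tile the
#' circle in nine 40-degree wedges, P-EN/P-EG in eight 45-degree wedges,
#' and each excitatory weight is the block value 20 scaled by the overlap
#' fraction of the two wedges involved (shift applied to the P-EN output
#' wedge).  This keeps the ring rotationally smooth - there is no seam
#' glomerulus at which the activity bump could stall or pin.
#'
#' @param layout a [build_layout()] (shape check only).
#' @param w_exc,w_inh,w_pintr block weights (excitatory, PIntr->P-EN/P-EG,
#'   PIntr->PIntr).
#' @return 60 x 60 numeric matrix, entry `[post, pre]`, over neurons 82-141
#'   in layout order, with a `dimnames` population labelling.
#' @export
build_connectome <- function(layout = build_layout(), w_exc = 20,
                             w_inh = -15, w_pintr = -20) {
  if (nrow(layout) != 141) stop("layout mismatch: expected 141 neurons")
  W <- matrix(0, 60, 60)
  epg <- layout[layout$population == "E-PG", ]
  ang <- matrix(rad2deg(epg$preferred_angle), 9, 2)  # [glomerulus, hemisphere]
  # circular overlap (degrees) of two wedges of widths w1, w2
  ov <- function(c1, c2, w1 = 40, w2 = 45) {
    d <- abs(wrap_deg(c1 - c2))
    pmax(0, pmin((w1 + w2) / 2 - d, w1, w2))
  }
  for (h in 1:2) {
    ps <- (0:7) * 45 + ang[1, h]   # P-EN/P-EG wedge centres (mirror pair)
    for (k in 1:8) {
      for (g in 1:9) {
        f_in <- ov(ang[g, h], ps[k]) / 40      # E-PG g -> P-EN/P-EG k
        if (f_in > 0) {
          W[.pen_i(h, k), .epg_i(h, g)] <- w_exc * f_in
          W[.peg_i(h, k), .epg_i(h, g)] <- w_exc * f_in
        }
        shift <- if (h == 2) 40 else -40       # right: CCW, left: CW
        for (h2 in 1:2) {
          f_pen <- ov(ang[g, h2], ps[k] + shift) / 45  # P-EN k -> E-PG
          f_peg <- ov(ang[g, h2], ps[k]) / 45          # P-EG k -> E-PG
          if (f_pen > 0) W[.epg_i(h2, g), .pen_i(h, k)] <- w_exc * f_pen
          if (f_peg > 0) W[.epg_i(h2, g), .peg_i(h, k)] <- w_exc * f_peg
        }
      }
    }
    # E-PG -> PIntr glomerulus grouping (9 glomeruli onto 5 PIntr); the
    # right hemisphere uses the mirrored grouping so the summed inhibition
    # landscape is mirror-symmetric and introduces no rotational bias
    for (g in 1:9) {
      i <- if (h == 1) ((g - 1) %% 5) + 1 else (((1 - g) %% 9) %% 5) + 1
      W[.pintr_i(h, i), .epg_i(h, g)] <- w_exc
    }
  }
  pintr <- c(.pintr_i(1, 1:5), .pintr_i(2, 1:5))
  pen <- c(.pen_i(1, 1:8), .pen_i(2, 1:8))
  peg <- c(.peg_i(1, 1:8), .peg_i(2, 1:8))
  W[pen, pintr] <- w_inh
  W[peg, pintr] <- w_inh
  W[pintr, pintr] <- w_pintr
  lbl <- c(paste0("E-PG_", rep(c("L", "R"), each = 9), 1:9),
           paste0("P-EN_", rep(c("L", "R"), each = 8), 1:8),
           paste0("P-EG_", rep(c("L", "R"), each = 8), 1:8),
           paste0("PIntr_", rep(c("L", "R"), each = 5), 1:5))
  dimnames(W) <- list(post = lbl, pre = lbl)
  W
}

#' Outgoing structural edge counts (spike fanout) for all 141 neurons
#'
#' Ring neurons carry their 18 plastic synapses (counted as structurally
#' present regardless of current weight value - the pessimistic
#' convention); the rest comes from the fixed connectome.
#'
#' @param conn the [build_connectome()] matrix.
#' @param count_plastic whether ring->E-PG plastic synapses count.
#' @return integer vector of length 141.
#' @export
structural_fanout <- function(conn = build_connectome(),
                              count_plastic = TRUE) {
  c(rep(if (count_plastic) 18L else 0L, 81),
    as.integer(colSums(conn != 0)))
}

#' Preferred angles of the 18 E-PG neurons
#' @return radians, layout order (L1-9 then R1-9).
#' @export
epg_preferred_angles <- function() {
  layout <- build_layout()
  layout$preferred_angle[layout$population == "E-PG"]
}

#' Simulate one trial of the network on a trajectory
#'
#' Runs the full spiking network for every timestep of `traj`: analytic
#' landmark bearings drive the ring neurons, noisy angular velocity drives
#' the P-EN neurons, and the E-PG bump is initialised with a 100 ms current
#' pulse at the true initial heading.  The plastic ring-to-E-PG matrix is
#' zero (`config = "av_only"`), learned online (`config = "online"`, rule
#' Eq.-1-style Hebbian or the error-minimising variant), or fixed to a
#' supplied matrix (`config = "optimal"`).
#'
#' @param wld a `cx_world`.
#' @param traj a `cx_trajectory`.
#' @param config one of `"av_only"`, `"online"`, `"optimal"`.
#' @param w_rc 18 x 81 starting plastic weights; required for
#'   `"optimal"`, default random uniform on `[-heb_b, 0]` for `"online"`.
#' @param rule online learning rule: `"hebbian"` or `"errmin"`.
#' @param mode ring activation fed to the plastic pathway and the learning
#'   rule: `"rate"` (analytic tuning value, deterministic) or `"spiking"`
#'   (filtered ring spikes).
#' @param noise a [noise_model()].
#' @param lif [lif_params()].
#' @param defaults calibration constants, see [cx_defaults()].
#' @param snapshot_every_s interval (s) between plastic-weight snapshots
#'   (0 = none).
#' @param learn_every update cadence in timesteps (63 matches the power
#'   model's amortisation assumption; default 1).
#' @return a `cx_run` list: `epg_trace` (T x 18 filtered spike trace),
#'   `t`, `w_final`, `w_snaps` (list), `snap_t`, `spike_count`,
#'   `comm_events`, `traj`, plus the pieces needed for decoding.
#' @export
simulate_trial <- function(wld, traj, config = c("av_only", "online", "optimal"),
                           w_rc = NULL, rule = c("hebbian", "errmin"),
                           mode = c("rate", "spiking"),
                           noise = noise_model(), lif = lif_params(),
                           defaults = cx_defaults(), snapshot_every_s = 1,
                           learn_every = 1, conn = build_connectome()) {
  config <- match.arg(config)
  rule <- match.arg(rule)
  mode <- match.arg(mode)
  d <- defaults
  dt_s <- attr(traj, "dt")

  bank <- ring_tuning_bank(fov = wld$fov, peak_current = d$ring_peak)
  bearings <- trajectory_bearings(traj, wld)
  vis <- ring_activation_matrix(bearings, bank)

  enc <- av_encoder(gain = d$av_gain, baseline = d$av_baseline,
                    exponent = d$av_exp,
                    calibration = av_shift_calibration(d$av_baseline, lif),
                    lif = lif)
  av_lr <- pen_drive(add_av_noise(traj$angular_velocity, noise), enc)

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
  h0 <- traj$heading[1]
  pulse <- d$pulse_amp * exp(-angle_diff(pref, h0)^2 / (2 * (2 * pi / 9)^2))
  pulse_steps <- as.integer(round(d$pulse_ms / lif$dt_ms))

  par <- list(dt_ms = lif$dt_ms, tau_m = lif$tau_m,
              threshold = lif$threshold, reset = lif$reset,
              ref_steps = lif$ref_steps, tau_syn = d$tau_syn,
              tau_trace = d$tau_trace, g_rec = d$g_rec, g_vis = d$g_vis,
              i_bias = d$i_bias, ring_peak = d$ring_peak,
              state_sigma = noise$state_sigma, pulse_steps = pulse_steps,
              rule = rule_id, eta_step = d$eta * d$learn_gain * dt_s,
              heb_a = d$heb_a, heb_b = d$heb_b, beta = d$beta,
              learn_every = as.integer(learn_every),
              learn_start = pulse_steps,
              ring_mode = if (mode == "rate") 0L else 1L, r_ref = d$r_ref,
              snap_every = as.integer(round(snapshot_every_s / dt_s)),
              fanout = as.numeric(fanout))

  res <- .simulate_core(vis, av_lr, conn, w0, pulse, par)
  n_snaps <- res$n_snaps
  snaps <- if (n_snaps > 0)
    lapply(seq_len(n_snaps), function(i) res$w_snaps[, , i]) else list()
  structure(list(epg_trace = res$epg_trace, t = traj$t,
                 w_init = w0, w_final = res$w_final,
                 w_snaps = snaps,
                 snap_t = if (n_snaps > 0) res$snap_t[seq_len(n_snaps)] else numeric(0),
                 spike_count = as.numeric(res$spike_count),
                 comm_events = res$comm_events,
                 n_steps = nrow(vis), dt = dt_s,
                 preferred_angles = pref, config = config, traj = traj),
            class = "cx_run")
}
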