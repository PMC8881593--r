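// Spiking core of the central-complex ring-attractor model.
//
// 141 leaky integrate-and-fire neurons at a 1 ms timestep:
//   ring (81) -> plastic inhibitory synapses onto E-PG (18);
//   E-PG / P-EN / P-EG / PIntr (60) wired by a fixed signed connectome.
// Membrane update is exact exponential (exponential Euler) between spikes;
// synaptic interaction uses an exponential low-pass trace of spikes whose
// steady state approximates the firing rate in spikes/ms.  All randomness
// is drawn from R's RNG so runs are reproducible from set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// population index offsets (0-based, fixed layout)
static const int N_RING = 81, N_EPG = 18, N_PEN = 16, N_PEG = 16, N_PINTR = 10;
static const int N_ALL = N_RING + N_EPG + N_PEN + N_PEG + N_PINTR; // 141
static const int OFF_EPG = N_RING;            // 81
static const int OFF_PEN = OFF_EPG + N_EPG;   // 99
static const int OFF_PEG = OFF_PEN + N_PEN;   // 115
static const int OFF_PINTR = OFF_PEG + N_PEG; // 131

// [[Rcpp::export(name = ".simulate_core")]]
List simulate_core(const arma::mat& vis_act,      // T x 81 normalised ring activation
                   const arma::mat& av_lr,        // T x 2 (left, right) P-EN currents
                   const arma::mat& w_fix,        // 60 x 60 fixed connectome (post x pre)
                   arma::mat w_rc,                // 18 x 81 plastic weights (raw, signed)
                   const arma::vec& pulse,        // 18 init-pulse currents for E-PG
                   const List& par) {
  const int T = vis_act.n_rows;
  const double dt        = par["dt_ms"];          // ms
  const double tau_m     = par["tau_m"];          // ms
  const double threshold = par["threshold"];
  const double reset     = par["reset"];
  const int    ref_steps = par["ref_steps"];
  const double tau_syn   = par["tau_syn"];        // ms
  const double tau_trace = par["tau_trace"];      // ms
  const double g_rec     = par["g_rec"];
  const double g_vis     = par["g_vis"];
  const double i_bias    = par["i_bias"];
  const double ring_peak = par["ring_peak"];
  const double state_sigma = par["state_sigma"];
  const int    pulse_steps = par["pulse_steps"];
  const int    rule        = par["rule"];         // 0 none, 1 hebbian, 2 errmin
  const double eta_step    = par["eta_step"];
  const double heb_a       = par["heb_a"];
  const double heb_b       = par["heb_b"];
  const double beta        = par["beta"];
  const int    learn_every = par["learn_every"];
  const int    learn_start = par["learn_start"];
  const int    ring_mode   = par["ring_mode"];    // 0 rate, 1 spiking
  const double r_ref       = par["r_ref"];        // kHz scale for spiking-mode r
  const int    snap_every  = par["snap_every"];   // 0 = no snapshots
  const arma::vec& fanout  = par["fanout"];       // 141 outgoing-edge counts

  const double decay_m  = std::exp(-dt / tau_m);
  const double decay_s  = std::exp(-dt / tau_syn);
  const double decay_tr = std::exp(-dt / tau_trace);

  arma::vec v(N_ALL, arma::fill::zeros);
  arma::ivec refr(N_ALL, arma::fill::zeros);
  arma::vec s_syn(N_ALL, arma::fill::zeros);   // ~ rate in spikes/ms
  arma::vec s_tr(N_ALL, arma::fill::zeros);    // decoding / learning trace
  arma::vec y(N_ALL, arma::fill::zeros);
  arma::vec cur(N_ALL, arma::fill::zeros);
  arma::vec spike_count(N_ALL, arma::fill::zeros);

  arma::mat epg_trace(T, N_EPG);
  int n_snap = snap_every > 0 ? (T / snap_every) : 0;
  arma::cube w_snaps(N_EPG, N_RING, n_snap > 0 ? n_snap : 1,
                     arma::fill::zeros);
  arma::vec snap_t(n_snap > 0 ? n_snap : 1, arma::fill::zeros);
  double comm_events = 0.0;

  arma::mat w_eff = arma::min(w_rc, arma::zeros<arma::mat>(N_EPG, N_RING));

  RNGScope scope;
  int snap_i = 0;

  for (int t = 0; t < T; ++t) {
    // ---- input currents ------------------------------------------------
    arma::rowvec va = vis_act.row(t);
    cur.zeros();
    // ring neurons: visual drive only
    cur.subvec(0, N_RING - 1) = ring_peak * va.t();

    // normalised ring activation used for the plastic pathway + learning
    arma::vec r(N_RING);
    if (ring_mode == 0) {
      r = va.t();
    } else {
      r = s_tr.subvec(0, N_RING - 1) / r_ref;
      r = arma::clamp(r, 0.0, 1.5);
    }

    // recurrent currents among the 60 non-ring neurons
    arma::vec s60 = s_syn.subvec(OFF_EPG, N_ALL - 1);
    arma::vec rec = g_rec * (w_fix * s60);
    cur.subvec(OFF_EPG, N_ALL - 1) = rec;

    // E-PG: bias + (plastic, non-positive) visual input + init pulse
    arma::vec vis_cur = g_vis * (w_eff * r);
    cur.subvec(OFF_EPG, OFF_EPG + N_EPG - 1) += i_bias + vis_cur;
    if (t < pulse_steps)
      cur.subvec(OFF_EPG, OFF_EPG + N_EPG - 1) += pulse;

    // P-EN: angular-velocity drive (left block then right block)
    cur.subvec(OFF_PEN, OFF_PEN + 7) += av_lr(t, 0);
    cur.subvec(OFF_PEN + 8, OFF_PEN + 15) += av_lr(t, 1);

    // state noise on P-EG and PIntr
    if (state_sigma > 0) {
      for (int i = OFF_PEG; i < N_ALL; ++i)
        cur(i) += R::rnorm(0.0, state_sigma);
    }

    // ---- LIF update ----------------------------------------------------
    y.zeros();
    for (int i = 0; i < N_ALL; ++i) {
      if (refr(i) > 0) {
        refr(i)--;
        v(i) = reset;
        continue;
      }
      v(i) = cur(i) + (v(i) - cur(i)) * decay_m;
      if (v(i) >= threshold) {
        y(i) = 1.0;
        v(i) = reset;
        refr(i) = ref_steps;
        spike_count(i) += 1.0;
        comm_events += fanout(i);
      }
    }

    // ---- traces --------------------------------------------------------
    s_syn = s_syn * decay_s + y / tau_syn;
    s_tr  = s_tr * decay_tr + y / tau_trace;
    epg_trace.row(t) = s_tr.subvec(OFF_EPG, OFF_EPG + N_EPG - 1).t();

    // ---- plasticity ----------------------------------------------------
    if (rule > 0 && t >= learn_start && ((t - learn_start) % learn_every == 0)) {
      arma::vec c_hz = 1000.0 * s_tr.subvec(OFF_EPG, OFF_EPG + N_EPG - 1);
      if (rule == 1) {
        // presynaptically-gated Hebbian: dw = eta r (a c + b - w)
        arma::vec post = heb_a * c_hz + heb_b;
        w_rc += eta_step * (post * r.t() - w_rc.each_row() % r.t());
      } else {
        // error-minimising: dw = eta r (c - beta I), I from effective weights
        arma::vec i_rn = w_eff * r;
        arma::vec post = c_hz - beta * i_rn;
        w_rc += eta_step * (post * r.t());
      }
      w_eff = arma::min(w_rc, arma::zeros<arma::mat>(N_EPG, N_RING));
    }

    if (snap_every > 0 && ((t + 1) % snap_every == 0) && snap_i < n_snap) {
      w_snaps.slice(snap_i) = w_rc;
      snap_t(snap_i) = (t + 1) * dt / 1000.0;
      snap_i++;
    }
  }

  return List::create(
    _["epg_trace"] = epg_trace,
    _["w_final"] = w_rc,
    _["w_snaps"] = w_snaps,
    _["snap_t"] = snap_t,
    _["n_snaps"] = snap_i,
    _["spike_count"] = spike_count,
    _["comm_events"] = comm_events);
}
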