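// Fixed-step RK4 integrator for the four-cell Mauthner escape circuit.
// State layout (16): vE nE CaE vGA nGA CaGA vGL nGL CaGL vM nM CaM sE sGA sGL gI
// Must stay in step with STATE_NAMES in R/params.R; the R-level
// derivatives() is the reference implementation this file is tested against.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct CellP {
  double C, gK, gL, gCa, gKCa, vK, vL, vCa, k1;
  double v1, v2, v3, v4, phi, eps, mu, kCa;
};

struct KinP {
  double alpha, beta, theta, sigma;
};

struct Params {
  CellP cell[4];   // E, GA, GL, M
  KinP kin[3];     // E, GA, GL
  double gE_GA, vE_GA, gE_GL, vE_GL, gGA_GL, vGA_GL;
  double gE_M, vE_M, gGA_M, gGL_M, vG_M, gM_M, vM_M, sM;
  double D1_M, D1_GL, gImax, k2, rho;
  double drive[4];
  int gI_law;      // 0 = saturating, 1 = linear_decay
};

CellP unpack_cell(const List& cl) {
  CellP p;
  p.C = cl["C"]; p.gK = cl["gK"]; p.gL = cl["gL"]; p.gCa = cl["gCa"];
  p.gKCa = cl["gKCa"]; p.vK = cl["vK"]; p.vL = cl["vL"]; p.vCa = cl["vCa"];
  p.k1 = cl["k1"]; p.v1 = cl["v1"]; p.v2 = cl["v2"]; p.v3 = cl["v3"];
  p.v4 = cl["v4"]; p.phi = cl["phi"]; p.eps = cl["eps"]; p.mu = cl["mu"];
  p.kCa = cl["kCa"];
  return p;
}

KinP unpack_kin(const List& kl) {
  KinP k;
  k.alpha = kl["alpha"]; k.beta = kl["beta"];
  k.theta = kl["theta_s"]; k.sigma = kl["sigma_s"];
  return k;
}

Params unpack(const List& cfg) {
  Params P;
  List cells = cfg["cells"], kin = cfg["kinetics"];
  const char* cid[4] = {"E", "GA", "GL", "M"};
  for (int i = 0; i < 4; ++i) P.cell[i] = unpack_cell(cells[cid[i]]);
  for (int i = 0; i < 3; ++i) P.kin[i] = unpack_kin(kin[cid[i]]);
  List cn = cfg["connections"];
  P.gE_GA = cn["gE_GA"]; P.vE_GA = cn["vE_GA"];
  P.gE_GL = cn["gE_GL"]; P.vE_GL = cn["vE_GL"];
  P.gGA_GL = cn["gGA_GL"]; P.vGA_GL = cn["vGA_GL"];
  P.gE_M = cn["gE_M"]; P.vE_M = cn["vE_M"];
  P.gGA_M = cn["gGA_M"]; P.gGL_M = cn["gGL_M"]; P.vG_M = cn["vG_M"];
  P.gM_M = cn["gM_M"]; P.vM_M = cn["vM_M"]; P.sM = cn["sM_const"];
  List md = cfg["modulation"];
  P.D1_M = md["D1_M"]; P.D1_GL = md["D1_GL"];
  P.gImax = md["gI_max"]; P.k2 = md["k2"]; P.rho = md["rho"];
  NumericVector dr = cfg["drives"];
  for (int i = 0; i < 4; ++i) P.drive[i] = dr[i];
  std::string law = as<std::string>(cfg["gI_law"]);
  P.gI_law = (law == "linear_decay") ? 1 : 0;
  return P;
}

inline void derivs(const Params& P, const double* y, double stim, double* dy) {
  const double sE = y[12], sGA = y[13], sGL = y[14], gI = y[15];

  // Synaptic currents per cell.
  double isyn[4];
  isyn[0] = 0.0;
  isyn[1] = P.gE_GA * (y[3] - P.vE_GA) * sE;
  isyn[2] = P.gE_GL * (1.0 + P.D1_GL) * (y[6] - P.vE_GL) * sE +
            P.gGA_GL * (y[6] - P.vGA_GL) * sGA;
  isyn[3] = P.gE_M * gI * (1.0 + P.D1_M) * (y[9] - P.vE_M) * sE +
            gI * (P.gGA_M * sGA + P.gGL_M * sGL) * (y[9] - P.vG_M) +
            P.gM_M * gI * (y[9] - P.vM_M) * P.sM;

  for (int c = 0; c < 4; ++c) {
    const CellP& p = P.cell[c];
    const double v = y[3 * c], n = y[3 * c + 1], Ca = y[3 * c + 2];
    const double m_inf = 0.5 * (1.0 + std::tanh((v - p.v1) / p.v2));
    const double n_inf = 0.5 * (1.0 + std::tanh((v - p.v3) / p.v4));
    const double tau_n = 1.0 / std::cosh((v - p.v3) / (2.0 * p.v4));
    const double ICa = p.gCa * m_inf * (v - p.vCa);
    const double IK = p.gK * n * (v - p.vK);
    const double IKCa = p.gKCa * (Ca / (Ca + p.k1)) * (v - p.vK);
    const double IL = p.gL * (v - p.vL);
    const double iapp = P.drive[c] + (c == 0 ? stim : 0.0);
    dy[3 * c] = (-ICa - IK - IL - IKCa - isyn[c] + iapp) / p.C;
    dy[3 * c + 1] = p.phi * (n_inf - n) / tau_n;
    dy[3 * c + 2] = p.eps * (-p.mu * ICa - p.kCa * Ca);
  }

  for (int c = 0; c < 3; ++c) {
    const KinP& k = P.kin[c];
    const double v = y[3 * c], s = y[12 + c];
    const double s_inf = 1.0 / (1.0 + std::exp(-(v - k.theta) / k.sigma));
    dy[12 + c] = k.alpha * s_inf * (1.0 - s) - k.beta * s;
  }

  const double CaM = y[11];
  dy[15] = (P.gI_law == 0)
    ? (P.gImax / (CaM + P.k2) - gI) / P.rho
    : P.gImax / (CaM + P.k2) - gI / P.rho;
}

inline double stim_at(double t, const double* onsets, int n_pulse, int j,
                      double pulse_ms, double WE) {
  // j indexes the first pulse whose offset has not yet passed.
  if (j < n_pulse && t >= onsets[j] && t < onsets[j] + pulse_ms) return WE;
  return 0.0;
}

}  // namespace

// Integrate the network from `state0` at time `t0` for `duration` ms with
// fixed step `dt`. Square current pulses of height WE and width pulse_ms
// start at `pulse_onsets` (absolute times). Records every `record_stride`-th
// sample if record_stride > 0, detects upward M-cell threshold crossings
// (linearly interpolated, with refractory), tracks state-bound extrema, and
// aborts on divergence (|v| > v_guard or non-finite state).
// [[Rcpp::export(name = ".sim_network_cpp")]]
List sim_network_cpp(List cfg, NumericVector state0, double t0, double duration,
                     double dt, NumericVector pulse_onsets, double pulse_ms,
                     double WE, int record_stride, double spike_threshold,
                     double refractory_ms, double v_guard) {
  if (dt <= 0) stop("dt must be > 0");
  if (state0.size() != 16) stop("state0 must have length 16");
  Params P = unpack(cfg);

  const long n_steps = (long)std::llround(duration / dt);
  double y[16], yt[16], k1[16], k2[16], k3[16], k4[16];
  for (int i = 0; i < 16; ++i) y[i] = state0[i];

  const int n_pulse = pulse_onsets.size();
  const double* onsets = n_pulse ? &pulse_onsets[0] : nullptr;
  int jp = 0;

  const long n_rec = record_stride > 0 ? n_steps / record_stride + 1 : 0;
  NumericMatrix trace(n_rec > 0 ? n_rec : 0, 16);
  NumericVector rec_t(n_rec > 0 ? n_rec : 0);
  long i_rec = 0;
  if (n_rec > 0) {
    rec_t[0] = t0;
    for (int i = 0; i < 16; ++i) trace(0, i) = y[i];
    i_rec = 1;
  }

  std::vector<double> spikes;
  double last_spike = -1e300;

  // Extrema of bounded state variables, updated every step.
  double n_min = R_PosInf, n_max = R_NegInf, s_min = R_PosInf,
         s_max = R_NegInf, ca_min = R_PosInf, gI_min = R_PosInf;
  for (int c = 0; c < 4; ++c) {
    n_min = std::min(n_min, y[3 * c + 1]);
    n_max = std::max(n_max, y[3 * c + 1]);
    ca_min = std::min(ca_min, y[3 * c + 2]);
  }
  for (int c = 0; c < 3; ++c) {
    s_min = std::min(s_min, y[12 + c]);
    s_max = std::max(s_max, y[12 + c]);
  }
  gI_min = y[15];

  double diverged_at = -1.0;

  for (long step = 0; step < n_steps; ++step) {
    const double t = t0 + step * dt;
    while (jp < n_pulse && t >= onsets[jp] + pulse_ms) ++jp;
    const double vM_prev = y[9];

    derivs(P, y, stim_at(t, onsets, n_pulse, jp, pulse_ms, WE), k1);
    for (int i = 0; i < 16; ++i) yt[i] = y[i] + 0.5 * dt * k1[i];
    derivs(P, yt, stim_at(t + 0.5 * dt, onsets, n_pulse, jp, pulse_ms, WE), k2);
    for (int i = 0; i < 16; ++i) yt[i] = y[i] + 0.5 * dt * k2[i];
    derivs(P, yt, stim_at(t + 0.5 * dt, onsets, n_pulse, jp, pulse_ms, WE), k3);
    for (int i = 0; i < 16; ++i) yt[i] = y[i] + dt * k3[i];
    derivs(P, yt, stim_at(t + dt, onsets, n_pulse, jp, pulse_ms, WE), k4);
    for (int i = 0; i < 16; ++i) {
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    }
    const double t_new = t0 + (step + 1) * dt;

    bool bad = false;
    for (int i = 0; i < 16; ++i) {
      if (!std::isfinite(y[i])) { bad = true; break; }
    }
    if (!bad) {
      for (int c = 0; c < 4; ++c) {
        if (std::fabs(y[3 * c]) > v_guard) { bad = true; break; }
      }
    }
    if (bad) { diverged_at = t_new; break; }

    for (int c = 0; c < 4; ++c) {
      n_min = std::min(n_min, y[3 * c + 1]);
      n_max = std::max(n_max, y[3 * c + 1]);
      ca_min = std::min(ca_min, y[3 * c + 2]);
    }
    for (int c = 0; c < 3; ++c) {
      s_min = std::min(s_min, y[12 + c]);
      s_max = std::max(s_max, y[12 + c]);
    }
    gI_min = std::min(gI_min, y[15]);

    if (vM_prev < spike_threshold && y[9] >= spike_threshold &&
        t_new - last_spike >= refractory_ms) {
      const double frac = (spike_threshold - vM_prev) / (y[9] - vM_prev);
      const double t_cross = t + frac * dt;
      spikes.push_back(t_cross);
      last_spike = t_cross;
    }

    if (n_rec > 0 && (step + 1) % record_stride == 0 && i_rec < n_rec) {
      rec_t[i_rec] = t_new;
      for (int i = 0; i < 16; ++i) trace(i_rec, i) = y[i];
      ++i_rec;
    }
  }

  NumericVector final_state(16);
  for (int i = 0; i < 16; ++i) final_state[i] = y[i];

  return List::create(
    _["final_state"] = final_state,
    _["t"] = rec_t,
    _["trace"] = trace,
    _["spikes"] = NumericVector(spikes.begin(), spikes.end()),
    _["bounds"] = NumericVector::create(
      _["n_min"] = n_min, _["n_max"] = n_max,
      _["s_min"] = s_min, _["s_max"] = s_max,
      _["ca_min"] = ca_min, _["gI_min"] = gI_min),
    _["diverged_at"] = diverged_at);
}
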