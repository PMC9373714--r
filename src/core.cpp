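// Compiled full-network ODE right-hand side and fixed-step Runge-Kutta 2(3)
// integration loop.  Mirrors the reference R implementation in compile.R
// (network_derivative_r); the two are cross-checked in the test suite.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Net {
  int nneuron, ncomp, ngate, nedge, npool, nchan, ncpl;
  std::vector<double> cm;
  std::vector<int> soma_comp;
  std::vector<int> cpl_a, cpl_b; std::vector<double> cpl_g;
  std::vector<int> g_comp, g_kind, g_pool, g_off;
  std::vector<double> g_vh, g_sl, g_tau, g_bp_v, g_bp_t, g_kd, g_hill;
  std::vector<int> c_comp, c_mode, c_act, c_inact, c_actp, c_inactp, c_pool;
  std::vector<double> c_g, c_e, c_a, c_pmax;
  std::vector<int> p_comp;
  std::vector<double> p_d, p_kt, p_kd, p_taur, p_k, p_p, p_rest;
  double ghk_z, ghk_f, ghk_rt, ghk_ca_out;
  std::vector<int> e_pre_comp, e_post_comp, e_kind;
  std::vector<double> e_g, e_e, e_alpha, e_beta, e_tmax, e_vp, e_kp, e_w;
  std::vector<double> stim_min, stim_max;
  double stim_on, stim_off;
};

std::vector<double> as_dvec(const List& l, const char* nm) {
  NumericVector v = l[nm];
  return std::vector<double>(v.begin(), v.end());
}
std::vector<int> as_ivec(const List& l, const char* nm) {
  IntegerVector v = l[nm];
  return std::vector<int>(v.begin(), v.end());
}

Net build_net(const List& cn) {
  Net n;
  n.nneuron = as<int>(cn["nneuron"]); n.ncomp = as<int>(cn["ncomp"]);
  n.ngate = as<int>(cn["ngate"]); n.nedge = as<int>(cn["nedge"]);
  n.npool = as<int>(cn["npool"]);
  n.cm = as_dvec(cn, "cm"); n.soma_comp = as_ivec(cn, "soma_comp");
  n.cpl_a = as_ivec(cn, "cpl_a"); n.cpl_b = as_ivec(cn, "cpl_b");
  n.cpl_g = as_dvec(cn, "cpl_g"); n.ncpl = (int)n.cpl_a.size();
  n.g_comp = as_ivec(cn, "g_comp"); n.g_kind = as_ivec(cn, "g_kind");
  n.g_pool = as_ivec(cn, "g_pool"); n.g_off = as_ivec(cn, "g_off");
  n.g_vh = as_dvec(cn, "g_vh"); n.g_sl = as_dvec(cn, "g_sl");
  n.g_tau = as_dvec(cn, "g_tau"); n.g_bp_v = as_dvec(cn, "g_bp_v");
  n.g_bp_t = as_dvec(cn, "g_bp_t"); n.g_kd = as_dvec(cn, "g_kd");
  n.g_hill = as_dvec(cn, "g_hill");
  n.c_comp = as_ivec(cn, "c_comp"); n.c_mode = as_ivec(cn, "c_mode");
  n.c_act = as_ivec(cn, "c_act"); n.c_inact = as_ivec(cn, "c_inact");
  n.c_actp = as_ivec(cn, "c_actp"); n.c_inactp = as_ivec(cn, "c_inactp");
  n.c_pool = as_ivec(cn, "c_pool");
  n.c_g = as_dvec(cn, "c_g"); n.c_e = as_dvec(cn, "c_e");
  n.c_a = as_dvec(cn, "c_a"); n.c_pmax = as_dvec(cn, "c_pmax");
  n.nchan = (int)n.c_comp.size();
  n.p_comp = as_ivec(cn, "p_comp"); n.p_d = as_dvec(cn, "p_d");
  n.p_kt = as_dvec(cn, "p_kt"); n.p_kd = as_dvec(cn, "p_kd");
  n.p_taur = as_dvec(cn, "p_taur"); n.p_k = as_dvec(cn, "p_k");
  n.p_p = as_dvec(cn, "p_p"); n.p_rest = as_dvec(cn, "p_rest");
  n.ghk_z = as<double>(cn["ghk_z"]); n.ghk_f = as<double>(cn["ghk_f"]);
  n.ghk_rt = as<double>(cn["ghk_rt"]);
  n.ghk_ca_out = as<double>(cn["ghk_ca_out"]);
  n.e_pre_comp = as_ivec(cn, "e_pre_comp");
  n.e_post_comp = as_ivec(cn, "e_post_comp");
  n.e_kind = as_ivec(cn, "e_kind");
  n.e_g = as_dvec(cn, "e_g"); n.e_e = as_dvec(cn, "e_e");
  n.e_alpha = as_dvec(cn, "e_alpha"); n.e_beta = as_dvec(cn, "e_beta");
  n.e_tmax = as_dvec(cn, "e_tmax"); n.e_vp = as_dvec(cn, "e_vp");
  n.e_kp = as_dvec(cn, "e_kp"); n.e_w = as_dvec(cn, "e_w");
  n.stim_min = as_dvec(cn, "stim_min"); n.stim_max = as_dvec(cn, "stim_max");
  n.stim_on = as<double>(cn["stim_on"]);
  n.stim_off = as<double>(cn["stim_off"]);
  return n;
}

inline double ipow(double x, int p) {
  double r = 1.0;
  for (int i = 0; i < p; ++i) r *= x;
  return r;
}

inline double gate_tau_at(const Net& n, int i, double v) {
  if (n.g_tau[i] > 0) return n.g_tau[i];
  int lo = n.g_off[i], hi = n.g_off[i + 1];  // breakpoint slice [lo, hi)
  if (v <= n.g_bp_v[lo]) return n.g_bp_t[lo];
  if (v >= n.g_bp_v[hi - 1]) return n.g_bp_t[hi - 1];
  int j = lo + 1;
  while (n.g_bp_v[j] < v) ++j;
  double f = (v - n.g_bp_v[j - 1]) / (n.g_bp_v[j] - n.g_bp_v[j - 1]);
  return n.g_bp_t[j - 1] + f * (n.g_bp_t[j] - n.g_bp_t[j - 1]);
}

// GHK constant-field flux, uA/cm^2; series branch below |xi| = 1e-4
inline double ghk_flux(const Net& n, double p, double v, double ca_in) {
  double cin = ca_in * 1e-6, cout = n.ghk_ca_out * 1e-6;  // mol/cm^3
  double xi = n.ghk_z * n.ghk_f * (v / 1000.0) / n.ghk_rt;
  double zf6 = n.ghk_z * n.ghk_f * 1e6;
  if (std::fabs(xi) < 1e-4)
    return p * zf6 * ((cin - cout) + xi * (cin + cout) * 0.5);
  double em = std::exp(-xi);
  return p * zf6 * xi * (cin - cout * em) / (1.0 - em);
}

// channel current at the channel's compartment; gates/ca from state
inline double chan_current(const Net& n, int i, const double* v,
                           const double* gates, const double* ca) {
  double m = n.c_act[i] >= 0 ? gates[n.c_act[i]] : 1.0;
  double h = n.c_inact[i] >= 0 ? gates[n.c_inact[i]] : 1.0;
  double mx = ipow(m, n.c_actp[i]);
  double vv = v[n.c_comp[i]];
  if (n.c_mode[i] == 0) {
    return n.c_g[i] * mx * ipow(h, n.c_inactp[i]) * (vv - n.c_e[i]);
  } else if (n.c_mode[i] == 1) {
    double a = n.c_a[i];
    return n.c_g[i] * mx * (a * h - (1.0 - a)) * (vv - n.c_e[i]);
  }
  double perm = n.c_pmax[i] * mx * ipow(h, n.c_inactp[i]);
  return ghk_flux(n, perm, vv, ca[n.c_pool[i]]);
}

inline double edge_current(const Net& n, int i, const double* v,
                           const double* r) {
  double vpost = v[n.e_post_comp[i]];
  double cur = n.e_w[i] * n.e_g[i] * r[i] * (vpost - n.e_e[i]);
  if (n.e_kind[i] == 1)
    cur *= 1.0 / (1.0 + std::exp(-(vpost + 15.0) / 16.3));
  return cur;
}

// full RHS: state [V | gates | r | ca], stim per neuron (uA/cm^2 at soma)
void rhs(const Net& n, const double* y, const double* stim, double* dy,
         std::vector<double>& i_acc, std::vector<double>& i_capool) {
  const double* v = y;
  const double* gates = y + n.ncomp;
  const double* r = gates + n.ngate;
  const double* ca = r + n.nedge;
  double* dv = dy;
  double* dgate = dy + n.ncomp;
  double* dr = dgate + n.ngate;
  double* dca = dr + n.nedge;

  std::fill(i_acc.begin(), i_acc.end(), 0.0);
  std::fill(i_capool.begin(), i_capool.end(), 0.0);

  for (int i = 0; i < n.ngate; ++i) {
    double minf;
    if (n.g_kind[i] == 1) {
      double cah = std::pow(ca[n.g_pool[i]], n.g_hill[i]);
      minf = cah / (cah + std::pow(n.g_kd[i], n.g_hill[i]));
    } else {
      minf = 1.0 /
        (1.0 + std::exp((v[n.g_comp[i]] - n.g_vh[i]) / n.g_sl[i]));
    }
    dgate[i] = (minf - gates[i]) / gate_tau_at(n, i, v[n.g_comp[i]]);
  }
  for (int i = 0; i < n.nchan; ++i) {
    double cur = chan_current(n, i, v, gates, ca);
    i_acc[n.c_comp[i]] += cur;
    if (n.c_mode[i] == 2) i_capool[n.c_pool[i]] += cur;
  }
  for (int i = 0; i < n.nedge; ++i) {
    double vpre = v[n.e_pre_comp[i]];
    double tt = n.e_tmax[i] /
      (1.0 + std::exp(-(vpre - n.e_vp[i]) / n.e_kp[i]));
    dr[i] = n.e_alpha[i] * tt * (1.0 - r[i]) - n.e_beta[i] * r[i];
    i_acc[n.e_post_comp[i]] += edge_current(n, i, v, r);
  }
  for (int i = 0; i < n.ncpl; ++i)
    i_acc[n.cpl_a[i]] += n.cpl_g[i] * (v[n.cpl_a[i]] - v[n.cpl_b[i]]);
  for (int c = 0; c < n.ncomp; ++c) dv[c] = -i_acc[c] / n.cm[c];
  for (int k = 0; k < n.nneuron; ++k)
    dv[n.soma_comp[k]] += stim[k] / n.cm[n.soma_comp[k]];
  for (int i = 0; i < n.npool; ++i) {
    double cai = ca[i];
    double influx = n.p_k[i] * (-(i_capool[i] * 1e-3)) /
      (2.0 * n.ghk_f * n.p_d[i]);
    double pump = n.p_p[i] * n.p_kt[i] * cai / (cai + n.p_kd[i]);
    dca[i] = influx - pump + (n.p_rest[i] - cai) / n.p_taur[i];
  }
}

// 64-bit SplitMix-seeded xorshift stream for the stimulus draws; fully
// determined by the seed and platform independent
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed + 0x9E3779B97F4A7C15ULL) {
    next_u64(); next_u64();
  }
  uint64_t next_u64() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double runif() { return (next_u64() >> 11) * (1.0 / 9007199254740992.0); }
};

}  // namespace

// [[Rcpp::export]]
NumericVector core_deriv(List cn, NumericVector state, NumericVector stim) {
  Net n = build_net(cn);
  int nstate = n.ncomp + n.ngate + n.nedge + n.npool;
  if ((int)state.size() != nstate) stop("state length mismatch");
  if ((int)stim.size() != n.nneuron) stop("stimulus length mismatch");
  NumericVector out(nstate);
  std::vector<double> i_acc(n.ncomp), i_capool(n.npool);
  rhs(n, REAL(state), REAL(stim), REAL(out), i_acc, i_capool);
  return out;
}

// [[Rcpp::export]]
List core_run(List cn, double duration, double dt, double stim_seed,
              int record_stride, IntegerVector rec_v, IntegerVector rec_chan,
              IntegerVector rec_syn_comp, IntegerVector rec_syn_exc,
              int err_every) {
  Net n = build_net(cn);
  int nstate = n.ncomp + n.ngate + n.nedge + n.npool;
  NumericVector state0 = cn["state0"];
  if ((int)state0.size() != nstate) stop("state0 length mismatch");
  std::vector<double> y(state0.begin(), state0.end());
  int nsteps = (int)std::lround(duration / dt);
  int nrec = nsteps / record_stride + 1;
  int nv = rec_v.size(), nc = rec_chan.size(), ns = rec_syn_comp.size();
  NumericMatrix out_v(nrec, nv), out_c(nrec, nc), out_s(nrec, ns);
  NumericVector out_t(nrec);

  std::vector<double> k1(nstate), k2(nstate), k3(nstate), k4(nstate),
      ytmp(nstate), stim(n.nneuron, 0.0);
  std::vector<double> i_acc(n.ncomp), i_capool(n.npool);
  Rng rng((uint64_t)stim_seed);
  double err_max = 0.0;

  const double* v = y.data();
  const double* gates = v + n.ncomp;
  const double* r = gates + n.ngate;
  const double* ca = r + n.nedge;

  auto record = [&](int row, double t) {
    out_t[row] = t;
    for (int j = 0; j < nv; ++j) out_v(row, j) = y[rec_v[j]];
    for (int j = 0; j < nc; ++j)
      out_c(row, j) = chan_current(n, rec_chan[j], v, gates, ca);
    for (int j = 0; j < ns; ++j) {
      double acc = 0.0;
      for (int i = 0; i < n.nedge; ++i) {
        if (n.e_post_comp[i] != rec_syn_comp[j]) continue;
        bool exc = n.e_kind[i] != 2;
        if ((rec_syn_exc[j] == 1) != exc) continue;
        acc += edge_current(n, i, v, r);
      }
      out_s(row, j) = acc;
    }
  };
  record(0, 0.0);

  int row = 1;
  for (int step = 0; step < nsteps; ++step) {
    double t = step * dt;
    bool on = (t >= n.stim_on) && (t < n.stim_off);
    for (int k = 0; k < n.nneuron; ++k) {
      double u = rng.runif();  // always consume: stream independent of window
      stim[k] = on ? n.stim_min[k] + u * (n.stim_max[k] - n.stim_min[k]) : 0.0;
    }
    rhs(n, y.data(), stim.data(), k1.data(), i_acc, i_capool);
    for (int i = 0; i < nstate; ++i) ytmp[i] = y[i] + 0.5 * dt * k1[i];
    rhs(n, ytmp.data(), stim.data(), k2.data(), i_acc, i_capool);
    for (int i = 0; i < nstate; ++i) ytmp[i] = y[i] + 0.75 * dt * k2[i];
    rhs(n, ytmp.data(), stim.data(), k3.data(), i_acc, i_capool);
    for (int i = 0; i < nstate; ++i)
      ytmp[i] = y[i] + dt * (2.0 / 9.0 * k1[i] + 1.0 / 3.0 * k2[i] +
                             4.0 / 9.0 * k3[i]);
    if (err_every > 0 && step % err_every == 0) {
      // embedded 2nd-order solution for a logged error estimate
      rhs(n, ytmp.data(), stim.data(), k4.data(), i_acc, i_capool);
      for (int i = 0; i < nstate; ++i) {
        double e = dt * (-5.0 / 72.0 * k1[i] + 1.0 / 12.0 * k2[i] +
                         1.0 / 9.0 * k3[i] - 1.0 / 8.0 * k4[i]);
        if (std::fabs(e) > err_max) err_max = std::fabs(e);
      }
    }
    std::copy(ytmp.begin(), ytmp.end(), y.begin());
    // physical clamps: gates and receptor fractions in [0,1], calcium > 0
    for (int i = n.ncomp; i < n.ncomp + n.ngate + n.nedge; ++i) {
      if (y[i] < 0.0) y[i] = 0.0;
      else if (y[i] > 1.0) y[i] = 1.0;
    }
    for (int i = n.ncomp + n.ngate + n.nedge; i < nstate; ++i)
      if (y[i] < 1e-9) y[i] = 1e-9;
    for (int c = 0; c < n.ncomp; ++c) {
      if (!std::isfinite(y[c]) || std::fabs(y[c]) > 1000.0) {
        stop("numerical blowup at t = %f ms in state %d", t + dt, c + 1);
      }
    }
    if ((step + 1) % record_stride == 0) record(row++, (step + 1) * dt);
    if (step % 25000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["t"] = out_t, _["v"] = out_v, _["channel"] = out_c,
                      _["synaptic"] = out_s, _["err_max"] = err_max,
                      _["state_final"] = NumericVector(y.begin(), y.end()));
}
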