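// Next-Subvolume event engine for the multiscale sprouting-angiogenesis
// model: per-voxel VEGF-Delta-Notch reaction channels coupled through
// disc-overlap neighbourhood averages, plus a persistent-random-walk
// migration channel executed by exact thinning of the von Mises polarity
// distribution.  Matrix density, basement membrane and the orientation
// landscape are deterministic between events and materialised lazily
// (the integrals are exact because each voxel's Delta level is constant
// between its own events).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const int N_CH = 13;      // 12 reaction channels + 1 migration channel
static const int CH_MIG = 12;

struct LineagePar {
  double b_N, b_D, b_R2, gamma, gamma_e, k_t, k_c, k_v, eta;
  double I0, lamIN, nN, lamIR2, nR2, R2s0, lamR2D, nD;
  int baseN, baseD, baseR2;  // influx initialisation baselines (copy numbers)
};

struct Glob {
  double Omega, Dtil;
  double pmax, sp, Dp, EF1, EF2, sF1, sF2, K, km, kD, aH, nH;
  double eta_max, s_c, D_c, gamma_max, s_m, D_m, Delta_l, eta_l, c_max;
  double xi;
  bool reactions_on, migration_on, fields_on, orientation_on, influx_on;
};

static inline double shifted_hill(double X, double X0, double lam, double n) {
  double r = std::pow(X / X0, n);
  return (1.0 + lam * r) / (1.0 + r);
}

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// indexed binary min-heap over per-voxel next-event times
struct Heap {
  std::vector<int> h, pos;
  std::vector<double> key;
  void init(int n) {
    h.resize(n); pos.resize(n); key.assign(n, R_PosInf);
    for (int i = 0; i < n; ++i) { h[i] = i; pos[i] = i; }
  }
  void swap_at(int a, int b) {
    std::swap(h[a], h[b]); pos[h[a]] = a; pos[h[b]] = b;
  }
  void up(int k) { while (k > 0) { int p = (k - 1) / 2;
      if (key[h[k]] < key[h[p]]) { swap_at(k, p); k = p; } else break; } }
  void down(int k) { int n = (int)h.size();
    for (;;) { int l = 2 * k + 1, r = l + 1, m = k;
      if (l < n && key[h[l]] < key[h[m]]) m = l;
      if (r < n && key[h[r]] < key[h[m]]) m = r;
      if (m == k) break; swap_at(k, m); k = m; } }
  void update(int v, double t) { key[v] = t; up(pos[v]); down(pos[v]); }
  int top() const { return h[0]; }
  double top_key() const { return key[h[0]]; }
};

struct Engine {
  int n, n_lin;
  IntegerMatrix nbr;               // n x 6, 0-based, -1 off-lattice
  std::vector<double> ux, uy;
  // CSR stencils (0-based indices)
  std::vector<int> a_ptr, a_idx, p_ptr, p_idx;
  std::vector<double> a_w, a_wsum, p_w, p_wsum;
  std::vector<double> V;
  std::vector<LineagePar> lin;
  Glob g;
  std::vector<int> plexus;         // 0-based voxel ids
  std::vector<char> is_plexus;
  std::vector<double> plexus_cum;  // cumulative lineage probabilities

  // dynamic state
  std::vector<int> E, lineage, label;
  std::vector<int> nN, nD, nI, nR2, nR2s;
  std::vector<double> c, m, t_cm;
  std::vector<double> l;           // n x 6 row-major
  std::vector<double> t_l;
  std::vector<double> SD, SN, ENsum;
  std::vector<double> prop;        // n x N_CH
  std::vector<double> a_tot;
  Heap heap;
  double clock_, T_max;
  int next_label;
  long n_events, n_moves, n_swaps, n_rej, influx_count;
  double first_event_time;

  // occupancy-time ledger
  std::vector<double> occ_time;    // n x n_lin
  std::vector<double> t_occ;

  // per-event dirty tracking
  std::vector<double> a_old;
  std::vector<int> stamp;
  std::vector<int> dirty;
  int cur_stamp;

  double Dconc(int i) const { return nD[i] / g.Omega; }
  double Nconc(int i) const { return nN[i] / g.Omega; }

  void materialize_cm(int i, double t) {
    if (t <= t_cm[i]) return;
    if (g.fields_on && E[i] == 1) {
      double tau = t - t_cm[i], D = Dconc(i);
      double ec = g.eta_max * logistic(g.s_c * (D - g.D_c));
      double gm = g.gamma_max * logistic(g.s_m * (D - g.D_m));
      c[i] = std::max(0.0, c[i] - ec * tau);
      m[i] = std::min(1.0, m[i] + gm * tau);
    }
    t_cm[i] = t;
  }
  void materialize_l(int i, double t) {
    if (t <= t_l[i]) return;
    if (g.orientation_on && g.eta_l > 0) {
      double f = std::exp(-g.eta_l * (t - t_l[i]));
      for (int s = 0; s < 6; ++s) l[i * 6 + s] *= f;
    }
    t_l[i] = t;
  }

  void recompute_voxel(int i) {
    double *pr = &prop[i * N_CH];
    double tot = 0;
    if (E[i] == 1 && g.reactions_on) {
      const LineagePar &q = lin[lineage[i]];
      double Ic = nI[i] / g.Omega, R2sc = nR2s[i] / g.Omega;
      double Dbar = a_wsum[i] > 0 ? SD[i] / a_wsum[i] : 0.0;
      double Nbar = a_wsum[i] > 0 ? SN[i] / a_wsum[i] : 0.0;
      pr[0] = g.Omega * q.b_N * shifted_hill(Ic, q.I0, q.lamIN, q.nN);
      pr[1] = g.Omega * q.b_D * shifted_hill(R2sc, q.R2s0, q.lamR2D, q.nD);
      pr[2] = g.Omega * q.b_R2 * shifted_hill(Ic, q.I0, q.lamIR2, q.nR2);
      pr[3] = q.gamma * nN[i];
      pr[4] = q.gamma * nD[i];
      pr[5] = q.gamma * nR2[i];
      pr[6] = q.gamma_e * nI[i];
      pr[7] = q.gamma_e * nR2s[i];
      pr[8] = q.k_t * Dbar * nN[i];
      pr[9] = q.eta * q.k_t * Nbar * nD[i];
      pr[10] = q.k_c / g.Omega * (double)nN[i] * (double)nD[i];
      pr[11] = q.k_v * V[i] * nR2[i];
    } else {
      for (int k = 0; k < 12; ++k) pr[k] = 0;
    }
    pr[CH_MIG] = 0;
    if (E[i] == 1 && g.migration_on) {
      double S = c[i] < g.c_max ? 1.0 - c[i] / g.c_max : 0.0;
      if (S < 0) S = 0;
      double EN = p_wsum[i] > 0 ? ENsum[i] / p_wsum[i] : 0.0;
      double F = logistic(g.sF1 * (EN - g.EF1)) +
                 logistic(-g.sF2 * (EN - g.EF2)) - 1.0;
      if (F < 0) F = 0;
      pr[CH_MIG] = g.Dtil * S * F;
    }
    for (int k = 0; k < N_CH; ++k) tot += pr[k];
    a_tot[i] = tot;
  }

  void mark(int i) {
    if (stamp[i] != cur_stamp) {
      stamp[i] = cur_stamp;
      a_old[i] = a_tot[i];
      dirty.push_back(i);
    }
  }

  // update neighbourhood Delta/Notch sums after species change at voxel i
  void bump_signals(int i, double dD, double dN) {
    if (dD == 0 && dN == 0) return;
    for (int k = a_ptr[i]; k < a_ptr[i + 1]; ++k) {
      int j = a_idx[k];
      double w = a_w[k];
      SD[j] += w * dD;
      SN[j] += w * dN;
      if (E[j] == 1 && g.reactions_on) {
        mark(j);
        const LineagePar &q = lin[lineage[j]];
        double Dbar = a_wsum[j] > 0 ? SD[j] / a_wsum[j] : 0.0;
        double Nbar = a_wsum[j] > 0 ? SN[j] / a_wsum[j] : 0.0;
        double *pr = &prop[j * N_CH];
        double old8 = pr[8], old9 = pr[9];
        pr[8] = q.k_t * Dbar * nN[j];
        pr[9] = q.eta * q.k_t * Nbar * nD[j];
        a_tot[j] += (pr[8] - old8) + (pr[9] - old9);
      }
    }
  }

  // update neighbourhood occupancy sums after E change at voxel i
  void bump_occupancy(int i, double dE) {
    for (int k = p_ptr[i]; k < p_ptr[i + 1]; ++k) {
      int j = p_idx[k];
      ENsum[j] += p_w[k] * dE;
      mark(j);
      recompute_voxel(j);  // F factor changed; cheap full refresh
    }
  }

  void flush_occupancy(int i, double t) {
    if (E[i] == 1) occ_time[i * n_lin + lineage[i]] += t - t_occ[i];
    t_occ[i] = t;
  }

  double rexp_rate(double a) {
    if (a <= 0) return R_PosInf;
    return -std::log(unif_rand()) / a;
  }

  double sample_vonmises(double mu, double kappa) {
    if (kappa < 1e-10) return 2.0 * M_PI * unif_rand() - M_PI;
    double a = 1.0 + std::sqrt(1.0 + 4.0 * kappa * kappa);
    double b = (a - std::sqrt(2.0 * a)) / (2.0 * kappa);
    double r = (1.0 + b * b) / (2.0 * b);
    double f;
    for (;;) {
      double u1 = unif_rand(), u2 = unif_rand();
      double z = std::cos(M_PI * u1);
      f = (1.0 + r * z) / (r + z);
      double cc = kappa * (r - f);
      if (cc * (2.0 - cc) - u2 > 0) break;
      if (cc / u2 > 0 && std::log(cc / u2) + 1.0 - cc >= 0) break;
    }
    double u3 = unif_rand();
    double th = (u3 - 0.5 >= 0 ? 1.0 : -1.0) * std::acos(f) + mu;
    // wrap to [-pi, pi)
    th -= 2.0 * M_PI * std::floor((th + M_PI) / (2.0 * M_PI));
    return th;
  }

  void spawn_cell(int i, double t) {
    // lineage from the plexus mix
    double u = unif_rand();
    int li = 0;
    while (li + 1 < n_lin && u > plexus_cum[li]) ++li;
    const LineagePar &q = lin[li];
    flush_occupancy(i, t);
    E[i] = 1; lineage[i] = li; label[i] = next_label++;
    auto draw = [&](int base) {
      int lo = (int)std::floor(base * (1.0 - g.xi));
      int hi = (int)std::ceil(base * (1.0 + g.xi));
      return lo + (int)std::floor(unif_rand() * (hi - lo + 1));
    };
    int dN_ = draw(q.baseN), dD_ = draw(q.baseD), dR2_ = draw(q.baseR2);
    nN[i] = dN_; nD[i] = dD_; nR2[i] = dR2_; nI[i] = 0; nR2s[i] = 0;
    t_cm[i] = t;
    bump_signals(i, dD_ / g.Omega, dN_ / g.Omega);
    bump_occupancy(i, 1.0);
    mark(i);
    recompute_voxel(i);
    ++influx_count;
  }

  void apply_reaction(int i, int ch, double t) {
    materialize_cm(i, t);
    int dNn = 0, dDn = 0;
    switch (ch) {
      case 0: nN[i] += 1; dNn = 1; break;
      case 1: nD[i] += 1; dDn = 1; break;
      case 2: nR2[i] += 1; break;
      case 3: nN[i] -= 1; dNn = -1; break;
      case 4: nD[i] -= 1; dDn = -1; break;
      case 5: nR2[i] -= 1; break;
      case 6: nI[i] -= 1; break;
      case 7: nR2s[i] -= 1; break;
      case 8: nN[i] -= 1; nI[i] += 1; dNn = -1; break;
      case 9: nD[i] -= 1; dDn = -1; break;
      case 10: nN[i] -= 1; nD[i] -= 1; dNn = -1; dDn = -1; break;
      case 11: nR2[i] -= 1; nR2s[i] += 1; break;
    }
    bump_signals(i, dDn / g.Omega, dNn / g.Omega);
    mark(i);
    recompute_voxel(i);
  }

  // returns direction fired (0..5) or -1, plus acceptance in *accepted
  int apply_migration(int i, double t, bool *accepted) {
    *accepted = false;
    materialize_cm(i, t);
    materialize_l(i, t);
    // polarity
    double px = 0, py = 0;
    for (int s = 0; s < 6; ++s) {
      double lv = l[i * 6 + s];
      double w = std::pow(lv, g.nH) / (std::pow(g.aH, g.nH) + std::pow(lv, g.nH));
      px += w * ux[s]; py += w * uy[s];
    }
    double mu, kappa;
    if (std::sqrt(px * px + py * py) < 1e-12) { mu = 0; kappa = 0; }
    else {
      mu = std::atan2(py, px);
      kappa = g.K * std::exp(g.km * m[i] - g.kD * Dconc(i));
    }
    double phi = sample_vonmises(mu, kappa);
    int s = (int)std::floor((phi + M_PI / 6.0) / (M_PI / 3.0));
    s = ((s % 6) + 6) % 6;
    int j = nbr(i, s);
    mark(i);
    if (j < 0) { recompute_voxel(i); return s; }
    if (E[j] == 1) {
      double ps = g.pmax * logistic(g.sp * (Dconc(i) - g.Dp));
      if (unif_rand() >= ps) { recompute_voxel(i); return s; }
    }
    *accepted = true;
    materialize_cm(j, t);
    double Di_conc = Dconc(i);
    if (g.orientation_on) {
      materialize_l(j, t);
      l[i * 6 + s] += g.Delta_l * Di_conc;
      l[j * 6 + s] += g.Delta_l * Di_conc;
    }
    flush_occupancy(i, t);
    flush_occupancy(j, t);
    double Di_old = Dconc(i), Ni_old = Nconc(i);
    double Dj_old = Dconc(j), Nj_old = Nconc(j);
    bool swap = (E[j] == 1);
    std::swap(nN[i], nN[j]); std::swap(nD[i], nD[j]);
    std::swap(nI[i], nI[j]); std::swap(nR2[i], nR2[j]);
    std::swap(nR2s[i], nR2s[j]);
    std::swap(lineage[i], lineage[j]);
    std::swap(label[i], label[j]);
    if (!swap) { E[i] = 0; E[j] = 1; ++n_moves; } else ++n_swaps;
    mark(j);
    bump_signals(i, Dconc(i) - Di_old, Nconc(i) - Ni_old);
    bump_signals(j, Dconc(j) - Dj_old, Nconc(j) - Nj_old);
    if (!swap) { bump_occupancy(i, -1.0); bump_occupancy(j, 1.0); }
    recompute_voxel(i);
    recompute_voxel(j);
    if (!swap && g.influx_on && is_plexus[i] && E[i] == 0) spawn_cell(i, t);
    return s;
  }
};

// [[Rcpp::export]]
List engine_run(List cfg) {
  Engine eng;
  eng.n = as<int>(cfg["n"]);
  eng.nbr = as<IntegerMatrix>(cfg["nbr0"]);
  eng.ux = as<std::vector<double>>(cfg["ux"]);
  eng.uy = as<std::vector<double>>(cfg["uy"]);
  eng.a_ptr = as<std::vector<int>>(cfg["a_ptr"]);
  eng.a_idx = as<std::vector<int>>(cfg["a_idx0"]);
  eng.a_w = as<std::vector<double>>(cfg["a_w"]);
  eng.a_wsum = as<std::vector<double>>(cfg["a_wsum"]);
  eng.p_ptr = as<std::vector<int>>(cfg["p_ptr"]);
  eng.p_idx = as<std::vector<int>>(cfg["p_idx0"]);
  eng.p_w = as<std::vector<double>>(cfg["p_w"]);
  eng.p_wsum = as<std::vector<double>>(cfg["p_wsum"]);
  eng.V = as<std::vector<double>>(cfg["V"]);

  NumericMatrix lp = as<NumericMatrix>(cfg["lin_par"]);
  IntegerMatrix lb = as<IntegerMatrix>(cfg["lin_base"]);
  eng.n_lin = lp.nrow();
  for (int r = 0; r < eng.n_lin; ++r) {
    LineagePar q;
    q.b_N = lp(r, 0); q.b_D = lp(r, 1); q.b_R2 = lp(r, 2);
    q.gamma = lp(r, 3); q.gamma_e = lp(r, 4); q.k_t = lp(r, 5);
    q.k_c = lp(r, 6); q.k_v = lp(r, 7); q.eta = lp(r, 8);
    q.I0 = lp(r, 9); q.lamIN = lp(r, 10); q.nN = lp(r, 11);
    q.lamIR2 = lp(r, 12); q.nR2 = lp(r, 13);
    q.R2s0 = lp(r, 14); q.lamR2D = lp(r, 15); q.nD = lp(r, 16);
    q.baseN = lb(r, 0); q.baseD = lb(r, 1); q.baseR2 = lb(r, 2);
    eng.lin.push_back(q);
  }

  NumericVector gv = as<NumericVector>(cfg["glob"]);
  Glob &g = eng.g;
  g.Omega = gv["Omega"]; g.Dtil = gv["Dtil"];
  g.pmax = gv["p_max"]; g.sp = gv["s_p"]; g.Dp = gv["D_p"];
  g.EF1 = gv["E_F1"]; g.EF2 = gv["E_F2"]; g.sF1 = gv["s_F1"]; g.sF2 = gv["s_F2"];
  g.K = gv["K"]; g.km = gv["k_m"]; g.kD = gv["k_D"];
  g.aH = gv["a_H"]; g.nH = gv["n_H"];
  g.eta_max = gv["eta_max"]; g.s_c = gv["s_c"]; g.D_c = gv["D_c"];
  g.gamma_max = gv["gamma_max"]; g.s_m = gv["s_m"]; g.D_m = gv["D_m"];
  g.Delta_l = gv["Delta_l"]; g.eta_l = gv["eta_l"]; g.c_max = gv["c_max"];
  g.xi = gv["xi"];
  LogicalVector fl = as<LogicalVector>(cfg["flags"]);
  g.reactions_on = fl["reactions"]; g.migration_on = fl["migration"];
  g.fields_on = fl["fields"]; g.orientation_on = fl["orientation"];
  g.influx_on = fl["influx"];

  eng.plexus = as<std::vector<int>>(cfg["plexus0"]);
  eng.is_plexus.assign(eng.n, 0);
  for (int v : eng.plexus) eng.is_plexus[v] = 1;
  std::vector<double> pl_probs = as<std::vector<double>>(cfg["plexus_lin_probs"]);
  eng.plexus_cum.resize(eng.n_lin);
  double acc = 0;
  for (int r = 0; r < eng.n_lin; ++r) {
    acc += (r < (int)pl_probs.size() ? pl_probs[r] : 0.0);
    eng.plexus_cum[r] = acc;
  }

  eng.E = as<std::vector<int>>(cfg["E0"]);
  eng.lineage = as<std::vector<int>>(cfg["lineage0"]);
  eng.label = as<std::vector<int>>(cfg["label0"]);
  IntegerMatrix pm = as<IntegerMatrix>(cfg["prot0"]);
  eng.nN.resize(eng.n); eng.nD.resize(eng.n); eng.nI.resize(eng.n);
  eng.nR2.resize(eng.n); eng.nR2s.resize(eng.n);
  for (int i = 0; i < eng.n; ++i) {
    eng.nN[i] = pm(i, 0); eng.nD[i] = pm(i, 1); eng.nI[i] = pm(i, 2);
    eng.nR2[i] = pm(i, 3); eng.nR2s[i] = pm(i, 4);
  }
  eng.c = as<std::vector<double>>(cfg["c0"]);
  eng.m = as<std::vector<double>>(cfg["m0"]);
  NumericMatrix lm = as<NumericMatrix>(cfg["l0"]);
  eng.l.resize(eng.n * 6);
  for (int i = 0; i < eng.n; ++i)
    for (int s = 0; s < 6; ++s) eng.l[i * 6 + s] = lm(i, s);
  eng.t_cm.assign(eng.n, 0.0);
  eng.t_l.assign(eng.n, 0.0);

  eng.T_max = as<double>(cfg["T_max"]);
  double dt_sample = as<double>(cfg["dt_sample"]);
  NumericVector snap_times = as<NumericVector>(cfg["snapshot_times"]);
  int record_events = as<int>(cfg["record_events"]);
  double max_events = as<double>(cfg["max_events"]);

  // derived sums and initial propensities
  eng.SD.assign(eng.n, 0.0); eng.SN.assign(eng.n, 0.0);
  eng.ENsum.assign(eng.n, 0.0);
  for (int i = 0; i < eng.n; ++i) {
    for (int k = eng.a_ptr[i]; k < eng.a_ptr[i + 1]; ++k) {
      int j = eng.a_idx[k];
      eng.SD[i] += eng.a_w[k] * eng.nD[j] / g.Omega;
      eng.SN[i] += eng.a_w[k] * eng.nN[j] / g.Omega;
    }
    for (int k = eng.p_ptr[i]; k < eng.p_ptr[i + 1]; ++k)
      eng.ENsum[i] += eng.p_w[k] * eng.E[eng.p_idx[k]];
  }
  eng.prop.assign(eng.n * N_CH, 0.0);
  eng.a_tot.assign(eng.n, 0.0);
  for (int i = 0; i < eng.n; ++i) eng.recompute_voxel(i);

  eng.occ_time.assign(eng.n * eng.n_lin, 0.0);
  eng.t_occ.assign(eng.n, 0.0);
  eng.a_old.assign(eng.n, 0.0);
  eng.stamp.assign(eng.n, -1);
  eng.cur_stamp = 0;
  eng.clock_ = 0;
  eng.next_label = as<int>(cfg["next_label"]);
  eng.n_events = eng.n_moves = eng.n_swaps = eng.n_rej = 0;
  eng.influx_count = 0;
  eng.first_event_time = NA_REAL;

  GetRNGstate();
  eng.heap.init(eng.n);
  for (int i = 0; i < eng.n; ++i)
    eng.heap.update(i, eng.rexp_rate(eng.a_tot[i]));

  // trajectory / snapshot / event buffers
  std::vector<double> tr_t, tr_D;
  std::vector<int> tr_label, tr_voxel, tr_lin;
  double next_sample = (dt_sample > 0) ? 0.0 : R_PosInf;
  int snap_ix = 0;
  List snapshots(snap_times.size());
  std::vector<double> ev_t; std::vector<int> ev_vox, ev_ch, ev_dir, ev_acc;

  auto emit_sample = [&](double ts) {
    for (int i = 0; i < eng.n; ++i) if (eng.E[i] == 1) {
      tr_t.push_back(ts); tr_label.push_back(eng.label[i]);
      tr_voxel.push_back(i + 1); tr_lin.push_back(eng.lineage[i]);
      tr_D.push_back(eng.Dconc(i));
    }
  };
  auto emit_snapshot = [&](double ts, int ix) {
    NumericVector cs(eng.n), ms(eng.n), Ds(eng.n);
    IntegerVector Es(eng.n), lbs(eng.n), lns(eng.n);
    NumericMatrix ls(eng.n, 6);
    for (int i = 0; i < eng.n; ++i) {
      eng.materialize_cm(i, ts);
      eng.materialize_l(i, ts);
      cs[i] = eng.c[i]; ms[i] = eng.m[i];
      Es[i] = eng.E[i]; lbs[i] = eng.label[i]; lns[i] = eng.lineage[i];
      Ds[i] = eng.Dconc(i);
      for (int s = 0; s < 6; ++s) ls(i, s) = eng.l[i * 6 + s];
    }
    snapshots[ix] = List::create(_["time"] = ts, _["E"] = Es,
      _["label"] = lbs, _["lineage"] = lns, _["D"] = Ds,
      _["c"] = cs, _["m"] = ms, _["l"] = ls);
  };
  auto flush_outputs = [&](double upto) {
    while (next_sample <= upto + 1e-12 && next_sample <= eng.T_max + 1e-12) {
      emit_sample(next_sample);
      next_sample += dt_sample;
    }
    while (snap_ix < snap_times.size() && snap_times[snap_ix] <= upto + 1e-12) {
      emit_snapshot(snap_times[snap_ix], snap_ix);
      ++snap_ix;
    }
  };

  for (;;) {
    double t_next = eng.heap.top_key();
    if (!R_finite(t_next) || t_next > eng.T_max ||
        eng.n_events >= max_events) {
      double t_end = (eng.n_events >= max_events && t_next <= eng.T_max)
                     ? eng.clock_ : eng.T_max;
      flush_outputs(t_end);
      eng.clock_ = t_end;
      break;
    }
    flush_outputs(t_next);  // pre-event state holds on [clock, t_next)
    int i = eng.heap.top();
    eng.clock_ = t_next;
    if (!R_finite(eng.first_event_time)) eng.first_event_time = t_next;

    // channel selection within the voxel
    double u = unif_rand() * eng.a_tot[i];
    double accu = 0; int ch = N_CH - 1;
    for (int k = 0; k < N_CH; ++k) {
      accu += eng.prop[i * N_CH + k];
      if (u < accu) { ch = k; break; }
    }

    ++eng.cur_stamp;
    eng.dirty.clear();
    int dir = -1, acc_flag = 1;
    if (ch == CH_MIG) {
      bool accepted;
      dir = eng.apply_migration(i, t_next, &accepted);
      acc_flag = accepted ? 1 : 0;
      if (!accepted) ++eng.n_rej;
    } else {
      eng.apply_reaction(i, ch, t_next);
    }
    ++eng.n_events;
    if (record_events > 0 && (int)ev_t.size() < record_events) {
      ev_t.push_back(t_next); ev_vox.push_back(i + 1);
      ev_ch.push_back(ch + 1); ev_dir.push_back(dir + 1);
      ev_acc.push_back(acc_flag);
    }

    // reschedule: fresh draw for the fired voxel, rescaling elsewhere
    for (int v : eng.dirty) {
      double anew = eng.a_tot[v];
      double told = eng.heap.key[v];
      double tnew;
      if (v == i) tnew = t_next + eng.rexp_rate(anew);
      else if (anew <= 0) tnew = R_PosInf;
      else if (!R_finite(told) || eng.a_old[v] <= 0)
        tnew = t_next + eng.rexp_rate(anew);
      else tnew = t_next + (eng.a_old[v] / anew) * (told - t_next);
      eng.heap.update(v, tnew);
    }
  }

  // close the occupancy ledger and materialise fields at the final clock
  for (int i = 0; i < eng.n; ++i) {
    eng.flush_occupancy(i, eng.clock_);
    eng.materialize_cm(i, eng.clock_);
    eng.materialize_l(i, eng.clock_);
  }
  PutRNGstate();

  IntegerMatrix prot_out(eng.n, 5);
  NumericMatrix l_out(eng.n, 6);
  for (int i = 0; i < eng.n; ++i) {
    prot_out(i, 0) = eng.nN[i]; prot_out(i, 1) = eng.nD[i];
    prot_out(i, 2) = eng.nI[i]; prot_out(i, 3) = eng.nR2[i];
    prot_out(i, 4) = eng.nR2s[i];
    for (int s = 0; s < 6; ++s) l_out(i, s) = eng.l[i * 6 + s];
  }
  NumericMatrix occ_out(eng.n, eng.n_lin);
  for (int i = 0; i < eng.n; ++i)
    for (int r = 0; r < eng.n_lin; ++r)
      occ_out(i, r) = eng.occ_time[i * eng.n_lin + r];
  NumericMatrix prop_out(eng.n, N_CH);
  for (int i = 0; i < eng.n; ++i)
    for (int k = 0; k < N_CH; ++k) prop_out(i, k) = eng.prop[i * N_CH + k];

  return List::create(
    _["clock"] = eng.clock_,
    _["n_events"] = (double)eng.n_events,
    _["n_moves"] = (double)eng.n_moves,
    _["n_swaps"] = (double)eng.n_swaps,
    _["n_rejected"] = (double)eng.n_rej,
    _["influx_count"] = (double)eng.influx_count,
    _["first_event_time"] = eng.first_event_time,
    _["next_label"] = eng.next_label,
    _["E"] = IntegerVector(eng.E.begin(), eng.E.end()),
    _["lineage"] = IntegerVector(eng.lineage.begin(), eng.lineage.end()),
    _["label"] = IntegerVector(eng.label.begin(), eng.label.end()),
    _["prot"] = prot_out,
    _["c"] = NumericVector(eng.c.begin(), eng.c.end()),
    _["m"] = NumericVector(eng.m.begin(), eng.m.end()),
    _["l"] = l_out,
    _["prop"] = prop_out,
    _["occ_time"] = occ_out,
    _["traj"] = List::create(_["t"] = tr_t, _["label"] = tr_label,
      _["voxel"] = tr_voxel, _["lineage"] = tr_lin, _["D"] = tr_D),
    _["snapshots"] = snapshots,
    _["events"] = List::create(_["t"] = ev_t, _["voxel"] = ev_vox,
      _["channel"] = ev_ch, _["direction"] = ev_dir, _["accepted"] = ev_acc)
  );
}
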