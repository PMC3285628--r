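// Exact stochastic simulation (direct-method Gillespie) of the lattice
// master equation: per-site Michaelis-Menten conversion, enzyme shuttling
// against shared integer cytosolic reservoirs, and nearest-neighbour
// diffusion jumps of the lipid species.
//
// Propensities are grouped so reservoir updates stay O(1):
//   total = W + A_cyt * CA + B_cyt * CB
// where W collects the 7 reservoir-independent channels per site and
// CA/CB the per-site binding coefficients (linear in the free counts).
// Each group is held in a Fenwick tree for O(log n) selection/update.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Fenwick {
  int n;
  std::vector<double> tree;   // 1-based
  std::vector<double> val;
  void init(int n_) {
    n = n_;
    tree.assign(n + 1, 0.0);
    val.assign(n, 0.0);
  }
  void set(int i, double v) {
    double d = v - val[i];
    val[i] = v;
    for (int j = i + 1; j <= n; j += j & (-j)) tree[j] += d;
  }
  double total() const {
    double s = 0.0;
    for (int j = n; j > 0; j -= j & (-j)) s += tree[j];
    return s;
  }
  // smallest index with prefix sum > u
  int select(double u) const {
    int pos = 0;
    int mask = 1;
    while ((mask << 1) <= n) mask <<= 1;
    for (; mask > 0; mask >>= 1) {
      int next = pos + mask;
      if (next <= n && tree[next] < u) {
        u -= tree[next];
        pos = next;
      }
    }
    return pos;  // 0-based index
  }
  void rebuild() {
    std::fill(tree.begin(), tree.end(), 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j <= n; j += j & (-j)) tree[j] += val[i];
  }
};

enum Channel { ACT = 0, DEACT, UNB_AR, UNB_AX, UNB_B, DIF_XS, DIF_X0,
               BIND_AR, BIND_AX, BIND_B };

}  // namespace

// [[Rcpp::export(name = ".ssa_core")]]
List ssa_core(IntegerMatrix counts0, double A_cyt0, double B_cyt0,
              NumericVector site_area, NumericVector receptor,
              IntegerVector nbr, IntegerVector nbr_ptr,
              List pars, double t0, double t_max,
              NumericVector snap_times, double max_events,
              bool record_events, int max_log) {
  const int n = counts0.nrow();
  const double k_cat_A = pars["k_cat_A"], k_cat_B = pars["k_cat_B"];
  const double K_A = pars["K_A"], K_B = pars["K_B"];
  const double k_on_R = pars["k_on_R"], k_on_X = pars["k_on_X"],
               k_on_B = pars["k_on_B"];
  const double k_off_AR = pars["k_off_AR"], k_off_AX = pars["k_off_AX"],
               k_off_B = pars["k_off_B"];
  const double V = pars["V_cyt"], D = pars["D"];
  double S = 0.0;
  for (int i = 0; i < n; ++i) S += site_area[i];
  const double hop = (n > 1) ? D * n / S : 0.0;  // per-molecule leave rate

  // state
  std::vector<double> XS(n), X0(n), AR(n), AX(n), BB(n);
  for (int i = 0; i < n; ++i) {
    XS[i] = counts0(i, 0); X0[i] = counts0(i, 1);
    AR[i] = counts0(i, 2); AX[i] = counts0(i, 3); BB[i] = counts0(i, 4);
  }
  double Acyt = A_cyt0, Bcyt = B_cyt0;

  Fenwick Wt, CAt, CBt;
  Wt.init(n); CAt.init(n); CBt.init(n);

  auto site_w = [&](int i) {
    double a = 0.0;
    a += k_cat_A * (AR[i] + AX[i]) * X0[i] / (K_A * site_area[i] + X0[i]);
    a += k_cat_B * BB[i] * XS[i] / (K_B * site_area[i] + XS[i]);
    a += k_off_AR * AR[i] + k_off_AX * AX[i] + k_off_B * BB[i];
    a += hop * (XS[i] + X0[i]);
    return a;
  };
  auto site_ca = [&](int i) {
    return (k_on_R * receptor[i] * site_area[i] + k_on_X * XS[i]) / V;
  };
  auto site_cb = [&](int i) { return k_on_B * X0[i] / V; };

  for (int i = 0; i < n; ++i) {
    Wt.set(i, site_w(i));
    CAt.set(i, site_ca(i));
    CBt.set(i, site_cb(i));
  }
  auto refresh_site = [&](int i) {
    Wt.set(i, site_w(i));
    CAt.set(i, site_ca(i));
    CBt.set(i, site_cb(i));
  };

  const int n_snap = snap_times.size();
  IntegerVector snaps(n_snap * n * 5);
  NumericMatrix reservoirs(n_snap, 2);
  int snap_idx = 0;

  std::vector<double> ev_t; std::vector<int> ev_site, ev_chan;

  double t = t0;
  double n_events = 0.0;
  bool absorbed = false;

  auto record_snaps_until = [&](double tt) {
    while (snap_idx < n_snap && snap_times[snap_idx] <= tt + 1e-12) {
      for (int i = 0; i < n; ++i) {
        snaps[snap_idx + n_snap * (i + (long)n * 0)] = (int)XS[i];
        snaps[snap_idx + n_snap * (i + (long)n * 1)] = (int)X0[i];
        snaps[snap_idx + n_snap * (i + (long)n * 2)] = (int)AR[i];
        snaps[snap_idx + n_snap * (i + (long)n * 3)] = (int)AX[i];
        snaps[snap_idx + n_snap * (i + (long)n * 4)] = (int)BB[i];
      }
      reservoirs(snap_idx, 0) = Acyt;
      reservoirs(snap_idx, 1) = Bcyt;
      ++snap_idx;
    }
  };

  long rebuild_counter = 0;
  while (t < t_max && n_events < max_events) {
    double W = Wt.total(), CA = CAt.total(), CB = CBt.total();
    double total = W + Acyt * CA + Bcyt * CB;
    if (total <= 0.0) { absorbed = true; break; }
    double dt = -std::log(unif_rand()) / total;
    double tn = t + dt;
    if (tn >= t_max) { t = t_max; break; }
    record_snaps_until(tn);
    t = tn;

    double u = unif_rand() * total;
    int site, chan;
    if (u < W) {
      site = Wt.select(u);
      // decode channel within site
      double r = u;
      {  // subtract prefix of previous sites
        // recompute this site's channels
        double c0 = k_cat_A * (AR[site] + AX[site]) * X0[site] /
                    (K_A * site_area[site] + X0[site]);
        double c1 = k_cat_B * BB[site] * XS[site] /
                    (K_B * site_area[site] + XS[site]);
        double c2 = k_off_AR * AR[site], c3 = k_off_AX * AX[site],
               c4 = k_off_B * BB[site];
        double c5 = hop * XS[site], c6 = hop * X0[site];
        // prefix within the W tree up to 'site'
        double before = 0.0;
        for (int j = site; j > 0; j -= j & (-j)) before += Wt.tree[j];
        r -= before;
        if (r < c0) chan = ACT;
        else if (r < c0 + c1) chan = DEACT;
        else if (r < c0 + c1 + c2) chan = UNB_AR;
        else if (r < c0 + c1 + c2 + c3) chan = UNB_AX;
        else if (r < c0 + c1 + c2 + c3 + c4) chan = UNB_B;
        else if (r < c0 + c1 + c2 + c3 + c4 + c5) chan = DIF_XS;
        else chan = DIF_X0;
      }
    } else if (u < W + Acyt * CA) {
      double v = (u - W) / std::max(Acyt, 1.0);
      if (v >= CA) v = CA * (1.0 - 1e-16);
      site = CAt.select(v);
      double before = 0.0;
      for (int j = site; j > 0; j -= j & (-j)) before += CAt.tree[j];
      double r = v - before;
      double cR = k_on_R * receptor[site] * site_area[site] / V;
      chan = (r < cR) ? BIND_AR : BIND_AX;
    } else {
      double v = (u - W - Acyt * CA) / std::max(Bcyt, 1.0);
      if (v >= CB) v = CB * (1.0 - 1e-16);
      site = CBt.select(v);
      chan = BIND_B;
    }

    switch (chan) {
      case ACT: XS[site] += 1; X0[site] -= 1; break;
      case DEACT: XS[site] -= 1; X0[site] += 1; break;
      case UNB_AR: AR[site] -= 1; Acyt += 1; break;
      case UNB_AX: AX[site] -= 1; Acyt += 1; break;
      case UNB_B: BB[site] -= 1; Bcyt += 1; break;
      case BIND_AR: AR[site] += 1; Acyt -= 1; break;
      case BIND_AX: AX[site] += 1; Acyt -= 1; break;
      case BIND_B: BB[site] += 1; Bcyt -= 1; break;
      case DIF_XS: case DIF_X0: {
        int lo = nbr_ptr[site], hi = nbr_ptr[site + 1];
        int j = nbr[lo + (int)(unif_rand() * (hi - lo))];
        if (chan == DIF_XS) { XS[site] -= 1; XS[j] += 1; }
        else { X0[site] -= 1; X0[j] += 1; }
        refresh_site(j);
        break;
      }
    }
    refresh_site(site);
    n_events += 1.0;
    if (record_events && (int)ev_t.size() < max_log) {
      ev_t.push_back(t); ev_site.push_back(site + 1); ev_chan.push_back(chan);
    }
    if (++rebuild_counter >= 4000000L) {  // limit fp drift in the trees
      Wt.rebuild(); CAt.rebuild(); CBt.rebuild();
      rebuild_counter = 0;
    }
  }
  record_snaps_until(t_max + 1.0);

  IntegerMatrix final_counts(n, 5);
  for (int i = 0; i < n; ++i) {
    final_counts(i, 0) = (int)XS[i]; final_counts(i, 1) = (int)X0[i];
    final_counts(i, 2) = (int)AR[i]; final_counts(i, 3) = (int)AX[i];
    final_counts(i, 4) = (int)BB[i];
  }
  List out = List::create(
    _["snapshots"] = snaps, _["reservoirs"] = reservoirs,
    _["final_counts"] = final_counts,
    _["A_cyt"] = Acyt, _["B_cyt"] = Bcyt,
    _["t_end"] = t, _["n_events"] = n_events, _["absorbed"] = absorbed);
  if (record_events)
    out["events"] = DataFrame::create(_["time"] = wrap(ev_t),
                                      _["site"] = wrap(ev_site),
                                      _["channel"] = wrap(ev_chan));
  return out;
}
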