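// Exact Gillespie engine for the HP1 / H3K9-methylation lattice model.
//
// State: per-site methylation and HP1 flags plus a dynamic contact graph
// with a valence cap. Contact formation between sites i and j occurs at
// k_c / L_ij^alpha where L_ij is the genomic distance possibly shortcut
// by at most ONE spatial contact. Key implementation facts:
//
//  * L_ij is an integer in [1, n-1], so contact propensities are table
//    lookups (ptab[d] = k_c / d^alpha).
//  * For canonically ordered pairs i<j and a contact (a,b) with a<b the
//    only shortcut orientation that can beat the genomic distance is
//    i -> a, b -> j: the reverse orientation costs
//    |i-b| + 1 + |a-j| >= (j-i) + (b-a+1) in every case. The distance
//    cache therefore only ever evaluates |i-a| + 1 + |b-j|.
//  * Site events (bind/unbind/methylate/demethylate/spread) leave L and
//    the contact-formation eligibility unchanged, so the total formation
//    propensity S is cached and refreshed only when a contact forms or
//    breaks (an O(n^2) pass).
//  * Removing contact c only invalidates pairs whose cached distance
//    equals the value through c; those are recomputed against the
//    remaining contacts.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <utility>
using namespace Rcpp;

namespace {

struct Params {
  double km, kd, kb, ku, ky, kn, kc, kw, kz, alpha;
  int nval;
  bool binding_only, spread_fiber, static_L;
};

Params read_params(const List& p) {
  Params P;
  P.km = as<double>(p["k_m"]);  P.kd = as<double>(p["k_d"]);
  P.kb = as<double>(p["k_b"]);  P.ku = as<double>(p["k_u"]);
  P.ky = as<double>(p["k_y"]);  P.kn = as<double>(p["k_n"]);
  P.kc = as<double>(p["k_c"]);  P.kw = as<double>(p["k_w"]);
  P.kz = as<double>(p["k_z"]);  P.alpha = as<double>(p["alpha"]);
  P.nval = as<int>(p["n_val"]);
  P.binding_only = as<std::string>(p["coupling_mode"]) == "binding_only";
  P.spread_fiber = p.containsElementNamed("spread_fiber") ?
    as<bool>(p["spread_fiber"]) : false;
  P.static_L = p.containsElementNamed("formation_distance") ?
    as<std::string>(p["formation_distance"]) == "genomic" : false;
  return P;
}

struct Totals {
  // category propensities in fixed enumeration order
  double a_meth, a_demeth, a_bind, a_ub_u, a_ub_y, a_spread, a_form,
         a_brk_w, a_brk_z, tot;
  int n_unmeth, n_demeth, n_unbound, n_ub_u, n_ub_y, n_spread,
      n_brk_w, n_brk_z;
};

struct Engine {
  int n;
  Params P;
  std::vector<char> meth, bound, bsite;
  std::vector<int> deg;
  std::vector<char> isCon;           // n*n symmetric adjacency
  std::vector<int> D;                // shortcut distances, upper triangle i<j
  std::vector<std::pair<int, int> > cons;  // canonical a<b
  std::vector<double> ptab;          // ptab[d] = kc / d^alpha
  double S;                          // cached total formation propensity

  Engine(int n_, const Params& P_, const IntegerVector& bsite0,
         const IntegerVector& meth0, const IntegerVector& bound0,
         const IntegerMatrix& con0)
      : n(n_), P(P_), meth(n_), bound(n_), bsite(n_), deg(n_, 0),
        isCon((size_t)n_ * n_, 0), D((size_t)n_ * n_, 0), ptab(n_ + 2, 0.0),
        S(0.0) {
    for (int i = 0; i < n; i++) {
      meth[i] = (char)meth0[i]; bound[i] = (char)bound0[i];
      bsite[i] = (char)bsite0[i];
    }
    for (int d = 1; d <= n + 1; d++)
      ptab[d] = P.kc / std::pow((double)d, P.alpha);
    for (int r = 0; r < con0.nrow(); r++) {
      int a = con0(r, 0), b = con0(r, 1);  // 0-based
      if (a > b) std::swap(a, b);
      if (a == b || a < 0 || b >= n) stop("invalid initial contact");
      cons.push_back(std::make_pair(a, b));
      isCon[(size_t)a * n + b] = isCon[(size_t)b * n + a] = 1;
      deg[a]++; deg[b]++;
      if (deg[a] > P.nval || deg[b] > P.nval)
        stop("initial contacts violate the valence cap");
    }
    rebuild_distances();
    recompute_S();
  }

  inline int& Dref(int i, int j) { return D[(size_t)i * n + j]; }  // i < j

  void rebuild_distances() {
    for (int i = 0; i < n - 1; i++)
      for (int j = i + 1; j < n; j++) Dref(i, j) = j - i;
    if (P.static_L) return;  // genomic kernel: contacts never shortcut
    for (size_t c = 0; c < cons.size(); c++)
      min_update(cons[c].first, cons[c].second, 0);
  }

  inline int Dat(int i, int j) const {          // any order, i != j
    return i < j ? D[(size_t)i * n + j] : D[(size_t)j * n + i];
  }

  inline bool eligible_with(int x) const {      // partner-side eligibility
    return deg[x] < P.nval;
  }

  // Contribution of all pairs (a,x), x != a and x != excl, to the total
  // contact-formation propensity (under the current deg/isCon/D).
  double row_contrib(int a, int excl) const {
    if (deg[a] >= P.nval) return 0.0;
    double s = 0.0;
    const char* rc = &isCon[(size_t)a * n];
    for (int x = 0; x < n; x++) {
      if (x == a || x == excl || rc[x] || deg[x] >= P.nval) continue;
      s += ptab[Dat(a, x)];
    }
    return s;
  }

  // Min-update pass after adding contact (a,b), a<b. Only pairs (i,j)
  // with i<j can improve through the orientation i->a, b->j, and only
  // when f = |i-a| + 1 + |b-j| < j - i; that bounds the scan to rows
  // i < b and a contiguous j range, and a fibre-adjacent contact
  // (b == a+1) can never strictly improve any pair. If dS is non-null,
  // accumulates the propensity change of updated pairs NOT incident to
  // a or b (their eligibility is unchanged by this event).
  void min_update(int a, int b, double* dS) {
    if (P.static_L || b - a < 2) return;
    for (int i = 0; i < b && i < n - 1; i++) {
      int ca = (i < a ? a - i : i - a) + 1;
      int jlo = (ca + b + i) / 2 + 1;
      int jhi = (ca < b - i) ? n - 1 : b - 1;
      if (jlo <= i) jlo = i + 1;
      if (jlo > jhi) continue;
      int* row = &D[(size_t)i * n];
      const char* rc = &isCon[(size_t)i * n];
      bool i_inc = (i == a);
      bool i_elig = deg[i] < P.nval;
      for (int j = jlo; j <= jhi; j++) {
        int f = ca + (j < b ? b - j : j - b);
        if (f < row[j]) {
          if (dS && !i_inc && j != b && i_elig && !rc[j] &&
              deg[j] < P.nval)
            *dS += ptab[f] - ptab[row[j]];
          row[j] = f;
        }
      }
    }
  }

  // Repair pass after removing contact (a,b), a<b (already removed from
  // cons): pairs whose cached distance equals the value through (a,b)
  // are recomputed against the remaining contacts. Same scan bounds as
  // min_update; same dS convention.
  void repair_after_removal(int a, int b, double* dS) {
    if (P.static_L || b - a < 2) return;
    for (int i = 0; i < b && i < n - 1; i++) {
      int ca = (i < a ? a - i : i - a) + 1;
      int jlo = (ca + b + i) / 2 + 1;
      int jhi = (ca < b - i) ? n - 1 : b - 1;
      if (jlo <= i) jlo = i + 1;
      if (jlo > jhi) continue;
      int* row = &D[(size_t)i * n];
      const char* rc = &isCon[(size_t)i * n];
      bool i_inc = (i == a);
      bool i_elig = deg[i] < P.nval;
      for (int j = jlo; j <= jhi; j++) {
        int f = ca + (j < b ? b - j : j - b);
        if (row[j] == f && f < j - i) {
          int best = j - i;
          for (size_t c = 0; c < cons.size(); c++) {
            int g = (i < cons[c].first ? cons[c].first - i
                                       : i - cons[c].first) + 1 +
                    (j < cons[c].second ? cons[c].second - j
                                        : j - cons[c].second);
            if (g < best) best = g;
          }
          if (best != f) {
            if (dS && !i_inc && j != b && i_elig && !rc[j] &&
                deg[j] < P.nval)
              *dS += ptab[best] - ptab[f];
            row[j] = best;
          }
        }
      }
    }
  }

  void recompute_S() {
    double s = 0.0;
    for (int i = 0; i < n - 1; i++) {
      if (deg[i] >= P.nval) continue;
      const char* rc = &isCon[(size_t)i * n];
      const int* rd = &D[(size_t)i * n];
      for (int j = i + 1; j < n; j++) {
        if (deg[j] >= P.nval || rc[j]) continue;
        s += ptab[rd[j]];
      }
    }
    S = s;
  }

  inline bool brk_slow(int a, int b) const {
    return !P.binding_only && meth[a] && bound[a] && meth[b] && bound[b];
  }

  Totals totals() const {
    Totals T;
    T.n_unmeth = T.n_demeth = T.n_unbound = T.n_ub_u = T.n_ub_y = 0;
    for (int i = 0; i < n; i++) {
      if (!meth[i]) T.n_unmeth++;
      if (meth[i] && !bound[i]) T.n_demeth++;
      if (!bound[i]) T.n_unbound++;
      if (bound[i] && deg[i] == 0) {
        bool use_u = P.binding_only ? (bool)meth[i] : (bool)bsite[i];
        if (use_u) T.n_ub_u++; else T.n_ub_y++;
      }
    }
    T.n_spread = 0; T.n_brk_w = 0; T.n_brk_z = 0;
    for (size_t c = 0; c < cons.size(); c++) {
      int a = cons[c].first, b = cons[c].second;
      if (meth[a] && bound[a] && !meth[b]) T.n_spread++;
      if (meth[b] && bound[b] && !meth[a]) T.n_spread++;
      if (brk_slow(a, b)) T.n_brk_w++; else T.n_brk_z++;
    }
    if (P.spread_fiber) {
      for (int i = 0; i < n; i++) {
        if (!(meth[i] && bound[i])) continue;
        if (i > 0 && !meth[i - 1]) T.n_spread++;
        if (i < n - 1 && !meth[i + 1]) T.n_spread++;
      }
    }
    T.a_meth   = P.km * T.n_unmeth;
    T.a_demeth = P.kd * T.n_demeth;
    T.a_bind   = P.kb * T.n_unbound;
    T.a_ub_u   = P.ku * T.n_ub_u;
    T.a_ub_y   = P.ky * T.n_ub_y;
    T.a_spread = P.kn * T.n_spread;
    T.a_form   = S;
    T.a_brk_w  = P.kw * T.n_brk_w;
    T.a_brk_z  = P.kz * T.n_brk_z;
    T.tot = T.a_meth + T.a_demeth + T.a_bind + T.a_ub_u + T.a_ub_y +
            T.a_spread + T.a_form + T.a_brk_w + T.a_brk_z;
    return T;
  }

  // find the k-th site satisfying a per-site predicate (enumeration order)
  template <class Pred>
  int kth_site(int k, Pred pred) const {
    for (int i = 0; i < n; i++)
      if (pred(i) && k-- == 0) return i;
    return -1;
  }

  // The total formation propensity S is maintained incrementally: the
  // contributions of the two endpoint rows are re-measured around the
  // event (pair (a,b) counted once, in row a), the distance pass adds the
  // deltas of non-incident pairs, and every 512 contact events S is
  // refreshed exactly to keep floating-point drift negligible.
  long contact_epoch = 0;

  void form_contact(int a, int b) {
    double before = row_contrib(a, -1) + row_contrib(b, a);
    cons.push_back(std::make_pair(a, b));
    isCon[(size_t)a * n + b] = isCon[(size_t)b * n + a] = 1;
    deg[a]++; deg[b]++;
    double dS = 0.0;
    min_update(a, b, &dS);
    S += row_contrib(a, -1) + row_contrib(b, a) - before + dS;
    if (++contact_epoch % 512 == 0) recompute_S();
  }

  void break_contact(size_t idx) {
    int a = cons[idx].first, b = cons[idx].second;
    double before = row_contrib(a, -1) + row_contrib(b, a);
    cons.erase(cons.begin() + idx);
    isCon[(size_t)a * n + b] = isCon[(size_t)b * n + a] = 0;
    deg[a]--; deg[b]--;
    double dS = 0.0;
    repair_after_removal(a, b, &dS);
    S += row_contrib(a, -1) + row_contrib(b, a) - before + dS;
    if (++contact_epoch % 512 == 0) recompute_S();
  }

  // choose + apply one event; returns the event class index 0..8
  int apply_event(const Totals& T, double u) {
    const double cats[9] = {T.a_meth, T.a_demeth, T.a_bind, T.a_ub_u,
                            T.a_ub_y, T.a_spread, T.a_form, T.a_brk_w,
                            T.a_brk_z};
    int cat = -1;
    double rem = u;
    for (int k = 0; k < 9; k++) {
      if (cats[k] <= 0) continue;
      if (rem < cats[k]) { cat = k; break; }
      rem -= cats[k];
    }
    if (cat < 0) {  // float drift past the end: take the last live category
      for (int k = 8; k >= 0; k--)
        if (cats[k] > 0) { cat = k; rem = cats[k] * 0.5; break; }
      if (cat < 0) stop("internal error: event chosen with zero propensity");
    }
    switch (cat) {
      case 0: {
        int k = std::min((int)(rem / P.km), T.n_unmeth - 1);
        meth[kth_site(k, [&](int i) { return !meth[i]; })] = 1;
        return 0;
      }
      case 1: {
        int k = std::min((int)(rem / P.kd), T.n_demeth - 1);
        meth[kth_site(k, [&](int i) { return meth[i] && !bound[i]; })] = 0;
        return 1;
      }
      case 2: {
        int k = std::min((int)(rem / P.kb), T.n_unbound - 1);
        bound[kth_site(k, [&](int i) { return !bound[i]; })] = 1;
        return 2;
      }
      case 3: {
        int k = std::min((int)(rem / P.ku), T.n_ub_u - 1);
        bound[kth_site(k, [&](int i) {
          return bound[i] && deg[i] == 0 &&
                 (P.binding_only ? (bool)meth[i] : (bool)bsite[i]);
        })] = 0;
        return 3;
      }
      case 4: {
        int k = std::min((int)(rem / P.ky), T.n_ub_y - 1);
        bound[kth_site(k, [&](int i) {
          return bound[i] && deg[i] == 0 &&
                 !(P.binding_only ? (bool)meth[i] : (bool)bsite[i]);
        })] = 0;
        return 4;
      }
      case 5: {
        int k = std::min((int)(rem / P.kn), T.n_spread - 1);
        for (size_t c = 0; c < cons.size(); c++) {
          int a = cons[c].first, b = cons[c].second;
          if (meth[a] && bound[a] && !meth[b] && k-- == 0) {
            meth[b] = 1; return 5;
          }
          if (meth[b] && bound[b] && !meth[a] && k-- == 0) {
            meth[a] = 1; return 5;
          }
        }
        if (P.spread_fiber) {
          for (int i = 0; i < n; i++) {
            if (!(meth[i] && bound[i])) continue;
            if (i > 0 && !meth[i - 1] && k-- == 0) {
              meth[i - 1] = 1; return 5;
            }
            if (i < n - 1 && !meth[i + 1] && k-- == 0) {
              meth[i + 1] = 1; return 5;
            }
          }
        }
        stop("internal error: spread target not found");
      }
      case 6: {
        int fa = -1, fb = -1;
        bool done = false;
        double acc = 0.0;
        for (int i = 0; i < n - 1 && !done; i++) {
          if (deg[i] >= P.nval) continue;
          const char* rc = &isCon[(size_t)i * n];
          const int* rd = &D[(size_t)i * n];
          for (int j = i + 1; j < n; j++) {
            if (deg[j] >= P.nval || rc[j]) continue;
            acc += ptab[rd[j]];
            fa = i; fb = j;             // remember last eligible pair
            if (acc > rem) { done = true; break; }
          }
        }
        if (fa < 0) stop("internal error: no eligible contact pair");
        form_contact(fa, fb); return 6;
      }
      case 7: {
        int k = std::min((int)(rem / P.kw), T.n_brk_w - 1);
        for (size_t c = 0; c < cons.size(); c++)
          if (brk_slow(cons[c].first, cons[c].second) && k-- == 0) {
            break_contact(c); return 7;
          }
        stop("internal error: slow-break target not found");
      }
      default: {
        int k = std::min((int)(rem / P.kz), T.n_brk_z - 1);
        for (size_t c = 0; c < cons.size(); c++)
          if (!brk_slow(cons[c].first, cons[c].second) && k-- == 0) {
            break_contact(c); return 8;
          }
        stop("internal error: fast-break target not found");
      }
    }
  }

  void check_invariants() const {
    std::vector<int> deg2(n, 0);
    for (size_t c = 0; c < cons.size(); c++) {
      int a = cons[c].first, b = cons[c].second;
      if (a >= b || a < 0 || b >= n) stop("consistency: bad contact pair");
      if (!isCon[(size_t)a * n + b]) stop("consistency: adjacency desync");
      deg2[a]++; deg2[b]++;
    }
    for (int i = 0; i < n; i++) {
      if (deg2[i] != deg[i]) stop("consistency: degree desync");
      if (deg[i] > P.nval) stop("consistency: valence cap violated");
    }
    Engine fresh(*this);
    fresh.rebuild_distances();
    for (int i = 0; i < n - 1; i++)
      for (int j = i + 1; j < n; j++)
        if (fresh.D[(size_t)i * n + j] != D[(size_t)i * n + j])
          stop("consistency: cached distance differs from scratch rebuild");
    fresh.recompute_S();
    if (std::fabs(fresh.S - S) > 1e-9 * (1.0 + std::fabs(S)))
      stop("consistency: cached formation propensity differs from scratch");
  }
};

}  // namespace

// Run one replicate. All site vectors/matrices use 0-based indices at this
// boundary; the R wrapper converts. Snapshots are taken at
// 0, dt, 2*dt, ..., <= duration; an absorbing state (zero total propensity)
// is held to the horizon.
// [[Rcpp::export]]
List gillespie_run_cpp(int n, IntegerVector binding_sites,
                       IntegerVector meth0, IntegerVector bound0,
                       IntegerMatrix contacts0, List params,
                       double duration, double sample_interval,
                       bool check_consistency = false) {
  if (n < 0) stop("negative lattice size");
  Params P = read_params(params);
  Engine E(n, P, binding_sites, meth0, bound0, contacts0);

  int n_samp = (int)std::floor(duration / sample_interval + 1e-9) + 1;
  NumericVector times(n_samp);
  for (int s = 0; s < n_samp; s++) times[s] = s * sample_interval;
  IntegerMatrix msnap(n_samp, n), bsnap(n_samp, n);
  List csnap(n_samp);

  double t = 0.0;
  int s = 0;
  long nsteps = 0;
  IntegerVector evcount(9);

  while (s < n_samp) {
    Totals T = E.totals();
    double tnext = (T.tot > 0) ? t + R::exp_rand() / T.tot : R_PosInf;
    while (s < n_samp && times[s] <= tnext) {
      for (int i = 0; i < n; i++) {
        msnap(s, i) = E.meth[i]; bsnap(s, i) = E.bound[i];
      }
      IntegerMatrix cm(E.cons.size(), 2);
      for (size_t c = 0; c < E.cons.size(); c++) {
        cm(c, 0) = E.cons[c].first + 1; cm(c, 1) = E.cons[c].second + 1;
      }
      csnap[s] = cm;
      s++;
    }
    if (s >= n_samp || !R_finite(tnext)) break;
    int kind = E.apply_event(T, unif_rand() * T.tot);
    evcount[kind]++;
    if (check_consistency) E.check_invariants();
    t = tnext;
    if (++nsteps % 4096 == 0) checkUserInterrupt();
  }

  evcount.attr("names") = CharacterVector::create(
      "methylate", "demethylate", "bind", "unbind_site", "unbind_nonsite",
      "spread", "form_contact", "break_contact_slow", "break_contact_fast");
  return List::create(_["times"] = times, _["methylated"] = msnap,
                      _["bound"] = bsnap, _["contacts"] = csnap,
                      _["n_steps"] = (double)nsteps,
                      _["event_counts"] = evcount);
}

// Per-category propensity totals recomputed from scratch on an arbitrary
// state (0-based contacts). Used to cross-check the R-level enumeration
// against the engine's bookkeeping.
// [[Rcpp::export]]
NumericVector propensity_breakdown_cpp(int n, IntegerVector binding_sites,
                                       IntegerVector meth0,
                                       IntegerVector bound0,
                                       IntegerMatrix contacts0, List params) {
  Params P = read_params(params);
  Engine E(n, P, binding_sites, meth0, bound0, contacts0);
  Totals T = E.totals();
  NumericVector out = NumericVector::create(
      _["methylate"] = T.a_meth, _["demethylate"] = T.a_demeth,
      _["bind"] = T.a_bind, _["unbind_site"] = T.a_ub_u,
      _["unbind_nonsite"] = T.a_ub_y, _["spread"] = T.a_spread,
      _["form_contact"] = T.a_form, _["break_contact_slow"] = T.a_brk_w,
      _["break_contact_fast"] = T.a_brk_z, _["total"] = T.tot);
  return out;
}

// Full matrix of single-shortcut effective distances (0-based contacts in,
// symmetric integer matrix out, zero diagonal).
// [[Rcpp::export]]
IntegerMatrix shortcut_distance_matrix_cpp(int n, IntegerMatrix contacts0) {
  Params P; P.km = P.kd = P.kb = P.ku = P.ky = P.kn = P.kw = P.kz = 0;
  P.kc = 1.0; P.alpha = 1.0; P.nval = n > 0 ? n : 1;
  P.binding_only = false; P.spread_fiber = false; P.static_L = false;
  IntegerVector zero(n);
  Engine E(n, P, zero, zero, zero, contacts0);
  IntegerMatrix out(n, n);
  for (int i = 0; i < n - 1; i++)
    for (int j = i + 1; j < n; j++)
      out(i, j) = out(j, i) = E.D[(size_t)i * n + j];
  return out;
}
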