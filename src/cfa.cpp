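// Core agent dynamics for cellular frustration algorithms.
//
// Conventions shared with the R side:
//  * presenters and detectors are 1-based indices; partner == 0 means alone
//  * detector j's token columns: connection c (1-based) owns columns
//    2c-1 (frequent) and 2c (rare); ranks[j, t] is the rank (1 = top) of
//    token t in detector j's interaction list
//  * pres_pref[i, j] is presenter i's rank (1 or 2) for detector j's digit;
//    det_pref[j, i] is detector j's rank of the token presenter i displays
//    under the current sample, 0 if i is not in j's connectivity
// All randomness comes from R's RNG so set.seed() controls everything.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline int ri(int k) {
  // uniform integer in 0..k-1
  int x = (int)(unif_rand() * k);
  return x >= k ? k - 1 : x;
}

static inline void form_pair(int i, int j,
                             IntegerVector& partner_p, IntegerVector& partner_d,
                             IntegerVector& tau_p, IntegerVector& tau_d) {
  partner_p[i - 1] = j;
  partner_d[j - 1] = i;
  tau_p[i - 1] = 0;
  tau_d[j - 1] = 0;
}

// The four branches of the pairing decision rule. Strict preferences only:
// equal ranks never break an existing pair.
static void decide_core(int i, int j,
                        const IntegerMatrix& pres_pref, const IntegerMatrix& det_pref,
                        IntegerVector& partner_p, IntegerVector& partner_d,
                        IntegerVector& tau_p, IntegerVector& tau_d) {
  int pi = partner_p[i - 1]; // detector currently paired with presenter i
  int pj = partner_d[j - 1]; // presenter currently paired with detector j
  if (pi == j) return;       // already together
  if (pi == 0 && pj == 0) {
    form_pair(i, j, partner_p, partner_d, tau_p, tau_d);
  } else if (pi != 0 && pj == 0) {
    if (pres_pref(i - 1, j - 1) < pres_pref(i - 1, pi - 1)) {
      partner_d[pi - 1] = 0; tau_d[pi - 1] = 0;
      form_pair(i, j, partner_p, partner_d, tau_p, tau_d);
    }
  } else if (pi == 0 && pj != 0) {
    if (det_pref(j - 1, i - 1) < det_pref(j - 1, pj - 1)) {
      partner_p[pj - 1] = 0; tau_p[pj - 1] = 0;
      form_pair(i, j, partner_p, partner_d, tau_p, tau_d);
    }
  } else {
    if (pres_pref(i - 1, j - 1) < pres_pref(i - 1, pi - 1) &&
        det_pref(j - 1, i - 1) < det_pref(j - 1, pj - 1)) {
      partner_d[pi - 1] = 0; tau_d[pi - 1] = 0;
      partner_p[pj - 1] = 0; tau_p[pj - 1] = 0;
      form_pair(i, j, partner_p, partner_d, tau_p, tau_d);
    }
  }
}

// [[Rcpp::export]]
List cpp_decide(int i, int j,
                IntegerMatrix pres_pref, IntegerMatrix det_pref,
                IntegerVector partner_p, IntegerVector partner_d,
                IntegerVector tau_p, IntegerVector tau_d) {
  if (det_pref(j - 1, i - 1) == 0)
    stop("presenter %d is not in detector %d's connectivity", i, j);
  IntegerVector pp = clone(partner_p), pd = clone(partner_d);
  IntegerVector tp = clone(tau_p), td = clone(tau_d);
  decide_core(i, j, pres_pref, det_pref, pp, pd, tp, td);
  return List::create(_["partner_p"] = pp, _["partner_d"] = pd,
                      _["tau_p"] = tp, _["tau_d"] = td);
}

// ---------------------------------------------------------------------------
// Shared engine machinery

struct Engine {
  int N;   // presenters
  int Nd;  // detectors
  int C;   // connectivity
  IntegerMatrix conn;       // Nd x C
  IntegerMatrix invconn;    // Nd x N: 1-based connection slot, 0 if absent
  IntegerMatrix ranks;      // Nd x 2C (working copy)
  LogicalMatrix sideL;      // Nd x C, TRUE = left tail
  NumericMatrix v;          // Nd x C tail probabilities
  IntegerMatrix pres_pref;  // N x Nd
  IntegerMatrix det_pref;   // Nd x N
  IntegerMatrix rare;       // Nd x C rare flag under current sample
  std::vector<std::vector<int>> dop; // detectors covering presenter i (1-based ids)
  IntegerVector partner_p, partner_d, tau_p, tau_d;
  std::vector<int> order;   // sweep buffer

  Engine(IntegerMatrix conn_, IntegerMatrix ranks_,
         IntegerVector subtype, IntegerVector digit,
         LogicalMatrix sideL_, NumericMatrix v_)
      : conn(conn_), ranks(clone(ranks_)), sideL(sideL_), v(v_) {
    Nd = conn.nrow();
    C = conn.ncol();
    N = subtype.size();
    invconn = IntegerMatrix(Nd, N);
    dop.assign(N, {});
    for (int j = 0; j < Nd; ++j)
      for (int c = 0; c < C; ++c) {
        int p = conn(j, c) - 1;
        invconn(j, p) = c + 1;
        dop[p].push_back(j + 1);
      }
    pres_pref = IntegerMatrix(N, Nd);
    for (int i = 0; i < N; ++i)
      for (int j = 0; j < Nd; ++j)
        pres_pref(i, j) = (digit[j] == subtype[i]) ? 1 : 2;
    det_pref = IntegerMatrix(Nd, N);
    rare = IntegerMatrix(Nd, C);
    partner_p = IntegerVector(N);
    partner_d = IntegerVector(Nd);
    tau_p = IntegerVector(N);
    tau_d = IntegerVector(Nd);
    order.resize(N + Nd);
  }

  void set_state(IntegerVector pp, IntegerVector pd,
                 IntegerVector tp, IntegerVector td) {
    partner_p = clone(pp); partner_d = clone(pd);
    tau_p = clone(tp); tau_d = clone(td);
  }

  // recompute rare flags and det_pref rows for a displayed sample (F values)
  void display_sample(const NumericVector& Fv) {
    for (int j = 0; j < Nd; ++j) {
      for (int c = 0; c < C; ++c) {
        int p = conn(j, c) - 1;
        bool r = sideL(j, c) ? (Fv[p] < v(j, c)) : (Fv[p] > 1.0 - v(j, c));
        rare(j, c) = r ? 1 : 0;
        det_pref(j, p) = ranks(j, 2 * c + (r ? 1 : 0));
      }
    }
  }

  void refresh_det_pref_row(int j) {
    for (int c = 0; c < C; ++c)
      det_pref(j, conn(j, c) - 1) = ranks(j, 2 * c + rare(j, c));
  }

  void sweep() {
    int total = N + Nd;
    for (int k = 0; k < total; ++k) order[k] = k;
    for (int k = total - 1; k > 0; --k) std::swap(order[k], order[ri(k + 1)]);
    for (int k = 0; k < total; ++k) {
      int a = order[k];
      if (a < N) {
        const std::vector<int>& cand = dop[a];
        if (cand.empty()) continue;
        int j = cand[ri((int)cand.size())];
        decide_core(a + 1, j, pres_pref, det_pref, partner_p, partner_d, tau_p, tau_d);
      } else {
        int j = a - N; // 0-based detector
        int i = conn(j, ri(C));
        decide_core(i, j + 1, pres_pref, det_pref, partner_p, partner_d, tau_p, tau_d);
      }
    }
  }

  void age_pairs() {
    for (int j = 0; j < Nd; ++j)
      if (partner_d[j] != 0) {
        ++tau_d[j];
        ++tau_p[partner_d[j] - 1];
      }
  }

  void unpair_detector(int j) { // 0-based
    int q = partner_d[j];
    if (q != 0) { partner_p[q - 1] = 0; tau_p[q - 1] = 0; }
    partner_d[j] = 0;
    tau_d[j] = 0;
  }
};

// ---------------------------------------------------------------------------
// Free-running dynamics with survival counting (diagnostics / toy populations)

// [[Rcpp::export]]
List cpp_run_dynamics(IntegerMatrix conn, IntegerMatrix ranks,
                      IntegerVector subtype, IntegerVector digit,
                      LogicalMatrix sideL, NumericMatrix v,
                      NumericVector Fv, int n_iter,
                      IntegerVector partner_p, IntegerVector partner_d,
                      IntegerVector tau_p, IntegerVector tau_d,
                      int tau_cap) {
  Engine e(conn, ranks, subtype, digit, sideL, v);
  e.set_state(partner_p, partner_d, tau_p, tau_d);
  e.display_sample(Fv);
  IntegerMatrix counts_p(e.N, tau_cap + 1), counts_d(e.Nd, tau_cap + 1);
  int max_tau = 0;
  for (int t = 0; t < n_iter; ++t) {
    e.sweep();
    for (int j = 0; j < e.Nd; ++j) {
      if (e.partner_d[j] != 0) {
        int age = e.tau_d[j];
        if (age > max_tau) max_tau = age;
        int bin = age > tau_cap ? tau_cap : age;
        counts_d(j, bin) += 1;
        counts_p(e.partner_d[j] - 1, bin) += 1;
      }
    }
    e.age_pairs();
    if ((t & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["partner_p"] = e.partner_p, _["partner_d"] = e.partner_d,
                      _["tau_p"] = e.tau_p, _["tau_d"] = e.tau_d,
                      _["counts_p"] = counts_p, _["counts_d"] = counts_d,
                      _["max_tau"] = max_tau);
}

// ---------------------------------------------------------------------------
// Repertoire education

static void educate_is_row(Engine& e, int j, const std::vector<int>& educ_cols) {
  int n_e = (int)educ_cols.size();
  // random permutation of ranks 1..n_e over the educable tokens
  std::vector<int> perm(n_e);
  for (int k = 0; k < n_e; ++k) perm[k] = k + 1;
  for (int k = n_e - 1; k > 0; --k) std::swap(perm[k], perm[ri(k + 1)]);
  for (int k = 0; k < n_e; ++k) e.ranks(j, educ_cols[k]) = perm[k];
}

static void educate_ais_row(Engine& e, int j, int n_educ_j, const LogicalMatrix& frozen) {
  int q = e.partner_d[j]; // presenter (1-based); caller guarantees paired
  int c = e.invconn(j, q - 1) - 1;
  int t = 2 * c + e.rare(j, c);
  if (frozen(j, t)) return;        // frozen tokens never move
  int r0 = e.ranks(j, t);
  if (r0 >= n_educ_j) return;      // already at the last educable rank
  int p = r0 + 1 + ri(n_educ_j - r0); // uniform in r0+1 .. n_educ_j
  int twoC = 2 * e.C;
  for (int t2 = 0; t2 < twoC; ++t2) {
    if (e.ranks(j, t2) == p) {
      e.ranks(j, t2) = r0;
      e.ranks(j, t) = p;
      break;
    }
  }
}

// [[Rcpp::export]]
List cpp_train(IntegerMatrix conn, IntegerMatrix ranks0, LogicalMatrix frozen,
               IntegerVector n_educ, IntegerVector subtype, IntegerVector digit,
               LogicalMatrix sideL, NumericMatrix v, NumericMatrix Fmat,
               int W_tau, int T_S, int t_max, int tau_target, int strategy) {
  Engine e(conn, ranks0, subtype, digit, sideL, v);
  int n_samples = Fmat.nrow();
  std::vector<std::vector<int>> educ_cols(e.Nd);
  for (int j = 0; j < e.Nd; ++j)
    for (int t = 0; t < 2 * e.C; ++t)
      if (!frozen(j, t)) educ_cols[j].push_back(t);

  int s = ri(n_samples);
  NumericVector Fv_cur = Fmat(s, _);
  e.display_sample(Fv_cur);
  int tau_n = W_tau;
  std::vector<int> tau_n_trace, n_subs_trace;
  double total_iter = 0;
  double iter_to_target = NA_REAL;
  int windows = 0;

  for (int t = 1; t <= t_max; ++t) {
    int N_subs = 0, tau_nW = 0;
    for (int tw = 1; tw <= W_tau; ++tw) {
      if (tw % T_S == 0) {
        s = ri(n_samples);
        Fv_cur = Fmat(s, _);
        e.display_sample(Fv_cur);
      }
      e.sweep();
      for (int j = 0; j < e.Nd; ++j) {
        if (e.partner_d[j] != 0 && e.tau_d[j] >= tau_n) {
          if (strategy == 0) educate_is_row(e, j, educ_cols[j]);
          else educate_ais_row(e, j, n_educ[j], frozen);
          e.unpair_detector(j);
          e.refresh_det_pref_row(j);
          ++N_subs;
        }
      }
      for (int j = 0; j < e.Nd; ++j)
        if (e.tau_d[j] > tau_nW) tau_nW = e.tau_d[j];
      e.age_pairs();
      total_iter += 1;
    }
    Rcpp::checkUserInterrupt();
    if (N_subs == 0 && tau_nW < tau_n) tau_n = tau_nW;
    tau_n_trace.push_back(tau_n);
    n_subs_trace.push_back(N_subs);
    windows = t;
    if (tau_target >= 0 && tau_n <= tau_target) {
      iter_to_target = total_iter;
      break;
    }
  }
  return List::create(_["ranks"] = e.ranks,
                      _["tau_n"] = wrap(tau_n_trace),
                      _["n_subs"] = wrap(n_subs_trace),
                      _["windows"] = windows,
                      _["total_iterations"] = total_iter,
                      _["iterations_to_target"] = iter_to_target);
}

// ---------------------------------------------------------------------------
// Monitoring with anergy (calibration and testing share this loop)

// [[Rcpp::export]]
List cpp_monitor(IntegerMatrix conn, List rep_ranks,
                 IntegerVector subtype, IntegerVector digit,
                 LogicalMatrix sideL, NumericMatrix v,
                 NumericVector Fv, int W_d, int tau_A) {
  int Npop = rep_ranks.size();
  IntegerMatrix first = rep_ranks[0];
  Engine e(conn, first, subtype, digit, sideL, v);
  // draw the initial repertoire member for every detector slot
  std::vector<IntegerMatrix> members(Npop);
  for (int m = 0; m < Npop; ++m) members[m] = as<IntegerMatrix>(rep_ranks[m]);
  int twoC = 2 * e.C;
  for (int j = 0; j < e.Nd; ++j) {
    int m = ri(Npop);
    for (int t = 0; t < twoC; ++t) e.ranks(j, t) = members[m](j, t);
  }
  e.display_sample(Fv);
  IntegerMatrix c_p(e.N, tau_A + 1), c_d(e.Nd, tau_A + 1);
  for (int t = 0; t < W_d; ++t) {
    e.sweep();
    for (int j = 0; j < e.Nd; ++j) {
      if (e.partner_d[j] != 0) {
        int age = e.tau_d[j]; // < tau_A by construction
        c_d(j, age) += 1;
        c_p(e.partner_d[j] - 1, age) += 1;
      }
    }
    e.age_pairs();
    for (int j = 0; j < e.Nd; ++j) {
      if (e.partner_d[j] != 0 && e.tau_d[j] >= tau_A) {
        c_d(j, tau_A) += 1;
        c_p(e.partner_d[j] - 1, tau_A) += 1;
        e.unpair_detector(j);
        int m = ri(Npop);
        for (int tt = 0; tt < twoC; ++tt) e.ranks(j, tt) = members[m](j, tt);
        e.refresh_det_pref_row(j);
      }
    }
    if ((t & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["c_p"] = c_p, _["c_d"] = c_d);
}

// ---------------------------------------------------------------------------
// Explicit single-list education process (Monte-Carlo oracle for the
// absorbing-chain theory). Items are of two types; the list is absorbed when
// the top n positions all hold correct-type items. Entering education costs
// one step, matching the chains' education states.

// [[Rcpp::export]]
NumericVector cpp_simulate_education(int strategy, int n, int N, int reps) {
  NumericVector out(reps);
  std::vector<int> typ(N);
  for (int r = 0; r < reps; ++r) {
    // start in W_0: top n incorrect; below, the remaining N/2 correct and
    // N/2 - n incorrect items in random order
    for (int k = 0; k < n; ++k) typ[k] = 0;
    int pos = n;
    for (int k = 0; k < N / 2; ++k) typ[pos++] = 1;
    for (int k = 0; k < N / 2 - n; ++k) typ[pos++] = 0;
    for (int k = N - 1; k > n; --k) {
      int o = n + ri(k - n + 1);
      std::swap(typ[k], typ[o]);
    }
    int m = 0; // correct items in the top n
    double steps = 0;
    while (m < n) {
      steps += 1; // selection step
      int sel = ri(N);
      if (sel < n && typ[sel] == 0) {
        steps += 1; // education step
        if (strategy == 0) {
          // negative selection: a fresh list drawn from a large pool,
          // each position correct-type with probability 1/2
          for (int k = 0; k < N; ++k) typ[k] = (unif_rand() < 0.5) ? 1 : 0;
          m = 0;
          for (int k = 0; k < n; ++k) m += typ[k];
        } else {
          // targeted swap with a uniform item from the N - n positions below
          int b = n + ri(N - n);
          std::swap(typ[sel], typ[b]);
          m += typ[sel];
        }
      }
    }
    out[r] = steps;
    if ((r & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
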