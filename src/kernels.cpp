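#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// States arrive from R as 1..q and are used 0-based internally.
// Couplings arrive as the R array J[q, q, L(L-1)/2] (column-major), slab k
// holding J_ij for the unordered pair i < j with
// k0 = i0*L - i0*(i0+1)/2 + j0 - i0 - 1 (0-based i0 < j0).

static inline int pair_k0(int i0, int j0, int L) {
  return i0 * L - i0 * (i0 + 1) / 2 + j0 - i0 - 1;
}

// J_ij(a, b) with a the state at site i0, b at site j0, any order of sites.
static inline double Jget(const double* J, int q, int L, int i0, int j0,
                          int a, int b) {
  if (i0 < j0) return J[(size_t)pair_k0(i0, j0, L) * q * q + b * q + a];
  return J[(size_t)pair_k0(j0, i0, L) * q * q + a * q + b];
}

// [[Rcpp::export]]
NumericVector cpp_hamiltonian(NumericVector J, NumericMatrix h,
                              IntegerMatrix msa) {
  const int M = msa.nrow(), L = msa.ncol(), q = h.ncol();
  const double* Jp = J.begin();
  NumericVector out(M);
  std::vector<int> s(L);
  for (int m = 0; m < M; ++m) {
    for (int i = 0; i < L; ++i) s[i] = msa(m, i) - 1;
    double H = 0.0;
    for (int i = 0; i < L; ++i) {
      H -= h(i, s[i]);
      for (int j = i + 1; j < L; ++j)
        H -= Jp[(size_t)pair_k0(i, j, L) * q * q + s[j] * q + s[i]];
    }
    out[m] = H;
  }
  return out;
}

// L x q matrix of energy shifts H(mutant) - H(wt); zero at the wt state.
// [[Rcpp::export]]
NumericMatrix cpp_mutational_effects(NumericVector J, NumericMatrix h,
                                     IntegerVector wt) {
  const int L = h.nrow(), q = h.ncol();
  const double* Jp = J.begin();
  NumericMatrix out(L, q);
  std::vector<int> s(L);
  for (int i = 0; i < L; ++i) s[i] = wt[i] - 1;
  for (int i = 0; i < L; ++i) {
    for (int a = 0; a < q; ++a) {
      if (a == s[i]) continue;
      double d = -(h(i, a) - h(i, s[i]));
      for (int j = 0; j < L; ++j) {
        if (j == i) continue;
        d -= Jget(Jp, q, L, i, j, a, s[j]) - Jget(Jp, q, L, i, j, s[i], s[j]);
      }
      out(i, a) = d;
    }
  }
  return out;
}

// Heat-bath update of site i0 given the rest of the sequence (0-based states).
static void gibbs_update(const double* J, const NumericMatrix& h,
                         std::vector<int>& s, int i0, int L, int q,
                         std::vector<double>& work) {
  double mx = -1e300;
  for (int a = 0; a < q; ++a) {
    double e = h(i0, a);
    for (int j = 0; j < L; ++j)
      if (j != i0) e += Jget(J, q, L, i0, j, a, s[j]);
    work[a] = e;
    if (e > mx) mx = e;
  }
  double tot = 0.0;
  for (int a = 0; a < q; ++a) { work[a] = std::exp(work[a] - mx); tot += work[a]; }
  double u = unif_rand() * tot, acc = 0.0;
  int pick = q - 1;
  for (int a = 0; a < q; ++a) { acc += work[a]; if (u <= acc) { pick = a; break; } }
  s[i0] = pick;
}

// M near-equilibrium sequences from a single Gibbs chain: burn_sweeps full
// sweeps, then one sample every thin_sweeps sweeps. Returns states 1..q.
// [[Rcpp::export]]
IntegerMatrix cpp_sample_iid(NumericVector J, NumericMatrix h, int M,
                             int burn_sweeps, int thin_sweeps) {
  const int L = h.nrow(), q = h.ncol();
  const double* Jp = J.begin();
  std::vector<int> s(L);
  std::vector<double> work(q);
  for (int i = 0; i < L; ++i) s[i] = (int)(unif_rand() * q) % q;
  for (int t = 0; t < burn_sweeps; ++t)
    for (int i = 0; i < L; ++i) gibbs_update(Jp, h, s, i, L, q, work);
  IntegerMatrix out(M, L);
  for (int m = 0; m < M; ++m) {
    for (int t = 0; t < thin_sweeps; ++t)
      for (int i = 0; i < L; ++i) gibbs_update(Jp, h, s, i, L, q, work);
    for (int i = 0; i < L; ++i) out(m, i) = s[i] + 1;
  }
  return out;
}

// Finite-time MCMC along one branch: Poisson(muLdt) mutation events, each
// redrawing a uniformly chosen site from its heat-bath conditional.
// [[Rcpp::export]]
IntegerVector cpp_evolve_branch(NumericVector J, NumericMatrix h,
                                IntegerVector parent, double muLdt) {
  const int L = h.nrow(), q = h.ncol();
  const double* Jp = J.begin();
  std::vector<int> s(L);
  std::vector<double> work(q);
  for (int i = 0; i < L; ++i) s[i] = parent[i] - 1;
  int nmut = (muLdt > 0) ? (int)R::rpois(muLdt) : 0;
  for (int t = 0; t < nmut; ++t) {
    int i = (int)(unif_rand() * L) % L;
    gibbs_update(Jp, h, s, i, L, q, work);
  }
  IntegerVector out(L);
  for (int i = 0; i < L; ++i) out[i] = s[i] + 1;
  return out;
}

// ---------------------------------------------------------------------------
// Felsenstein pruning, independent-site model.
// edges: E x 2 (parent, child), 1-based node ids, postorder (children first);
// tips are nodes 1..n_tip carrying tip_states; root node id passed in.
// Propagator: P(B|A) = e^{-mu dt} delta_AB + (1 - e^{-mu dt}) omega_B.
// Partial vectors are rescaled per node; log scale accumulates.

static double site_loglik_core(const IntegerMatrix& edges,
                               const NumericVector& elen, int n_node, int root,
                               const IntegerVector& tip_states, int q,
                               const double* w, double mu) {
  const int E = edges.nrow();
  const int n_tip = tip_states.size();
  std::vector<double> part((size_t)q * n_node, 1.0);
  std::vector<double> lsc(n_node, 0.0);
  for (int t = 0; t < n_tip; ++t) {
    double* p = &part[(size_t)q * t];
    for (int a = 0; a < q; ++a) p[a] = 0.0;
    p[tip_states[t] - 1] = 1.0;
  }
  for (int e = 0; e < E; ++e) {
    int pa = edges(e, 0) - 1, ch = edges(e, 1) - 1;
    double ee = std::exp(-mu * elen[e]);
    double* pc = &part[(size_t)q * ch];
    double* pp = &part[(size_t)q * pa];
    double S = 0.0;
    for (int b = 0; b < q; ++b) S += w[b] * pc[b];
    double mx = 0.0;
    for (int a = 0; a < q; ++a) {
      pp[a] *= ee * pc[a] + (1.0 - ee) * S;
      if (pp[a] > mx) mx = pp[a];
    }
    lsc[pa] += lsc[ch];
    if (mx <= 0.0) return R_NegInf;
    for (int a = 0; a < q; ++a) pp[a] /= mx;
    lsc[pa] += std::log(mx);
  }
  double* pr = &part[(size_t)q * (root - 1)];
  double tot = 0.0;
  for (int a = 0; a < q; ++a) tot += w[a] * pr[a];
  if (tot <= 0.0) return R_NegInf;
  return std::log(tot) + lsc[root - 1];
}

// [[Rcpp::export]]
double cpp_site_loglik(IntegerMatrix edges, NumericVector elen, int n_node,
                       int root, IntegerVector tip_states, NumericVector omega,
                       double mu) {
  return site_loglik_core(edges, elen, n_node, root, tip_states,
                          omega.size(), omega.begin(), mu);
}

// Stochastic hill climb over the q-simplex (global/local additive Gaussian
// moves, shrinking magnitude, strict-increase acceptance, best kept).
// [[Rcpp::export]]
List cpp_site_optimize(IntegerMatrix edges, NumericVector elen, int n_node,
                       int root, IntegerVector tip_states, NumericVector omega0,
                       double mu, int n_iter, double mag0, double mag1,
                       double p_global, double floor_eps) {
  const int q = omega0.size();
  std::vector<double> cur(omega0.begin(), omega0.end());
  std::vector<double> prop(q);
  double ll = site_loglik_core(edges, elen, n_node, root, tip_states, q,
                               cur.data(), mu);
  NumericVector trace(n_iter);
  int n_acc = 0;
  double decay = (n_iter > 1) ? std::pow(mag1 / mag0, 1.0 / (n_iter - 1)) : 1.0;
  double mag = mag0;
  for (int t = 0; t < n_iter; ++t, mag *= decay) {
    prop = cur;
    if (unif_rand() < p_global) {
      for (int a = 0; a < q; ++a) prop[a] += mag * norm_rand();
    } else {
      int a = (int)(unif_rand() * q) % q;
      prop[a] += mag * norm_rand();
    }
    double tot = 0.0;
    for (int a = 0; a < q; ++a) {
      if (prop[a] < floor_eps) prop[a] = floor_eps;
      tot += prop[a];
    }
    for (int a = 0; a < q; ++a) prop[a] /= tot;
    double llp = site_loglik_core(edges, elen, n_node, root, tip_states, q,
                                  prop.data(), mu);
    if (llp > ll) { cur = prop; ll = llp; ++n_acc; }
    trace[t] = ll;
  }
  return List::create(_["omega"] = NumericVector(cur.begin(), cur.end()),
                      _["loglik"] = ll, _["trace"] = trace,
                      _["n_accepted"] = n_acc);
}

// ---------------------------------------------------------------------------
// Independent-pair pruning. Pair states are encoded s = (a-1)*q + b for
// (a, b) = (state at i, state at j), i.e. 1..q^2 (row-major in a).
// Propagator (e = e^{-mu dt}):
//   P(C,D|A,B) = e^2 d_AC d_BD
//              + e(1-e) [ w(D|A) d_AC + w(C|B) d_BD ]
//              + (1-e)^2 w_ij(C,D)
// The message to the parent contracts in O(q^2) via the partial sums
//   u(A) = sum_D w(A,D)/r(A) Lc(A,D),  v(B) = sum_C w(C,B)/c(B) Lc(C,B),
//   S    = sum_{C,D} w(C,D) Lc(C,D).
// elen_scaled must already be mu * dt per edge.

static double pair_loglik_core(const IntegerMatrix& edges,
                               const NumericVector& elen_scaled, int n_node,
                               int root, const IntegerVector& tip_pair_states,
                               const double* w, int q, bool* bad_marg) {
  const int E = edges.nrow();
  const int n_tip = tip_pair_states.size();
  const int S = q * q;
  std::vector<double> rsum(q, 0.0), csum(q, 0.0);
  for (int a = 0; a < q; ++a)
    for (int b = 0; b < q; ++b) {
      rsum[a] += w[a * q + b];
      csum[b] += w[a * q + b];
    }
  for (int a = 0; a < q; ++a)
    if (rsum[a] <= 0.0 || csum[a] <= 0.0) { *bad_marg = true; return R_NegInf; }
  // conditionals precomputed once: wji = w(D|A), wij = w(C|B)
  std::vector<double> wji(S), wij(S);
  for (int a = 0; a < q; ++a)
    for (int b = 0; b < q; ++b) {
      wji[a * q + b] = w[a * q + b] / rsum[a];
      wij[a * q + b] = w[a * q + b] / csum[b];
    }
  std::vector<double> part((size_t)S * n_node, 1.0);
  std::vector<double> lsc(n_node, 0.0);
  for (int t = 0; t < n_tip; ++t) {
    double* p = &part[(size_t)S * t];
    for (int s = 0; s < S; ++s) p[s] = 0.0;
    p[tip_pair_states[t] - 1] = 1.0;
  }
  std::vector<double> u(q), v(q);
  const int* epar = &edges(0, 0);
  const int* echi = &edges(0, 1);
  double prev_len = -1.0, e1 = 0.0;
  for (int e = 0; e < E; ++e) {
    int pa = epar[e] - 1, ch = echi[e] - 1;
    double* pc = &part[(size_t)S * ch];
    double* pp = &part[(size_t)S * pa];
    if (elen_scaled[e] != prev_len) {
      prev_len = elen_scaled[e];
      e1 = std::exp(-prev_len);
    }
    double c2 = e1 * e1, c1 = e1 * (1.0 - e1), c0 = (1.0 - e1) * (1.0 - e1);
    double tot, mx = 0.0;
    if (ch < n_tip) {
      // leaf child: the partial is one-hot, so the contractions are O(1)
      int s0 = tip_pair_states[ch] - 1;
      int a0 = s0 / q, b0 = s0 % q;
      tot = c0 * w[s0];
      double ua0 = c1 * wji[s0], vb0 = c1 * wij[s0];
      for (int a = 0; a < q; ++a)
        for (int b = 0; b < q; ++b) {
          int s = a * q + b;
          double m = tot + (a == a0 ? ua0 : 0.0) + (b == b0 ? vb0 : 0.0) +
                     (s == s0 ? c2 : 0.0);
          pp[s] *= m;
          if (pp[s] > mx) mx = pp[s];
        }
    } else {
      tot = 0.0;
      for (int a = 0; a < q; ++a) { u[a] = 0.0; v[a] = 0.0; }
      for (int a = 0; a < q; ++a)
        for (int b = 0; b < q; ++b) {
          int s = a * q + b;
          double lc = pc[s];
          tot += w[s] * lc;
          u[a] += wji[s] * lc;
          v[b] += wij[s] * lc;
        }
      for (int a = 0; a < q; ++a)
        for (int b = 0; b < q; ++b) {
          int s = a * q + b;
          pp[s] *= c2 * pc[s] + c1 * (u[a] + v[b]) + c0 * tot;
          if (pp[s] > mx) mx = pp[s];
        }
    }
    lsc[pa] += lsc[ch];
    if (mx <= 0.0) return R_NegInf;
    for (int s = 0; s < S; ++s) pp[s] /= mx;
    lsc[pa] += std::log(mx);
  }
  double* pr = &part[(size_t)S * (root - 1)];
  double tot = 0.0;
  for (int s = 0; s < S; ++s) tot += w[s] * pr[s];
  if (tot <= 0.0) return R_NegInf;
  return std::log(tot) + lsc[root - 1];
}

// [[Rcpp::export]]
double cpp_pair_loglik(IntegerMatrix edges, NumericVector elen, int n_node,
                       int root, IntegerVector tip_pair_states,
                       NumericMatrix omega_ij, double mu) {
  const int q = omega_ij.nrow();
  std::vector<double> w(q * q);
  for (int a = 0; a < q; ++a)
    for (int b = 0; b < q; ++b) w[a * q + b] = omega_ij(a, b);
  NumericVector scaled(elen.size());
  for (int e = 0; e < elen.size(); ++e) scaled[e] = mu * elen[e];
  bool bad = false;
  double ll = pair_loglik_core(edges, scaled, n_node, root, tip_pair_states,
                               w.data(), q, &bad);
  if (bad) stop("pair propagator undefined: omega_ij has a zero marginal");
  return ll;
}

// Iterative proportional fitting of exp(J) to given row/column marginals.
static int ipf_core(const double* J, const double* tr, const double* tc, int q,
                    double tol, int maxit, double* w, double* lhi, double* lhj,
                    double* resid) {
  for (int a = 0; a < q; ++a) { lhi[a] = 0.0; lhj[a] = 0.0; }
  for (int a = 0; a < q; ++a)
    for (int b = 0; b < q; ++b) w[a * q + b] = std::exp(J[a * q + b]);
  int it = 0;
  double err = 1e300;
  for (; it < maxit; ++it) {
    for (int a = 0; a < q; ++a) {
      double s = 0.0;
      for (int b = 0; b < q; ++b) s += w[a * q + b];
      double f = tr[a] / s;
      for (int b = 0; b < q; ++b) w[a * q + b] *= f;
      lhi[a] += std::log(f);
    }
    err = 0.0;
    for (int b = 0; b < q; ++b) {
      double s = 0.0;
      for (int a = 0; a < q; ++a) s += w[a * q + b];
      double f = tc[b] / s;
      for (int a = 0; a < q; ++a) w[a * q + b] *= f;
      lhj[b] += std::log(f);
    }
    for (int a = 0; a < q; ++a) {
      double s = 0.0;
      for (int b = 0; b < q; ++b) s += w[a * q + b];
      double d = std::fabs(s - tr[a]);
      if (d > err) err = d;
    }
    if (err < tol) { ++it; break; }
  }
  *resid = err;
  return it;
}

// [[Rcpp::export]]
List cpp_ipf(NumericMatrix J, NumericVector target_row, NumericVector target_col,
             double tol, int maxit) {
  const int q = J.nrow();
  std::vector<double> Jf(q * q), w(q * q), lhi(q), lhj(q);
  for (int a = 0; a < q; ++a)
    for (int b = 0; b < q; ++b) Jf[a * q + b] = J(a, b);
  double resid;
  int it = ipf_core(Jf.data(), target_row.begin(), target_col.begin(), q, tol,
                    maxit, w.data(), lhi.data(), lhj.data(), &resid);
  NumericMatrix omega(q, q);
  for (int a = 0; a < q; ++a)
    for (int b = 0; b < q; ++b) omega(a, b) = w[a * q + b];
  return List::create(_["omega"] = omega,
                      _["h_i"] = NumericVector(lhi.begin(), lhi.end()),
                      _["h_j"] = NumericVector(lhj.begin(), lhj.end()),
                      _["iterations"] = it, _["residual"] = resid,
                      _["converged"] = resid < tol);
}

// Hill climb over the q x q coupling reparameterization; after every proposed
// J the compensatory fields are refit by IPF so the marginal constraints hold
// exactly; acceptance requires a strict pruning-likelihood increase.
// [[Rcpp::export]]
List cpp_pair_optimize(IntegerMatrix edges, NumericVector elen, int n_node,
                       int root, IntegerVector tip_pair_states,
                       NumericVector target_row, NumericVector target_col,
                       NumericMatrix J0, double mu, int n_iter, double mag0,
                       double mag1, double p_global, double j_bound,
                       double ipf_tol, int ipf_maxit) {
  const int q = J0.nrow(), S = q * q;
  NumericVector scaled(elen.size());
  for (int e = 0; e < elen.size(); ++e) scaled[e] = mu * elen[e];
  std::vector<double> J(S), Jp(S), w(S), lhi(q), lhj(q);
  for (int a = 0; a < q; ++a)
    for (int b = 0; b < q; ++b) J[a * q + b] = J0(a, b);
  double resid;
  bool bad = false;
  ipf_core(J.data(), target_row.begin(), target_col.begin(), q, ipf_tol,
           ipf_maxit, w.data(), lhi.data(), lhj.data(), &resid);
  double ll = pair_loglik_core(edges, scaled, n_node, root, tip_pair_states,
                               w.data(), q, &bad);
  std::vector<double> wbest(w);
  double llbest = ll;
  int n_acc = 0;
  double decay = (n_iter > 1) ? std::pow(mag1 / mag0, 1.0 / (n_iter - 1)) : 1.0;
  double mag = mag0;
  NumericVector trace(n_iter);
  for (int t = 0; t < n_iter; ++t, mag *= decay) {
    Jp = J;
    if (unif_rand() < p_global) {
      for (int s = 0; s < S; ++s) Jp[s] += mag * norm_rand();
    } else {
      int s = (int)(unif_rand() * S) % S;
      Jp[s] += mag * norm_rand();
    }
    for (int s = 0; s < S; ++s) {
      if (Jp[s] > j_bound) Jp[s] = j_bound;
      if (Jp[s] < -j_bound) Jp[s] = -j_bound;
    }
    ipf_core(Jp.data(), target_row.begin(), target_col.begin(), q, ipf_tol,
             ipf_maxit, w.data(), lhi.data(), lhj.data(), &resid);
    bad = false;
    double llp = pair_loglik_core(edges, scaled, n_node, root, tip_pair_states,
                                  w.data(), q, &bad);
    if (!bad && llp > ll) {
      // zero-center J: a pure gauge change, absorbed by the compensatory fields
      double mn = 0.0;
      for (int s = 0; s < S; ++s) mn += Jp[s];
      mn /= S;
      for (int s = 0; s < S; ++s) J[s] = Jp[s] - mn;
      ll = llp;
      ++n_acc;
      if (llp > llbest) { llbest = llp; wbest = w; }
    }
    trace[t] = ll;
  }
  NumericMatrix omega(q, q), Jout(q, q);
  for (int a = 0; a < q; ++a)
    for (int b = 0; b < q; ++b) {
      omega(a, b) = wbest[a * q + b];
      Jout(a, b) = J[a * q + b];
    }
  return List::create(_["omega"] = omega, _["J"] = Jout, _["loglik"] = llbest,
                      _["trace"] = trace, _["n_accepted"] = n_acc);
}

// ---------------------------------------------------------------------------
// Weighted pair frequency tables f_ij for all i < j, as the R array
// (q, q, L(L-1)/2): entry (a, b, k) at (k-1)*q*q + (b-1)*q + (a-1).
// [[Rcpp::export]]
NumericVector cpp_pair_counts(IntegerMatrix msa, int q, NumericVector wts) {
  const int M = msa.nrow(), L = msa.ncol();
  const int np = L * (L - 1) / 2;
  NumericVector out((size_t)np * q * q);
  double W = 0.0;
  for (int m = 0; m < M; ++m) W += wts[m];
  for (int m = 0; m < M; ++m) {
    double wm = wts[m];
    for (int i = 0; i < L; ++i) {
      int a = msa(m, i) - 1;
      for (int j = i + 1; j < L; ++j) {
        int b = msa(m, j) - 1;
        out[(size_t)pair_k0(i, j, L) * q * q + b * q + a] += wm;
      }
    }
  }
  for (R_xlen_t s = 0; s < out.size(); ++s) out[s] /= W;
  return out;
}

// Similarity reweighting: w_m = 1 / #{n : identity(m, n) >= thr}, self included.
// [[Rcpp::export]]
NumericVector cpp_reweighting(IntegerMatrix msa, double thr) {
  const int M = msa.nrow(), L = msa.ncol();
  std::vector<int> cnt(M, 1); // self
  const int max_mismatch = (int)std::floor((1.0 - thr) * L + 1e-9);
  for (int m = 0; m < M; ++m)
    for (int n = m + 1; n < M; ++n) {
      int d = 0;
      for (int i = 0; i < L; ++i) {
        if (msa(m, i) != msa(n, i)) { ++d; if (d > max_mismatch) break; }
      }
      if (d <= max_mismatch) { ++cnt[m]; ++cnt[n]; }
    }
  NumericVector w(M);
  for (int m = 0; m < M; ++m) w[m] = 1.0 / cnt[m];
  return w;
}

// ---------------------------------------------------------------------------
// Simulated annealing of within-column permutations toward a target connected
// correlation matrix: Metropolis acceptance on the change of the Frobenius
// distance ||C - C_target||, with the inverse temperature raised per stage.
// c_target is the (q, q, np) array flattened column-major. Column marginals
// are exactly invariant under the swap moves. The best configuration seen is
// returned.
// [[Rcpp::export]]
List cpp_anneal(IntegerMatrix msa_in, int q, NumericVector c_target,
                NumericVector betas, int moves_per_stage) {
  IntegerMatrix msa = clone(msa_in);
  const int M = msa.nrow(), L = msa.ncol();
  const int np = L * (L - 1) / 2;
  const double Minv = 1.0 / M;
  std::vector<int> npair((size_t)np * q * q, 0);
  std::vector<int> nsite((size_t)L * q, 0);
  std::vector<int> klo(np), khi(np);
  {
    int k = 0;
    for (int i = 0; i < L; ++i)
      for (int j = i + 1; j < L; ++j, ++k) { klo[k] = i; khi[k] = j; }
  }
  for (int m = 0; m < M; ++m)
    for (int i = 0; i < L; ++i) {
      int a = msa(m, i) - 1;
      ++nsite[(size_t)i * q + a];
      for (int j = i + 1; j < L; ++j)
        ++npair[(size_t)pair_k0(i, j, L) * q * q + (msa(m, j) - 1) * q + a];
    }
  double d2 = 0.0;
  for (int k = 0; k < np; ++k)
    for (int b = 0; b < q; ++b)
      for (int a = 0; a < q; ++a) {
        size_t cell = (size_t)k * q * q + b * q + a;
        double c = npair[cell] * Minv -
                   (nsite[(size_t)klo[k] * q + a] * Minv) *
                   (nsite[(size_t)khi[k] * q + b] * Minv);
        double d = c - c_target[cell];
        d2 += d * d;
      }
  double d_init = std::sqrt(d2);
  double d_best = d_init;
  IntegerMatrix best = clone(msa);
  const int n_stage = betas.size();
  NumericVector trace_d(n_stage), trace_b(n_stage);
  std::vector<int> cells(8), deltas(8);
  for (int st = 0; st < n_stage; ++st) {
    double beta = betas[st];
    for (int mv = 0; mv < moves_per_stage; ++mv) {
      int i = (int)(unif_rand() * L) % L;
      int m = (int)(unif_rand() * M) % M;
      int n = (int)(unif_rand() * M) % M;
      int am = msa(m, i) - 1, an = msa(n, i) - 1;
      if (am == an) continue; // identical symbols: distance unchanged, accept
      double dd2 = 0.0;
      // collect the <= 4 touched cells per partner column, netting duplicates
      for (int j = 0; j < L; ++j) {
        if (j == i) continue;
        int bm = msa(m, j) - 1, bn = msa(n, j) - 1;
        int k, base;
        int c1, c2, c3, c4;
        if (i < j) {
          k = pair_k0(i, j, L); base = k * q * q;
          c1 = base + bm * q + am; c2 = base + bm * q + an; // row m: am -> an
          c3 = base + bn * q + an; c4 = base + bn * q + am; // row n: an -> am
        } else {
          k = pair_k0(j, i, L); base = k * q * q;
          c1 = base + am * q + bm; c2 = base + an * q + bm;
          c3 = base + an * q + bn; c4 = base + am * q + bn;
        }
        cells[0] = c1; deltas[0] = -1;
        cells[1] = c2; deltas[1] = +1;
        cells[2] = c3; deltas[2] = -1;
        cells[3] = c4; deltas[3] = +1;
        for (int u = 0; u < 4; ++u)
          for (int vv = u + 1; vv < 4; ++vv)
            if (cells[vv] == cells[u] && deltas[vv] != 0 && deltas[u] != 0) {
              deltas[u] += deltas[vv]; deltas[vv] = 0;
            }
        int lo = klo[k], hi = khi[k];
        for (int u = 0; u < 4; ++u) {
          if (deltas[u] == 0) continue;
          int rem = cells[u] - k * q * q;
          int a = rem % q, b = rem / q;
          double fi = nsite[(size_t)lo * q + a] * Minv;
          double fj = nsite[(size_t)hi * q + b] * Minv;
          double ct = c_target[cells[u]];
          double c_old = npair[cells[u]] * Minv - fi * fj;
          double c_new = c_old + deltas[u] * Minv;
          dd2 += (c_new - ct) * (c_new - ct) - (c_old - ct) * (c_old - ct);
        }
      }
      double d_old = std::sqrt(d2);
      double d_new = std::sqrt(std::max(0.0, d2 + dd2));
      if (d_new <= d_old || unif_rand() < std::exp(-beta * (d_new - d_old))) {
        // apply: update counts, swap symbols
        for (int j = 0; j < L; ++j) {
          if (j == i) continue;
          int bm = msa(m, j) - 1, bn = msa(n, j) - 1;
          if (i < j) {
            int base = pair_k0(i, j, L) * q * q;
            --npair[base + bm * q + am]; ++npair[base + bm * q + an];
            --npair[base + bn * q + an]; ++npair[base + bn * q + am];
          } else {
            int base = pair_k0(j, i, L) * q * q;
            --npair[base + am * q + bm]; ++npair[base + an * q + bm];
            --npair[base + an * q + bn]; ++npair[base + am * q + bn];
          }
        }
        msa(m, i) = an + 1;
        msa(n, i) = am + 1;
        d2 = std::max(0.0, d2 + dd2);
        if (d_new < d_best) { d_best = d_new; best = clone(msa); }
      }
    }
    trace_d[st] = std::sqrt(d2);
    trace_b[st] = beta;
  }
  return List::create(_["msa"] = best, _["d_init"] = d_init,
                      _["d_best"] = d_best, _["d_final"] = std::sqrt(d2),
                      _["trace_beta"] = trace_b, _["trace_d"] = trace_d);
}

// ---------------------------------------------------------------------------
// Pseudo-likelihood objective and gradient for one site's conditional
// multinomial logit, normalized by total weight. Parameter layout: h (q),
// then for each other site j in increasing order a q x q block J_rj stored
// column-major with row = state at the focal site r, column = state at j.
// [[Rcpp::export]]
List cpp_plm_obj(NumericVector par, IntegerMatrix msa, NumericVector wts,
                 int site, int q, double lambda_J, double lambda_h,
                 bool want_grad) {
  const int M = msa.nrow(), L = msa.ncol();
  const int r = site - 1;
  const double* h = par.begin();
  const double* Jb = par.begin() + q; // (L-1) blocks of q*q
  double W = 0.0;
  for (int m = 0; m < M; ++m) W += wts[m];
  std::vector<double> E(q), p(q);
  double nll = 0.0;
  NumericVector grad(want_grad ? par.size() : 1);
  for (int m = 0; m < M; ++m) {
    double wm = wts[m] / W;
    for (int a = 0; a < q; ++a) E[a] = h[a];
    int jj = 0;
    for (int j = 0; j < L; ++j) {
      if (j == r) continue;
      const double* blk = Jb + (size_t)jj * q * q + (size_t)(msa(m, j) - 1) * q;
      for (int a = 0; a < q; ++a) E[a] += blk[a];
      ++jj;
    }
    double mx = E[0];
    for (int a = 1; a < q; ++a) if (E[a] > mx) mx = E[a];
    double Z = 0.0;
    for (int a = 0; a < q; ++a) { p[a] = std::exp(E[a] - mx); Z += p[a]; }
    int am = msa(m, r) - 1;
    nll += wm * (std::log(Z) + mx - E[am]);
    if (want_grad) {
      for (int a = 0; a < q; ++a) {
        double g = wm * (p[a] / Z - (a == am ? 1.0 : 0.0));
        grad[a] += g;
        p[a] = g;
      }
      int jj2 = 0;
      for (int j = 0; j < L; ++j) {
        if (j == r) continue;
        double* gblk = grad.begin() + q + (size_t)jj2 * q * q +
                       (size_t)(msa(m, j) - 1) * q;
        for (int a = 0; a < q; ++a) gblk[a] += p[a];
        ++jj2;
      }
    }
  }
  double pen = 0.0;
  for (int a = 0; a < q; ++a) pen += lambda_h * h[a] * h[a];
  const size_t nj = (size_t)(L - 1) * q * q;
  for (size_t s = 0; s < nj; ++s) pen += lambda_J * Jb[s] * Jb[s];
  nll += pen;
  if (want_grad) {
    for (int a = 0; a < q; ++a) grad[a] += 2.0 * lambda_h * h[a];
    for (size_t s = 0; s < nj; ++s) grad[q + s] += 2.0 * lambda_J * Jb[s];
    return List::create(_["value"] = nll, _["gradient"] = grad);
  }
  return List::create(_["value"] = nll);
}

// Patristic (path-length) time separation for given tip pairs.
// edges must be in preorder (parents before children).
// [[Rcpp::export]]
NumericVector cpp_patristic_pairs(IntegerMatrix edges, NumericVector elen,
                                  int n_node, IntegerMatrix pairs) {
  std::vector<int> parent(n_node, 0), level(n_node, 0);
  std::vector<double> tdep(n_node, 0.0);
  for (int e = 0; e < edges.nrow(); ++e) {
    int pa = edges(e, 0), ch = edges(e, 1);
    parent[ch - 1] = pa;
    level[ch - 1] = level[pa - 1] + 1;
    tdep[ch - 1] = tdep[pa - 1] + elen[e];
  }
  NumericVector out(pairs.nrow());
  for (int k = 0; k < pairs.nrow(); ++k) {
    int u = pairs(k, 0), v = pairs(k, 1);
    double du = tdep[u - 1], dv = tdep[v - 1];
    while (level[u - 1] > level[v - 1]) u = parent[u - 1];
    while (level[v - 1] > level[u - 1]) v = parent[v - 1];
    while (u != v) { u = parent[u - 1]; v = parent[v - 1]; }
    out[k] = du + dv - 2.0 * tdep[u - 1];
  }
  return out;
}
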