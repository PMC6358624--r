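#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dirichlet-multinomial product-partition posterior on a rounded,
// 1/c-scaled coancestry count matrix. One partition plays both roles:
// it groups recipient rows into clusters (rows in a cluster share an
// integrated-out Dirichlet copying profile) and aggregates donor columns.
// A CRP prior completes the posterior. Fixed individuals (external donor
// groups in block-matrix mode) never move and their clusters never merge.

namespace {

struct LgTab {
  std::vector<double> t;   // t[x] = lgamma(shift + x)
  double shift;
  void init(double sh, long cap) {
    shift = sh;
    if (cap > 8000000L) cap = 8000000L;
    t.resize(cap + 1);
    for (long x = 0; x <= cap; x++) t[x] = R::lgammafn(shift + x);
  }
  inline double operator()(double x) const {
    long xi = (long)(x + 0.5);
    if (xi >= 0 && xi < (long)t.size() && std::abs(x - xi) < 1e-9) return t[xi];
    return R::lgammafn(shift + x);
  }
};

struct State {
  int N;
  const IntegerMatrix* n;            // N x N counts
  std::vector<int> z;                // cluster of each individual (0-based)
  std::vector<std::vector<double>> M; // M[c][r] = sum_{j in c} n(r, j)
  std::vector<int> size;
  std::vector<char> cfixed;          // cluster contains fixed individuals
  std::vector<double> Trow;          // row totals (constant)
  double beta, crp;
  LgTab lg1, lgb;                    // lgamma(1 + x), lgamma(beta + x)

  int K() const { return (int)M.size(); }

  void init(const IntegerMatrix& counts, const IntegerVector& z0,
            const LogicalVector& fixed, double beta_, double crp_) {
    n = &counts;
    N = counts.nrow();
    beta = beta_; crp = crp_;
    z.assign(z0.begin(), z0.end());
    int K0 = 0;
    for (int i = 0; i < N; i++) { z[i] -= 1; if (z[i] + 1 > K0) K0 = z[i] + 1; }
    M.assign(K0, std::vector<double>(N, 0.0));
    size.assign(K0, 0);
    cfixed.assign(K0, 0);
    Trow.assign(N, 0.0);
    double tot = 0;
    for (int j = 0; j < N; j++) {
      size[z[j]]++;
      if (fixed[j]) cfixed[z[j]] = 1;
      for (int r = 0; r < N; r++) {
        M[z[j]][r] += counts(r, j);
        Trow[r] += counts(r, j);
        tot += counts(r, j);
      }
    }
    lg1.init(1.0, (long)tot + 2);
    lgb.init(beta, (long)tot + 2);
  }

  void add(int i, int c) {
    z[i] = c; size[c]++;
    std::vector<double>& col = M[c];
    for (int r = 0; r < N; r++) col[r] += (*n)(r, i);
  }

  // remove i from its cluster; returns former cluster id, possibly after
  // deleting an emptied cluster (swap-with-last relabelling)
  int remove(int i) {
    int c = z[i]; z[i] = -1; size[c]--;
    std::vector<double>& col = M[c];
    for (int r = 0; r < N; r++) col[r] -= (*n)(r, i);
    if (size[c] == 0) drop_cluster(c);
    return c;
  }

  void drop_cluster(int c) {
    int last = K() - 1;
    if (c != last) {
      M[c] = std::move(M[last]);
      size[c] = size[last];
      cfixed[c] = cfixed[last];
      for (int j = 0; j < N; j++) if (z[j] == last) z[j] = c;
    }
    M.pop_back(); size.pop_back(); cfixed.pop_back();
  }

  int new_cluster() {
    M.push_back(std::vector<double>(N, 0.0));
    size.push_back(0);
    cfixed.push_back(0);
    return K() - 1;
  }

  // full log posterior (likelihood + CRP prior), O(N*K + K^2).
  // Likelihood: rows are multinomial over donor columns with probabilities
  // equal within a donor cluster (q_{a,b}/n_b), cluster-level q integrated
  // out under symmetric Dirichlet(beta); constant multinomial coefficients
  // dropped. Matches fs_dm_loglik() in R.
  double logpost() const {
    const int Kc = K();
    double lp = 0.0;
    // CRP prior
    lp += Kc * std::log(crp) + R::lgammafn(crp) - R::lgammafn(crp + N);
    for (int c = 0; c < Kc; c++) lp += R::lgammafn((double)size[c]);
    // Dirichlet-multinomial per row-cluster over column clusters
    const double lgKb = R::lgammafn(Kc * beta);
    const double lgb0 = R::lgammafn(beta);
    std::vector<std::vector<double>> S(Kc, std::vector<double>(Kc, 0.0));
    for (int r = 0; r < N; r++) {
      int c = z[r];
      for (int b = 0; b < Kc; b++) S[c][b] += M[b][r];
    }
    // uniform-within-cluster spread, self column excluded (n_b - 1 available
    // columns for rows inside cluster b)
    for (int b = 0; b < Kc; b++) {
      double colT = 0;
      for (int c = 0; c < Kc; c++) colT += S[c][b];
      lp -= (colT - S[b][b]) * std::log((double)size[b]);
      if (size[b] > 1) lp -= S[b][b] * std::log((double)(size[b] - 1));
    }
    for (int c = 0; c < Kc; c++) {
      double T = 0;
      for (int b = 0; b < Kc; b++) {
        lp += lgb(S[c][b]) - lgb0;
        T += S[c][b];
      }
      lp += lgKb - R::lgammafn(Kc * beta + T);
    }
    return lp;
  }
};

} // namespace

// [[Rcpp::export]]
double fs_eval_cpp(const IntegerMatrix& counts, const IntegerVector& z,
                   const LogicalVector& fixed, double beta, double crp_alpha) {
  State st;
  st.init(counts, z, fixed, beta, crp_alpha);
  return st.logpost();
}

// [[Rcpp::export]]
List fs_mcmc_cpp(const IntegerMatrix& counts, const IntegerVector& z0,
                 const LogicalVector& fixed, int n_burn, int n_sample, int thin,
                 double beta, double crp_alpha, bool allow_sm) {
  State st;
  st.init(counts, z0, fixed, beta, crp_alpha);
  const int N = st.N;
  std::vector<int> free_idx;
  for (int i = 0; i < N; i++) if (!fixed[i]) free_idx.push_back(i);
  const int nf = (int)free_idx.size();
  if (nf == 0) stop("no free individuals to cluster");

  IntegerMatrix samples(n_sample, N);
  NumericVector lps(n_sample);
  std::vector<int> map_z(st.z);
  double map_lp = st.logpost();
  int accept_sm = 0, try_sm = 0;

  const int total = n_burn + n_sample * thin;
  int rec = 0;
  std::vector<double> cand_lp;
  std::vector<int> cand_c;

  for (int it = 0; it < total; it++) {
    // Gibbs sweep over free individuals
    for (int ii = 0; ii < nf; ii++) {
      int i = free_idx[ii];
      st.remove(i);
      cand_lp.clear(); cand_c.clear();
      for (int c = 0; c < st.K(); c++) {
        if (st.cfixed[c]) continue;
        st.add(i, c);
        cand_lp.push_back(st.logpost());
        st.remove(i);   // cluster cannot empty here (it had members before)
      }
      int cn = st.new_cluster();
      st.add(i, cn);
      cand_lp.push_back(st.logpost());
      st.remove(i);     // drops the singleton again
      // rebuild candidate ids after removals: free clusters in order + new
      for (int c = 0; c < st.K(); c++) if (!st.cfixed[c]) cand_c.push_back(c);
      cand_c.push_back(-1);
      // Gibbs draw
      double mx = cand_lp[0];
      for (double v : cand_lp) if (v > mx) mx = v;
      double tot = 0;
      for (double& v : cand_lp) { v = std::exp(v - mx); tot += v; }
      double u = unif_rand() * tot, acc = 0;
      int pick = (int)cand_lp.size() - 1;
      for (size_t kk = 0; kk < cand_lp.size(); kk++) {
        acc += cand_lp[kk];
        if (u <= acc) { pick = (int)kk; break; }
      }
      int target = cand_c[pick];
      if (target < 0) target = st.new_cluster();
      st.add(i, target);
    }

    // one split/merge Metropolis-Hastings proposal. Clusters are referred to
    // through representative members because remove() can relabel indices.
    if (allow_sm) {
      std::vector<int> fc;
      for (int c = 0; c < st.K(); c++) if (!st.cfixed[c]) fc.push_back(c);
      int Kf = (int)fc.size();
      double lp_old = st.logpost();
      if (unif_rand() < 0.5) {
        if (Kf >= 2) {
          try_sm++;
          int a = fc[(int)(unif_rand() * Kf)];
          int b = fc[(int)(unif_rand() * Kf)];
          if (a != b) {
            std::vector<int> members_b;
            for (int j = 0; j < N; j++) if (st.z[j] == b) members_b.push_back(j);
            int ra = -1;
            for (int j = 0; j < N; j++) if (st.z[j] == a) { ra = j; break; }
            int m = st.size[a] + st.size[b];
            for (int j : members_b) { st.remove(j); st.add(j, st.z[ra]); }
            double lp_new = st.logpost();
            double lq_fwd = std::log(0.5) - std::log((double)Kf * (Kf - 1) / 2.0);
            double lq_rev = std::log(0.5) - std::log((double)(Kf - 1))
              + std::log(2.0) - (m * M_LN2 + std::log1p(-std::pow(2.0, 1.0 - m)));
            if (std::log(unif_rand()) < lp_new - lp_old + lq_rev - lq_fwd) {
              accept_sm++;
            } else {
              int nb = st.new_cluster();
              for (int j : members_b) { st.remove(j); st.add(j, nb); }
            }
          }
        }
      } else {
        // split a free cluster by independent coin flips
        std::vector<int> reps;
        for (int c = 0; c < st.K(); c++) if (!st.cfixed[c] && st.size[c] >= 2)
          for (int j = 0; j < N; j++) if (st.z[j] == c) { reps.push_back(j); break; }
        if (!reps.empty()) {
          try_sm++;
          int ra = reps[(int)(unif_rand() * reps.size())];
          int a = st.z[ra];
          std::vector<int> members, moved;
          for (int j = 0; j < N; j++) if (st.z[j] == a) members.push_back(j);
          int m = (int)members.size();
          for (int j : members) if (unif_rand() < 0.5) moved.push_back(j);
          if (!moved.empty() && (int)moved.size() < m) {
            int rkeep = -1;
            for (int j : members) {
              bool was_moved = false;
              for (int q : moved) if (q == j) { was_moved = true; break; }
              if (!was_moved) { rkeep = j; break; }
            }
            int nb = st.new_cluster();
            for (int j : moved) { st.remove(j); st.add(j, nb); }
            double lp_new = st.logpost();
            double lq_fwd = std::log(0.5) - std::log((double)Kf)
              + std::log(2.0) - (m * M_LN2 + std::log1p(-std::pow(2.0, 1.0 - m)));
            double lq_rev = std::log(0.5) - std::log((double)(Kf + 1) * Kf / 2.0);
            if (std::log(unif_rand()) < lp_new - lp_old + lq_rev - lq_fwd) {
              accept_sm++;
            } else {
              for (int j : moved) { st.remove(j); st.add(j, st.z[rkeep]); }
            }
          }
        }
      }
    }

    if (it >= n_burn && ((it - n_burn) % thin) == (thin - 1) && rec < n_sample) {
      double lp = st.logpost();
      for (int j = 0; j < N; j++) samples(rec, j) = st.z[j] + 1;
      lps[rec] = lp;
      if (lp > map_lp) { map_lp = lp; map_z = st.z; }
      rec++;
    }
  }

  IntegerVector mz(N);
  for (int j = 0; j < N; j++) mz[j] = map_z[j] + 1;
  return List::create(_["samples"] = samples, _["logpost"] = lps,
                      _["map_z"] = mz, _["map_logpost"] = map_lp,
                      _["sm_tried"] = try_sm, _["sm_accepted"] = accept_sm);
}
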