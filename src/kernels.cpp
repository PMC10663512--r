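// O(N^2) inner loops of the embedding: likelihood sweeps, global
// log-likelihood, position-conditional expected degrees, greedy routing.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double LOGEPS = -34.538776394910684; // log(1e-15), clamp for ln p

// stable log(1 + exp(w))
static inline double log1pexp_(double w) {
  if (w > 37.0) return w;
  if (w > -37.0) return std::log1p(std::exp(w));
  return std::exp(w);
}

static inline double clip1_(double t) {
  return t > 1.0 ? 1.0 : (t < -1.0 ? -1.0 : t);
}

// ln L_i of one candidate position against all other nodes.
// lc[j] = log(R) - (log(mu) + log(kappa_i) + log(kappa_j)) / D, so that
// w = beta * (log(theta) + lc[j]) = beta * log(chi_ij).
static double local_ll(const double* cand, const NumericMatrix& V,
                       const std::vector<char>& isnb,
                       const std::vector<double>& lc,
                       int i, double beta, int M) {
  const int N = V.nrow();
  double ll = 0.0;
  for (int j = 0; j < N; ++j) {
    if (j == i) continue;
    double t = 0.0;
    for (int m = 0; m < M; ++m) t += cand[m] * V(j, m);
    double th = std::acos(clip1_(t));
    if (th < 1e-300) th = 1e-300;
    double w = beta * (std::log(th) + lc[j]);
    double lp = isnb[j] ? -log1pexp_(w) : -log1pexp_(-w);
    if (lp < LOGEPS) lp = LOGEPS;
    ll += lp;
  }
  return ll;
}

// One full sweep of per-node candidate moves. V has unit rows; adj is a
// 0-based adjacency list; order is a 0-based permutation. Returns new V.
// [[Rcpp::export]]
NumericMatrix cpp_sweep_refine(NumericMatrix V, NumericVector kappa,
                               List adj, IntegerVector order,
                               double beta, double R, double mu, int D,
                               int ncand, bool spread_min) {
  const int N = V.nrow(), M = V.ncol();
  NumericMatrix W = clone(V);
  std::vector<double> lk(N);
  for (int j = 0; j < N; ++j) lk[j] = std::log(kappa[j]);
  const double lmu = std::log(mu), lR = std::log(R);
  std::vector<char> isnb(N, 0);
  std::vector<double> lc(N), vbar(M), cand(M), best(M);

  for (int oi = 0; oi < N; ++oi) {
    int i = order[oi];
    IntegerVector nb = adj[i];
    int ki = nb.size();
    if (ki == 0) continue;

    // kappa^(-2)-weighted neighbour mean in ambient space
    for (int m = 0; m < M; ++m) vbar[m] = 0.0;
    for (int q = 0; q < ki; ++q) {
      int j = nb[q];
      double wq = 1.0 / (kappa[j] * kappa[j]);
      for (int m = 0; m < M; ++m) vbar[m] += wq * W(j, m);
    }
    double nv = 0.0;
    for (int m = 0; m < M; ++m) nv += vbar[m] * vbar[m];
    nv = std::sqrt(nv);
    if (nv < 1e-12) { // degenerate mean: stay around the incumbent
      for (int m = 0; m < M; ++m) vbar[m] = W(i, m);
      nv = 1.0;
    }

    // spread from the separation to the farthest neighbour
    double dmax = 0.0;
    for (int q = 0; q < ki; ++q) {
      int j = nb[q];
      double t = 0.0;
      for (int m = 0; m < M; ++m) t += (vbar[m] / nv) * W(j, m);
      double th = std::acos(clip1_(t));
      if (th > dmax) dmax = th;
    }
    double sigma = spread_min ? std::min(M_PI / 2.0, dmax / 2.0)
                              : std::max(M_PI / 2.0, dmax / 2.0);
    if (sigma < 1e-8) sigma = 1e-8;

    for (int j = 0; j < N; ++j)
      lc[j] = lR - (lmu + lk[i] + lk[j]) / (double)D;
    for (int q = 0; q < ki; ++q) isnb[nb[q]] = 1;

    // incumbent first, then random candidates
    for (int m = 0; m < M; ++m) best[m] = W(i, m);
    double best_ll = local_ll(best.data(), W, isnb, lc, i, beta, M);
    for (int c = 0; c < ncand; ++c) {
      double nrm = 0.0;
      do {
        nrm = 0.0;
        for (int m = 0; m < M; ++m) {
          cand[m] = vbar[m] + sigma * norm_rand();
          nrm += cand[m] * cand[m];
        }
        nrm = std::sqrt(nrm);
      } while (nrm < 1e-12);
      for (int m = 0; m < M; ++m) cand[m] /= nrm;
      double ll = local_ll(cand.data(), W, isnb, lc, i, beta, M);
      if (ll > best_ll) {
        best_ll = ll;
        for (int m = 0; m < M; ++m) best[m] = cand[m];
      }
    }
    for (int m = 0; m < M; ++m) W(i, m) = best[m];
    for (int q = 0; q < ki; ++q) isnb[nb[q]] = 0;
  }
  return W;
}

// Global log-likelihood: sum over unordered pairs of the clamped Bernoulli
// log-probabilities of the gravity law.
// [[Rcpp::export]]
double cpp_global_loglik(NumericMatrix V, NumericVector kappa, List adj,
                         double beta, double R, double mu, int D) {
  const int N = V.nrow(), M = V.ncol();
  std::vector<double> lk(N);
  for (int j = 0; j < N; ++j) lk[j] = std::log(kappa[j]);
  const double lmu = std::log(mu), lR = std::log(R);
  std::vector<char> isnb(N, 0);
  double ll = 0.0;
  for (int i = 0; i < N; ++i) {
    IntegerVector nb = adj[i];
    for (int q = 0; q < nb.size(); ++q) isnb[nb[q]] = 1;
    for (int j = i + 1; j < N; ++j) {
      double t = 0.0;
      for (int m = 0; m < M; ++m) t += V(i, m) * V(j, m);
      double th = std::acos(clip1_(t));
      if (th < 1e-300) th = 1e-300;
      double w = beta * (std::log(th) + lR - (lmu + lk[i] + lk[j]) / (double)D);
      double lp = isnb[j] ? -log1pexp_(w) : -log1pexp_(-w);
      if (lp < LOGEPS) lp = LOGEPS;
      ll += lp;
    }
    for (int q = 0; q < nb.size(); ++q) isnb[nb[q]] = 0;
  }
  return ll;
}

// Position-conditional expected degrees: kbar_i = sum_{j != i} p_ij.
// [[Rcpp::export]]
NumericVector cpp_expected_degrees_pos(NumericMatrix V, NumericVector kappa,
                                       double beta, double R, double mu,
                                       int D) {
  const int N = V.nrow(), M = V.ncol();
  std::vector<double> lk(N);
  for (int j = 0; j < N; ++j) lk[j] = std::log(kappa[j]);
  const double lmu = std::log(mu), lR = std::log(R);
  NumericVector kbar(N);
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double t = 0.0;
      for (int m = 0; m < M; ++m) t += V(i, m) * V(j, m);
      double th = std::acos(clip1_(t));
      if (th < 1e-300) th = 1e-300;
      double w = beta * (std::log(th) + lR - (lmu + lk[i] + lk[j]) / (double)D);
      double p = 1.0 / (1.0 + std::exp(w));
      kbar[i] += p;
      kbar[j] += p;
    }
  }
  return kbar;
}

// Greedy routing on effective hyperbolic distances x = r_j + r_t +
// 2 ln(dtheta/2). Forward to the neighbour closest to the target; failure on
// revisiting a node or exceeding max_hops. Ties resolved toward the smallest
// node index (ascending scan with strict improvement).
// [[Rcpp::export]]
IntegerVector cpp_greedy_route(List adj, NumericMatrix V, NumericVector r,
                               IntegerVector src, IntegerVector dst,
                               int max_hops) {
  const int N = V.nrow(), M = V.ncol(), P = src.size();
  IntegerVector hops(P);
  std::vector<int> stamp(N, -1);
  for (int p = 0; p < P; ++p) {
    int cur = src[p], tgt = dst[p];
    int h = 0;
    bool ok = false, fail = false;
    while (!fail) {
      if (cur == tgt) { ok = true; break; }
      if (h >= max_hops) break;
      stamp[cur] = p;
      IntegerVector nb = adj[cur];
      int bestj = -1;
      double bestx = R_PosInf;
      for (int q = 0; q < nb.size(); ++q) {
        int j = nb[q];
        if (j == tgt) { bestj = j; bestx = R_NegInf; break; }
        double t = 0.0;
        for (int m = 0; m < M; ++m) t += V(j, m) * V(tgt, m);
        double th = std::acos(clip1_(t));
        if (th < 1e-300) th = 1e-300;
        double x = r[j] + r[tgt] + 2.0 * std::log(th / 2.0);
        if (x < bestx) { bestx = x; bestj = j; }
      }
      if (bestj < 0) break;
      if (bestj != tgt && stamp[bestj] == p) break; // loop: failure
      cur = bestj;
      ++h;
    }
    hops[p] = ok ? h : -1;
  }
  return hops;
}
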