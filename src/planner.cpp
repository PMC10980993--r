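// Belief-state planning core.
//
// A patient's planning state is (s_E, m0, m1, b) where b is the belief that
// the clinical state is HbA1c < 8. Because an Engaged month always produces
// an HbA1c observation (collapsing b to 0 or 1), the set of beliefs reachable
// over a finite horizon is small, so the reachable belief-MDP is built
// explicitly as a layered graph and solved by backward induction. The same
// graph is reused across all lambda (action-charge) evaluations, which is
// what makes Whittle-index bisection and Lagrangian curve evaluation cheap.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Params {
  double pIMtoE, pIEtoE, pIMtoD, pUMtoD, pImp, pRel, boost, qObs;
};

Params as_params(const NumericVector& v) {
  if (v.size() != 8) stop("parameter vector must have 8 entries");
  Params p;
  p.pIMtoE = v[0]; p.pIEtoE = v[1]; p.pIMtoD = v[2]; p.pUMtoD = v[3];
  p.pImp = v[4]; p.pRel = v[5]; p.boost = v[6]; p.qObs = v[7];
  return p;
}

Params row_params(const NumericMatrix& m, int i) {
  if (m.ncol() != 8) stop("parameter matrix must have 8 columns");
  Params p;
  p.pIMtoE = m(i, 0); p.pIEtoE = m(i, 1); p.pIMtoD = m(i, 2); p.pUMtoD = m(i, 3);
  p.pImp = m(i, 4); p.pRel = m(i, 5); p.boost = m(i, 6); p.qObs = m(i, 7);
  return p;
}

// engagement codes: 0 = Engaged, 1 = Maintenance, 2 = Dropout
inline void engagement_probs(const Params& p, int e, int a, double out[3]) {
  out[0] = out[1] = out[2] = 0.0;
  if (e == 2) { out[2] = 1.0; return; }
  if (a == 1) {
    const double respond = (e == 0) ? p.pIEtoE : p.pIMtoE;
    out[2] = p.pIMtoD;
    out[0] = (1.0 - p.pIMtoD) * respond;
    out[1] = (1.0 - p.pIMtoD) * (1.0 - respond);
  } else {
    out[2] = p.pUMtoD;
    out[1] = 1.0 - p.pUMtoD;
  }
}

// one-month belief propagation; m1 is the engagement state two months back
inline double propagate_belief(const Params& p, double b, int m1) {
  const double pimp = (m1 == 0) ? std::min(1.0, (1.0 + p.boost) * p.pImp) : p.pImp;
  return b * (1.0 - p.pRel) + (1.0 - b) * pimp;
}

struct Edge { int child; double prob; };

struct Graph {
  std::vector<int> e, m0, m1;
  std::vector<double> b;
  std::vector<std::vector<Edge>> edges[2];
  std::vector<std::vector<int>> layers;  // layers[d] = node ids reachable at depth d
  std::unordered_map<uint64_t, int> index;
  Params par;

  explicit Graph(const Params& p) : par(p) {}

  static uint64_t key_of(int e_, int m0_, int m1_, double b_) {
    const int64_t qb = llround(b_ * 1e12);
    const uint64_t st = static_cast<uint64_t>(e_ * 9 + m0_ * 3 + m1_);
    return (static_cast<uint64_t>(qb) << 5) | st;
  }

  int get_node(int e_, int m0_, int m1_, double b_) {
    const uint64_t k = key_of(e_, m0_, m1_, b_);
    auto it = index.find(k);
    if (it != index.end()) return it->second;
    const int id = static_cast<int>(e.size());
    if (id >= 200000) stop("belief-state graph exceeded node cap");
    e.push_back(e_); m0.push_back(m0_); m1.push_back(m1_); b.push_back(b_);
    edges[0].push_back({}); edges[1].push_back({});
    index.emplace(k, id);
    return id;
  }

  void expand(int id) {
    if (!edges[0][id].empty()) return;  // every node has self-care successors once expanded
    const double bprime = propagate_belief(par, b[id], m1[id]);
    const int nm0 = e[id], nm1 = m0[id];
    for (int a = 0; a < 2; ++a) {
      double pe[3];
      engagement_probs(par, e[id], a, pe);
      for (int ne = 0; ne < 3; ++ne) {
        if (pe[ne] <= 0.0) continue;
        const double q = (ne == 0) ? 1.0 : (ne == 1 ? par.qObs : 0.0);
        // get_node may reallocate the edge arrays, so resolve children first
        if (q > 0.0) {
          if (bprime > 0.0) {
            const int c = get_node(ne, nm0, nm1, 1.0);
            edges[a][id].push_back({c, pe[ne] * q * bprime});
          }
          if (bprime < 1.0) {
            const int c = get_node(ne, nm0, nm1, 0.0);
            edges[a][id].push_back({c, pe[ne] * q * (1.0 - bprime)});
          }
        }
        if (q < 1.0) {
          const int c = get_node(ne, nm0, nm1, bprime);
          edges[a][id].push_back({c, pe[ne] * (1.0 - q)});
        }
      }
    }
  }

  // build layers 0..T from the root state
  void build(int e0, int m00, int m10, double b0, int T) {
    const int root = get_node(e0, m00, m10, b0);
    layers.assign(T + 1, {});
    layers[0].push_back(root);
    std::vector<int> stamp;  // last depth at which a node was enqueued
    stamp.assign(1, 0);
    for (int d = 0; d < T; ++d) {
      for (int id : layers[d]) {
        expand(id);
        for (int a = 0; a < 2; ++a) {
          for (const Edge& ed : edges[a][id]) {
            if (ed.child >= static_cast<int>(stamp.size())) stamp.resize(ed.child + 1, -1);
            if (stamp[ed.child] != d + 1) {
              stamp[ed.child] = d + 1;
              layers[d + 1].push_back(ed.child);
            }
          }
        }
      }
    }
  }

  inline double reward(int id, double alpha) const {
    return alpha * (e[id] != 2 ? 1.0 : 0.0) + (1.0 - alpha) * b[id];
  }
};

struct RootValues { double V, QU, QI; };

// backward induction at a single action charge lambda
RootValues dp_root(const Graph& g, int T, double alpha, double lambda) {
  const size_t n = g.e.size();
  if (T == 0) return {0.0, 0.0, 0.0};
  std::vector<double> vnext(n, 0.0), vcur(n, 0.0);
  RootValues out{0.0, 0.0, 0.0};
  for (int d = T - 1; d >= 0; --d) {
    for (int id : g.layers[d]) {
      double qa[2];
      for (int a = 0; a < 2; ++a) {
        double q = (a == 1) ? -lambda : 0.0;
        for (const Edge& ed : g.edges[a][id])
          q += ed.prob * (g.reward(ed.child, alpha) + vnext[ed.child]);
        qa[a] = q;
      }
      vcur[id] = qa[0] > qa[1] ? qa[0] : qa[1];
      if (d == 0 && id == g.layers[0][0]) { out.QU = qa[0]; out.QI = qa[1]; }
    }
    std::swap(vcur, vnext);
  }
  out.V = out.QU > out.QI ? out.QU : out.QI;
  return out;
}

// backward induction for a whole vector of lambdas in one pass
void dp_root_multi(const Graph& g, int T, double alpha, const NumericVector& lambdas,
                   std::vector<double>& V, std::vector<double>& QU, std::vector<double>& QI) {
  const size_t n = g.e.size();
  const int L = lambdas.size();
  V.assign(L, 0.0); QU.assign(L, 0.0); QI.assign(L, 0.0);
  if (T == 0) return;
  std::vector<double> vnext(n * L, 0.0), vcur(n * L, 0.0), qu(L), qi(L);
  for (int d = T - 1; d >= 0; --d) {
    for (int id : g.layers[d]) {
      for (int l = 0; l < L; ++l) { qu[l] = 0.0; qi[l] = -lambdas[l]; }
      for (int a = 0; a < 2; ++a) {
        std::vector<double>& acc = (a == 0) ? qu : qi;
        for (const Edge& ed : g.edges[a][id]) {
          const double r = g.reward(ed.child, alpha);
          const double* vn = &vnext[static_cast<size_t>(ed.child) * L];
          const double p = ed.prob;
          for (int l = 0; l < L; ++l) acc[l] += p * (r + vn[l]);
        }
      }
      double* vc = &vcur[static_cast<size_t>(id) * L];
      for (int l = 0; l < L; ++l) vc[l] = qu[l] > qi[l] ? qu[l] : qi[l];
      if (d == 0 && id == g.layers[0][0]) {
        for (int l = 0; l < L; ++l) { QU[l] = qu[l]; QI[l] = qi[l]; }
      }
    }
    std::swap(vcur, vnext);
  }
  for (int l = 0; l < L; ++l) V[l] = QU[l] > QI[l] ? QU[l] : QI[l];
}

double whittle_on_graph(const Graph& g, int T, double alpha, double tol) {
  if (T < 1) stop("whittle index needs at least one remaining decision epoch");
  auto f = [&](double lam) { RootValues r = dp_root(g, T, alpha, lam); return r.QI - r.QU; };
  double lo = -1.0, hi = 2.0;
  double flo = f(lo), fhi = f(hi);
  while (fhi > 0.0 && hi < 64.0) { lo = hi; flo = fhi; hi *= 2.0; fhi = f(hi); }
  while (flo < 0.0 && lo > -64.0) { hi = lo; fhi = flo; lo *= 2.0; flo = f(lo); }
  if (fhi > 0.0) { warning("non-indexable edge: no sign change up to lambda = %f", hi); return hi; }
  if (flo < 0.0) { warning("non-indexable edge: no sign change down to lambda = %f", lo); return lo; }
  while (hi - lo > tol) {
    const double mid = 0.5 * (lo + hi);
    if (f(mid) >= 0.0) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

void check_state(int e, int m0, int m1, double b) {
  if (e < 1 || e > 3 || m0 < 1 || m0 > 3 || m1 < 1 || m1 > 3)
    stop("engagement/memory codes must be in 1..3");
  if (!(b >= 0.0 && b <= 1.0)) stop("clinical belief must lie in [0, 1]");
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_arm_dp(NumericVector par, int e, int m0, int m1, double b,
                         int T, double alpha, double lambda) {
  check_state(e, m0, m1, b);
  Graph g(as_params(par));
  g.build(e - 1, m0 - 1, m1 - 1, b, T);
  RootValues r = dp_root(g, T, alpha, lambda);
  return NumericVector::create(_["V"] = r.V, _["Q_U"] = r.QU, _["Q_I"] = r.QI);
}

// [[Rcpp::export]]
DataFrame cpp_arm_dp_table(NumericVector par, int e, int m0, int m1, double b,
                           int T, double alpha, double lambda) {
  check_state(e, m0, m1, b);
  Graph g(as_params(par));
  g.build(e - 1, m0 - 1, m1 - 1, b, T);
  const size_t n = g.e.size();
  std::vector<double> vnext(n, 0.0), vcur(n, 0.0);
  std::vector<int> rd, re, rm0, rm1;
  std::vector<double> rb, rV, rQU, rQI;
  // collect rows depth-major, computed backwards then reported forwards
  std::vector<std::vector<double>> Vd(T + 1), QUd(T + 1), QId(T + 1);
  for (int d = T - 1; d >= 0; --d) {
    Vd[d].reserve(g.layers[d].size());
    for (int id : g.layers[d]) {
      double qa[2];
      for (int a = 0; a < 2; ++a) {
        double q = (a == 1) ? -lambda : 0.0;
        for (const Edge& ed : g.edges[a][id])
          q += ed.prob * (g.reward(ed.child, alpha) + vnext[ed.child]);
        qa[a] = q;
      }
      vcur[id] = qa[0] > qa[1] ? qa[0] : qa[1];
      Vd[d].push_back(vcur[id]); QUd[d].push_back(qa[0]); QId[d].push_back(qa[1]);
    }
    std::swap(vcur, vnext);
  }
  for (int d = 0; d <= T; ++d) {
    for (size_t i = 0; i < g.layers[d].size(); ++i) {
      const int id = g.layers[d][i];
      rd.push_back(d); re.push_back(g.e[id] + 1);
      rm0.push_back(g.m0[id] + 1); rm1.push_back(g.m1[id] + 1);
      rb.push_back(g.b[id]);
      if (d == T) { rV.push_back(0.0); rQU.push_back(NA_REAL); rQI.push_back(NA_REAL); }
      else { rV.push_back(Vd[d][i]); rQU.push_back(QUd[d][i]); rQI.push_back(QId[d][i]); }
    }
  }
  return DataFrame::create(
    _["t"] = rd, _["e"] = re, _["m0"] = rm0, _["m1"] = rm1, _["belief"] = rb,
    _["V"] = rV, _["Q_U"] = rQU, _["Q_I"] = rQI);
}

// [[Rcpp::export]]
double cpp_whittle(NumericVector par, int e, int m0, int m1, double b,
                   int T, double alpha, double tol) {
  check_state(e, m0, m1, b);
  Graph g(as_params(par));
  g.build(e - 1, m0 - 1, m1 - 1, b, T);
  return whittle_on_graph(g, T, alpha, tol);
}

// [[Rcpp::export]]
NumericVector cpp_whittle_batch(NumericMatrix par, IntegerVector e, IntegerVector m0,
                                IntegerVector m1, NumericVector b, int T,
                                double alpha, double tol) {
  const int n = e.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    check_state(e[i], m0[i], m1[i], b[i]);
    if (e[i] == 3) { out[i] = 0.0; continue; }  // Dropout: acting never changes anything
    Graph g(row_params(par, i));
    g.build(e[i] - 1, m0[i] - 1, m1[i] - 1, b[i], T);
    out[i] = whittle_on_graph(g, T, alpha, tol);
  }
  return out;
}

// Sum over arms of the per-arm optimal value at each lambda in `lambdas`.
// [[Rcpp::export]]
NumericVector cpp_group_value_curve(NumericMatrix par, IntegerVector e, IntegerVector m0,
                                    IntegerVector m1, NumericVector b, int T,
                                    double alpha, NumericVector lambdas) {
  const int n = e.size(), L = lambdas.size();
  NumericVector out(L);
  std::vector<double> V, QU, QI;
  for (int i = 0; i < n; ++i) {
    check_state(e[i], m0[i], m1[i], b[i]);
    Graph g(row_params(par, i));
    g.build(e[i] - 1, m0[i] - 1, m1[i] - 1, b[i], T);
    dp_root_multi(g, T, alpha, lambdas, V, QU, QI);
    for (int l = 0; l < L; ++l) out[l] += V[l];
  }
  return out;
}

// Per-arm optimal values at a single lambda.
// [[Rcpp::export]]
NumericVector cpp_group_values_at(NumericMatrix par, IntegerVector e, IntegerVector m0,
                                  IntegerVector m1, NumericVector b, int T,
                                  double alpha, double lambda) {
  const int n = e.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    check_state(e[i], m0[i], m1[i], b[i]);
    Graph g(row_params(par, i));
    g.build(e[i] - 1, m0[i] - 1, m1[i] - 1, b[i], T);
    out[i] = dp_root(g, T, alpha, lambda).V;
  }
  return out;
}

// Per-arm action advantage Q_I - Q_U at the root under a single lambda.
// [[Rcpp::export]]
NumericVector cpp_group_advantages(NumericMatrix par, IntegerVector e, IntegerVector m0,
                                   IntegerVector m1, NumericVector b, int T,
                                   double alpha, double lambda) {
  const int n = e.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    check_state(e[i], m0[i], m1[i], b[i]);
    if (e[i] == 3) { out[i] = -lambda; continue; }
    Graph g(row_params(par, i));
    g.build(e[i] - 1, m0[i] - 1, m1[i] - 1, b[i], T);
    RootValues r = dp_root(g, T, alpha, lambda);
    out[i] = r.QI - r.QU;
  }
  return out;
}
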