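// Heat-bath simulated-annealing engine for the multi-layer Potts cost.
// The instance arrives pre-compiled from R as flat CSR arrays:
//   classes: per sign-class adjacency (within one layer), degree vector k,
//            coefficient coef (= sign / 2m when normalized), lam2m = lambda/2m
//   orth:    symmetric CSR of orthology links, weights premultiplied by kappa
//   tri:     per-node CSR of 1-1-1 triplets, weight premultiplied by kappa_t
// All cost bookkeeping works on the gain G = -H; the annealer maximizes G.
#include <Rcpp.h>
#include <set>
using namespace Rcpp;

struct Inst {
  int M;
  IntegerVector layer_of;             // 1-based layer id per node
  int n_class;
  std::vector<NumericVector> k;       // per class, length M
  std::vector<IntegerVector> aptr;    // per class, length M+1
  std::vector<IntegerVector> aidx;
  std::vector<double> coef, lam2m;
  IntegerVector optr, oidx;
  NumericVector ow;
  IntegerVector tptr, ta, tb;
  double tw;
};

static Inst unpack(const List& inst) {
  Inst I;
  I.M = as<int>(inst["M"]);
  I.layer_of = inst["layer_of"];
  List classes = inst["classes"];
  I.n_class = classes.size();
  for (int c = 0; c < I.n_class; ++c) {
    List cl = classes[c];
    I.k.push_back(cl["k"]);
    I.aptr.push_back(cl["aptr"]);
    I.aidx.push_back(cl["aidx"]);
    I.coef.push_back(as<double>(cl["coef"]));
    I.lam2m.push_back(as<double>(cl["lam2m"]));
  }
  I.optr = inst["optr"]; I.oidx = inst["oidx"]; I.ow = inst["ow"];
  I.tptr = inst["tptr"]; I.ta = inst["ta"]; I.tb = inst["tb"];
  I.tw = as<double>(inst["tw"]);
  return I;
}

// Per-class per-label degree sums K[c][s].
static std::vector<std::vector<double> > label_degrees(const Inst& I,
                                                       const IntegerVector& sigma,
                                                       int q) {
  std::vector<std::vector<double> > K(I.n_class, std::vector<double>(q, 0.0));
  for (int c = 0; c < I.n_class; ++c)
    for (int i = 0; i < I.M; ++i) K[c][sigma[i] - 1] += I.k[c][i];
  return K;
}

// Gains g(s) for relabeling `node` (0-based) to each s, excluding terms that
// do not depend on the node's label (its modularity self-term).
static void local_gains(const Inst& I, const IntegerVector& sigma, int q,
                        int node, const std::vector<std::vector<double> >& K,
                        std::vector<double>& g) {
  std::fill(g.begin(), g.end(), 0.0);
  int cur = sigma[node] - 1;
  for (int c = 0; c < I.n_class; ++c) {
    double kv = I.k[c][node];
    if (kv == 0.0 && I.aptr[c][node + 1] == I.aptr[c][node]) continue;
    // edge contributions
    for (int p = I.aptr[c][node]; p < I.aptr[c][node + 1]; ++p)
      g[sigma[I.aidx[c][p]] - 1] += 2.0 * I.coef[c];
    // null-model contributions, label sums excluding the node itself
    double a = 2.0 * I.coef[c] * I.lam2m[c] * kv;
    if (a != 0.0) {
      for (int s = 0; s < q; ++s) g[s] -= a * K[c][s];
      g[cur] += a * kv;
    }
  }
  for (int p = I.optr[node]; p < I.optr[node + 1]; ++p)
    g[sigma[I.oidx[p]] - 1] += I.ow[p];
  for (int p = I.tptr[node]; p < I.tptr[node + 1]; ++p) {
    int sa = sigma[I.ta[p]], sb = sigma[I.tb[p]];
    if (sa == sb) g[sa - 1] += I.tw;
  }
}

// [[Rcpp::export]]
NumericVector cpp_local_gains(List inst, IntegerVector sigma, int q, int node1) {
  Inst I = unpack(inst);
  std::vector<std::vector<double> > K = label_degrees(I, sigma, q);
  std::vector<double> g(q);
  local_gains(I, sigma, q, node1 - 1, K, g);
  return wrap(g);
}

// Total gain G(sigma) = -H(sigma), including label-independent self terms.
// [[Rcpp::export]]
double cpp_total_gain(List inst, IntegerVector sigma, int q) {
  Inst I = unpack(inst);
  std::vector<std::vector<double> > K = label_degrees(I, sigma, q);
  double G = 0.0;
  for (int c = 0; c < I.n_class; ++c) {
    double esame = 0.0;
    for (int i = 0; i < I.M; ++i)
      for (int p = I.aptr[c][i]; p < I.aptr[c][i + 1]; ++p)
        if (sigma[i] == sigma[I.aidx[c][p]]) esame += 1.0; // both directions
    double ksq = 0.0;
    for (int s = 0; s < q; ++s) ksq += K[c][s] * K[c][s];
    G += I.coef[c] * (esame - I.lam2m[c] * ksq);
  }
  double orth = 0.0;
  for (int i = 0; i < I.M; ++i)
    for (int p = I.optr[i]; p < I.optr[i + 1]; ++p)
      if (sigma[i] == sigma[I.oidx[p]]) orth += I.ow[p];
  G += 0.5 * orth;
  double tri = 0.0;
  for (int i = 0; i < I.M; ++i)
    for (int p = I.tptr[i]; p < I.tptr[i + 1]; ++p)
      if (sigma[i] == sigma[I.ta[p]] && sigma[I.ta[p]] == sigma[I.tb[p]])
        tri += 1.0;
  G += I.tw * tri / 3.0;
  return G;
}

static int sample_label(const std::vector<double>& g, int q, double T) {
  double gmax = g[0];
  for (int s = 1; s < q; ++s) if (g[s] > gmax) gmax = g[s];
  double tot = 0.0;
  std::vector<double> w(q);
  for (int s = 0; s < q; ++s) { w[s] = std::exp((g[s] - gmax) / T); tot += w[s]; }
  double u = unif_rand() * tot, acc = 0.0;
  for (int s = 0; s < q; ++s) { acc += w[s]; if (u <= acc) return s; }
  return q - 1;
}

// One full sweep in randomized node order; returns number of label changes.
static int sweep(const Inst& I, IntegerVector& sigma, int q, double T,
                 std::vector<std::vector<double> >& K,
                 std::vector<int>& order, std::vector<double>& g,
                 double& G) {
  int n = I.M;
  for (int i = 0; i < n; ++i) order[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(order[i], order[j]);
  }
  int flips = 0;
  for (int t = 0; t < n; ++t) {
    int v = order[t];
    local_gains(I, sigma, q, v, K, g);
    int olds = sigma[v] - 1;
    int news = sample_label(g, q, T);
    if (news != olds) {
      G += g[news] - g[olds];
      for (int c = 0; c < I.n_class; ++c) {
        K[c][olds] -= I.k[c][v];
        K[c][news] += I.k[c][v];
      }
      sigma[v] = news + 1;
      ++flips;
    }
  }
  return flips;
}

// One collective sweep: every (layer, label) group is offered a heat-bath
// relabeling of the whole group. Single-node moves cannot merge the
// fragments of a module or align an already-crystallized module with its
// orthologous counterpart in another layer (both require crossing a barrier
// proportional to module size); whole-group moves do both in one step.
// Groups are materialized lazily from the current labeling.
static int group_sweep(const Inst& I, IntegerVector& sigma, int q, double T,
                       std::vector<std::vector<double> >& K,
                       std::vector<double>& g, double& G) {
  int n = I.M;
  // snapshot of occupied (layer, label) cells
  std::vector<std::pair<int, int> > cells;
  {
    std::set<std::pair<int, int> > seen;
    for (int i = 0; i < n; ++i)
      seen.insert(std::make_pair(I.layer_of[i], sigma[i]));
    cells.assign(seen.begin(), seen.end());
  }
  for (int i = (int)cells.size() - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(cells[i], cells[j]);
  }
  int moves = 0;
  std::vector<double> kS(I.n_class);
  for (size_t ci = 0; ci < cells.size(); ++ci) {
    int layer = cells[ci].first, lab = cells[ci].second;
    std::vector<int> members;
    for (int i = 0; i < n; ++i)
      if (I.layer_of[i] == layer && sigma[i] == lab) members.push_back(i);
    if (members.empty()) continue;
    std::vector<char> inS(n, 0);
    for (size_t t = 0; t < members.size(); ++t) inS[members[t]] = 1;
    // gains of moving the whole group to label s, relative to staying
    std::fill(g.begin(), g.end(), 0.0);
    std::fill(kS.begin(), kS.end(), 0.0);
    for (int c = 0; c < I.n_class; ++c) {
      for (size_t t = 0; t < members.size(); ++t) {
        int v = members[t];
        kS[c] += I.k[c][v];
        for (int p = I.aptr[c][v]; p < I.aptr[c][v + 1]; ++p) {
          int u = I.aidx[c][p];
          if (!inS[u]) g[sigma[u] - 1] += 2.0 * I.coef[c];
        }
      }
      double a = 2.0 * I.coef[c] * I.lam2m[c] * kS[c];
      if (a != 0.0) {
        for (int s = 0; s < q; ++s) g[s] -= a * K[c][s];
        g[lab - 1] += a * kS[c];
      }
    }
    for (size_t t = 0; t < members.size(); ++t) {
      int v = members[t];
      for (int p = I.optr[v]; p < I.optr[v + 1]; ++p)
        g[sigma[I.oidx[p]] - 1] += I.ow[p];   // partners are in other layers
      for (int p = I.tptr[v]; p < I.tptr[v + 1]; ++p) {
        int sa = sigma[I.ta[p]], sb = sigma[I.tb[p]];
        if (sa == sb) g[sa - 1] += I.tw;
      }
    }
    int news = sample_label(g, q, T);
    if (news != lab - 1) {
      G += g[news] - g[lab - 1];
      for (int c = 0; c < I.n_class; ++c) {
        K[c][lab - 1] -= kS[c];
        K[c][news] += kS[c];
      }
      for (size_t t = 0; t < members.size(); ++t) sigma[members[t]] = news + 1;
      ++moves;
    }
  }
  return moves;
}

// Measured flip rate over n_sweeps sweeps from the given start labeling.
// [[Rcpp::export]]
double cpp_measure_fliprate(List inst, IntegerVector sigma0, int q, double T,
                            int n_sweeps) {
  Inst I = unpack(inst);
  IntegerVector sigma = clone(sigma0);
  std::vector<std::vector<double> > K = label_degrees(I, sigma, q);
  std::vector<int> order(I.M);
  std::vector<double> g(q);
  double G = 0.0;
  long flips = 0;
  for (int s = 0; s < n_sweeps; ++s)
    flips += sweep(I, sigma, q, T, K, order, g, G);
  return (double)flips / ((double)n_sweeps * I.M);
}

// Full annealing run: geometric cooling from T0 until the flip rate of the
// last sweep at a temperature drops below stop_rate. Returns the best
// (maximum-gain) labeling seen and the per-temperature trace.
// [[Rcpp::export]]
List cpp_anneal(List inst, IntegerVector sigma0, int q, double T0,
                double cooling, double stop_rate, int sweeps_per_T,
                int max_temps, int group_sweeps_per_T) {
  Inst I = unpack(inst);
  IntegerVector sigma = clone(sigma0);
  std::vector<std::vector<double> > K = label_degrees(I, sigma, q);
  std::vector<int> order(I.M);
  std::vector<double> g(q);
  double G = cpp_total_gain(inst, sigma, q);
  double bestG = G;
  IntegerVector best = clone(sigma);
  std::vector<double> trT, trRate, trCost;
  double T = T0;
  bool converged = false;
  for (int step = 0; step < max_temps; ++step) {
    int flips = 0;
    for (int s = 0; s < sweeps_per_T; ++s) {
      flips = sweep(I, sigma, q, T, K, order, g, G);
      if (G > bestG + 1e-12) { bestG = G; best = clone(sigma); }
    }
    for (int s = 0; s < group_sweeps_per_T; ++s) {
      group_sweep(I, sigma, q, T, K, g, G);
      if (G > bestG + 1e-12) { bestG = G; best = clone(sigma); }
    }
    double rate = (double)flips / I.M;
    trT.push_back(T); trRate.push_back(rate); trCost.push_back(-G);
    if (rate < stop_rate) { converged = true; break; }
    T *= cooling;
  }
  return List::create(_["sigma_best"] = best, _["cost_best"] = -bestG,
                      _["sigma_final"] = sigma, _["cost_final"] = -G,
                      _["trace_T"] = wrap(trT), _["trace_fliprate"] = wrap(trRate),
                      _["trace_cost"] = wrap(trCost),
                      _["converged"] = converged);
}
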