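#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// All-pairs Dijkstra on a dense nonnegative cost matrix with deterministic
// lowest-index tie-breaking (linear scan keeps the first minimum) and
// predecessor retention for downstream path walks.
// [[Rcpp::export]]
List cpp_dijkstra_all(NumericMatrix cost) {
  const int n = cost.nrow();
  NumericMatrix dist(n, n);
  IntegerMatrix pred(n, n); // 1-based predecessor, 0 = none
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> d(n);
  std::vector<int> p(n);
  std::vector<bool> done(n);
  for (int s = 0; s < n; ++s) {
    std::fill(d.begin(), d.end(), INF);
    std::fill(p.begin(), p.end(), -1);
    std::fill(done.begin(), done.end(), false);
    d[s] = 0.0;
    for (int iter = 0; iter < n; ++iter) {
      int u = -1;
      double best = INF;
      for (int i = 0; i < n; ++i) {
        if (!done[i] && d[i] < best) { best = d[i]; u = i; }
      }
      if (u < 0) break; // remaining nodes unreachable
      done[u] = true;
      for (int v = 0; v < n; ++v) {
        if (v == u || done[v]) continue;
        double c = cost(u, v);
        if (!std::isfinite(c)) continue;
        double nd = d[u] + c;
        if (nd < d[v]) { d[v] = nd; p[v] = u; }
      }
    }
    for (int v = 0; v < n; ++v) {
      dist(s, v) = d[v];
      pred(s, v) = p[v] + 1;
    }
  }
  return List::create(_["dist"] = dist, _["pred"] = pred);
}

// Walk the predecessor tree from t back to s; returns path node count, or 0
// if unreachable. Writes nodes (0-based, s..t order) into buf.
static int walk_path(const IntegerMatrix &pred, int s, int t,
                     std::vector<int> &buf) {
  buf.clear();
  int cur = t;
  while (cur != s) {
    buf.push_back(cur);
    int pr = pred(s, cur) - 1;
    if (pr < 0) return 0;
    cur = pr;
    if ((int)buf.size() > pred.nrow()) return 0; // defensive
  }
  buf.push_back(s);
  std::reverse(buf.begin(), buf.end());
  return (int)buf.size();
}

// Search information: -log2 of the probability that an unbiased random walk
// (transition probabilities prob(i,j) = A_ij / s_i) follows the retained
// shortest path s -> t. Asymmetric; symmetrization happens in R.
// [[Rcpp::export]]
NumericMatrix cpp_search_information(IntegerMatrix pred, NumericMatrix prob) {
  const int n = pred.nrow();
  NumericMatrix si(n, n);
  std::vector<int> buf;
  for (int s = 0; s < n; ++s) {
    for (int t = 0; t < n; ++t) {
      if (s == t) { si(s, t) = 0.0; continue; }
      int k = walk_path(pred, s, t, buf);
      if (k == 0) { si(s, t) = NA_REAL; continue; }
      double logp = 0.0;
      for (int i = 0; i + 1 < k; ++i) {
        logp += std::log2(prob(buf[i], buf[i + 1]));
      }
      si(s, t) = -logp;
    }
  }
  return si;
}

// Path transitivity: mean matching index over all pairs of nodes on the
// retained shortest path (including endpoints); the k = 2 direct-edge case
// reduces to the matching index of the pair itself.
// [[Rcpp::export]]
NumericMatrix cpp_path_transitivity(IntegerMatrix pred, NumericMatrix match) {
  const int n = pred.nrow();
  NumericMatrix pt(n, n);
  std::vector<int> buf;
  for (int s = 0; s < n; ++s) {
    for (int t = s + 1; t < n; ++t) {
      int k = walk_path(pred, s, t, buf);
      if (k < 2) { pt(s, t) = pt(t, s) = NA_REAL; continue; }
      double acc = 0.0;
      for (int i = 0; i < k; ++i)
        for (int j = i + 1; j < k; ++j)
          acc += match(buf[i], buf[j]);
      double val = 2.0 * acc / ((double)k * (k - 1));
      pt(s, t) = pt(t, s) = val;
    }
  }
  return pt;
}

// Greedy navigation: from s, repeatedly hop to the neighbor closest (in the
// supplied metric) to the target t; stop at t. A revisited node or more than
// n hops is a failed route and both outputs carry +Inf. Asymmetric;
// symmetrization happens in R.
// [[Rcpp::export]]
List cpp_navigate(NumericMatrix sc, NumericMatrix metric) {
  const int n = sc.nrow();
  NumericMatrix hops(n, n), plen(n, n);
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<bool> visited(n);
  for (int s = 0; s < n; ++s) {
    for (int t = 0; t < n; ++t) {
      if (s == t) { hops(s, t) = 0.0; plen(s, t) = 0.0; continue; }
      std::fill(visited.begin(), visited.end(), false);
      int cur = s;
      visited[s] = true;
      double nh = 0.0, np = 0.0;
      bool ok = false, fail = false;
      while (!fail) {
        int nxt = -1;
        double best = INF;
        for (int v = 0; v < n; ++v) {
          if (v == cur || sc(cur, v) <= 0.0) continue;
          if (metric(v, t) < best) { best = metric(v, t); nxt = v; }
        }
        if (nxt < 0 || visited[nxt]) { fail = true; break; }
        np += metric(cur, nxt);
        nh += 1.0;
        cur = nxt;
        if (cur == t) { ok = true; break; }
        visited[cur] = true;
        if (nh > (double)n) { fail = true; break; }
      }
      if (ok) { hops(s, t) = nh; plen(s, t) = np; }
      else    { hops(s, t) = INF; plen(s, t) = INF; }
    }
  }
  return List::create(_["hops"] = hops, _["length"] = plen);
}

// One simulated-annealing run over permutations of the coreness template.
// Maximizes R = sum_{i != j} G_ij C_i C_j by Metropolis pair swaps with
// geometric cooling. Uses R's RNG (seed handled by the caller via set.seed).
static double quality_offdiag(const NumericMatrix &G, const std::vector<double> &c) {
  const int n = G.nrow();
  double r = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j) r += G(i, j) * c[i] * c[j];
  return r;
}

// [[Rcpp::export]]
List cpp_anneal_coreness(NumericMatrix G, NumericVector tmpl, int restarts,
                         double cooling, int per_temp, int patience,
                         int max_temps) {
  const int n = G.nrow();
  std::vector<double> best_c(n);
  double best_r = -std::numeric_limits<double>::infinity();
  std::vector<double> c(n), gc(n);
  for (int rs = 0; rs < restarts; ++rs) {
    // random initial permutation of the template (Fisher-Yates with R RNG)
    for (int i = 0; i < n; ++i) c[i] = tmpl[i];
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(c[i], c[j]);
    }
    // gc[i] = sum_j G_ij c_j (diagonal of G is zero by contract)
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int j = 0; j < n; ++j) acc += G(i, j) * c[j];
      gc[i] = acc;
    }
    double r = quality_offdiag(G, c);
    // calibrate initial temperature from the magnitude of proposal deltas
    double mean_abs = 0.0;
    int probe = std::min(200, n * n);
    for (int k = 0; k < probe; ++k) {
      int a = (int)std::floor(unif_rand() * n);
      int b = (int)std::floor(unif_rand() * n);
      if (a == b) continue;
      double d = c[b] - c[a];
      double delta = 2.0 * d * ((gc[a] - G(a, b) * c[b]) - (gc[b] - G(a, b) * c[a]));
      mean_abs += std::fabs(delta);
    }
    mean_abs /= probe;
    double temp = mean_abs > 0 ? mean_abs / std::log(2.0) : 1.0;
    double run_best = r;
    std::vector<double> run_best_c = c;
    int stale = 0;
    for (int step = 0; step < max_temps && stale < patience; ++step) {
      bool improved = false;
      for (int k = 0; k < per_temp; ++k) {
        int a = (int)std::floor(unif_rand() * n);
        int b = (int)std::floor(unif_rand() * n);
        if (a == b) continue;
        double d = c[b] - c[a];
        // delta R for swapping entries a and b (c_a c_b product unchanged)
        double delta = 2.0 * d * ((gc[a] - G(a, b) * c[b]) - (gc[b] - G(a, b) * c[a]));
        if (delta >= 0 || unif_rand() < std::exp(delta / temp)) {
          std::swap(c[a], c[b]);
          for (int i = 0; i < n; ++i) gc[i] += d * (G(i, a) - G(i, b));
          r += delta;
          if (r > run_best + 1e-15) {
            run_best = r;
            run_best_c = c;
            improved = true;
          }
        }
      }
      temp *= cooling;
      stale = improved ? 0 : stale + 1;
    }
    if (run_best > best_r) {
      best_r = run_best;
      best_c = run_best_c;
    }
  }
  return List::create(_["coreness"] = NumericVector(best_c.begin(), best_c.end()),
                      _["quality"] = best_r);
}
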