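// IIC engine: per-component all-pairs topological shortest paths (BFS),
// the IIC numerator, and the exact intra / flux / connector partition of
// each node's removal impact.
//
// Notation: a_i = node attribute (area), nl_ij = minimum number of links
// on a path i..j. iic_num = sum_i sum_j a_i a_j / (1 + nl_ij) over ordered
// pairs including i = j; pairs in different components contribute zero.
//
// Node-removal impact is computed from pair terms, not by naive
// re-enumeration: removing k changes nl(i,j) only when *every*
// shortest i-j path runs through k, which requires both
// nl(i,k) + nl(k,j) == nl(i,j) and sigma(i,k) * sigma(k,j) == sigma(i,j),
// where sigma counts shortest paths (saturating, so the test is exact
// or errs on the conservative side). BFS re-runs are restricted to the
// nodes passing that test, inside k's component only.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

const uint64_t SIG_SAT = UINT64_C(1) << 62; // saturation cap for path counts

inline uint64_t satAdd(uint64_t a, uint64_t b) {
  uint64_t s = a + b;
  return (s >= SIG_SAT || s < a) ? SIG_SAT : s;
}

// BFS from src over adj, skipping node `skip` (-1 for none); writes
// distances into dist (-1 = unreached). When sigma != NULL, also
// accumulates saturating shortest-path counts.
void bfs(int src, int skip, const std::vector<std::vector<int> > &adj,
         std::vector<int> &dist, std::vector<int> &queue,
         std::vector<uint64_t> *sigma = 0) {
  std::fill(dist.begin(), dist.end(), -1);
  if (sigma) std::fill(sigma->begin(), sigma->end(), UINT64_C(0));
  if (src == skip) return;
  dist[src] = 0;
  if (sigma) (*sigma)[src] = 1;
  queue.clear();
  queue.push_back(src);
  for (size_t head = 0; head < queue.size(); ++head) {
    int v = queue[head];
    int dv = dist[v];
    for (size_t t = 0; t < adj[v].size(); ++t) {
      int w = adj[v][t];
      if (w == skip) continue;
      if (dist[w] < 0) {
        dist[w] = dv + 1;
        queue.push_back(w);
        if (sigma) (*sigma)[w] = (*sigma)[v];
      } else if (sigma && dist[w] == dv + 1) {
        (*sigma)[w] = satAdd((*sigma)[w], (*sigma)[v]);
      }
    }
  }
}

// do ALL shortest i-j paths pass through k? (conservative under saturation)
inline bool allPathsThrough(int dik, int dkj, int dij, uint64_t sik,
                            uint64_t skj, uint64_t sij) {
  if (dik < 0 || dkj < 0 || dij < 0) return false;
  if (dik + dkj != dij) return false;
  if (sik >= SIG_SAT || skj >= SIG_SAT || sij >= SIG_SAT) return true;
  if (skj != 0 && sik > SIG_SAT / skj) return true; // product saturates
  return sik * skj == sij;
}

} // namespace

// areas: node attributes; edges: m x 2 matrix of 1-based node indices.
// Returns membership, iic numerator, and (if importance) the per-node
// intra/flux/connector numerators (same squared-attribute units).
// [[Rcpp::export]]
List cpp_iic_engine(NumericVector areas, IntegerMatrix edges,
                    bool importance) {
  int n = areas.size();
  std::vector<std::vector<int> > adj(n);
  for (int e = 0; e < edges.nrow(); ++e) {
    int u = edges(e, 0) - 1, v = edges(e, 1) - 1;
    if (u < 0 || u >= n || v < 0 || v >= n)
      stop("edge references unknown node");
    if (u == v) stop("self-loop in edge list");
    adj[u].push_back(v);
    adj[v].push_back(u);
  }

  // components
  IntegerVector membership(n, 0);
  std::vector<std::vector<int> > comps;
  {
    std::vector<int> stack;
    for (int s = 0; s < n; ++s) {
      if (membership[s]) continue;
      comps.push_back(std::vector<int>());
      int c = comps.size();
      stack.clear();
      stack.push_back(s);
      membership[s] = c;
      while (!stack.empty()) {
        int v = stack.back();
        stack.pop_back();
        comps.back().push_back(v);
        for (size_t t = 0; t < adj[v].size(); ++t) {
          int w = adj[v][t];
          if (!membership[w]) { membership[w] = c; stack.push_back(w); }
        }
      }
    }
  }

  double iic_num = 0.0;
  for (int i = 0; i < n; ++i) iic_num += areas[i] * areas[i];

  NumericVector intra(n), flux(n), conn(n);
  for (int i = 0; i < n; ++i) intra[i] = areas[i] * areas[i];

  std::vector<int> dist(n), queue;
  queue.reserve(n);

  for (size_t ci = 0; ci < comps.size(); ++ci) {
    const std::vector<int> &mem = comps[ci];
    int s = mem.size();
    if (s < 2) continue;

    // local all-pairs link counts (and path counts when needed)
    std::vector<int> loc(n, -1);
    for (int i = 0; i < s; ++i) loc[mem[i]] = i;
    std::vector<int> D((size_t)s * s);
    std::vector<uint64_t> Sig;
    std::vector<uint64_t> sigv;
    if (importance && s >= 3) {
      Sig.resize((size_t)s * s);
      sigv.resize(n);
    }
    for (int i = 0; i < s; ++i) {
      bfs(mem[i], -1, adj, dist, queue, Sig.empty() ? 0 : &sigv);
      int *row = &D[(size_t)i * s];
      for (int j = 0; j < s; ++j) row[j] = dist[mem[j]];
      if (!Sig.empty()) {
        uint64_t *srow = &Sig[(size_t)i * s];
        for (int j = 0; j < s; ++j) srow[j] = sigv[mem[j]];
      }
    }

    double S = 0.0;                 // sum over unordered pairs i<j
    std::vector<double> rowterm(s, 0.0);
    for (int i = 0; i < s; ++i) {
      double ai = areas[mem[i]];
      const int *row = &D[(size_t)i * s];
      for (int j = i + 1; j < s; ++j) {
        double w = ai * areas[mem[j]] / (1.0 + row[j]);
        S += w;
        rowterm[i] += w;
        rowterm[j] += w;
      }
    }
    iic_num += 2.0 * S;

    if (!importance) continue;

    std::vector<int> affected;
    affected.reserve(s);
    for (int k = 0; k < s; ++k) {
      int gk = mem[k];
      flux[gk] = 2.0 * rowterm[k];
      if (adj[gk].size() < 2 || s < 3) continue;

      // nodes with some pair losing *all* its shortest paths through k
      affected.clear();
      const int *rowk = &D[(size_t)k * s];
      const uint64_t *srowk = &Sig[(size_t)k * s];
      for (int i = 0; i < s; ++i) {
        if (i == k) continue;
        const int *rowi = &D[(size_t)i * s];
        const uint64_t *srowi = &Sig[(size_t)i * s];
        int dik = rowi[k];
        uint64_t sik = srowi[k];
        for (int j = 0; j < s; ++j) {
          if (j == k || j == i) continue;
          if (allPathsThrough(dik, rowk[j], rowi[j], sik, srowk[j],
                              srowi[j])) {
            affected.push_back(i);
            break;
          }
        }
      }
      if (affected.size() < 2) continue;

      // re-run BFS without k from each affected node; only pairs with both
      // endpoints affected can have changed link counts
      double diff = 0.0;
      for (size_t t = 0; t + 1 < affected.size(); ++t) {
        int i = affected[t];
        bfs(mem[i], gk, adj, dist, queue);
        double ai = areas[mem[i]];
        const int *rowi = &D[(size_t)i * s];
        for (size_t t2 = t + 1; t2 < affected.size(); ++t2) {
          int j = affected[t2];
          int dnew = dist[mem[j]];
          int dold = rowi[j];
          if (dnew == dold) continue;
          double aij = ai * areas[mem[j]];
          double term = aij / (1.0 + dold);
          if (dnew >= 0) term -= aij / (1.0 + dnew);
          diff += term;
        }
      }
      conn[gk] = 2.0 * diff;
    }
  }

  return List::create(_["membership"] = membership,
                      _["iic_num"] = iic_num,
                      _["intra"] = intra,
                      _["flux"] = flux,
                      _["connector"] = conn);
}

// All-pairs link counts, sparse: one row per reachable unordered pair
// (i < j, 1-based) with its minimum link count. Pairs in different
// components are absent (unreachable).
// [[Rcpp::export]]
List cpp_all_pairs_nl(int n, IntegerMatrix edges) {
  std::vector<std::vector<int> > adj(n);
  for (int e = 0; e < edges.nrow(); ++e) {
    int u = edges(e, 0) - 1, v = edges(e, 1) - 1;
    if (u < 0 || u >= n || v < 0 || v >= n)
      stop("edge references unknown node");
    adj[u].push_back(v);
    adj[v].push_back(u);
  }
  std::vector<int> dist(n), queue;
  std::vector<int> from, to, nl;
  for (int i = 0; i < n; ++i) {
    bfs(i, -1, adj, dist, queue);
    for (int j = i + 1; j < n; ++j) {
      if (dist[j] >= 0) {
        from.push_back(i + 1);
        to.push_back(j + 1);
        nl.push_back(dist[j]);
      }
    }
  }
  return List::create(_["from"] = wrap(from), _["to"] = wrap(to),
                      _["nl"] = wrap(nl));
}
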