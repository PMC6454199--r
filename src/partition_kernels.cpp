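// Hot kernels of the multilevel hypergraph partitioner: connectivity-1 cut
// evaluation, agglomerative inner-product matching, Fiduccia-Mattheyses
// refinement passes with best-prefix rollback, and greedy load rebalancing.
// Hypergraphs arrive in CSR form: eptr (m+1 offsets, 0-based) and pins
// (0-based vertex ids); vertex incidence as veptr/vedges. Assignments are
// 0-based part ids. All routines are deterministic given their inputs.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Sum over hyperedges of (number of distinct parts touched - 1).
// [[Rcpp::export]]
double cut_connectivity_cpp(IntegerVector eptr, IntegerVector pins,
                            IntegerVector part, int P) {
  const int m = eptr.size() - 1;
  std::vector<int> stamp(P, -1);
  double cut = 0.0;
  for (int e = 0; e < m; ++e) {
    int distinct = 0;
    for (int k = eptr[e]; k < eptr[e + 1]; ++k) {
      int p = part[pins[k]];
      if (stamp[p] != e) { stamp[p] = e; ++distinct; }
    }
    if (distinct > 0) cut += distinct - 1;
  }
  return cut;
}

// Per-edge counts of members per part, flattened m x P (row-major by edge).
static std::vector<int> edge_part_counts(const IntegerVector& eptr,
                                         const IntegerVector& pins,
                                         const IntegerVector& part, int P) {
  const int m = eptr.size() - 1;
  std::vector<int> cnt((size_t)m * P, 0);
  for (int e = 0; e < m; ++e)
    for (int k = eptr[e]; k < eptr[e + 1]; ++k)
      ++cnt[(size_t)e * P + part[pins[k]]];
  return cnt;
}

// Greedy agglomerative inner-product matching. Vertices are visited in the
// supplied order; an unmatched vertex v accumulates, over each incident
// hyperedge e with |e| >= 2, a score 1/(|e|-1) for every other unmatched
// member u, and is merged with the best-scoring u whose combined weight
// stays within max_wt. Ties break to the smaller combined weight, then the
// lower vertex id. Returns 0-based group ids (one group per merged pair or
// unmatched singleton) and the number of score updates performed.
// [[Rcpp::export]]
List ip_match_cpp(IntegerVector eptr, IntegerVector pins,
                  IntegerVector veptr, IntegerVector vedges,
                  NumericVector vwt, IntegerVector order, double max_wt) {
  const int n = veptr.size() - 1;
  std::vector<int> mate(n, -1);
  std::vector<double> score(n, 0.0);
  std::vector<int> touched;
  touched.reserve(256);
  double ops = 0.0;
  for (int oi = 0; oi < order.size(); ++oi) {
    int v = order[oi];
    if (mate[v] != -1) continue;
    touched.clear();
    for (int k = veptr[v]; k < veptr[v + 1]; ++k) {
      int e = vedges[k];
      int sz = eptr[e + 1] - eptr[e];
      if (sz < 2) continue;
      double s = 1.0 / (sz - 1);
      for (int t = eptr[e]; t < eptr[e + 1]; ++t) {
        int u = pins[t];
        if (u == v || mate[u] != -1) continue;
        if (score[u] == 0.0) touched.push_back(u);
        score[u] += s;
        ops += 1.0;
      }
    }
    int best = -1;
    double best_score = 0.0, best_wt = 0.0;
    for (size_t t = 0; t < touched.size(); ++t) {
      int u = touched[t];
      double cw = vwt[v] + vwt[u];
      if (cw > max_wt) continue;
      bool better = score[u] > best_score ||
        (score[u] == best_score &&
         (best == -1 || cw < best_wt || (cw == best_wt && u < best)));
      if (better) { best = u; best_score = score[u]; best_wt = cw; }
    }
    for (size_t t = 0; t < touched.size(); ++t) score[touched[t]] = 0.0;
    if (best != -1) { mate[v] = best; mate[best] = v; }
  }
  IntegerVector group(n);
  int ng = 0;
  std::vector<int> gid(n, -1);
  for (int v = 0; v < n; ++v) {
    if (gid[v] != -1) { group[v] = gid[v]; continue; }
    gid[v] = ng;
    if (mate[v] != -1 && gid[mate[v]] == -1) gid[mate[v]] = ng;
    group[v] = ng;
    ++ng;
  }
  return List::create(_["group"] = group, _["n_groups"] = ng,
                      _["ops"] = ops);
}

// One Fiduccia-Mattheyses pass. Visits boundary vertices in the supplied
// order; each is tentatively moved to the admissible part with maximal
// connectivity-1 gain (gain of moving v from a to b equals the number of
// incident edges containing b minus the number of incident edges in which
// v is not the sole member of a). A move is admissible if the target load
// stays within max_load and the source part keeps at least one vertex.
// After the sweep the pass rolls back to the prefix of moves with maximal
// cumulative gain (possibly the empty prefix), so the returned cut is
// never worse than the input cut.
// [[Rcpp::export]]
List fm_pass_cpp(IntegerVector eptr, IntegerVector pins,
                 IntegerVector veptr, IntegerVector vedges,
                 NumericVector vwt, IntegerVector part_in, int P,
                 double max_load, IntegerVector order) {
  const int n = veptr.size() - 1;
  IntegerVector part = clone(part_in);
  std::vector<int> cnt = edge_part_counts(eptr, pins, part, P);
  std::vector<double> load(P, 0.0);
  std::vector<int> psize(P, 0);
  for (int v = 0; v < n; ++v) {
    load[part[v]] += vwt[v];
    ++psize[part[v]];
  }
  // Boundary = member of any edge spanning > 1 part, frozen at pass start.
  std::vector<bool> boundary(n, false);
  {
    const int m = eptr.size() - 1;
    for (int e = 0; e < m; ++e) {
      int parts_here = 0;
      for (int p = 0; p < P && parts_here < 2; ++p)
        if (cnt[(size_t)e * P + p] > 0) ++parts_here;
      if (parts_here > 1)
        for (int k = eptr[e]; k < eptr[e + 1]; ++k)
          boundary[pins[k]] = true;
    }
  }
  std::vector<double> acc(P, 0.0);       // per-candidate edge-presence count
  std::vector<int> stampP(P, -1);        // per-edge dedup of candidate parts
  std::vector<int> touched; touched.reserve(64);
  std::vector<int> mv_v, mv_from, mv_to;
  std::vector<double> cumgain;
  double gain_run = 0.0;
  int visit_tag = 0;

  for (int oi = 0; oi < order.size(); ++oi) {
    int v = order[oi];
    if (!boundary[v]) continue;
    int a = part[v];
    if (psize[a] <= 1) continue;
    // Candidate parts = parts present in v's incident edges. The gain of
    // moving v from a to b is (#incident edges containing b) - c_v, where
    // c_v = #incident edges in which v is not the sole member of a.
    touched.clear();
    int c_v = 0;
    for (int k = veptr[v]; k < veptr[v + 1]; ++k) {
      int e = vedges[k];
      if (cnt[(size_t)e * P + a] > 1) ++c_v;
      ++visit_tag;  // new dedup scope for this edge
      for (int t = eptr[e]; t < eptr[e + 1]; ++t) {
        int q = part[pins[t]];
        if (q == a || stampP[q] == visit_tag) continue;
        stampP[q] = visit_tag;
        if (acc[q] == 0.0) touched.push_back(q);
        acc[q] += 1.0;
      }
    }
    int best = -1; double best_gain = 0.0; double best_load = 0.0;
    for (size_t t = 0; t < touched.size(); ++t) {
      int b = touched[t];
      double g = acc[b] - c_v;
      if (load[b] + vwt[v] > max_load) continue;
      bool better = (best == -1) || g > best_gain ||
        (g == best_gain && (load[b] < best_load ||
                            (load[b] == best_load && b < best)));
      if (better) { best = b; best_gain = g; best_load = load[b]; }
    }
    for (size_t t = 0; t < touched.size(); ++t) acc[touched[t]] = 0.0;
    if (best == -1) continue;
    // Apply the tentative move and lock v (boundary flag cleared).
    int b = best;
    for (int k = veptr[v]; k < veptr[v + 1]; ++k) {
      int e = vedges[k];
      --cnt[(size_t)e * P + a];
      ++cnt[(size_t)e * P + b];
    }
    load[a] -= vwt[v]; load[b] += vwt[v];
    --psize[a]; ++psize[b];
    part[v] = b;
    boundary[v] = false;
    gain_run += best_gain;
    mv_v.push_back(v); mv_from.push_back(a); mv_to.push_back(b);
    cumgain.push_back(gain_run);
  }
  // Best prefix (empty allowed).
  int best_k = 0; double best_cum = 0.0;
  for (size_t k = 0; k < cumgain.size(); ++k)
    if (cumgain[k] > best_cum) { best_cum = cumgain[k]; best_k = (int)k + 1; }
  for (int k = (int)mv_v.size() - 1; k >= best_k; --k)
    part[mv_v[k]] = mv_from[k];
  return List::create(_["part"] = part, _["gain"] = best_cum,
                      _["moves"] = best_k,
                      _["moves_tried"] = (int)mv_v.size());
}

// Greedy rebalancing toward max part load <= max_load. Repeatedly moves,
// from the heaviest part to the lightest, the vertex with the best
// connectivity-1 gain among those whose weight does not exceed the load
// gap (guaranteeing monotone progress); if none qualifies the lightest
// vertex of the heaviest part is moved. Stops when balanced or after
// max_iter moves.
// [[Rcpp::export]]
List rebalance_cpp(IntegerVector eptr, IntegerVector pins,
                   IntegerVector veptr, IntegerVector vedges,
                   NumericVector vwt, IntegerVector part_in, int P,
                   double max_load, int max_iter) {
  const int n = veptr.size() - 1;
  IntegerVector part = clone(part_in);
  std::vector<int> cnt = edge_part_counts(eptr, pins, part, P);
  std::vector<double> load(P, 0.0);
  std::vector<int> psize(P, 0);
  for (int v = 0; v < n; ++v) { load[part[v]] += vwt[v]; ++psize[part[v]]; }
  int moves = 0;
  std::vector<int> seen; seen.reserve(64);
  for (int iter = 0; iter < max_iter; ++iter) {
    int a = 0, b = 0;
    for (int p = 1; p < P; ++p) {
      if (load[p] > load[a]) a = p;
      if (load[p] < load[b]) b = p;
    }
    if (load[a] <= max_load || a == b) break;
    double gap = load[a] - load[b];
    int best = -1, fallback = -1;
    double best_gain = 0.0, fallback_wt = 0.0;
    for (int v = 0; v < n; ++v) {
      if (part[v] != a) continue;
      if (fallback == -1 || vwt[v] < fallback_wt) {
        fallback = v; fallback_wt = vwt[v];
      }
      if (vwt[v] > gap) continue;
      // gain of v: a -> b
      int c_v = 0; double present_b = 0.0;
      for (int k = veptr[v]; k < veptr[v + 1]; ++k) {
        int e = vedges[k];
        if (cnt[(size_t)e * P + a] > 1) ++c_v;
        if (cnt[(size_t)e * P + b] > 0) present_b += 1.0;
      }
      double g = present_b - c_v;
      bool better = (best == -1) || g > best_gain ||
        (g == best_gain && vwt[v] > vwt[best]) ;
      if (better) { best = v; best_gain = g; }
    }
    int v = (best != -1) ? best : fallback;
    if (v == -1) break;
    for (int k = veptr[v]; k < veptr[v + 1]; ++k) {
      int e = vedges[k];
      --cnt[(size_t)e * P + part[v]];
      ++cnt[(size_t)e * P + b];
    }
    load[a] -= vwt[v]; load[b] += vwt[v];
    --psize[a]; ++psize[b];
    part[v] = b;
    ++moves;
  }
  return List::create(_["part"] = part, _["moves"] = moves);
}
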