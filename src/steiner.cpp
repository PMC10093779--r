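// Exact single-node Steiner refinement for interval-event parsimony, one
// chromosome and one haplotype at a time: choose the integer vector x
// minimizing events(parent -> x) + sum_k events(x -> child_k), where
// events() is the segment-increment count, by a positional DP over the
// value of x at each bin. Feasibility encodes LOH irreversibility:
// x may not regain a parent 0, and a child may not regain an x 0.

#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector steiner_dp_cpp(IntegerVector pv, IntegerMatrix kids) {
  const int nb = pv.size(), nk = kids.ncol();
  if (kids.nrow() != nb) stop("dimension mismatch");
  int M = 0;
  for (int i = 0; i < nb; ++i) {
    if (pv[i] > M) M = pv[i];
    for (int k = 0; k < nk; ++k) if (kids(i, k) > M) M = kids(i, k);
  }
  M += 1;
  const int S = M + 1;          // candidate values 0..M
  const int nd = 2 + 2 * nk;    // delta components per edge direction
  const int INF = INT_MAX / 4;

  std::vector<int> cost(S, INF), ncost(S);
  std::vector<int> deltas((size_t)S * nd), ndeltas((size_t)S * nd);
  std::vector<int> back((size_t)nb * S, -1);

  auto fill_deltas = [&](int i, std::vector<int>& D, std::vector<bool>& okv) {
    for (int x = 0; x <= M; ++x) {
      bool ok = !(pv[i] == 0 && x > 0);
      if (x == 0) for (int k = 0; k < nk; ++k) if (kids(i, k) > 0) ok = false;
      okv[x] = ok;
      int* d = &D[(size_t)x * nd];
      d[0] = std::max(x - pv[i], 0);
      d[1] = std::max(pv[i] - x, 0);
      for (int k = 0; k < nk; ++k) {
        d[2 + 2 * k] = std::max(kids(i, k) - x, 0);
        d[3 + 2 * k] = std::max(x - kids(i, k), 0);
      }
    }
  };

  std::vector<bool> ok0(S), ok1(S);
  fill_deltas(0, deltas, ok0);
  for (int x = 0; x <= M; ++x) {
    if (!ok0[x]) { cost[x] = INF; continue; }
    int s = 0; const int* d = &deltas[(size_t)x * nd];
    for (int t = 0; t < nd; ++t) s += d[t];
    cost[x] = s;
  }
  for (int i = 1; i < nb; ++i) {
    fill_deltas(i, ndeltas, ok1);
    for (int x = 0; x <= M; ++x) {
      ncost[x] = INF;
      if (!ok1[x]) continue;
      const int* dx = &ndeltas[(size_t)x * nd];
      int best = INF, barg = -1;
      for (int xp = 0; xp <= M; ++xp) {
        if (cost[xp] >= INF) continue;
        const int* dp = &deltas[(size_t)xp * nd];
        int v = cost[xp];
        for (int t = 0; t < nd; ++t) {
          int inc = dx[t] - dp[t];
          if (inc > 0) v += inc;
        }
        if (v < best) { best = v; barg = xp; }
      }
      ncost[x] = best;
      back[(size_t)i * S + x] = barg;
    }
    cost.swap(ncost);
    deltas.swap(ndeltas);
  }
  int bestx = -1, bestc = INF;
  for (int x = 0; x <= M; ++x) if (cost[x] < bestc) { bestc = cost[x]; bestx = x; }
  if (bestx < 0) return IntegerVector(0);
  IntegerVector out(nb);
  out[nb - 1] = bestx;
  for (int i = nb - 1; i > 0; --i)
    out[i - 1] = back[(size_t)i * S + out[i]];
  return out;
}
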