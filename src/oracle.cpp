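// Exhaustive breadth-first reference for the interval-event distance.
//
// States are per-bin copy numbers of a single haplotype on one chromosome.
// Moves are +/-1 over any contiguous bin interval, with loss of
// heterozygosity irreversible (a gain may not touch a bin at 0) and no
// negative copy numbers. These BFS routines enumerate the true shortest
// event paths and exist purely to validate the closed-form distance; the
// intermediate-state cap is kept above the profile maxima so the oracle
// does not assume the no-overshoot property it is used to check.

#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

static inline uint64_t encode(const std::vector<int>& s) {
  uint64_t k = 0;
  for (size_t i = 0; i < s.size(); ++i) k = (k << 4) | (uint64_t)s[i];
  return k;
}

// All-pairs shortest event distances between states in {0..maxcn}^nbins,
// allowing intermediate states up to `cap` per bin. Returns a square
// matrix indexed by base-(maxcn+1) state code + 1; -1 marks unreachable
// targets (LOH irreversibility).
// [[Rcpp::export]]
IntegerMatrix bfs_all_event_distances(int nbins, int maxcn, int cap) {
  const int base = maxcn + 1, cbase = cap + 1;
  int nsmall = 1, nbig = 1;
  for (int i = 0; i < nbins; ++i) { nsmall *= base; nbig *= cbase; }

  // decode helpers over the capped space
  std::vector<std::vector<int>> states(nbig, std::vector<int>(nbins));
  for (int code = 0; code < nbig; ++code) {
    int c = code;
    for (int i = nbins - 1; i >= 0; --i) { states[code][i] = c % cbase; c /= cbase; }
  }
  // adjacency in the capped space
  std::vector<std::vector<int>> adj(nbig);
  for (int code = 0; code < nbig; ++code) {
    const std::vector<int>& s = states[code];
    for (int i = 0; i < nbins; ++i) {
      for (int j = i; j < nbins; ++j) {
        bool up = true, down = true;
        for (int b = i; b <= j; ++b) {
          if (s[b] == 0 || s[b] == cap) up = false;   // no regain, capped
          if (s[b] == 0) down = false;                // no negative
        }
        int stride = 1, off = 0;
        // compute neighbour codes
        if (up || down) {
          int delta_code = 0;
          int mult = 1;
          for (int b = nbins - 1; b >= 0; --b) {
            if (b >= i && b <= j) delta_code += mult;
            mult *= cbase;
          }
          if (up) adj[code].push_back(code + delta_code);
          if (down) adj[code].push_back(code - delta_code);
        }
        (void)stride; (void)off;
      }
    }
  }
  // map small-space index -> capped-space code
  std::vector<int> small2big(nsmall);
  for (int code = 0; code < nsmall; ++code) {
    int c = code, big = 0, mult = 1;
    std::vector<int> digs(nbins);
    for (int i = nbins - 1; i >= 0; --i) { digs[i] = c % base; c /= base; }
    for (int i = nbins - 1; i >= 0; --i) { big += digs[i] * mult; mult *= cbase; }
    small2big[code] = big;
  }
  std::vector<int> big2small(nbig, -1);
  for (int code = 0; code < nsmall; ++code) big2small[small2big[code]] = code;

  IntegerMatrix D(nsmall, nsmall);
  std::fill(D.begin(), D.end(), -1);
  std::vector<int> dist(nbig);
  for (int src = 0; src < nsmall; ++src) {
    std::fill(dist.begin(), dist.end(), -1);
    std::queue<int> q;
    int s0 = small2big[src];
    dist[s0] = 0; q.push(s0);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int v : adj[u]) if (dist[v] < 0) { dist[v] = dist[u] + 1; q.push(v); }
    }
    for (int big = 0; big < nbig; ++big)
      if (big2small[big] >= 0 && dist[big] >= 0)
        D(src, big2small[big]) = dist[big];
  }
  return D;
}

// Shortest event path between one (parent, child) pair by breadth-first
// search with hashing, capped per bin at `cap` and at `max_depth` moves.
// Returns the distance, or -1 if the child is not reachable within
// max_depth.
// [[Rcpp::export]]
int bfs_pair_distance(IntegerVector parent, IntegerVector child,
                      int cap, int max_depth) {
  int nb = parent.size();
  if (child.size() != nb) stop("length mismatch");
  std::vector<int> p(parent.begin(), parent.end());
  std::vector<int> c(child.begin(), child.end());
  uint64_t target = encode(c);
  std::unordered_map<uint64_t, int> seen;
  std::queue<std::pair<uint64_t, int>> q;
  uint64_t s0 = encode(p);
  if (s0 == target) return 0;
  seen[s0] = 0; q.push({s0, 0});
  std::vector<int> s(nb);
  while (!q.empty()) {
    auto cur = q.front(); q.pop();
    if (cur.second >= max_depth) continue;
    uint64_t k = cur.first;
    for (int i = nb - 1; i >= 0; --i) { s[i] = (int)(k & 0xF); k >>= 4; }
    for (int i = 0; i < nb; ++i) {
      for (int j = i; j < nb; ++j) {
        bool up = true, down = true;
        for (int b = i; b <= j; ++b) {
          if (s[b] == 0 || s[b] == cap) up = false;
          if (s[b] == 0) down = false;
        }
        for (int dir = 0; dir < 2; ++dir) {
          if (dir == 0 && !up) continue;
          if (dir == 1 && !down) continue;
          std::vector<int> t(s);
          for (int b = i; b <= j; ++b) t[b] += (dir == 0 ? 1 : -1);
          uint64_t kt = encode(t);
          if (kt == target) return cur.second + 1;
          if (seen.find(kt) == seen.end()) {
            seen[kt] = cur.second + 1;
            q.push({kt, cur.second + 1});
          }
        }
      }
    }
  }
  return -1;
}
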